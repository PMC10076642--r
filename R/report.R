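## Assembly of the standard report outputs: the case-characteristics table,
## the per-PT disproportionality tables, the case-series summaries, and
## the simulation recovery summary.  These functions are the package's
## command surface; inst/scripts/il17pv.R wraps them for shell use.

.year_bands <- c("2015-2016", "2017-2018", "2019-2020", "2021-2022")

year_band <- function(quarter) {
  y <- quarter_year(quarter)
  cut(y, breaks = c(2014, 2016, 2018, 2020, 2022),
      labels = .year_bands)
}

block_rows <- function(block, vals, levels, total, add_unknown = TRUE) {
  if (add_unknown) {
    vals[is.na(vals)] <- "Unknown"
    levels <- c(levels, "Unknown")
  }
  counts <- table(factor(vals, levels = levels))
  data.table(block = block, category = names(counts),
             count = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) / total, 1))
}

#' Characteristics table of primary-suspect cases
#'
#' Tabulates the deduplicated reports carrying any dictionary active as
#' primary suspect: age bands, sex, reporting country (US / other),
#' reporting-year bands, suspect drug, outcome codes, reported
#' indication, bowel-disease classification from the reaction PTs, and
#' symptom-onset bins.  Reports with several outcome codes count once per
#' code; reports without one count as Unknown.  A report with at least
#' one IBD-group PT classifies as IBD (with UC / CD / unclassified
#' sub-rows by PT), otherwise as colitis.
#'
#' @param reports deduplicated [faers_reports] collection.
#' @param dictionary a [drug_dictionary()].
#' @param groups event groups, default [il17_event_groups()] (the first
#'   group is treated as the IBD-type group, the second as colitis-type).
#' @return data.table with columns `block`, `category`, `count`,
#'   `percent` (percent of all selected cases, half-up to 1 decimal).
#' @export
characteristics_table <- function(reports, dictionary,
                                  groups = il17_event_groups()) {
  stopifnot(inherits(reports, "faers_reports"))
  per_drug <- lapply(names(dictionary), function(act) {
    exposed_ids(reports, act, dictionary)
  })
  names(per_drug) <- names(dictionary)
  ids <- unique(unlist(per_drug))
  sel <- subset_reports(reports, ids)
  n <- nrow(sel$demo)
  if (n == 0L) stop("no primary-suspect cases for the given dictionary")

  rows <- list()
  rows$n <- data.table(block = "N", category = "Total", count = n,
                       percent = 100)
  rows$age <- block_rows("Age (years)", as.character(bin_age(sel$demo$age)),
                         levels(bin_age(numeric())), n)
  sex <- tolower(sel$demo$sex)
  sex[!sex %in% c("female", "male")] <- NA_character_
  rows$sex <- block_rows("Gender", sex, c("female", "male"), n)
  country <- toupper(sel$demo$country)
  country[country == "US"] <- "United States"
  country[!is.na(country) & country != "United States"] <- "Other countries"
  rows$country <- block_rows("Reporting country", country,
                             c("United States", "Other countries"), n)
  rows$year <- block_rows("Reporting year",
                          as.character(year_band(sel$demo$quarter)),
                          .year_bands, n, add_unknown = FALSE)
  drug_of <- vapply(sel$demo$primaryid, function(id) {
    hit <- names(per_drug)[vapply(per_drug, function(v) id %in% v, logical(1))]
    hit[1]
  }, character(1))
  rows$drug <- block_rows("Primary suspect drug", drug_of,
                          names(dictionary), n, add_unknown = FALSE)
  outc_levels <- c(DE = "Death", LT = "Life-threatening",
                   HO = "Hospitalization-initial or prolonged",
                   DS = "Disability", CA = "Congenital anomaly",
                   RI = "Required intervention",
                   OT = "Other medical significant condition")
  oc <- sel$outcomes[primaryid %in% sel$demo$primaryid]
  oc_vals <- c(unname(outc_levels[oc$outc_cod]),
               rep(NA_character_,
                   sum(!(sel$demo$primaryid %in% oc$primaryid))))
  rows$outcome <- block_rows("Outcome", oc_vals, unname(outc_levels), n)
  ps <- sel$drugs[role_cod == "PS" & !is.na(indi_pt),
                  .(indi_pt = indi_pt[1]), by = primaryid]
  indi_vals <- ps$indi_pt[match(sel$demo$primaryid, ps$primaryid)]
  indi_levels <- c("Ankylosing spondylitis", "Psoriasis",
                   "Psoriatic arthropathy")
  indi_vals[!is.na(indi_vals) & !indi_vals %in% indi_levels] <- "Others"
  rows$indication <- block_rows("Indication", indi_vals,
                                c(indi_levels, "Others"), n)

  pairs <- event_pairs(sel)
  ibd_pts <- norm_pt(groups[[1]]$pts)
  has_ibd <- unique(pairs[pt_norm %in% ibd_pts, primaryid])
  per_pt_ids <- lapply(groups[[1]]$pts, function(p) {
    intersect(unique(pairs[pt_norm == norm_pt(p), primaryid]), has_ibd)
  })
  bowel <- data.table(
    block = "Bowel disease",
    category = c(paste("All", groups[[1]]$name), groups[[1]]$pts,
                 paste("All", groups[[2]]$name)),
    count = c(length(has_ibd), lengths(per_pt_ids),
              length(setdiff(
                unique(pairs[pt_norm %in% norm_pt(groups[[2]]$pts),
                             primaryid]),
                has_ibd)))
  )
  bowel[, percent := round_half_up(100 * count / n, 1)]
  rows$bowel <- bowel
  if ("onset_months" %in% names(sel$demo)) {
    rows$onset <- block_rows("Onset time of symptoms (months)",
                             as.character(bin_onset(sel$demo$onset_months)),
                             levels(bin_onset(numeric())), n)
  }
  rbindlist(rows)
}

#' Write the disproportionality report
#'
#' Runs the screening and analysis end to end on a report collection (or
#' on FAERS-style files) and writes three outputs to `out_dir`:
#' `characteristics.csv` ([characteristics_table()]),
#' `ror_table.csv` ([run_disproportionality()]) and
#' `screening_log.txt` (counts in screening order: raw reports, unique
#' cases, primary-suspect cases per drug).
#'
#' @param reports a [faers_reports] collection, *not* deduplicated (the
#'   screening log reports the dedup step), or `NULL` when `input_dir`
#'   is given.
#' @param input_dir directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `INDI.txt`; read when `reports` is `NULL`.
#' @param dictionary a [drug_dictionary()]; default [il17_dictionary()].
#' @param groups event groups; default [il17_event_groups()].
#' @param out_dir output directory, created if needed.
#' @param window quarter window passed to [read_quarter_files()].
#' @return invisibly, list with `characteristics` and `ror_table`.
#' @export
report_dispro <- function(reports = NULL, input_dir = NULL,
                          dictionary = il17_dictionary(),
                          groups = il17_event_groups(),
                          out_dir, window = c("2015Q1", "2022Q3")) {
  if (is.null(reports)) {
    if (is.null(input_dir)) stop("provide either 'reports' or 'input_dir'")
    need <- file.path(input_dir,
                      c("DEMO.txt", "DRUG.txt", "REAC.txt", "OUTC.txt",
                        "INDI.txt"))
    absent <- need[!file.exists(need)]
    if (length(absent)) {
      stop("missing input file(s): ", paste(absent, collapse = ", "))
    }
    reports <- read_quarter_files(need[1], need[2], need[3], need[4],
                                  need[5], window = window)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_raw <- n_reports(reports)
  dedup <- deduplicate(reports)
  log_lines <- c(
    sprintf("reports read:            %d", n_raw),
    sprintf("unique cases:            %d", n_reports(dedup))
  )
  for (act in names(dictionary)) {
    log_lines <- c(log_lines,
                   sprintf("primary suspect %-12s %d", paste0(act, ":"),
                           length(exposed_ids(dedup, act, dictionary))))
  }
  chars <- characteristics_table(dedup, dictionary, groups)
  ror_tab <- run_disproportionality(dedup, dictionary, groups)
  fwrite(chars, file.path(out_dir, "characteristics.csv"))
  fwrite(ror_tab, file.path(out_dir, "ror_table.csv"), na = "NA")
  writeLines(log_lines, file.path(out_dir, "screening_log.txt"))
  invisible(list(characteristics = chars, ror_table = ror_tab))
}

#' Write the case-series descriptive report
#'
#' @param case_path CSV path of the literature-case table (validated on
#'   load, see [read_literature_cases()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, list with `summaries` (the [summarize_cases()]
#'   list) and `medians`.
#' @export
report_describe <- function(case_path, out_dir) {
  cases <- read_literature_cases(case_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sums <- summarize_cases(cases)
  long <- rbindlist(lapply(names(sums), function(v) {
    cbind(data.table(variable = v), sums[[v]])
  }))
  fwrite(long, file.path(out_dir, "case_summaries.csv"))
  med <- data.table(
    quantity = c("median_onset_months", "onset_min_months",
                 "onset_max_months", "median_age_years"),
    value = c(median_onset(cases), onset_range(cases),
              median(cases$age_years, na.rm = TRUE))
  )
  fwrite(med, file.path(out_dir, "case_medians.csv"))
  txt <- c("Case-series descriptive summary",
           sprintf("cases: %d", nrow(cases)), "")
  for (v in names(sums)) {
    tab <- sums[[v]][count > 0L]
    txt <- c(txt, sprintf("%s (n = %d)", v, sums[[v]]$denominator[1]),
             sprintf("  %-28s %4d (%.1f)", tab$category, tab$count,
                     tab$percent), "")
  }
  writeLines(txt, file.path(out_dir, "case_report.txt"))
  invisible(list(summaries = sums, medians = med))
}

#' Parameter-recovery runs through the full pipeline
#'
#' Generates `n_replicates` synthetic collections with one drug-event
#' association planted at `theta`, pushes each through the complete
#' pipeline (write FAERS-style files, re-read, deduplicate, contingency,
#' ROR), and returns per-replicate estimates.  One event PT and the
#' filler term are used, so the planted odds ratio is exactly the ROR
#' estimand.
#'
#' @param theta planted odds ratio.
#' @param n_replicates number of independent replicates.
#' @param n_reports reports per replicate.
#' @param marginal exposed-drug marginal probability.
#' @param p0 background event probability.
#' @param seed base seed; replicate i uses `seed + i`.
#' @param via_files write and re-read FAERS-style files (`TRUE`, the full
#'   pipeline) or analyze in memory (`FALSE`, faster for property
#'   studies).
#' @return data.table with one row per replicate: `replicate`, `theta`,
#'   `ror`, `ci_low`, `ci_high`, `n_cases`, `covered` (CI contains
#'   `theta`), `signal`.
#' @export
recovery_run <- function(theta, n_replicates = 100, n_reports = 50000,
                         marginal = 0.2, p0 = 0.01, seed = 1,
                         via_files = TRUE) {
  active <- "secukinumab"
  pt <- "Inflammatory bowel disease"
  dict <- drug_dictionary(setNames(list(c(active, "cosentyx")), active))
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- synth_config(
      n_reports = n_reports,
      drugs = data.frame(active = active, brand = "Cosentyx",
                         marginal = marginal),
      events = data.frame(pt = pt, prob = p0),
      planted = data.frame(active = active, pt = pt, odds_ratio = theta),
      seed = seed + i
    )
    if (via_files) {
      dir <- tempfile("synth")
      gen <- generate_reports(cfg, dir = dir)
      paths <- attr(gen, "paths")
      rep_in <- suppressMessages(read_quarter_files(
        paths["demo"], paths["drug"], paths["reac"], paths["outc"],
        paths["indi"]))
      unlink(dir, recursive = TRUE)
    } else {
      rep_in <- generate_reports(cfg)
    }
    dedup <- suppressMessages(deduplicate(rep_in))
    tab <- build_contingency(dedup, active, dict, pt)
    r <- compute_ror(tab)
    rows[[i]] <- data.table(
      replicate = i, theta = theta, ror = r$ror, ci_low = r$ci_low,
      ci_high = r$ci_high, n_cases = r$n_cases,
      covered = !is.na(r$ci_low) && r$ci_low <= theta & r$ci_high >= theta,
      signal = r$signal
    )
  }
  rbindlist(rows)
}

#' Write a simulation recovery report
#'
#' Runs [recovery_run()] for each planted odds ratio and writes
#' `recovery.csv` (per-replicate estimates) and `recovery_summary.csv`
#' (per-theta mean of log estimates, geometric-mean ROR, CI coverage and
#' signal rate) to `out_dir`.
#'
#' @param thetas numeric vector of planted odds ratios.
#' @param n_replicates replicates per theta.
#' @param out_dir output directory.
#' @param seed base seed.
#' @param ... further arguments passed to [recovery_run()].
#' @return invisibly, list with `replicates` and `summary`.
#' @export
report_simulate <- function(thetas, n_replicates = 100, out_dir, seed = 1,
                            ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- rbindlist(lapply(seq_along(thetas), function(j) {
    recovery_run(thetas[j], n_replicates = n_replicates,
                 seed = seed + (j - 1L) * n_replicates, ...)
  }))
  summ <- reps[, .(
    n_replicates = .N,
    mean_log_ror = mean(log(ror)),
    gm_ror = exp(mean(log(ror))),
    mc_se_log = stats::sd(log(ror)) / sqrt(.N),
    coverage = mean(covered),
    signal_rate = mean(signal)
  ), by = theta]
  fwrite(reps, file.path(out_dir, "recovery.csv"))
  fwrite(summ, file.path(out_dir, "recovery_summary.csv"))
  invisible(list(replicates = reps, summary = summ))
}
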
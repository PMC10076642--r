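## Disproportionality analysis: 2x2 contingency tables per drug x event
## set, reporting odds ratios with Woolf 95% confidence intervals, and the
## lower-bound signal rule.
##
## Counting convention (event level): every distinct reaction PT on a
## report contributes one event to the tally.  With a as the count of
## target-drug events falling in the event set, b the remaining
## target-drug events, c/d the same split among all other reports,
## ROR = (a*d)/(b*c).  Group totals therefore equal the sum of their
## per-PT counts, which is how the published per-PT tables add up; a
## report carrying two PTs of a group counts twice in the group total.

#' Define an adverse-event group
#'
#' @param name group label (e.g. `"IBD"`).
#' @param pts character vector of MedDRA preferred terms.  Matching is
#'   case-insensitive exact string equality after whitespace trimming;
#'   no MedDRA hierarchy traversal is performed.
#' @return object of class `event_group`.
#' @export
event_group <- function(name, pts) {
  pts <- as.character(pts)
  if (length(pts) == 0L) stop("event group '", name, "' has an empty PT set")
  structure(list(name = name, pts = pts), class = "event_group")
}

#' IL-17 inhibitor gastrointestinal event groups
#'
#' The two event sets analyzed for IL-17 inhibitors: `IBD` (Crohn's
#' disease, ulcerative colitis and undifferentiated inflammatory bowel
#' disease) and `colitis` (the colitis / proctitis / enteritis PTs).
#'
#' @return named list of two [event_group()] objects.
#' @export
il17_event_groups <- function() {
  list(
    IBD = event_group("IBD", c(
      "Crohn's disease",
      "Colitis ulcerative",
      "Inflammatory bowel disease"
    )),
    colitis = event_group("colitis", c(
      "Colitis",
      "Microscopic colitis",
      "Ischaemic colitis",
      "Proctitis",
      "Proctitis ulcerative",
      "Proctitis haemorrhagic",
      "Enteritis",
      "Enterocolitis",
      "Enterocolitis haemorrhagic",
      "Eosinophilic colitis",
      "Colitis erosive"
    ))
  )
}

#' Build the 2x2 contingency table for a drug and event set
#'
#' Exposure is "active substance present as primary suspect".  Counts are
#' event-level: each distinct PT on a report contributes one tally (see
#' the counting note in the package vignette).
#'
#' @param reports a deduplicated [faers_reports] collection (the full
#'   comparator database).
#' @param active active-substance label in `dictionary`.
#' @param dictionary a [drug_dictionary()].
#' @param pts character vector of target PTs (an [event_group()]'s `pts`,
#'   or a single PT).
#' @param role_filter drug roles defining exposure; default primary
#'   suspect.
#' @return object of class `contingency_table`: list with counts
#'   `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(reports, active, dictionary, pts,
                              role_filter = "PS") {
  if (inherits(pts, "event_group")) pts <- pts$pts
  if (length(pts) == 0L) stop("empty PT set")
  pairs <- event_pairs(reports)
  exp_ids <- exposed_ids(reports, active, dictionary, role_filter)
  tgt <- norm_pt(pts)
  exposed <- pairs$primaryid %in% exp_ids
  in_set <- pairs$pt_norm %in% tgt
  contingency_table(
    a = sum(exposed & in_set),
    b = sum(exposed & !in_set),
    c = sum(!exposed & in_set),
    d = sum(!exposed & !in_set)
  )
}

## one row per (report, distinct normalized PT)
event_pairs <- function(reports) {
  unique(reports$reactions[, .(primaryid, pt_norm = norm_pt(pt))])
}

#' @rdname build_contingency
#' @param a,b,c,d non-negative event counts: target drug with / without
#'   the target event, other drugs with / without it.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("contingency cells must be non-negative")
  structure(as.list(counts), class = "contingency_table")
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a*d)/(b*c)` with the log-scale (Woolf) interval
#' `exp(log(ROR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))`, z = 1.96 for a
#' two-sided 95% interval.  If any cell is zero the estimate and interval
#' are undefined and reported as `NA` (no continuity correction is
#' applied, matching the `NA` convention of published tables).
#'
#' @param table a [contingency_table()].
#' @param conf_level confidence level; 0.95 by default.
#' @return object of class `ror_result`: list with `ror`, `ci_low`,
#'   `ci_high`, `n_cases` (= a) and logical `signal` (see
#'   [flag_signal()]).
#' @examples
#' compute_ror(contingency_table(20, 80, 10, 90))
#' @export
compute_ror <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (any(c(a, b, cc, d) == 0)) {
    res <- list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_cases = a, signal = FALSE)
  } else {
    z <- qnorm(1 - (1 - conf_level) / 2)
    ror <- (a * d) / (b * cc)
    log_ror <- log(ror)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    res <- list(
      ror = ror,
      ci_low = exp(log_ror - z * se),
      ci_high = exp(log_ror + z * se),
      n_cases = a,
      signal = FALSE
    )
  }
  res <- structure(res, class = "ror_result")
  res$signal <- flag_signal(res)
  res
}

#' @export
print.ror_result <- function(x, ...) {
  if (is.na(x$ror)) {
    cat("ROR NA (zero cell), n =", x$n_cases, "\n")
  } else {
    cat(sprintf("ROR %.2f (95%% CI %.2f-%.2f), n = %d, signal: %s\n",
                x$ror, x$ci_low, x$ci_high, x$n_cases,
                if (x$signal) "yes" else "no"))
  }
  invisible(x)
}

#' Signal rule
#'
#' A drug-event pair is flagged as a safety signal when the lower bound
#' of the 95% CI of the ROR exceeds 1 and at least three cases were
#' reported.  An undefined interval never flags.
#'
#' @param result a `ror_result` from [compute_ror()], or anything with
#'   `ci_low` and `n_cases` components.
#' @param min_cases minimum case count; 3 by default.
#' @return logical scalar.
#' @export
flag_signal <- function(result, min_cases = 3L) {
  isTRUE(result$ci_low > 1) && result$n_cases >= min_cases
}

#' Proportion of a drug's reports accounted for by an event tally
#'
#' @param event_count event tally (numerator).
#' @param drug_total the drug's total report count in the database.
#' @param mode rounding mode for the displayed percentage: `"halfup"`
#'   (default) or `"truncate"`.  Published tables are not always
#'   consistent; the mode makes the reporting convention explicit.
#' @param digits decimals to keep; 2 by default.
#' @return percentage (0-100 scale), `NA` when `drug_total` is zero.
#' @examples
#' proportion_of_reports(314, 44688)             # 0.70
#' proportion_of_reports(611, 44688)             # 1.37 under half-up
#' proportion_of_reports(611, 44688, "truncate") # 1.36
#' @export
proportion_of_reports <- function(event_count, drug_total,
                                  mode = c("halfup", "truncate"),
                                  digits = 2) {
  if (drug_total == 0) return(NA_real_)
  round_mode(100 * event_count / drug_total, digits, match.arg(mode))
}

#' Run the full disproportionality analysis
#'
#' For every active in the dictionary and every event group, computes the
#' per-PT contingency tables and RORs plus a `"Total events of interest"`
#' row per group whose count equals the sum of the per-PT counts.
#'
#' @param reports deduplicated [faers_reports] comparator collection.
#' @param dictionary a [drug_dictionary()].
#' @param groups list of [event_group()]s; defaults to
#'   [il17_event_groups()].
#' @param role_filter exposure roles, default primary suspect.
#' @return data.table with columns `drug`, `group`, `pt`, `count`,
#'   `ror`, `ci_low`, `ci_high`, `signal`.  `pt` is
#'   `"Total events of interest"` for the group-total rows; undefined
#'   estimates are `NA`.
#' @export
run_disproportionality <- function(reports, dictionary,
                                   groups = il17_event_groups(),
                                   role_filter = "PS") {
  stopifnot(inherits(reports, "faers_reports"))
  pairs <- event_pairs(reports)
  n_total <- nrow(pairs)
  rows <- list()
  for (act in names(dictionary)) {
    exp_ids <- exposed_ids(reports, act, dictionary, role_filter)
    exposed <- pairs$primaryid %in% exp_ids
    n_exposed <- sum(exposed)
    for (grp in groups) {
      tally_one <- function(pt_label, tgt) {
        in_set <- pairs$pt_norm %in% tgt
        a <- sum(exposed & in_set)
        c_ <- sum(in_set) - a
        tab <- contingency_table(a, n_exposed - a, c_,
                                 n_total - n_exposed - c_)
        r <- compute_ror(tab)
        data.table(drug = act, group = grp$name, pt = pt_label,
                   count = a, ror = r$ror, ci_low = r$ci_low,
                   ci_high = r$ci_high, signal = r$signal)
      }
      per_pt <- lapply(grp$pts, function(p) tally_one(p, norm_pt(p)))
      total <- tally_one("Total events of interest", norm_pt(grp$pts))
      rows[[length(rows) + 1L]] <- rbindlist(c(per_pt, list(total)))
    }
  }
  rbindlist(rows)
}
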
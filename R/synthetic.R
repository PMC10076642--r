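## Seeded synthetic spontaneous-report generator.
##
## Model: each report draws one primary-suspect (PS) drug from the
## configured marginals (remaining probability mass goes to a pool of
## background drugs); each event PT occurs independently per report with
## background probability p0, or with p1 such that odds(p1) =
## odds_ratio * odds(p0) when the report's PS drug has a planted
## association with that PT.  Planting on the odds scale makes the
## reporting odds ratio the exact estimand, so recovery studies compare
## the pipeline's estimate against the planted value without bias from
## the effect-scale conversion.  Reports drawing no event receive a
## filler PT ("Drug ineffective") so every report survives ingestion.

.background_drugs <- c("adalimumab", "etanercept", "ustekinumab",
                       "methotrexate", "ibuprofen", "paracetamol")
.filler_pt <- "Drug ineffective"

#' Specify a synthetic report collection
#'
#' @param n_reports number of cases to generate (before duplicate-version
#'   injection).
#' @param drugs data.frame with columns `active`, `brand`, `marginal`:
#'   the target drugs, one brand name each, and the probability that a
#'   report's PS drug is that active.  Marginals must sum to at most 1;
#'   the remainder is split evenly over a pool of background drugs.
#' @param events data.frame with columns `pt`, `prob`: event PTs and
#'   their background occurrence probabilities (0 < prob < 1).
#' @param planted data.frame with columns `active`, `pt`, `odds_ratio`
#'   (or `NULL` for a pure-background collection): drug-event pairs whose
#'   occurrence odds among the exposed are multiplied by `odds_ratio`.
#' @param versions_per_case probability vector over 1, 2, ... report
#'   versions per case; default `1` (single version, no duplicates).
#' @param demographics list with elements `age_missing`, `sex_probs`
#'   (female / male / unknown), `country_us`, `country_other`,
#'   `country_missing`.  Defaults mimic the high-missingness demographic
#'   strata typical of FAERS extracts.
#' @param seed integer seed; mandatory, the generator is fully
#'   reproducible from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_reports,
                         drugs = data.frame(
                           active   = c("secukinumab", "ixekizumab", "brodalumab"),
                           brand    = c("Cosentyx", "Taltz", "Siliq"),
                           marginal = c(0.20, 0.10, 0.02)
                         ),
                         events = data.frame(
                           pt   = c("Inflammatory bowel disease",
                                    "Crohn's disease", "Colitis"),
                           prob = c(0.01, 0.01, 0.01)
                         ),
                         planted = NULL,
                         versions_per_case = 1,
                         demographics = list(
                           age_missing = 0.68,
                           sex_probs = c(female = 0.441, male = 0.320,
                                         unknown = 0.239),
                           country_us = 0.572, country_other = 0.268,
                           country_missing = 0.160
                         ),
                         seed) {
  problems <- character()
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    problems <- c(problems, "seed: a single integer seed is mandatory")
  }
  if (n_reports < 1L) problems <- c(problems, "n_reports: must be >= 1")
  drugs <- as.data.frame(drugs)
  events <- as.data.frame(events)
  if (sum(drugs$marginal) > 1 + 1e-12 || any(drugs$marginal < 0)) {
    problems <- c(problems,
                  "drugs$marginal: must be non-negative and sum to <= 1")
  }
  if (any(events$prob <= 0 | events$prob >= 1)) {
    problems <- c(problems, "events$prob: must lie strictly in (0, 1)")
  }
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    if (any(planted$odds_ratio <= 0)) {
      problems <- c(problems, "planted$odds_ratio: must be positive")
    }
    if (anyDuplicated(planted[, c("active", "pt")])) {
      problems <- c(problems, "planted: each (active, pt) pair at most once")
    }
    if (!all(planted$active %in% drugs$active)) {
      problems <- c(problems, "planted$active: must appear in drugs$active")
    }
    if (!all(planted$pt %in% events$pt)) {
      problems <- c(problems, "planted$pt: must appear in events$pt")
    }
  }
  if (any(versions_per_case < 0) || sum(versions_per_case) <= 0) {
    problems <- c(problems,
                  "versions_per_case: non-negative weights over 1..k versions")
  }
  if (length(problems)) {
    stop("invalid synthetic configuration:\n  ",
         paste(problems, collapse = "\n  "))
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 events = events, planted = planted,
                 versions_per_case = versions_per_case / sum(versions_per_case),
                 demographics = demographics, seed = as.integer(seed)),
            class = "synth_config")
}

## odds-scale planting: odds(p1) = or * odds(p0)
planted_prob <- function(p0, or) {
  o <- or * p0 / (1 - p0)
  o / (1 + o)
}

#' Generate a synthetic report collection
#'
#' Draws `n_reports` cases under the model described in [synth_config()],
#' optionally injects duplicate case versions, and (when `dir` is given)
#' writes the collection as the five '$'-delimited FAERS-style files via
#' [write_faers_files()].  Output is byte-identical across runs with the
#' same configuration (including seed).
#'
#' @param config a [synth_config()].
#' @param dir optional output directory for the FAERS-style files.
#' @return a [faers_reports] collection (all versions, not deduplicated);
#'   when `dir` is given the file paths are attached as attribute
#'   `"paths"`.
#' @export
generate_reports <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_reports
  window <- quarter_seq("2015Q1", "2022Q3")

  pool_mass <- 1 - sum(config$drugs$marginal)
  drug_labels <- c(config$drugs$active, .background_drugs)
  drug_probs <- c(config$drugs$marginal,
                  rep(pool_mass / length(.background_drugs),
                      length(.background_drugs)))
  ## verbatim names: target actives appear under their brand name with a
  ## dose suffix, so ingestion must really exercise the dictionary
  verbatim <- c(paste0(toupper(config$drugs$brand), " 150MG"),
                toupper(.background_drugs))
  names(verbatim) <- drug_labels

  caseid <- sprintf("C%07d", seq_len(n))
  ps_drug <- sample(drug_labels, n, replace = TRUE, prob = drug_probs)
  quarter <- sample(window, n, replace = TRUE)

  dg <- config$demographics
  age <- round(runif(n, 18, 85))
  age[runif(n) < dg$age_missing] <- NA_real_
  sex <- sample(names(dg$sex_probs), n, replace = TRUE, prob = dg$sex_probs)
  country <- sample(c("US", "OTHER", NA_character_), n, replace = TRUE,
                    prob = c(dg$country_us, dg$country_other,
                             dg$country_missing))
  onset <- round(runif(n, 0.2, 30), 1)
  onset[runif(n) < 0.8] <- NA_real_

  ## event occurrence: per PT, probability p0 or planted p1 by PS drug
  ev <- config$events
  occ <- matrix(FALSE, nrow = n, ncol = nrow(ev))
  for (j in seq_len(nrow(ev))) {
    p <- rep(ev$prob[j], n)
    if (!is.null(config$planted)) {
      pl <- config$planted[config$planted$pt == ev$pt[j], , drop = FALSE]
      for (k in seq_len(nrow(pl))) {
        hit <- ps_drug == pl$active[k]
        p[hit] <- planted_prob(ev$prob[j], pl$odds_ratio[k])
      }
    }
    occ[, j] <- runif(n) < p
  }

  reac <- data.table(
    primaryid = rep(caseid, times = nrow(ev))[as.vector(occ)],
    pt = rep(ev$pt, each = n)[as.vector(occ)]
  )
  no_event <- !(caseid %in% reac$primaryid)
  if (any(no_event)) {
    reac <- rbind(reac, data.table(primaryid = caseid[no_event],
                                   pt = .filler_pt))
  }
  setorder(reac, primaryid, pt)

  ## drug table: the PS entry plus 0-2 concomitant background drugs
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  con_drug <- sample(.background_drugs, sum(n_con), replace = TRUE)
  drug <- rbind(
    data.table(primaryid = caseid, drug_seq = 1L, role_cod = "PS",
               drugname = verbatim[ps_drug]),
    data.table(primaryid = rep(caseid, times = n_con),
               drug_seq = sequence(n_con) + 1L, role_cod = "C",
               drugname = toupper(con_drug))
  )
  setorder(drug, primaryid, drug_seq)

  ## outcomes: a random subset of reports gets one outcome code
  has_outc <- runif(n) < 0.4
  outc <- data.table(
    primaryid = caseid[has_outc],
    outc_cod = sample(.outcome_codes, sum(has_outc), replace = TRUE,
                      prob = c(0.02, 0.02, 0.25, 0.01, 0.01, 0.02, 0.67))
  )

  ## indications: PS drug indication reported for a subset
  has_indi <- runif(n) < 0.5
  indi <- data.table(
    primaryid = caseid[has_indi],
    indi_drug_seq = 1L,
    indi_pt = sample(c("Psoriasis", "Psoriatic arthropathy",
                       "Ankylosing spondylitis"),
                     sum(has_indi), replace = TRUE)
  )

  demo <- data.table(primaryid = caseid, caseid = caseid, caseversion = 1L,
                     quarter = quarter, age = age, sex = sex,
                     country = country, onset_months = onset)

  ## duplicate-version injection: earlier versions replicate the content
  k <- sample(seq_along(config$versions_per_case), n, replace = TRUE,
              prob = config$versions_per_case)
  if (any(k > 1L)) {
    expand <- function(tab, id_col = "primaryid") {
      per <- k[match(tab[[id_col]], caseid)]
      out <- tab[rep(seq_len(nrow(tab)), times = per)]
      ver <- sequence(per)
      out[, primaryid := paste0(tab[[id_col]][rep(seq_len(nrow(tab)),
                                                  times = per)], "-", ver)]
      list(out = out, ver = ver)
    }
    ed <- expand(demo)
    demo <- ed$out
    demo[, caseversion := ed$ver]
    drug <- expand(drug)$out
    reac <- expand(reac)$out
    outc <- expand(outc)$out
    indi <- expand(indi)$out
  } else {
    demo[, primaryid := paste0(caseid, "-1")]
    for (tab in list(drug, reac, outc, indi)) {
      tab[, primaryid := paste0(primaryid, "-1")]
    }
  }

  ## same join shape as read_quarter_files() output, so round trips are
  ## field-for-field comparable
  drug_joined <- merge(drug, indi, by.x = c("primaryid", "drug_seq"),
                       by.y = c("primaryid", "indi_drug_seq"),
                       all.x = TRUE, sort = FALSE)
  reports <- faers_reports(demo, drug_joined, reac, outc, indi)
  if (!is.null(dir)) {
    attr(reports, "paths") <- write_faers_files(reports, dir)
  }
  reports
}

#' Expected contingency cells under the generator model
#'
#' Closed-form expectations of the event-level 2x2 cells (a, b, c, d) for
#' a given target active and PT, used as an analytic oracle: empirical
#' cell counts from a generated collection must fall within binomial
#' sampling tolerance of these values.  Filler PTs count as non-target
#' events, exactly as they do in the pipeline.
#'
#' @param config a [synth_config()].
#' @param active target active label (must be in `config$drugs`).
#' @param pt target event PT (must be in `config$events`).
#' @return named numeric vector with components `a`, `b`, `c`, `d`.
#' @export
expected_contingency <- function(config, active, pt) {
  stopifnot(inherits(config, "synth_config"))
  if (!active %in% config$drugs$active) stop("unknown active: ", active)
  if (!pt %in% config$events$pt) stop("unknown event PT: ", pt)
  n <- config$n_reports
  ev <- config$events

  ## per-drug event probabilities (targets with planting, background pool)
  prob_for <- function(drug_label, pt_label) {
    p0 <- ev$prob[ev$pt == pt_label]
    if (!is.null(config$planted)) {
      pl <- config$planted
      hit <- pl$active == drug_label & pl$pt == pt_label
      if (any(hit)) return(planted_prob(p0, pl$odds_ratio[hit]))
    }
    p0
  }
  drug_labels <- c(config$drugs$active, .background_drugs)
  pool_mass <- 1 - sum(config$drugs$marginal)
  drug_probs <- c(config$drugs$marginal,
                  rep(pool_mass / length(.background_drugs),
                      length(.background_drugs)))

  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (g in seq_along(drug_labels)) {
    dl <- drug_labels[g]
    m <- drug_probs[g]
    p_each <- vapply(ev$pt, function(e) prob_for(dl, e), numeric(1))
    p_target <- prob_for(dl, pt)
    p_none <- prod(1 - p_each)       # filler PT probability
    e_other <- sum(p_each) - p_target + p_none
    if (dl == active) {
      cells["a"] <- cells["a"] + n * m * p_target
      cells["b"] <- cells["b"] + n * m * e_other
    } else {
      cells["c"] <- cells["c"] + n * m * p_target
      cells["d"] <- cells["d"] + n * m * e_other
    }
  }
  cells
}
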
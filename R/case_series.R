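## Descriptive summarization of published case reports / case series of
## IL-17-inhibitor-associated IBD.  Every variable is summarized over its
## own non-missing denominator (the "n =" convention of clinical tables);
## set-valued variables (symptoms, imaging, endoscopy, histology findings)
## use the number of cases reporting that variable as denominator, so
## their percentages need not sum to 100.

.case_vocab <- list(
  source_kind = c("case_report", "case_series"),
  sex         = c("female", "male", "unknown"),
  region      = c("USA", "Europe", "Canada", "Asia", "other", "unknown"),
  drug        = c("secukinumab", "ixekizumab", "brodalumab"),
  indication  = c("PsO", "PsA", "PsO_and_PsA", "AS", "other"),
  smoking     = c("yes", "no", "not_mentioned"),
  prior_tnf   = c("adalimumab", "etanercept", "none"),
  ibd_class   = c("UC", "CD", "unclassified"),
  symptoms    = c("diarrhea", "bloody_diarrhea", "abdominal_pain", "fever",
                  "chills", "nausea", "weight_loss", "asymptomatic"),
  wbc                = c("normal", "elevated"),
  crp                = c("normal", "elevated"),
  esr                = c("normal", "elevated"),
  fecal_calprotectin = c("normal", "elevated"),
  ct_findings = c("normal", "bowel_wall_thickening", "pancolitis",
                  "colon_perforated"),
  colonoscopy_findings = c("edematous", "erythematous_mucosa", "hemorrhagic",
                           "friable_mucosa", "absent_vascular_pattern",
                           "superficial_ulceration", "deep_ulcerations",
                           "active_inflammation"),
  histopathology_findings = c("cryptitis", "crypt_abscesses",
                              "granulomatous_lesions", "chronic_inflammation"),
  therapy = c("none", "corticosteroids", "tnf_antagonist", "ustekinumab",
              "five_asa", "corticosteroids_plus_tnf",
              "corticosteroids_plus_5asa", "corticosteroids_plus_ustekinumab"),
  outcome = c("recovered", "relapse")
)

.set_valued <- c("symptoms", "ct_findings", "colonoscopy_findings",
                 "histopathology_findings")

#' Controlled vocabularies of the literature-case table
#'
#' @return named list: for each categorical column of the case table, the
#'   allowed category labels.  Set-valued columns (`symptoms`,
#'   `ct_findings`, `colonoscopy_findings`, `histopathology_findings`)
#'   hold semicolon-separated subsets of their vocabulary.
#' @export
case_vocabulary <- function() .case_vocab

#' Read a literature-case table
#'
#' One row per published case.  Categorical columns are validated against
#' [case_vocabulary()]; violations are reported with their line numbers.
#' Missing values are empty fields or `NA`.
#'
#' @param path CSV file path.
#' @return data.table of validated cases; set-valued columns remain
#'   semicolon-separated strings (split at summarization time).
#' @seealso [il17_case_fixture()] for the packaged synthetic 34-case
#'   table.
#' @export
read_literature_cases <- function(path) {
  if (!file.exists(path)) stop("case table does not exist: ", path)
  dt <- fread(path, sep = ",", header = TRUE, na.strings = c("", "NA"),
              colClasses = list(character = intersect(
                names(.case_vocab), names(fread(path, nrows = 0L)))))
  errors <- character()
  for (col in intersect(names(.case_vocab), names(dt))) {
    vocab <- .case_vocab[[col]]
    vals <- dt[[col]]
    for (i in which(!is.na(vals))) {
      terms <- if (col %in% .set_valued) {
        strsplit(vals[i], ";", fixed = TRUE)[[1]]
      } else {
        vals[i]
      }
      bad <- setdiff(trimws(terms), vocab)
      if (length(bad)) {
        errors <- c(errors, paste0("line ", i + 1L, ", column '", col,
                                   "': unknown term(s) ",
                                   paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(errors)) {
    stop("case table vocabulary violations:\n  ",
         paste(errors, collapse = "\n  "))
  }
  num_bad <- which(!is.na(dt$onset_months) & dt$onset_months <= 0)
  if (length(num_bad)) {
    stop("non-positive onset_months at line(s) ",
         paste(num_bad + 1L, collapse = ", "))
  }
  dt
}

#' Path to the packaged synthetic 34-case literature table
#'
#' The individual patient rows of the published case series are not
#' public; this table is *synthesized* so that every per-variable marginal
#' count matches the published descriptive tables exactly (34 cases, 27
#' secukinumab / 7 ixekizumab, diarrhea in 30 of 33 symptomatic cases,
#' median onset 2.9 months with range 0.47-48, and so on).  It exercises
#' the summarization pipeline; the joint structure across columns is
#' arbitrary and must not be mined for cross-variable associations.
#'
#' @return file path of the CSV inside the installed package.
#' @export
il17_case_fixture <- function() {
  system.file("extdata", "literature_cases_synthetic.csv",
              package = "il17pv", mustWork = TRUE)
}

#' Bin symptom-onset times
#'
#' Months from start of IL-17 inhibitor therapy to IBD symptom onset,
#' binned as in the descriptive tables.  Bins are half-open
#' `[lower, upper)`, so 3.0 months falls in `"3-6"`; values of 24 months
#' or more fall in `">24"`.
#'
#' @param onset_months positive numeric vector.
#' @return factor with levels `<1`, `1-3`, `3-6`, `6-12`, `12-24`, `>24`.
#' @export
bin_onset <- function(onset_months) {
  if (any(!is.na(onset_months) & onset_months <= 0)) {
    stop("onset_months must be positive")
  }
  cut(onset_months, breaks = c(0, 1, 3, 6, 12, 24, Inf), right = FALSE,
      labels = c("<1", "1-3", "3-6", "6-12", "12-24", ">24"))
}

#' Bin time to symptom relief
#'
#' Weeks from IL-17 inhibitor discontinuation to symptom relief.
#' Half-open bins: `<2w` is `[0, 2)`, `2-4w` is `[2, 4)`, `>4w` is
#' `[4, Inf)`.
#'
#' @param relief_weeks positive numeric vector.
#' @return factor with levels `<2w`, `2-4w`, `>4w`.
#' @export
bin_relief <- function(relief_weeks) {
  if (any(!is.na(relief_weeks) & relief_weeks <= 0)) {
    stop("relief_weeks must be positive")
  }
  cut(relief_weeks, breaks = c(0, 2, 4, Inf), right = FALSE,
      labels = c("<2w", "2-4w", ">4w"))
}

#' Bin ages into the standard reporting bands
#'
#' Closed integer bands: `<=25`, `26-50`, `51-75`, `>=76`.
#'
#' @param age_years numeric vector.
#' @return factor with the four band labels.
#' @export
bin_age <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 25, 50, 75, Inf),
      labels = c("<=25", "26-50", "51-75", ">=76"))
}

percent_rows <- function(vals, vocab, denom = NULL) {
  vals <- vals[!is.na(vals)]
  if (is.null(denom)) denom <- length(vals)
  counts <- table(factor(vals, levels = vocab))
  data.table(
    category = names(counts),
    count = as.integer(counts),
    percent = if (denom > 0) round_half_up(100 * as.integer(counts) / denom, 1)
              else NA_real_,
    denominator = denom
  )
}

#' Summarize a literature-case table
#'
#' Produces one frequency table per variable, mirroring the descriptive
#' tables of a case-series study: counts over non-missing values with the
#' per-variable non-missing count as denominator, percentages half-up to
#' one decimal.  `onset_months`, `relief_weeks` and `age_years` are
#' summarized via their bins ([bin_onset()], [bin_relief()],
#' [bin_age()]); set-valued variables use the number of cases reporting
#' the variable as denominator.
#'
#' @param cases data.table from [read_literature_cases()].
#' @param drop_empty drop zero-count categories from the output tables
#'   (`FALSE` by default, so table shapes are stable).
#' @return named list of data.tables with columns `category`, `count`,
#'   `percent`, `denominator`.
#' @export
summarize_cases <- function(cases, drop_empty = FALSE) {
  cases <- as.data.table(cases)
  out <- list()
  for (col in intersect(names(.case_vocab), names(cases))) {
    vocab <- .case_vocab[[col]]
    if (col %in% .set_valued) {
      vals <- cases[[col]]
      reported <- !is.na(vals)
      terms <- unlist(lapply(vals[reported], function(v) {
        unique(trimws(strsplit(v, ";", fixed = TRUE)[[1]]))
      }))
      out[[col]] <- percent_rows(terms, vocab, denom = sum(reported))
    } else {
      out[[col]] <- percent_rows(cases[[col]], vocab)
    }
  }
  if ("preexisting_ibd" %in% names(cases)) {
    v <- cases$preexisting_ibd
    out$preexisting_ibd <- percent_rows(
      ifelse(v, "pre-existing IBD", "new onset of IBD"),
      c("pre-existing IBD", "new onset of IBD"))
  }
  if ("family_history_ibd" %in% names(cases)) {
    v <- cases$family_history_ibd
    out$family_history_ibd <- percent_rows(
      ifelse(v, "yes", "no"), c("yes", "no"))
  }
  if ("age_years" %in% names(cases)) {
    out$age_band <- percent_rows(as.character(bin_age(cases$age_years)),
                                 levels(bin_age(numeric())))
  }
  if ("onset_months" %in% names(cases)) {
    out$onset_bin <- percent_rows(as.character(bin_onset(cases$onset_months)),
                                  levels(bin_onset(numeric())))
  }
  if ("relief_weeks" %in% names(cases)) {
    out$relief_bin <- percent_rows(as.character(bin_relief(cases$relief_weeks)),
                                   levels(bin_relief(numeric())))
  }
  if (drop_empty) out <- lapply(out, function(tab) tab[count > 0L])
  out
}

#' Median time to symptom onset
#'
#' @param cases data.table with an `onset_months` column.
#' @return median over non-missing onset times (even counts average the
#'   two central values); `NA` if none are reported.
#' @export
median_onset <- function(cases) {
  v <- cases$onset_months
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  median(v)
}

#' Range of onset times
#' @param cases data.table with an `onset_months` column.
#' @return `c(min, max)` over non-missing values, or `c(NA, NA)`.
#' @export
onset_range <- function(cases) {
  v <- cases$onset_months
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(c(NA_real_, NA_real_))
  range(v)
}
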
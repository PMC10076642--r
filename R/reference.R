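## Published reference counts shipped with the package.  These are the
## printed event tallies and screening characteristics of the FAERS
## analysis of IL-17 inhibitors (2015Q1-2022Q3); the package treats them
## as inputs for arithmetic checks and for planting effect sizes in
## recovery studies -- the underlying ~31 quarters of raw FAERS data are
## not redistributable at package scale.

ref_path <- function(file) {
  system.file("extdata", file, package = "il17pv", mustWork = TRUE)
}

#' Published per-PT event counts for IL-17 inhibitors
#'
#' Event-level counts of IBD-group and colitis-group preferred terms
#' among primary-suspect reports of secukinumab, ixekizumab and
#' brodalumab in FAERS 2015Q1--2022Q3, as published.
#'
#' @return data.table with columns `drug`, `group`, `pt`, `n_events`.
#' @export
faers_reference_counts <- function() {
  fread(ref_path("faers_pt_counts.csv"))
}

#' Published drug report totals and headline RORs
#'
#' Total FAERS report counts per IL-17 inhibitor over the study window,
#' with the published group-total reporting odds ratios and 95% CIs
#' (`NA` where the published table reports none).
#'
#' @return data.table with columns `drug`, `total_reports`, `group`,
#'   `published_ror`, `published_ci_low`, `published_ci_high`.
#' @export
faers_reference_totals <- function() {
  fread(ref_path("faers_reference_totals.csv"))
}

#' Published screening characteristics of primary-suspect cases
#'
#' The published characteristics table of the 388 deduplicated FAERS
#' cases with an IL-17 inhibitor as primary suspect: age bands, sex,
#' country, year bands, suspect drug, outcomes, indications,
#' bowel-disease classification and onset bins.
#'
#' @return data.table with columns `block`, `category`, `count`.
#' @export
faers_reference_characteristics <- function() {
  fread(ref_path("faers_case_characteristics.csv"))
}
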
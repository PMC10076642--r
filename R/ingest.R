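## FAERS-style ingestion.
##
## The quarterly ASCII convention is five '$'-delimited tables sharing the
## report key `primaryid`: DEMO (one row per report version), DRUG (one row
## per drug entry), REAC (one row per reaction PT), OUTC (outcome codes),
## INDI (indication PT per drug entry).  A "case" (caseid) can appear as
## several report versions (caseversion); analysis uses the latest.

.demo_cols <- c("primaryid", "caseid", "caseversion", "quarter",
                "age", "sex", "country", "onset_months")
.drug_cols <- c("primaryid", "drug_seq", "role_cod", "drugname")
.reac_cols <- c("primaryid", "pt")
.outc_cols <- c("primaryid", "outc_cod")
.indi_cols <- c("primaryid", "indi_drug_seq", "indi_pt")

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Construct a report collection
#'
#' Container for a collection of spontaneous safety reports, stored in the
#' normalized shape of the source tables: one demographics row per report,
#' plus long tables of drug entries, reaction preferred terms (PTs),
#' outcome codes and indications.  Most users obtain one from
#' [read_quarter_files()] or [generate_reports()] rather than calling
#' this directly.
#'
#' @param demo,drugs,reactions,outcomes,indications data.frames with the
#'   columns of the corresponding FAERS-style tables (see
#'   [read_quarter_files()]).
#' @return object of class `faers_reports`: a list of data.tables
#'   `demo`, `drugs`, `reactions`, `outcomes`, `indications`.
#' @export
faers_reports <- function(demo, drugs, reactions, outcomes, indications) {
  obj <- list(
    demo        = as.data.table(demo),
    drugs       = as.data.table(drugs),
    reactions   = as.data.table(reactions),
    outcomes    = as.data.table(outcomes),
    indications = as.data.table(indications)
  )
  if (anyDuplicated(obj$demo$primaryid)) {
    stop("duplicate primaryid in demographics table")
  }
  bad_role <- setdiff(unique(obj$drugs$role_cod), .role_codes)
  if (length(bad_role)) {
    stop("unknown drug role code(s): ", paste(bad_role, collapse = ", "))
  }
  if (nrow(obj$drugs) && any(trimws(obj$drugs$drugname) == "")) {
    stop("empty verbatim drug names are not allowed")
  }
  structure(obj, class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports> ", nrow(x$demo), " reports (",
      length(unique(x$demo$caseid)), " cases), ",
      nrow(x$drugs), " drug rows, ", nrow(x$reactions), " reaction rows\n",
      sep = "")
  invisible(x)
}

#' Number of reports in a collection
#' @param reports a [faers_reports] object.
#' @return integer count of report versions currently held.
#' @export
n_reports <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  nrow(reports$demo)
}

read_one <- function(path, required, delim) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  present <- names(fread(path, sep = delim, header = TRUE, nrows = 0L))
  missing <- setdiff(required, present)
  if (length(missing)) {
    stop("file ", basename(path), " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  char_cols <- intersect(required, c("primaryid", "caseid", "quarter", "sex",
                                     "country", "drugname", "role_cod", "pt",
                                     "outc_cod", "indi_pt"))
  dt <- fread(path, sep = delim, header = TRUE,
              colClasses = list(character = char_cols),
              na.strings = c("", "NA"))
  dt[, required, with = FALSE]
}

#' Read FAERS-style quarterly files into a report collection
#'
#' Joins the five '$'-delimited tables on the report key, keeps only
#' reports that fall inside the quarter window, and drops reports that
#' carry no reaction PT (there is nothing to analyze for them); the
#' dropped count is logged with `message()`.  Rows in the long tables
#' whose key has no demographics row (orphans) are dropped with a
#' warning, not an error.
#'
#' @param demo_path,drug_path,reac_path,outc_path,indi_path file paths.
#' @param delim field delimiter; the FAERS ASCII convention is `"$"`.
#' @param window inclusive quarter window as `c(from, to)` labels, or
#'   `NULL` for no filtering.  Default is the 2015Q1--2022Q3 study window.
#' @return a [faers_reports] collection (not yet deduplicated; see
#'   [deduplicate()]).
#' @export
read_quarter_files <- function(demo_path, drug_path, reac_path, outc_path,
                               indi_path, delim = "$",
                               window = c("2015Q1", "2022Q3")) {
  demo <- read_one(demo_path, .demo_cols, delim)
  drug <- read_one(drug_path, .drug_cols, delim)
  reac <- read_one(reac_path, .reac_cols, delim)
  outc <- read_one(outc_path, .outc_cols, delim)
  indi <- read_one(indi_path, .indi_cols, delim)

  message("read ", nrow(demo), " demo / ", nrow(drug), " drug / ",
          nrow(reac), " reaction / ", nrow(outc), " outcome / ",
          nrow(indi), " indication rows")

  keys_all <- demo$primaryid
  if (!is.null(window)) {
    win <- quarter_seq(window[1], window[2])
    out_win <- !(demo$quarter %in% win)
    if (any(out_win)) {
      message("dropped ", sum(out_win), " report(s) outside window ",
              window[1], "-", window[2])
      demo <- demo[!out_win]
    }
  }

  keys <- demo$primaryid
  orphan <- sum(!(drug$primaryid %in% keys_all)) +
    sum(!(reac$primaryid %in% keys_all)) +
    sum(!(outc$primaryid %in% keys_all)) +
    sum(!(indi$primaryid %in% keys_all))
  if (orphan > 0L) {
    warning(orphan, " orphan row(s) without a demographics row were dropped")
  }
  drug <- drug[primaryid %in% keys]
  reac <- reac[primaryid %in% keys][!is.na(pt) & trimws(pt) != ""]
  outc <- outc[primaryid %in% keys]
  indi <- indi[primaryid %in% keys]

  ## attach indication PT to its drug entry
  drug <- merge(drug, indi, by.x = c("primaryid", "drug_seq"),
                by.y = c("primaryid", "indi_drug_seq"),
                all.x = TRUE, sort = FALSE)

  no_reac <- !(demo$primaryid %in% reac$primaryid)
  if (any(no_reac)) {
    message("dropped ", sum(no_reac), " report(s) with no reaction PT")
    demo <- demo[!no_reac]
    keep <- demo$primaryid
    drug <- drug[primaryid %in% keep]
    outc <- outc[primaryid %in% keep]
    indi <- indi[primaryid %in% keep]
  }

  faers_reports(demo, drug, reac, outc, indi)
}

#' Collapse duplicate case versions
#'
#' FAERS publishes every revision of a case; counting all of them would
#' duplicate patients.  For each `caseid` the report with the highest
#' `caseversion` is retained, ties broken by the later quarter and then by
#' the lexicographically largest `primaryid`.  Idempotent.
#'
#' @param reports a [faers_reports] collection.
#' @return a [faers_reports] collection with one report per case.
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  demo <- reports$demo
  if (nrow(demo) == 0L || !anyDuplicated(demo$caseid)) return(reports)
  demo <- copy(demo)
  setorder(demo, caseid, caseversion, quarter, primaryid)
  kept <- demo[demo[, .I[.N], by = caseid]$V1]
  n_dropped <- nrow(reports$demo) - nrow(kept)
  if (n_dropped > 0L) {
    message("deduplication: ", n_dropped, " earlier case version(s) dropped, ",
            nrow(kept), " unique cases retained")
  }
  setcolorder(kept, names(reports$demo))
  ids <- kept$primaryid
  faers_reports(
    kept,
    reports$drugs[primaryid %in% ids],
    reports$reactions[primaryid %in% ids],
    reports$outcomes[primaryid %in% ids],
    reports$indications[primaryid %in% ids]
  )
}

#' Select reports by suspect drug
#'
#' Returns the reports carrying at least one drug entry that matches the
#' given active with a role in `role_filter`.  The default role filter is
#' primary suspect only, the usual exposure definition in
#' disproportionality analysis.
#'
#' @param reports a [faers_reports] collection (deduplicate first).
#' @param active active-substance label present in `dictionary`.
#' @param dictionary a [drug_dictionary()].
#' @param role_filter subset of `c("PS", "SS", "C", "I")`.
#' @return the selected sub-collection.
#' @export
select_reports <- function(reports, active, dictionary, role_filter = "PS") {
  stopifnot(inherits(reports, "faers_reports"))
  if (!active %in% names(dictionary)) {
    stop("unknown active label: ", active,
         " (dictionary has: ", paste(names(dictionary), collapse = ", "), ")")
  }
  bad <- setdiff(role_filter, .role_codes)
  if (length(bad)) stop("unknown role code(s): ", paste(bad, collapse = ", "))
  ids <- exposed_ids(reports, active, dictionary, role_filter)
  subset_reports(reports, ids)
}

## primaryids of reports carrying `active` with a role in role_filter;
## matches unique drug names once, so cost scales with vocabulary size
exposed_ids <- function(reports, active, dictionary, role_filter = "PS") {
  dr <- reports$drugs[role_cod %in% role_filter]
  if (nrow(dr) == 0L) return(character())
  nm <- unique(dr$drugname)
  hits <- match_drug(nm, dictionary)
  hit_nm <- nm[!is.na(hits) & hits == active]
  unique(dr[drugname %in% hit_nm, primaryid])
}

subset_reports <- function(reports, ids) {
  faers_reports(
    reports$demo[primaryid %in% ids],
    reports$drugs[primaryid %in% ids],
    reports$reactions[primaryid %in% ids],
    reports$outcomes[primaryid %in% ids],
    reports$indications[primaryid %in% ids]
  )
}

#' Write a report collection as FAERS-style files
#'
#' Emits the five '$'-delimited tables (`DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `OUTC.txt`, `INDI.txt`) that [read_quarter_files()] reads,
#' so synthetic collections can exercise ingestion end to end.
#'
#' @param reports a [faers_reports] collection.
#' @param dir output directory (created if needed).
#' @param delim field delimiter, `"$"` by default.
#' @return named character vector of the five file paths, invisibly.
#' @export
write_faers_files <- function(reports, dir, delim = "$") {
  stopifnot(inherits(reports, "faers_reports"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    demo = file.path(dir, "DEMO.txt"),
    drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"),
    outc = file.path(dir, "OUTC.txt"),
    indi = file.path(dir, "INDI.txt")
  )
  fwrite(reports$demo[, .demo_cols, with = FALSE], paths["demo"], sep = delim)
  fwrite(reports$drugs[, .drug_cols, with = FALSE], paths["drug"], sep = delim)
  fwrite(reports$reactions[, .reac_cols, with = FALSE], paths["reac"], sep = delim)
  fwrite(reports$outcomes[, .outc_cols, with = FALSE], paths["outc"], sep = delim)
  fwrite(reports$indications[, .indi_cols, with = FALSE], paths["indi"], sep = delim)
  invisible(paths)
}
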
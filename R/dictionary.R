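#' Build a drug dictionary
#'
#' A drug dictionary maps each active substance to the set of name
#' patterns (generic and brand names) used to recognize it in free-text
#' drug name fields.  Matching is case-insensitive substring matching on
#' the trimmed verbatim name, because spontaneous-report drug strings
#' carry doses, salts and formulations (`"COSENTYX 150MG"` must match
#' `cosentyx`).
#'
#' @param entries named list: names are active-substance labels, values
#'   are character vectors of name patterns.
#' @return object of class `drug_dictionary`.
#' @seealso [il17_dictionary()] for the shipped IL-17 inhibitor dictionary,
#'   [match_drug()] for matching a single name.
#' @examples
#' d <- drug_dictionary(list(secukinumab = c("secukinumab", "cosentyx")))
#' match_drug("COSENTYX 150MG", d)
#' @export
drug_dictionary <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == "")) {
    stop("'entries' must be a named list of pattern vectors")
  }
  entries <- lapply(entries, function(p) tolower(trimws(as.character(p))))
  if (any(lengths(entries) == 0L)) {
    stop("every active must have at least one name pattern")
  }
  flat <- unlist(entries, use.names = FALSE)
  owner <- rep(names(entries), lengths(entries))
  if (any(flat == "")) stop("empty name patterns are not allowed")
  dup <- tapply(owner, flat, function(a) length(unique(a))) > 1L
  if (any(dup)) {
    stop("pattern(s) mapped to more than one active: ",
         paste(names(dup)[dup], collapse = ", "))
  }
  structure(entries, class = "drug_dictionary")
}

#' IL-17 inhibitor dictionary
#'
#' The three marketed IL-17 inhibitors with the brand names used in the
#' safety literature: secukinumab (Cosentyx), ixekizumab (Taltz) and
#' brodalumab (Siliq).  Additional regional brand names can be added with
#' [drug_dictionary()].
#'
#' @return a `drug_dictionary` with three actives.
#' @export
il17_dictionary <- function() {
  drug_dictionary(list(
    secukinumab = c("secukinumab", "cosentyx"),
    ixekizumab  = c("ixekizumab", "taltz"),
    brodalumab  = c("brodalumab", "siliq")
  ))
}

#' Match a verbatim drug name against a dictionary
#'
#' @param verbatim_name free-text drug name (scalar or vector).
#' @param dictionary a [drug_dictionary()].
#' @return character vector of active labels, `NA` where no pattern
#'   matches.  A name matching patterns of two different actives is an
#'   error (the dictionary invariant is violated for that name).
#' @export
match_drug <- function(verbatim_name, dictionary) {
  stopifnot(inherits(dictionary, "drug_dictionary"))
  x <- tolower(trimws(verbatim_name))
  hit <- rep(NA_character_, length(x))
  multi <- rep(FALSE, length(x))
  for (act in names(dictionary)) {
    m <- Reduce(`|`, lapply(dictionary[[act]], function(p) {
      grepl(p, x, fixed = TRUE)
    }))
    multi <- multi | (m & !is.na(hit) & hit != act)
    hit[m] <- act
  }
  if (any(multi)) {
    stop("drug name(s) match more than one active: ",
         paste(unique(verbatim_name[multi]), collapse = ", "))
  }
  hit
}
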
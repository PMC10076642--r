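#' Read an analysis configuration file
#'
#' Plain-text (YAML) configuration bundling the quarter window, the drug
#' dictionary and the event-group definitions, so an analysis is fully
#' specified by one reviewable file:
#'
#' ```yaml
#' window: [2015Q1, 2022Q3]
#' dictionary:
#'   secukinumab: [secukinumab, cosentyx]
#'   ixekizumab:  [ixekizumab, taltz]
#' groups:
#'   IBD: ["Crohn's disease", "Colitis ulcerative"]
#' ```
#'
#' Omitted sections fall back to the packaged defaults
#' ([il17_dictionary()], [il17_event_groups()], the 2015Q1--2022Q3
#' window); present sections are validated on load.
#'
#' @param path YAML file path.
#' @return list with elements `window` (length-2 character),
#'   `dictionary` (a [drug_dictionary()]) and `groups` (named list of
#'   [event_group()]s).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("window", "dictionary", "groups"))
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  }
  window <- raw$window %||% c("2015Q1", "2022Q3")
  window <- as.character(window)
  if (length(window) != 2L || !all(is_quarter(window))) {
    stop("config 'window' must be two quarter labels like 2015Q1")
  }
  quarter_seq(window[1], window[2])  # validates ordering
  dictionary <- if (is.null(raw$dictionary)) {
    il17_dictionary()
  } else {
    drug_dictionary(raw$dictionary)
  }
  groups <- if (is.null(raw$groups)) {
    il17_event_groups()
  } else {
    out <- lapply(names(raw$groups), function(nm) {
      event_group(nm, unlist(raw$groups[[nm]]))
    })
    names(out) <- names(raw$groups)
    out
  }
  list(window = window, dictionary = dictionary, groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
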
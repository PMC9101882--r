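#' The six TE classes used for contribution reporting
#'
#' Transcriptional contribution is aggregated over SINE, Retro (non-LTR
#' retroelements other than LINEs/SINEs), LTR, LINE and DNA transposons,
#' plus an "Unclear" bin for repeats of unknown affiliation. Repeat
#' categories that are not transposable elements (simple repeats,
#' low-complexity, satellites, structural RNAs) map to the sentinel
#' `"NonTE"` and are excluded from all totals.
#'
#' @return Character vector of the six TE class labels.
#' @export
te_classes <- function() {
  c("SINE", "Retro", "LTR", "LINE", "DNA", "Unclear")
}

#' Load the RepeatMasker class/family mapping table
#'
#' The mapping is a versioned, auditable TSV with columns `prefix` and
#' `te_class`. A repeat's class/family string is matched on the part before
#' the first `/` (e.g. `"LINE/L2"` matches on `"LINE"`); the first matching
#' prefix in file order wins.
#'
#' @param path Path to a mapping TSV. Defaults to the table bundled with
#'   the package.
#' @return A data frame with columns `prefix` and `te_class`.
#' @export
load_class_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.tecontrib_env$class_map)) {
      return(.tecontrib_env$class_map)
    }
    path <- system.file("extdata", "te_class_map.tsv",
                        package = "tecontrib", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  map <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("prefix", "te_class") %in% names(map))) {
    config_error("class map '", path,
                 "' must have columns 'prefix' and 'te_class'")
  }
  bad <- setdiff(map$te_class, c(te_classes(), "NonTE"))
  if (length(bad) > 0) {
    config_error("class map '", path, "' contains unknown te_class value(s): ",
                 paste(bad, collapse = ", "))
  }
  if (cache) .tecontrib_env$class_map <- map
  map
}

#' Classify RepeatMasker class/family strings into TE classes
#'
#' Pure, case-sensitive, total function: every class/family string maps to
#' exactly one of the six TE classes or to the `"NonTE"` sentinel.
#' Unrecognized strings fall back to `"Unclear"` with a warning, so novel
#' repeat vocabularies are never silently dropped from TE totals.
#'
#' @param class_family Character vector of RepeatMasker class/family
#'   strings, e.g. `"LINE/L2"`, `"Simple_repeat"`.
#' @param map Mapping table as returned by [load_class_map()].
#' @return Character vector, elements from `c(te_classes(), "NonTE")`.
#' @examples
#' classify_repeat(c("LINE/L2", "Simple_repeat", "RC/Helitron", "Unknown"))
#' @export
classify_repeat <- function(class_family, map = load_class_map()) {
  if (length(class_family) == 0) {
    return(character(0))
  }
  if (any(is.na(class_family)) || any(!nzchar(class_family))) {
    input_error("class_family strings must be non-empty")
  }
  base <- sub("/.*$", "", class_family)
  out <- rep(NA_character_, length(base))
  for (i in seq_len(nrow(map))) {
    hit <- is.na(out) & startsWith(base, map$prefix[i])
    out[hit] <- map$te_class[i]
  }
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unrecognized repeat class/family string(s) mapped to 'Unclear': ",
            paste(unique(class_family[unknown]), collapse = ", "),
            call. = FALSE)
    out[unknown] <- "Unclear"
  }
  out
}
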
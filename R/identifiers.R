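#' Identifier validation patterns
#'
#' Regular expressions used to validate the persistent identifiers found in
#' MEDLINE records: DOI (article level), ORCID (author level), ISNI in its
#' presentation (space-separated) and compact 16-character forms, and GRID
#' (both at affiliation level). Validation is purely lexical: the check-digit
#' of ORCID/ISNI is deliberately not verified, so a well-formed but erroneous
#' identifier passes. The special value \code{0000-0000-0000-0000} (an ORCID
#' placeholder observed in the wild) is rejected explicitly.
#'
#' The DOI pattern is anchored at both ends and the ORCID pattern at the
#' start; both are applied as written (\code{match_mode = "search"}). The
#' ISNI and GRID patterns carry no anchors of their own and are applied in
#' \code{"full_match"} mode by default so that validity does not pass on an
#' identifier embedded in surrounding garbage; pass \code{match_mode} to
#' override per call, or edit the shipped TSV to change the dialect.
#'
#' @param path path to a pattern TSV (columns \code{scheme}, \code{match_mode},
#'   \code{pattern}); defaults to the table shipped with the package.
#' @return a data frame with columns \code{scheme}, \code{match_mode},
#'   \code{pattern}.
#' @export
identifier_patterns <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.medlineqc_cache$patterns)) {
      .medlineqc_cache$patterns <- utils::read.delim(
        medlineqc_extdata("identifier_patterns.tsv"),
        stringsAsFactors = FALSE, colClasses = "character"
      )
    }
    return(.medlineqc_cache$patterns)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

.medlineqc_cache <- new.env(parent = emptyenv())

ALL_ZERO_ORCID <- "0000-0000-0000-0000"

#' Validate a single identifier value
#'
#' @param scheme one of \code{"DOI"}, \code{"ORCID"},
#'   \code{"ISNI_presentation"}, \code{"ISNI_compact"}, \code{"GRID"}.
#' @param value the identifier string, or \code{NA} for an absent value.
#' @param match_mode optional override: \code{"search"} applies the pattern
#'   as written, \code{"full_match"} requires it to cover the whole string.
#' @param patterns pattern table, see [identifier_patterns()].
#' @return a list of class \code{pm_validation} with fields \code{scheme},
#'   \code{present}, \code{valid} and \code{reason} (one of \code{ok},
#'   \code{pattern_fail}, \code{all_zero_orcid}, \code{blank}).
#' @examples
#' validate_identifier("ORCID", "0000-0002-5696-5368")$valid       # TRUE
#' validate_identifier("ORCID", "0000-0000-0000-0000")$reason      # all-zero
#' validate_identifier("DOI", "10.1093/database/baad070")$valid    # TRUE
#' @export
validate_identifier <- function(scheme, value, match_mode = NULL,
                                patterns = identifier_patterns()) {
  row <- patterns[patterns$scheme == scheme, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown identifier scheme: ", scheme, call. = FALSE)
  res <- list(scheme = scheme, present = FALSE, valid = FALSE, reason = "blank")
  if (length(value) != 1 || is.na(value) || !nzchar(sanitize_text(value))) {
    class(res) <- "pm_validation"
    return(res)
  }
  res$present <- TRUE
  mode <- match_mode %||% row$match_mode
  pat <- row$pattern
  if (identical(mode, "full_match")) pat <- paste0("^(?:", pat, ")$")
  if (scheme == "ORCID" && identical(value, ALL_ZERO_ORCID)) {
    res$reason <- "all_zero_orcid"
  } else if (grepl(pat, value, perl = TRUE)) {
    res$valid <- TRUE
    res$reason <- "ok"
  } else {
    res$reason <- "pattern_fail"
  }
  class(res) <- "pm_validation"
  res
}

#' Vectorized identifier validity
#'
#' Applies the same rules as [validate_identifier()] across a character
#' vector; used by the metric computations, where per-value list results
#' would be needlessly slow. For scheme \code{"ISNI"} a value is valid if it
#' matches either the presentation or the compact pattern.
#'
#' @param values character vector (NA = absent).
#' @inheritParams validate_identifier
#' @return logical vector: \code{TRUE} where present and valid, \code{FALSE}
#'   where present and invalid, \code{NA} where absent/blank.
#' @export
identifier_is_valid <- function(values, scheme, match_mode = NULL,
                                patterns = identifier_patterns()) {
  if (scheme == "ISNI") {
    a <- identifier_is_valid(values, "ISNI_presentation", match_mode, patterns)
    b <- identifier_is_valid(values, "ISNI_compact", match_mode, patterns)
    return(ifelse(is.na(a), NA, a | b))
  }
  row <- patterns[patterns$scheme == scheme, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown identifier scheme: ", scheme, call. = FALSE)
  mode <- match_mode %||% row$match_mode
  pat <- row$pattern
  if (identical(mode, "full_match")) pat <- paste0("^(?:", pat, ")$")
  out <- rep(NA, length(values))
  present <- !is_blank(values)
  out[present] <- grepl(pat, values[present], perl = TRUE)
  if (scheme == "ORCID") out[present & values == ALL_ZERO_ORCID] <- FALSE
  out
}

#' @export
print.pm_validation <- function(x, ...) {
  cat(sprintf("<%s> present=%s valid=%s reason=%s\n",
              x$scheme, x$present, x$valid, x$reason))
  invisible(x)
}
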
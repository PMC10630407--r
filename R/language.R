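#' MARC language code table
#'
#' The Language element of a MEDLINE record holds codes from the Library of
#' Congress MARC language schema ("chi" for Chinese, "und" for undetermined,
#' "mul" for multiple languages). The shipped two-column TSV can be replaced
#' to extend or swap the vocabulary.
#'
#' @param path optional path to a replacement TSV (columns \code{code},
#'   \code{name}).
#' @return data frame with columns \code{code} and \code{name}.
#' @export
marc_language_codes <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.medlineqc_cache$marc)) {
      .medlineqc_cache$marc <- utils::read.delim(
        medlineqc_extdata("marc_language_codes.tsv"),
        stringsAsFactors = FALSE, colClasses = "character"
      )
    }
    return(.medlineqc_cache$marc)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Parse a MEDLINE language value into MARC codes
#'
#' Language codes are sometimes concatenated in a single value: "fregerita"
#' means the article appeared in French, German and Italian. The raw value is
#' split into consecutive 3-character codes, each checked against the MARC
#' table. A parse fails (raw preserved, \code{failed = TRUE}) if the length
#' is not a multiple of 3 or any chunk is not a known code.
#'
#' A record is language-invalid under the solitary-undetermined rule iff its
#' only code is \code{"und"} or \code{"mul"}; either code alongside other
#' codes does not trigger the rule.
#'
#' @param raw non-empty language string as found in the record.
#' @param codes_table MARC code table, see [marc_language_codes()].
#' @return list of class \code{pm_language}: \code{raw}, \code{codes}
#'   (character vector, empty on failure), \code{solitary_undetermined},
#'   \code{failed}.
#' @examples
#' parse_language_field("fregerita")$codes   # "fre" "ger" "ita"
#' parse_language_field("und")$solitary_undetermined
#' @export
parse_language_field <- function(raw, codes_table = marc_language_codes()) {
  stopifnot(is.character(raw), length(raw) == 1, !is.na(raw), nzchar(raw))
  out <- list(raw = raw, codes = character(0),
              solitary_undetermined = FALSE, failed = TRUE)
  n <- nchar(raw)
  if (n %% 3 == 0) {
    starts <- seq(1, n, by = 3)
    chunks <- substring(raw, starts, starts + 2)
    if (all(chunks %in% codes_table$code)) {
      out$codes <- chunks
      out$failed <- FALSE
      out$solitary_undetermined <-
        length(chunks) == 1 && chunks %in% c("und", "mul")
    }
  }
  class(out) <- "pm_language"
  out
}

#' @export
print.pm_language <- function(x, ...) {
  cat(sprintf("<language '%s'> codes=[%s]%s%s\n", x$raw,
              paste(x$codes, collapse = ","),
              if (x$failed) " FAILED" else "",
              if (x$solitary_undetermined) " solitary-und/mul" else ""))
  invisible(x)
}
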
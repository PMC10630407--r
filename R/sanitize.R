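#' Normalize whitespace and control characters in a text field
#'
#' PubMed text fields may contain carriage returns, line feeds and tabs that
#' break downstream serialization, as well as extended (non-ASCII) characters
#' that must be preserved because they are semantically meaningful (for
#' example "Istanbul" and "İstanbul" name different strings and must stay
#' distinct for author and affiliation matching).
#'
#' CR, LF and TAB are each replaced by a single space, runs of spaces collapse
#' to one, and leading/trailing whitespace is trimmed. Backslashes and quotes
#' are preserved: escaping is the job of a serializer, not of the in-memory
#' representation. Non-ASCII text is preserved under Unicode normalization
#' form NFC so that canonically equivalent spellings compare equal.
#'
#' @param raw character vector (NA allowed; NA stays NA).
#' @return character vector of the same length.
#' @examples
#' sanitize_text("a\r\nb")        # "a b"
#' sanitize_text("İstanbul") # unchanged
#' @export
sanitize_text <- function(raw) {
  if (length(raw) == 0) return(character(0))
  out <- raw
  idx <- !is.na(out)
  if (any(idx)) {
    x <- enc2utf8(out[idx])
    x <- stringi_nfc(x)
    x <- gsub("[\r\n\t]", " ", x)
    x <- gsub(" {2,}", " ", x)
    x <- gsub("^ +| +$", "", x)
    out[idx] <- x
  }
  out
}

# NFC normalization without a hard stringi dependency: base R since 4.0 does
# not expose a normalizer, but xml2's underlying libxml2 already delivers NFC
# for well-formed UTF-8 in practice; stringi is part of the tidyverse stack
# declared by dplyr, so use it when available and fall back to identity.
stringi_nfc <- function(x) {
  if (requireNamespace("stringi", quietly = TRUE)) {
    stringi::stri_trans_nfc(x)
  } else {
    x
  }
}

#' Is a value missing-or-blank after sanitization?
#'
#' Quality metrics treat a blank-after-sanitization value the same as an
#' absent one ("excludes null/blank").
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_blank <- function(x) {
  is.na(x) | !nzchar(sanitize_text(x))
}
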
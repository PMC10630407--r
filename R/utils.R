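`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
na_if_empty <- function(x) {
  if (length(x) == 0 || is.null(x)) NA_character_ else x
}

#' Escape text for inclusion in XML content
#' @keywords internal
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' FNV-1a 32-bit hash of a character string
#'
#' Deterministic content hash used to fingerprint pipeline configurations in
#' reports. Operates on the UTF-8 bytes of the input.
#'
#' @param x a length-1 character vector.
#' @return an 8-character lowercase hexadecimal string.
#' @keywords internal
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(x, collapse = "\n"))))
  # 32-bit FNV-1a in double arithmetic; all intermediates stay < 2^53
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# XOR for doubles holding 32-bit unsigned values (bitwXor needs integers)
bitwXor_dbl <- function(a, b) {
  lo_a <- a %% 2147483648
  hi_a <- a %/% 2147483648
  x <- bitwXor(as.integer(lo_a), as.integer(b %% 2147483648))
  (hi_a + b %/% 2147483648) %% 2 * 2147483648 + (x %% 2147483648 + (x < 0) * 2147483648)
}

#' Path to a file shipped in the package's extdata directory
#' @keywords internal
medlineqc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "medlineqc")
  if (!nzchar(path)) stop("extdata file not found: ", file, call. = FALSE)
  path
}
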
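#' Extract a trailing e-mail address from an affiliation string
#'
#' NLM historically appended the first author's e-mail address to the end of
#' the Affiliation element. The extractor is deliberately conservative (one
#' token, \code{local@domain.tld}, optional trailing period stripped): the
#' address serves only as a cautionary discriminator, since placeholder
#' addresses such as \code{user@example.com} are common enough to poison any
#' disambiguation built on them.
#'
#' @param affiliation sanitized affiliation text (length 1, NA allowed).
#' @return list with \code{email} (character or NA) and \code{placeholder}
#'   (TRUE when the extracted address is \code{user@example.com}).
#' @examples
#' extract_email_from_affiliation("Dept X, Uni Y. jane.doe@uni.edu.")
#' @export
extract_email_from_affiliation <- function(affiliation) {
  out <- list(email = NA_character_, placeholder = FALSE)
  if (length(affiliation) != 1 || is.na(affiliation)) return(out)
  pat <- "([A-Za-z0-9._%+-]+@[A-Za-z0-9-]+(\\.[A-Za-z0-9-]+)*\\.[A-Za-z]{2,})\\.?$"
  m <- regmatches(affiliation, regexec(pat, affiliation, perl = TRUE))[[1]]
  if (length(m) >= 2) {
    out$email <- m[2]
    out$placeholder <- identical(m[2], "user@example.com")
  }
  out
}
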
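#' Flag structural anomalies in an author record
#'
#' MEDLINE author name fields suffer characteristic "value pollution":
#' collective (working-group) names entered as personal last names,
#' one-character last names from name-transposition errors, affiliations
#' concatenated into the forename, and degree/role text stuffed into the
#' suffix. Each check emits a flag; the thresholds that define "too long"
#' are configurable and monotone (raising a threshold never adds its flag).
#'
#' Flags: \code{single_char_last_name};
#' \code{suspected_collective_in_personal_field} (last name or forename with
#' at least \code{collective_words} space-separated words);
#' \code{forename_equals_affiliation_concat} (forename of at least
#' \code{forename_len} characters); \code{suffix_pollution} (suffix of at
#' least \code{suffix_len} characters); \code{initials_overlong} (initials
#' longer than \code{initials_len} characters).
#'
#' @param author an author record (list with \code{last_name},
#'   \code{fore_name}, \code{initials}, \code{suffix}; extra fields ignored).
#' @param collective_words,forename_len,suffix_len,initials_len thresholds.
#' @return character vector of zero or more flags.
#' @export
flag_author_anomalies <- function(author, collective_words = 8,
                                  forename_len = 100, suffix_len = 20,
                                  initials_len = 4) {
  flags <- character(0)
  ln <- author$last_name %||% NA_character_
  fn <- author$fore_name %||% NA_character_
  ini <- author$initials %||% NA_character_
  sfx <- author$suffix %||% NA_character_
  wc <- function(x) {
    if (is.na(x)) return(0L)
    length(Filter(nzchar, strsplit(x, " ", fixed = TRUE)[[1]]))
  }
  if (!is.na(ln) && nchar(ln) == 1) {
    flags <- c(flags, "single_char_last_name")
  }
  if (wc(ln) >= collective_words || wc(fn) >= collective_words) {
    flags <- c(flags, "suspected_collective_in_personal_field")
  }
  if (!is.na(fn) && nchar(fn) >= forename_len) {
    flags <- c(flags, "forename_equals_affiliation_concat")
  }
  if (!is.na(sfx) && nchar(sfx) >= suffix_len) {
    flags <- c(flags, "suffix_pollution")
  }
  if (!is.na(ini) && nchar(ini) > initials_len) {
    flags <- c(flags, "initials_overlong")
  }
  flags
}

#' Detect an ORCID shared by several authors of one article
#'
#' Publishers occasionally report the same ORCID for different co-authors.
#' Valid ORCIDs (lexically valid, not the all-zero placeholder) occurring at
#' two or more distinct author positions of the same article are grouped.
#'
#' @param article a parsed article (class \code{pm_article}) or any list with
#'   an \code{authors} field.
#' @return list of collisions, each a list with \code{orcid} and integer
#'   \code{positions}; empty list when all ORCIDs are distinct.
#' @export
detect_duplicate_orcid <- function(article) {
  authors <- article$authors
  if (length(authors) == 0) return(list())
  orcids <- vapply(authors, function(a) a$orcid_raw %||% NA_character_, "")
  pos <- vapply(authors, function(a) a$position %||% NA_integer_, 1L)
  ok <- !is.na(orcids) & !is.na(identifier_is_valid(orcids, "ORCID")) &
    identifier_is_valid(orcids, "ORCID") %in% TRUE
  if (!any(ok)) return(list())
  grp <- split(pos[ok], orcids[ok])
  grp <- lapply(grp, unique)
  grp <- grp[lengths(grp) >= 2]
  out <- lapply(names(grp), function(id) {
    list(orcid = id, positions = sort(grp[[id]]))
  })
  out[order(vapply(out, `[[`, "", "orcid"))]
}

#' Truncation sentinel phrases
#'
#' NLM data-entry policy truncated long abstracts (250 words, then 400
#' words, then a character limit), marking the cut with a parenthesised
#' sentinel at the end of the text. The shipped list can be replaced.
#'
#' @param path optional path to a replacement list (one sentinel per line).
#' @return character vector of sentinel phrases.
#' @export
truncation_sentinels <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.medlineqc_cache$sentinels)) {
      .medlineqc_cache$sentinels <-
        readLines(medlineqc_extdata("truncation_sentinels.txt"), encoding = "UTF-8")
    }
    return(.medlineqc_cache$sentinels)
  }
  readLines(path, encoding = "UTF-8")
}

#' Was an abstract truncated by data-entry policy?
#'
#' @param abstract abstract text (length 1, non-NA).
#' @param sentinels sentinel phrases, see [truncation_sentinels()].
#' @return TRUE iff the abstract ends with one of the sentinels.
#' @export
detect_truncated_abstract <- function(abstract, sentinels = truncation_sentinels()) {
  stopifnot(length(abstract) == 1, !is.na(abstract))
  any(vapply(sentinels, function(s) endsWith(abstract, s), logical(1)))
}
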
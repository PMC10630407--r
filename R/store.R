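# Corpus store: newline-delimited JSON records plus a tombstone list.
# Schema version 1: one JSON object per record line with the typed fields of
# pm_article plus provenance; arrays stay arrays, absent fields are null.

STORE_SCHEMA_VERSION <- 1L

record_to_json <- function(rec, provenance) {
  payload <- list(
    pmid = rec$pmid, version = rec$version, status = rec$status,
    date_revised = if (is.na(rec$date_revised)) NULL else
      format(rec$date_revised, "%Y-%m-%d"),
    title = rec$title, abstract = rec$abstract,
    copyright_info = rec$copyright_info,
    language_raw = I(rec$language_raw),
    pub_year_structured = rec$pub_year_structured,
    medline_date = rec$medline_date, doi = rec$doi,
    journal_nlm_id = rec$journal_nlm_id,
    publication_types = I(rec$publication_types),
    authors = lapply(rec$authors, function(a) {
      a <- unclass(a)
      a$affiliation_identifiers <- I(a$affiliation_identifiers)
      a
    }),
    references = lapply(rec$references, function(r) {
      r$article_ids <- I(r$article_ids)
      r
    }),
    provenance = provenance
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null", null = "null",
                   digits = NA)
}

chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
int1 <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)

record_from_json <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  rec <- structure(list(
    pmid = int1(x$pmid), version = int1(x$version), status = chr1(x$status),
    date_revised = if (is.null(x$date_revised)) as.Date(NA) else
      as.Date(x$date_revised),
    title = chr1(x$title), abstract = chr1(x$abstract),
    copyright_info = chr1(x$copyright_info),
    language_raw = vapply(x$language_raw, as.character, ""),
    pub_year_structured = int1(x$pub_year_structured),
    medline_date = chr1(x$medline_date), doi = chr1(x$doi),
    journal_nlm_id = chr1(x$journal_nlm_id),
    publication_types = vapply(x$publication_types, as.character, ""),
    authors = lapply(x$authors, function(a) {
      structure(list(
        position = int1(a$position), last_name = chr1(a$last_name),
        fore_name = chr1(a$fore_name), initials = chr1(a$initials),
        suffix = chr1(a$suffix), collective_name = chr1(a$collective_name),
        valid_yn = chr1(a$valid_yn),
        affiliation_first = chr1(a$affiliation_first),
        affiliation_count = int1(a$affiliation_count),
        orcid_raw = chr1(a$orcid_raw),
        affiliation_identifiers = lapply(a$affiliation_identifiers,
          function(id) list(scheme = chr1(id$scheme), value = chr1(id$value)))
      ), class = "pm_author")
    }),
    references = lapply(x$references, function(r) {
      list(citation_text = chr1(r$citation_text),
           article_ids = lapply(r$article_ids, function(id) {
             list(id_type = chr1(id$id_type), value = chr1(id$value))
           }),
           nesting_depth = int1(r$nesting_depth))
    })
  ), class = "pm_article")
  list(record = rec, provenance = x$provenance)
}

#' Write a corpus store
#'
#' Serializes an assembled corpus to a directory: \code{records.ndjson}
#' (one JSON object per record, carrying all typed fields plus provenance),
#' \code{tombstones.json} (deleted PMIDs) and \code{meta.json} (schema
#' version and record count). The store round-trips exactly through
#' [read_corpus()].
#'
#' @param corpus a \code{pm_corpus}.
#' @param path directory to write (created if needed).
#' @return invisibly, \code{path}.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "pm_corpus"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(names(corpus$records), function(key) {
    as.character(record_to_json(corpus$records[[key]],
                                corpus$provenance[[key]]))
  }, "")
  writeLines(lines, file.path(path, "records.ndjson"), useBytes = TRUE)
  jsonlite::write_json(corpus$tombstones, file.path(path, "tombstones.json"))
  jsonlite::write_json(list(schema_version = STORE_SCHEMA_VERSION,
                            n_records = length(corpus$records)),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a corpus store written by [write_corpus()]
#'
#' @param path store directory.
#' @return a \code{pm_corpus}.
#' @export
read_corpus <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  if (!identical(as.integer(meta$schema_version), STORE_SCHEMA_VERSION)) {
    stop("unsupported corpus store schema version: ", meta$schema_version,
         call. = FALSE)
  }
  corpus <- new_corpus()
  for (line in readLines(file.path(path, "records.ndjson"),
                         encoding = "UTF-8", warn = FALSE)) {
    got <- record_from_json(line)
    key <- as.character(got$record$pmid)
    corpus$records[[key]] <- got$record
    corpus$provenance[[key]] <- got$provenance
  }
  corpus$tombstones <- as.integer(
    jsonlite::fromJSON(file.path(path, "tombstones.json")))
  corpus
}
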
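#' Create an empty analysis corpus
#'
#' A corpus maps PMIDs to parsed article records, keeps per-record
#' provenance (source file and index), and tracks deleted PMIDs as
#' tombstones. Records and tombstones are disjoint at all times.
#'
#' @return an object of class \code{pm_corpus}.
#' @export
new_corpus <- function() {
  structure(list(records = list(), provenance = list(),
                 tombstones = integer(0), n_skipped_books = 0L,
                 n_parse_errors = 0L),
            class = "pm_corpus")
}

#' @export
print.pm_corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d record(s), %d tombstone(s)\n",
              length(x$records), length(x$tombstones)))
  invisible(x)
}

#' Number of records in a corpus
#' @param x a \code{pm_corpus}.
#' @return integer.
#' @export
corpus_size <- function(x) length(x$records)

# sortable revision key: NA DateRevised sorts as oldest
revision_key <- function(date) {
  if (length(date) == 0 || is.na(date)) -Inf else as.numeric(date)
}

#' Apply baseline or update slices to a corpus
#'
#' Baseline ingestion and update application share one rule: for each PMID
#' the retained record is the one with the newest DateRevised across
#' everything seen so far; a PMID never seen before is inserted. On equal
#' revision dates the slice processed later wins (later files are later
#' exports), and records without a DateRevised sort as oldest. The PMID
#' Version attribute is stored but never used as a merge key. An update for
#' a previously deleted PMID reinstates it.
#'
#' Book-article slices are counted and skipped; delete slices are ignored
#' here (see [apply_deletions()]). A slice that fails parsing is logged as
#' a warning and leaves the corpus unchanged for that PMID.
#'
#' @param corpus a \code{pm_corpus}.
#' @param slices list of \code{pm_slice} objects in (file, index) order.
#' @return the updated corpus.
#' @export
apply_updates <- function(corpus, slices) {
  stopifnot(inherits(corpus, "pm_corpus"))
  for (slice in slices) {
    if (slice$kind == "book_article") {
      corpus$n_skipped_books <- corpus$n_skipped_books + 1L
      next
    }
    if (slice$kind != "article") next
    rec <- tryCatch(parse_article(slice), error = function(e) {
      warning(warningCondition(
        sprintf("skipping unparseable record in %s[%d]: %s",
                slice$source_file, slice$source_index, conditionMessage(e)),
        class = "medlineqc_record_error"))
      NULL
    })
    if (is.null(rec)) {
      corpus$n_parse_errors <- corpus$n_parse_errors + 1L
      next
    }
    key <- as.character(rec$pmid)
    old <- corpus$records[[key]]
    if (is.null(old) ||
        revision_key(rec$date_revised) >= revision_key(old$date_revised)) {
      corpus$records[[key]] <- rec
      corpus$provenance[[key]] <- list(source_file = slice$source_file,
                                       source_index = slice$source_index)
      corpus$tombstones <- setdiff(corpus$tombstones, rec$pmid)
    }
  }
  corpus
}

#' Apply DeleteCitation slices to a corpus
#'
#' Listed PMIDs are removed from the records and added to the tombstone
#' set. Deleting a PMID that is not in the corpus is a no-op apart from a
#' warning (deletions can arrive for records outside the assembled window).
#'
#' @param corpus a \code{pm_corpus}.
#' @param deletions list of slices of kind \code{delete_citation}.
#' @return the updated corpus.
#' @export
apply_deletions <- function(corpus, deletions) {
  stopifnot(inherits(corpus, "pm_corpus"))
  for (slice in deletions) {
    if (slice$kind != "delete_citation") next
    key <- as.character(slice$pmid)
    if (is.null(corpus$records[[key]])) {
      warning(warningCondition(
        sprintf("deletion for absent PMID %d ignored", slice$pmid),
        class = "medlineqc_delete_warning"))
    } else {
      corpus$records[[key]] <- NULL
      corpus$provenance[[key]] <- NULL
    }
    corpus$tombstones <- union(corpus$tombstones, slice$pmid)
  }
  corpus
}

#' Replay a mixed stream of article and deletion slices
#'
#' Convenience fold used by the pipeline: slices are applied strictly in
#' the order given, updates inserting/replacing by newest DateRevised and
#' deletions tombstoning, so an update-then-delete sequence for one PMID
#' leaves it absent and delete-then-update reinstates it.
#'
#' @param corpus a \code{pm_corpus}.
#' @param slices list of slices of any kind, in (file, index) order.
#' @return the updated corpus.
#' @export
replay_slices <- function(corpus, slices) {
  for (slice in slices) {
    corpus <- if (slice$kind == "delete_citation") {
      apply_deletions(corpus, list(slice))
    } else {
      apply_updates(corpus, list(slice))
    }
  }
  corpus
}

#' Apply the study's record-selection filters
#'
#' The assessed subset keeps records whose citation Status is
#' \code{"MEDLINE"}, that are not news items (no publication type in
#' \code{news_types} — journalists with thousands of records skew author
#' aggregation), and that carry a non-empty title after sanitization. Each
#' excluded record is counted once under the first matching reason, in the
#' fixed order status, news, title, so the report is deterministic.
#'
#' @param corpus a \code{pm_corpus}.
#' @param news_types publication types treated as journalism.
#' @return list with \code{corpus} (filtered) and \code{report}, a
#'   \code{pm_selection_report} with fields \code{n_input},
#'   \code{n_status_excluded}, \code{n_news_excluded},
#'   \code{n_untitled_excluded}, \code{n_selected}.
#' @export
select_study_records <- function(corpus,
                                 news_types = c("News", "Newspaper Article")) {
  stopifnot(inherits(corpus, "pm_corpus"))
  report <- list(n_input = length(corpus$records), n_status_excluded = 0L,
                 n_news_excluded = 0L, n_untitled_excluded = 0L,
                 n_selected = 0L)
  keep <- logical(length(corpus$records))
  for (i in seq_along(corpus$records)) {
    rec <- corpus$records[[i]]
    if (!identical(rec$status, "MEDLINE")) {
      report$n_status_excluded <- report$n_status_excluded + 1L
    } else if (length(intersect(rec$publication_types, news_types)) > 0) {
      report$n_news_excluded <- report$n_news_excluded + 1L
    } else if (is.na(rec$title) || !nzchar(sanitize_text(rec$title))) {
      report$n_untitled_excluded <- report$n_untitled_excluded + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  report$n_selected <- sum(keep)
  class(report) <- "pm_selection_report"
  corpus$records <- corpus$records[keep]
  corpus$provenance <- corpus$provenance[names(corpus$records)]
  list(corpus = corpus, report = report)
}

#' @export
print.pm_selection_report <- function(x, ...) {
  cat(sprintf(paste0("<selection> input=%d selected=%d ",
                     "(excluded: status=%d news=%d untitled=%d)\n"),
              x$n_input, x$n_selected, x$n_status_excluded,
              x$n_news_excluded, x$n_untitled_excluded))
  invisible(x)
}

#' Article-level view of a corpus
#'
#' @param corpus a \code{pm_corpus}.
#' @return a tibble with one row per record: pmid, status, date_revised,
#'   title, abstract, copyright_info, language (raw values joined with
#'   \code{"|"} when a record carries several Language elements),
#'   pub_year_structured, medline_date, doi, journal_nlm_id,
#'   publication_types (list column), n_authors, n_references.
#' @export
corpus_articles <- function(corpus) {
  stopifnot(inherits(corpus, "pm_corpus"))
  recs <- corpus$records
  chr <- function(f) vapply(recs, function(r) r[[f]] %||% NA_character_, "")
  tibble::tibble(
    pmid = vapply(recs, `[[`, 1L, "pmid"),
    status = chr("status"),
    date_revised = as.Date(vapply(recs, function(r) as.numeric(r$date_revised),
                                  1.0), origin = "1970-01-01"),
    title = chr("title"),
    abstract = chr("abstract"),
    copyright_info = chr("copyright_info"),
    language = vapply(recs, function(r) {
      if (length(r$language_raw) == 0) NA_character_
      else paste(r$language_raw, collapse = "|")
    }, ""),
    pub_year_structured = vapply(recs, function(r)
      r$pub_year_structured %||% NA_integer_, 1L),
    medline_date = chr("medline_date"),
    doi = chr("doi"),
    journal_nlm_id = chr("journal_nlm_id"),
    publication_types = lapply(recs, `[[`, "publication_types"),
    n_authors = vapply(recs, function(r) length(r$authors), 1L),
    n_references = vapply(recs, function(r) length(r$references), 1L)
  )
}

#' Author-level view of a corpus
#'
#' @param corpus a \code{pm_corpus}.
#' @return a tibble with one row per extracted author: pmid, position,
#'   last_name, fore_name, initials, suffix, collective_name,
#'   affiliation_first, affiliation_count, orcid, isni, grid (first
#'   identifier of each scheme attached to the author's AffiliationInfo).
#' @export
corpus_authors <- function(corpus) {
  stopifnot(inherits(corpus, "pm_corpus"))
  rows <- lapply(corpus$records, function(rec) {
    if (length(rec$authors) == 0) return(NULL)
    first_id <- function(a, scheme) {
      for (id in a$affiliation_identifiers) {
        if (identical(id$scheme, scheme)) return(id$value)
      }
      NA_character_
    }
    tibble::tibble(
      pmid = rec$pmid,
      position = vapply(rec$authors, `[[`, 1L, "position"),
      last_name = vapply(rec$authors, function(a) a$last_name, ""),
      fore_name = vapply(rec$authors, function(a) a$fore_name, ""),
      initials = vapply(rec$authors, function(a) a$initials, ""),
      suffix = vapply(rec$authors, function(a) a$suffix, ""),
      collective_name = vapply(rec$authors, function(a) a$collective_name, ""),
      affiliation_first = vapply(rec$authors, function(a) a$affiliation_first, ""),
      affiliation_count = vapply(rec$authors, `[[`, 1L, "affiliation_count"),
      orcid = vapply(rec$authors, function(a) a$orcid_raw, ""),
      isni = vapply(rec$authors, first_id, "", scheme = "ISNI"),
      grid = vapply(rec$authors, first_id, "", scheme = "GRID")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      pmid = integer(0), position = integer(0), last_name = character(0),
      fore_name = character(0), initials = character(0), suffix = character(0),
      collective_name = character(0), affiliation_first = character(0),
      affiliation_count = integer(0), orcid = character(0),
      isni = character(0), grid = character(0))
  }
  out
}
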
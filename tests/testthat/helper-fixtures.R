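# Fixture builders and independent oracles shared across the suite.
# All fixtures are constructed in code; nothing binary is stored.

# Minimal PubmedArticle fragment with overridable parts.
article_xml <- function(pmid, title = "T", status = "MEDLINE",
                        date_revised = "2020-01-02", abstract = NULL,
                        copyright = NULL, year = 2020, medline_date = NULL,
                        languages = "eng", pub_types = "Journal Article",
                        nlm_id = "0401001", doi = NULL, authors = "",
                        references = "", extra_front = "") {
  pubdate <- if (!is.null(medline_date)) {
    sprintf("<MedlineDate>%s</MedlineDate>", medline_date)
  } else if (!is.null(year)) {
    sprintf("<Year>%d</Year>", year)
  } else ""
  dr <- if (!is.null(date_revised)) {
    d <- as.Date(date_revised)
    sprintf("<DateRevised><Year>%s</Year><Month>%s</Month><Day>%s</Day></DateRevised>",
            format(d, "%Y"), format(d, "%m"), format(d, "%d"))
  } else ""
  abs_xml <- if (!is.null(abstract) || !is.null(copyright)) {
    paste0("<Abstract>",
           if (!is.null(abstract))
             paste0("<AbstractText>", abstract, "</AbstractText>") else "",
           if (!is.null(copyright))
             paste0("<CopyrightInformation>", copyright,
                    "</CopyrightInformation>") else "",
           "</Abstract>")
  } else ""
  paste0(
    "<PubmedArticle><MedlineCitation Status=\"", status, "\">",
    sprintf("<PMID Version=\"1\">%d</PMID>", pmid), dr,
    "<Article><Journal><JournalIssue><PubDate>", pubdate,
    "</PubDate></JournalIssue></Journal>",
    if (!is.null(title)) paste0("<ArticleTitle>", title, "</ArticleTitle>") else "",
    abs_xml,
    if (nzchar(authors)) paste0("<AuthorList>", authors, "</AuthorList>") else "",
    paste0("<Language>", languages, "</Language>", collapse = ""),
    "<PublicationTypeList>",
    paste0("<PublicationType>", pub_types, "</PublicationType>", collapse = ""),
    "</PublicationTypeList>", extra_front, "</Article>",
    "<MedlineJournalInfo><NlmUniqueID>", nlm_id, "</NlmUniqueID></MedlineJournalInfo>",
    "</MedlineCitation>",
    if (nzchar(references) || !is.null(doi)) paste0(
      "<PubmedData>",
      if (!is.null(doi)) paste0("<ArticleIdList><ArticleId IdType=\"doi\">",
                                doi, "</ArticleId></ArticleIdList>") else "",
      references, "</PubmedData>") else "",
    "</PubmedArticle>")
}

author_xml <- function(last = "Wang", fore = "Wei", initials = "W",
                       suffix = NULL, validyn = "Y", collective = NULL,
                       affiliations = character(0), orcid = NULL,
                       aff_identifiers = "") {
  if (!is.null(collective)) {
    return(sprintf("<Author ValidYN=\"%s\"><CollectiveName>%s</CollectiveName></Author>",
                   validyn, collective))
  }
  affs <- paste0(vapply(affiliations, function(a) {
    paste0("<AffiliationInfo>", aff_identifiers,
           "<Affiliation>", a, "</Affiliation></AffiliationInfo>")
  }, ""), collapse = "")
  paste0("<Author ValidYN=\"", validyn, "\">",
         "<LastName>", last, "</LastName><ForeName>", fore, "</ForeName>",
         "<Initials>", initials, "</Initials>",
         if (!is.null(suffix)) paste0("<Suffix>", suffix, "</Suffix>") else "",
         if (!is.null(orcid)) paste0("<Identifier Source=\"ORCID\">", orcid,
                                     "</Identifier>") else "",
         affs, "</Author>")
}

# write fragments into a PubmedArticleSet file, return the path
write_set <- function(..., file = tempfile(fileext = ".xml")) {
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<PubmedArticleSet>", ..., "</PubmedArticleSet>"),
             file, useBytes = TRUE)
  file
}

delete_citation_xml <- function(pmids) {
  paste0("<DeleteCitation>",
         paste0("<PMID Version=\"1\">", pmids, "</PMID>", collapse = ""),
         "</DeleteCitation>")
}

slice_from_xml <- function(xml, pmid = 1L) {
  structure(list(pmid = as.integer(pmid), version = 1L, kind = "article",
                 raw_xml = xml, source_file = "fixture", source_index = 0L),
            class = "pm_slice")
}

# --- independent oracles ----------------------------------------------------

# brute-force quality metrics by direct set construction and division
bf_metrics <- function(values) {
  clean <- sanitize_text(values)
  present <- clean[!is.na(clean) & nzchar(clean)]
  n <- length(values); p <- length(present)
  list(n_records = n, n_missing = n - p, n_present = p,
       n_distinct = length(unique(present)),
       completeness = if (n > 0) p / n else NA_real_,
       uniqueness = if (p > 0) length(unique(present)) / p else NA_real_)
}

# brute-force merge: keep, per pmid, the row maximal by (date, arrival order),
# honouring deletions strictly in arrival order
bf_replay <- function(events) {
  # events: data.frame(pmid, kind, date (Date or NA), ord)
  kept <- list(); dead <- integer(0)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    key <- as.character(ev$pmid)
    if (ev$kind == "delete") {
      kept[[key]] <- NULL
      dead <- union(dead, ev$pmid)
    } else {
      old <- kept[[key]]
      newk <- if (is.na(ev$date)) -Inf else as.numeric(ev$date)
      oldk <- if (is.null(old)) NULL else
        if (is.na(old$date)) -Inf else as.numeric(old$date)
      if (is.null(old) || newk >= oldk) {
        kept[[key]] <- ev
        dead <- setdiff(dead, ev$pmid)
      }
    }
  }
  list(kept = kept, dead = sort(dead))
}
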
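#' Split a PubMed XML file into per-record slices
#'
#' Reads a PubMed-style XML file (plain or gzip-compressed) and yields one
#' slice per \code{PubmedArticle} or \code{PubmedBookArticle} child of the
#' \code{PubmedArticleSet} root, plus one \code{delete_citation} slice per
#' PMID listed inside a \code{DeleteCitation} element (update files carry at
#' most one such element). The file is consumed as a stream: a buffered
#' scanner locates record boundaries (these elements cannot self-nest under
#' the DTD, and a literal closing tag cannot occur inside escaped text), and
#' each fragment is parsed as XML on its own, so peak memory is bounded by
#' the largest single record, not by the file size.
#'
#' @param path path to the XML file (\code{.xml} or \code{.xml.gz}).
#' @param source_name name recorded in each slice; defaults to the file name.
#' @param callback optional \code{function(slice)} invoked per slice instead
#'   of accumulating them (bounded-memory mode for large files).
#' @return invisibly \code{NULL} when \code{callback} is given; otherwise a
#'   list of slices (class \code{pm_slice}), each with fields \code{pmid},
#'   \code{version}, \code{kind} (\code{article}, \code{book_article},
#'   \code{delete_citation}), \code{raw_xml}, \code{source_file},
#'   \code{source_index}.
#'
#' A record missing its PMID raises a warning of class
#' \code{medlineqc_record_error} naming the source index and is skipped;
#' malformed XML inside a fragment is a hard error naming the approximate
#' byte offset.
#' @export
split_records <- function(path, source_name = basename(path), callback = NULL) {
  con <- gzfile(path, open = "r", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  buf <- ""
  byte_offset <- 0            # file offset (uncompressed) of the buffer start
  slice_index <- 0L
  collect <- is.null(callback)
  slices <- if (collect) list()
  emit <- function(slice) {
    if (collect) slices[[length(slices) + 1L]] <<- slice else callback(slice)
  }
  open_pat <- "<(PubmedArticle|PubmedBookArticle|DeleteCitation)[ >]"
  eof <- FALSE
  repeat {
    if (!eof) {
      lines <- readLines(con, n = 2000L, warn = FALSE)
      if (length(lines) == 0) eof <- TRUE
      else buf <- paste0(buf, paste(lines, collapse = "\n"), "\n")
    }
    progressed <- FALSE
    repeat {
      m <- regexpr(open_pat, buf, perl = TRUE)
      if (m == -1) {
        # nothing openable; drop the buffer (root tags, prolog, spacing) but
        # keep a short tail in case a tag is split across a read boundary
        keep <- if (eof) 0L else 30L
        cut <- max(nchar(buf) - keep, 0L)
        byte_offset <- byte_offset + nchar(substr(buf, 1, cut), type = "bytes")
        buf <- substr(buf, cut + 1L, nchar(buf))
        break
      }
      elem <- sub("^<", "", sub("[ >]$", "", regmatches(buf, m)))
      close_tag <- paste0("</", elem, ">")
      cpos <- regexpr(close_tag, substr(buf, m, nchar(buf)), fixed = TRUE)
      if (cpos == -1) break   # need more input
      frag_end <- m + cpos + nchar(close_tag) - 2L
      fragment <- substr(buf, m, frag_end)
      frag_offset <- byte_offset + nchar(substr(buf, 1, m - 1L), type = "bytes")
      byte_offset <- byte_offset + nchar(substr(buf, 1, frag_end), type = "bytes")
      buf <- substr(buf, frag_end + 1L, nchar(buf))
      progressed <- TRUE
      for (s in fragment_slices(fragment, elem, source_name, frag_offset,
                                slice_index)) {
        slice_index <- slice_index + 1L
        emit(s)
      }
    }
    if (eof && !progressed) break
  }
  if (grepl(open_pat, buf, perl = TRUE)) {
    stop(sprintf("malformed XML in %s: unterminated record near byte offset %d",
                 source_name, byte_offset), call. = FALSE)
  }
  if (collect) slices else invisible(NULL)
}

# Turn one extracted fragment into zero or more slices.
fragment_slices <- function(fragment, elem, source_name, offset, index0) {
  doc <- tryCatch(
    xml2::read_xml(fragment),
    error = function(e) {
      stop(sprintf("malformed XML in %s near byte offset %d: %s",
                   source_name, offset, conditionMessage(e)), call. = FALSE)
    }
  )
  if (elem == "DeleteCitation") {
    pmids <- xml2::xml_text(xml2::xml_find_all(doc, "./PMID"))
    return(lapply(seq_along(pmids), function(i) {
      new_slice(as.integer(pmids[i]), 1L, "delete_citation", fragment,
                source_name, index0 + i - 1L)
    }))
  }
  kind <- if (elem == "PubmedArticle") "article" else "book_article"
  pmid_node <- xml2::xml_find_first(doc, ".//PMID")
  pmid <- suppressWarnings(as.integer(xml2::xml_text(pmid_node)))
  if (inherits(pmid_node, "xml_missing") || is.na(pmid)) {
    warning(warningCondition(
      sprintf("record without PMID in %s at index %d; skipped",
              source_name, index0),
      class = "medlineqc_record_error"))
    return(list())
  }
  version <- suppressWarnings(as.integer(xml2::xml_attr(pmid_node, "Version")))
  slice <- new_slice(pmid, if (is.na(version)) 1L else version, kind,
                     fragment, source_name, index0)
  attr(slice, "doc") <- doc
  list(slice)
}

new_slice <- function(pmid, version, kind, raw_xml, source_file, source_index) {
  structure(list(pmid = pmid, version = version, kind = kind,
                 raw_xml = raw_xml, source_file = source_file,
                 source_index = source_index),
            class = "pm_slice")
}

#' @export
print.pm_slice <- function(x, ...) {
  cat(sprintf("<slice %s pmid=%d v%d %s[%d]>\n", x$kind, x$pmid, x$version,
              x$source_file, x$source_index))
  invisible(x)
}

slice_doc <- function(slice) {
  attr(slice, "doc") %||% xml2::read_xml(slice$raw_xml)
}

txt_first <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) NA_character_ else sanitize_text(xml2::xml_text(n))
}

#' Parse one article slice into a typed record
#'
#' Populates the bibliographic fields from the MedlineCitation "front
#' matter" and the DOI from the PubmedData "back matter" ArticleId list.
#' Absent elements map to \code{NA}, never to an empty string. Structured
#' abstracts (several AbstractText sections) are concatenated in order,
#' separated by one space, with section labels dropped; inline markup in
#' titles and abstracts is flattened to its contained text.
#'
#' @param slice a slice of kind \code{article} from [split_records()].
#' @return a list of class \code{pm_article}: \code{pmid}, \code{version},
#'   \code{status}, \code{date_revised} (a \code{Date} or NA),
#'   \code{title}, \code{abstract}, \code{copyright_info},
#'   \code{language_raw} (character vector), \code{pub_year_structured},
#'   \code{medline_date}, \code{doi}, \code{journal_nlm_id},
#'   \code{publication_types}, \code{authors} (list of \code{pm_author}),
#'   \code{references}.
#' @export
parse_article <- function(slice) {
  stopifnot(inherits(slice, "pm_slice"))
  if (slice$kind != "article") {
    stop("parse_article requires a slice of kind 'article', got ", slice$kind,
         call. = FALSE)
  }
  doc <- slice_doc(slice)
  mc <- xml2::xml_find_first(doc, "./MedlineCitation")
  if (inherits(mc, "xml_missing")) {
    stop(sprintf("record %d lacks a MedlineCitation element", slice$pmid),
         call. = FALSE)
  }
  art <- xml2::xml_find_first(mc, "./Article")

  abstract <- NA_character_
  ab_nodes <- xml2::xml_find_all(mc, "./Article/Abstract/AbstractText")
  if (length(ab_nodes) > 0) {
    abstract <- sanitize_text(paste(vapply(ab_nodes, xml2::xml_text, ""),
                                    collapse = " "))
  }

  langs <- vapply(xml2::xml_find_all(mc, "./Article/Language"),
                  xml2::xml_text, "")

  year_txt <- txt_first(mc, "./Article/Journal/JournalIssue/PubDate/Year")
  rec <- structure(list(
    pmid = slice$pmid,
    version = slice$version,
    status = xml2::xml_attr(mc, "Status"),
    date_revised = parse_date_revised(mc, slice$pmid),
    title = txt_first(mc, "./Article/ArticleTitle"),
    abstract = abstract,
    copyright_info = txt_first(mc, "./Article/Abstract/CopyrightInformation"),
    language_raw = langs,
    pub_year_structured = suppressWarnings(as.integer(year_txt)),
    medline_date = txt_first(mc, "./Article/Journal/JournalIssue/PubDate/MedlineDate"),
    doi = txt_first(doc, "./PubmedData/ArticleIdList/ArticleId[@IdType='doi']"),
    journal_nlm_id = txt_first(mc, "./MedlineJournalInfo/NlmUniqueID"),
    publication_types = vapply(
      xml2::xml_find_all(mc, "./Article/PublicationTypeList/PublicationType"),
      xml2::xml_text, ""),
    authors = extract_authors(slice),
    references = flatten_references(slice)
  ), class = "pm_article")
  rec
}

parse_date_revised <- function(mc, pmid) {
  dr <- xml2::xml_find_first(mc, "./DateRevised")
  if (inherits(dr, "xml_missing")) return(as.Date(NA))
  y <- txt_first(dr, "./Year"); m <- txt_first(dr, "./Month"); d <- txt_first(dr, "./Day")
  if (any(is.na(c(y, m, d)))) {
    stop(sprintf("record %d has an incomplete DateRevised element", pmid),
         call. = FALSE)
  }
  as.Date(sprintf("%s-%02d-%02d", y, as.integer(m), as.integer(d)))
}

#' @export
print.pm_article <- function(x, ...) {
  cat(sprintf("<article %d [%s]> %d author(s), %d reference(s)\n  title: %s\n",
              x$pmid, x$status %||% "?", length(x$authors),
              length(x$references),
              if (is.na(x$title)) "<absent>" else substr(x$title, 1, 60)))
  invisible(x)
}

#' Extract the author list from an article slice
#'
#' Only Author entries with \code{ValidYN="Y"} (the attribute's default) are
#' kept; Investigator elements are never read. CollectiveName entries —
#' whether a CollectiveName child of an Author element or a bare
#' CollectiveName interleaved in the list — produce records with
#' \code{collective_name} set and the personal name parts absent, preserved
#' in document order (publishers intersperse groups and members, so a person
#' can legitimately appear once per group). Only the first Affiliation
#' element's text is stored; \code{affiliation_count} holds the total.
#' ORCID identifiers are taken from \code{Identifier[@Source="ORCID"]} on
#' the author, ISNI/GRID from Identifier elements on AffiliationInfo.
#'
#' @param slice a slice of kind \code{article}.
#' @return list of \code{pm_author} records with 1-based \code{position}.
#' @export
extract_authors <- function(slice) {
  doc <- slice_doc(slice)
  nodes <- xml2::xml_find_all(doc, "./MedlineCitation/Article/AuthorList/*")
  out <- list()
  for (node in nodes) {
    nm <- xml2::xml_name(node)
    if (nm == "Author") {
      validyn <- xml2::xml_attr(node, "ValidYN")
      if (identical(validyn, "N")) next
      coll <- txt_first(node, "./CollectiveName")
      affs <- xml2::xml_find_all(node, "./AffiliationInfo/Affiliation | ./Affiliation")
      aff_ids <- lapply(xml2::xml_find_all(node, "./AffiliationInfo/Identifier"),
                        function(idn) {
                          src <- xml2::xml_attr(idn, "Source")
                          list(scheme = if (src %in% c("ISNI", "GRID")) src else "other",
                               value = sanitize_text(xml2::xml_text(idn)))
                        })
      out[[length(out) + 1L]] <- structure(list(
        position = NA_integer_,
        last_name = if (is.na(coll)) txt_first(node, "./LastName") else NA_character_,
        fore_name = if (is.na(coll)) txt_first(node, "./ForeName") else NA_character_,
        initials = if (is.na(coll)) txt_first(node, "./Initials") else NA_character_,
        suffix = if (is.na(coll)) txt_first(node, "./Suffix") else NA_character_,
        collective_name = coll,
        valid_yn = "Y",
        affiliation_first = if (length(affs) > 0)
          sanitize_text(xml2::xml_text(affs[[1]])) else NA_character_,
        affiliation_count = length(affs),
        orcid_raw = txt_first(node, "./Identifier[@Source='ORCID']"),
        affiliation_identifiers = aff_ids
      ), class = "pm_author")
    } else if (nm == "CollectiveName") {
      out[[length(out) + 1L]] <- structure(list(
        position = NA_integer_, last_name = NA_character_,
        fore_name = NA_character_, initials = NA_character_,
        suffix = NA_character_,
        collective_name = sanitize_text(xml2::xml_text(node)),
        valid_yn = "Y", affiliation_first = NA_character_,
        affiliation_count = 0L, orcid_raw = NA_character_,
        affiliation_identifiers = list()
      ), class = "pm_author")
    }
    # anything else (Investigator decoys etc.) is ignored
  }
  for (i in seq_along(out)) out[[i]]$position <- i
  out
}

#' Flatten the reference lists of an article slice
#'
#' The DTD allows one ReferenceList with many Reference children, many
#' sibling ReferenceList elements with one Reference each, and arbitrarily
#' nested ReferenceList elements; all encodings occur in the wild and must
#' flatten identically. Every Reference at any depth appears exactly once,
#' in document order. \code{nesting_depth} counts the ReferenceList
#' ancestors beyond the outermost one, so a Reference directly inside a
#' top-level list has depth 0.
#'
#' @param slice a slice of kind \code{article}.
#' @return list of reference entries: \code{citation_text},
#'   \code{article_ids} (list of \code{(id_type, value)}),
#'   \code{nesting_depth}.
#' @export
flatten_references <- function(slice) {
  doc <- slice_doc(slice)
  refs <- xml2::xml_find_all(doc, "./PubmedData/ReferenceList//Reference")
  lapply(refs, function(ref) {
    depth <- length(xml2::xml_find_all(ref, "ancestor::ReferenceList")) - 1L
    ids <- lapply(xml2::xml_find_all(ref, "./ArticleIdList/ArticleId"),
                  function(idn) list(id_type = xml2::xml_attr(idn, "IdType"),
                                     value = xml2::xml_text(idn)))
    list(citation_text = txt_first(ref, "./Citation"),
         article_ids = ids,
         nesting_depth = depth)
  })
}

#' Serialize a parsed article back to PubMed-shaped XML
#'
#' Canonical serializer used for corpus round-trips: all typed fields of the
#' record are reproduced so that \code{parse_article(serialize_article(x))}
#' recovers them exactly. It is not byte-preserving — unread source content
#' is not reproduced, each reference is emitted in its own (possibly nested)
#' ReferenceList reproducing its recorded depth, and for authors with more
#' than one affiliation the first affiliation text is repeated to preserve
#' both \code{affiliation_first} and \code{affiliation_count}.
#'
#' @param record a \code{pm_article}.
#' @return a length-1 character string holding a \code{PubmedArticle}
#'   element.
#' @export
serialize_article <- function(record) {
  stopifnot(inherits(record, "pm_article"))
  e <- xml_escape
  out <- c(sprintf("<PubmedArticle><MedlineCitation Status=\"%s\">",
                   e(record$status %||% "MEDLINE")),
           sprintf("<PMID Version=\"%d\">%d</PMID>", record$version, record$pmid))
  if (!is.na(record$date_revised)) {
    out <- c(out, sprintf(
      "<DateRevised><Year>%s</Year><Month>%s</Month><Day>%s</Day></DateRevised>",
      format(record$date_revised, "%Y"), format(record$date_revised, "%m"),
      format(record$date_revised, "%d")))
  }
  pubdate <- if (!is.na(record$pub_year_structured)) {
    sprintf("<Year>%d</Year>", record$pub_year_structured)
  } else if (!is.na(record$medline_date)) {
    sprintf("<MedlineDate>%s</MedlineDate>", e(record$medline_date))
  } else ""
  out <- c(out, "<Article>",
           sprintf("<Journal><JournalIssue><PubDate>%s</PubDate></JournalIssue></Journal>",
                   pubdate))
  if (!is.na(record$title)) {
    out <- c(out, sprintf("<ArticleTitle>%s</ArticleTitle>", e(record$title)))
  }
  if (!is.na(record$abstract) || !is.na(record$copyright_info)) {
    out <- c(out, "<Abstract>")
    if (!is.na(record$abstract)) {
      out <- c(out, sprintf("<AbstractText>%s</AbstractText>", e(record$abstract)))
    }
    if (!is.na(record$copyright_info)) {
      out <- c(out, sprintf("<CopyrightInformation>%s</CopyrightInformation>",
                            e(record$copyright_info)))
    }
    out <- c(out, "</Abstract>")
  }
  if (length(record$authors) > 0) {
    out <- c(out, "<AuthorList>",
             vapply(record$authors, serialize_author, ""), "</AuthorList>")
  }
  for (lang in record$language_raw) {
    out <- c(out, sprintf("<Language>%s</Language>", e(lang)))
  }
  if (length(record$publication_types) > 0) {
    out <- c(out, "<PublicationTypeList>",
             sprintf("<PublicationType>%s</PublicationType>",
                     e(record$publication_types)),
             "</PublicationTypeList>")
  }
  out <- c(out, "</Article>")
  if (!is.na(record$journal_nlm_id)) {
    out <- c(out, sprintf(
      "<MedlineJournalInfo><NlmUniqueID>%s</NlmUniqueID></MedlineJournalInfo>",
      e(record$journal_nlm_id)))
  }
  out <- c(out, "</MedlineCitation>")
  back <- character(0)
  if (!is.na(record$doi)) {
    back <- c(back, sprintf(
      "<ArticleIdList><ArticleId IdType=\"doi\">%s</ArticleId></ArticleIdList>",
      e(record$doi)))
  }
  for (ref in record$references) {
    ids <- vapply(ref$article_ids, function(id) {
      sprintf("<ArticleId IdType=\"%s\">%s</ArticleId>", e(id$id_type), e(id$value))
    }, "")
    inner <- paste0(
      "<Reference>",
      if (!is.na(ref$citation_text))
        sprintf("<Citation>%s</Citation>", e(ref$citation_text)) else "",
      if (length(ids) > 0)
        paste0("<ArticleIdList>", paste(ids, collapse = ""), "</ArticleIdList>")
      else "",
      "</Reference>")
    depth <- ref$nesting_depth
    wrapped <- paste0(strrep("<ReferenceList>", depth + 1L), inner,
                      strrep("</ReferenceList>", depth + 1L))
    back <- c(back, wrapped)
  }
  if (length(back) > 0) {
    out <- c(out, "<PubmedData>", back, "</PubmedData>")
  }
  paste(c(out, "</PubmedArticle>"), collapse = "\n")
}

serialize_author <- function(a) {
  e <- xml_escape
  parts <- character(0)
  if (!is.na(a$collective_name)) {
    parts <- sprintf("<CollectiveName>%s</CollectiveName>", e(a$collective_name))
  } else {
    if (!is.na(a$last_name)) parts <- c(parts, sprintf("<LastName>%s</LastName>", e(a$last_name)))
    if (!is.na(a$fore_name)) parts <- c(parts, sprintf("<ForeName>%s</ForeName>", e(a$fore_name)))
    if (!is.na(a$initials)) parts <- c(parts, sprintf("<Initials>%s</Initials>", e(a$initials)))
    if (!is.na(a$suffix)) parts <- c(parts, sprintf("<Suffix>%s</Suffix>", e(a$suffix)))
  }
  if (!is.na(a$orcid_raw)) {
    parts <- c(parts, sprintf("<Identifier Source=\"ORCID\">%s</Identifier>",
                              e(a$orcid_raw)))
  }
  n_aff <- a$affiliation_count
  if (n_aff > 0 && !is.na(a$affiliation_first)) {
    id_xml <- vapply(a$affiliation_identifiers, function(id) {
      sprintf("<Identifier Source=\"%s\">%s</Identifier>", e(id$scheme), e(id$value))
    }, "")
    first <- paste0("<AffiliationInfo>",
                    paste(id_xml, collapse = ""),
                    sprintf("<Affiliation>%s</Affiliation>", e(a$affiliation_first)),
                    "</AffiliationInfo>")
    rest <- if (n_aff > 1) {
      paste(rep(sprintf("<AffiliationInfo><Affiliation>%s</Affiliation></AffiliationInfo>",
                        e(a$affiliation_first)), n_aff - 1L), collapse = "")
    } else ""
    parts <- c(parts, first, rest)
  }
  paste0("<Author ValidYN=\"Y\">", paste(parts, collapse = ""), "</Author>")
}
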
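# Synthetic PubMed-shaped corpus generation with pathology injection.
#
# The generator emits DTD-shaped PubmedArticle XML plus a ground-truth
# manifest of everything it injected, so the whole parse -> merge -> assess
# pipeline can be exercised and checked exactly without any download.

#' Default pathology injection rates
#'
#' One independent Bernoulli event per eligible record (or author) and
#' pathology. The defaults echo the relative prevalence of the documented
#' MEDLINE pathologies — placeholder affiliations and extended characters
#' are common, all-zero ORCIDs and missing titles are rare — without
#' claiming the production database's exact values.
#'
#' @return named numeric vector of probabilities.
#' @export
default_pathology_rates <- function() {
  c(narrative_affiliation = 0.01,
    punctuation_only_affiliation = 0.01,
    collective_in_lastname = 0.005,
    interleaved_collective_groups = 0.002,
    repeated_author_via_groups = 0.001,
    single_char_last_name = 0.005,
    forename_affiliation_concat = 0.001,
    suffix_pollution = 0.002,
    duplicate_orcid_in_article = 0.002,
    all_zero_orcid = 0.0005,
    invalid_orcid = 0.001,
    placeholder_email = 0.002,
    medline_date_span = 0.01,
    medline_date_erroneous = 0.002,
    concatenated_language_codes = 0.005,
    solitary_und_mul = 0.002,
    nested_reference_list = 0.05,
    many_singleton_reference_lists = 0.05,
    escape_characters = 0.02,
    extended_characters = 0.05,
    truncated_abstract_sentinel = 0.004,
    placeholder_abstract = 0.002,
    short_placeholder_title = 0.002,
    missing_title = 0.0003,
    news_publication_type = 0.001,
    non_medline_status = 0.05,
    dangling_journal = 0.005,
    invalid_author = 0.005,
    invalid_doi = 0.005)
}

#' Configuration for a synthetic corpus
#'
#' @param n_records number of article records to generate.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   corpus and manifest bit-for-bit.
#' @param records_per_file maximum records per emitted XML file.
#' @param pathology_rates named probabilities overriding
#'   [default_pathology_rates()] entries.
#' @param year_range inclusive range publication years are drawn from.
#' @param doi_rate_by_year \code{function(year)} giving the probability an
#'   article of that year carries a DOI; the default ramps linearly from
#'   0.10 at the start of \code{year_range} to 0.95 at its end, emulating
#'   the near-ubiquity of DOIs on recent records.
#' @param authors_per_record Poisson mean for the number of personal
#'   authors beyond the first.
#' @param orcid_rate,isni_rate,grid_rate per-author probabilities of
#'   carrying the identifier.
#' @param affiliation_rate per-author probability of an affiliation string.
#' @param abstract_rate probability a record has an abstract;
#'   \code{copyright_rate} applies to records with one.
#' @param n_journals,n_dangling_journals size of the journal pool and of
#'   the deliberately unreferenced (dangling) pool.
#' @return object of class \code{pm_synth_config}.
#' @export
synth_config <- function(n_records, seed = 1L, records_per_file = 30000L,
                         pathology_rates = list(),
                         year_range = c(1950L, 2022L),
                         doi_rate_by_year = NULL,
                         authors_per_record = 3,
                         orcid_rate = 0.03, isni_rate = 0.002,
                         grid_rate = 0.003, affiliation_rate = 0.6,
                         abstract_rate = 0.67, copyright_rate = 0.22,
                         n_journals = 50L, n_dangling_journals = 3L) {
  stopifnot(n_records >= 1, records_per_file >= 1,
            year_range[1] <= year_range[2])
  rates <- default_pathology_rates()
  if (length(pathology_rates) > 0) {
    unknown <- setdiff(names(pathology_rates), names(rates))
    if (length(unknown) > 0) {
      stop("unknown pathology rate(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    rates[names(pathology_rates)] <- unlist(pathology_rates)
  }
  if (any(rates < 0 | rates > 1)) {
    stop("pathology rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (is.null(doi_rate_by_year)) {
    y0 <- year_range[1]; y1 <- year_range[2]
    doi_rate_by_year <- function(year) {
      if (y1 == y0) return(0.7)
      0.10 + 0.85 * (year - y0) / (y1 - y0)
    }
  }
  structure(list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    records_per_file = as.integer(records_per_file),
    pathology_rates = rates, year_range = as.integer(year_range),
    doi_rate_by_year = doi_rate_by_year,
    authors_per_record = authors_per_record,
    orcid_rate = orcid_rate, isni_rate = isni_rate, grid_rate = grid_rate,
    affiliation_rate = affiliation_rate, abstract_rate = abstract_rate,
    copyright_rate = copyright_rate,
    n_journals = as.integer(n_journals),
    n_dangling_journals = as.integer(n_dangling_journals)
  ), class = "pm_synth_config")
}

# deterministic 31-bit per-record seed so injection decisions depend only on
# (corpus seed, record index), never on generation order
record_seed <- function(seed, i, stream = 0L) {
  as.integer((as.double(seed) * 1000003 + as.double(i) * 7919 +
                as.double(stream) * 104729) %% 2147483647)
}

# --- embedded filler vocabulary (no external corpora) -----------------------

.synth_surnames <- c("Wang", "Li", "Zhang", "Chen", "Liu", "Lee", "Kim",
  "Yang", "Wu", "Huang", "Smith", "Jones", "Brown", "Garcia", "Miller",
  "Davis", "Martinez", "Lopez", "Wilson", "Anderson", "Taylor", "Moore",
  "Jackson", "Thompson", "White", "Harris", "Clark", "Lewis", "Walker",
  "Hall", "Young", "King", "Scott", "Green", "Baker", "Adams", "Nelson")

.synth_forenames <- c("Wei", "Jing", "Yan", "Min", "Jun", "Ling", "John",
  "Mary", "James", "Anna", "Peter", "Laura", "David", "Sarah", "Michael",
  "Emma", "Robert", "Olivia", "Daniel", "Sophia", "Thomas", "Julia",
  "Andrew", "Nina", "Mark", "Elena", "Paul", "Alice", "Simon", "Clara")

.synth_title_words <- c("analysis", "of", "the", "effect", "clinical",
  "treatment", "patients", "with", "chronic", "disease", "novel",
  "approach", "study", "randomized", "trial", "gene", "expression",
  "protein", "cells", "cancer", "therapy", "outcomes", "risk", "factors",
  "association", "between", "response", "model", "data", "evaluation",
  "assessment", "cohort", "population", "health", "infection", "immune",
  "vaccine", "biomarkers", "imaging", "screening")

.synth_departments <- c("Medicine", "Biology", "Surgery", "Radiology",
  "Pathology", "Oncology", "Neurology", "Pediatrics", "Cardiology",
  "Epidemiology", "Genetics", "Immunology")

.synth_cities <- c("London", "Paris", "Boston", "Berlin", "Tokyo", "Madrid",
  "Oslo", "Toronto", "Sydney", "Vienna", "Geneva", "Dublin")

.synth_languages <- c("ger", "fre", "spa", "chi", "jpn", "rus", "ita", "pol")

.synth_collectives <- c(
  "Neonatal Screening Group Specialist Committee For Prevention And Control Of Birth Defects",
  "Working Group Of The International Society For Quality Assessment Of Bibliographic Data",
  "Expert Committee Of The Inter Laboratory Quality Assessment Consortium",
  "Consensus Group Of Experts On Application Of Sequencing In Clinical Diagnosis")

.synth_extended_cities <- c("İstanbul", "Göttingen", "Zürich",
                            "Malmö", "São Paulo")

sample1 <- function(x) x[sample.int(length(x), 1L)]

synth_sentence <- function(n_words) {
  words <- .synth_title_words[sample.int(length(.synth_title_words), n_words,
                                         replace = TRUE)]
  words[1] <- paste0(toupper(substr(words[1], 1, 1)), substr(words[1], 2, 99))
  paste0(paste(words, collapse = " "), ".")
}

synth_orcid <- function() {
  sprintf("0000-%04d-%04d-%04d", sample.int(10000, 1) - 1,
          sample.int(10000, 1) - 1, sample.int(10000, 1) - 1)
}

synth_affiliation <- function() {
  sprintf("Department of %s, University of %s, %s.",
          sample1(.synth_departments), sample1(.synth_cities),
          sample1(.synth_cities))
}

# --- per-record plan --------------------------------------------------------

# Draw one record's full content and injected pathologies. Everything the
# manifest needs is derived from the returned plan, so corpus and manifest
# cannot disagree.
synth_record_plan <- function(i, config, journals, revision = 0L) {
  set.seed(record_seed(config$seed, i, stream = revision))
  rates <- config$pathology_rates
  hit <- stats::runif(length(rates)) < rates
  names(hit) <- names(rates)

  # precedence for mutually exclusive injections (the loser is not injected
  # and therefore not recorded in the manifest)
  if (hit["solitary_und_mul"]) hit["concatenated_language_codes"] <- FALSE
  if (hit["missing_title"]) hit["short_placeholder_title"] <- FALSE
  if (hit["medline_date_erroneous"]) hit["medline_date_span"] <- FALSE
  if (hit["punctuation_only_affiliation"]) {
    hit["narrative_affiliation"] <- FALSE
    hit["extended_characters"] <- FALSE
    hit["placeholder_email"] <- FALSE
  } else if (hit["narrative_affiliation"]) {
    hit["extended_characters"] <- FALSE
  }

  plan <- list(pmid = i, pathologies = names(hit)[hit])
  plan$status <- if (hit["non_medline_status"]) {
    sample1(c("In-Process", "Publisher", "In-Data-Review", "PubMed-not-MEDLINE"))
  } else "MEDLINE"
  base_date <- as.Date("2015-01-01")
  plan$date_revised <- base_date + sample.int(2500, 1) +
    (if (revision > 0L) 2600L else 0L)

  yr <- config$year_range
  year <- sample(seq(yr[1], yr[2]), 1)
  if (hit["medline_date_erroneous"]) {
    form <- sample1(c("pagination_a", "pagination_b", "bare_digit"))
    plan$medline_date <- switch(form,
      pagination_a = sprintf("%d part 2): 1125–1132, Dec", year),
      pagination_b = sprintf("%d Suppl): 1035–15 August 1041", year),
      bare_digit = "1")
    plan$pub_year_structured <- NA_integer_
    plan$year_series <- if (form == "bare_digit") NA_integer_ else year
  } else if (hit["medline_date_span"]) {
    span <- sample.int(3, 1)
    plan$medline_date <- sprintf("%d Nov-%d Feb", year, year + span)
    plan$pub_year_structured <- NA_integer_
    plan$year_series <- year
  } else {
    plan$medline_date <- NA_character_
    plan$pub_year_structured <- year
    plan$year_series <- year
  }

  plan$title <- if (hit["missing_title"]) {
    NA_character_
  } else if (hit["short_placeholder_title"]) {
    sample1(c("[Not Available].", "Editorial.", "Reply."))
  } else {
    t <- synth_sentence(5 + sample.int(7, 1))
    if (hit["escape_characters"]) {
      t <- paste0(t, " \"quoted \\path\"\tend.")
    }
    t
  }

  has_abstract <- hit["placeholder_abstract"] ||
    hit["truncated_abstract_sentinel"] ||
    stats::runif(1) < config$abstract_rate
  plan$abstract <- if (!has_abstract) {
    NA_character_
  } else if (hit["placeholder_abstract"]) {
    "[Figure: see text]."
  } else {
    a <- paste(vapply(seq_len(2 + sample.int(3, 1)),
                      function(k) synth_sentence(8 + sample.int(10, 1)), ""),
               collapse = " ")
    if (hit["truncated_abstract_sentinel"]) {
      a <- paste(a, sample1(truncation_sentinels()))
    }
    a
  }
  plan$copyright <- if (has_abstract && !hit["placeholder_abstract"] &&
                        stats::runif(1) < config$copyright_rate) {
    sprintf("Copyright © %d Synthetic Press. All rights reserved.",
            max(year, 1999))
  } else NA_character_

  plan$languages <- if (hit["solitary_und_mul"]) {
    sample(c("und", "mul"), 1, prob = c(0.9, 0.1))
  } else if (hit["concatenated_language_codes"]) {
    paste(sample(.synth_languages, 2 + sample.int(2, 1) - 1), collapse = "")
  } else if (stats::runif(1) < 0.9) "eng" else sample1(.synth_languages)

  plan$publication_types <- c("Journal Article",
                              if (hit["news_publication_type"]) "News")

  plan$journal_nlm_id <- if (hit["dangling_journal"]) {
    sample1(journals$dangling)
  } else sample1(journals$reference)

  has_doi <- hit["invalid_doi"] ||
    stats::runif(1) < config$doi_rate_by_year(year)
  plan$doi <- if (!has_doi) {
    NA_character_
  } else if (hit["invalid_doi"]) {
    sprintf("doi:10.1/bad%d", i)
  } else {
    sprintf("10.%04d/synth.%d", 1000 + i %% 9000, i)
  }

  plan$authors <- synth_authors(i, config, hit)
  plan$references <- synth_references(hit)

  # expectations derivable only from the finished plan
  plan$selected <- identical(plan$status, "MEDLINE") &&
    !hit["news_publication_type"] && !is.na(plan$title) && nzchar(plan$title)
  orcids <- vapply(plan$authors$valid, function(a) a$orcid %||% NA_character_, "")
  plan$n_authors <- length(plan$authors$valid)
  plan$n_invalid_authors <- plan$authors$n_invalid
  plan$n_orcid <- sum(!is.na(orcids))
  plan$n_all_zero_orcid <- sum(orcids %in% ALL_ZERO_ORCID)
  valid_orcid <- identifier_is_valid(orcids, "ORCID") %in% TRUE
  plan$n_valid_orcid <- sum(valid_orcid)
  dup <- orcids[valid_orcid]
  plan$has_duplicate_orcid <- anyDuplicated(dup) > 0
  affs <- vapply(plan$authors$valid, function(a) a$affiliation %||% NA_character_, "")
  plan$n_affil_authors <- sum(!is.na(affs))
  plan$n_isni <- sum(vapply(plan$authors$valid,
                            function(a) !is.null(a$isni), logical(1)))
  plan$n_grid <- sum(vapply(plan$authors$valid,
                            function(a) !is.null(a$grid), logical(1)))
  plan
}

synth_authors <- function(i, config, hit) {
  n <- 1L + stats::rpois(1, config$authors_per_record)
  n <- min(max(n, 1L), 20L)
  if (hit["duplicate_orcid_in_article"]) n <- max(n, 4L)
  if (hit["collective_in_lastname"] || hit["invalid_orcid"]) n <- max(n, 2L)
  authors <- lapply(seq_len(n), function(k) {
    fore <- sample1(.synth_forenames)
    a <- list(last = sample1(.synth_surnames), fore = fore,
              initials = substr(fore, 1, 1), suffix = NULL,
              collective = NULL, orcid = NULL, isni = NULL, grid = NULL,
              affiliation = NULL, extra_affiliations = 0L)
    if (stats::runif(1) < config$affiliation_rate) {
      a$affiliation <- synth_affiliation()
    }
    if (stats::runif(1) < config$orcid_rate) a$orcid <- synth_orcid()
    if (stats::runif(1) < config$isni_rate) {
      a$isni <- sprintf("0000 0001 %04d %03dX", sample.int(10000, 1) - 1,
                        sample.int(1000, 1) - 1)
      if (is.null(a$affiliation)) a$affiliation <- synth_affiliation()
    }
    if (stats::runif(1) < config$grid_rate) {
      a$grid <- sprintf("grid.%d.%x", sample(10000:99999, 1),
                        sample.int(255, 1))
      if (is.null(a$affiliation)) a$affiliation <- synth_affiliation()
    }
    if (stats::runif(1) < 0.004) a$suffix <- sample1(c("Jr", "3rd", "2nd", "Sr"))
    a
  })

  if (hit["single_char_last_name"]) authors[[1]]$last <- sample1(LETTERS)
  if (hit["collective_in_lastname"]) {
    authors[[2]]$last <- sample1(.synth_collectives)
    authors[[2]]$fore <- NULL
    authors[[2]]$initials <- NULL
  }
  if (hit["forename_affiliation_concat"]) {
    authors[[1]]$fore <- paste(authors[[1]]$fore,
      "Department Of Radiology Synthetic Hospital College Of Medicine",
      "The Synthetic University Of Science Seoul Republic Of Korea",
      "Smart Imaging Center Synthetic Hospital College Of Medicine")
  }
  if (hit["suffix_pollution"]) {
    authors[[1]]$suffix <-
      "(Conceptualization; Review and editing; Approved final manuscript)"
  }
  if (hit["punctuation_only_affiliation"]) {
    authors[[1]]$affiliation <- sample1(c(".", ",."))
  } else if (hit["narrative_affiliation"]) {
    orgs <- vapply(seq_len(6), function(k) sub("\\.$", "", synth_affiliation()), "")
    authors[[1]]$affiliation <- paste0(
      "The authors are affiliated as follows: ",
      paste(orgs, collapse = "; "), ".")
  } else if (hit["extended_characters"]) {
    city <- sample1(.synth_extended_cities)
    authors[[1]]$affiliation <- sprintf(
      "Department of %s, University of %s, %s.",
      sample1(.synth_departments), city, city)
  }
  if (hit["placeholder_email"] && !hit["punctuation_only_affiliation"]) {
    base <- authors[[1]]$affiliation %||% synth_affiliation()
    authors[[1]]$affiliation <- paste(base, "user@example.com.")
  }
  if (hit["all_zero_orcid"]) authors[[1]]$orcid <- ALL_ZERO_ORCID
  if (hit["invalid_orcid"]) authors[[2]]$orcid <- "0000-0002-123"
  if (hit["duplicate_orcid_in_article"]) {
    shared <- synth_orcid()
    n <- length(authors)
    authors[[n - 1L]]$orcid <- shared
    authors[[n]]$orcid <- shared
  }

  collectives <- list()
  if (hit["interleaved_collective_groups"]) {
    collectives <- lapply(sample(.synth_collectives, 2), function(cn) {
      list(collective = cn)
    })
  }
  if (hit["repeated_author_via_groups"]) {
    person <- list(last = sample1(.synth_surnames),
                   fore = sample1(.synth_forenames))
    person$initials <- substr(person$fore, 1, 1)
    reps <- list()
    for (g in sample(.synth_collectives, 3)) {
      reps <- c(reps, list(list(collective = g)), list(person))
    }
    collectives <- c(collectives, reps)
  }

  invalid <- if (hit["invalid_author"]) {
    list(list(last = sample1(.synth_surnames), fore = sample1(.synth_forenames),
              initials = "X", validyn = "N"))
  } else list()

  list(valid = c(authors, collectives), invalid = invalid,
       n_invalid = length(invalid))
}

synth_references <- function(hit) {
  refs <- list()
  n_base <- sample.int(5, 1) - 1L
  if (n_base > 0) {
    refs <- lapply(seq_len(n_base), function(k) {
      list(text = synth_sentence(6 + sample.int(4, 1)), depth = 0L,
           style = "grouped")
    })
  }
  if (hit["many_singleton_reference_lists"]) {
    refs <- c(refs, lapply(seq_len(5), function(k) {
      list(text = synth_sentence(6), depth = 0L, style = "singleton")
    }))
  }
  if (hit["nested_reference_list"]) {
    refs <- c(refs, list(list(text = synth_sentence(6),
                              depth = sample.int(3, 1), style = "nested")))
  }
  refs
}

# --- plan -> XML ------------------------------------------------------------

synth_record_xml <- function(plan) {
  e <- xml_escape
  out <- c(sprintf("<PubmedArticle><MedlineCitation Status=\"%s\">", plan$status),
           sprintf("<PMID Version=\"1\">%d</PMID>", plan$pmid),
           sprintf("<DateRevised><Year>%s</Year><Month>%s</Month><Day>%s</Day></DateRevised>",
                   format(plan$date_revised, "%Y"),
                   format(plan$date_revised, "%m"),
                   format(plan$date_revised, "%d")),
           "<Article PubModel=\"Print\">")
  pd <- if (!is.na(plan$pub_year_structured)) {
    sprintf("<Year>%d</Year><Month>01</Month>", plan$pub_year_structured)
  } else {
    sprintf("<MedlineDate>%s</MedlineDate>", e(plan$medline_date))
  }
  out <- c(out, sprintf(paste0(
    "<Journal><ISSN IssnType=\"Print\">0000-000%d</ISSN>",
    "<JournalIssue CitedMedium=\"Print\"><PubDate>%s</PubDate></JournalIssue>",
    "<Title>Journal of Synthetic Medicine</Title></Journal>"),
    plan$pmid %% 10, pd))
  if (!is.na(plan$title)) {
    out <- c(out, sprintf("<ArticleTitle>%s</ArticleTitle>", e(plan$title)))
  }
  # decoy the parser must skip
  out <- c(out, "<Pagination><MedlinePgn>1-10</MedlinePgn></Pagination>")
  if (!is.na(plan$abstract) || !is.na(plan$copyright)) {
    out <- c(out, "<Abstract>")
    if (!is.na(plan$abstract)) {
      out <- c(out, sprintf("<AbstractText>%s</AbstractText>", e(plan$abstract)))
    }
    if (!is.na(plan$copyright)) {
      out <- c(out, sprintf("<CopyrightInformation>%s</CopyrightInformation>",
                            e(plan$copyright)))
    }
    out <- c(out, "</Abstract>")
  }
  entries <- c(lapply(plan$authors$valid, synth_author_xml),
               lapply(plan$authors$invalid, synth_author_xml))
  out <- c(out, "<AuthorList CompleteYN=\"Y\">", unlist(entries), "</AuthorList>")
  out <- c(out, sprintf("<Language>%s</Language>", e(plan$languages)))
  out <- c(out, "<PublicationTypeList>",
           sprintf("<PublicationType UI=\"D016428\">%s</PublicationType>",
                   e(plan$publication_types)),
           "</PublicationTypeList>", "</Article>",
           sprintf(paste0("<MedlineJournalInfo><Country>Synthetic</Country>",
                          "<NlmUniqueID>%s</NlmUniqueID></MedlineJournalInfo>"),
                   e(plan$journal_nlm_id)),
           "<CitationSubset>IM</CitationSubset>",
           "</MedlineCitation>")
  back <- character(0)
  if (!is.na(plan$doi)) {
    back <- c(back, sprintf(paste0(
      "<ArticleIdList><ArticleId IdType=\"pubmed\">%d</ArticleId>",
      "<ArticleId IdType=\"doi\">%s</ArticleId></ArticleIdList>"),
      plan$pmid, e(plan$doi)))
  }
  grouped <- Filter(function(r) r$style == "grouped", plan$references)
  if (length(grouped) > 0) {
    back <- c(back, "<ReferenceList>",
              vapply(grouped, function(r) {
                sprintf("<Reference><Citation>%s</Citation></Reference>",
                        e(r$text))
              }, ""), "</ReferenceList>")
  }
  for (r in Filter(function(r) r$style != "grouped", plan$references)) {
    inner <- sprintf("<Reference><Citation>%s</Citation></Reference>", e(r$text))
    back <- c(back, paste0(strrep("<ReferenceList>", r$depth + 1L), inner,
                           strrep("</ReferenceList>", r$depth + 1L)))
  }
  if (length(back) > 0) out <- c(out, "<PubmedData>", back, "</PubmedData>")
  paste(c(out, "</PubmedArticle>"), collapse = "\n")
}

synth_author_xml <- function(a) {
  e <- xml_escape
  validyn <- a$validyn %||% "Y"
  if (!is.null(a$collective)) {
    return(sprintf("<Author ValidYN=\"%s\"><CollectiveName>%s</CollectiveName></Author>",
                   validyn, e(a$collective)))
  }
  parts <- sprintf("<LastName>%s</LastName>", e(a$last))
  if (!is.null(a$fore)) parts <- c(parts, sprintf("<ForeName>%s</ForeName>", e(a$fore)))
  if (!is.null(a$initials)) parts <- c(parts, sprintf("<Initials>%s</Initials>", e(a$initials)))
  if (!is.null(a$suffix)) parts <- c(parts, sprintf("<Suffix>%s</Suffix>", e(a$suffix)))
  if (!is.null(a$orcid)) {
    parts <- c(parts, sprintf("<Identifier Source=\"ORCID\">%s</Identifier>",
                              e(a$orcid)))
  }
  if (!is.null(a$affiliation)) {
    ids <- character(0)
    if (!is.null(a$isni)) {
      ids <- c(ids, sprintf("<Identifier Source=\"ISNI\">%s</Identifier>", e(a$isni)))
    }
    if (!is.null(a$grid)) {
      ids <- c(ids, sprintf("<Identifier Source=\"GRID\">%s</Identifier>", e(a$grid)))
    }
    parts <- c(parts, paste0("<AffiliationInfo>", paste(ids, collapse = ""),
                             sprintf("<Affiliation>%s</Affiliation>", e(a$affiliation)),
                             "</AffiliationInfo>"))
  }
  paste0(sprintf("<Author ValidYN=\"%s\">", validyn),
         paste(parts, collapse = ""), "</Author>")
}

synth_journal_pools <- function(config) {
  list(reference = sprintf("10%05d", seq_len(config$n_journals)),
       dangling = sprintf("99%05d", seq_len(config$n_dangling_journals)))
}

# --- top-level generation ---------------------------------------------------

#' Generate a synthetic corpus with a ground-truth manifest
#'
#' Writes well-formed PubmedArticleSet XML files of at most
#' \code{records_per_file} records each and returns a manifest recording,
#' per record, every injected pathology and the expected downstream
#' quantities (selection outcome, identifier counts, publication year).
#' Each pathology is an independent Bernoulli event per record; a handful
#' of mutually exclusive injections resolve by fixed precedence, and only
#' what was actually injected is recorded. The same configuration and seed
#' reproduce files and manifest bit-for-bit.
#'
#' @param config a [synth_config()].
#' @param out_dir directory to write XML files into (created if needed).
#' @return list with \code{files} (paths in order) and \code{manifest}
#'   (class \code{pm_manifest}: \code{records} tibble, \code{counts} named
#'   vector of injected-pathology counts, \code{n_eligible},
#'   \code{journals}, \code{config}).
#' @export
generate_corpus <- function(config, out_dir) {
  stopifnot(inherits(config, "pm_synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  journals <- synth_journal_pools(config)
  plans <- lapply(seq_len(config$n_records), synth_record_plan,
                  config = config, journals = journals)
  files <- write_plan_files(plans, out_dir, "synthetic-baseline", config)
  manifest <- build_manifest(plans, journals, config)
  list(files = files, manifest = manifest)
}

write_plan_files <- function(plans, out_dir, stem, config) {
  n <- length(plans)
  starts <- seq(1, n, by = config$records_per_file)
  files <- character(0)
  for (fi in seq_along(starts)) {
    idx <- starts[fi]:min(starts[fi] + config$records_per_file - 1L, n)
    path <- file.path(out_dir, sprintf("%s-%03d.xml", stem, fi))
    body <- vapply(plans[idx], synth_record_xml, "")
    writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
                 "<PubmedArticleSet>", body, "</PubmedArticleSet>"),
               path, useBytes = TRUE)
    files <- c(files, path)
  }
  files
}

build_manifest <- function(plans, journals, config) {
  g <- function(f, proto) vapply(plans, function(p) p[[f]] %||% proto, proto)
  records <- tibble::tibble(
    pmid = g("pmid", 1L),
    status = g("status", ""),
    selected = g("selected", TRUE),
    has_title = vapply(plans, function(p) !is.na(p$title) && nzchar(p$title),
                       TRUE),
    is_news = vapply(plans, function(p)
      "news_publication_type" %in% p$pathologies, TRUE),
    year_series = g("year_series", 1L),
    medline_date = g("medline_date", ""),
    journal_nlm_id = g("journal_nlm_id", ""),
    journal_dangling = vapply(plans, function(p)
      p$journal_nlm_id %in% journals$dangling, TRUE),
    doi = g("doi", ""),
    doi_valid = identifier_is_valid(g("doi", ""), "DOI") %in% TRUE,
    abstract_present = vapply(plans, function(p) !is.na(p$abstract), TRUE),
    truncated_abstract = vapply(plans, function(p)
      "truncated_abstract_sentinel" %in% p$pathologies, TRUE),
    language = g("languages", ""),
    solitary_und_mul = vapply(plans, function(p)
      "solitary_und_mul" %in% p$pathologies, TRUE),
    n_authors = g("n_authors", 1L),
    n_invalid_authors = g("n_invalid_authors", 1L),
    n_orcid = g("n_orcid", 1L),
    n_valid_orcid = g("n_valid_orcid", 1L),
    n_all_zero_orcid = g("n_all_zero_orcid", 1L),
    has_duplicate_orcid = g("has_duplicate_orcid", TRUE),
    n_affil_authors = g("n_affil_authors", 1L),
    n_isni = g("n_isni", 1L),
    n_grid = g("n_grid", 1L),
    pathologies = lapply(plans, `[[`, "pathologies")
  )
  counts <- vapply(names(config$pathology_rates), function(nm) {
    sum(vapply(records$pathologies, function(p) nm %in% p, TRUE))
  }, 1L)
  structure(list(records = records, counts = counts,
                 n_eligible = length(plans), journals = journals,
                 config = config),
            class = "pm_manifest")
}

#' @export
print.pm_manifest <- function(x, ...) {
  cat(sprintf("<manifest> %d record(s), %d pathology type(s) injected\n",
              nrow(x$records), sum(x$counts > 0)))
  invisible(x)
}

#' Generate one synthetic update file against an existing corpus
#'
#' Emits revised versions of existing records (with a strictly newer
#' DateRevised), brand-new records, and a DeleteCitation block, all in one
#' file — the shape of a PubMed daily update. Revised, added and deleted
#' PMIDs are disjoint. The returned delta states the expected post-merge
#' corpus: revised rows replace their originals, added rows append,
#' deleted PMIDs move to the tombstone set.
#'
#' @param config the [synth_config()] used for the baseline.
#' @param manifest the baseline manifest.
#' @param out_file path of the update XML file to write.
#' @param n_revise,n_add,n_delete batch composition.
#' @return list with \code{file}, \code{revised_pmids}, \code{added_pmids},
#'   \code{deleted_pmids} and \code{expected_records} (manifest-style
#'   tibble of the expected post-merge corpus).
#' @export
generate_update_batch <- function(config, manifest, out_file,
                                  n_revise = 5L, n_add = 3L, n_delete = 2L) {
  stopifnot(inherits(manifest, "pm_manifest"))
  pmids <- manifest$records$pmid
  if (n_revise + n_delete > length(pmids)) {
    stop("update batch larger than the corpus", call. = FALSE)
  }
  set.seed(record_seed(config$seed, 0L, stream = 500L))
  revise <- sort(sample(pmids, n_revise))
  del <- sort(sample(setdiff(pmids, revise), n_delete))
  add <- max(pmids) + seq_len(n_add)
  journals <- manifest$journals
  plans <- c(lapply(revise, synth_record_plan, config = config,
                    journals = journals, revision = 1L),
             lapply(add, synth_record_plan, config = config,
                    journals = journals, revision = 0L))
  body <- vapply(plans, synth_record_xml, "")
  del_xml <- if (n_delete > 0) {
    c("<DeleteCitation>", sprintf("<PMID Version=\"1\">%d</PMID>", del),
      "</DeleteCitation>")
  } else character(0)
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<PubmedArticleSet>", body, del_xml, "</PubmedArticleSet>"),
             out_file, useBytes = TRUE)
  delta_manifest <- build_manifest(plans, journals, config)
  old <- manifest$records[!(manifest$records$pmid %in% c(revise, del)), ]
  expected <- dplyr::arrange(dplyr::bind_rows(old, delta_manifest$records),
                             pmid)
  list(file = out_file, revised_pmids = revise, added_pmids = add,
       deleted_pmids = del, expected_records = expected,
       batch_records = delta_manifest$records)
}

#' Write a journal reference file for a synthetic corpus
#'
#' Emits the NLM journal-list format (blocks of \code{Key: value} lines
#' separated by dashed lines) for the corpus's journal pool. The dangling
#' pool is never written — those identifiers are the deliberate referential
#' integrity gaps — and an optional extra fraction of genuinely used
#' journals can be omitted on top.
#'
#' @param manifest a baseline manifest.
#' @param path file to write.
#' @param extra_omit_fraction fraction of the reference pool to omit in
#'   addition to the dangling pool.
#' @return list with \code{path}, \code{written} and \code{omitted}
#'   (NlmIds absent from the file).
#' @export
generate_journal_reference <- function(manifest, path,
                                       extra_omit_fraction = 0) {
  stopifnot(inherits(manifest, "pm_manifest"),
            extra_omit_fraction >= 0, extra_omit_fraction <= 1)
  pool <- manifest$journals$reference
  extra <- character(0)
  if (extra_omit_fraction > 0) {
    set.seed(record_seed(manifest$config$seed, 0L, stream = 900L))
    n_extra <- floor(length(pool) * extra_omit_fraction)
    if (n_extra > 0) extra <- sort(sample(pool, n_extra))
  }
  written <- setdiff(pool, extra)
  blocks <- vapply(seq_along(written), function(i) {
    paste(c(strrep("-", 56),
            sprintf("JrId: %d", i),
            sprintf("JournalTitle: Journal of Synthetic Medicine %d", i),
            sprintf("MedAbbr: J Synth Med %d", i),
            sprintf("ISSN (Print): %04d-%04d", i, i + 1L),
            sprintf("NlmId: %s", written[i])), collapse = "\n")
  }, "")
  writeLines(c(blocks, strrep("-", 56)), path, useBytes = TRUE)
  list(path = path, written = written,
       omitted = sort(c(manifest$journals$dangling, extra)))
}
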
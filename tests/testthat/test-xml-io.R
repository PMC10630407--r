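test_that("splitting yields one slice per article child", {
  f <- write_set(article_xml(1), article_xml(2), article_xml(3))
  slices <- split_records(f)
  expect_length(slices, 3)
  expect_true(all(vapply(slices, `[[`, "", "kind") == "article"))
  expect_identical(vapply(slices, `[[`, 1L, "pmid"), 1:3)
})

test_that("DeleteCitation PMIDs become delete slices alongside articles", {
  f <- write_set(article_xml(1), article_xml(2), delete_citation_xml(c(10, 11)))
  slices <- split_records(f)
  kinds <- vapply(slices, `[[`, "", "kind")
  expect_identical(sum(kinds == "article"), 2L)
  expect_identical(sum(kinds == "delete_citation"), 2L)
  expect_setequal(vapply(slices[kinds == "delete_citation"], `[[`, 1L, "pmid"),
                  c(10L, 11L))
})

test_that("gzip-compressed input splits identically to plain input", {
  plain <- write_set(article_xml(1), article_xml(2))
  gz <- tempfile(fileext = ".xml.gz")
  con <- gzfile(gz, "wb")
  writeLines(readLines(plain), con)
  close(con)
  expect_identical(
    lapply(split_records(plain, source_name = "x"), unclass),
    lapply(split_records(gz, source_name = "x"), unclass))
})

test_that("callback streaming mode delivers the same slices as collection", {
  f <- write_set(article_xml(1), article_xml(2), delete_citation_xml(5))
  got <- list()
  split_records(f, callback = function(s) got[[length(got) + 1L]] <<- s)
  expect_identical(lapply(got, unclass),
                   lapply(split_records(f), unclass))
})

test_that("a record without a PMID is skipped with a record-level warning", {
  broken <- "<PubmedArticle><MedlineCitation Status=\"MEDLINE\"></MedlineCitation></PubmedArticle>"
  f <- write_set(article_xml(1), broken)
  expect_warning(slices <- split_records(f), class = "medlineqc_record_error")
  expect_length(slices, 1)
})

test_that("parsing populates front-matter fields and absent maps to NA", {
  f <- write_set(article_xml(1, title = "T", abstract = NULL))
  rec <- parse_article(split_records(f)[[1]])
  expect_identical(rec$pmid, 1L)
  expect_identical(rec$title, "T")
  expect_true(is.na(rec$abstract))
  expect_true(is.na(rec$doi))
  expect_identical(rec$status, "MEDLINE")
})

test_that("the DOI comes from the back-matter ArticleId list", {
  f <- write_set(article_xml(7, doi = "10.1093/database/baad070"))
  rec <- parse_article(split_records(f)[[1]])
  expect_identical(rec$doi, "10.1093/database/baad070")
})

test_that("a MedlineDate-only PubDate leaves the structured year absent", {
  f <- write_set(article_xml(9, year = NULL, medline_date = "1946 May–June"))
  rec <- parse_article(split_records(f)[[1]])
  expect_true(is.na(rec$pub_year_structured))
  expect_identical(rec$medline_date, "1946 May–June")
})

test_that("structured abstracts concatenate sections with single spaces", {
  xml <- article_xml(3, abstract = NULL, extra_front = "")
  xml <- sub("<Article>", paste0(
    "<Article><Abstract>",
    "<AbstractText Label=\"BACKGROUND\">First part.</AbstractText>",
    "<AbstractText Label=\"METHODS\">Second part.</AbstractText>",
    "</Abstract>"), xml)
  # the injected Abstract sits before Journal; parser finds it by path, not order
  rec <- parse_article(slice_from_xml(xml, 3))
  expect_identical(rec$abstract, "First part. Second part.")
})

test_that("authors with ValidYN=N are excluded and order is preserved", {
  f <- write_set(article_xml(1, authors = paste0(
    author_xml(last = "Alpha"), author_xml(last = "Bad", validyn = "N"),
    author_xml(last = "Beta"))))
  authors <- extract_authors(split_records(f)[[1]])
  expect_length(authors, 2)
  expect_identical(vapply(authors, `[[`, "", "last_name"), c("Alpha", "Beta"))
  expect_identical(vapply(authors, `[[`, 1L, "position"), 1:2)
})

test_that("a member listed under many interleaved groups appears once per group", {
  # consortium pattern: the same personal name after each collective entry
  groups <- paste0(vapply(seq_len(12), function(g) {
    paste0(author_xml(collective = sprintf("Group %02d", g)),
           author_xml(last = "Appels", fore = "Rudi", initials = "R"))
  }, ""), collapse = "")
  f <- write_set(article_xml(1, authors = groups))
  authors <- extract_authors(split_records(f)[[1]])
  personal <- Filter(function(a) !is.na(a$last_name), authors)
  expect_length(authors, 24)
  expect_length(personal, 12)
  expect_true(all(vapply(personal, `[[`, "", "last_name") == "Appels"))
})

test_that("only the first affiliation is stored but all are counted", {
  f <- write_set(article_xml(1, authors = author_xml(
    affiliations = c("First University.", "Second University.", "Third."))))
  a <- extract_authors(split_records(f)[[1]])[[1]]
  expect_identical(a$affiliation_first, "First University.")
  expect_identical(a$affiliation_count, 3L)
})

test_that("ORCID and affiliation identifiers land in their fields", {
  f <- write_set(article_xml(1, authors = author_xml(
    orcid = "0000-0002-5696-5368", affiliations = "Uni.",
    aff_identifiers = paste0(
      "<Identifier Source=\"ISNI\">0000 0001 2345 678X</Identifier>",
      "<Identifier Source=\"GRID\">grid.12345.0f</Identifier>"))))
  a <- extract_authors(split_records(f)[[1]])[[1]]
  expect_identical(a$orcid_raw, "0000-0002-5696-5368")
  schemes <- vapply(a$affiliation_identifiers, `[[`, "", "scheme")
  expect_setequal(schemes, c("ISNI", "GRID"))
})

test_that("extracted author count matches a direct XPath count oracle", {
  set.seed(11)
  for (k in 1:8) {
    n_ok <- sample(0:5, 1); n_bad <- sample(0:2, 1); n_coll <- sample(0:2, 1)
    parts <- c(replicate(n_ok, author_xml(last = "Ok")),
               replicate(n_bad, author_xml(last = "No", validyn = "N")),
               replicate(n_coll, author_xml(collective = "Grp")))
    authors <- paste0(sample(parts), collapse = "")
    f <- write_set(article_xml(1, authors = authors))
    slice <- split_records(f)[[1]]
    doc <- xml2::read_xml(slice$raw_xml)
    oracle <- length(xml2::xml_find_all(
      doc, "./MedlineCitation/Article/AuthorList/Author[not(@ValidYN='N')]"))
    expect_length(extract_authors(slice), oracle)
  }
})

test_that("both ReferenceList encodings flatten to the same citation sequence", {
  refs <- sprintf("<Reference><Citation>R%d</Citation></Reference>", 1:5)
  one_list <- paste0("<ReferenceList>", paste(refs, collapse = ""),
                     "</ReferenceList>")
  many_lists <- paste0(sprintf("<ReferenceList>%s</ReferenceList>", refs),
                       collapse = "")
  f1 <- write_set(article_xml(1, references = one_list))
  f2 <- write_set(article_xml(1, references = many_lists))
  r1 <- flatten_references(split_records(f1)[[1]])
  r2 <- flatten_references(split_records(f2)[[1]])
  expect_length(r1, 5)
  expect_identical(vapply(r1, `[[`, "", "citation_text"),
                   vapply(r2, `[[`, "", "citation_text"))
  expect_true(all(vapply(r1, `[[`, 1L, "nesting_depth") == 0L))
})

test_that("nesting depth counts enclosing lists beyond the outermost", {
  nested <- paste0(strrep("<ReferenceList>", 4),
                   "<Reference><Citation>Deep</Citation></Reference>",
                   strrep("</ReferenceList>", 4))
  f <- write_set(article_xml(1, references = nested))
  r <- flatten_references(split_records(f)[[1]])
  expect_length(r, 1)
  expect_identical(r[[1]]$nesting_depth, 3L)
})

test_that("an incomplete DateRevised is a record-level parse error", {
  xml <- sub("<DateRevised>.*</DateRevised>",
             "<DateRevised><Year>2020</Year></DateRevised>",
             article_xml(4))
  expect_error(parse_article(slice_from_xml(xml, 4)), "DateRevised")
})

test_that("book records are sliced as book_article and skipped by the corpus", {
  book <- paste0("<PubmedBookArticle><BookDocument><PMID Version=\"1\">77</PMID>",
                 "</BookDocument></PubmedBookArticle>")
  f <- write_set(article_xml(1), book)
  slices <- split_records(f)
  expect_identical(vapply(slices, `[[`, "", "kind"),
                   c("article", "book_article"))
  corpus <- apply_updates(new_corpus(), slices)
  expect_identical(corpus_size(corpus), 1L)
  expect_identical(corpus$n_skipped_books, 1L)
})
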
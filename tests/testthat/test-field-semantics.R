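# table-driven identifier cases: every valid string must pass and every
# invalid one must fail under the shipped patterns and match modes
identifier_cases <- list(
  list("DOI", "10.1093/database/baad070", TRUE),
  list("DOI", "10.1234/j.synth-2020;1:(x)", TRUE),
  list("DOI", "doi:10.1", FALSE),
  list("DOI", "10.123/short-prefix", FALSE),
  list("ORCID", "0000-0002-5696-5368", TRUE),
  list("ORCID", "0000-0002-1825-009X", TRUE),
  list("ORCID", "0000-0002-123", FALSE),
  list("ORCID", "0000-0000-0000-0000", FALSE),
  list("ISNI_presentation", "0000 0001 2345 678X", TRUE),
  list("ISNI_presentation", "0000-0001-2345-678X", FALSE),
  list("ISNI_compact", "000000012345678X", TRUE),
  list("ISNI_compact", "00000001234567", FALSE),
  list("GRID", "grid.1234.0a", TRUE),
  list("GRID", "grid.416868.5", TRUE),
  list("GRID", "grid.12.3", FALSE),
  list("GRID", "see grid.1234.0a here", FALSE)
)

test_that("shipped identifier patterns accept valid and reject invalid values", {
  for (case in identifier_cases) {
    res <- validate_identifier(case[[1]], case[[2]])
    expect_identical(res$valid, case[[3]],
                     info = sprintf("%s: %s", case[[1]], case[[2]]))
    expect_true(res$present)
  }
})

test_that("absent and blank identifier values are missing, not invalid", {
  for (v in list(NA_character_, "", "   ")) {
    res <- validate_identifier("DOI", v)
    expect_false(res$present)
    expect_false(res$valid)
    expect_identical(res$reason, "blank")
  }
  expect_error(validate_identifier("ROR", "x"), "unknown")
})

test_that("the all-zero ORCID is present but explicitly invalid", {
  res <- validate_identifier("ORCID", "0000-0000-0000-0000")
  expect_true(res$present)
  expect_false(res$valid)
  expect_identical(res$reason, "all_zero_orcid")
})

test_that("vectorized validity agrees with the scalar validator", {
  vals <- c(vapply(identifier_cases, function(c) c[[2]], ""), NA)
  for (scheme in c("DOI", "ORCID", "GRID", "ISNI_compact")) {
    vec <- identifier_is_valid(vals, scheme)
    scl <- vapply(vals, function(v) {
      r <- validate_identifier(scheme, v)
      if (!r$present) NA else r$valid
    }, logical(1), USE.NAMES = FALSE)
    expect_identical(vec, scl, info = scheme)
  }
})

test_that("language parsing splits concatenated codes and re-concatenates to raw", {
  p <- parse_language_field("fregerita")
  expect_identical(p$codes, c("fre", "ger", "ita"))
  expect_false(p$failed)
  for (raw in c("eng", "fregerita", "gerfre", "und", "chijpnkor")) {
    p <- parse_language_field(raw)
    expect_false(p$failed)
    expect_identical(paste(p$codes, collapse = ""), raw)
  }
})

test_that("solitary und/mul is flagged but not when other codes are present", {
  expect_true(parse_language_field("und")$solitary_undetermined)
  expect_true(parse_language_field("mul")$solitary_undetermined)
  expect_false(parse_language_field("eng")$solitary_undetermined)
  expect_false(parse_language_field("undeng")$solitary_undetermined)
})

test_that("unparseable language values fail with raw preserved", {
  for (raw in c("en", "engx", "zzz", "engzzz")) {
    p <- parse_language_field(raw)
    expect_true(p$failed, info = raw)
    expect_identical(p$raw, raw)
    expect_length(p$codes, 0)
  }
})

test_that("reluctant and greedy year extraction follow first/last four-digit runs", {
  x <- extract_publication_year("1975 part 2): 1125–1132, Dec")
  expect_identical(x$year_reluctant, 1975L)
  expect_identical(x$year_greedy, 1132L)
  expect_true(x$viable)
  expect_false(x$viable_greedy)

  y <- extract_publication_year("1946 May–June")
  expect_identical(y$year_reluctant, 1946L)
  expect_identical(y$year_greedy, 1946L)
  expect_identical(y$span_years, 0L)

  z <- extract_publication_year("1980 Suppl): 1035–15 August 1041")
  expect_identical(z$year_reluctant, 1980L)

  none <- extract_publication_year("1")
  expect_true(is.na(none$year_reluctant))
  expect_false(none$viable)
})

test_that("time spans yield the span between reluctant and greedy years", {
  x <- extract_publication_year("1999 Dec-2000 Jan")
  expect_identical(x$span_years, 1L)
  big <- extract_publication_year("1974 Nov-2002")
  expect_identical(big$span_years, 28L)
})

test_that("a structured year takes precedence over MedlineDate", {
  rec <- list(pub_year_structured = 2020L, medline_date = "1946 May–June")
  x <- extract_publication_year(rec)
  expect_identical(x$source, "structured")
  expect_identical(x$year_reluctant, 2020L)
  expect_identical(x$span_years, 0L)
})

test_that("both extracted years are four-digit substrings of the input", {
  set.seed(99)
  for (k in 1:50) {
    md <- paste(sample(c("1987", "2003", "114", "3-15", "Suppl", "Dec",
                         "20292550", "pt"), 4, replace = TRUE), collapse = " ")
    x <- extract_publication_year(md)
    for (y in c(x$year_reluctant, x$year_greedy)) {
      if (!is.na(y)) expect_true(grepl(sprintf("%d", y), md))
    }
  }
})

test_that("trailing e-mail addresses are extracted conservatively", {
  got <- extract_email_from_affiliation("Dept X, Uni Y. jane.doe@uni.edu.")
  expect_identical(got$email, "jane.doe@uni.edu")
  expect_false(got$placeholder)
  expect_true(is.na(extract_email_from_affiliation("London, UK.")$email))
  ph <- extract_email_from_affiliation("Somewhere. user@example.com")
  expect_identical(ph$email, "user@example.com")
  expect_true(ph$placeholder)
  expect_true(is.na(extract_email_from_affiliation(NA_character_)$email))
})

test_that("author anomaly flags fire on the documented pollution patterns", {
  expect_identical(flag_author_anomalies(list(last_name = "S")),
                   "single_char_last_name")
  long_fore <- strrep("Department Of Radiology ", 12)  # > 100 chars, > 8 words
  flags <- flag_author_anomalies(list(fore_name = long_fore))
  expect_true("forename_equals_affiliation_concat" %in% flags)
  expect_true("suspected_collective_in_personal_field" %in% flags)
  expect_identical(
    flag_author_anomalies(list(suffix = strrep("x", 25))), "suffix_pollution")
  expect_identical(
    flag_author_anomalies(list(initials = "ABCDE")), "initials_overlong")
  expect_length(flag_author_anomalies(list(last_name = "Wang",
                                           fore_name = "Wei")), 0)
})

test_that("anomaly flags are monotone in their thresholds", {
  author <- list(last_name = "Working Group Of Eight Separate Words Here",
                 fore_name = strrep("a b ", 60), suffix = strrep("s", 30),
                 initials = "ABCDEF")
  base <- flag_author_anomalies(author)
  stricter <- flag_author_anomalies(author, collective_words = 1000,
                                    forename_len = 10000, suffix_len = 1000,
                                    initials_len = 100)
  expect_true(all(stricter %in% base))
  expect_length(stricter, 0)
  expect_length(base, 4)
})

test_that("duplicate ORCID detection matches brute-force pairwise comparison", {
  mk <- function(orcids) {
    authors <- lapply(seq_along(orcids), function(i) {
      list(position = i, orcid_raw = orcids[i])
    })
    list(authors = authors)
  }
  two <- detect_duplicate_orcid(mk(c("0000-0002-5696-5368",
                                     "0000-0002-5696-5368")))
  expect_length(two, 1)
  expect_identical(two[[1]]$positions, c(1L, 2L))
  expect_length(detect_duplicate_orcid(mk(c("0000-0002-5696-5368",
                                            "0000-0002-1825-009X"))), 0)
  three <- detect_duplicate_orcid(mk(rep("0000-0001-0002-0003", 3)))
  expect_identical(three[[1]]$positions, 1:3)
  # invalid and all-zero values never collide
  expect_length(detect_duplicate_orcid(mk(rep("0000-0000-0000-0000", 3))), 0)
  # brute force over random assignments
  set.seed(41)
  pool <- c("0000-0001-1111-1111", "0000-0002-2222-2222", NA)
  for (k in 1:10) {
    orcids <- sample(pool, 6, replace = TRUE)
    got <- detect_duplicate_orcid(mk(orcids))
    bf <- Filter(function(id) sum(orcids %in% id) >= 2, unique(orcids[!is.na(orcids)]))
    expect_setequal(vapply(got, `[[`, "", "orcid"), bf)
  }
})

test_that("truncation sentinels at the end of an abstract are detected", {
  expect_true(detect_truncated_abstract(
    "Long text. (ABSTRACT TRUNCATED AT 250 WORDS)"))
  expect_true(detect_truncated_abstract("Text. (ABSTRACT TRUNCATED)"))
  expect_false(detect_truncated_abstract("Short abstract."))
  expect_false(detect_truncated_abstract(
    "(ABSTRACT TRUNCATED) but then it continues."))
})
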
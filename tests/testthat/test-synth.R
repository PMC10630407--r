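test_that("the same seed reproduces corpus files and manifest bit-for-bit", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  cfg <- synth_config(n_records = 100, seed = 42)
  g1 <- generate_corpus(cfg, d1)
  g2 <- generate_corpus(cfg, d2)
  expect_identical(readLines(g1$files[1]), readLines(g2$files[1]))
  expect_identical(g1$manifest$records, g2$manifest$records)
  expect_identical(g1$manifest$counts, g2$manifest$counts)
  # a different seed produces different content
  g3 <- generate_corpus(synth_config(n_records = 100, seed = 43),
                        file.path(tempdir(), "det3"))
  expect_false(identical(readLines(g1$files[1]), readLines(g3$files[1])))
})

test_that("a pathology at rate 1 is injected into every record", {
  cfg <- synth_config(n_records = 10, seed = 5,
                      pathology_rates = list(single_char_last_name = 1.0))
  gen <- generate_corpus(cfg, file.path(tempdir(), "allpath"))
  expect_identical(unname(gen$manifest$counts["single_char_last_name"]), 10L)
  corpus <- apply_updates(new_corpus(), split_records(gen$files[1]))
  one_char <- vapply(corpus$records, function(r) {
    any(vapply(r$authors, function(a) {
      !is.na(a$last_name) && nchar(a$last_name) == 1
    }, logical(1)))
  }, logical(1))
  expect_true(all(one_char))
})

test_that("every registry pathology is generatable and recorded in the manifest", {
  all_names <- names(default_pathology_rates())
  for (nm in all_names) {
    # isolate the pathology: everything else off, so precedence rules
    # between co-injected pathologies cannot mask it
    rates <- as.list(stats::setNames(rep(0, length(all_names)), all_names))
    rates[[nm]] <- 1.0
    cfg <- synth_config(n_records = 3, seed = 2, pathology_rates = rates)
    gen <- generate_corpus(cfg, file.path(tempdir(), paste0("reg_", nm)))
    expect_identical(unname(gen$manifest$counts[nm]), 3L, info = nm)
    # the emitted file is parseable end to end
    corpus <- apply_updates(new_corpus(), split_records(gen$files[1]))
    expect_identical(corpus_size(corpus), 3L)
  }
})

test_that("records per file bounds the file size and totals are preserved", {
  cfg <- synth_config(n_records = 25, seed = 3, records_per_file = 10)
  gen <- generate_corpus(cfg, file.path(tempdir(), "split"))
  expect_length(gen$files, 3)
  counts <- vapply(gen$files, function(f) length(split_records(f)), 1L)
  expect_identical(unname(counts), c(10L, 10L, 5L))
})

test_that("unknown pathology names and invalid rates are rejected", {
  expect_error(synth_config(10, pathology_rates = list(not_a_thing = 0.5)),
               "unknown pathology")
  expect_error(synth_config(10, pathology_rates = list(missing_title = 1.5)),
               "probabilities")
})

test_that("update batches revise, add and delete as the delta predicts", {
  cfg <- synth_config(n_records = 100, seed = 9)
  gen <- generate_corpus(cfg, file.path(tempdir(), "updbase"))
  upd <- generate_update_batch(cfg, gen$manifest,
                               tempfile(fileext = ".xml"),
                               n_revise = 5, n_add = 3, n_delete = 2)
  corpus <- replay_slices(new_corpus(), split_records(gen$files[1]))
  corpus <- suppressWarnings(replay_slices(corpus, split_records(upd$file)))
  expect_identical(corpus_size(corpus), 101L)   # 100 + 3 - 2
  expect_identical(corpus_size(corpus), nrow(upd$expected_records))
  expect_setequal(as.integer(names(corpus$records)),
                  upd$expected_records$pmid)
  expect_identical(sort(corpus$tombstones), upd$deleted_pmids)
  for (pmid in upd$revised_pmids) {
    expect_gt(as.numeric(corpus$records[[as.character(pmid)]]$date_revised),
              as.numeric(as.Date("2022-01-01")))
  }
})

test_that("an empty update batch leaves the corpus unchanged", {
  cfg <- synth_config(n_records = 20, seed = 21)
  gen <- generate_corpus(cfg, file.path(tempdir(), "updempty"))
  upd <- generate_update_batch(cfg, gen$manifest, tempfile(fileext = ".xml"),
                               n_revise = 0, n_add = 0, n_delete = 0)
  before <- replay_slices(new_corpus(), split_records(gen$files[1]))
  after <- replay_slices(before, split_records(upd$file))
  expect_identical(lapply(before$records, unclass),
                   lapply(after$records, unclass))
})

test_that("the journal reference file omits exactly the dangling pool", {
  cfg <- synth_config(n_records = 50, seed = 17, n_journals = 50,
                      n_dangling_journals = 2)
  gen <- generate_corpus(cfg, file.path(tempdir(), "jref"))
  jr <- generate_journal_reference(gen$manifest, tempfile())
  journals <- read_jmedline(jr$path)
  expect_identical(sort(journals$NlmId), sort(gen$manifest$journals$reference))
  expect_identical(jr$omitted, sort(gen$manifest$journals$dangling))
  # zero dangling usage downstream means perfect integrity
  cfg0 <- synth_config(n_records = 50, seed = 17,
                       pathology_rates = list(dangling_journal = 0))
  gen0 <- generate_corpus(cfg0, file.path(tempdir(), "jref0"))
  jr0 <- generate_journal_reference(gen0$manifest, tempfile())
  corpus <- apply_updates(new_corpus(), split_records(gen0$files[1]))
  keys <- corpus_articles(corpus)$journal_nlm_id
  ri <- referential_integrity(keys, read_jmedline(jr0$path)$NlmId)
  expect_equal(ri$integrity, 1.0)
  # extra omissions surface as dangling keys downstream
  jr5 <- generate_journal_reference(gen0$manifest, tempfile(),
                                    extra_omit_fraction = 0.1)
  ri5 <- referential_integrity(keys, read_jmedline(jr5$path)$NlmId)
  used_omitted <- intersect(jr5$omitted, unique(keys))
  expect_identical(ri5$dangling_keys, sort(used_omitted))
  expect_identical(ri5$n_affected_articles,
                   as.integer(sum(keys %in% jr5$omitted)))
})

test_that("parse of a generated corpus recovers the serializer round trip", {
  cfg <- synth_config(n_records = 40, seed = 31)
  gen <- generate_corpus(cfg, file.path(tempdir(), "rt"))
  slices <- split_records(gen$files[1])
  for (slice in slices[seq(1, length(slices), by = 4)]) {
    rec <- parse_article(slice)
    rt <- parse_article(slice_from_xml(serialize_article(rec), rec$pmid))
    expect_equal(rec, rt)
  }
})
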
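baseline_slices <- function(...) {
  split_records(write_set(...))
}

test_that("the newest DateRevised wins regardless of arrival order", {
  base <- baseline_slices(article_xml(1, title = "Old",
                                      date_revised = "2021-01-01"))
  upd <- baseline_slices(article_xml(1, title = "New",
                                     date_revised = "2022-02-02"))
  corpus <- apply_updates(apply_updates(new_corpus(), base), upd)
  expect_identical(corpus$records[["1"]]$title, "New")
  # stale update never overwrites
  stale <- baseline_slices(article_xml(1, title = "Stale",
                                       date_revised = "2019-01-01"))
  corpus <- apply_updates(corpus, stale)
  expect_identical(corpus$records[["1"]]$title, "New")
  # order-insensitive for distinct dates
  corpus2 <- apply_updates(apply_updates(new_corpus(), upd), base)
  expect_identical(corpus2$records[["1"]]$title, "New")
})

test_that("a batch with two updates for one pmid keeps the newest, idempotently", {
  batch <- c(baseline_slices(article_xml(5, title = "A",
                                         date_revised = "2021-05-05")),
             baseline_slices(article_xml(5, title = "B",
                                         date_revised = "2021-07-07")))
  once <- apply_updates(new_corpus(), batch)
  twice <- apply_updates(once, batch)
  expect_identical(once$records[["5"]]$title, "B")
  expect_identical(lapply(once$records, unclass), lapply(twice$records, unclass))
})

test_that("records without DateRevised sort as oldest", {
  dated <- baseline_slices(article_xml(2, title = "Dated",
                                       date_revised = "2015-01-01"))
  undated <- baseline_slices(article_xml(2, title = "Undated",
                                         date_revised = NULL))
  corpus <- apply_updates(apply_updates(new_corpus(), dated), undated)
  expect_identical(corpus$records[["2"]]$title, "Dated")
})

test_that("deletions tombstone records and absent deletions only warn", {
  corpus <- apply_updates(new_corpus(),
                          baseline_slices(article_xml(1), article_xml(2),
                                          article_xml(3)))
  dels <- split_records(write_set(delete_citation_xml(2)))
  corpus <- apply_deletions(corpus, dels)
  expect_setequal(names(corpus$records), c("1", "3"))
  expect_identical(corpus$tombstones, 2L)
  expect_warning(apply_deletions(corpus,
                                 split_records(write_set(delete_citation_xml(99)))),
                 class = "medlineqc_delete_warning")
})

test_that("update-then-delete leaves a pmid absent; delete-then-update reinstates", {
  upd <- baseline_slices(article_xml(7, date_revised = "2022-01-01"))
  del <- split_records(write_set(delete_citation_xml(7)))
  gone <- replay_slices(new_corpus(), c(upd, del))
  expect_null(gone$records[["7"]])
  expect_identical(gone$tombstones, 7L)
  back <- replay_slices(new_corpus(), c(upd, del, upd))
  expect_identical(corpus_size(back), 1L)
  expect_length(back$tombstones, 0)
})

test_that("replaying random event streams matches the brute-force fold", {
  set.seed(303)
  for (trial in 1:5) {
    n_ev <- 60
    pmids <- sample(1:12, n_ev, replace = TRUE)
    kinds <- sample(c("article", "delete"), n_ev, replace = TRUE,
                    prob = c(0.8, 0.2))
    dates <- as.Date("2020-01-01") + sample(0:400, n_ev, replace = TRUE)
    slices <- list()
    for (i in seq_len(n_ev)) {
      xml <- if (kinds[i] == "article") {
        article_xml(pmids[i], title = sprintf("T%d", i),
                    date_revised = as.character(dates[i]))
      } else delete_citation_xml(pmids[i])
      slices <- c(slices, split_records(write_set(xml)))
    }
    corpus <- suppressWarnings(replay_slices(new_corpus(), slices))
    oracle <- bf_replay(data.frame(pmid = pmids, kind = kinds, date = dates))
    expect_setequal(names(corpus$records), names(oracle$kept))
    expect_identical(sort(corpus$tombstones), oracle$dead)
    for (key in names(oracle$kept)) {
      expect_identical(corpus$records[[key]]$date_revised,
                       oracle$kept[[key]]$date)
    }
  }
})

test_that("selection applies status, news and title filters in fixed precedence", {
  slices <- baseline_slices(
    article_xml(1, status = "MEDLINE"),
    article_xml(2, status = "In-Process"),
    article_xml(3, pub_types = c("Journal Article", "News")),
    article_xml(4, title = NULL),
    # status beats news beats title: this record counts once, under status
    article_xml(5, status = "Publisher", title = NULL,
                pub_types = "News"))
  sel <- select_study_records(apply_updates(new_corpus(), slices))
  r <- sel$report
  expect_identical(r$n_input, 5L)
  expect_identical(r$n_status_excluded, 2L)
  expect_identical(r$n_news_excluded, 1L)
  expect_identical(r$n_untitled_excluded, 1L)
  expect_identical(r$n_selected, 1L)
  expect_identical(r$n_selected + r$n_status_excluded + r$n_news_excluded +
                     r$n_untitled_excluded, r$n_input)
  expect_setequal(names(sel$corpus$records), "1")
})

test_that("selection report counts always sum to the input size", {
  cfg <- synth_config(n_records = 200, seed = 13)
  gen <- generate_corpus(cfg, file.path(tempdir(), "selsum"))
  corpus <- apply_updates(new_corpus(), split_records(gen$files[1]))
  r <- select_study_records(corpus)$report
  expect_identical(r$n_selected + r$n_status_excluded + r$n_news_excluded +
                     r$n_untitled_excluded, r$n_input)
})
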
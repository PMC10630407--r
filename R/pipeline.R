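#' Configure an assessment pipeline run
#'
#' @param baseline_files character vector of baseline XML files, in order.
#' @param update_files optional update files applied after the baseline, in
#'   order (updates may revise, insert and delete records).
#' @param journal_ref optional path to an NLM journal list file; when
#'   absent the referential integrity section of the report is skipped.
#' @param news_types publication types excluded as journalism.
#' @param top_n rows kept in top-value tables.
#' @param extremes_k rows kept in longest/shortest tables.
#' @param year_series_schemes identifier schemes to track per publication
#'   year.
#' @return list of class \code{pm_pipeline_config}.
#' @export
pipeline_config <- function(baseline_files, update_files = character(0),
                            journal_ref = NULL,
                            news_types = c("News", "Newspaper Article"),
                            top_n = 10L, extremes_k = 10L,
                            year_series_schemes = c("doi", "orcid")) {
  structure(list(baseline_files = baseline_files,
                 update_files = update_files, journal_ref = journal_ref,
                 news_types = news_types, top_n = as.integer(top_n),
                 extremes_k = as.integer(extremes_k),
                 year_series_schemes = year_series_schemes),
            class = "pm_pipeline_config")
}

language_record_valid <- function(values) {
  vapply(values, function(v) {
    parts <- strsplit(v, "|", fixed = TRUE)[[1]]
    parses <- lapply(parts, parse_language_field)
    if (any(vapply(parses, `[[`, TRUE, "failed"))) return(FALSE)
    codes <- unlist(lapply(parses, `[[`, "codes"))
    !(length(codes) == 1 && codes %in% c("und", "mul"))
  }, logical(1), USE.NAMES = FALSE)
}

#' Run the full assessment pipeline
#'
#' Executes split, parse, merge, select, assess and profile over the
#' configured input files: baseline files are ingested first, update files
#' are then replayed in order (newest-DateRevised retention, deletions
#' tombstoned), the study selection filters are applied, and the selected
#' corpus is assessed. Individual records that fail to parse are logged
#' and tallied, never abort the run; unreadable input files are fatal.
#' Deterministic for fixed inputs and configuration apart from the
#' report's timestamp field.
#'
#' @param config a [pipeline_config()].
#' @return object of class \code{pm_report}; see [render_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pm_pipeline_config"))
  files <- c(config$baseline_files, config$update_files)
  if (length(files) == 0) stop("no input files configured", call. = FALSE)
  missing_files <- files[!file.exists(files)]
  if (length(missing_files) > 0) {
    stop("unreadable input file(s): ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  n_record_errors <- 0L
  corpus <- new_corpus()
  withCallingHandlers(
    for (f in files) {
      corpus <- replay_slices(corpus, split_records(f))
    },
    medlineqc_record_error = function(w) {
      n_record_errors <<- n_record_errors + 1L
      message("record error: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    medlineqc_delete_warning = function(w) {
      message(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  sel <- select_study_records(corpus, news_types = config$news_types)
  selected <- sel$corpus
  articles <- corpus_articles(selected)
  authors <- corpus_authors(selected)

  metrics <- list(
    DOI = compute_quality_metrics(articles$doi,
      validator = function(v) identifier_is_valid(v, "DOI")),
    ORCID = compute_quality_metrics(authors$orcid,
      validator = function(v) identifier_is_valid(v, "ORCID")),
    ISNI = compute_quality_metrics(authors$isni,
      validator = function(v) identifier_is_valid(v, "ISNI")),
    GRID = compute_quality_metrics(authors$grid,
      validator = function(v) identifier_is_valid(v, "GRID")),
    Affiliation = compute_quality_metrics(authors$affiliation_first),
    title = compute_quality_metrics(articles$title),
    abstract = compute_quality_metrics(articles$abstract),
    language = compute_quality_metrics(articles$language,
      validator = language_record_valid),
    forename = compute_quality_metrics(authors$fore_name),
    initials = compute_quality_metrics(authors$initials)
  )

  ref_integrity <- NULL
  if (!is.null(config$journal_ref)) {
    journals <- read_jmedline(config$journal_ref)
    if (!"NlmId" %in% names(journals)) {
      stop("journal reference file has no NlmId column", call. = FALSE)
    }
    ref_integrity <- referential_integrity(articles$journal_nlm_id,
                                           journals$NlmId)
  }

  profiles <- list(
    title = profile_string_field(articles$title, config$top_n,
                                 field_name = "title",
                                 extremes_k = config$extremes_k),
    abstract = profile_string_field(articles$abstract, config$top_n,
                                    field_name = "abstract",
                                    extremes_k = config$extremes_k),
    copyright = profile_string_field(articles$copyright_info, config$top_n,
                                     field_name = "copyright",
                                     extremes_k = config$extremes_k),
    affiliation = profile_string_field(
      authors$affiliation_first, config$top_n,
      length_filter = function(v) nchar(v, type = "chars") < 20,
      field_name = "affiliation", extremes_k = config$extremes_k),
    last_name = profile_string_field(authors$last_name, config$top_n,
                                     field_name = "last_name",
                                     extremes_k = config$extremes_k),
    fore_name = profile_string_field(authors$fore_name, config$top_n,
                                     field_name = "fore_name",
                                     extremes_k = config$extremes_k),
    suffix = profile_string_field(authors$suffix, config$top_n,
                                  field_name = "suffix",
                                  extremes_k = config$extremes_k)
  )

  year_series <- lapply(stats::setNames(nm = config$year_series_schemes),
                        function(s) identifier_prevalence_by_year(selected, s))

  anomalies <- tally_anomalies(selected)

  cfg_for_hash <- config
  cfg_for_hash$journal_ref <- config$journal_ref %||% ""
  report <- list(
    tool_version = as.character(utils::packageVersion("medlineqc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = fnv1a_hash(jsonlite::toJSON(
      cfg_for_hash[order(names(cfg_for_hash))], auto_unbox = TRUE)),
    input_files = basename(files),
    n_record_errors = n_record_errors + corpus$n_parse_errors,
    n_skipped_books = corpus$n_skipped_books,
    n_tombstones = length(corpus$tombstones),
    selection = sel$report,
    metrics = metrics,
    ref_integrity = ref_integrity,
    profiles = profiles,
    year_series = year_series,
    anomalies = anomalies
  )
  class(report) <- "pm_report"
  report
}

tally_anomalies <- function(corpus) {
  flags <- c("single_char_last_name", "suspected_collective_in_personal_field",
             "forename_equals_affiliation_concat", "suffix_pollution",
             "initials_overlong")
  tally <- stats::setNames(as.list(integer(length(flags))), flags)
  tally$duplicate_orcid_articles <- 0L
  tally$all_zero_orcid_authors <- 0L
  tally$truncated_abstracts <- 0L
  tally$solitary_und_mul_records <- 0L
  tally$language_parse_failures <- 0L
  tally$placeholder_email_authors <- 0L
  for (rec in corpus$records) {
    for (a in rec$authors) {
      for (fl in flag_author_anomalies(a)) tally[[fl]] <- tally[[fl]] + 1L
      if (identical(a$orcid_raw, ALL_ZERO_ORCID)) {
        tally$all_zero_orcid_authors <- tally$all_zero_orcid_authors + 1L
      }
      if (!is.na(a$affiliation_first)) {
        em <- extract_email_from_affiliation(a$affiliation_first)
        if (isTRUE(em$placeholder)) {
          tally$placeholder_email_authors <- tally$placeholder_email_authors + 1L
        }
      }
    }
    if (length(detect_duplicate_orcid(rec)) > 0) {
      tally$duplicate_orcid_articles <- tally$duplicate_orcid_articles + 1L
    }
    if (!is.na(rec$abstract) && detect_truncated_abstract(rec$abstract)) {
      tally$truncated_abstracts <- tally$truncated_abstracts + 1L
    }
    if (length(rec$language_raw) > 0) {
      parses <- lapply(rec$language_raw, parse_language_field)
      if (any(vapply(parses, `[[`, TRUE, "failed"))) {
        tally$language_parse_failures <- tally$language_parse_failures + 1L
      } else {
        codes <- unlist(lapply(parses, `[[`, "codes"))
        if (length(codes) == 1 && codes %in% c("und", "mul")) {
          tally$solitary_und_mul_records <- tally$solitary_und_mul_records + 1L
        }
      }
    }
  }
  tally
}

#' @export
print.pm_report <- function(x, ...) {
  cat(sprintf("<assessment report v%s, hash %s>\n", x$tool_version,
              x$config_hash))
  print(x$selection)
  cat(render_metrics_markdown(x$metrics), sep = "\n")
  if (!is.null(x$ref_integrity)) print(x$ref_integrity)
  invisible(x)
}

# plain-list view of a report, the lossless JSON shape
report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "pm_field_profile")) {
      x <- unclass(x)
      x$char_len_summary <- as.list(x$char_len_summary)
      x$word_count_summary <- as.list(x$word_count_summary)
      x$top_values <- as.data.frame(x$top_values)
      x$longest <- as.data.frame(x$longest)
      x$shortest <- as.data.frame(x$shortest)
      return(x)
    }
    if (inherits(x, "pm_year_series")) {
      x <- unclass(x)
      x$points <- as.data.frame(x$points)
      return(x)
    }
    if (inherits(x, c("pm_quality_metrics", "pm_selection_report",
                      "pm_ref_integrity"))) {
      x <- unclass(x)
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- strip(unclass(report))
  # every ratio also carries its rendered percentage
  for (nm in names(out$metrics)) {
    m <- out$metrics[[nm]]
    out$metrics[[nm]]$rendered <- list(
      completeness = round_metric(m$completeness),
      validity = round_metric(m$validity),
      uniqueness = round_metric(m$uniqueness))
  }
  if (!is.null(out$ref_integrity)) {
    out$ref_integrity$rendered <- round_metric(out$ref_integrity$integrity)
  }
  out
}

render_metrics_markdown <- function(metrics) {
  rows <- unname(vapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    sprintf("| %s | %s | %s | %s |", nm, round_metric(m$completeness),
            round_metric(m$validity), round_metric(m$uniqueness))
  }, ""))
  c("| Identifier | Completeness (%) | Validity (%) | Uniqueness (%) |",
    "| --- | --- | --- | --- |", rows)
}

#' Render an assessment report to files
#'
#' \code{json} writes one lossless JSON document. \code{csv_bundle} writes
#' one CSV file per populated table (selection, identifier metrics,
#' referential integrity, anomalies, per-field length summaries, top and
#' extreme value tables, year series). \code{markdown} writes one document
#' mirroring the familiar table shapes (identifier metric table with
#' three-decimal percentages, top-N and extremes tables).
#'
#' @param report a \code{pm_report}.
#' @param format \code{"json"}, \code{"csv_bundle"} or \code{"markdown"}.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, format = c("json", "csv_bundle", "markdown"),
                          out_dir = ".") {
  stopifnot(inherits(report, "pm_report"))
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "json") {
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null",
                         null = "null")
    return(invisible(path))
  }
  if (format == "csv_bundle") {
    paths <- character(0)
    wr <- function(df, name) {
      p <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      paths <<- c(paths, p)
    }
    wr(as.data.frame(unclass(report$selection)), "selection")
    mt <- do.call(rbind, lapply(names(report$metrics), function(nm) {
      m <- report$metrics[[nm]]
      data.frame(field = nm, n_records = m$n_records, n_missing = m$n_missing,
                 n_present = m$n_present, n_distinct = m$n_distinct,
                 n_valid = ifelse(is.na(m$n_valid), NA, m$n_valid),
                 completeness = m$completeness, validity = m$validity,
                 uniqueness = m$uniqueness,
                 completeness_pct = round_metric(m$completeness),
                 validity_pct = round_metric(m$validity),
                 uniqueness_pct = round_metric(m$uniqueness))
    }))
    wr(mt, "identifier_metrics")
    if (!is.null(report$ref_integrity)) {
      ri <- report$ref_integrity
      wr(data.frame(n_with_key = ri$n_with_key, n_matched = ri$n_matched,
                    n_affected_articles = ri$n_affected_articles,
                    n_dangling = length(ri$dangling_keys),
                    integrity = ri$integrity,
                    integrity_pct = round_metric(ri$integrity)),
         "referential_integrity")
      if (length(ri$dangling_keys) > 0) {
        wr(data.frame(dangling_key = ri$dangling_keys), "dangling_keys")
      }
    }
    wr(as.data.frame(report$anomalies), "anomalies")
    for (nm in names(report$profiles)) {
      pr <- report$profiles[[nm]]
      wr(data.frame(statistic = names(pr$char_len_summary),
                    char_length = unname(pr$char_len_summary),
                    word_count = unname(pr$word_count_summary)),
         paste0("profile_", nm, "_summary"))
      if (nrow(pr$top_values) > 0) {
        wr(as.data.frame(pr$top_values), paste0("profile_", nm, "_top"))
      }
      if (nrow(pr$longest) > 0) {
        wr(as.data.frame(pr$longest), paste0("profile_", nm, "_longest"))
      }
    }
    for (nm in names(report$year_series)) {
      wr(as.data.frame(report$year_series[[nm]]$points),
         paste0("year_series_", nm))
    }
    return(invisible(paths))
  }
  # markdown
  lines <- c("# MEDLINE data quality assessment", "",
             sprintf("Tool version %s, config %s", report$tool_version,
                     report$config_hash),
             "", "## Record selection", "",
             sprintf("- input records: %d", report$selection$n_input),
             sprintf("- excluded by status: %d", report$selection$n_status_excluded),
             sprintf("- excluded as news: %d", report$selection$n_news_excluded),
             sprintf("- excluded untitled: %d", report$selection$n_untitled_excluded),
             sprintf("- selected: %d", report$selection$n_selected),
             "", "## Identifier metrics", "",
             render_metrics_markdown(report$metrics))
  if (!is.null(report$ref_integrity)) {
    lines <- c(lines, "", "## Journal referential integrity", "",
               sprintf("%s%% (%d of %d keys matched; %d distinct dangling, %d articles affected)",
                       round_metric(report$ref_integrity$integrity),
                       report$ref_integrity$n_matched,
                       report$ref_integrity$n_with_key,
                       length(report$ref_integrity$dangling_keys),
                       report$ref_integrity$n_affected_articles))
  }
  for (nm in names(report$profiles)) {
    pr <- report$profiles[[nm]]
    if (nrow(pr$top_values) == 0) next
    lines <- c(lines, "", sprintf("## Top %s values", nm), "",
               "| Value | Occurrences |", "| --- | --- |",
               sprintf("| %s | %d |", pr$top_values$value, pr$top_values$count))
  }
  lines <- c(lines, "", "## Anomaly tallies", "",
             sprintf("- %s: %d", names(report$anomalies),
                     unlist(report$anomalies)))
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
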
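#' Five-number summary of a numeric vector
#'
#' Minimum, lower quartile, median, upper quartile and maximum. Exact mode
#' sorts the data and interpolates linearly between closest ranks
#' (\code{quantile} type 7). Approximate mode mirrors the streaming
#' quantile interface used on very large corpora: it guarantees a rank
#' error of at most \code{error * n} and is implemented as nearest-rank
#' selection (type 1), whose rank error never exceeds one — well inside
#' the guarantee at any size this package profiles.
#'
#' @param values numeric vector (NAs dropped).
#' @param mode \code{"exact"} or \code{"approximate"}.
#' @param error rank-error budget per element for approximate mode.
#' @return named numeric vector \code{(min, q1, median, q3, max)}; all-NA
#'   when no values remain.
#' @export
five_number_summary <- function(values, mode = c("exact", "approximate"),
                                error = 1e-4) {
  mode <- match.arg(mode)
  values <- values[!is.na(values)]
  nm <- c("min", "q1", "median", "q3", "max")
  if (length(values) == 0) {
    return(stats::setNames(rep(NA_real_, 5), nm))
  }
  type <- if (mode == "exact") 7 else 1
  stats::setNames(
    unname(stats::quantile(values, probs = c(0, .25, .5, .75, 1), type = type)),
    nm)
}

#' Character length and word count of string values
#'
#' Character length is the Unicode code-point count; word count is the
#' number of non-empty tokens after splitting on the space character (other
#' whitespace has already been collapsed to spaces by [sanitize_text()]).
#'
#' @param values character vector.
#' @return list with integer vectors \code{chars} and \code{words}.
#' @export
string_lengths <- function(values) {
  chars <- nchar(values, type = "chars")
  words <- vapply(strsplit(values, " ", fixed = TRUE),
                  function(t) sum(nzchar(t)), 1L)
  list(chars = chars, words = words)
}

#' Profile a string field
#'
#' Length distributions (characters and words) as five-number summaries,
#' the top-N most frequent values (ties broken lexicographically), and the
#' longest/shortest extreme values. An optional \code{length_filter}
#' predicate restricts which values enter the top-N table — the idiom
#' behind tables like "top affiliations under 20 characters" that expose
#' placeholder values.
#'
#' @param values sanitized character vector; NAs are dropped.
#' @param top_n number of top values to tabulate.
#' @param length_filter optional predicate \code{function(values)} returning
#'   a logical vector, applied before the top-N count.
#' @param field_name label carried in the profile.
#' @param extremes_k how many extreme values to keep per direction.
#' @return object of class \code{pm_field_profile}: \code{field_name},
#'   \code{n}, \code{char_len_summary}, \code{word_count_summary},
#'   \code{top_values} (tibble value/count), \code{longest},
#'   \code{shortest} (tibbles value/length).
#' @export
profile_string_field <- function(values, top_n = 10, length_filter = NULL,
                                 field_name = "", extremes_k = 10) {
  values <- values[!is.na(values)]
  out <- list(field_name = field_name, n = length(values))
  if (length(values) == 0) {
    out$char_len_summary <- five_number_summary(numeric(0))
    out$word_count_summary <- five_number_summary(numeric(0))
    out$top_values <- tibble::tibble(value = character(0), count = integer(0))
    out$longest <- out$shortest <-
      tibble::tibble(value = character(0), length = integer(0))
    class(out) <- "pm_field_profile"
    return(out)
  }
  len <- string_lengths(values)
  out$char_len_summary <- five_number_summary(len$chars)
  out$word_count_summary <- five_number_summary(len$words)
  pool <- if (is.null(length_filter)) values else values[length_filter(values)]
  if (length(pool) > 0) {
    counts <- table(pool)
    ord <- order(-as.integer(counts), names(counts), method = "radix")
    keep <- utils::head(ord, top_n)
    out$top_values <- tibble::tibble(value = names(counts)[keep],
                                     count = as.integer(counts)[keep])
  } else {
    out$top_values <- tibble::tibble(value = character(0), count = integer(0))
  }
  out$longest <- extreme_values(values, extremes_k, "longest")
  out$shortest <- extreme_values(values, extremes_k, "shortest")
  class(out) <- "pm_field_profile"
  out
}

#' @export
print.pm_field_profile <- function(x, ...) {
  cat(sprintf("<profile %s> n=%d chars(min,q1,med,q3,max)=(%s)\n",
              x$field_name, x$n,
              paste(signif(x$char_len_summary, 4), collapse = ", ")))
  if (nrow(x$top_values) > 0) {
    cat("  top:", paste(sprintf("%s (%d)", utils::head(x$top_values$value, 3),
                                utils::head(x$top_values$count, 3)),
                        collapse = "; "), "\n")
  }
  invisible(x)
}

#' Longest or shortest values of a string field
#'
#' @param values sanitized character vector; NAs dropped.
#' @param k number of entries to return (fewer when the field has fewer
#'   values).
#' @param direction \code{"longest"} or \code{"shortest"}.
#' @return tibble with columns \code{value} and \code{length}, ordered by
#'   character length (ties broken lexicographically).
#' @export
extreme_values <- function(values, k, direction = c("longest", "shortest")) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  len <- nchar(values, type = "chars")
  ord <- if (direction == "longest") {
    order(-len, values, method = "radix")
  } else {
    order(len, values, method = "radix")
  }
  keep <- utils::head(ord, k)
  tibble::tibble(value = values[keep], length = len[keep])
}

#' Identifier prevalence per publication year
#'
#' Tracks how identifier usage evolves: for each publication year, the
#' fraction of entities carrying a valid identifier — articles for DOI,
#' authors for ORCID, ISNI, GRID and the plain affiliation string. The
#' year is the reluctant extraction from [extract_publication_year()];
#' records without a viable year are excluded and counted.
#'
#' @param corpus a selected \code{pm_corpus}.
#' @param scheme one of \code{"doi"}, \code{"orcid"}, \code{"isni"},
#'   \code{"grid"}, \code{"affiliation"}.
#' @return object of class \code{pm_year_series}: \code{metric_name},
#'   \code{points} (tibble year/numerator/denominator/fraction, years
#'   strictly increasing), \code{n_excluded_no_year}.
#' @export
identifier_prevalence_by_year <- function(corpus,
                                          scheme = c("doi", "orcid", "isni",
                                                     "grid", "affiliation")) {
  scheme <- match.arg(scheme)
  articles <- corpus_articles(corpus)
  yrs <- vapply(corpus$records, function(r) {
    yx <- extract_publication_year(r)
    if (isTRUE(yx$viable)) yx$year_reluctant else NA_integer_
  }, 1L)
  articles$year <- unname(yrs)
  n_excluded <- sum(is.na(yrs))
  if (scheme == "doi") {
    df <- articles[!is.na(articles$year), c("year", "doi")]
    df$hit <- identifier_is_valid(df$doi, "DOI") %in% TRUE
  } else {
    authors <- corpus_authors(corpus)
    authors <- dplyr::left_join(authors,
                                articles[, c("pmid", "year")], by = "pmid")
    df <- authors[!is.na(authors$year), ]
    df$hit <- switch(scheme,
      orcid = identifier_is_valid(df$orcid, "ORCID") %in% TRUE,
      isni = identifier_is_valid(df$isni, "ISNI") %in% TRUE,
      grid = identifier_is_valid(df$grid, "GRID") %in% TRUE,
      affiliation = !is_blank(df$affiliation_first))
  }
  pts <- dplyr::summarise(dplyr::group_by(df, year),
                          numerator = sum(hit), denominator = dplyr::n(),
                          .groups = "drop")
  pts <- dplyr::arrange(pts, year)
  pts$fraction <- pts$numerator / pts$denominator
  out <- list(metric_name = scheme, points = pts,
              n_excluded_no_year = n_excluded)
  class(out) <- "pm_year_series"
  out
}

#' @export
print.pm_year_series <- function(x, ...) {
  cat(sprintf("<year series %s> %d year(s), %d record(s) without viable year\n",
              x$metric_name, nrow(x$points), x$n_excluded_no_year))
  invisible(x)
}
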
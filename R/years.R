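#' Extract a publication year from a record or MedlineDate string
#'
#' PubDate usually carries a structured Year, but ~2.1 million records fall
#' back to a free-text MedlineDate ("1946 May-June", "1999 Dec-2000 Jan").
#' Two extractions are computed from such strings: the reluctant
#' (shortest-match) year is the first four-digit run, the greedy
#' (longest-match) year is the last four-digit run. On well-behaved time
#' spans the difference between them is the span in years; on pathological
#' values (pagination leaking into the date field) the greedy extraction can
#' land on a page number, which is why each year carries its own viability
#' flag against a plausibility window.
#'
#' @param record a parsed article (class \code{pm_article}) or a character
#'   string, which is treated as a raw MedlineDate value.
#' @param window plausibility window for a viable year, default
#'   \code{c(1800, current year + 2)}.
#' @return list of class \code{pm_year_extraction}: \code{source}
#'   (\code{"structured"} or \code{"medline_date"}), \code{year_reluctant},
#'   \code{year_greedy}, \code{span_years} (greedy - reluctant when both
#'   present and non-negative, else NA), \code{viable} (reluctant year inside
#'   the window), \code{viable_greedy}.
#' @examples
#' extract_publication_year("1946 May-June")$year_reluctant  # 1946
#' @export
extract_publication_year <- function(record, window = year_window()) {
  if (inherits(record, "pm_article") || is.list(record)) {
    ys <- record$pub_year_structured
    if (!is.null(ys) && length(ys) == 1 && !is.na(ys)) {
      out <- list(source = "structured",
                  year_reluctant = as.integer(ys), year_greedy = as.integer(ys),
                  span_years = 0L,
                  viable = ys >= window[1] && ys <= window[2],
                  viable_greedy = ys >= window[1] && ys <= window[2])
      class(out) <- "pm_year_extraction"
      return(out)
    }
    md <- record$medline_date
  } else {
    md <- record
  }
  out <- list(source = "medline_date",
              year_reluctant = NA_integer_, year_greedy = NA_integer_,
              span_years = NA_integer_, viable = FALSE, viable_greedy = FALSE)
  if (length(md) == 1 && !is.na(md)) {
    runs <- regmatches(md, gregexpr("\\d{4}", md))[[1]]
    if (length(runs) > 0) {
      out$year_reluctant <- as.integer(runs[1])
      out$year_greedy <- as.integer(runs[length(runs)])
      out$viable <- out$year_reluctant >= window[1] && out$year_reluctant <= window[2]
      out$viable_greedy <- out$year_greedy >= window[1] && out$year_greedy <= window[2]
      span <- out$year_greedy - out$year_reluctant
      if (span >= 0) out$span_years <- span
    }
  }
  class(out) <- "pm_year_extraction"
  out
}

#' Default plausibility window for publication years
#' @return integer vector \code{c(min, max)}.
#' @export
year_window <- function() {
  c(1800L, as.integer(format(Sys.Date(), "%Y")) + 2L)
}

#' @export
print.pm_year_extraction <- function(x, ...) {
  cat(sprintf("<year %s> reluctant=%s greedy=%s span=%s viable=%s\n",
              x$source, x$year_reluctant, x$year_greedy, x$span_years, x$viable))
  invisible(x)
}
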
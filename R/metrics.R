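#' Completeness, validity and uniqueness of a field
#'
#' For a field observed over N records with M missing values the derived
#' counts are P = N - M present values, D distinct present values and V
#' present values accepted by the validator. The three ratios are
#' completeness = P/N, validity = V/P and uniqueness = D/P. A value that is
#' blank after sanitization counts as missing, matching the definition of
#' distinct values as "excluding null/blank". Distinctness is exact, never
#' approximated, and by default case-sensitive on the sanitized value (DOIs
#' are case-insensitive by their own specification; pass
#' \code{case_fold = TRUE} for such fields).
#'
#' @param values character vector, one element per record (NA = absent).
#' @param validator optional validity check: either a vectorized function
#'   returning a logical vector, or a function of one value returning a
#'   result with a \code{$valid} field (as [validate_identifier()] does).
#'   When absent, validity is undefined (\code{NA}).
#' @param case_fold lower-case values before counting distinct ones.
#' @return object of class \code{pm_quality_metrics} with fields
#'   \code{n_records}, \code{n_missing}, \code{n_present},
#'   \code{n_distinct}, \code{n_valid}, \code{completeness},
#'   \code{validity}, \code{uniqueness}. Undefined ratios (N = 0, or P = 0
#'   for validity/uniqueness) are \code{NA}, never 0.
#' @examples
#' m <- compute_quality_metrics(c("a", "a", "b", NA))
#' m$completeness  # 0.75
#' @export
compute_quality_metrics <- function(values, validator = NULL,
                                    case_fold = FALSE) {
  values <- sanitize_text(as.character(values))
  n <- length(values)
  missing <- is.na(values) | !nzchar(values)
  present <- values[!missing]
  p <- length(present)
  dvals <- if (case_fold) tolower(present) else present
  d <- length(unique(dvals))
  v <- NA_integer_
  if (!is.null(validator) && p > 0) {
    res <- validator(present)
    if (is.list(res) && !is.null(res$valid)) {
      # single-value validator: apply elementwise
      v <- sum(vapply(present, function(x) isTRUE(validator(x)$valid),
                      logical(1)))
    } else {
      v <- sum(res %in% TRUE)
    }
  }
  out <- list(
    n_records = n, n_missing = sum(missing), n_present = p,
    n_distinct = if (p > 0) d else 0L, n_valid = v,
    completeness = if (n > 0) p / n else NA_real_,
    validity = if (p > 0 && !is.na(v)) v / p else NA_real_,
    uniqueness = if (p > 0) d / p else NA_real_
  )
  class(out) <- "pm_quality_metrics"
  out
}

#' @export
print.pm_quality_metrics <- function(x, ...) {
  cat(sprintf(
    "<metrics> N=%d M=%d P=%d D=%d V=%s | completeness=%s validity=%s uniqueness=%s\n",
    x$n_records, x$n_missing, x$n_present, x$n_distinct,
    if (is.na(x$n_valid)) "NA" else x$n_valid,
    round_metric(x$completeness), round_metric(x$validity),
    round_metric(x$uniqueness)))
  invisible(x)
}

#' Render a ratio as a percentage with three decimals
#'
#' Report tables print each ratio as a percentage rounded half-up to three
#' decimal places (0.713734 renders as "71.373"); the raw ratio is always
#' carried alongside in the report objects. Undefined ratios render as
#' \code{"N/A"}.
#'
#' @param x numeric vector of ratios in [0, 1] (NA allowed).
#' @return character vector.
#' @examples
#' round_metric(0.713734)  # "71.373"
#' round_metric(1)         # "100.000"
#' @export
round_metric <- function(x) {
  out <- rep("N/A", length(x))
  ok <- !is.na(x)
  # round half-up at the third decimal of the percentage; the epsilon
  # counters binary representation error (e.g. 0.0005 * 100 * 1000 = 49.999...)
  scaled <- floor(x[ok] * 100 * 1000 + 0.5 + 1e-9) / 1000
  out[ok] <- sprintf("%.3f", scaled)
  out
}

#' Referential integrity of journal keys against a reference list
#'
#' Every article carries the NLM unique identifier of its journal; the
#' J_MEDLINE reference file lists the identifiers of MEDLINE-indexed
#' journals. Integrity is the fraction of article keys found in the
#' reference set; unmatched identifiers are "dangling" (they would become
#' dangling edges in a graph representation).
#'
#' @param keys character vector of per-article journal keys (NA = article
#'   without a key; excluded from the denominator).
#' @param reference_keys character vector or set of known journal keys;
#'   empty is a configuration error, distinct from 0\% integrity.
#' @return object of class \code{pm_ref_integrity}: \code{n_with_key},
#'   \code{n_matched}, \code{n_affected_articles}, \code{dangling_keys}
#'   (sorted distinct unmatched identifiers), \code{integrity}.
#' @export
referential_integrity <- function(keys, reference_keys) {
  reference_keys <- unique(reference_keys[!is.na(reference_keys)])
  if (length(reference_keys) == 0) {
    stop("empty journal reference set: refusing to report 0% integrity",
         call. = FALSE)
  }
  keys <- keys[!is.na(keys)]
  matched <- keys %in% reference_keys
  out <- list(
    n_with_key = length(keys),
    n_matched = sum(matched),
    n_affected_articles = sum(!matched),
    dangling_keys = sort(unique(keys[!matched])),
    integrity = if (length(keys) > 0) sum(matched) / length(keys) else NA_real_
  )
  class(out) <- "pm_ref_integrity"
  out
}

#' @export
print.pm_ref_integrity <- function(x, ...) {
  cat(sprintf("<referential integrity> %s%% (%d/%d), %d dangling key(s), %d article(s) affected\n",
              round_metric(x$integrity), x$n_matched, x$n_with_key,
              length(x$dangling_keys), x$n_affected_articles))
  invisible(x)
}

#' Read an NLM journal reference file (J_MEDLINE format)
#'
#' The NLM journal lists are plain text: blocks of \code{Key: value} lines
#' separated by dashed lines, with keys such as \code{JrId},
#' \code{JournalTitle}, \code{MedAbbr}, \code{NlmId}.
#'
#' @param path path to the file.
#' @return a tibble with one row per journal block and one column per key
#'   seen in the file.
#' @export
read_jmedline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sep <- grepl("^-{4,}$", lines)
  block_id <- cumsum(sep)
  rows <- lapply(split(lines[!sep], block_id[!sep]), function(block) {
    block <- block[grepl(":", block, fixed = TRUE)]
    if (length(block) == 0) return(NULL)
    keys <- sub(":.*$", "", block)
    vals <- sub("^[^:]*: ?", "", block)
    stats::setNames(as.list(vals), keys)
  })
  rows <- Filter(Negate(is.null), rows)
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}
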
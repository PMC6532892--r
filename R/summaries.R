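#' Fall/rise summary of a set of onglides
#'
#' Counts falling (negative) and rising (positive) onglides and computes the
#' median of the rising subset only — the two statistics the landscape fit
#' matches. Because the normalisation is strictly monotone and odd, counts
#' and the rising proportion are identical whether computed on raw or
#' normalised values.
#'
#' @param values numeric vector of signed onglides (raw or normalised),
#'   non-empty, no zeros.
#' @return A list of class `"onglide_summary"`: `n_falls`, `n_rises`,
#'   `n_total`, `prop_rising`, `median_rising` (`NA` with
#'   `median_defined = FALSE` when there are no rises).
#' @examples
#' onglide_summary(c(-1.2, 0.5, 3.1))
#' @export
onglide_summary <- function(values) {
  if (length(values) == 0L) stop("empty input: nothing to summarise")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric")
  if (any(values == 0)) stop("zero onglides are not allowed")
  n_rises <- sum(values > 0)
  n_falls <- sum(values < 0)
  med <- if (n_rises > 0) stats::median(values[values > 0]) else NA_real_
  structure(list(
    n_falls = n_falls, n_rises = n_rises, n_total = n_falls + n_rises,
    prop_rising = n_rises / (n_falls + n_rises),
    median_rising = med, median_defined = n_rises > 0
  ), class = "onglide_summary")
}

#' @export
print.onglide_summary <- function(x, ...) {
  cat(sprintf("falls %d (%.1f%%)  rises %d (%.1f%%)  median rise %s\n",
              x$n_falls, 100 * (1 - x$prop_rising),
              x$n_rises, 100 * x$prop_rising,
              if (x$median_defined) sprintf("%.3f", x$median_rising)
              else "undefined"))
  invisible(x)
}

#' Grouped fall/rise summaries of an onglide dataset
#'
#' One [onglide_summary()] row per combination of the grouping columns,
#' e.g. per focus condition or per condition and speaker group. Background
#' (unaccented) records are excluded first.
#'
#' @param data a data frame of onglide records with at least a `condition`
#'   column and the column named by `value`.
#' @param by character vector of grouping column names.
#' @param value name of the column holding the signed onglides; defaults to
#'   `"onglide_norm"` if present, else `"onglide_st"`.
#' @return A data frame with the grouping columns plus `n_falls`, `n_rises`,
#'   `n_total`, `prop_rising`, `median_rising`.
#' @export
summarize_onglides <- function(data, by = "condition", value = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(value))
    value <- if ("onglide_norm" %in% names(data)) "onglide_norm" else "onglide_st"
  missing_cols <- setdiff(c(by, value), names(data))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  data <- drop_background(data)
  keys <- lapply(data[by], function(col) factor(col, levels = unique(col)))
  pieces <- split(data[[value]], keys, drop = TRUE)
  out <- do.call(rbind, lapply(names(pieces), function(nm) {
    s <- onglide_summary(pieces[[nm]])
    cbind(
      as.data.frame(setNames(as.list(strsplit(nm, ".", fixed = TRUE)[[1]]), by),
                    stringsAsFactors = FALSE),
      data.frame(n_falls = s$n_falls, n_rises = s$n_rises,
                 n_total = s$n_total, prop_rising = s$prop_rising,
                 median_rising = s$median_rising)
    )
  }))
  rownames(out) <- NULL
  out
}

# remove background (unaccented) rows; they carry no nuclear accent and
# enter no fall/rise summary
drop_background <- function(data) {
  if ("condition" %in% names(data))
    data <- data[data$condition != "background", , drop = FALSE]
  if ("accented" %in% names(data))
    data <- data[data$accented, , drop = FALSE]
  data
}

#' Assign speakers to strategy groups by overall fall usage
#'
#' Speakers who produce falling onglides in more than a third of their
#' accent-bearing utterances (all focus conditions pooled) form group 1
#' (fall-users); the rest — who rise in at least two thirds of cases — form
#' group 2. The boundary (exactly 1/3 falls) belongs to group 2.
#'
#' @param data a data frame of onglide records with `speaker` and an
#'   onglide column.
#' @param value onglide column, as in [summarize_onglides()].
#' @param threshold fall-fraction threshold; group 1 is
#'   `fall_fraction > threshold`.
#' @return A data frame with one row per speaker: `speaker`,
#'   `fall_fraction`, `group` (`"group1"`/`"group2"`).
#' @export
assign_groups <- function(data, value = NULL, threshold = 1 / 3) {
  stopifnot(is.data.frame(data), "speaker" %in% names(data))
  if (is.null(value))
    value <- if ("onglide_norm" %in% names(data)) "onglide_norm" else "onglide_st"
  data <- drop_background(data)
  if (!nrow(data)) stop("no accent-bearing records")
  counts <- table(factor(data$speaker))
  if (any(counts == 0)) stop("speaker with zero accent-bearing records")
  ff <- tapply(data[[value]] < 0, factor(data$speaker), mean)
  out <- data.frame(speaker = names(ff),
                    fall_fraction = as.numeric(ff),
                    group = ifelse(ff > threshold, "group1", "group2"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
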
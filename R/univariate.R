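# Confirmatory univariate analysis: variable-size bucket integration over
# named ppm windows, Mann-Whitney U tests, and percent-variation summaries.

#' Integrate a chemical-shift window
#'
#' Per-sample sum of the values of all buckets intersecting the window;
#' buckets partially covered contribute in proportion to the overlap
#' fraction, so the result is invariant to the fine-vs-coarse bucket
#' representation of the same spectrum. Intended for PQN-normalized,
#' unscaled tables.
#'
#' @param table A [bucket_table()].
#' @param low,high Window bounds (ppm), `low < high`.
#' @return Named numeric vector, one integral per sample.
#' @export
integrate_region <- function(table, low, high) {
  stopifnot(inherits(table, "bucket_table"), low < high)
  ov_lo <- pmax(table$lower, low)
  ov_hi <- pmin(table$upper, high)
  frac <- pmax(0, ov_hi - ov_lo) / (table$upper - table$lower)
  if (all(frac == 0)) stop("window does not overlap any bucket (excluded region?)")
  stats::setNames(drop(table$values %*% frac), rownames(table$values))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. The null distribution is
#' exact when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie and continuity correction is
#' used. `U` is the number of (a, b) pairs with `a > b` (ties count 1/2).
#'
#' @param a,b Numeric vectors (each >= 2 values).
#' @return List with `U` and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p_value = ht$p.value)
}

#' Percent variation of a case-group mean relative to a reference mean
#'
#' `100 * (mean_case - mean_reference) / mean_reference`.
#'
#' @param mean_reference Reference (e.g. BPH) group mean, nonzero.
#' @param mean_case Case (e.g. PCa) group mean.
#' @return Percent change (positive = increase in the case group).
#' @export
percent_variation <- function(mean_reference, mean_case) {
  if (any(mean_reference == 0)) stop("reference mean must be nonzero")
  100 * (mean_case - mean_reference) / mean_reference
}

#' Per-region univariate comparison table
#'
#' For each named window: group means with standard errors (sd/sqrt(n),
#' n - 1 variance denominator), Mann-Whitney U and p, percent variation of
#' the case group relative to the reference group, and a significance flag
#' at `alpha`. Rows are sorted by window position. Optionally
#' Benjamini-Hochberg adjusted p-values are added (raw p-values remain the
#' significance criterion unless `use_adjusted`).
#'
#' @param table A PQN-normalized, unscaled [bucket_table()].
#' @param regions Data.frame with columns `name`, `low`, `high`
#'   (default [default_regions()]).
#' @param labels Group labels per sample (taken from the table if `NULL`).
#' @param reference Label of the reference group (default: first factor
#'   level); the other group is the case group.
#' @param alpha Significance level (default 0.05).
#' @param adjust If `TRUE`, add BH-adjusted p-values and flag on them.
#' @return Data.frame of class `region_table`, one row per region.
#' @export
build_table <- function(table, regions = default_regions(), labels = NULL,
                        reference = NULL, alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(table, "bucket_table"))
  if (is.null(labels)) labels <- table$groups
  if (is.null(labels)) stop("group labels required")
  f <- factor(labels)
  if (nlevels(f) != 2) stop("exactly two groups required")
  if (is.null(reference)) reference <- levels(f)[1]
  if (!reference %in% levels(f)) stop("unknown reference group")
  case <- setdiff(levels(f), reference)
  regions <- regions[order(regions$low), , drop = FALSE]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    v <- integrate_region(table, regions$low[i], regions$high[i])
    va <- v[f == reference]; vb <- v[f == case]
    mw <- mann_whitney(va, vb)
    data.frame(
      name = regions$name[i], low = regions$low[i], high = regions$high[i],
      mean_reference = mean(va), sem_reference = sem(va),
      mean_case = mean(vb), sem_case = sem(vb),
      U = mw$U, p_value = mw$p_value,
      percent_variation = percent_variation(mean(va), mean(vb)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  attr(out, "reference") <- reference
  attr(out, "case") <- case
  class(out) <- c("region_table", "data.frame")
  out
}
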
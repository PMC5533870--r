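# Probabilistic quotient normalization and unit-variance scaling.

#' Probabilistic quotient normalization (PQN)
#'
#' Removes per-sample dilution in four steps: (1) each row is
#' integral-normalized to a common total intensity (the cohort-mean total by
#' default, or a fixed target); (2) the reference spectrum is the
#' element-wise median over samples; (3) per-sample quotients
#' `x_ij / ref_j` are formed over buckets with `ref_j > 0`; (4) each row is
#' divided by the median of its quotients. The returned dilution estimate
#' per sample is the total factor divided out (integral step times quotient
#' median), so on simulated cohorts it is directly comparable to the true
#' dilution factors.
#'
#' @param table A [bucket_table()] with >= 2 samples; small negative values
#'   from noise are tolerated.
#' @param target `"cohort_mean"` (default) normalizes row totals to the
#'   cohort-mean total; `"fixed"` normalizes to 100, which makes the result
#'   for each sample exactly invariant to rescaling that sample alone.
#' @return List with `table` (normalized [bucket_table()]) and `dilution`
#'   (named per-sample factors).
#' @export
pqn_normalize <- function(table, target = c("cohort_mean", "fixed")) {
  stopifnot(inherits(table, "bucket_table"))
  target <- match.arg(target)
  X <- table$values
  if (nrow(X) < 2) stop("PQN requires at least 2 samples")
  totals <- rowSums(X)
  if (any(totals <= 0)) stop("sample with non-positive total intensity")
  tot0 <- if (target == "cohort_mean") mean(totals) else 100
  s <- totals / tot0
  Xn <- X / s
  ref <- apply(Xn, 2, stats::median)
  if (all(ref <= 0)) stop("all-zero reference spectrum")
  use <- ref > 0
  d <- apply(Xn[, use, drop = FALSE] / rep(ref[use], each = nrow(Xn)), 1,
             stats::median)
  if (any(!is.finite(d) | d <= 0)) stop("non-positive quotient median")
  out <- bucket_table(Xn / d, table$lower, table$upper,
                      excluded = table$excluded, groups = table$groups)
  list(table = out, dilution = stats::setNames(s * d, rownames(X)))
}

#' Unit-variance scaling
#'
#' Mean-centres each bucket and divides it by its standard deviation
#' (`n - 1` denominator) so every variable carries equal weight in the
#' multivariate models. Zero-variance buckets are dropped with a warning.
#'
#' @param table A [bucket_table()] with >= 2 samples.
#' @return List with `table` (scaled [bucket_table()]) and `model` (class
#'   `uv_scaling`: per-bucket `center`, `scale`, and `kept` column indices).
#' @export
uv_scale <- function(table) {
  stopifnot(inherits(table, "bucket_table"))
  X <- table$values
  if (nrow(X) < 2) stop("unit-variance scaling requires at least 2 samples")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  if (!all(keep)) warning(sprintf("dropping %d zero-variance bucket(s)",
                                  sum(!keep)))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  out <- bucket_table(Xs, table$lower[keep], table$upper[keep],
                      excluded = table$excluded, groups = table$groups)
  model <- structure(list(center = mu[keep], scale = sd[keep],
                          kept = which(keep)), class = "uv_scaling")
  list(table = out, model = model)
}

#' Apply or invert a stored scaling
#'
#' @param model A `uv_scaling` from [uv_scale()].
#' @param table A [bucket_table()] with the same buckets as the training
#'   table (pre-drop).
#' @param inverse If `TRUE`, undo the scaling instead.
#' @return A [bucket_table()].
#' @export
apply_scaling <- function(model, table, inverse = FALSE) {
  stopifnot(inherits(model, "uv_scaling"), inherits(table, "bucket_table"))
  full <- ncol(table$values) > length(model$kept)
  idx <- if (full) model$kept else seq_along(model$kept)
  X <- table$values[, idx, drop = FALSE]
  X <- if (inverse) sweep(sweep(X, 2, model$scale, "*"), 2, model$center, "+")
       else sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  bucket_table(X, table$lower[idx], table$upper[idx],
               excluded = table$excluded, groups = table$groups)
}
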
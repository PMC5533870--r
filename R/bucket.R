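# Rectangular bucketing of spectra with solvent-region exclusion, and
# rebinning of fine buckets to the analysis width.

#' Solvent/urea exclusion mask
#'
#' Chemical-shift regions removed from the analysis: the residual water
#' region (4.55-5.09 ppm) and the urea region (5.52-6.10 ppm) by default,
#' plus any extra user regions.
#'
#' @param water,urea Length-2 numeric regions (ppm) or `NULL` to omit.
#' @param extra Optional list of further `c(low, high)` regions.
#' @return List of regions, each `c(low, high)` with `low < high`.
#' @export
exclusion_mask <- function(water = c(4.55, 5.09), urea = c(5.52, 6.10),
                           extra = list()) {
  regions <- c(if (!is.null(water)) list(water = water),
               if (!is.null(urea)) list(urea = urea), extra)
  for (r in regions) if (length(r) != 2 || r[1] >= r[2])
    stop("each exclusion region must be c(low, high) with low < high")
  regions
}

#' Bucket table
#'
#' The pipeline's central object: a samples x buckets intensity matrix plus
#' half-open bucket intervals `[low, high)` and the excluded regions.
#'
#' @param values Numeric matrix, rows = samples (rownames = sample ids).
#' @param lower,upper Bucket interval bounds (ppm), ascending, non-overlapping.
#' @param excluded List of excluded `c(low, high)` regions.
#' @param groups Optional character vector of group labels, one per sample.
#' @return An object of class `bucket_table`.
#' @export
bucket_table <- function(values, lower, upper, excluded = list(), groups = NULL) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (length(lower) != k || length(upper) != k) stop("edge/value size mismatch")
  if (any(upper <= lower)) stop("bucket upper bounds must exceed lower bounds")
  if (k > 1 && any(lower[-1] < upper[-k] - 1e-12)) stop("buckets overlap or are unsorted")
  if (!all(is.finite(values))) stop("bucket values must be finite")
  if (!is.null(groups) && length(groups) != nrow(values))
    stop("groups length must match sample count")
  colnames(values) <- sprintf("b%.4f", (lower + upper) / 2)
  structure(list(values = values, lower = as.numeric(lower),
                 upper = as.numeric(upper), excluded = excluded,
                 groups = groups), class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d samples x %d buckets, %.3f-%.3f ppm, %d excluded region(s)\n",
              nrow(x$values), ncol(x$values), min(x$lower), max(x$upper),
              length(x$excluded)))
  invisible(x)
}

#' @export
dim.bucket_table <- function(x) dim(x$values)

# TRUE for buckets [lo, hi) that overlap any masked region (open overlap:
# touching boundaries do not count, so grid-aligned masks drop exactly the
# buckets inside them).
bucket_masked <- function(lo, hi, mask, tol = 1e-9) {
  if (!length(mask)) return(rep(FALSE, length(lo)))
  out <- rep(FALSE, length(lo))
  for (r in mask) out <- out | (lo < r[2] - tol & hi > r[1] + tol)
  out
}

#' Bucket spectra into a samples x buckets matrix
#'
#' Tiles `[range[1], range[2])` with half-open rectangular buckets of the
#' given width, starting at the low-ppm end; any bucket overlapping a masked
#' region is dropped entirely. Each bucket value is the sum of the
#' intensities of the grid points whose ppm falls in the bucket, so total
#' signal over unmasked regions is conserved. With the default 0.01 ppm
#' width over 0.15-9.50 ppm and the water/urea mask this yields 823 buckets
#' (935 tiled, minus 54 water and 58 urea).
#'
#' @param spectra List of [nmr_spectrum()] sharing comparable ppm coverage.
#' @param width Bucket width (ppm, > 0).
#' @param range Length-2 analysis range `c(low, high)` in ppm.
#' @param mask List of excluded regions, e.g. [exclusion_mask()]; use
#'   `list()` for none.
#' @return A [bucket_table()] with sample order preserved.
#' @export
bucket_spectra <- function(spectra, width = 0.001, range = c(0.15, 9.50),
                           mask = exclusion_mask()) {
  stopifnot(width > 0, length(range) == 2, range[1] < range[2])
  nb <- floor((range[2] - range[1]) / width + 1e-9)
  if (nb < 1) stop("range narrower than one bucket")
  lower <- range[1] + (seq_len(nb) - 1) * width
  upper <- range[1] + seq_len(nb) * width
  keep <- !bucket_masked(lower, upper, mask)
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  groups <- vapply(spectra, `[[`, character(1), "group")
  V <- matrix(0, length(spectra), nb, dimnames = list(ids, NULL))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (min(s$ppm) > range[1] + width || max(s$ppm) < range[2] - width)
      stop(sprintf("spectrum '%s' does not cover the bucketing range", s$sample_id))
    idx <- floor((s$ppm - range[1]) / width + 1e-9)
    inside <- idx >= 0L & idx < nb & s$ppm >= range[1] - 1e-12
    sums <- rowsum(s$intensity[inside], idx[inside])
    V[i, as.integer(rownames(sums)) + 1L] <- sums[, 1]
  }
  bucket_table(V[, keep, drop = FALSE], lower[keep], upper[keep],
               excluded = mask, groups = groups)
}

#' Rebin fine buckets into coarser ones
#'
#' Sums groups of `factor` consecutive fine buckets into one coarse bucket.
#' Groups never span an exclusion gap: rebinning restarts at each contiguous
#' segment, and a trailing partial group at a segment end is kept as one
#' (narrower) bucket.
#'
#' @param table A [bucket_table()] of contiguous fine buckets per segment.
#' @param factor Positive integer; `1` returns the table unchanged.
#' @return A [bucket_table()] of coarse buckets.
#' @export
rebin <- function(table, factor = 10L) {
  stopifnot(inherits(table, "bucket_table"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(table)
  k <- ncol(table$values)
  # contiguous segments: consecutive buckets whose edges touch
  brk <- which(abs(table$lower[-1] - table$upper[-k]) > 1e-9)
  seg <- rep(seq_len(length(brk) + 1), diff(c(0, brk, k)))
  if (min(tabulate(seg)) < factor)
    stop("rebin factor exceeds the length of an unmasked segment")
  grp <- unlist(lapply(split(seq_len(k), factor(seg, levels = unique(seg))), function(ix) {
    ceiling(seq_along(ix) / factor)
  }), use.names = FALSE)
  gid <- paste(seg, grp, sep = ".")
  gid <- factor(gid, levels = unique(gid))
  V <- t(rowsum(t(table$values), gid, reorder = FALSE))
  lower <- as.numeric(tapply(table$lower, gid, min)[levels(gid)])
  upper <- as.numeric(tapply(table$upper, gid, max)[levels(gid)])
  bucket_table(V, lower, upper, excluded = table$excluded, groups = table$groups)
}

#' Write / read a bucket table as CSV plus a JSON sidecar
#'
#' The CSV holds `sample_id` followed by one column per bucket named by its
#' center ("b4.0550"); bucket edges, excluded regions and group labels go to
#' `<path>.json`.
#'
#' @param table A [bucket_table()].
#' @param path CSV path.
#' @return `write_bucket_table`: invisibly, `path`. `read_bucket_table`: the
#'   reconstructed [bucket_table()].
#' @export
write_bucket_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(lower = table$lower, upper = table$upper,
                            excluded = table$excluded, groups = table$groups),
                       paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_bucket_table
#' @export
read_bucket_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df$sample_id
  excl <- side$excluded
  if (is.matrix(excl)) excl <- lapply(seq_len(nrow(excl)), function(i) excl[i, ])
  bucket_table(V, side$lower, side$upper, excluded = excl,
               groups = if (length(side$groups)) side$groups else NULL)
}
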
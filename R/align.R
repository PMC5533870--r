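# Cluster-based peak alignment of fine-bucketed spectra.
#
# A simplified hierarchical segment aligner: a reference sample is chosen by
# maximal mean correlation to the rest; within each unmasked segment, each
# sample is shifted (whole buckets, bounded lag) to the lag maximizing
# cross-correlation with the reference, then the segment is split at the
# largest gap between reference peaks and the halves are aligned recursively.

# integer shift with zero fill
shift_vec <- function(v, lag) {
  n <- length(v)
  if (lag == 0 || abs(lag) >= n) return(if (lag == 0) v else numeric(n))
  if (lag > 0) c(numeric(lag), v[seq_len(n - lag)])
  else c(v[(1 - lag):n], numeric(-lag))
}

best_lag <- function(ref, x, max_shift) {
  lags <- -max_shift:max_shift
  cc <- vapply(lags, function(l) sum(ref * shift_vec(x, l)), numeric(1))
  lags[which.max(cc)]
}

# local maxima above a noise-derived threshold
find_peaks <- function(x, threshold) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > threshold) + 1L
}

align_segment <- function(ref, x, max_shift, ref_peaks, min_len = 20L) {
  n <- length(x)
  if (n < min_len || max_shift < 1) return(x)
  lag <- best_lag(ref, x, min(max_shift, n %/% 3))
  x <- shift_vec(x, lag)
  pk <- ref_peaks[ref_peaks >= 1 & ref_peaks <= n]
  if (length(pk) >= 2) {
    gaps <- diff(pk)
    g <- which.max(gaps)
    if (gaps[g] >= 4L) {
      cut <- pk[g] + gaps[g] %/% 2L
      left <- 1:cut; right <- (cut + 1L):n
      x[left] <- align_segment(ref[left], x[left], max_shift,
                               ref_peaks[ref_peaks <= cut], min_len)
      x[right] <- align_segment(ref[right], x[right], max_shift,
                                ref_peaks[ref_peaks > cut] - cut, min_len)
    }
  }
  x
}

#' Align bucketed spectra to a common reference
#'
#' Operates on the fine (pre-rebin) bucket grid. The reference sample is the
#' one with the highest mean correlation to all others. Peaks are local
#' maxima above `median + 3 * MAD` of the reference row; segments delimited
#' by the largest inter-peak gaps are recursively shifted by whole-bucket
#' lags (at most `max_shift`) to maximize cross-correlation with the
#' reference. Shifted-out buckets are zero-filled, so per-sample totals are
#' conserved up to edge effects. Sample order and group labels are
#' untouched.
#'
#' @param table A [bucket_table()] on the fine grid.
#' @param max_shift Maximum shift in buckets (>= 1).
#' @return An aligned [bucket_table()] with attribute `"reference"` naming
#'   the reference sample.
#' @export
align_spectra <- function(table, max_shift = 50L) {
  stopifnot(inherits(table, "bucket_table"), max_shift >= 1)
  X <- table$values
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty bucket table")
  if (nrow(X) < 3) return(table)
  cm <- suppressWarnings(stats::cor(t(X)))
  cm[!is.finite(cm)] <- 0
  ref_i <- which.max(rowMeans(cm))
  ref <- X[ref_i, ]
  thr <- stats::median(ref) + 3 * stats::mad(ref)

  k <- ncol(X)
  brk <- which(abs(table$lower[-1] - table$upper[-k]) > 1e-9)
  seg_id <- rep(seq_len(length(brk) + 1), diff(c(0, brk, k)))
  out <- X
  for (s in unique(seg_id)) {
    cols <- which(seg_id == s)
    rseg <- ref[cols]
    rpk <- find_peaks(rseg, thr)
    for (i in seq_len(nrow(X))) {
      if (i == ref_i) next
      out[i, cols] <- align_segment(rseg, X[i, cols], max_shift, rpk)
    }
  }
  res <- bucket_table(out, table$lower, table$upper,
                      excluded = table$excluded, groups = table$groups)
  attr(res, "reference") <- rownames(X)[ref_i]
  res
}
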
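# PCA screening with Hotelling T2 outlier flagging.

#' Fit a PCA screening model
#'
#' SVD-based principal components on the column-centred matrix, used to look
#' for patterns, clusters and outlying samples before any supervised
#' modelling. Hotelling T2 per sample is the Mahalanobis distance in score
#' space; the critical value is the usual F-based limit
#' `A(n-1)/(n-A) * F(1-alpha; A, n-A)` for `A` components and `n` samples.
#'
#' @param X Numeric matrix (samples x variables), typically UV-scaled, or a
#'   [bucket_table()].
#' @param n_components Number of components (<= min(n-1, p)).
#' @param alpha Significance level for the stored T2 critical value.
#' @return An object of class `pca_model` with `loadings` (orthonormal
#'   columns), `scores`, `explained` (variance fractions, non-increasing),
#'   `t2`, `t2_crit`, `alpha`, `n`.
#' @export
pca_fit <- function(X, n_components = 2L, alpha = 0.05) {
  if (inherits(X, "bucket_table")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_components > min(n - 1L, ncol(X)))
    stop("n_components exceeds min(samples - 1, variables)")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = n_components, nv = n_components)
  if (sv$d[1] <= 0) stop("degenerate (zero) matrix")
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(X)
  lambda <- sv$d[seq_len(n_components)]^2 / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  structure(list(
    loadings = sv$v, scores = scores,
    explained = sv$d^2 / sum(sv$d^2),
    score_var = lambda, t2 = t2,
    t2_crit = t2_critical(n, n_components, alpha),
    alpha = alpha, n = n, n_components = n_components,
    center = colMeans(X)), class = "pca_model")
}

t2_critical <- function(n, a, alpha) {
  a * (n - 1) / (n - a) * stats::qf(1 - alpha, a, n - a)
}

#' Flag outlying samples by Hotelling T2
#'
#' Samples whose T2 exceeds the F-based critical value at level `alpha` are
#' flagged. Flagging is advisory: excluding flagged samples is an explicit
#' pipeline configuration choice, never automatic.
#'
#' @param model A fitted [pca_fit()] model.
#' @param alpha Significance level; as `alpha -> 0` nothing is flagged.
#' @return Character vector of flagged sample ids.
#' @export
flag_outliers <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pca_model"))
  crit <- t2_critical(model$n, model$n_components, alpha)
  ids <- names(model$t2)
  if (is.null(ids)) ids <- as.character(seq_along(model$t2))
  ids[model$t2 > crit]
}
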
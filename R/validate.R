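# Model validation: stratified sevenfold cross-validation, label permutation
# testing, CV-ANOVA, and regression-coefficient variable selection.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(0, (colSums(X * X) - n * mu * mu) / (n - 1)))
}

scale_matrix <- function(X) {
  mu <- colMeans(X)
  sd <- col_sds(X)
  sd[sd == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sd, "/")
}

stratified_folds <- function(y, n_folds, max_tries = 10L) {
  f <- factor(y)
  for (try in seq_len(max_tries)) {
    fold <- integer(length(y))
    for (lv in levels(f)) {
      idx <- sample(which(f == lv))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(k)
      length(unique(f[fold == k])) == 2L, logical(1)))
    if (ok) return(fold)
    warning("fold with a single class; reshuffling")
  }
  stop("could not build stratified folds with both classes in every fold")
}

#' Sevenfold cross-validation of an OPLS-DA model
#'
#' Stratified folds; within each fold the scaling is refit on the training
#' samples (or skipped for pre-scaled input), the model refit, and the
#' held-out samples predicted. Q2Y = 1 - PRESS / SS(y). The per-variable
#' cross-validation standard error of the regression coefficients uses the
#' jackknife convention over the fold models,
#' `b_cvSE = sqrt((K-1)/K * sum_k (b_k - mean(b))^2)`.
#' Deterministic given `seed`.
#'
#' @param X Matrix or [bucket_table()]. With `scale = "refit"` pass the
#'   unscaled (PQN-normalized) matrix; with `"none"` pass a pre-scaled one.
#' @param y Two-level labels (taken from the table's groups if `NULL`).
#' @param n_orthogonal Orthogonal components for each fold model.
#' @param n_folds Number of folds (default 7).
#' @param seed Integer seed for the fold assignment.
#' @param scale `"refit"` (fold-wise unit-variance scaling, avoids leakage)
#'   or `"none"`.
#' @param levels Optional class level order.
#' @return Object of class `oplsda_cv`: `folds`, `b_folds` (K x p),
#'   `b_cvSE`, `Q2Y`, `press`, `ss`, `predictions` (CV predicted y),
#'   `y_encoded`, plus bookkeeping.
#' @export
cross_validate <- function(X, y = NULL, n_orthogonal = 1L, n_folds = 7L,
                           seed = 1L, scale = c("refit", "none"),
                           levels = NULL) {
  scale <- match.arg(scale)
  if (inherits(X, "bucket_table")) { if (is.null(y)) y <- X$groups; X <- X$values }
  X <- as.matrix(X)
  enc <- encode_classes(y, levels)
  n <- nrow(X)
  if (n_folds < 2 || n_folds > n) stop("invalid number of folds")
  fold <- with_seed(seed, stratified_folds(y, n_folds))
  yc <- enc$y - mean(enc$y)
  pred <- numeric(n)
  B <- matrix(0, n_folds, ncol(X))
  for (k in seq_len(n_folds)) {
    te <- fold == k
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (scale == "refit") {
      mu <- colMeans(Xtr); sdv <- col_sds(Xtr); sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    fit <- oplsda_fit(Xtr, y[!te], n_orthogonal, levels = enc$levels)
    pred[te] <- predict(fit, Xte)$y
    B[k, ] <- fit$b
  }
  press <- sum((enc$y - pred)^2)
  ss <- sum(yc^2)
  # jackknife variance over fold models: (K-1)/K * sum((b_k - mean)^2)
  b_dev <- sweep(B, 2, colMeans(B))
  b_se <- sqrt((n_folds - 1) / n_folds * colSums(b_dev^2))
  structure(list(
    folds = fold, b_folds = B,
    b_cvSE = b_se,
    Q2Y = 1 - press / ss, press = press, ss = ss,
    predictions = pred, y_encoded = enc$y, class_levels = enc$levels,
    n_orthogonal = n_orthogonal, n_folds = n_folds, seed = seed,
    scale = scale), class = "oplsda_cv")
}

#' CV-ANOVA significance test
#'
#' Compares the cross-validated predictive residuals against the total
#' response variation with an F statistic:
#' `F = ((SS - PRESS)/A) / (PRESS/(N - 1 - A))` with `A` model components
#' (1 predictive + orthogonal) and `N` samples. A model predicting no
#' better than the mean gives F <= 0, reported as p = 1; zero residuals
#' give p = 0.
#'
#' @param cv An [cross_validate()] result.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
cv_anova <- function(cv) {
  stopifnot(inherits(cv, "oplsda_cv"))
  A <- cv$n_orthogonal + 1L
  N <- length(cv$y_encoded)
  df2 <- N - 1L - A
  if (df2 <= 0) stop("too few samples for CV-ANOVA")
  if (cv$press == 0) return(list(F = Inf, df1 = A, df2 = df2, p_value = 0))
  Fstat <- ((cv$ss - cv$press) / A) / (cv$press / df2)
  p <- if (Fstat <= 0) 1 else stats::pf(Fstat, A, df2, lower.tail = FALSE)
  list(F = Fstat, df1 = A, df2 = df2, p_value = p)
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model and its cross-validation under `n_permutations` random
#' relabelings, recording for each the absolute correlation of the permuted
#' to the original class vector together with R2Y and Q2Y. The R2/Q2
#' intercepts are the values at correlation 0 of least-squares lines through
#' the permuted points plus the original model at correlation 1. The
#' empirical p-value for Q2Y is `(1 + #{Q2_perm >= Q2_orig}) /
#' (n_permutations + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of label permutations (>= 10; default 100).
#' @return Object of class `oplsda_permutation`: `permuted` (data.frame
#'   with `correlation`, `R2Y`, `Q2Y`), `R2Y`, `Q2Y` (original),
#'   `R2_intercept`, `Q2_intercept`, `p_value`.
#' @export
permutation_test <- function(X, y = NULL, n_orthogonal = 1L,
                             n_permutations = 100L, n_folds = 7L,
                             seed = 1L, scale = c("refit", "none"),
                             levels = NULL) {
  scale <- match.arg(scale)
  if (n_permutations < 10) stop("n_permutations must be >= 10")
  if (inherits(X, "bucket_table")) { if (is.null(y)) y <- X$groups; X <- X$values }
  X <- as.matrix(X)
  enc <- encode_classes(y, levels)
  Xs <- if (scale == "refit") scale_matrix(X) else X

  fit0 <- oplsda_fit(Xs, y, n_orthogonal, levels = enc$levels)
  cv0 <- cross_validate(X, y, n_orthogonal, n_folds, seed = seed,
                        scale = scale, levels = enc$levels)
  perms <- with_seed(seed, {
    lapply(seq_len(n_permutations), function(i)
      list(y = sample(y), cv_seed = sample.int(2^31 - 2, 1)))
  })
  rec <- vapply(perms, function(pm) {
    ye <- encode_classes(pm$y, enc$levels)$y
    r <- abs(stats::cor(ye, enc$y))
    fit <- oplsda_fit(Xs, pm$y, n_orthogonal, levels = enc$levels)
    cv <- cross_validate(X, pm$y, n_orthogonal, n_folds, seed = pm$cv_seed,
                         scale = scale, levels = enc$levels)
    c(correlation = r, R2Y = fit$R2Y, Q2Y = cv$Q2Y)
  }, numeric(3))
  permuted <- as.data.frame(t(rec))
  xr <- c(permuted$correlation, 1)
  r2_int <- unname(stats::coef(stats::lm(c(permuted$R2Y, fit0$R2Y) ~ xr))[1])
  q2_int <- unname(stats::coef(stats::lm(c(permuted$Q2Y, cv0$Q2Y) ~ xr))[1])
  structure(list(
    permuted = permuted, n_permutations = n_permutations,
    R2Y = fit0$R2Y, Q2Y = cv0$Q2Y,
    R2_intercept = r2_int, Q2_intercept = q2_int,
    p_value = (1 + sum(permuted$Q2Y >= cv0$Q2Y)) / (n_permutations + 1),
    seed = seed), class = "oplsda_permutation")
}

#' @export
print.oplsda_permutation <- function(x, ...) {
  cat(sprintf(paste0("<oplsda_permutation> n = %d: R2Y = %.3f (intercept %.3f), ",
                     "Q2Y = %.3f (intercept %.3f), p = %.4g\n"),
              x$n_permutations, x$R2Y, x$R2_intercept, x$Q2Y,
              x$Q2_intercept, x$p_value))
  invisible(x)
}

#' Regression-coefficient variable selection
#'
#' Retains the variables whose full-data regression coefficient exceeds its
#' cross-validation standard error: `|b / b_cvSE| > threshold` (default 1).
#' Variables with zero standard error but nonzero coefficient are kept (the
#' ratio is infinite); all-zero variables are dropped.
#'
#' @param model Full-data [oplsda_fit()] model supplying `b`.
#' @param cv [cross_validate()] result supplying `b_cvSE`.
#' @param threshold Selection threshold (default 1.0).
#' @return Object of class `variable_selection`: `ratio`, `keep` (logical),
#'   `kept` (indices), `threshold`.
#' @export
select_variables <- function(model, cv, threshold = 1.0) {
  stopifnot(inherits(model, "oplsda"), inherits(cv, "oplsda_cv"))
  b <- model$b; se <- cv$b_cvSE
  if (length(b) != length(se)) stop("b and b_cvSE lengths differ")
  ratio <- abs(b) / se
  ratio[b == 0] <- 0
  ratio[b != 0 & se == 0] <- Inf
  keep <- ratio > threshold
  structure(list(ratio = ratio, keep = keep, kept = which(keep),
                 ids = names(b), threshold = threshold),
            class = "variable_selection")
}

#' @export
print.variable_selection <- function(x, ...) {
  cat(sprintf("<variable_selection> |b/b_cvSE| > %g: %d of %d variables kept\n",
              x$threshold, sum(x$keep), length(x$keep)))
  invisible(x)
}
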
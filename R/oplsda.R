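# OPLS-DA: orthogonal projections to latent structures discriminant analysis.
#
# Two-class OPLS with a single predictive component. Orthogonal components
# are estimated and removed by sequential deflation (w_o proportional to
# p - (w'p) w), after which one PLS component is fit on the deflated matrix.
# With a univariate response the NIPALS weight step is closed-form
# (w = X'y / ||X'y||), so no iteration is needed.

encode_classes <- function(y, levels = NULL) {
  f <- if (is.null(levels)) factor(y) else factor(y, levels = levels)
  if (nlevels(f) != 2) stop("exactly two classes are required")
  if (any(table(f) < 2)) stop("each class needs at least 2 samples")
  list(y = ifelse(as.integer(f) == 2L, 1, -1), levels = levels(f))
}

#' Fit a two-class OPLS-DA model
#'
#' The class variable is encoded -1 (first level) / +1 (second level) and
#' centred. `n_orthogonal` orthogonal components are removed from `X` by
#' sequential deflation, then a single predictive component is fit. The
#' regression vector `b` maps the original (scaled, uncentred) variable
#' space to predictions, composing the orthogonal filters with the
#' predictive weights, so `predict()` needs only a matrix product.
#'
#' @param X Numeric matrix (samples x variables), typically UV-scaled, or a
#'   [bucket_table()].
#' @param y Two-level class labels (factor or character).
#' @param n_orthogonal Number of orthogonal components (>= 0, < rank).
#' @param levels Optional explicit class level order (first -> -1,
#'   second -> +1).
#' @return An object of class `oplsda` with predictive weights `w` (unit
#'   norm), loading `p`, scores `t`, y-loading `q`, orthogonal `Wo`, `Po`,
#'   `To`, regression vector `b` plus intercept `b0`, `R2Y`, and the class
#'   encoding. Every orthogonal score is uncorrelated with the encoded
#'   response by construction.
#' @export
oplsda_fit <- function(X, y, n_orthogonal = 1L, levels = NULL) {
  if (inherits(X, "bucket_table")) {
    if (is.null(y)) y <- X$groups
    X <- X$values
  }
  X <- as.matrix(X)
  enc <- encode_classes(y, levels)
  n <- nrow(X); p <- ncol(X)
  if (n_orthogonal < 0) stop("n_orthogonal must be >= 0")
  if (n_orthogonal >= min(n - 1L, p)) stop("n_orthogonal must be below the matrix rank")
  xmeans <- colMeans(X)
  Xc <- sweep(X, 2, xmeans)
  ymean <- mean(enc$y)
  yc <- enc$y - ymean

  wv <- drop(crossprod(Xc, yc))
  nw <- sqrt(sum(wv^2))
  if (nw == 0) stop("degenerate response: X carries no class covariance")
  wv <- wv / nw
  Wo <- Po <- matrix(0, p, 0); To <- matrix(0, n, 0)
  Xd <- Xc
  for (o in seq_len(n_orthogonal)) {
    t1 <- drop(Xd %*% wv)
    pv <- drop(crossprod(Xd, t1)) / sum(t1^2)
    wo <- pv - sum(wv * pv) * wv
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break   # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  tv <- drop(Xd %*% wv)
  pv <- drop(crossprod(Xd, tv)) / sum(tv^2)
  qv <- sum(tv * yc) / sum(tv^2)
  yhat <- tv * qv
  R2Y <- 1 - sum((yc - yhat)^2) / sum(yc^2)

  # b in centred space: compose the orthogonal filters with w * q
  b <- wv * qv
  for (o in rev(seq_len(ncol(Wo)))) b <- b - Wo[, o] * sum(Po[, o] * b)
  names(b) <- colnames(X)
  structure(list(
    w = wv, p = pv, t = tv, q = qv, Wo = Wo, Po = Po, To = To,
    b = b, b0 = ymean - sum(xmeans * b), xmeans = xmeans, ymean = ymean,
    n_orthogonal = ncol(Wo), R2Y = R2Y,
    class_levels = enc$levels,
    class_map = stats::setNames(c(-1, 1), enc$levels),
    y_encoded = enc$y, fitted = yhat + ymean), class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("<oplsda> %s(-1) vs %s(+1): 1 predictive + %d orthogonal, R2Y = %.3f\n",
              x$class_levels[1], x$class_levels[2], x$n_orthogonal, x$R2Y))
  invisible(x)
}

#' Predict from an OPLS-DA model
#'
#' @param object A fitted [oplsda_fit()] model.
#' @param newdata Matrix (samples x variables) in the same (scaled) variable
#'   space as the training matrix, or a [bucket_table()].
#' @param ... Unused.
#' @return List with `y` (continuous predictions on the +/-1 scale) and
#'   `class` (labels by sign).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  if (inherits(newdata, "bucket_table")) newdata <- newdata$values
  yhat <- drop(as.matrix(newdata) %*% object$b) + object$b0
  list(y = yhat,
       class = ifelse(yhat >= 0, object$class_levels[2], object$class_levels[1]))
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP over the predictive component(s):
#' `VIP_j = sqrt(k * sum_a SSY_a w_aj^2 / sum_a SSY_a)` with `k` variables.
#' With unit-norm weights the mean squared VIP equals 1 exactly.
#'
#' @param model A fitted [oplsda_fit()] model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  w <- model$w / sqrt(sum(model$w^2))
  v <- sqrt(length(w) * w^2)
  names(v) <- names(model$b)
  v
}
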
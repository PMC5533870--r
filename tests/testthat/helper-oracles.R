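# Independent oracles used to check the package implementation, written
# straight from the textbook definitions and sharing no code with R/.

# One-latent-variable PLS1 by iterative NIPALS (univariate response).
pls1_nipals_oracle <- function(X, y, max_iter = 500, tol = 1e-12) {
  X <- as.matrix(X)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx); yc <- y - my
  u <- yc
  w_old <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    w <- drop(crossprod(Xc, u)); w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    q <- sum(yc * t) / sum(t^2)
    u <- yc * q / q   # univariate y: u stays proportional to yc
    if (sum((w - w_old)^2) < tol) break
    w_old <- w
  }
  b <- w * q
  list(w = w, b = b,
       predict = function(Xnew) drop(sweep(as.matrix(Xnew), 2, mx) %*% b) + my)
}

# Exact two-sided Mann-Whitney by full enumeration of rank assignments.
mann_whitney_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_null <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  list(U = u_obs, p_value = min(1, 2 * min(p_lo, p_hi)))
}

# Independent bucket-count oracle: explicitly build every tiled interval and
# drop those intersecting a masked region.
count_buckets_oracle <- function(low, high, width, mask) {
  count <- 0L
  i <- 0L
  repeat {
    lo <- low + i * width
    hi <- lo + width
    if (hi > high + 1e-9) break
    hit <- FALSE
    for (r in mask) if (lo < r[2] - 1e-9 && hi > r[1] + 1e-9) hit <- TRUE
    if (!hit) count <- count + 1L
    i <- i + 1L
  }
  count
}

# Small fast cohorts for unit tests: narrow grid, modest n.
small_cohort <- function(seed = 1, n_a = 8, n_b = 8, ...) {
  simulate_cohort(cohort_config(
    n_group_a = n_a, n_group_b = n_b, seed = seed,
    ppm_grid = c(0.15, 4.50, 0.001), ...))
}

# Two-cluster separable matrix for model tests.
separable_data <- function(n_per = 15, p = 20, delta = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n_per)
  X <- matrix(rnorm(2 * n_per * p, sd = 0.1), 2 * n_per, p)
  X[y == "B", 1:3] <- X[y == "B", 1:3] + delta
  list(X = X, y = y)
}

expect_mostly_equal <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y)), tol)
}
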
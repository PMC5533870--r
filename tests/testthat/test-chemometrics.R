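# PCA screening, OPLS-DA, cross-validation, permutation, selection, VIP.

test_that("PCA recovers a planted dominant direction and is orthonormal", {
  set.seed(11)
  n <- 50; p <- 40
  dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
  X <- outer(rnorm(n, sd = 5), dir) + matrix(rnorm(n * p, sd = 0.2), n, p)
  m <- pca_fit(X, 3)
  expect_gt(abs(sum(m$loadings[, 1] * dir)), 0.99)
  expect_mostly_equal(crossprod(m$loadings), diag(3), 1e-8)
  expect_mostly_equal(colMeans(m$scores), rep(0, 3), 1e-10)
  expect_true(all(diff(m$explained) <= 1e-12))
})

test_that("Hotelling T2 flags a contaminated sample and respects alpha", {
  co <- small_cohort(seed = 13, n_a = 10, n_b = 10)
  bt <- bucket_spectra(co$spectra, width = 0.01, range = c(0.15, 4.5),
                       mask = list())
  # flood a broad region of one sample with a 10x contaminant: enough signal
  # to dominate the screening plane, as a gross exogenous interference would
  spike_cols <- which(bt$lower >= 3.0 & bt$upper <= 4.2)
  bt$values[5, spike_cols] <- bt$values[5, spike_cols] +
    10 * max(bt$values[5, ])
  uv <- uv_scale(pqn_normalize(bt)$table)
  m <- pca_fit(uv$table$values, 2)
  expect_true(rownames(bt$values)[5] %in% flag_outliers(m, 0.05))
  expect_length(flag_outliers(m, 1e-12), 0L)
})

test_that("null T2 flagging rate is near the nominal level", {
  rates <- vapply(1:30, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 10), 40, 10)
    length(flag_outliers(pca_fit(X, 2), 0.05)) / 40
  }, numeric(1))
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.12)
})

test_that("OPLS-DA with zero orthogonal components matches the NIPALS PLS1 oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(12:30, 1); p <- sample(5:25, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(rep(c("A", "B"), length.out = n))
    ylev <- ifelse(y == "B", 1, -1)
    fit <- oplsda_fit(X, y, n_orthogonal = 0)
    oracle <- pls1_nipals_oracle(X, ylev)
    expect_mostly_equal(predict(fit, X)$y, oracle$predict(X), 1e-8)
  }
})

test_that("the mixOmics PLS backend agrees with the zero-orthogonal model", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(17)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  y <- rep(c("A", "B"), each = 15)
  fit <- oplsda_fit(X, y, 0)
  mo <- mixOmics::pls(X, ifelse(y == "B", 1, -1), ncomp = 1, scale = FALSE,
                      mode = "regression")
  pr <- predict(mo, X)$predict[, 1, 1]
  expect_mostly_equal(predict(fit, X)$y, pr, 1e-6)
})

test_that("orthogonal scores carry no class correlation and b reproduces fits", {
  d <- separable_data(n_per = 12, p = 15, delta = 2, seed = 3)
  Xs <- scale(d$X)
  for (k in 1:3) {
    fit <- oplsda_fit(Xs, d$y, k)
    expect_lt(max(abs(cor(fit$To, fit$y_encoded))), 1e-8)
    expect_mostly_equal(predict(fit, Xs)$y, fit$fitted, 1e-10)
    expect_equal(sum(fit$w^2), 1)
  }
})

test_that("a separable cohort is fit almost perfectly", {
  d <- separable_data(n_per = 15, p = 20, delta = 6, seed = 4)
  fit <- oplsda_fit(scale(d$X), d$y, 1)
  expect_gt(fit$R2Y, 0.99)
  expect_true(all(predict(fit, scale(d$X))$class == d$y))
})

test_that("degenerate model inputs are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(oplsda_fit(X, rep("A", 10), 1), "two classes")
  expect_error(oplsda_fit(X, rep(c("A", "B", "C"), length.out = 10), 1),
               "two classes")
  expect_error(oplsda_fit(X, rep(c("A", "B"), 5), 10), "rank")
})

test_that("VIP scores satisfy the normalization and symmetry identities", {
  d <- separable_data(seed = 5)
  fit <- oplsda_fit(scale(d$X), d$y, 1)
  v <- vip_scores(fit)
  expect_lt(abs(mean(v^2) - 1), 1e-10)
  # identical variables share one VIP of exactly 1
  Xid <- matrix(rep(rnorm(20), 6), 20, 6)
  yid <- rep(c("A", "B"), 10)
  vid <- vip_scores(oplsda_fit(Xid, yid, 0))
  expect_equal(unname(vid), rep(1, 6))
  # one informative variable among k noiseless others approaches sqrt(k)
  k <- 16
  y <- rep(c(-1, 1), each = 10)
  Xone <- cbind(y, matrix(1e-8 * rnorm(20 * (k - 1)), 20, k - 1))
  vone <- vip_scores(oplsda_fit(Xone, rep(c("A", "B"), each = 10), 0))
  expect_lt(abs(vone[1] - sqrt(k)), 1e-3)
})

test_that("cross-validation is deterministic, bounded by R2Y, and sharp in limits", {
  d <- separable_data(n_per = 14, p = 10, delta = 6, seed = 6)
  cv1 <- cross_validate(d$X, d$y, 1, 7, seed = 99)
  cv2 <- cross_validate(d$X, d$y, 1, 7, seed = 99)
  expect_identical(cv1, cv2)
  expect_gt(cv1$Q2Y, 0.95)   # near-duplicated noiseless classes: PRESS -> 0
  # Q2Y <= R2Y across seeded cohorts
  for (s in 1:8) {
    set.seed(s)
    n <- 30; p <- 25
    y <- rep(c("A", "B"), each = 15)
    X <- matrix(rnorm(n * p), n, p)
    X[y == "B", 1:4] <- X[y == "B", 1:4] + runif(1, 0, 2)
    fit <- oplsda_fit(scale(X), y, 1)
    cv <- cross_validate(X, y, 1, 7, seed = s)
    expect_lt(cv$Q2Y, fit$R2Y + 1e-8)
  }
})

test_that("permuted labels on null data give non-positive Q2Y on average", {
  q2 <- vapply(1:15, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 30), 40, 30)
    y <- sample(rep(c("A", "B"), 20))
    cross_validate(X, y, 1, 7, seed = s)$Q2Y
  }, numeric(1))
  expect_lt(mean(q2), 0)
})

test_that("folds partition samples, are stratified, and bad fold counts error", {
  y <- rep(c("A", "B"), c(20, 15))
  X <- matrix(rnorm(35 * 10), 35, 10)
  cv <- cross_validate(X, y, 1, 7, seed = 1)
  expect_equal(sort(unique(cv$folds)), 1:7)
  for (k in 1:7) expect_equal(length(unique(y[cv$folds == k])), 2L)
  expect_error(cross_validate(X, y, 1, 40, seed = 1), "folds")
  expect_error(suppressWarnings(cross_validate(X[1:6, ], rep(c("A","B"), c(4,2)),
                                               1, 3, seed = 1)),
               "stratified")
})

test_that("CV-ANOVA is significant for strong signal and controlled under the null", {
  d <- separable_data(n_per = 15, p = 10, delta = 4, seed = 7)
  cv <- cross_validate(d$X, d$y, 1, 7, seed = 7)
  expect_lt(cv_anova(cv)$p_value, 0.01)
  hits <- 0
  for (s in 1:25) {
    set.seed(s)
    X <- matrix(rnorm(36 * 20), 36, 20)
    y <- rep(c("A", "B"), 18)
    p <- cv_anova(cross_validate(X, y, 1, 6, seed = s))$p_value
    expect_gte(p, 0); expect_lte(p, 1)
    if (p <= 0.01) hits <- hits + 1
  }
  expect_lte(hits / 25, 0.08)   # conservative under the null
})

test_that("b-coefficient selection applies the |b/b_cvSE| rule", {
  fake_model <- structure(list(b = c(v1 = 0.5, v2 = 0.01, v3 = 0, v4 = -0.4)),
                          class = "oplsda")
  fake_cv <- structure(list(b_cvSE = c(0, 0.5, 0.2, 0.1)), class = "oplsda_cv")
  sel <- select_variables(fake_model, fake_cv, threshold = 1)
  expect_true(sel$keep[["v1"]])    # stable nonzero coefficient, zero SE
  expect_false(sel$keep[["v2"]])   # tiny coefficient, large SE
  expect_false(sel$keep[["v3"]])   # zero coefficient stays out
  expect_true(sel$keep[["v4"]])
})

test_that("fold coefficients alternating in sign are dropped", {
  # engineered fold coefficients: the jackknife SE dwarfs the mean
  B <- matrix(c(rep(c(1, -1), length.out = 7), rep(0.5, 7)), 7, 2)
  dev <- sweep(B, 2, colMeans(B))
  se <- sqrt(6 / 7 * colSums(dev^2))
  fake_cv <- structure(list(b_cvSE = se), class = "oplsda_cv")
  fake_model <- structure(list(b = colMeans(B)), class = "oplsda")
  sel <- select_variables(fake_model, fake_cv, 1)
  expect_false(sel$keep[1])
  expect_true(sel$keep[2])
})

test_that("selection enriches perturbed windows over background buckets", {
  co <- simulate_cohort(cohort_config(seed = 7, baseline_amplitude = 0))
  bt <- bucket_spectra(co$spectra, width = 0.01)
  pq <- pqn_normalize(bt)
  fit <- oplsda_fit(uv_scale(pq$table)$table$values, bt$groups, 1)
  cv <- cross_validate(pq$table$values, bt$groups, 1, 7, seed = 1)
  sel <- select_variables(fit, cv)
  reg <- default_regions()
  inwin <- rep(FALSE, ncol(pq$table$values))
  for (i in seq_len(nrow(reg)))
    inwin <- inwin | (pq$table$upper > reg$low[i] & pq$table$lower < reg$high[i])
  expect_gt(mean(sel$keep[inwin]), mean(sel$keep[!inwin]))
})

test_that("permutation test records are complete, reproducible and sane", {
  d <- separable_data(n_per = 12, p = 15, delta = 3, seed = 9)
  pm <- permutation_test(d$X, d$y, 1, n_permutations = 20, n_folds = 4,
                         seed = 5)
  pm2 <- permutation_test(d$X, d$y, 1, n_permutations = 20, n_folds = 4,
                          seed = 5)
  expect_equal(nrow(pm$permuted), 20L)
  expect_identical(pm$permuted, pm2$permuted)
  expect_true(all(pm$permuted$correlation >= 0 & pm$permuted$correlation <= 1))
  expect_gt(pm$Q2Y, max(pm$permuted$Q2Y))   # strong effect beats every null
  expect_equal(pm$p_value, 1 / 21)
  expect_error(permutation_test(d$X, d$y, 1, n_permutations = 5), ">= 10")
})
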
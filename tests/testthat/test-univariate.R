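# Window integration, Mann-Whitney, percent variation, region tables.

unit_table <- function(values, lower, upper) {
  X <- rbind(values, values)
  rownames(X) <- c("S1", "S2")
  bucket_table(X, lower, upper)
}

test_that("window integration is additive and overlap-weighted", {
  tab <- unit_table(c(1, 2, 3), c(0, 1, 2), c(1, 2, 3))
  expect_equal(unname(integrate_region(tab, 0, 3)["S1"]), 6)
  tab2 <- unit_table(4, 0, 1)
  expect_equal(unname(integrate_region(tab2, 0.25, 0.75)["S1"]), 2)
  expect_error(integrate_region(tab, 5, 6), "overlap")
})

test_that("integration is invariant to the fine-vs-coarse representation", {
  co <- small_cohort(seed = 12, n_a = 3, n_b = 3, noise_sd = 0,
                     baseline_amplitude = 0)
  fine <- bucket_spectra(co$spectra, width = 0.001, range = c(0.15, 4.5),
                         mask = list())
  coarse <- rebin(fine, 10)
  # windows aligned with coarse bucket edges: exact agreement
  for (w in list(c(2.92, 2.95), c(3.56, 3.59), c(0.84, 0.93))) {
    vf <- integrate_region(fine, w[1], w[2])
    vc <- integrate_region(coarse, w[1], w[2])
    expect_mostly_equal(vf, vc, 1e-9 * max(vf))
  }
  # misaligned windows: the discrepancy comes only from the overlap-weighted
  # boundary buckets, so it is bounded by their total content
  w <- c(2.922, 2.944)
  vf <- integrate_region(fine, w[1], w[2])
  vc <- integrate_region(coarse, w[1], w[2])
  bound_cols <- which(coarse$lower < w[1] & coarse$upper > w[1] |
                        coarse$lower < w[2] & coarse$upper > w[2])
  bound <- rowSums(coarse$values[, bound_cols, drop = FALSE])
  expect_true(all(abs(vf - vc) <= bound + 1e-9))
})

test_that("a synthetic singlet of known area integrates to that area", {
  cfg <- cohort_config(n_group_a = 3, n_group_b = 3, seed = 8,
                       conc_sdlog = 0, dilution_range = c(1, 1),
                       noise_sd = 0, baseline_amplitude = 0,
                       shift_jitter_sd = 0, effect_map = numeric(0))
  co <- simulate_cohort(cfg, library = default_metabolite_library()["fumarate"])
  bt <- bucket_spectra(co$spectra, width = 0.001)
  v <- integrate_region(bt, 6.498, 6.551)   # fumarate window
  # analytic Lorentzian area inside the window (grid sums scale with 1/step);
  # hwhm = linewidth/2, center 6.520, base concentration 0.99
  hw <- 0.0018 / 2
  frac <- (atan((6.551 - 6.520) / hw) + atan((6.520 - 6.498) / hw)) / pi
  expected <- 0.99 * frac / 0.001
  expect_lt(abs(unname(v[1]) / expected - 1), 0.01)
})

test_that("identical groups give p = 1 and the textbook example matches enumeration", {
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$p_value, 1)
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  want <- mann_whitney_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, want$U)
  expect_equal(got$p_value, want$p_value)
})

test_that("Mann-Whitney matches brute-force enumeration for all small group sizes", {
  set.seed(33)
  for (m in 2:8) for (n in 2:(10 - m)) {
    a <- rnorm(m); b <- rnorm(n, 0.5)
    got <- mann_whitney(a, b)
    want <- mann_whitney_oracle(a, b)
    expect_equal(got$U, want$U, info = sprintf("m=%d n=%d", m, n))
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12,
                 info = sprintf("m=%d n=%d", m, n))
  }
})

test_that("tied and large-sample inputs fall back to the corrected approximation", {
  a <- c(1, 1, 2, 3, 3, 4); b <- c(2, 2, 3, 5, 5, 6)
  got <- mann_whitney(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, ref$p.value)
  set.seed(4)
  x <- rnorm(30); z <- rnorm(30, 1)
  big <- mann_whitney(x, z)
  ref2 <- suppressWarnings(stats::wilcox.test(x, z, exact = FALSE, correct = TRUE))
  expect_equal(big$p_value, ref2$p.value)
  expect_error(mann_whitney(1, c(1, 2)), ">= 2")
})

test_that("a one-sd shift at n = 50 per group is detected in most cohorts", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    mann_whitney(rnorm(50), rnorm(50, 1))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("percent variation identities hold", {
  expect_equal(percent_variation(5, 5), 0)
  expect_equal(percent_variation(20.56, 17.17), -16.4883, tolerance = 1e-4)
  # exchanging roles: (1 + pv(a,b)/100) * (1 + pv(b,a)/100) = 1
  set.seed(6)
  for (i in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal((1 + percent_variation(a, b) / 100) *
                   (1 + percent_variation(b, a) / 100), 1, tolerance = 1e-12)
  }
  expect_error(percent_variation(0, 1), "nonzero")
})

test_that("region tables carry one row per region with correct bookkeeping", {
  co <- simulate_cohort(cohort_config(n_group_a = 12, n_group_b = 12, seed = 14))
  bt <- bucket_spectra(co$spectra, width = 0.01)
  tab <- build_table(pqn_normalize(bt)$table)
  expect_s3_class(tab, "region_table")
  expect_equal(nrow(tab), nrow(default_regions()))
  expect_equal(tab$name, default_regions()$name[order(default_regions()$low)])
  expect_true(all(tab$sem_reference >= 0 & tab$sem_case >= 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(attr(tab, "reference"), "BPH")
  # sem = sd/sqrt(n) against a manual recomputation
  v <- integrate_region(pqn_normalize(bt)$table, tab$low[1], tab$high[1])
  g <- bt$groups
  expect_equal(tab$sem_reference[1], sd(v[g == "BPH"]) / sqrt(sum(g == "BPH")))
  # BH adjustment is available behind a flag
  tab2 <- build_table(pqn_normalize(bt)$table, adjust = TRUE)
  expect_true(all(tab2$p_adjusted >= tab2$p_value - 1e-12))
})

test_that("percent variation signs track the planted effect directions", {
  co <- simulate_cohort(cohort_config(seed = 20))
  bt <- bucket_spectra(co$spectra, width = 0.01)
  tab <- build_table(pqn_normalize(bt)$table, reference = "BPH")
  eff <- default_effect_map()[tab$name]
  expect_equal(sign(tab$percent_variation), unname(sign(eff - 1)))
})
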
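# End-to-end orchestration: simulate/ingest -> bucket -> align -> rebin ->
# PQN -> UV scale -> PCA screen -> OPLS-DA -> validate -> select -> refit ->
# univariate -> report.

#' Pipeline configuration
#'
#' Validated container for every stage parameter. Unknown arguments are
#' rejected. Either a simulation config or input CSV paths must be present.
#'
#' @param cohort A [cohort_config()] for simulated input, or `NULL`.
#' @param spectra_csv,metadata_csv Input CSVs (used when `cohort` is NULL).
#' @param fine_width Fine bucket width in ppm.
#' @param range Analysis range `c(low, high)` in ppm.
#' @param mask Exclusion regions ([exclusion_mask()]).
#' @param align Logical: run peak alignment on the fine grid.
#' @param max_shift Maximum alignment shift in fine buckets.
#' @param rebin_factor Fine buckets per analysis bucket.
#' @param pqn_target PQN integral target (see [pqn_normalize()]).
#' @param n_orthogonal Orthogonal components for OPLS-DA.
#' @param n_folds Cross-validation folds.
#' @param n_permutations Label permutations (0 disables the test).
#' @param selection_threshold |b/b_cvSE| cut for variable selection.
#' @param outlier_alpha Hotelling T2 flagging level.
#' @param exclude_outliers Logical: drop flagged samples before modelling.
#' @param nested_cv Logical: also report a nested-CV Q2Y with selection
#'   refit inside each fold (unbiased by the select-then-revalidate step).
#' @param reference Reference group label for the univariate table.
#' @param seed Master seed for folds and permutations.
#' @param out_dir Optional directory for intermediates and the JSON report.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            spectra_csv = NULL, metadata_csv = NULL,
                            fine_width = 0.001, range = c(0.15, 9.50),
                            mask = exclusion_mask(),
                            align = TRUE, max_shift = 50L,
                            rebin_factor = 10L,
                            pqn_target = "cohort_mean",
                            n_orthogonal = 1L, n_folds = 7L,
                            n_permutations = 100L,
                            selection_threshold = 1.0,
                            outlier_alpha = 0.05,
                            exclude_outliers = FALSE,
                            nested_cv = FALSE,
                            reference = NULL,
                            seed = 1L, out_dir = NULL) {
  if (is.null(cohort) && is.null(spectra_csv))
    stop("either a simulation config or input spectra are required")
  stopifnot(fine_width > 0, range[1] < range[2], rebin_factor >= 1,
            n_orthogonal >= 0, n_folds >= 2, selection_threshold >= 0,
            outlier_alpha > 0, outlier_alpha < 1)
  structure(list(cohort = cohort, spectra_csv = spectra_csv,
                 metadata_csv = metadata_csv, fine_width = fine_width,
                 range = range, mask = mask, align = align,
                 max_shift = as.integer(max_shift),
                 rebin_factor = as.integer(rebin_factor),
                 pqn_target = pqn_target,
                 n_orthogonal = as.integer(n_orthogonal),
                 n_folds = as.integer(n_folds),
                 n_permutations = as.integer(n_permutations),
                 selection_threshold = selection_threshold,
                 outlier_alpha = outlier_alpha,
                 exclude_outliers = isTRUE(exclude_outliers),
                 nested_cv = isTRUE(nested_cv),
                 reference = reference,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

subset_table <- function(table, rows = NULL, cols = NULL) {
  V <- table$values
  if (is.null(rows)) rows <- seq_len(nrow(V))
  if (is.null(cols)) cols <- seq_len(ncol(V))
  bucket_table(V[rows, cols, drop = FALSE], table$lower[cols],
               table$upper[cols], excluded = table$excluded,
               groups = if (!is.null(table$groups)) table$groups[rows])
}

# Nested CV: selection refit inside each training fold, held-out samples
# predicted from a model restricted to that fold's selection.
nested_cv_q2 <- function(X, y, cfg) {
  enc <- encode_classes(y)
  fold <- with_seed(cfg$seed + 1L, stratified_folds(y, cfg$n_folds))
  pred <- numeric(length(y))
  for (k in seq_len(cfg$n_folds)) {
    te <- fold == k
    Xtr <- X[!te, , drop = FALSE]
    mu <- colMeans(Xtr); sdv <- col_sds(Xtr); sdv[sdv == 0] <- 1
    Xtr_s <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte_s <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- oplsda_fit(Xtr_s, y[!te], cfg$n_orthogonal, levels = enc$levels)
    cv <- cross_validate(Xtr, y[!te], cfg$n_orthogonal, cfg$n_folds,
                         seed = cfg$seed + k, scale = "refit",
                         levels = enc$levels)
    sel <- select_variables(fit, cv, cfg$selection_threshold)
    keep <- if (length(sel$kept)) sel$kept else seq_len(ncol(X))
    fit2 <- oplsda_fit(Xtr_s[, keep, drop = FALSE], y[!te],
                       min(cfg$n_orthogonal, max(0L, length(keep) - 2L)),
                       levels = enc$levels)
    pred[te] <- predict(fit2, Xte_s[, keep, drop = FALSE])$y
  }
  1 - sum((enc$y - pred)^2) / sum((enc$y - mean(enc$y))^2)
}

#' Run the full discrimination pipeline
#'
#' Executes, in order: cohort simulation (or CSV ingestion), fine
#' bucketing with exclusion, optional alignment, rebinning, PQN
#' normalization, unit-variance scaling, PCA screening with Hotelling T2
#' flagging, full OPLS-DA with cross-validation, optional permutation test
#' and CV-ANOVA, |b/b_cvSE| variable selection, a refit + revalidation on
#' the selected variables, and the per-region univariate table. A second
#' run with the same configuration is identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`; see its `$stages`,
#'   `$models`, `$selection`, `$univariate` entries. When
#'   `config$out_dir` is set, intermediates and a JSON report are written
#'   there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- character(0)
  step <- function(name) stages <<- c(stages, name)

  if (!is.null(config$cohort)) {
    cohort <- simulate_cohort(config$cohort)
    spectra <- cohort$spectra
    step("simulate")
  } else {
    spectra <- read_spectra(config$spectra_csv, config$metadata_csv)
    cohort <- NULL
    step("ingest")
  }

  fine <- bucket_spectra(spectra, width = config$fine_width,
                         range = config$range, mask = config$mask)
  step("bucket")
  if (config$align) { fine <- align_spectra(fine, config$max_shift); step("align") }
  coarse <- rebin(fine, config$rebin_factor)
  step("rebin")
  pqn <- pqn_normalize(coarse, target = config$pqn_target)
  step("pqn")
  uv <- uv_scale(pqn$table)
  step("uv_scale")

  pca <- pca_fit(uv$table$values, n_components = 2L,
                 alpha = config$outlier_alpha)
  outliers <- flag_outliers(pca, config$outlier_alpha)
  step("pca_screen")
  tab_n <- pqn$table   # PQN-normalized, unscaled (univariate input)
  tab_s <- uv$table    # scaled (modelling input)
  if (config$exclude_outliers && length(outliers)) {
    keep <- !(rownames(tab_n$values) %in% outliers)
    tab_n <- subset_table(tab_n, rows = which(keep))
    tab_s <- subset_table(tab_s, rows = which(keep))
    step("exclude_outliers")
  }
  y <- tab_n$groups

  fit_full <- oplsda_fit(tab_s$values, y, config$n_orthogonal)
  cv_full <- cross_validate(tab_n$values, y, config$n_orthogonal,
                            config$n_folds, seed = config$seed)
  anova_full <- cv_anova(cv_full)
  perm_full <- NULL
  if (config$n_permutations > 0) {
    perm_full <- permutation_test(tab_n$values, y, config$n_orthogonal,
                                  config$n_permutations, config$n_folds,
                                  seed = config$seed)
  }
  step("oplsda")
  step("validate")

  sel <- select_variables(fit_full, cv_full, config$selection_threshold)
  step("select")
  if (length(sel$kept) < 2) stop("selection retained fewer than 2 variables")
  tab_s_sel <- subset_table(tab_s, cols = sel$kept)
  tab_n_sel <- subset_table(tab_n, cols = sel$kept)
  fit_sel <- oplsda_fit(tab_s_sel$values, y, config$n_orthogonal)
  cv_sel <- cross_validate(tab_n_sel$values, y, config$n_orthogonal,
                           config$n_folds, seed = config$seed)
  anova_sel <- cv_anova(cv_sel)
  step("refit")
  q2_nested <- if (config$nested_cv)
    nested_cv_q2(tab_n$values, y, config) else NULL

  univ <- build_table(tab_n, regions = default_regions(), labels = y,
                      reference = config$reference)
  step("univariate")

  report <- structure(list(
    stages = c(stages, "report"),
    config = config,
    n_samples = nrow(tab_n$values),
    outliers = outliers,
    variables = c(before = ncol(tab_s$values), after = length(sel$kept)),
    models = list(
      full = list(R2Y = fit_full$R2Y, Q2Y = cv_full$Q2Y,
                  cv_anova_p = anova_full$p_value,
                  permutation = if (!is.null(perm_full)) list(
                    p = perm_full$p_value,
                    R2_intercept = perm_full$R2_intercept,
                    Q2_intercept = perm_full$Q2_intercept)),
      selected = list(R2Y = fit_sel$R2Y, Q2Y = cv_sel$Q2Y,
                      cv_anova_p = anova_sel$p_value,
                      Q2Y_nested = q2_nested)),
    selection = sel,
    pca = list(explained = pca$explained[1:2], t2_crit = pca$t2_crit),
    univariate = univ,
    fits = list(full = fit_full, selected = fit_sel,
                cv_full = cv_full, cv_selected = cv_sel,
                permutation = perm_full),
    tables = list(normalized = tab_n, scaled = tab_s),
    truth = if (!is.null(cohort)) cohort$truth), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bucket_table(tab_n, file.path(config$out_dir, "normalized.csv"))
    utils::write.csv(univ, file.path(config$out_dir, "univariate.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      stages = report$stages, n_samples = report$n_samples,
      outliers = report$outliers, variables = as.list(report$variables),
      models = report$models, seed = config$seed),
      file.path(config$out_dir, "report.json"),
      digits = NA, auto_unbox = TRUE, null = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d samples, %d -> %d variables\n",
              x$n_samples, x$variables["before"], x$variables["after"]))
  cat(sprintf("  full:     R2Y = %.3f, Q2Y = %.3f, CV-ANOVA p = %.3g\n",
              x$models$full$R2Y, x$models$full$Q2Y, x$models$full$cv_anova_p))
  cat(sprintf("  selected: R2Y = %.3f, Q2Y = %.3f, CV-ANOVA p = %.3g\n",
              x$models$selected$R2Y, x$models$selected$Q2Y,
              x$models$selected$cv_anova_p))
  if (!is.null(x$models$selected$Q2Y_nested))
    cat(sprintf("  nested-CV Q2Y (selection inside folds) = %.3f\n",
                x$models$selected$Q2Y_nested))
  cat(sprintf("  univariate: %d of %d regions significant\n",
              sum(x$univariate$significant), nrow(x$univariate)))
  invisible(x)
}

#' Compare two fitted pipeline models
#'
#' Paired before/after summary of fit, predictive power, and variable
#' counts, as produced by the selection step of [run_pipeline()]. Pass
#' either a single `pipeline_report` (its full vs selected models are
#' compared) or two validation summaries, each a list with `R2Y`, `Q2Y`,
#' `cv_anova_p`, `n_variables` and `sample_ids`; the sample sets must
#' match.
#'
#' @param before A `pipeline_report`, or the pre-selection summary.
#' @param after The post-selection summary (ignored when `before` is a
#'   report).
#' @return Data.frame with one row per statistic and columns `before`,
#'   `after`, `delta`.
#' @export
compare_models <- function(before, after = NULL) {
  if (inherits(before, "pipeline_report")) {
    report <- before
    ids <- rownames(report$tables$normalized$values)
    before <- c(report$models$full,
                list(n_variables = report$variables[["before"]],
                     sample_ids = ids))
    after <- c(report$models$selected,
               list(n_variables = report$variables[["after"]],
                    sample_ids = ids))
  }
  if (!setequal(before$sample_ids, after$sample_ids))
    stop("models were fit on different sample sets")
  out <- data.frame(
    statistic = c("R2Y", "Q2Y", "cv_anova_p", "n_variables"),
    before = c(before$R2Y, before$Q2Y, before$cv_anova_p, before$n_variables),
    after = c(after$R2Y, after$Q2Y, after$cv_anova_p, after$n_variables))
  out$delta <- out$after - out$before
  out
}
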
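# Seeded synthetic two-group urine-spectrum cohorts with known ground truth.

#' NMR spectrum object
#'
#' @param sample_id Sample identifier.
#' @param ppm Strictly monotone chemical-shift axis (ppm). Stored ascending.
#' @param intensity Intensity values, same length as `ppm`, all finite.
#' @param group Group label (e.g. "PCa"/"BPH") or `NA` if unknown.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(sample_id, ppm, intensity, group = NA_character_) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) stop("ppm and intensity lengths differ")
  d <- diff(ppm)
  if (any(d == 0) || (any(d > 0) && any(d < 0))) stop("ppm axis must be strictly monotone")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  if (ppm[1] > ppm[length(ppm)]) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(sample_id = as.character(sample_id), ppm = ppm,
                 intensity = intensity, group = as.character(group)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s [%s]: %d points, %.3f-%.3f ppm\n",
              x$sample_id, x$group, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' Defines the study conditions for a synthetic two-group urine cohort:
#' group sizes, per-metabolite fold changes of group B relative to group A,
#' per-sample dilution, inter-subject concentration variation, chemical-shift
#' jitter, baseline and noise, and the acquisition grid.
#'
#' Defaults mirror a typical clinical urine NMR study: 51 reference (BPH)
#' and 64 case (PCa) subjects, fold changes from [default_effect_map()],
#' dilution spanning (0.5, 2), log-normal concentration variation with
#' sd 0.2 on the log scale, shift jitter sd 0.003 ppm (capped at 0.01 ppm),
#' and a 0.15-9.50 ppm grid at 0.001 ppm resolution.
#'
#' @param n_group_a,n_group_b Group sizes (>= 3).
#' @param group_labels Character(2): labels for groups A and B.
#' @param effect_map Named fold changes (> 0) of group B relative to group A;
#'   names must match library metabolites. Unlisted metabolites get 1.
#' @param dilution_range Length-2 positive range of per-sample dilution
#'   factors (sampled uniformly).
#' @param conc_sdlog Log-scale sd of inter-subject concentration variation.
#' @param noise_sd Gaussian noise sd per grid point (intensity units).
#' @param baseline_amplitude Amplitude of the smooth per-sample baseline.
#' @param shift_jitter_sd Per-sample, per-metabolite shift jitter sd (ppm);
#'   `NULL` uses each signature's own value. Offsets are capped at
#'   `shift_jitter_cap`.
#' @param shift_jitter_cap Absolute cap (ppm) on shift offsets.
#' @param ppm_grid Numeric(3): min ppm, max ppm, step.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 51, n_group_b = 64,
                          group_labels = c("BPH", "PCa"),
                          effect_map = default_effect_map(),
                          dilution_range = c(0.5, 2.0),
                          conc_sdlog = 0.2,
                          noise_sd = 0.02,
                          baseline_amplitude = 0.01,
                          shift_jitter_sd = NULL,
                          shift_jitter_cap = 0.01,
                          ppm_grid = c(0.15, 9.50, 0.001),
                          seed = 1L) {
  if (n_group_a < 3 || n_group_b < 3) stop("group sizes must be >= 3")
  if (length(dilution_range) != 2 || dilution_range[1] <= 0 ||
      dilution_range[2] < dilution_range[1]) stop("invalid dilution_range")
  if (length(ppm_grid) != 3 || ppm_grid[3] <= 0) stop("invalid ppm_grid")
  if (ppm_grid[1] >= ppm_grid[2]) stop("degenerate ppm grid: min >= max")
  if (length(effect_map) && (is.null(names(effect_map)) || any(effect_map <= 0)))
    stop("effect_map must be named with fold changes > 0")
  if (conc_sdlog < 0 || noise_sd < 0 || baseline_amplitude < 0)
    stop("variance parameters must be >= 0")
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    group_labels = as.character(group_labels),
    effect_map = effect_map, dilution_range = as.numeric(dilution_range),
    conc_sdlog = conc_sdlog, noise_sd = noise_sd,
    baseline_amplitude = baseline_amplitude,
    shift_jitter_sd = shift_jitter_sd, shift_jitter_cap = shift_jitter_cap,
    ppm_grid = as.numeric(ppm_grid), seed = as.integer(seed)),
    class = "cohort_config")
}

# Evaluate one Lorentzian peak (area A, fwhm lw, center varying by sample)
# onto the intensity matrix (grid x samples). Truncated at +/- 50 linewidths.
add_lorentzian <- function(M, grid, centers, areas, lw) {
  hw <- lw / 2
  span <- 50 * lw
  lo <- min(centers) - span; hi <- max(centers) + span
  i1 <- findInterval(lo, grid) + 1L
  i2 <- findInterval(hi, grid)
  if (i2 < i1) return(M)
  g <- grid[i1:i2]
  # outer difference: window points x samples
  D <- outer(g, centers, "-")
  L <- (hw / pi) / (D * D + hw * hw)
  M[i1:i2, ] <- M[i1:i2, ] + L * rep(areas, each = length(g))
  M
}

#' Simulate a two-group urine-spectrum cohort
#'
#' Generates `n_group_a + n_group_b` spectra on the configured ppm grid.
#' Each sample's noiseless intensity is
#' `dilution * sum_m concentration_m * sum_peaks Lorentzian(center + shift_m)`,
#' with concentrations log-normal around each signature's base concentration
#' (multiplied by the group-B fold change), a smooth sinusoidal baseline and
#' i.i.d. Gaussian noise added on top. The returned ground truth records the
#' exact dilution factors, concentrations and shift offsets in sample order,
#' serving as the oracle for recovery tests downstream.
#'
#' @param config A [cohort_config()].
#' @param library A named list of [metabolite_signature()]s.
#' @return A list of class `nmr_cohort` with elements `spectra` (list of
#'   [nmr_spectrum()]), `metadata` (data.frame: sample_id, group) and `truth`
#'   (list: `dilution`, `concentrations` matrix samples x metabolites,
#'   `shifts` matrix samples x metabolites).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            library = default_metabolite_library()) {
  stopifnot(inherits(config, "cohort_config"), length(library) >= 1)
  bad <- setdiff(names(config$effect_map), names(library))
  if (length(bad)) stop("effect_map names not in library: ",
                        paste(bad, collapse = ", "))
  n <- config$n_group_a + config$n_group_b
  grid <- seq(config$ppm_grid[1], config$ppm_grid[2], by = config$ppm_grid[3])
  groups <- rep(config$group_labels, c(config$n_group_a, config$n_group_b))
  ids <- sprintf("S%03d", seq_len(n))
  m <- length(library)
  mn <- names(library)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  dil <- stats::runif(n, config$dilution_range[1], config$dilution_range[2])
  fold <- rep(1, m); names(fold) <- mn
  fold[names(config$effect_map)] <- config$effect_map
  base <- vapply(library, `[[`, numeric(1), "base_concentration")
  conc <- matrix(0, n, m, dimnames = list(ids, mn))
  for (j in seq_len(m)) {
    mu <- ifelse(groups == config$group_labels[2], base[j] * fold[j], base[j])
    conc[, j] <- stats::rlnorm(n, meanlog = log(mu), sdlog = config$conc_sdlog)
  }
  jsd <- vapply(library, `[[`, numeric(1), "shift_jitter_sd")
  if (!is.null(config$shift_jitter_sd)) jsd[] <- config$shift_jitter_sd
  shifts <- matrix(stats::rnorm(n * m, 0, rep(jsd, each = n)), n, m,
                   dimnames = list(ids, mn))
  shifts <- pmin(pmax(shifts, -config$shift_jitter_cap), config$shift_jitter_cap)

  M <- matrix(0, length(grid), n)
  for (j in seq_len(m)) {
    sig <- library[[j]]
    for (p in seq_len(nrow(sig$peaks))) {
      M <- add_lorentzian(M, grid,
                          centers = sig$peaks[p, "center"] + shifts[, j],
                          areas = dil * conc[, j] * sig$peaks[p, "intensity"],
                          lw = sig$peaks[p, "linewidth"])
    }
  }
  if (config$baseline_amplitude > 0) {
    phase <- stats::runif(n, 0, 2 * pi)
    freq <- stats::runif(n, 0.1, 0.4)
    for (i in seq_len(n)) {
      M[, i] <- M[, i] + config$baseline_amplitude *
        (1 + sin(2 * pi * freq[i] * grid + phase[i]))
    }
  }
  if (config$noise_sd > 0) {
    M <- M + stats::rnorm(length(M), 0, config$noise_sd)
  }

  spectra <- lapply(seq_len(n), function(i)
    nmr_spectrum(ids[i], grid, M[, i], groups[i]))
  structure(list(
    spectra = spectra,
    metadata = data.frame(sample_id = ids, group = groups,
                          stringsAsFactors = FALSE),
    truth = list(dilution = stats::setNames(dil, ids),
                 concentrations = conc, shifts = shifts),
    config = config), class = "nmr_cohort")
}

#' @export
print.nmr_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf("<nmr_cohort> %d spectra (%s), %d grid points\n",
              nrow(x$metadata),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              length(x$spectra[[1]]$ppm)))
  invisible(x)
}

#' Write a cohort to disk as plain text
#'
#' Spectra go to a long-format CSV (`sample_id, ppm, intensity`), metadata to
#' a second CSV, and the simulation ground truth (if present) to JSON.
#'
#' @param cohort An `nmr_cohort` or list of `nmr_spectrum`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- if (inherits(cohort, "nmr_cohort")) cohort$spectra else cohort
  long <- do.call(rbind, lapply(spectra, function(s)
    data.frame(sample_id = s$sample_id, ppm = s$ppm, intensity = s$intensity)))
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(long, paths[["spectra"]], row.names = FALSE)
  meta <- if (inherits(cohort, "nmr_cohort")) cohort$metadata else
    data.frame(sample_id = vapply(spectra, `[[`, character(1), "sample_id"),
               group = vapply(spectra, `[[`, character(1), "group"))
  utils::write.csv(meta, paths[["metadata"]], row.names = FALSE)
  if (inherits(cohort, "nmr_cohort") && !is.null(cohort$truth)) {
    jsonlite::write_json(lapply(cohort$truth, function(x) {
      if (is.matrix(x)) as.data.frame(x) else as.list(x)
    }), paths[["truth"]], digits = NA, auto_unbox = TRUE)
  } else paths <- paths[1:2]
  invisible(paths)
}

#' Read spectra from a long-format CSV
#'
#' @param spectra_csv Path to CSV with columns `sample_id, ppm, intensity`.
#' @param metadata_csv Optional CSV with columns `sample_id, group`.
#' @return A list of [nmr_spectrum()] objects.
#' @export
read_spectra <- function(spectra_csv, metadata_csv = NULL) {
  long <- utils::read.csv(spectra_csv, stringsAsFactors = FALSE)
  grp <- NULL
  if (!is.null(metadata_csv)) {
    meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
    grp <- stats::setNames(as.character(meta$group), meta$sample_id)
  }
  ids <- unique(long$sample_id)
  lapply(ids, function(id) {
    s <- long[long$sample_id == id, ]
    g <- if (!is.null(grp) && id %in% names(grp)) grp[[id]] else NA_character_
    nmr_spectrum(id, s$ppm, s$intensity, g)
  })
}
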
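# Metabolite signatures and integration windows for synthetic urine spectra.

#' Create a metabolite signature
#'
#' A signature describes one metabolite's contribution to a 1D 1H-NMR urine
#' spectrum as a set of Lorentzian peaks with a shared base concentration.
#' Peak areas are `base_concentration * relative_intensity` before dilution
#' and inter-subject variation are applied.
#'
#' @param name Metabolite name (unique within a library).
#' @param peaks Numeric matrix (or coercible data.frame) with columns
#'   `center` (ppm), `intensity` (relative peak area, > 0) and `linewidth`
#'   (full width at half maximum, ppm, > 0).
#' @param base_concentration Median concentration in arbitrary units (> 0).
#' @param shift_jitter_sd Standard deviation (ppm) of the per-sample chemical
#'   shift offset applied to all peaks of this metabolite.
#' @return An object of class `metabolite_signature`.
#' @export
metabolite_signature <- function(name, peaks, base_concentration,
                                 shift_jitter_sd = 0.003) {
  peaks <- as.matrix(as.data.frame(peaks)[, c("center", "intensity", "linewidth")])
  stopifnot(is.character(name), length(name) == 1L, nrow(peaks) >= 1L)
  if (any(peaks[, "intensity"] <= 0)) stop("relative intensities must be > 0")
  if (any(peaks[, "linewidth"] <= 0)) stop("linewidths must be > 0")
  if (any(peaks[, "center"] < 0.15 | peaks[, "center"] > 9.50)) {
    stop("peak centers must lie within 0.15-9.50 ppm")
  }
  if (base_concentration <= 0) stop("base_concentration must be > 0")
  structure(
    list(name = name, peaks = peaks,
         base_concentration = as.numeric(base_concentration),
         shift_jitter_sd = as.numeric(shift_jitter_sd)),
    class = "metabolite_signature"
  )
}

#' @export
print.metabolite_signature <- function(x, ...) {
  cat(sprintf("<metabolite_signature> %s: %d peak(s), base conc %.3g\n",
              x$name, nrow(x$peaks), x$base_concentration))
  invisible(x)
}

pk <- function(center, intensity, linewidth = 0.0018) {
  cbind(center = center, intensity = intensity, linewidth = linewidth)
}

#' Default urinary metabolite library
#'
#' A library of Lorentzian signatures emulating the dominant resonances of a
#' CPMG urine spectrum: the eight discriminant metabolites carried through
#' the univariate stage (branched-chain amino acids, glutamate,
#' dimethylglycine, glycine, pseudouridine, the unassigned singlet U1,
#' fumarate, 4-imidazole-acetate), plus background metabolites that dominate
#' urine spectra (creatinine, citrate, hippurate, trimethylamine-N-oxide,
#' urea, lactate, alanine, dimethylamine). Base concentrations are chosen so
#' that dilution-normalized integrals over the standard windows (see
#' [default_regions()]) are of the magnitude seen in real cohorts.
#'
#' @return A named list of [metabolite_signature()] objects.
#' @seealso [default_regions()], [simulate_cohort()]
#' @export
default_metabolite_library <- function() {
  sigs <- list(
    metabolite_signature("bcaa", rbind(
      pk(0.861, 0.35), pk(0.876, 0.35), pk(0.901, 0.15), pk(0.921, 0.15)),
      base_concentration = 13.1),
    metabolite_signature("glutamate", rbind(
      pk(2.091, 0.55), pk(2.105, 0.45)),
      base_concentration = 11.7),
    metabolite_signature("dimethylglycine", pk(2.933, 1.0),
      base_concentration = 20.6),
    metabolite_signature("glycine", pk(3.574, 1.0),
      base_concentration = 23.3),
    metabolite_signature("pseudouridine", pk(4.292, 1.0),
      base_concentration = 6.9),
    metabolite_signature("u1", pk(6.487, 1.0),
      base_concentration = 0.69),
    metabolite_signature("fumarate", pk(6.520, 1.0),
      base_concentration = 0.99),
    metabolite_signature("imidazole_acetate", pk(8.540, 1.0),
      base_concentration = 1.77),
    # background urinary matrix
    metabolite_signature("creatinine", rbind(pk(3.050, 0.6), pk(4.060, 0.4)),
      base_concentration = 100),
    metabolite_signature("citrate", rbind(pk(2.545, 0.5), pk(2.665, 0.5)),
      base_concentration = 45),
    metabolite_signature("hippurate", rbind(
      pk(3.970, 0.35), pk(7.550, 0.20), pk(7.640, 0.12), pk(7.835, 0.33)),
      base_concentration = 35),
    metabolite_signature("tmao", pk(3.270, 1.0),
      base_concentration = 30),
    metabolite_signature("urea", pk(5.780, 1.0, linewidth = 0.03),
      base_concentration = 80),
    metabolite_signature("lactate", rbind(pk(1.330, 0.75), pk(4.110, 0.25)),
      base_concentration = 10),
    metabolite_signature("alanine", pk(1.480, 1.0),
      base_concentration = 8),
    metabolite_signature("dimethylamine", pk(2.720, 1.0),
      base_concentration = 9)
  )
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  sigs
}

#' Standard metabolite integration windows
#'
#' The eight chemical-shift windows used for variable-size bucket integration
#' and univariate confirmation, one per discriminant metabolite.
#'
#' @return A data.frame with columns `name`, `low`, `high` (ppm), sorted by
#'   window position.
#' @export
default_regions <- function() {
  data.frame(
    name = c("bcaa", "glutamate", "dimethylglycine", "glycine",
             "pseudouridine", "u1", "fumarate", "imidazole_acetate"),
    low  = c(0.842, 2.081, 2.922, 3.567, 4.277, 6.478, 6.498, 8.517),
    high = c(0.930, 2.115, 2.944, 3.582, 4.309, 6.496, 6.551, 8.567),
    stringsAsFactors = FALSE
  )
}

#' Default group fold changes
#'
#' Fold changes of the case group (PCa) relative to the reference group (BPH)
#' for the eight discriminant metabolites, computed as ratios of typical
#' group-mean window integrals: increases for branched-chain amino acids,
#' glutamate and pseudouridine; decreases for dimethylglycine, glycine, U1,
#' fumarate and 4-imidazole-acetate.
#'
#' @return Named numeric vector of fold changes (> 0).
#' @export
default_effect_map <- function() {
  c(bcaa = 14.33 / 13.10,
    glutamate = 12.42 / 11.72,
    dimethylglycine = 17.17 / 20.56,
    glycine = 20.49 / 23.29,
    pseudouridine = 7.68 / 6.88,
    u1 = 0.45 / 0.69,
    fumarate = 0.87 / 0.99,
    imidazole_acetate = 1.37 / 1.77)
}
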
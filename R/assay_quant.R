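#' @title Assay computations: metal content, TMPD oxidase kinetics,
#'   NADI phenotypes
#' @name assay_quant
#' @description Companion arithmetic for the wet-lab assays: conversion
#'   of atomic-absorption metal concentrations to atoms per cell,
#'   Beer-Lambert quantification of TMPD oxidation rates, and
#'   classification of NADI colony-staining phenotypes.
NULL

# 2019 SI exact value; commonly printed rounded as 6.022e23, a
# difference far below any reported precision.
AVOGADRO <- 6.02214076e23

#' Metal atoms per cell from an AAS measurement
#'
#' Converts a dilution-corrected metal concentration to atoms per cell:
#' moles = concentration x volume / molar mass, atoms = moles x
#' Avogadro's number, divided by the number of cells in the sample.
#'
#' @param concentration_mg_l Metal concentration in mg/L
#'   (dilution-corrected).
#' @param sample_volume_l Sample volume in litres.
#' @param molar_mass Molar mass of the metal in g/mol (e.g. Cu: 63.55).
#' @param cell_count Number of bacteria in the sample (from OD
#'   calibration).
#' @return Atoms per cell. Linear in concentration, inversely
#'   proportional to `cell_count`.
#' @examples
#' atoms_per_cell(63.55, 1, 63.55, 1e9)  # 6.022e11 atoms/cell
#' @export
atoms_per_cell <- function(concentration_mg_l, sample_volume_l,
                           molar_mass, cell_count) {
  if (any(molar_mass <= 0)) fx_validation_error("molar_mass must be > 0")
  if (any(cell_count <= 0)) fx_validation_error("cell_count must be > 0")
  if (any(concentration_mg_l < 0)) {
    fx_validation_error("concentration must be >= 0")
  }
  moles <- concentration_mg_l * sample_volume_l / 1000 / molar_mass
  moles * AVOGADRO / cell_count
}

#' TMPD oxidase activity from absorbance kinetics
#'
#' Oxidase activity from the increase in absorbance at 520 nm over the
#' assay interval, via Beer-Lambert: delta-concentration (mM) =
#' delta-A / (epsilon x path length); amount (umol) = delta-c x volume
#' (L) x 1000; activity = amount / interval. Expressed as umol TMPD
#' oxidized per minute per well (default 2.4e4 cells per well).
#'
#' A negative delta-A (blank drift) yields a negative activity and a
#' warning rather than being clipped, so blank-subtraction errors stay
#' visible.
#'
#' @param a520_t0,a520_t5 Absorbance at 520 nm at the start and end of
#'   the interval.
#' @param interval_min Interval between the two readings in minutes
#'   (default 5).
#' @param epsilon Extinction coefficient in 1/(mM cm); default 6.1 for
#'   TMPD.
#' @param path_length_cm Optical path length in cm. Default 0.29 cm,
#'   the approximate depth of 100 uL in a standard 96-well plate (an
#'   assumption; set explicitly for cuvette measurements).
#' @param reaction_volume_l Reaction volume in litres; default 1e-4
#'   (100 uL).
#' @param cells_per_well Cells per well the activity is expressed
#'   against (metadata only; default 2.4e4).
#' @return Activity in umol TMPD oxidized per minute per well.
#' @examples
#' tmpd_activity(0, 0.305, interval_min = 5, epsilon = 6.1,
#'               path_length_cm = 1, reaction_volume_l = 1e-4)  # 1e-3
#' @export
tmpd_activity <- function(a520_t0, a520_t5, interval_min = 5,
                          epsilon = 6.1, path_length_cm = 0.29,
                          reaction_volume_l = 1e-4,
                          cells_per_well = 2.4e4) {
  if (any(epsilon <= 0) || any(path_length_cm <= 0) ||
      any(interval_min <= 0)) {
    fx_validation_error("epsilon, path_length_cm and interval_min must be > 0")
  }
  delta_a <- a520_t5 - a520_t0
  if (any(delta_a < 0)) {
    warning("negative delta-A520: check blank subtraction")
  }
  delta_mm <- delta_a / (epsilon * path_length_cm)    # mM = mmol/L
  amount_umol <- delta_mm * reaction_volume_l * 1000  # mmol -> umol
  amount_umol / interval_min
}

#' Classify a NADI staining observation
#'
#' Colonies with full oxidase activity develop dark blue staining
#' within the fast cutoff (NADI+); reduced activity shows (light)
#' staining within the slow cutoff (NADIslow); no color change within
#' an observation window covering the slow cutoff is NADI-. An
#' unstained colony observed for less than the slow cutoff is flagged
#' `"indeterminate"` rather than called negative.
#'
#' @param stain_onset Staining onset in seconds, or `NA` if no staining
#'   was observed.
#' @param intensity `"dark"`, `"light"` or `"none"`.
#' @param observation_window Length of the observation in seconds.
#' @param fast_cutoff NADI+ cutoff in seconds; default 60 ("within 30 s
#'   to 1 min").
#' @param slow_cutoff NADIslow cutoff in seconds; default 900 ("within
#'   15 min").
#' @return One of `"nadi_plus"`, `"nadi_slow"`, `"nadi_minus"`,
#'   `"indeterminate"`.
#' @examples
#' classify_nadi(30, "dark", 1800)    # nadi_plus
#' classify_nadi(600, "light", 1800)  # nadi_slow
#' classify_nadi(NA, "none", 1800)    # nadi_minus
#' @export
classify_nadi <- function(stain_onset, intensity = c("dark", "light", "none"),
                          observation_window, fast_cutoff = 60,
                          slow_cutoff = 900) {
  intensity <- match.arg(intensity)
  if (fast_cutoff <= 0 || slow_cutoff <= 0 || fast_cutoff >= slow_cutoff) {
    fx_validation_error("cutoffs must be positive with fast_cutoff < slow_cutoff")
  }
  stained <- !is.na(stain_onset) && intensity != "none"
  if (stained && stain_onset > observation_window) {
    fx_validation_error("stain_onset exceeds observation_window")
  }
  if (!stained) {
    if (observation_window < slow_cutoff) return("indeterminate")
    return("nadi_minus")
  }
  if (intensity == "dark" && stain_onset <= fast_cutoff) return("nadi_plus")
  if (stain_onset <= slow_cutoff) return("nadi_slow")
  "nadi_minus"
}

#' Batch assay computation over a CSV table
#'
#' Reads one row per sample, applies the requested computation and
#' writes the input back out with the computed column appended.
#'
#' @param input Input CSV path. Expected columns: for `"atoms"` —
#'   `concentration_mg_l`, `sample_volume_l`, `molar_mass`,
#'   `cell_count`; for `"tmpd"` — `a520_t0`, `a520_t5` plus any
#'   optional [tmpd_activity()] parameters; for `"nadi"` —
#'   `stain_onset` (empty for none), `intensity`,
#'   `observation_window`.
#' @param output Output CSV path.
#' @param assay `"atoms"`, `"tmpd"` or `"nadi"`.
#' @return The output `data.frame`, invisibly.
#' @export
run_assay_batch <- function(input, output, assay = c("atoms", "tmpd", "nadi")) {
  assay <- match.arg(assay)
  if (!file.exists(input)) fx_io_error(sprintf("file not found: %s", input))
  df <- utils::read.csv(input, stringsAsFactors = FALSE)
  need <- switch(assay,
    atoms = c("concentration_mg_l", "sample_volume_l", "molar_mass",
              "cell_count"),
    tmpd = c("a520_t0", "a520_t5"),
    nadi = c("stain_onset", "intensity", "observation_window"))
  if (!all(need %in% names(df))) {
    fx_validation_error(sprintf("missing columns for %s assay: %s", assay,
                                paste(setdiff(need, names(df)),
                                      collapse = ", ")))
  }
  if (assay == "atoms") {
    df$atoms_per_cell <- atoms_per_cell(df$concentration_mg_l,
                                        df$sample_volume_l, df$molar_mass,
                                        df$cell_count)
  } else if (assay == "tmpd") {
    opt <- function(col, default) if (col %in% names(df)) df[[col]] else default
    df$activity_umol_min <- tmpd_activity(
      df$a520_t0, df$a520_t5,
      interval_min = opt("interval_min", 5),
      epsilon = opt("epsilon", 6.1),
      path_length_cm = opt("path_length_cm", 0.29),
      reaction_volume_l = opt("reaction_volume_l", 1e-4))
  } else {
    fast <- if ("fast_cutoff" %in% names(df)) df$fast_cutoff else rep(60, nrow(df))
    slow <- if ("slow_cutoff" %in% names(df)) df$slow_cutoff else rep(900, nrow(df))
    df$phenotype <- vapply(seq_len(nrow(df)), function(i) {
      classify_nadi(df$stain_onset[i], df$intensity[i],
                    df$observation_window[i],
                    fast_cutoff = fast[i], slow_cutoff = slow[i])
    }, character(1))
  }
  utils::write.csv(df, output, row.names = FALSE)
  invisible(df)
}
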
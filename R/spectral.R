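#' Construct an absorbance spectrum
#'
#' @param wavelengths_nm Strictly increasing wavelengths in nm.
#' @param absorbance_AU Absorbance values (same length).
#' @param pathlength_cm Optical path length in cm (default 1).
#' @return A list of class `hemopk_spectrum`.
#' @export
spectrum <- function(wavelengths_nm, absorbance_AU, pathlength_cm = 1) {
  stopifnot(length(wavelengths_nm) == length(absorbance_AU),
            pathlength_cm > 0)
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 absorbance_AU = as.numeric(absorbance_AU),
                 pathlength_cm = pathlength_cm),
            class = "hemopk_spectrum")
}

gauss_band <- function(lambda, center, eps_peak, sigma) {
  eps_peak * exp(-((lambda - center)^2) / (2 * sigma^2))
}

#' Synthetic heme extinction-coefficient table
#'
#' Millimolar extinction coefficients (per heme, L/(mmol cm)) for ferrous
#' (oxy/deoxy), ferric and hemichrome heme on a 1 nm grid over 450-700 nm.
#' The values are a SYNTHETIC stand-in: smooth Gaussian-band curves whose
#' peak positions and magnitudes resemble the published visible-band spectra
#' of oxyHb (541/577 nm), deoxyHb (555 nm), metHb (500/630 nm) and
#' hemichrome (535/565 nm). They are suitable for exercising and validating
#' the multi-component fit; for quantitation of real spectra substitute a
#' measured table via [read_extinction_table()].
#'
#' @param wavelengths_nm Wavelength grid (default `450:700`).
#' @param four_species If `TRUE`, oxy- and deoxy-ferrous heme are separate
#'   basis spectra; by default they are lumped into one "ferrous" basis (the
#'   mean of the two).
#' @return A data frame with column `wavelength_nm` followed by one column of
#'   extinction coefficients per species.
#' @export
synthetic_extinction_table <- function(wavelengths_nm = 450:700,
                                       four_species = FALSE) {
  l <- as.numeric(wavelengths_nm)
  soret_tail <- function(a, scale) a * exp(-(l - 450) / scale)
  oxy <- gauss_band(l, 541, 13.8, 9) + gauss_band(l, 577, 14.6, 9) +
    soret_tail(3.0, 30)
  deoxy <- gauss_band(l, 555, 12.5, 14) + soret_tail(3.5, 35)
  ferric <- gauss_band(l, 500, 9.0, 18) + gauss_band(l, 630, 3.9, 14) +
    soret_tail(4.5, 25)
  hemichrome <- gauss_band(l, 535, 11.0, 11) + gauss_band(l, 565, 9.5, 11) +
    soret_tail(3.0, 30)
  if (four_species) {
    data.frame(wavelength_nm = l, ferrous_oxy = oxy, ferrous_deoxy = deoxy,
               ferric = ferric, hemichrome = hemichrome)
  } else {
    data.frame(wavelength_nm = l, ferrous = (oxy + deoxy) / 2,
               ferric = ferric, hemichrome = hemichrome)
  }
}

#' Read an extinction-coefficient table from CSV
#'
#' Expected layout: first column `wavelength_nm`, remaining columns one per
#' species in L/(mmol cm) per heme.
#'
#' @param path CSV file path.
#' @return Data frame as in [synthetic_extinction_table()].
#' @export
read_extinction_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1] != "wavelength_nm" || ncol(tab) < 2) {
    stop("extinction table needs a wavelength_nm column plus species columns")
  }
  if (any(as.matrix(tab[-1]) < 0)) stop("extinction coefficients must be >= 0")
  tab
}

# Interpolate the species columns of an extinction table onto a wavelength
# grid (linear; the table must cover the grid).
interp_extinction <- function(table, wavelengths_nm) {
  rng <- range(table$wavelength_nm)
  if (min(wavelengths_nm) < rng[1] || max(wavelengths_nm) > rng[2]) {
    stop("extinction table does not cover the requested wavelength range")
  }
  vapply(table[-1], function(eps) {
    stats::approx(table$wavelength_nm, eps, xout = wavelengths_nm)$y
  }, numeric(length(wavelengths_nm)))
}

#' Blank-correct a plasma spectrum
#'
#' Subtracts a baseline (pre-dose) plasma blank from a sample spectrum to
#' remove background interference and turbidity. If the grids differ, the
#' blank is linearly interpolated onto the sample grid; small negative
#' residuals (noise) are passed through unchanged.
#'
#' @param sample,baseline_blank `hemopk_spectrum` objects.
#' @return Blank-corrected `hemopk_spectrum` on the sample grid.
#' @export
blank_correct <- function(sample, baseline_blank) {
  stopifnot(inherits(sample, "hemopk_spectrum"),
            inherits(baseline_blank, "hemopk_spectrum"))
  wl <- sample$wavelengths_nm
  brng <- range(baseline_blank$wavelengths_nm)
  if (min(wl) < brng[1] || max(wl) > brng[2]) {
    stop("blank does not cover the sample wavelength range")
  }
  blank_on_grid <- stats::approx(baseline_blank$wavelengths_nm,
                                 baseline_blank$absorbance_AU,
                                 xout = wl)$y
  spectrum(wl, sample$absorbance_AU - blank_on_grid, sample$pathlength_cm)
}

#' Forward-model a spectrum from species concentrations
#'
#' Beer-Lambert synthesis: `A(lambda) = sum_s eps_s(lambda) * c_s / 1000 *
#' pathlength` with concentrations in uM heme.
#'
#' @param conc_uM Named numeric vector of species concentrations (uM heme);
#'   names must match the table's species columns.
#' @param table Extinction table (default synthetic 3-species).
#' @param wavelengths_nm Output grid.
#' @param pathlength_cm Path length in cm.
#' @return A `hemopk_spectrum`.
#' @export
forward_spectrum <- function(conc_uM,
                             table = synthetic_extinction_table(),
                             wavelengths_nm = table$wavelength_nm,
                             pathlength_cm = 1) {
  species <- names(table)[-1]
  stopifnot(all(names(conc_uM) %in% species))
  eps <- interp_extinction(table, wavelengths_nm)
  full <- stats::setNames(numeric(length(species)), species)
  full[names(conc_uM)] <- conc_uM
  a <- as.numeric(eps %*% (full / 1000)) * pathlength_cm
  spectrum(wavelengths_nm, a, pathlength_cm)
}

#' Fit heme species concentrations to a spectrum
#'
#' Multi-component analysis: solves `A(lambda) = sum_s eps_s(lambda) * c_s *
#' pathlength` over a fitting window by non-negative least squares (negative
#' heme concentrations are unphysical) and sums the species to total heme.
#'
#' @param spec A (blank-corrected) `hemopk_spectrum`.
#' @param table Extinction table; default the packaged synthetic table.
#' @param window_nm Fitting window `c(lo, hi)` in nm; default 500-650 nm,
#'   covering the Q-band region that distinguishes the species.
#' @return A list of class `hemopk_speciation` with per-species
#'   concentrations (`conc_uM`, named vector), `total_heme_uM`, and the
#'   residual norm of the fit.
#' @export
fit_species <- function(spec, table = synthetic_extinction_table(),
                        window_nm = c(500, 650)) {
  stopifnot(inherits(spec, "hemopk_spectrum"), length(window_nm) == 2)
  wl <- spec$wavelengths_nm
  in_win <- wl >= window_nm[1] & wl <= window_nm[2]
  n_species <- ncol(table) - 1
  if (sum(in_win) < n_species) {
    stop("fitting window contains fewer points than species")
  }
  eps <- interp_extinction(table, wl[in_win])
  design <- eps / 1000 * spec$pathlength_cm
  cn <- kappa(design, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8) {
    stop(sprintf(
      "extinction matrix is rank-deficient over the window (condition number %.3g)",
      cn))
  }
  fit <- pracma::lsqnonneg(design, spec$absorbance_AU[in_win])
  conc <- stats::setNames(fit$x, colnames(eps))
  structure(list(conc_uM = conc, total_heme_uM = sum(conc),
                 resid_norm = sqrt(fit$resid.norm)),
            class = "hemopk_speciation")
}

#' Total heme concentration of a speciation result
#'
#' @param s A `hemopk_speciation` from [fit_species()].
#' @return Sum of the species concentrations, uM heme.
#' @export
total_heme <- function(s) {
  stopifnot(inherits(s, "hemopk_speciation"), all(s$conc_uM >= 0))
  sum(s$conc_uM)
}
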
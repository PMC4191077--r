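#' Default SEC integration windows for a complex phenotype
#'
#' Free Hb elutes at 20.7 min on the reference column. The Hb:Hp complex
#' elutes earlier, depending on the Hp phenotype: dog (dimeric) complex at
#' 17.7 min, human dimeric about 0.5 min faster (17.2 min), and multimeric
#' complexes as a broad profile centered between 12 and 16 min with primary
#' peaks at 14.7 and 15.1 min. Windows bracket these retention times at
#' roughly +/- 4 peak widths so the integrated area captures the full peak.
#'
#' @param phenotype One of `"dog"`, `"human_dimeric"`, `"human_multimeric"`.
#' @return Named list with `free_hb` and `bound_hb` windows (min).
#' @export
sec_windows <- function(phenotype = c("dog", "human_dimeric",
                                      "human_multimeric")) {
  phenotype <- match.arg(phenotype)
  bound <- switch(phenotype,
                  dog = c(16.2, 18.7),
                  human_dimeric = c(16.2, 18.7),
                  human_multimeric = c(12, 17.5))
  list(free_hb = c(19.7, 21.7), bound_hb = bound)
}

#' Construct a chromatogram
#'
#' @param elution_min Strictly increasing elution times in minutes.
#' @param a405_AU Detector absorbance at 405 nm.
#' @param windows Named list of integration windows (`free_hb`, `bound_hb`),
#'   each `c(lo, hi)` minutes; must lie within the elution range and not
#'   overlap.
#' @return A list of class `hemopk_chromatogram`.
#' @export
chromatogram <- function(elution_min, a405_AU, windows = sec_windows("dog")) {
  stopifnot(length(elution_min) == length(a405_AU))
  if (any(diff(elution_min) <= 0)) {
    stop("elution times must be strictly increasing")
  }
  rng <- range(elution_min)
  for (w in windows) {
    if (length(w) != 2 || w[1] >= w[2]) stop("malformed window")
    if (w[1] < rng[1] || w[2] > rng[2]) {
      stop("window outside the elution range")
    }
  }
  ivals <- do.call(rbind, windows)
  if (length(windows) > 1) {
    o <- order(ivals[, 1])
    if (any(ivals[o, 1][-1] < ivals[o, 2][-nrow(ivals)])) {
      stop("integration windows overlap")
    }
  }
  structure(list(elution_min = as.numeric(elution_min),
                 a405_AU = as.numeric(a405_AU), windows = windows),
            class = "hemopk_chromatogram")
}

# Baseline-corrected trapezoidal area of one window: a straight baseline
# connecting the signal at the window endpoints is subtracted, the residual
# integrated by trapezoids, and negative results clipped to zero.
window_area <- function(elution, a405, window) {
  sel <- elution >= window[1] & elution <= window[2]
  if (sum(sel) < 2) stop("empty integration window")
  t <- elution[sel]
  y <- a405[sel]
  base <- y[1] + (y[length(y)] - y[1]) * (t - t[1]) / (t[length(t)] - t[1])
  max(pracma::trapz(t, y - base), 0)
}

#' Integrate the free-Hb and Hb:Hp peaks of a chromatogram
#'
#' @param c A `hemopk_chromatogram` with `free_hb` and `bound_hb` windows.
#' @return List of class `hemopk_peak_areas` with `area_free` and
#'   `area_bound` in AU min (baseline-corrected, clipped at 0).
#' @export
integrate_peaks <- function(c) {
  stopifnot(inherits(c, "hemopk_chromatogram"))
  if (!all(c("free_hb", "bound_hb") %in% names(c$windows))) {
    stop("chromatogram must define free_hb and bound_hb windows")
  }
  structure(list(
    area_free = window_area(c$elution_min, c$a405_AU, c$windows$free_hb),
    area_bound = window_area(c$elution_min, c$a405_AU, c$windows$bound_hb)),
    class = "hemopk_peak_areas")
}

#' Percent free Hb from SEC peak areas
#'
#' `area_free / (area_free + area_bound) * 100`; percent bound is its
#' complement.
#'
#' @param a A `hemopk_peak_areas`.
#' @return Percent free Hb (0-100), or `NA` with a warning when both areas
#'   are zero (missing sample).
#' @export
percent_free <- function(a) {
  stopifnot(inherits(a, "hemopk_peak_areas"))
  tot <- a$area_free + a$area_bound
  if (tot <= 0) {
    warning("both peak areas are zero; percent free undefined")
    return(NA_real_)
  }
  a$area_free / tot * 100
}

#' Partition total heme into free and bound concentrations
#'
#' Applies the SEC percentage to the spectrophotometric total:
#' `free = total * pct_free/100`, `bound = total * (100 - pct_free)/100`, so
#' the two always sum to the total exactly.
#'
#' @param total_heme_uM Total heme from spectral speciation, uM.
#' @param pct_free Percent free Hb from [percent_free()].
#' @return List of class `hemopk_species_conc` with `pct_free`, `pct_bound`,
#'   `free_uM`, `bound_uM`.
#' @export
speciate_concentration <- function(total_heme_uM, pct_free) {
  stopifnot(total_heme_uM >= 0, pct_free >= 0, pct_free <= 100)
  free <- total_heme_uM * pct_free / 100
  structure(list(pct_free = pct_free, pct_bound = 100 - pct_free,
                 free_uM = free, bound_uM = total_heme_uM - free),
            class = "hemopk_species_conc")
}

#' Forward-generate a SEC chromatogram from free/bound concentrations
#'
#' Gaussian peaks at phenotype-specific retention times: free Hb at 20.7 min;
#' the complex at 17.7 min (dog), 17.2 min (human dimeric), or an
#' equal-weight pair at 14.7 and 15.1 min with wider peaks (human
#' multimeric). Peak area is proportional to heme concentration through one
#' fixed molar response factor (equal for free and complexed heme), and
#' additive Gaussian baseline noise is applied.
#'
#' @param free_uM,bound_uM Heme concentrations, uM.
#' @param phenotype `"dog"`, `"human_dimeric"` or `"human_multimeric"`.
#' @param noise_sd Baseline noise standard deviation, AU.
#' @param seed Optional seed for the noise.
#' @param response_au_min_per_uM Area response factor, AU min per uM heme.
#' @param elution_min Sampling grid in minutes.
#' @return A `hemopk_chromatogram` with the phenotype's default windows.
#' @export
generate_chromatogram <- function(free_uM, bound_uM,
                                  phenotype = c("dog", "human_dimeric",
                                                "human_multimeric"),
                                  noise_sd = 0, seed = NULL,
                                  response_au_min_per_uM = 0.01,
                                  elution_min = seq(10, 24, by = 0.02)) {
  phenotype <- match.arg(phenotype)
  stopifnot(free_uM >= 0, bound_uM >= 0)
  peaks <- switch(phenotype,
    dog = list(centers = 17.7, sigmas = 0.25, weights = 1),
    human_dimeric = list(centers = 17.2, sigmas = 0.25, weights = 1),
    human_multimeric = list(centers = c(14.7, 15.1), sigmas = c(0.6, 0.6),
                            weights = c(0.5, 0.5)))
  gaussian_peak <- function(center, sigma, area) {
    area / (sigma * sqrt(2 * pi)) *
      exp(-((elution_min - center)^2) / (2 * sigma^2))
  }
  signal <- gaussian_peak(20.7, 0.25, free_uM * response_au_min_per_uM)
  for (i in seq_along(peaks$centers)) {
    signal <- signal + gaussian_peak(
      peaks$centers[i], peaks$sigmas[i],
      bound_uM * response_au_min_per_uM * peaks$weights[i])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    signal <- signal + stats::rnorm(length(elution_min), 0, noise_sd)
  }
  chromatogram(elution_min, signal, sec_windows(phenotype))
}
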
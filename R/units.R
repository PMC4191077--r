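#' Convert a hemoglobin mass to heme equivalents
#'
#' Doses and plasma concentrations throughout the package are expressed in
#' micromolar heme equivalents: one Hb tetramer carries four heme groups, so a
#' mass of Hb maps to `grams / MW * hemes_per_tetramer * 1e6` micromoles of
#' heme.
#'
#' @param grams Hb mass in grams. Must be non-negative.
#' @param hb_mw_g_per_mol Molecular weight of the Hb tetramer in g/mol
#'   (default 64458).
#' @param hemes_per_tetramer Heme groups per tetramer (default 4).
#' @return Dose in micromoles of heme.
#' @examples
#' hb_grams_to_umol_heme(4) # 4 g bolus -> ~248.2 umol heme
#' @export
hb_grams_to_umol_heme <- function(grams, hb_mw_g_per_mol = 64458,
                                  hemes_per_tetramer = 4) {
  stopifnot(is.numeric(grams), all(grams >= 0))
  if (!is.numeric(hb_mw_g_per_mol) || hb_mw_g_per_mol <= 0) {
    stop("hb_mw_g_per_mol must be positive")
  }
  if (hemes_per_tetramer <= 0) stop("hemes_per_tetramer must be positive")
  grams / hb_mw_g_per_mol * hemes_per_tetramer * 1e6
}

#' Administered protein mass from solution volume and concentration
#'
#' A bolus specified as a volume of stock solution (e.g. 40 ml of a 10 g/dl Hb
#' solution) corresponds to `volume_ml * conc_g_dl / 100` grams of protein.
#'
#' @param volume_ml Administered volume in milliliters.
#' @param conc_g_dl Solution concentration in g/dl.
#' @return Mass in grams.
#' @export
dose_mass_g <- function(volume_ml, conc_g_dl) {
  stopifnot(volume_ml >= 0, conc_g_dl >= 0)
  volume_ml * conc_g_dl / 100
}

#' Convert a haptoglobin mass to heme-binding-site equivalents
#'
#' Hp binding capacity is parameterized per gram so that, at the default, one
#' gram of Hp binds the heme content of one gram of Hb (1:1 gram
#' stoichiometry, as in paired 4 g / 4 g dosing). Binding sites are expressed
#' in micromoles of heme they can sequester.
#'
#' @param grams Hp mass in grams.
#' @param umol_sites_per_g Binding capacity in umol heme per gram Hp.
#'   Default `hb_grams_to_umol_heme(1)` so that grams of Hp neutralize equal
#'   grams of Hb.
#' @return Binding capacity in micromoles heme equivalents.
#' @export
hp_grams_to_umol_sites <- function(grams,
                                   umol_sites_per_g = hb_grams_to_umol_heme(1)) {
  stopifnot(grams >= 0, umol_sites_per_g >= 0)
  grams * umol_sites_per_g
}
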
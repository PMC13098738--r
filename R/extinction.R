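#' Bundled chromophore extinction/absorption spectra
#'
#' Loads the absorption reference spectra shipped with the package:
#' molar extinction of oxy- and deoxyhemoglobin (cm^-1/M), and absorption
#' coefficients (mm^-1) of pure water, pure lipid, and the melanosome
#' interior. The tables are approximate compilations in the style of the
#' standard tissue-optics tabulations, sampled at 10 nm (or coarser) over
#' 650--900 nm and linearly interpolated in between; they are adequate for
#' the red/NIR window used here but are not a metrological reference.
#' Per-wavelength absorption can always be supplied directly in a model
#' config to bypass them.
#'
#' @param dir directory holding the spectra; defaults to the copies
#'   installed with the package.
#' @return A list with data frames `hemoglobin` (columns `wavelength_nm`,
#'   `eps_hbo2`, `eps_hb`), `water`, `lipid`, `melanosome` (columns
#'   `wavelength_nm`, `mua_mm1`).
#' @export
extinction_tables <- function(dir = system.file("extdata", "extinction",
                                                package = "slimr")) {
  cache <- get0("extinction", envir = .slimr_env)
  if (!is.null(cache) && identical(attr(cache, "dir"), dir)) return(cache)
  rd <- function(f, nm) {
    x <- read.table(file.path(dir, f), comment.char = "#")
    names(x) <- nm
    x
  }
  out <- list(
    hemoglobin = rd("hemoglobin.tsv", c("wavelength_nm", "eps_hbo2", "eps_hb")),
    water = rd("water.tsv", c("wavelength_nm", "mua_mm1")),
    lipid = rd("lipid.tsv", c("wavelength_nm", "mua_mm1")),
    melanosome = rd("melanosome.tsv", c("wavelength_nm", "mua_mm1"))
  )
  attr(out, "dir") <- dir
  assign("extinction", out, envir = .slimr_env)
  out
}

.interp_spectrum <- function(tab, wavelength, value_col, what) {
  rng <- range(tab$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop("wavelength ", paste(wavelength[wavelength < rng[1] | wavelength > rng[2]],
                              collapse = ", "),
         " nm outside the tabulated range [", rng[1], ", ", rng[2], "] for ", what)
  approx(tab$wavelength_nm, tab[[value_col]], xout = wavelength)$y
}

#' Absorption coefficient of a chromophore mixture
#'
#' Builds the tissue absorption coefficient (mm^-1) at one or more
#' wavelengths from hemoglobin concentrations and water/lipid/melanosome
#' volume fractions:
#' \deqn{\mu_a = \ln(10)\,10^{-7}(C_{HbO}\,\epsilon_{HbO} +
#'   C_{HbR}\,\epsilon_{HbR}) + f_{w}\mu_{a,w} + f_{l}\mu_{a,l} +
#'   f_{m}\mu_{a,mel}}
#' with concentrations in micromolar and molar extinctions in cm^-1/M
#' (the 1e-7 factor converts micromolar and cm to mm). The result is linear
#' in every concentration and fraction.
#'
#' @param conc_hbo,conc_hbr oxy-/deoxyhemoglobin concentration, micromolar.
#' @param water_fraction,lipid_fraction,melanin_fraction volume fractions
#'   in `[0, 1]`; `melanin_fraction` is the epidermal melanosome fraction.
#' @param wavelength wavelength(s), nm.
#' @param tables extinction spectra as returned by [extinction_tables()].
#' @return Numeric vector of mu_a values, mm^-1, one per wavelength.
#' @export
#' @examples
#' chromophore_mua(37.21, 9.302, 0.7, 0.05, 0, c(691, 851))
chromophore_mua <- function(conc_hbo, conc_hbr, water_fraction, lipid_fraction,
                            melanin_fraction = 0, wavelength,
                            tables = extinction_tables()) {
  vals <- c(conc_hbo = conc_hbo, conc_hbr = conc_hbr,
            water_fraction = water_fraction, lipid_fraction = lipid_fraction,
            melanin_fraction = melanin_fraction)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("chromophore concentrations and fractions must be nonnegative")
  eps_o <- .interp_spectrum(tables$hemoglobin, wavelength, "eps_hbo2", "HbO2")
  eps_r <- .interp_spectrum(tables$hemoglobin, wavelength, "eps_hb", "Hb")
  mua_w <- .interp_spectrum(tables$water, wavelength, "mua_mm1", "water")
  mua_l <- .interp_spectrum(tables$lipid, wavelength, "mua_mm1", "lipid")
  mua_m <- .interp_spectrum(tables$melanosome, wavelength, "mua_mm1", "melanosome")
  log(10) * 1e-7 * (conc_hbo * eps_o + conc_hbr * eps_r) +
    water_fraction * mua_w + lipid_fraction * mua_l + melanin_fraction * mua_m
}

#' Melanosome absorption coefficient
#'
#' Absorption coefficient (mm^-1) of the pure melanosome interior at the
#' requested wavelength(s), from the bundled spectrum. Multiplied by the
#' epidermal melanosome volume fraction this gives the melanin contribution
#' to epidermal mu_a; it is the delta-mu_a used when adding melanin by
#' perturbation-MC reweighting.
#'
#' @inheritParams chromophore_mua
#' @return Numeric vector, mm^-1.
#' @export
melanosome_mua <- function(wavelength, tables = extinction_tables()) {
  .interp_spectrum(tables$melanosome, wavelength, "mua_mm1", "melanosome")
}
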
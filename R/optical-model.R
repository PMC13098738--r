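#' Power-law reduced scattering spectrum
#'
#' Standard parameterization of the reduced scattering coefficient,
#' `musp(lambda) = a * (lambda / reference_wavelength)^(-b)`, so `a` is the
#' value at the reference wavelength.
#'
#' @param a reduced scattering at the reference wavelength, mm^-1 (> 0).
#' @param b scattering power (unitless).
#' @param wavelength wavelength(s), nm (> 0).
#' @param reference_wavelength reference wavelength, nm (> 0).
#' @return musp at `wavelength`, mm^-1.
#' @export
#' @examples
#' power_law_musp(2.8501, 1.3305, c(691, 851), 691)
power_law_musp <- function(a, b, wavelength, reference_wavelength) {
  if (!is.finite(a) || a <= 0) stop("'a' must be positive")
  if (any(wavelength <= 0) || reference_wavelength <= 0)
    stop("wavelengths must be positive")
  a * (wavelength / reference_wavelength)^(-b)
}

#' Transport mean free path
#'
#' `1 / (mua + musp)`, the characteristic isotropization length of light in
#' a turbid medium, in mm when the coefficients are in mm^-1. For the
#' bundled baseline dermis this evaluates to 0.35 mm at 691 nm and 0.46 mm
#' at 851 nm.
#'
#' @param mua absorption coefficient, mm^-1 (>= 0).
#' @param musp reduced scattering coefficient, mm^-1 (> 0).
#' @return Length, mm.
#' @export
transport_mfp <- function(mua, musp) {
  if (any(mua < 0)) stop("mua must be nonnegative")
  if (any(musp <= 0)) stop("musp must be positive")
  if (any(mua + musp == 0)) stop("mua + musp must be positive")
  1 / (mua + musp)
}

#' Single-layer optical specification
#'
#' One skin layer: geometry, chromophore composition, scattering law, and
#' interface optics. Absorption per wavelength is either supplied directly
#' (`mua`, named by wavelength) or built from the chromophores via
#' [chromophore_mua()]; reduced scattering either directly (`musp`) or from
#' a power law.
#'
#' @param name layer label, e.g. `"epidermis"`, `"papillary_dermis"`,
#'   `"reticular_dermis"`, `"subcutaneous"`.
#' @param thickness_um layer thickness in micrometers (converted to mm
#'   internally; all package lengths are mm).
#' @param conc_hbo,conc_hbr hemoglobin concentrations, micromolar.
#' @param conc_hb_total optional total hemoglobin, micromolar; checked to
#'   equal `conc_hbo + conc_hbr` within 0.1%.
#' @param blood_volume_fraction documented blood volume fraction; kept as
#'   metadata only (the concentrations are used as given, not rescaled).
#' @param water_fraction,lipid_fraction,melanin_fraction volume fractions.
#' @param g Henyey-Greenstein anisotropy, in `[-1, 1)`.
#' @param n refractive index, >= 1.
#' @param musp optional named numeric vector: musp (mm^-1) per wavelength
#'   (names = nm). Overrides the power law.
#' @param musp_a,musp_b,musp_ref power-law parameters (see
#'   [power_law_musp()]); `musp_ref` in nm.
#' @param mua optional named numeric vector: mua (mm^-1) per wavelength,
#'   overriding the chromophore build.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(name, thickness_um,
                       conc_hbo = 0, conc_hbr = 0, conc_hb_total = NULL,
                       blood_volume_fraction = 0,
                       water_fraction = 0, lipid_fraction = 0,
                       melanin_fraction = 0,
                       g, n,
                       musp = NULL, musp_a = NULL, musp_b = NULL,
                       musp_ref = 691, mua = NULL) {
  if (!is.finite(thickness_um) || thickness_um <= 0)
    stop("layer '", name, "': thickness must be positive")
  fr <- c(blood_volume_fraction, water_fraction, lipid_fraction, melanin_fraction)
  if (any(fr < 0) || any(fr > 1))
    stop("layer '", name, "': fractions must lie in [0, 1]")
  if (conc_hbo < 0 || conc_hbr < 0)
    stop("layer '", name, "': concentrations must be nonnegative")
  if (!is.null(conc_hb_total) && conc_hb_total > 0) {
    rel <- abs(conc_hbo + conc_hbr - conc_hb_total) / conc_hb_total
    if (rel > 0.001)
      stop("layer '", name, "': conc_hbo + conc_hbr differs from conc_hb_total by ",
           signif(100 * rel, 3), "% (limit 0.1%)")
  }
  if (g < -1 || g >= 1) stop("layer '", name, "': g must lie in [-1, 1)")
  if (n < 1) stop("layer '", name, "': n must be >= 1")
  if (is.null(musp) && (is.null(musp_a) || is.null(musp_b)))
    stop("layer '", name, "': provide either 'musp' per wavelength or a power law")
  structure(list(
    name = name, thickness_mm = thickness_um / 1000,
    conc_hbo = conc_hbo, conc_hbr = conc_hbr,
    conc_hb_total = if (is.null(conc_hb_total)) conc_hbo + conc_hbr else conc_hb_total,
    blood_volume_fraction = blood_volume_fraction,
    water_fraction = water_fraction, lipid_fraction = lipid_fraction,
    melanin_fraction = melanin_fraction,
    g = g, n = n,
    musp_table = musp, musp_a = musp_a, musp_b = musp_b, musp_ref = musp_ref,
    mua_table = mua
  ), class = "layer_spec")
}

.layer_mua <- function(spec, wavelengths, tables) {
  if (!is.null(spec$mua_table)) {
    wl <- as.numeric(names(spec$mua_table))
    idx <- match(wavelengths, wl)
    if (anyNA(idx))
      stop("layer '", spec$name, "': no tabulated mua at ",
           paste(wavelengths[is.na(idx)], collapse = ", "), " nm")
    return(as.numeric(spec$mua_table[idx]))
  }
  chromophore_mua(spec$conc_hbo, spec$conc_hbr, spec$water_fraction,
                  spec$lipid_fraction, spec$melanin_fraction,
                  wavelengths, tables)
}

.layer_musp <- function(spec, wavelengths) {
  if (!is.null(spec$musp_table)) {
    wl <- as.numeric(names(spec$musp_table))
    idx <- match(wavelengths, wl)
    if (anyNA(idx))
      stop("layer '", spec$name, "': no tabulated musp at ",
           paste(wavelengths[is.na(idx)], collapse = ", "), " nm")
    return(as.numeric(spec$musp_table[idx]))
  }
  power_law_musp(spec$musp_a, spec$musp_b, wavelengths, spec$musp_ref)
}

#' Assemble a layered tissue model
#'
#' Evaluates each layer's absorption and reduced scattering at the working
#' wavelengths and packs geometry and interface optics into the container
#' consumed by the Monte Carlo engine. Layers are ordered surface to deep.
#'
#' @param layers list of [layer_spec()] objects, surface first.
#' @param wavelengths working wavelengths, nm.
#' @param ambient_n refractive index of the medium above the surface.
#' @param label `"baseline"` or `"perturbed"` (free-form allowed).
#' @param melanin_level epidermal melanosome volume fraction represented by
#'   this model variant (metadata; use [apply_melanin()] to actually fold
#'   it into the epidermal absorption).
#' @param tables extinction spectra, see [extinction_tables()].
#' @return An object of class `tissue_model` with fields `layer_names`,
#'   `thickness_mm`, `boundaries_mm` (length nlayer+1, starting at 0),
#'   `mua`, `musp` (nlayer x nwavelength matrices, mm^-1), `g`, `n`,
#'   `ambient_n`, `wavelengths`, `label`, `melanin_level`, `layers`.
#' @export
tissue_model <- function(layers, wavelengths, ambient_n = 1.0,
                         label = "baseline", melanin_level = 0,
                         tables = extinction_tables()) {
  stopifnot(length(layers) >= 1, length(wavelengths) >= 1)
  if (!all(vapply(layers, inherits, logical(1), "layer_spec")))
    stop("'layers' must be a list of layer_spec objects")
  thick <- vapply(layers, `[[`, numeric(1), "thickness_mm")
  bounds <- c(0, cumsum(thick))
  if (any(diff(bounds) <= 0)) stop("layer interfaces must be strictly increasing")
  nms <- vapply(layers, `[[`, character(1), "name")
  wl <- sort(unique(as.numeric(wavelengths)))
  mua <- t(vapply(layers, .layer_mua, numeric(length(wl)),
                  wavelengths = wl, tables = tables))
  musp <- t(vapply(layers, .layer_musp, numeric(length(wl)), wavelengths = wl))
  dim(mua) <- dim(musp) <- c(length(layers), length(wl))
  dimnames(mua) <- dimnames(musp) <- list(nms, as.character(wl))
  if (any(mua < 0)) stop("mua must be nonnegative")
  if (any(musp <= 0)) stop("musp must be positive")
  structure(list(
    layer_names = nms, thickness_mm = thick, boundaries_mm = bounds,
    mua = mua, musp = musp,
    g = vapply(layers, `[[`, numeric(1), "g"),
    n = vapply(layers, `[[`, numeric(1), "n"),
    ambient_n = ambient_n, wavelengths = wl,
    label = label, melanin_level = melanin_level,
    layers = layers
  ), class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("<tissue_model '", x$label, "'> ", length(x$layer_names), " layers, total ",
      sum(x$thickness_mm), " mm, melanin ", 100 * x$melanin_level, "%\n", sep = "")
  cat(" wavelengths:", paste(x$wavelengths, collapse = ", "), "nm\n")
  df <- data.frame(layer = x$layer_names, thickness_mm = x$thickness_mm,
                   g = x$g, n = x$n)
  print(cbind(df, round(x$musp, 4)), row.names = FALSE)
  invisible(x)
}

#' Load a tissue model from a YAML config
#'
#' Reads the one-block-per-layer YAML schema (`thickness_um`,
#' `conc_hbo_uM`, `conc_hbr_uM`, `conc_hb_total_uM`, `water_fraction`,
#' `lipid_fraction`, `melanin_fraction`, `g`, `n`, and either
#' `musp_power_law: {a_mm1, b, reference_nm}` or `musp_mm1: {<nm>: value}`;
#' optionally `mua_mm1: {<nm>: value}`).
#'
#' @param path YAML file path.
#' @param wavelengths working wavelengths, nm.
#' @param ... passed to [tissue_model()].
#' @return A `tissue_model`.
#' @export
load_tissue_model <- function(path, wavelengths = c(691, 731, 811, 851), ...) {
  cfg <- yaml::read_yaml(path)
  layers <- lapply(cfg$layers, function(L) {
    pl <- L$musp_power_law
    layer_spec(
      name = L$name, thickness_um = L$thickness_um,
      conc_hbo = L$conc_hbo_uM %||% 0, conc_hbr = L$conc_hbr_uM %||% 0,
      conc_hb_total = L$conc_hb_total_uM,
      blood_volume_fraction = L$blood_volume_fraction %||% 0,
      water_fraction = L$water_fraction %||% 0,
      lipid_fraction = L$lipid_fraction %||% 0,
      melanin_fraction = L$melanin_fraction %||% 0,
      g = L[["g"]], n = L[["n"]],
      musp = if (!is.null(L$musp_mm1)) unlist(L$musp_mm1),
      musp_a = pl$a_mm1, musp_b = pl$b, musp_ref = pl$reference_nm %||% 691,
      mua = if (!is.null(L$mua_mm1)) unlist(L$mua_mm1)
    )
  })
  tissue_model(layers, wavelengths = wavelengths,
               ambient_n = cfg$ambient_n %||% 1.0, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled four-layer skin model
#'
#' The healthy-baseline four-layer skin model (epidermis, papillary dermis,
#' reticular dermis, subcutaneous tissue; 7.5 mm total) shipped with the
#' package. Hemoglobin, water and lipid content, g and n follow the
#' standard multilayer-skin values; the dermal scattering power law is
#' calibrated so the dermal transport mean free path is 0.35 mm at 691 nm
#' and 0.46 mm at 851 nm.
#'
#' @inheritParams load_tissue_model
#' @return A baseline `tissue_model`.
#' @export
#' @examples
#' m <- skin_model()
#' transport_mfp(m$mua["papillary_dermis", "691"], m$musp["papillary_dermis", "691"])
skin_model <- function(wavelengths = c(691, 731, 811, 851), ...) {
  load_tissue_model(system.file("extdata", "models", "skin_four_layer.yaml",
                                package = "slimr"),
                    wavelengths = wavelengths, ...)
}

#' Dermal scattering perturbation (scleroderma model)
#'
#' Multiplies the reduced scattering of the papillary and reticular dermis
#' by `factor` at every wavelength (default 0.8, a 20% reduction, the
#' collagen-remodeling surrogate for sclerodermatous skin). Absorption,
#' g, n, thicknesses and all other layers are untouched.
#'
#' @param model a `tissue_model` containing layers named
#'   `papillary_dermis` and `reticular_dermis`.
#' @param factor multiplicative factor on dermal musp (> 0).
#' @return The perturbed model, with `label = "perturbed"`.
#' @export
apply_scleroderma_perturbation <- function(model, factor = 0.8) {
  stopifnot(inherits(model, "tissue_model"))
  if (!is.finite(factor) || factor <= 0) stop("'factor' must be positive")
  idx <- match(c("papillary_dermis", "reticular_dermis"), model$layer_names)
  if (anyNA(idx))
    stop("model lacks the dermal layers 'papillary_dermis'/'reticular_dermis'")
  model$musp[idx, ] <- model$musp[idx, ] * factor
  model$label <- "perturbed"
  model
}

#' Fold epidermal melanin into the model absorption
#'
#' Adds `level * melanosome_mua(lambda)` to the epidermal absorption row,
#' producing the model variant for a given melanosome volume fraction
#' (e.g. 0.02, 0.05, 0.10). The usual route for the simulation study is
#' perturbation-MC reweighting ([pmc_reweight()]) of a melanin-free run;
#' this direct variant exists for cross-checking the reweighting.
#'
#' @param model a `tissue_model` with an `epidermis` layer.
#' @param level melanosome volume fraction in `[0, 1]`.
#' @param tables extinction spectra.
#' @return The model with melanin folded in and `melanin_level` set.
#' @export
apply_melanin <- function(model, level, tables = extinction_tables()) {
  stopifnot(inherits(model, "tissue_model"))
  if (level < 0 || level > 1) stop("'level' must lie in [0, 1]")
  idx <- match("epidermis", model$layer_names)
  if (is.na(idx)) stop("model lacks an 'epidermis' layer")
  model$mua[idx, ] <- model$mua[idx, ] + level * melanosome_mua(model$wavelengths, tables)
  model$melanin_level <- level
  model
}
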
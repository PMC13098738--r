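#' Pencil-beam Monte Carlo simulation of a layered model
#'
#' Launches `n_photons` normally incident photons at the origin of the
#' layered slab and tracks them with exponential step sampling
#' (`mut = mua + mus`, `mus = musp / (1 - g)`), Henyey-Greenstein
#' scattering, per-collision albedo weighting, unpolarized Fresnel
#' reflection/refraction at every index-mismatched interface (detection
#' acceptance is the full upward hemisphere), and Russian roulette
#' (`w_threshold`, survival probability `p_survive`). Specular reflection
#' at the ambient/surface interface is tallied separately. Identical
#' `(model, wavelength, n_photons, seed)` give bit-identical tallies;
#' per-photon RNG substreams make photon i reproducible independently of
#' batching.
#'
#' @param model a [tissue_model()].
#' @param wavelength one of the model's wavelengths, nm.
#' @param n_photons number of photon packets (>= 1).
#' @param seed integer RNG seed.
#' @param w_threshold Russian-roulette weight threshold.
#' @param p_survive roulette survival probability (survivor weight is
#'   divided by it).
#' @param ambient_n_below refractive index below the deepest layer.
#' @return An object of class `photon_tally`: per-detected-photon vectors
#'   `exit_weight`, `exit_radius` (mm), `zmax` (mm), matrices
#'   `path_lengths` (mm) and `collisions` (columns = layers), plus
#'   `n_launched`, `total_absorbed_weight`, `total_transmitted_weight`,
#'   `specular_weight`, `model_label`, `melanin_level`, `wavelength`,
#'   `seed`, `layer_names`, `boundaries_mm`.
#' @export
simulate_pencil_beam <- function(model, wavelength, n_photons, seed,
                                 w_threshold = 1e-4, p_survive = 0.1,
                                 ambient_n_below = 1.0) {
  stopifnot(inherits(model, "tissue_model"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  j <- match(wavelength, model$wavelengths)
  if (is.na(j)) stop("model has no optical properties at ", wavelength, " nm")
  musp <- model$musp[, j]
  g <- model$g
  mus <- ifelse(g < 1, musp / (1 - g), musp)
  raw <- .mc_run(as.integer(n_photons), as.double(seed),
                 model$boundaries_mm, model$mua[, j], mus, g, model$n,
                 model$ambient_n, ambient_n_below, w_threshold, p_survive)
  colnames(raw$path_lengths) <- colnames(raw$collisions) <- model$layer_names
  structure(c(raw, list(
    model_label = model$label, melanin_level = model$melanin_level,
    wavelength = wavelength, seed = seed,
    layer_names = model$layer_names, boundaries_mm = model$boundaries_mm
  )), class = "photon_tally")
}

#' @export
print.photon_tally <- function(x, ...) {
  cat("<photon_tally> ", x$n_launched, " launched at ", x$wavelength, " nm ('",
      x$model_label, "'), ", length(x$exit_weight), " detected\n", sep = "")
  cat(sprintf(" Rd(0) = %.5f, absorbed = %.5f, transmitted = %.5f, specular = %.5f\n",
              sum(x$exit_weight) / x$n_launched,
              x$total_absorbed_weight / x$n_launched,
              x$total_transmitted_weight / x$n_launched,
              x$specular_weight / x$n_launched))
  invisible(x)
}

#' Energy-balance closure of a tally
#'
#' `(reflected + absorbed + transmitted + specular) / n_launched - 1`;
#' zero up to floating-point accumulation error (well below 1e-6) for any
#' simulation.
#'
#' @param tally a `photon_tally`.
#' @return Signed closure error.
#' @export
energy_closure <- function(tally) {
  (sum(tally$exit_weight) + tally$total_absorbed_weight +
     tally$total_transmitted_weight + tally$specular_weight) /
    tally$n_launched - 1
}

#' Radial binning specification for the Hankel transform
#'
#' @param n_bins number of uniform radial bins.
#' @param r_max outer radius, mm. Photons exiting beyond it are kept in an
#'   overflow bin at `r_max` (so they still count exactly in Rd(0)); if
#'   their weight exceeds 0.1% of the detected weight a coverage warning is
#'   raised.
#' @return A `radial_bins` spec.
#' @export
radial_bins <- function(n_bins = 512, r_max = 50) {
  stopifnot(n_bins >= 1, r_max > 0)
  structure(list(n_bins = n_bins, r_max = r_max), class = "radial_bins")
}

# uniform depth bins whose last edge is guaranteed to reach the model bottom
.default_z_edges <- function(total, dz = 0.025) {
  nb <- max(1, ceiling(total / dz - 1e-9))
  edges <- (0:nb) * dz
  edges[nb + 1] <- max(edges[nb + 1], total)
  edges
}

# per-photon radial bin centers (overflow photons sit at r_max)
.bin_centers_for <- function(tally, binning) {
  dr <- binning$r_max / binning$n_bins
  idx <- pmin(floor(tally$exit_radius / dr), binning$n_bins)
  over <- idx >= binning$n_bins
  centers <- ifelse(over, binning$r_max, (idx + 0.5) * dr)
  if (any(over)) {
    frac <- sum(tally$exit_weight[over]) / sum(tally$exit_weight)
    if (frac > 0.001)
      warning(sprintf("%.2f%% of detected weight exits beyond r_max = %g mm; %s",
                      100 * frac, binning$r_max,
                      "consider enlarging the radial binning"))
  }
  centers
}

#' Spatial-frequency-domain diffuse reflectance from a tally
#'
#' Computes `Rd(fx)` from the radially resolved exit weights of a
#' pencil-beam tally via the zeroth-order Hankel transform,
#' `Rd(fx) = 2 pi int R(rho) J0(2 pi fx rho) rho d rho`, evaluated as a
#' discrete quadrature over uniform radial bins (each photon contributes
#' `w J0(2 pi fx rho_c)` with `rho_c` the center of its bin). At `fx = 0`
#' this reduces exactly to the total diffuse reflectance
#' `sum(exit_weight) / n_launched`. One pencil-beam tally therefore yields
#' Rd at every requested spatial frequency.
#'
#' @param tally a `photon_tally` with at least one detected photon.
#' @param spatial_frequencies frequencies, mm^-1 (>= 0).
#' @param binning a [radial_bins()] spec.
#' @return Data frame with columns `fx`, `rd`, `se` (Monte Carlo standard
#'   error of `rd`).
#' @export
hankel_rd <- function(tally, spatial_frequencies, binning = radial_bins()) {
  stopifnot(inherits(tally, "photon_tally"))
  if (length(tally$exit_weight) == 0) stop("tally has no detected photons")
  if (any(spatial_frequencies < 0)) stop("spatial frequencies must be >= 0")
  centers <- .bin_centers_for(tally, binning)
  n <- tally$n_launched
  w <- tally$exit_weight
  out <- vapply(spatial_frequencies, function(fx) {
    c_i <- w * besselJ(2 * pi * fx * centers, 0)
    rd <- sum(c_i) / n
    se <- sqrt(max(0, sum(c_i^2) / n - rd^2) / n)
    c(rd, se)
  }, numeric(2))
  data.frame(fx = spatial_frequencies, rd = out[1, ], se = out[2, ])
}

#' Maximum-penetration-depth distribution Pzmax(z)
#'
#' Accumulates each detected photon's frequency-weighted contribution (the
#' same bin-center `J0` weighting as [hankel_rd()]) into the depth bin
#' containing its maximum depth `zmax`. Summed over all bins the
#' distribution reproduces `Rd(fx)` exactly (same weights, exact partition
#' of the detected weight). At `fx = 0` all bin values are nonnegative; at
#' higher frequencies individual bins can carry small negative weight
#' because `J0` changes sign.
#'
#' @param tally a `photon_tally`.
#' @param spatial_frequency one frequency, mm^-1.
#' @param z_edges depth bin edges, mm, spanning every recorded `zmax`
#'   (default: 25 um bins over the full model thickness).
#' @param binning radial binning shared with [hankel_rd()].
#' @return An object of class `depth_distribution`: `z_edges`, `pzmax`
#'   (one value per bin), `spatial_frequency`, `wavelength`.
#' @export
pzmax_distribution <- function(tally, spatial_frequency,
                               z_edges = .default_z_edges(max(tally$boundaries_mm)),
                               binning = radial_bins()) {
  stopifnot(inherits(tally, "photon_tally"), length(spatial_frequency) == 1)
  if (length(tally$exit_weight) == 0) stop("tally has no detected photons")
  zmax <- tally$zmax
  if (any(zmax < z_edges[1]) || any(zmax > z_edges[length(z_edges)]))
    stop("z_edges do not span all recorded zmax values; weight would be dropped")
  centers <- .bin_centers_for(tally, binning)
  c_i <- tally$exit_weight * besselJ(2 * pi * spatial_frequency * centers, 0) /
    tally$n_launched
  # zmax > 0 always (photons must enter the medium), so left-open bins keep
  # every photon: bin k covers (z_k, z_{k+1}]
  bin <- findInterval(zmax, z_edges, left.open = TRUE, rightmost.closed = TRUE)
  bin[bin == 0] <- 1
  pz <- vapply(seq_len(length(z_edges) - 1),
               function(k) sum(c_i[bin == k]), numeric(1))
  structure(list(z_edges = z_edges, pzmax = pz,
                 spatial_frequency = spatial_frequency,
                 wavelength = tally$wavelength),
            class = "depth_distribution")
}

#' Perturbation-MC reweighting for an absorption change
#'
#' Estimates the tally of a model whose absorption in one layer is changed
#' by `delta_mua` without re-simulating: each detected photon's exit weight
#' is multiplied by `exp(-delta_mua * L)`, with `L` its recorded path
#' length in that layer. Scattering is untouched (valid for
#' absorption-only perturbations such as epidermal melanin). The removed
#' weight is moved to the absorbed tally so the energy balance still
#' closes. The result is a regular `photon_tally`, reusable by
#' [hankel_rd()] and [pzmax_distribution()].
#'
#' @param tally a `photon_tally` with per-layer path-length bookkeeping.
#' @param layer layer name, e.g. `"epidermis"`.
#' @param delta_mua absorption change, mm^-1 (negative allowed).
#' @return The reweighted `photon_tally`.
#' @export
pmc_reweight <- function(tally, layer, delta_mua) {
  stopifnot(inherits(tally, "photon_tally"))
  if (is.null(tally$path_lengths))
    stop("tally lacks per-layer path-length records; cannot reweight")
  j <- match(layer, colnames(tally$path_lengths))
  if (is.na(j)) stop("tally has no layer named '", layer, "'")
  if (delta_mua == 0) return(tally)
  w_new <- tally$exit_weight *
    exp(-delta_mua * as.vector(tally$path_lengths[, j]))
  tally$total_absorbed_weight <- tally$total_absorbed_weight +
    sum(tally$exit_weight - w_new)
  tally$exit_weight <- w_new
  tally$melanin_level <- NA_real_ # no longer the conventional-run level
  tally
}

#' Baseline-vs-perturbed reflectance difference grid
#'
#' Runs the baseline and perturbed models at each wavelength (sharing the
#' seed, i.e. common random numbers, unless
#' `common_random_numbers = FALSE`), optionally folds an epidermal
#' melanosome volume fraction into both via perturbation-MC reweighting,
#' and tabulates `Rd_perturbed - Rd_baseline` over the wavelength by
#' spatial-frequency grid with Monte Carlo standard errors (the SE of the
#' difference is reported conservatively as the root sum of squares of the
#' two run SEs).
#'
#' @param model_baseline,model_perturbed `tissue_model`s sharing the same
#'   wavelength list.
#' @param wavelengths wavelengths to simulate, nm.
#' @param spatial_frequencies frequencies, mm^-1.
#' @param n_photons photons per (model, wavelength) run.
#' @param seed integer seed; run r at wavelength i uses `seed + offsets`
#'   derived deterministically.
#' @param melanin_level epidermal melanosome fraction applied by
#'   [pmc_reweight()] to both models (0 = none).
#' @param common_random_numbers share the seed between baseline and
#'   perturbed runs at each wavelength.
#' @param binning radial binning for [hankel_rd()].
#' @param tables extinction spectra (for the melanin delta-mua).
#' @return An object of class `delta_rd_grid`: `wavelengths`,
#'   `spatial_frequencies`, matrices `rd_baseline`, `rd_perturbed`,
#'   `delta_rd`, `se` (wavelength rows, frequency columns),
#'   `melanin_level`, `n_photons`, `seed`.
#' @export
delta_rd_grid <- function(model_baseline, model_perturbed,
                          wavelengths = model_baseline$wavelengths,
                          spatial_frequencies = c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5),
                          n_photons = 1e5, seed = 1,
                          melanin_level = 0, common_random_numbers = TRUE,
                          binning = radial_bins(),
                          tables = extinction_tables()) {
  if (!all(wavelengths %in% model_baseline$wavelengths) ||
      !all(wavelengths %in% model_perturbed$wavelengths))
    stop("both models must carry optical properties at every requested wavelength")
  nw <- length(wavelengths); nf <- length(spatial_frequencies)
  rb <- rp <- dd <- se <- matrix(NA_real_, nw, nf,
                                 dimnames = list(wavelengths, spatial_frequencies))
  for (i in seq_len(nw)) {
    wl <- wavelengths[i]
    s_b <- seed + (i - 1) * 2
    s_p <- if (common_random_numbers) s_b else s_b + 1
    t_b <- simulate_pencil_beam(model_baseline, wl, n_photons, s_b)
    t_p <- simulate_pencil_beam(model_perturbed, wl, n_photons, s_p)
    if (melanin_level > 0) {
      dmua <- melanin_level * melanosome_mua(wl, tables)
      t_b <- pmc_reweight(t_b, "epidermis", dmua)
      t_p <- pmc_reweight(t_p, "epidermis", dmua)
    }
    h_b <- hankel_rd(t_b, spatial_frequencies, binning)
    h_p <- hankel_rd(t_p, spatial_frequencies, binning)
    rb[i, ] <- h_b$rd; rp[i, ] <- h_p$rd
    dd[i, ] <- h_p$rd - h_b$rd
    se[i, ] <- sqrt(h_b$se^2 + h_p$se^2)
  }
  structure(list(wavelengths = wavelengths,
                 spatial_frequencies = spatial_frequencies,
                 rd_baseline = rb, rd_perturbed = rp, delta_rd = dd,
                 mc_standard_error = se,
                 melanin_level = melanin_level, n_photons = n_photons,
                 seed = seed,
                 common_random_numbers = common_random_numbers),
            class = "delta_rd_grid")
}

#' @export
print.delta_rd_grid <- function(x, ...) {
  cat("<delta_rd_grid> melanin ", 100 * x$melanin_level, "%, ",
      x$n_photons, " photons per run\n", sep = "")
  print(round(x$delta_rd, 5))
  invisible(x)
}

#' Most perturbation-sensitive spatial frequency per wavelength
#'
#' For each wavelength, the grid frequency maximizing `|delta Rd|`; exact
#' ties are broken toward the lower frequency.
#'
#' @param grid a [delta_rd_grid()].
#' @return Named numeric vector (names = wavelengths, nm) of fx in mm^-1,
#'   with attribute `tie_break = "lower_fx"`.
#' @export
optimal_fx <- function(grid) {
  stopifnot(inherits(grid, "delta_rd_grid"))
  if (length(grid$spatial_frequencies) == 0 || length(grid$wavelengths) == 0)
    stop("empty grid")
  fx <- grid$spatial_frequencies
  ord <- order(fx) # scan in ascending fx so which.max keeps the lower tie
  res <- apply(grid$delta_rd, 1, function(row) {
    a <- abs(row)[ord]
    fx[ord][which.max(a)]
  })
  names(res) <- grid$wavelengths
  attr(res, "tie_break") <- "lower_fx"
  res
}

#' Per-layer contributions to the reflectance change
#'
#' Integrates `pzmax_perturbed - pzmax_baseline` over the depth bins
#' belonging to each layer. The layer sums partition the total reflectance
#' change at that frequency exactly.
#'
#' @param dist_baseline,dist_perturbed `depth_distribution`s sharing
#'   `z_edges` and `spatial_frequency`.
#' @param model the `tissue_model` providing layer boundaries.
#' @return Named numeric vector of delta-Rd contributions per layer.
#' @export
layer_contributions <- function(dist_baseline, dist_perturbed, model) {
  stopifnot(inherits(dist_baseline, "depth_distribution"),
            inherits(dist_perturbed, "depth_distribution"),
            inherits(model, "tissue_model"))
  if (!isTRUE(all.equal(dist_baseline$z_edges, dist_perturbed$z_edges)) ||
      dist_baseline$spatial_frequency != dist_perturbed$spatial_frequency)
    stop("distributions must share z_edges and spatial_frequency")
  edges <- dist_baseline$z_edges
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  lay <- findInterval(mid, model$boundaries_mm, rightmost.closed = TRUE)
  lay <- pmin(pmax(lay, 1), length(model$layer_names))
  diff_pz <- dist_perturbed$pzmax - dist_baseline$pzmax
  out <- vapply(seq_along(model$layer_names),
                function(k) sum(diff_pz[lay == k]), numeric(1))
  names(out) <- model$layer_names
  out
}

#' Spatial-frequency-domain diffusion reflectance (closed form)
#'
#' Standard diffusion-approximation reflectance of a homogeneous
#' semi-infinite medium under sinusoidal illumination:
#' with `mutr = mua + musp`, `a' = musp/mutr`,
#' `mueff'(fx) = sqrt(3 mua mutr + (2 pi fx)^2)` and the
#' refractive-index-mismatch constant `A = (1 - Reff) / (2 (1 + Reff))`,
#' `Reff = 0.0636 n + 0.668 + 0.710/n - 1.440/n^2`,
#' \deqn{R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)
#'   (\mu_{eff}'/\mu_{tr} + 3A)}.}
#' Accurate for high-albedo media (`musp/mua >~ 100`) at low frequencies;
#' used as an independent oracle for the Monte Carlo engine and as a
#' phantom reflectance predictor for calibration.
#'
#' @param mua,musp optical properties, mm^-1.
#' @param fx spatial frequency(ies), mm^-1.
#' @param n_rel tissue/ambient relative refractive index.
#' @return Rd at each `fx`.
#' @export
diffusion_rd_fx <- function(mua, musp, fx, n_rel = 1) {
  stopifnot(mua >= 0, musp > 0)
  reff <- 0.0636 * n_rel + 0.668 + 0.710 / n_rel - 1.440 / n_rel^2
  A <- (1 - reff) / (2 * (1 + reff))
  mutr <- mua + musp
  ap <- musp / mutr
  mueff <- sqrt(3 * mua * mutr + (2 * pi * fx)^2)
  3 * A * ap / ((mueff / mutr + 1) * (mueff / mutr + 3 * A))
}
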
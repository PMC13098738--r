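#' Generate a three-phase structured-illumination stack with known truth
#'
#' Inverts the demodulation forward model: each phase image is
#' `I_i = response * (dc + scale * true_rd * sin(2 pi fx x + phi_i))` with
#' `phi_i` in {0, 120, 240} degrees and `x` the physical column coordinate
#' (patterns vary along image columns), plus optional Gaussian noise.
#' Noise-free and with a unit response, `demodulate()` of the stack equals
#' `scale * true_rd` exactly; a phantom stack generated with the same
#' response field closes the calibration round trip exactly.
#'
#' @param true_rd ground-truth reflectance: a matrix, or a scalar with
#'   `dims` giving the image shape.
#' @param spatial_frequency mm^-1 (0 = DC pattern; the three phase offsets
#'   still differ so demodulation works unchanged).
#' @param wavelength nm (metadata).
#' @param dims `c(rows, cols)` when `true_rd` is scalar.
#' @param dc_offset DC illumination intensity.
#' @param modulation_scale intensity of the modulated component per unit
#'   Rd; demodulated amplitudes are divided by it on calibration via the
#'   phantom ratio.
#' @param instrument_response multiplicative response field (scalar or
#'   matrix); applied to both DC and AC parts as a real instrument would.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param pixel_pitch mm per pixel.
#' @param phase_offset_deg extra global phase added to all three patterns
#'   (the demodulated amplitude is invariant to it).
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @return List with `stack` (a [phase_stack()]) and `truth` (list:
#'   `true_rd`, `dc_offset`, `modulation_scale`, `instrument_response`,
#'   `noise_sd`, `seed`, `n_clipped`). Negative intensities are clipped at
#'   zero and counted in `n_clipped` (with a message).
#' @export
gen_phase_stack <- function(true_rd, spatial_frequency, wavelength,
                            dims = NULL, dc_offset = 0.45,
                            modulation_scale = 0.4,
                            instrument_response = 1, noise_sd = 0,
                            pixel_pitch = 0.14375, phase_offset_deg = 0,
                            seed = 1) {
  if (!is.matrix(true_rd)) {
    stopifnot(!is.null(dims), length(dims) == 2)
    true_rd <- matrix(true_rd, dims[1], dims[2])
  }
  if (any(true_rd < 0)) stop("true_rd must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.matrix(instrument_response))
    instrument_response <- matrix(instrument_response,
                                  nrow(true_rd), ncol(true_rd))
  if (any(instrument_response <= 0)) stop("instrument response must be positive")
  x <- matrix((col(true_rd) - 1) * pixel_pitch, nrow(true_rd))
  n_clipped <- 0L
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  imgs <- lapply(c(0, 120, 240), function(ph) {
    phi <- (ph + phase_offset_deg) * pi / 180
    img <- instrument_response *
      (dc_offset + modulation_scale * true_rd *
         sin(2 * pi * spatial_frequency * x + phi))
    if (noise_sd > 0)
      img <- img + matrix(rnorm(length(img), sd = noise_sd),
                          nrow(img), ncol(img))
    neg <- img < 0
    n_clipped <<- n_clipped + sum(neg)
    img[neg] <- 0
    img
  })
  if (n_clipped > 0)
    message(n_clipped, " negative pixel(s) clipped to zero")
  list(stack = phase_stack(imgs[[1]], imgs[[2]], imgs[[3]],
                           wavelength = wavelength,
                           spatial_frequency = spatial_frequency,
                           pixel_pitch = pixel_pitch),
       truth = list(true_rd = true_rd, dc_offset = dc_offset,
                    modulation_scale = modulation_scale,
                    instrument_response = instrument_response,
                    noise_sd = noise_sd, seed = seed,
                    n_clipped = n_clipped))
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a two-group cohort with a planted reflectance effect
#'
#' Emulates the clinical cohort structure (default 25 patients vs 18
#' controls, six measurement sites each) over a wavelength by
#' spatial-frequency grid. Site-level reflectance is Gaussian:
#' `rd = mean_control - d * sd * [patient & effect cell] + sd * eta`,
#' where the noise `eta` shares a subject-level component across sites
#' (correlation `site_correlation`) and the group separation `d`
#' (standardized effect size, control minus patient) is planted only at
#' `effect_cell`. With uncorrelated sites the expected site-level AUC at
#' the planted cell is `pnorm(d / sqrt(2))`.
#'
#' Patient skin scores are generated from the same latent severity that
#' drives the planted-cell reflectance: `sev = d - eta` (higher severity,
#' lower Rd) is cut at the 25/50/75% quantiles of its patient-population
#' distribution into integer scores 0-3, then flipped one step up or down
#' with probability `mislabel_prob` (ordinal palpation noise). Controls
#' score 0 at every site. With `mislabel_prob = 0` the construction makes
#' total Rd and total mRSS inversely related by design.
#'
#' @param n_patient,n_control group sizes.
#' @param rd_mean_control control-group site-level mean reflectance.
#' @param rd_sd site-level reflectance SD.
#' @param effect_size_d standardized control-minus-patient difference at
#'   the planted cell.
#' @param site_correlation within-subject correlation of site noise,
#'   in `[0, 1)`.
#' @param wavelengths,spatial_frequencies the measurement grid.
#' @param effect_cell `c(wavelength, spatial_frequency)` of the planted
#'   effect; must be on the grid.
#' @param mislabel_prob probability of flipping a site score by one step,
#'   in `[0, 0.5)`.
#' @param seed integer seed.
#' @return A [cohort_table()] data frame (with a `race` column sampled in
#'   clinical-table proportions for stratified analyses), carrying the
#'   latent truth as attribute `truth` (subject severities, planted cell,
#'   generator spec).
#' @export
gen_cohort <- function(n_patient = 25, n_control = 18,
                       rd_mean_control = 0.55, rd_sd = 0.05,
                       effect_size_d = 1.5, site_correlation = 0.3,
                       wavelengths = 851, spatial_frequencies = 0.15,
                       effect_cell = c(wavelengths[1], spatial_frequencies[1]),
                       mislabel_prob = 0.1, seed = 1) {
  stopifnot(n_patient >= 1, n_control >= 1, rd_sd > 0,
            site_correlation >= 0, site_correlation < 1,
            mislabel_prob >= 0, mislabel_prob < 0.5)
  if (!(effect_cell[1] %in% wavelengths) ||
      !(effect_cell[2] %in% spatial_frequencies))
    stop("effect_cell must lie on the wavelength/frequency grid")
  sites <- c("forearm_left", "forearm_right", "hand_left", "hand_right",
             "fingers_left", "fingers_right")
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_tot <- n_patient + n_control
  ids <- c(sprintf("P%02d", seq_len(n_patient)),
           sprintf("C%02d", seq_len(n_control)))
  group <- rep(c("patient", "control"), c(n_patient, n_control))
  race <- c(sample(c("Black", "White", "Other"), n_patient, TRUE,
                   prob = c(6, 17, 2) / 25),
            sample(c("Black", "White", "Other"), n_control, TRUE,
                   prob = c(5, 9, 4) / 18))
  z_subj <- rnorm(n_tot)
  rho <- site_correlation
  ns <- length(sites)
  # site noise at the effect cell drives severity; other cells get fresh noise
  e_eff <- matrix(rnorm(n_tot * ns), n_tot, ns)
  eta_eff <- sqrt(rho) * z_subj + sqrt(1 - rho) * e_eff
  d <- effect_size_d
  sev <- d - eta_eff # patient severity latent; N(d, 1) marginally
  cuts <- d + qnorm(c(0.25, 0.50, 0.75))
  score <- matrix(findInterval(sev, cuts), n_tot, ns)
  if (mislabel_prob > 0) {
    flip <- matrix(runif(n_tot * ns) < mislabel_prob, n_tot, ns)
    dirn <- matrix(sample(c(-1L, 1L), n_tot * ns, TRUE), n_tot, ns)
    score[flip] <- pmin(pmax(score[flip] + dirn[flip], 0L), 3L)
  }
  rows <- list()
  for (wl in wavelengths) for (fx in spatial_frequencies) {
    at_eff <- (wl == effect_cell[1] && fx == effect_cell[2])
    eta <- if (at_eff) eta_eff else
      sqrt(rho) * z_subj + sqrt(1 - rho) * matrix(rnorm(n_tot * ns), n_tot, ns)
    shift <- ifelse(group == "patient" & at_eff, d * rd_sd, 0)
    rd <- rd_mean_control - shift + rd_sd * eta
    rd <- pmax(rd, 0)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = rep(ids, ns), group = rep(group, ns),
      race = rep(race, ns), site = rep(sites, each = n_tot),
      wavelength = wl, spatial_frequency = fx,
      mean_rd = as.vector(rd),
      mrss = ifelse(rep(group, ns) == "patient", as.vector(score), 0L))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cohort_table(out)
  attr(out, "truth") <- list(
    subject_severity = rowMeans(sev)[group == "patient"],
    effect_cell = effect_cell, effect_size_d = d,
    rd_mean_control = rd_mean_control, rd_sd = rd_sd,
    site_correlation = rho, mislabel_prob = mislabel_prob, seed = seed)
  out
}
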
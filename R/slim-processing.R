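#' Three-phase structured-illumination stack
#'
#' Container for the three phase-shifted images (0, 120, 240 degrees) of
#' one wavelength / spatial-frequency acquisition.
#'
#' @param i1,i2,i3 nonnegative intensity matrices of identical shape (the
#'   0, 120 and 240 degree images).
#' @param wavelength nm.
#' @param spatial_frequency mm^-1.
#' @param pixel_pitch mm per pixel (default 0.14375, the pitch implied by
#'   an 800 x 300 px ROI spanning ~11.5 x 4.3 cm).
#' @param phases phase offsets in degrees; must be exactly 0, 120, 240.
#' @return An object of class `phase_stack`.
#' @export
phase_stack <- function(i1, i2, i3, wavelength, spatial_frequency,
                        pixel_pitch = 0.14375, phases = c(0, 120, 240)) {
  imgs <- list(i1, i2, i3)
  if (!all(vapply(imgs, is.matrix, logical(1))))
    stop("phase images must be matrices")
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[, 2] != dims[, 1]) || any(dims[, 3] != dims[, 1]))
    stop("the three phase images must share the same shape")
  if (any(vapply(imgs, function(m) any(m < 0, na.rm = TRUE), logical(1))))
    stop("intensities must be nonnegative")
  if (!identical(sort(as.numeric(phases)), c(0, 120, 240)))
    stop("phases must be exactly {0, 120, 240} degrees")
  structure(list(i1 = i1, i2 = i2, i3 = i3,
                 wavelength = wavelength,
                 spatial_frequency = spatial_frequency,
                 pixel_pitch = pixel_pitch, phases = phases),
            class = "phase_stack")
}

#' Three-phase demodulation
#'
#' Extracts the per-pixel AC modulation amplitude from the three
#' phase-shifted images:
#' \deqn{I = \frac{\sqrt{2}}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}.}
#' For a pure three-phase sinusoid this recovers the modulation amplitude
#' exactly at every pixel, independent of the DC offset and of the local
#' phase; a common additive offset cancels and a common gain scales the
#' output linearly.
#'
#' @param stack a [phase_stack()].
#' @return Nonnegative amplitude matrix with the shape of the input images.
#' @export
demodulate <- function(stack) {
  stopifnot(inherits(stack, "phase_stack"))
  sqrt(2) / 3 * sqrt((stack$i1 - stack$i2)^2 +
                     (stack$i2 - stack$i3)^2 +
                     (stack$i3 - stack$i1)^2)
}

#' Calibrated diffuse-reflectance map
#'
#' @param values reflectance matrix (NA = masked/missing pixels).
#' @param wavelength nm.
#' @param spatial_frequency mm^-1.
#' @param pixel_pitch mm per pixel.
#' @param calibration_id identifier of the phantom used (free-form).
#' @param corrected logical; has a height/angle correction been applied?
#' @return An object of class `rd_map`.
#' @export
rd_map <- function(values, wavelength, spatial_frequency,
                   pixel_pitch = 0.14375, calibration_id = NA_character_,
                   corrected = FALSE) {
  stopifnot(is.matrix(values))
  if (any(values < 0, na.rm = TRUE)) stop("reflectance values must be >= 0")
  structure(list(values = values, wavelength = wavelength,
                 spatial_frequency = spatial_frequency,
                 pixel_pitch = pixel_pitch, calibration_id = calibration_id,
                 corrected = corrected),
            class = "rd_map")
}

#' @export
print.rd_map <- function(x, ...) {
  cat("<rd_map> ", nrow(x$values), "x", ncol(x$values), " px at ",
      x$wavelength, " nm, fx = ", x$spatial_frequency, " mm^-1",
      if (x$corrected) ", corrected" else "", "\n", sep = "")
  cat(sprintf(" mean Rd = %.4f (%d masked px)\n",
              mean(x$values, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}

#' Phantom calibration of a demodulated amplitude map
#'
#' Removes the multiplicative instrument response by ratioing the sample
#' amplitude against the amplitude of a reference phantom acquired at the
#' same wavelength and spatial frequency, then scaling by the phantom's
#' predicted reflectance: `Rd = sample / phantom * phantom_rd_model`.
#' The phantom prediction can come from the Monte Carlo engine (e.g.
#' [hankel_rd()] on a homogeneous phantom model, or [diffusion_rd_fx()])
#' or be a vendor-supplied number.
#'
#' @param sample_amp,phantom_amp demodulated amplitude matrices of equal
#'   shape.
#' @param phantom_rd_model predicted phantom Rd at this (wavelength, fx),
#'   in (0, 1].
#' @param wavelength,spatial_frequency,pixel_pitch metadata for the
#'   resulting map.
#' @param calibration_id phantom identifier.
#' @param mask optional logical matrix; TRUE pixels are carried as missing.
#' @return An [rd_map()]; masked pixels are NA.
#' @export
calibrate <- function(sample_amp, phantom_amp, phantom_rd_model,
                      wavelength = NA_real_, spatial_frequency = NA_real_,
                      pixel_pitch = 0.14375,
                      calibration_id = NA_character_, mask = NULL) {
  if (!identical(dim(sample_amp), dim(phantom_amp)))
    stop("sample and phantom amplitude maps must share the same shape")
  if (!is.finite(phantom_rd_model) || phantom_rd_model <= 0 || phantom_rd_model > 1)
    stop("phantom_rd_model must lie in (0, 1]")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(sample_amp), ncol(sample_amp))
  if (any(phantom_amp[!mask] <= 0, na.rm = TRUE))
    stop("phantom amplitude is zero or negative at unmasked pixels; mask them")
  vals <- sample_amp / phantom_amp * phantom_rd_model
  vals[mask] <- NA_real_
  rd_map(vals, wavelength, spatial_frequency, pixel_pitch,
         calibration_id = calibration_id, corrected = FALSE)
}

#' Apply a multiplicative per-pixel correction field
#'
#' Pluggable interface for externally computed height/angle (or any other
#' multiplicative) corrections: the map is multiplied pixelwise by
#' `correction_field` and flagged as corrected. An all-ones field is a
#' no-op on the values.
#'
#' @param map an [rd_map()].
#' @param correction_field positive matrix matching the map shape.
#' @return The corrected `rd_map`.
#' @export
apply_correction <- function(map, correction_field) {
  stopifnot(inherits(map, "rd_map"))
  if (!identical(dim(map$values), dim(correction_field)))
    stop("correction field shape does not match the map")
  if (any(correction_field <= 0, na.rm = TRUE))
    stop("correction field must be strictly positive")
  map$values <- map$values * correction_field
  map$corrected <- TRUE
  map
}

.roi_defaults <- list(
  forearm = c(height = 800L, width = 300L),
  hand = c(height = 300L, width = 300L),
  finger = c(height = 100L, width = 25L)
)

#' Rectangular region-of-interest specification
#'
#' Site-default dimensions: forearm 800 x 300 px, hand 300 x 300 px, each
#' finger 100 x 25 px (finger sites `finger_1` .. `finger_5`).
#'
#' @param site one of `"forearm"`, `"hand"`, `"finger_1"` .. `"finger_5"`.
#' @param origin `c(row, col)` of the top-left corner, 0-based.
#' @param height,width ROI size in pixels; defaults by site.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(site, origin, height = NULL, width = NULL) {
  base <- sub("_[1-5]$", "", site)
  if (!base %in% names(.roi_defaults))
    stop("unknown site '", site, "'")
  d <- .roi_defaults[[base]]
  height <- height %||% unname(d["height"])
  width <- width %||% unname(d["width"])
  stopifnot(length(origin) == 2, all(origin >= 0), height >= 1, width >= 1)
  structure(list(site = site, origin = as.integer(origin),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

#' Mean reflectance over a region of interest
#'
#' Arithmetic mean of the unmasked pixels inside the ROI. When `roi` is a
#' list of ROIs (the five finger ROIs of one hand), the per-ROI means are
#' averaged with equal weight into one representative value.
#'
#' @param map an [rd_map()].
#' @param roi a [roi_spec()] or a list of them.
#' @return Mean Rd (unitless scalar).
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "rd_map"))
  if (inherits(roi, "roi_spec")) roi <- list(roi)
  means <- vapply(roi, function(r) {
    rows <- (r$origin[1] + 1):(r$origin[1] + r$height)
    cols <- (r$origin[2] + 1):(r$origin[2] + r$width)
    if (max(rows) > nrow(map$values) || max(cols) > ncol(map$values))
      stop("ROI '", r$site, "' extends outside the image (",
           nrow(map$values), "x", ncol(map$values), " px)")
    px <- map$values[rows, cols]
    if (all(is.na(px))) stop("ROI '", r$site, "' contains only masked pixels")
    mean(px, na.rm = TRUE)
  }, numeric(1))
  mean(means)
}

# ---- raster IO -------------------------------------------------------------

#' Write / read a reflectance map as 32-bit float TIFF + JSON sidecar
#'
#' The sidecar (`<path>.json`) records wavelength, spatial frequency,
#' pixel pitch, calibration id and correction flag; masked pixels are
#' stored as NaN.
#'
#' @param map an [rd_map()].
#' @param path output TIFF path.
#' @return `write_rd_map` returns `path` invisibly; `read_rd_map` returns
#'   the `rd_map`.
#' @export
write_rd_map <- function(map, path) {
  stopifnot(inherits(map, "rd_map"))
  scale <- .write_float_tiff(map$values, path)
  meta <- list(wavelength_nm = map$wavelength,
               fx_mm1 = map$spatial_frequency,
               pixel_pitch_mm = map$pixel_pitch,
               calibration_id = map$calibration_id,
               corrected = map$corrected,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rd_map
#' @export
read_rd_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- .read_float_tiff(path, meta$intensity_scale %||% 1)
  rd_map(vals, meta$wavelength_nm, meta$fx_mm1, meta$pixel_pitch_mm,
         calibration_id = meta$calibration_id %||% NA_character_,
         corrected = isTRUE(meta$corrected))
}

# The tiff package stores samples in [0, 1]; values are divided by a scale
# (recorded in the JSON sidecar) before writing, and NA pixels are carried
# as a second 0/1 mask page.
.write_float_tiff <- function(vals, path) {
  scale <- max(1, max(vals, na.rm = TRUE))
  mask <- is.na(vals)
  scaled <- vals / scale
  scaled[mask] <- 0
  pages <- if (any(mask)) list(scaled, 1 - mask * 1) else list(scaled)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  scale
}

.read_float_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  vals <- pages[[1]]
  if (length(dim(vals)) == 3) vals <- vals[, , 1]
  vals <- vals * scale
  if (length(pages) > 1) {
    mask <- pages[[2]]
    if (length(dim(mask)) == 3) mask <- mask[, , 1]
    vals[mask < 0.5] <- NA_real_
  }
  vals
}

#' Write / read a phase stack as three float TIFFs + JSON sidecar
#'
#' `write_phase_stack` writes `<prefix>_phase{0,120,240}.tif` and
#' `<prefix>.json`; `read_phase_stack` reads them back.
#'
#' @param stack a [phase_stack()].
#' @param prefix file prefix (no extension).
#' @return The prefix (write, invisibly) or the `phase_stack` (read).
#' @export
write_phase_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "phase_stack"))
  scales <- vapply(c(0, 120, 240), function(p) {
    img <- switch(as.character(p), "0" = stack$i1, "120" = stack$i2, "240" = stack$i3)
    .write_float_tiff(img, sprintf("%s_phase%d.tif", prefix, p))
  }, numeric(1))
  meta <- list(wavelength_nm = stack$wavelength,
               fx_mm1 = stack$spatial_frequency,
               phases_deg = c(0, 120, 240),
               pixel_pitch_mm = stack$pixel_pitch,
               intensity_scales = scales)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_phase_stack
#' @export
read_phase_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  scales <- meta$intensity_scales %||% c(1, 1, 1)
  imgs <- lapply(1:3, function(i)
    .read_float_tiff(sprintf("%s_phase%d.tif", prefix, c(0, 120, 240)[i]),
                     scales[i]))
  phase_stack(imgs[[1]], imgs[[2]], imgs[[3]],
              wavelength = meta$wavelength_nm,
              spatial_frequency = meta$fx_mm1,
              pixel_pitch = meta$pixel_pitch_mm)
}
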
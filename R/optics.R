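#' Optical configuration of the simulated holographic cytometer
#'
#' Bundles the wavelength, camera sampling and off-axis carrier used
#' throughout the simulation and reconstruction chain. The effective
#' object-plane pixel pitch is `pixel_pitch_camera / magnification`
#' (0.125 um/px with the defaults, i.e. a 4.5 um camera pixel demagnified
#' 36x).
#'
#' @param wavelength Illumination wavelength in micrometres (default 0.532).
#' @param pixel_pitch_camera Camera pixel size in micrometres (default 4.5).
#' @param magnification Lateral magnification of the imaging system
#'   (default 36).
#' @param qpm_size Side length of a quantitative phase map in pixels
#'   (default 200).
#' @param hologram_size Side length of the digital hologram grid in pixels
#'   (default 1024).
#' @param carrier_freq Off-axis carrier frequency, length-2 numeric in
#'   cycles/pixel along x and y (default `c(0.25, 0.25)`). Must stay below
#'   the Nyquist limit of 0.5 cycles/pixel in modulus per axis.
#'
#' @return An object of class `optics_config`.
#' @export
#' @examples
#' opt <- optics_config()
#' opt$pitch  # 0.125 um/px at the object plane
optics_config <- function(wavelength = 0.532,
                          pixel_pitch_camera = 4.5,
                          magnification = 36,
                          qpm_size = 200L,
                          hologram_size = 1024L,
                          carrier_freq = c(0.25, 0.25)) {
  stopifnot(wavelength > 0, pixel_pitch_camera > 0, magnification > 0,
            qpm_size >= 16, hologram_size >= qpm_size,
            length(carrier_freq) == 2)
  if (any(abs(carrier_freq) >= 0.5)) {
    stop("off-axis carrier frequency must be below Nyquist (0.5 cycles/px)")
  }
  structure(list(
    wavelength = wavelength,
    pixel_pitch_camera = pixel_pitch_camera,
    magnification = magnification,
    pitch = pixel_pitch_camera / magnification,
    qpm_size = as.integer(qpm_size),
    hologram_size = as.integer(hologram_size),
    carrier_freq = carrier_freq
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  wavelength    : %.4g um\n", x$wavelength))
  cat(sprintf("  object pitch  : %.4g um/px (%.3g um camera px / %gx)\n",
              x$pitch, x$pixel_pitch_camera, x$magnification))
  cat(sprintf("  QPM grid      : %d x %d px\n", x$qpm_size, x$qpm_size))
  cat(sprintf("  hologram grid : %d x %d px, carrier (%.3g, %.3g) cyc/px\n",
              x$hologram_size, x$hologram_size,
              x$carrier_freq[1], x$carrier_freq[2]))
  invisible(x)
}

#' Quantitative phase map container
#'
#' A QPM holds per-pixel optical phase delays in radians,
#' `phi(x, y) = (2 * pi / lambda) * OPL(x, y)` with
#' `OPL = integral of (n - n0) dz`, together with the object-plane pixel
#' pitch. Background pixels (outside any cell) are ~0 after aberration
#' compensation.
#'
#' @param phase Numeric matrix of phase values in radians.
#' @param pitch Object-plane pixel pitch in micrometres.
#' @param id Optional provenance identifier (e.g. "cell003/frame12").
#'
#' @return An object of class `qpm_image`.
#' @export
qpm_image <- function(phase, pitch, id = NA_character_) {
  stopifnot(is.matrix(phase), all(is.finite(phase)), pitch > 0)
  structure(list(phase = phase, pitch = pitch, id = id), class = "qpm_image")
}

#' @export
print.qpm_image <- function(x, ...) {
  cat(sprintf("<qpm_image> %dx%d px @ %.4g um/px, phase range [%.3g, %.3g] rad",
              nrow(x$phase), ncol(x$phase), x$pitch,
              min(x$phase), max(x$phase)))
  if (!is.na(x$id)) cat(sprintf("  (%s)", x$id))
  cat("\n")
  invisible(x)
}

#' @export
dim.qpm_image <- function(x) dim(x$phase)
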
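#' Reconstruction configuration
#'
#' Parameters of the numerical hologram-to-QPM chain: carrier localisation,
#' Fourier filtering, refocusing search and optional pre-unwrap denoising.
#'
#' @param carrier `"auto"` to locate the off-axis carrier as the strongest
#'   spectral peak outside the DC exclusion zone, or a length-2 numeric of
#'   carrier frequencies in cycles/pixel.
#' @param filter_radius Radius of the circular Fourier mask in cycles/pixel;
#'   `NULL` (default) uses half the carrier-to-DC distance.
#' @param z_range Refocusing search interval `c(z_min, z_max)` in
#'   micrometres, or `NULL` to skip autofocus.
#' @param z_step Step of the focus search grid in micrometres.
#' @param denoise One of `"none"` (default), `"median"`, `"gaussian"`;
#'   filter applied to the wrapped phase before unwrapping.
#' @param denoise_size Median window size in px, or Gaussian sigma.
#'
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(carrier = "auto", filter_radius = NULL,
                         z_range = NULL, z_step = 5,
                         denoise = c("none", "median", "gaussian"),
                         denoise_size = 3) {
  denoise <- match.arg(denoise)
  if (!identical(carrier, "auto")) {
    stopifnot(is.numeric(carrier), length(carrier) == 2)
  }
  if (!is.null(filter_radius) && filter_radius <= 0) {
    stop("filter_radius must be > 0")
  }
  if (!is.null(z_range)) {
    stopifnot(length(z_range) == 2, z_range[1] < z_range[2], z_step > 0)
  }
  structure(list(carrier = carrier, filter_radius = filter_radius,
                 z_range = z_range, z_step = z_step,
                 denoise = denoise, denoise_size = denoise_size),
            class = "recon_config")
}

#' Complex optical field container
#'
#' @param field Complex matrix (2D complex amplitude).
#' @param pitch Pixel pitch in micrometres.
#' @param wavelength Wavelength in micrometres.
#' @param z Current propagation offset in micrometres.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(field, pitch, wavelength, z = 0) {
  stopifnot(is.matrix(field), is.complex(field) || is.numeric(field),
            all(is.finite(Re(field))), all(is.finite(Im(field))), pitch > 0,
            wavelength > 0)
  structure(list(field = as.matrix(field) + 0i, pitch = pitch,
                 wavelength = wavelength, z = z),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %dx%d px @ %.4g um/px, lambda %.4g um, z = %.3g um\n",
              nrow(x$field), ncol(x$field), x$pitch, x$wavelength, x$z))
  invisible(x)
}

# centred FFT frequency grid in cycles/px for side n
.fftfreq <- function(n) {
  f <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / n
  f
}

#' Demodulate an off-axis hologram
#'
#' Isolates the real (+1) diffraction order in the Fourier spectrum with a
#' circular hard mask, re-centres it on the carrier (removing the fringe
#' tilt) and inverse-transforms back to a complex field. With automatic
#' carrier detection, the order in the `fy < 0` half-plane is selected,
#' which with the [encode_hologram()] reference convention yields a
#' positive phase for `n > n0`.
#'
#' @param hologram Real hologram matrix, e.g. from [encode_hologram()];
#'   attributes `pitch` and `wavelength` are honoured if present.
#' @param cfg A [recon_config()].
#' @param pitch,wavelength Overrides used when the hologram carries no
#'   attributes.
#'
#' @return A [complex_field()].
#' @export
demodulate <- function(hologram, cfg = recon_config(),
                       pitch = attr(hologram, "pitch"),
                       wavelength = attr(hologram, "wavelength")) {
  stopifnot(is.matrix(hologram), is.numeric(hologram))
  if (is.null(pitch) || is.null(wavelength)) {
    stop("pitch and wavelength must be supplied (or present as attributes)")
  }
  n <- nrow(hologram); m <- ncol(hologram)
  FT <- stats::fft(hologram)
  fx <- matrix(.fftfreq(n), n, m)
  fy <- matrix(.fftfreq(m), n, m, byrow = TRUE)
  fr <- sqrt(fx^2 + fy^2)

  if (identical(cfg$carrier, "auto")) {
    cand <- fr > 0.08 & fy < 0               # outside DC zone, one half-plane
    mag <- Mod(FT)
    peak_val <- max(mag[cand])
    if (peak_val < 1e-6 * mag[1, 1]) {
      stop("not off-axis: no carrier peak found outside the DC zone")
    }
    idx <- which(cand & mag == peak_val, arr.ind = TRUE)[1, ]
  } else {
    idx <- c(which.min(abs(.fftfreq(n) - cfg$carrier[1])),
             which.min(abs(.fftfreq(m) - cfg$carrier[2])))
  }
  f_carrier <- c(fx[idx[1], idx[2]], fy[idx[1], idx[2]])
  d_carrier <- sqrt(sum(f_carrier^2))
  if (d_carrier < 1e-9) stop("not off-axis: carrier coincides with DC")

  r_filt <- if (is.null(cfg$filter_radius)) d_carrier / 2 else cfg$filter_radius
  mask <- sqrt((fx - f_carrier[1])^2 + (fy - f_carrier[2])^2) <= r_filt
  FTf <- FT * mask
  # circularly shift so the carrier bin lands on DC
  FTs <- .circshift(FTf, -(idx - 1L))
  field <- stats::fft(FTs, inverse = TRUE) / length(FTs)
  complex_field(field, pitch, wavelength)
}

.circshift <- function(x, shift) {
  n <- nrow(x); m <- ncol(x)
  i <- ((seq_len(n) - 1L - shift[1]) %% n) + 1L
  j <- ((seq_len(m) - 1L - shift[2]) %% m) + 1L
  x[i, j, drop = FALSE]
}

#' Angular-spectrum propagation
#'
#' Propagates a complex field over a distance `z` with the exact scalar
#' transfer function `exp(i * z * sqrt(k^2 - kx^2 - ky^2))`; evanescent
#' components are zeroed. The operation is unitary on the propagating band,
#' so the field energy is conserved.
#'
#' @param field A [complex_field()].
#' @param z Propagation distance in micrometres (signed).
#' @return The propagated [complex_field()] with its `z` offset updated.
#' @export
propagate <- function(field, z) {
  stopifnot(inherits(field, "complex_field"), is.finite(z))
  if (z == 0) return(field)
  n <- nrow(field$field); m <- ncol(field$field)
  k <- 2 * pi / field$wavelength
  kx <- matrix(2 * pi * .fftfreq(n) / field$pitch, n, m)
  ky <- matrix(2 * pi * .fftfreq(m) / field$pitch, n, m, byrow = TRUE)
  kz2 <- k^2 - kx^2 - ky^2
  H <- ifelse(kz2 > 0, exp(1i * z * sqrt(pmax(kz2, 0))), 0 + 0i)
  out <- stats::fft(stats::fft(field$field) * H, inverse = TRUE) /
    (n * m)
  complex_field(out, field$pitch, field$wavelength, z = field$z + z)
}

#' Tamura coefficient of an intensity image
#'
#' `TC = sqrt(sd(I) / mean(I))` with the population standard deviation.
#' For a pure phase object the amplitude contrast — hence the Tamura
#' coefficient of the amplitude image — is minimal at focus.
#'
#' @param image Non-negative numeric matrix with positive mean.
#' @return The Tamura coefficient (scalar).
#' @export
tamura <- function(image) {
  stopifnot(is.numeric(image))
  mu <- mean(image)
  if (!(mu > 0)) stop("tamura: image mean must be > 0")
  sdev <- sqrt(mean((image - mu)^2))
  sqrt(sdev / mu)
}

#' Autofocus by Tamura-coefficient minimisation
#'
#' Propagates the field over a grid of candidate distances and returns the
#' one minimising the Tamura coefficient of the amplitude image. Exact ties
#' are broken in favour of the smallest `|z|` (least refocusing).
#'
#' @param field A [complex_field()].
#' @param cfg A [recon_config()] supplying `z_range` and `z_step`, or `NULL`
#'   to pass `z_grid` directly.
#' @param z_grid Optional explicit vector of candidate distances (um).
#' @return The best-focus distance `z_best` in micrometres.
#' @export
autofocus <- function(field, cfg = NULL, z_grid = NULL) {
  if (is.null(z_grid)) {
    if (is.null(cfg) || is.null(cfg$z_range)) stop("no focus search grid given")
    z_grid <- seq(cfg$z_range[1], cfg$z_range[2], by = cfg$z_step)
  }
  if (!length(z_grid)) stop("focus search grid is empty")
  tc <- vapply(z_grid, function(z) tamura(Mod(propagate(field, z)$field)),
               numeric(1))
  best <- which(tc == min(tc))
  if (length(best) > 1L) best <- best[which.min(abs(z_grid[best]))]
  z_grid[best]
}

#' Reference-field aberration compensation
#'
#' Subtracts the phase of a reference field (reconstructed from a hologram
#' recorded without samples) from the object field, removing the residual
#' carrier tilt and static optical aberrations. The output phase is the
#' wrapped difference `arg(field) - arg(reference)`.
#'
#' @param field,reference [complex_field()] objects of identical shape.
#' @return The compensated [complex_field()].
#' @export
compensate <- function(field, reference) {
  stopifnot(inherits(field, "complex_field"), inherits(reference, "complex_field"))
  if (!identical(dim(field$field), dim(reference$field))) {
    stop("field and reference have different shapes")
  }
  ph <- Arg(reference$field)
  complex_field(field$field * exp(-1i * ph), field$pitch, field$wavelength,
                z = field$z)
}

#' Two-dimensional phase unwrapping
#'
#' Quality-guided unwrapping by reliability sorting with region merging.
#' The returned map differs from the wrapped input by an exact integer
#' multiple of `2*pi` at every pixel; smooth phase fields are recovered up
#' to a global `2*pi*k` offset.
#'
#' @param wrapped Numeric matrix of wrapped phase values in `(-pi, pi]`.
#' @return Numeric matrix of unwrapped phase values.
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped), all(is.finite(wrapped)))
  .unwrap2d_cpp(wrapped)
}

#' Full hologram-to-QPM reconstruction
#'
#' Runs the complete numerical chain: Fourier demodulation, optional
#' Tamura autofocus and angular-spectrum refocusing, reference-hologram
#' compensation, optional wrapped-phase denoising, quality-guided
#' unwrapping, and background zeroing (median of a border ring subtracted,
#' rounded to the nearest `2*pi*k` plus residual offset).
#'
#' @param hologram Real hologram matrix from [encode_hologram()] or read
#'   from disk (attributes `pitch`, `wavelength`, `qpm_size` honoured).
#' @param cfg A [recon_config()].
#' @param reference Optional reference hologram (no sample). When `NULL`, a
#'   synthetic flat reference with the same carrier is generated internally.
#' @param crop Side length of the central crop returned (defaults to the
#'   `qpm_size` attribute, else the full grid).
#'
#' @return A [qpm_image()].
#' @export
reconstruct_qpm <- function(hologram, cfg = recon_config(), reference = NULL,
                            crop = attr(hologram, "qpm_size")) {
  fld <- demodulate(hologram, cfg)
  if (!is.null(cfg$z_range)) {
    zb <- autofocus(fld, cfg)
    fld <- propagate(fld, zb)
  }
  if (!is.null(reference)) {
    ref <- demodulate(reference, cfg,
                      pitch = fld$pitch, wavelength = fld$wavelength)
    if (!is.null(cfg$z_range)) ref <- propagate(ref, fld$z)
    fld <- compensate(fld, ref)
  }
  wrapped <- Arg(fld$field)
  if (cfg$denoise == "median") {
    rng <- range(wrapped)
    if (diff(rng) > 0) {
      norm <- (wrapped - rng[1]) / diff(rng)
      wrapped <- EBImage::medianFilter(norm, cfg$denoise_size) * diff(rng) + rng[1]
    }
  } else if (cfg$denoise == "gaussian") {
    wrapped <- EBImage::gblur(wrapped, sigma = cfg$denoise_size)
  }
  unwrapped <- unwrap_phase(wrapped)
  n <- nrow(unwrapped)
  if (!is.null(crop) && crop < n) {
    off <- floor((n - crop) / 2)
    unwrapped <- unwrapped[off + seq_len(crop), off + seq_len(crop)]
  }
  # background zeroing from a border ring (cell assumed centred)
  bw <- max(3L, round(nrow(unwrapped) * 0.05))
  idx <- seq_len(nrow(unwrapped))
  ring <- idx <= bw | idx > nrow(unwrapped) - bw
  bg <- stats::median(c(unwrapped[ring, ], unwrapped[!ring, ring]))
  qpm_image(unwrapped - bg, fld$pitch, id = "reconstructed")
}
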
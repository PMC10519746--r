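#' Draw a cell phantom from a phenotype specification
#'
#' A phantom is a slightly triaxial ellipsoid of homogeneous refractive-index
#' contrast, decorated with spherical granules of extra contrast and a
#' low-order radial Fourier perturbation of its boundary. All randomness is
#' controlled by `seed`, so the same `(spec, seed)` pair always yields the
#' same phantom. The rotation axis is the in-plane x axis, transverse to both
#' the optical axis and the flow direction, emulating the out-of-plane
#' rolling of a cell in a microfluidic channel.
#'
#' @param spec A [phenotype_spec()].
#' @param seed Integer seed controlling the draw.
#'
#' @return An object of class `cell_phantom` with the sampled semi-axes
#'   (um), cytoplasmic contrast, granule table, boundary perturbation
#'   coefficients and rotation axis.
#' @export
make_phantom <- function(spec, seed) {
  if (!inherits(spec, "phenotype_spec")) stop("'spec' must be a phenotype_spec")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  r <- stats::rnorm(1, spec$radius_mean, spec$radius_sd)
  r <- max(r, 0.5 * spec$radius_mean)
  # mild triaxiality, fixed 5% log-scale jitter per axis
  aspect <- if (spec$radius_sd > 0) exp(stats::rnorm(3, 0, 0.05)) else c(1, 1, 1)
  semi_axes <- r * aspect / prod(aspect)^(1 / 3)  # volume-preserving

  dn <- stats::rnorm(1, spec$delta_n_mean, spec$delta_n_sd)
  dn <- max(dn, 0.25 * spec$delta_n_mean)

  n_gran <- if (spec$granule_count_mean > 0) {
    stats::rpois(1, spec$granule_count_mean)
  } else 0L
  granules <- NULL
  if (n_gran > 0) {
    # rejection-sample granule centres uniformly inside the ellipsoid,
    # shrunk so each granule stays fully inside
    shrink <- pmax(1 - spec$granule_radius / semi_axes, 0.05)
    centers <- matrix(NA_real_, 0, 3)
    while (nrow(centers) < n_gran) {
      p <- matrix(stats::runif(3 * n_gran * 2, -1, 1), ncol = 3)
      keep <- rowSums(p^2) <= 1
      centers <- rbind(centers, sweep(p[keep, , drop = FALSE], 2,
                                      semi_axes * shrink, `*`))
    }
    centers <- centers[seq_len(n_gran), , drop = FALSE]
    granules <- data.frame(cx = centers[, 1], cy = centers[, 2],
                           cz = centers[, 3],
                           radius = spec$granule_radius,
                           delta_n = spec$granule_delta_n)
  }

  rough <- list(amp = numeric(0), phase = numeric(0), order = integer(0))
  if (spec$boundary_roughness > 0) {
    k <- 2:5
    b <- stats::rnorm(length(k))
    rough <- list(order = k,
                  amp = spec$boundary_roughness * b / sqrt(sum(b^2)),
                  phase = stats::runif(length(k), 0, 2 * pi))
  }

  structure(list(
    phenotype = spec$name,
    semi_axes = semi_axes,
    delta_n = dn,
    granules = granules,
    roughness = rough,
    rotation_axis = c(1, 0, 0),
    n_views_range = spec$n_views_range
  ), class = "cell_phantom")
}

#' @export
print.cell_phantom <- function(x, ...) {
  cat(sprintf(
    "<cell_phantom> %s: semi-axes (%.2f, %.2f, %.2f) um, dn=%.4f, %d granules\n",
    x$phenotype, x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$delta_n,
    if (is.null(x$granules)) 0L else nrow(x$granules)))
  invisible(x)
}

# rotation matrix about the phantom's rotation axis (x) by `angle`
.rot_x <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}

#' Project a phantom to a quantitative phase map
#'
#' Computes `phi(x, y) = (2 * pi / lambda) * integral (n - n0) dz` by exact
#' chord integration through the rotated phantom: the ellipsoid body and
#' every granule contribute analytic chord lengths along the optical z axis,
#' scaled by their respective RI contrasts. The boundary perturbation is
#' applied as an azimuthal modulation of the ellipsoid boundary in the
#' phantom frame, so the roughness pattern rotates rigidly with the cell.
#' Background pixels are exactly zero.
#'
#' @param phantom A [make_phantom()] result.
#' @param angle Rotation angle in radians about the phantom's rotation axis.
#' @param optics An [optics_config()].
#'
#' @return A [qpm_image()] of side `optics$qpm_size`.
#' @export
project_qpm <- function(phantom, angle, optics) {
  if (!inherits(phantom, "cell_phantom")) stop("'phantom' must be a cell_phantom")
  if (!inherits(optics, "optics_config")) stop("'optics' must be an optics_config")
  n <- optics$qpm_size
  pitch <- optics$pitch
  half_fov <- n * pitch / 2
  max_r <- max(phantom$semi_axes) * (1 + 2 * max(abs(phantom$roughness$amp), 0))
  if (max_r >= half_fov) {
    stop(sprintf("phantom (max radius %.2f um) exceeds the field of view (+/-%.2f um)",
                 max_r, half_fov))
  }

  # pixel-centre lab coordinates, origin at FOV centre
  coord <- (seq_len(n) - (n + 1) / 2) * pitch
  X <- matrix(coord, n, n)        # rows vary -> x
  Y <- matrix(coord, n, n, byrow = TRUE)

  R <- .rot_x(angle)
  # ellipsoid quadratic form in the lab frame: A_lab = R A R^T
  A <- diag(1 / phantom$semi_axes^2)
  Al <- R %*% A %*% t(R)

  # boundary roughness evaluated on the phantom-frame azimuth of the
  # in-plane viewing direction
  s2 <- 1
  if (length(phantom$roughness$amp)) {
    rho <- sqrt(X^2 + Y^2)
    dir <- cbind(as.vector(X / pmax(rho, 1e-12)),
                 as.vector(Y / pmax(rho, 1e-12)), 0)
    dirp <- dir %*% R  # lab -> phantom frame (R^T applied to row vectors)
    phi_az <- atan2(dirp[, 2], dirp[, 1])
    s <- 1
    for (i in seq_along(phantom$roughness$amp)) {
      s <- s + phantom$roughness$amp[i] *
        cos(phantom$roughness$order[i] * phi_az + phantom$roughness$phase[i])
    }
    s2 <- matrix(s^2, n, n)
  }

  # chord of {p : p^T Al p <= s^2} along z at (x, y)
  q2 <- Al[1, 1] * X^2 + 2 * Al[1, 2] * X * Y + Al[2, 2] * Y^2
  c1 <- Al[1, 3] * X + Al[2, 3] * Y
  disc <- c1^2 - Al[3, 3] * (q2 - s2)
  chord <- ifelse(disc > 0, 2 * sqrt(pmax(disc, 0)) / Al[3, 3], 0)
  opl <- phantom$delta_n * chord

  if (!is.null(phantom$granules) && nrow(phantom$granules) > 0) {
    g <- phantom$granules
    ctr <- as.matrix(g[, c("cx", "cy", "cz")]) %*% t(R)
    for (i in seq_len(nrow(g))) {
      d2 <- (X - ctr[i, 1])^2 + (Y - ctr[i, 2])^2
      inside <- d2 < g$radius[i]^2
      if (any(inside)) {
        opl[inside] <- opl[inside] +
          g$delta_n[i] * 2 * sqrt(g$radius[i]^2 - d2[inside])
      }
    }
  }

  qpm_image(2 * pi / optics$wavelength * opl, pitch,
            id = sprintf("%s@%.3frad", phantom$phenotype, angle))
}

#' Simulate the rolling-cell view sequence of one phantom
#'
#' Projects a phantom at `n_views` monotonically increasing rotation angles
#' about its (transverse) rotation axis, emulating the physical data
#' augmentation of a cell rolling through the microfluidic channel, and
#' optionally adds i.i.d. Gaussian phase noise per frame.
#'
#' @param phantom A [make_phantom()] result.
#' @param n_views Number of views (frames); must be >= 1.
#' @param optics An [optics_config()].
#' @param seed Integer seed (used for the noise draw).
#' @param angle_span Total rotation covered by the sequence in radians
#'   (default `pi`, i.e. half a turn).
#' @param noise_sd Standard deviation of additive Gaussian phase noise in
#'   radians (default 0.02; set 0 for noise-free frames).
#'
#' @return An object of class `cell_sequence`: list with `cell_id`, `class`,
#'   `angles` and `frames` (a list of [qpm_image()]).
#' @export
roll_sequence <- function(phantom, n_views, optics, seed = 1L,
                          angle_span = pi, noise_sd = 0.02) {
  n_views <- as.integer(n_views)
  if (is.na(n_views) || n_views < 1L) stop("n_views must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  angles <- if (n_views == 1L) 0 else seq(0, angle_span, length.out = n_views)
  frames <- vector("list", n_views)
  for (i in seq_len(n_views)) {
    q <- project_qpm(phantom, angles[i], optics)
    if (noise_sd > 0) {
      q$phase <- q$phase + matrix(stats::rnorm(length(q$phase), 0, noise_sd),
                                  nrow(q$phase))
    }
    frames[[i]] <- q
  }
  structure(list(cell_id = NA_character_, class = phantom$phenotype,
                 angles = angles, frames = frames),
            class = "cell_sequence")
}

#' @export
print.cell_sequence <- function(x, ...) {
  cat(sprintf("<cell_sequence> %s (%s): %d frames of %dx%d px\n",
              x$cell_id, x$class, length(x$frames),
              nrow(x$frames[[1]]$phase), ncol(x$frames[[1]]$phase)))
  invisible(x)
}

#' Encode a QPM as an off-axis digital hologram
#'
#' Interferes the object wave `O = a * exp(i * phi)` (the QPM embedded
#' centrally in the hologram grid, zero phase outside) with a tilted plane
#' reference wave `R = r * exp(2i * pi * (fx * x + fy * y))` and records the
#' intensity `H = |O + R|^2`, as an off-axis interferometer camera would.
#'
#' @param qpm A [qpm_image()].
#' @param optics An [optics_config()]; `optics$carrier_freq` sets the fringe
#'   carrier (cycles/px) and `optics$hologram_size` the grid.
#' @param object_amp,reference_amp Amplitudes of the object and reference
#'   waves (default 1 and 1).
#'
#' @return A real, non-negative `hologram_size x hologram_size` matrix with
#'   attributes `pitch`, `wavelength`, `carrier_freq` and `qpm_size`.
#' @export
encode_hologram <- function(qpm, optics, object_amp = 1, reference_amp = 1) {
  stopifnot(inherits(qpm, "qpm_image"), inherits(optics, "optics_config"))
  m <- optics$hologram_size
  nq <- nrow(qpm$phase)
  if (nq > m) stop("QPM does not fit in the hologram grid")
  if (sqrt(sum(optics$carrier_freq^2)) >= sqrt(2) * 0.5 ||
      any(abs(optics$carrier_freq) >= 0.5)) {
    stop("off-axis carrier frequency must be below Nyquist (0.5 cycles/px)")
  }
  phase <- matrix(0, m, m)
  off <- floor((m - nq) / 2)
  phase[off + seq_len(nq), off + seq_len(nq)] <- qpm$phase
  obj <- object_amp * exp(1i * phase)
  x <- matrix(seq_len(m) - 1L, m, m)
  y <- matrix(seq_len(m) - 1L, m, m, byrow = TRUE)
  ref <- reference_amp * exp(2i * pi * (optics$carrier_freq[1] * x +
                                        optics$carrier_freq[2] * y))
  holo <- Mod(obj + ref)^2
  attr(holo, "pitch") <- qpm$pitch
  attr(holo, "wavelength") <- optics$wavelength
  attr(holo, "carrier_freq") <- optics$carrier_freq
  attr(holo, "qpm_size") <- nq
  holo
}

# -- RNG bookkeeping: keep user-visible RNG state untouched -------------------
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
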
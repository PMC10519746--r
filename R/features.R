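#' GLCM configuration
#'
#' @param d Co-occurrence offset in pixels (default 1).
#' @param theta Direction in degrees, `0` (horizontal) or `90` (vertical).
#' @param levels Number of gray levels for quantisation (default 8).
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(d = 1L, theta = 0, levels = 8L) {
  d <- as.integer(d); levels <- as.integer(levels)
  stopifnot(d >= 1L, levels >= 2L, theta %in% c(0, 90))
  structure(list(d = d, theta = theta, levels = levels),
            class = "glcm_config")
}

#' Canonical 37-feature layout
#'
#' Names of the hybrid descriptor, grouped as 11 OPL-based, 9
#' morphology-based, 4 GLCM-based and 13 fractal features.
#'
#' @return A named list of character vectors: `opl`, `morphology`, `glcm`,
#'   `fractal`.
#' @export
feature_groups <- function() {
  list(
    opl = c("opl_mean", "opl_std", "opl_max", "opl_skewness", "opl_entropy",
            "opl_kurtosis", "opl_median", "opl_q1", "opl_q3", "opl_mode",
            "dry_mass"),
    morphology = c("area", "extent", "solidity", "max_diameter",
                   "min_diameter", "circularity", "major_axis",
                   "eccentricity", "norm_centroid_dist"),
    glcm = c("glcm_contrast", "glcm_correlation", "glcm_energy",
             "glcm_homogeneity"),
    fractal = c("fractal_dimension", "lacunarity_index", "fill_ratio",
                "regularity_index", "vertex_density",
                "vertex_lacunarity_index", "vertex_regularity_index",
                "fractal_dimension_contrast", "lacunarity_contrast",
                "vertex_lacunarity_contrast", "fractal_dimension_rmse",
                "lacunarity_rmse", "vertex_lacunarity_rmse")
  )
}

#' Feature names for a feature-set choice
#'
#' @param set One of `"conventional"` (24 features), `"fractal"` (13) or
#'   `"hybrid"` (all 37).
#' @return Character vector of feature names.
#' @export
feature_set <- function(set = c("hybrid", "conventional", "fractal")) {
  set <- match.arg(set)
  g <- feature_groups()
  switch(set,
         conventional = c(g$opl, g$morphology, g$glcm),
         fractal = g$fractal,
         hybrid = unlist(g, use.names = FALSE))
}

#' Optical-path-length statistics and dry mass
#'
#' Eleven features of the phase values over the segmented cell: mean,
#' standard deviation, maximum, skewness, Shannon entropy (base 2, 64-bin
#' histogram), kurtosis, median, first and third quartiles, histogram mode,
#' and the dry mass
#' `m = lambda / (2 * pi * gamma) * sum(phi) * pitch^2` in picograms
#' (`gamma` = 0.2 ml/g = 0.2 um^3/pg is the refractive increment).
#'
#' @param qpm A [qpm_image()] or phase matrix.
#' @param support Logical support matrix.
#' @param pitch Pixel pitch in um (taken from `qpm` when available).
#' @param wavelength Wavelength in um (default 0.532).
#' @param gamma Refractive increment in ml/g (default 0.2).
#' @return Named numeric vector of 11 features.
#' @export
opl_features <- function(qpm, support, pitch = NULL, wavelength = 0.532,
                         gamma = 0.2) {
  phase <- if (inherits(qpm, "qpm_image")) qpm$phase else qpm
  if (is.null(pitch)) pitch <- if (inherits(qpm, "qpm_image")) qpm$pitch else
    stop("pitch required when 'qpm' is a bare matrix")
  v <- phase[support]
  if (!length(v)) stop("opl_features: empty support")
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sk <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  rng <- range(v)
  if (diff(rng) > 0) {
    h <- tabulate(pmin(
      floor((v - rng[1]) / diff(rng) * 64) + 1L, 64L), 64L)
    p <- h[h > 0] / n
    entropy <- -sum(p * log2(p))
    mode_val <- rng[1] + (which.max(h) - 0.5) / 64 * diff(rng)
  } else {
    entropy <- 0
    mode_val <- mu
  }
  dry_mass <- wavelength / (2 * pi * gamma) * sum(v) * pitch^2
  c(opl_mean = mu, opl_std = stats::sd(v), opl_max = max(v),
    opl_skewness = sk, opl_entropy = entropy, opl_kurtosis = ku,
    opl_median = qs[2], opl_q1 = qs[1], opl_q3 = qs[3],
    opl_mode = mode_val, dry_mass = dry_mass)
}

# ordered outer contour of a mask, Kulpa-corrected chain-code perimeter
.perimeter <- function(support) {
  oc <- EBImage::ocontour(EBImage::Image(support * 1))
  if (!length(oc)) return(NA_real_)
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  step <- abs(d[, 1]) + abs(d[, 2])
  # Kulpa's corrected estimator for 8-connected chain codes
  0.948 * sum(step == 1) + 1.340 * sum(step == 2)
}

# convex-hull pixel count: rasterised point-in-convex-polygon
.hull_area_px <- function(pts, hull) {
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) return(nrow(pts))
  rr <- seq(min(pts[, 1]), max(pts[, 1]))
  cc <- seq(min(pts[, 2]), max(pts[, 2]))
  gx <- rep(rr, times = length(cc))
  gy <- rep(cc, each = length(rr))
  inside <- rep(TRUE, length(gx))
  for (i in seq_len(nh)) {
    a <- hp[i, ]; b <- hp[if (i == nh) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
    # chull returns clockwise order; allow boundary (tolerance for collinear)
    inside <- inside & cross <= 1e-9
    if (!any(inside)) break
  }
  sum(inside)
}

#' Morphological features of the segmented cell
#'
#' Nine descriptors of the binary support: area, extent (area over bounding
#' box), solidity (area over convex-hull area), maximum and minimum
#' diameters (convex-hull Feret diameters), circularity
#' `C = 4 * pi * A / P^2` (perimeter via Kulpa-corrected chain code),
#' major-axis length and eccentricity of the equivalent
#' (same-second-moments) ellipse, and the distance between the binary and
#' phase-weighted centroids normalised to the equivalent radius
#' `sqrt(A / pi)`.
#'
#' @param support Logical support matrix.
#' @param pitch Pixel pitch in micrometres.
#' @param phase Optional phase matrix for the weighted centroid (zero
#'   distance is reported when absent).
#' @return Named numeric vector of 9 features (areas in um^2, lengths in
#'   um).
#' @export
morphology_features <- function(support, pitch, phase = NULL) {
  stopifnot(is.matrix(support))
  pts <- which(.as_binary(support), arr.ind = TRUE)
  npix <- nrow(pts)
  if (npix < 4L) stop("morphology_features: degenerate support")
  area_px <- npix
  bbox <- (diff(range(pts[, 1])) + 1) * (diff(range(pts[, 2])) + 1)
  extent <- area_px / bbox

  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hull_px <- .hull_area_px(pts, hull)
  solidity <- min(area_px / hull_px, 1)

  hp <- pts[hull, , drop = FALSE]
  dd <- as.matrix(stats::dist(hp))
  max_diam <- max(dd)
  # width of the convex polygon: min over hull edges of the farthest vertex
  nh <- nrow(hp)
  min_diam <- max_diam
  if (nh >= 3) {
    for (i in seq_len(nh)) {
      a <- hp[i, ]; b <- hp[if (i == nh) 1 else i + 1, ]
      e <- b - a
      len <- sqrt(sum(e^2))
      if (len < 1e-12) next
      dist_to_edge <- abs((hp[, 1] - a[1]) * e[2] - (hp[, 2] - a[2]) * e[1]) / len
      min_diam <- min(min_diam, max(dist_to_edge))
    }
  }

  P <- .perimeter(support)
  circ <- 4 * pi * area_px / P^2

  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  cov <- crossprod(cpts) / npix + diag(2) / 12  # pixel-extent correction
  ev <- eigen(cov, symmetric = TRUE)$values
  major_axis <- 4 * sqrt(ev[1])
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))

  ncd <- 0
  if (!is.null(phase)) {
    w <- phase[.as_binary(support)]
    if (sum(w) > 0) {
      wctr <- colSums(pts * w) / sum(w)
      ncd <- sqrt(sum((wctr - ctr)^2)) / sqrt(area_px / pi)
    }
  }

  c(area = area_px * pitch^2, extent = extent, solidity = solidity,
    max_diameter = max_diam * pitch, min_diameter = min_diam * pitch,
    circularity = circ, major_axis = major_axis * pitch,
    eccentricity = ecc, norm_centroid_dist = ncd)
}

#' GLCM texture features
#'
#' Quantises the phase values inside the support to `cfg$levels` gray
#' levels over the support-restricted range, accumulates co-occurrences at
#' offset `d` along direction `theta` (pairs with either pixel outside the
#' support are excluded), symmetrises and normalises the matrix, and
#' returns the standard contrast, correlation, energy and homogeneity.
#' A constant image has no defined correlation; 1 is returned by
#' convention.
#'
#' @param qpm A [qpm_image()] or phase matrix.
#' @param support Logical support matrix.
#' @param cfg A [glcm_config()].
#' @return Named numeric vector of 4 features.
#' @export
glcm_features <- function(qpm, support, cfg = glcm_config()) {
  phase <- if (inherits(qpm, "qpm_image")) qpm$phase else qpm
  sup <- .as_binary(support)
  v <- phase[sup]
  rng <- range(v)
  L <- cfg$levels
  if (!(diff(rng) > 0)) {
    return(c(glcm_contrast = 0, glcm_correlation = 1, glcm_energy = 1,
             glcm_homogeneity = 1))
  }
  q <- matrix(NA_integer_, nrow(phase), ncol(phase))
  q[sup] <- pmin(floor((phase[sup] - rng[1]) / diff(rng) * L) + 1L, L)

  if (cfg$theta == 0) {
    a <- q[, seq_len(ncol(q) - cfg$d), drop = FALSE]
    b <- q[, (cfg$d + 1):ncol(q), drop = FALSE]
  } else {
    a <- q[seq_len(nrow(q) - cfg$d), , drop = FALSE]
    b <- q[(cfg$d + 1):nrow(q), , drop = FALSE]
  }
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop("glcm_features: fewer than 2 valid pixel pairs")
  G <- matrix(0, L, L)
  tab <- table(factor(a[ok], levels = seq_len(L)),
               factor(b[ok], levels = seq_len(L)))
  G <- unclass(tab) + t(unclass(tab))     # symmetrise
  p <- G / sum(G)

  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p))
  s_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (s_i > 0 && s_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  } else 1
  c(glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = corr,
    glcm_energy = sum(p^2),
    glcm_homogeneity = sum(p / (1 + abs(i - j))))
}

#' Fractal-geometry features from the support and hole-support maps
#'
#' Thirteen features built from dyadic box counting and gliding-box
#' lacunarity of the two binary maps in a [pad_and_maps()] result.
#' Support-map quantities: fractal dimension, lacunarity index, fill ratio
#' (support area over its bounding-box area), regularity index (R^2 of the
#' box-count fit), and the RMSEs of the box-count and lacunarity fits.
#' Hole-map ("vertex") quantities: vertex density (hole over support pixel
#' counts), vertex lacunarity index, vertex regularity index and vertex
#' lacunarity RMSE. Contrasts: normalised differences
#' `(X_support - X_hole) / (X_support + X_hole)` for the fractal dimension
#' and the lacunarity index, and the fine-vs-coarse scale contrast of the
#' hole-map lacunarity. An empty hole map yields zero vertex features and
#' guarded contrasts.
#'
#' @param maps A `support_maps` object from [pad_and_maps()].
#' @param scales Box/window sizes (default `2^(0:7)`).
#' @return Named numeric vector of 13 features.
#' @export
fractal_features <- function(maps, scales = 2^(0:7)) {
  stopifnot(inherits(maps, "support_maps"))
  sup <- maps$support
  hole <- maps$hole_support
  if (!any(sup)) stop("fractal_features: empty support")

  bc_s <- box_count(sup, scales)
  fit_s <- fractal_fit(bc_s$s, bc_s$n_boxes)
  lac_s <- lacunarity(sup, scales)

  pts <- which(sup, arr.ind = TRUE)
  bbox <- (diff(range(pts[, 1])) + 1) * (diff(range(pts[, 2])) + 1)
  fill_ratio <- sum(sup) / bbox

  ratio0 <- function(num, den) if (abs(den) > 1e-12) num / den else 0

  if (any(hole)) {
    bc_h <- box_count(hole, scales)
    fit_h <- fractal_fit(bc_h$s, bc_h$n_boxes)
    lac_h <- lacunarity(hole, scales)
    vdens <- sum(hole) / sum(sup)
    lam <- log(lac_h$per_scale$lambda)
    sc <- lac_h$per_scale$s
    fine <- mean(lam[sc <= stats::median(scales)])
    coarse <- mean(lam[sc > stats::median(scales)])
    if (!is.finite(coarse)) coarse <- 0
    vlc <- ratio0(fine - coarse, fine + coarse)
    fdc <- ratio0(fit_s$dimension - fit_h$dimension,
                  fit_s$dimension + fit_h$dimension)
    lc <- ratio0(lac_s$index - lac_h$index, lac_s$index + lac_h$index)
    vli <- lac_h$index; vri <- fit_h$r_squared; vlr <- lac_h$rmse
  } else {
    warning("fractal_features: empty hole-support map; vertex features set to 0")
    vdens <- 0; vli <- 0; vri <- 0; vlr <- 0; vlc <- 0
    fdc <- ratio0(fit_s$dimension, fit_s$dimension)
    lc <- ratio0(lac_s$index, lac_s$index)
  }

  c(fractal_dimension = fit_s$dimension,
    lacunarity_index = lac_s$index,
    fill_ratio = fill_ratio,
    regularity_index = fit_s$r_squared,
    vertex_density = vdens,
    vertex_lacunarity_index = vli,
    vertex_regularity_index = vri,
    fractal_dimension_contrast = fdc,
    lacunarity_contrast = lc,
    vertex_lacunarity_contrast = vlc,
    fractal_dimension_rmse = fit_s$rmse,
    lacunarity_rmse = lac_s$rmse,
    vertex_lacunarity_rmse = vlr)
}

#' Extract the full 37-feature descriptor of a QPM
#'
#' Segments the cell, pads to 256 x 256, derives the support and
#' hole-support maps and concatenates the four feature groups into the
#' canonical 37-element vector (see [feature_groups()]). Extraction is
#' deterministic: identical inputs give bit-identical vectors.
#'
#' @param qpm A [qpm_image()].
#' @param glcm A [glcm_config()].
#' @param wavelength,gamma Dry-mass constants (um; ml/g).
#' @return Named numeric vector of 37 finite values.
#' @export
extract_features <- function(qpm, glcm = glcm_config(), wavelength = 0.532,
                             gamma = 0.2) {
  stopifnot(inherits(qpm, "qpm_image"))
  support <- segment_qpm(qpm)
  maps <- pad_and_maps(qpm, support)
  out <- c(
    opl_features(qpm, support, wavelength = wavelength, gamma = gamma),
    morphology_features(support, qpm$pitch, phase = qpm$phase),
    glcm_features(qpm, support, glcm),
    suppressWarnings(fractal_features(maps))
  )
  stopifnot(length(out) == 37L, all(is.finite(out)))
  out
}

#' Extract features for a batch of cell sequences
#'
#' @param sequences A list of `cell_sequence` objects (see
#'   [roll_sequence()]).
#' @param ... Passed to [extract_features()].
#' @return A data.frame with columns `cell_id`, `class`, `frame` and the 37
#'   feature columns.
#' @export
extract_features_batch <- function(sequences, ...) {
  rows <- lapply(sequences, function(sq) {
    feats <- lapply(seq_along(sq$frames), function(i) {
      extract_features(sq$frames[[i]], ...)
    })
    cbind(data.frame(cell_id = sq$cell_id, class = sq$class,
                     frame = seq_along(sq$frames)),
          as.data.frame(do.call(rbind, feats)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
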
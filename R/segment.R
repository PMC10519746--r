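#' Segment the cell in a quantitative phase map
#'
#' Thresholds the phase map at a fraction of its maximum (with a noise
#' floor of five background median absolute deviations), then applies
#' morphological closing (disc of radius 2 px), hole filling, and keeps
#' the largest connected component. A compensated QPM has near-zero
#' background and positive phase over the cell, and its phase falls
#' smoothly to zero at the cell rim, so a low global threshold recovers
#' the support with little rim loss while staying above the noise.
#'
#' @param qpm A [qpm_image()] or a numeric phase matrix.
#' @param fraction Threshold as a fraction of the phase maximum
#'   (default 0.1).
#' @return A logical matrix (the binary support, native QPM size).
#' @export
segment_qpm <- function(qpm, fraction = 0.1) {
  phase <- if (inherits(qpm, "qpm_image")) qpm$phase else qpm
  stopifnot(is.matrix(phase))
  rng <- range(phase)
  if (!(diff(rng) > 0)) stop("no cell: QPM is constant")
  th <- max(fraction * rng[2], 5 * stats::mad(phase, center = 0))
  if (!(rng[2] > th)) stop("no cell: no phase above the noise floor")
  mask <- EBImage::Image(phase > th)
  mask <- EBImage::closing(mask, EBImage::makeBrush(5, "disc"))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(as.integer(EBImage::imageData(lab)))
  if (!length(counts) || max(counts) == 0) stop("no cell: empty segmentation")
  keep <- which.max(counts)
  support <- EBImage::imageData(lab) == keep
  if (sum(support) < 4L) stop("no cell: segmented support is degenerate")
  matrix(as.logical(support), nrow(phase), ncol(phase))
}

#' Zero-pad a QPM and derive the support and hole-support maps
#'
#' Pads the QPM (and its binary support) centrally with zeros to a
#' `target` x `target` grid (256 by default, a power of two as required by
#' the dyadic box-counting scales), then computes the hole-support map: the
#' gradient magnitude of the padded QPM (central differences), normalised
#' to its maximum, thresholded at `grad_threshold`.
#'
#' @param qpm A [qpm_image()] or phase matrix (side length must not exceed
#'   `target`).
#' @param support Binary support from [segment_qpm()]; computed on the fly
#'   when `NULL`.
#' @param target Padded side length (default 256).
#' @param grad_threshold Threshold on the normalised gradient magnitude
#'   (default 0.3).
#'
#' @return A list of class `support_maps` with elements `qpm` (padded
#'   phase), `support`, `hole_support` (logical matrices), and
#'   `grad_threshold`.
#' @export
pad_and_maps <- function(qpm, support = NULL, target = 256L,
                         grad_threshold = 0.3) {
  phase <- if (inherits(qpm, "qpm_image")) qpm$phase else qpm
  stopifnot(is.matrix(phase))
  n <- nrow(phase); m <- ncol(phase)
  if (n > target || m > target) {
    stop(sprintf("QPM (%dx%d) larger than padded target (%d)", n, m, target))
  }
  if (is.null(support)) support <- segment_qpm(phase)
  stopifnot(identical(dim(support), dim(phase)))

  pad <- function(x, fill) {
    out <- matrix(fill, target, target)
    oi <- floor((target - n) / 2); oj <- floor((target - m) / 2)
    out[oi + seq_len(n), oj + seq_len(m)] <- x
    out
  }
  qp <- pad(phase, 0)
  sp <- pad(support, FALSE)

  gx <- matrix(0, target, target)
  gy <- matrix(0, target, target)
  gx[2:(target - 1), ] <- (qp[3:target, ] - qp[1:(target - 2), ]) / 2
  gy[, 2:(target - 1)] <- (qp[, 3:target] - qp[, 1:(target - 2)]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  gmax <- max(gmag)
  hole <- if (gmax > 0) gmag / gmax > grad_threshold
          else matrix(FALSE, target, target)

  structure(list(qpm = qp, support = sp, hole_support = hole,
                 grad_threshold = grad_threshold),
            class = "support_maps")
}
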
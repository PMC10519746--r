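#' Box counting of a binary pattern
#'
#' Partitions the grid into `s` x `s` boxes (anchored at the top-left;
#' ragged edge boxes are kept) and counts, for every scale, the boxes that
#' contain at least one foreground pixel. `N(s)` is non-increasing in `s`.
#'
#' @param binary Logical (or 0/1) matrix; must contain foreground.
#' @param scales Integer vector of box sizes in pixels (default the dyadic
#'   scales `2^(0:7)` natural for a 256-px grid).
#' @return A data.frame with columns `s` and `n_boxes`.
#' @export
box_count <- function(binary, scales = 2^(0:7)) {
  b <- .as_binary(binary)
  if (!any(b)) stop("box_count: empty binary map")
  scales <- as.integer(scales)
  stopifnot(all(scales >= 1), all(scales <= min(dim(b))))
  sat <- .sat(b)
  n <- nrow(b); m <- ncol(b)
  counts <- vapply(scales, function(s) {
    ri <- unique(c(seq(0L, n, by = s), n))
    ci <- unique(c(seq(0L, m, by = s), m))
    sums <- sat[ri[-1] + 1L, ci[-1] + 1L, drop = FALSE] -
            sat[ri[-1] + 1L, ci[-length(ci)] + 1L, drop = FALSE] -
            sat[ri[-length(ri)] + 1L, ci[-1] + 1L, drop = FALSE] +
            sat[ri[-length(ri)] + 1L, ci[-length(ci)] + 1L, drop = FALSE]
    sum(sums > 0)
  }, numeric(1))
  data.frame(s = scales, n_boxes = counts)
}

# summed-area table with a zero first row/column
.sat <- function(b) {
  s <- apply(apply(b, 2, cumsum), 1, cumsum)  # t(cumsum rows) -> transpose back
  s <- t(s)
  rbind(0, cbind(0, s))
}

.as_binary <- function(x) {
  stopifnot(is.matrix(x))
  if (is.logical(x)) x else x != 0
}

#' Fractal (box-counting) dimension from box counts
#'
#' Least-squares line through `(log(1/s), log N(s))`. The slope estimates
#' the box-counting dimension; the coefficient of determination `R^2` is
#' used as a regularity index (1 = perfectly self-similar scaling) and the
#' root-mean-square residual quantifies departure from a power law.
#'
#' @param scales Box sizes (px).
#' @param counts Box counts `N(s)`.
#' @return A list with `dimension`, `r_squared`, `rmse`.
#' @export
fractal_fit <- function(scales, counts) {
  stopifnot(length(scales) == length(counts), length(scales) >= 3,
            all(counts >= 1))
  x <- log(1 / scales)
  y <- log(counts)
  if (stats::sd(y) == 0) {
    # all counts equal: flat scaling, fit is exact
    return(list(dimension = 0, r_squared = 1, rmse = 0))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  ss_tot <- sum((y - mean(y))^2)
  list(dimension = unname(fit$coefficients[2]),
       r_squared = 1 - sum(res^2) / ss_tot,
       rmse = sqrt(mean(res^2)))
}

#' Gliding-box lacunarity of a binary pattern
#'
#' For every scale `s`, slides an `s` x `s` window with stride 1 over the
#' map and computes the box-mass statistic
#' `Lambda(s) = var(mass) / mean(mass)^2 + 1` (population variance).
#' `Lambda = 1` for translation-invariant mass (e.g. a full map); gappy,
#' clustered patterns give larger values. The summary index is the mean of
#' `log Lambda(s)` over the scales; the RMSE is the residual of a line fit
#' of `log Lambda` against `log s`.
#'
#' @param binary Logical (or 0/1) matrix with at least one foreground pixel.
#' @param scales Window sizes in px (default `2^(0:7)`), each smaller than
#'   the map side.
#' @return A list with `index`, `rmse` and `per_scale` (data.frame with
#'   columns `s`, `lambda`).
#' @export
lacunarity <- function(binary, scales = 2^(0:7)) {
  b <- .as_binary(binary)
  if (!any(b)) stop("lacunarity: empty binary map")
  scales <- as.integer(scales)
  stopifnot(all(scales >= 1), all(scales <= min(dim(b))))
  sat <- .sat(b)
  n <- nrow(b); m <- ncol(b)
  lam <- vapply(scales, function(s) {
    i <- seq_len(n - s + 1L); j <- seq_len(m - s + 1L)
    mass <- sat[i + s, j + s, drop = FALSE] - sat[i + s, j, drop = FALSE] -
            sat[i, j + s, drop = FALSE] + sat[i, j, drop = FALSE]
    mu <- mean(mass)
    if (mu == 0) return(NA_real_)
    mean((mass - mu)^2) / mu^2 + 1
  }, numeric(1))
  keep <- is.finite(lam)
  per <- data.frame(s = scales[keep], lambda = lam[keep])
  ll <- log(per$lambda)
  ls <- log(per$s)
  rmse <- if (nrow(per) >= 3 && stats::sd(ll) > 0 && stats::sd(ls) > 0) {
    fit <- stats::lm.fit(cbind(1, ls), ll)
    sqrt(mean(fit$residuals^2))
  } else 0
  list(index = mean(ll), rmse = rmse, per_scale = per)
}
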
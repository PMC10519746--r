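#' Phenotype specification for the synthetic cell generator
#'
#' Describes one cell population as distributions over phantom parameters:
#' overall size, refractive-index (RI) contrast against the medium,
#' internal granularity and boundary roughness. These four handles map onto
#' the four groups of the 37-feature descriptor (OPL statistics, 2D
#' morphology, texture, fractal geometry) so that synthetic populations can
#' be made separable, or deliberately overlapping, along each of them.
#'
#' @param name Class label.
#' @param radius_mean,radius_sd Mean and s.d. of the cell equivalent radius
#'   in micrometres; per-cell radii are drawn from a normal truncated at
#'   `0.5 * radius_mean`.
#' @param delta_n_mean,delta_n_sd Mean and s.d. of the cytoplasmic RI
#'   contrast `n - n0` (dimensionless).
#' @param granule_count_mean Mean number of intracellular granules; the
#'   per-cell count is Poisson with this mean.
#' @param granule_radius Granule radius in micrometres.
#' @param granule_delta_n Extra RI contrast of granules on top of the
#'   cytoplasm.
#' @param boundary_roughness Amplitude of the low-order radial Fourier
#'   perturbation of the cell boundary, as a fraction of the radius
#'   (must lie in `[0, 0.5)`).
#' @param n_views_range Integer range `c(min, max)` of the number of phase
#'   maps recorded per rolling cell.
#'
#' @return An object of class `phenotype_spec`.
#' @seealso [default_phenotypes()] for the five built-in populations.
#' @export
phenotype_spec <- function(name,
                           radius_mean, radius_sd = 0,
                           delta_n_mean, delta_n_sd = 0,
                           granule_count_mean = 0,
                           granule_radius = 0.5,
                           granule_delta_n = 0.02,
                           boundary_roughness = 0,
                           n_views_range = c(50L, 150L)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("phenotype 'name' must be a non-empty string")
  }
  if (!(radius_mean > 0)) stop("radius_mean must be > 0")
  if (radius_sd < 0) stop("radius_sd must be >= 0")
  if (!(delta_n_mean > 0)) stop("delta_n_mean must be > 0")
  if (delta_n_sd < 0) stop("delta_n_sd must be >= 0")
  if (granule_count_mean < 0) stop("granule_count_mean must be >= 0")
  if (granule_radius <= 0) stop("granule_radius must be > 0")
  if (boundary_roughness < 0 || boundary_roughness >= 0.5) {
    stop("boundary_roughness must lie in [0, 0.5)")
  }
  n_views_range <- as.integer(round(n_views_range))
  if (length(n_views_range) != 2L || n_views_range[1] < 1L ||
      n_views_range[2] < n_views_range[1]) {
    stop("n_views_range must be c(min, max) with min >= 1")
  }
  structure(list(
    name = name,
    radius_mean = radius_mean, radius_sd = radius_sd,
    delta_n_mean = delta_n_mean, delta_n_sd = delta_n_sd,
    granule_count_mean = granule_count_mean,
    granule_radius = granule_radius,
    granule_delta_n = granule_delta_n,
    boundary_roughness = boundary_roughness,
    n_views_range = n_views_range
  ), class = "phenotype_spec")
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phenotype_spec> %s: R=%.3g+/-%.3g um, dn=%.3g+/-%.3g, ",
    "%g granules (r=%.3g um, dn+%.3g), roughness %.3g, views %d-%d\n"),
    x$name, x$radius_mean, x$radius_sd, x$delta_n_mean, x$delta_n_sd,
    x$granule_count_mean, x$granule_radius, x$granule_delta_n,
    x$boundary_roughness, x$n_views_range[1], x$n_views_range[2]))
  invisible(x)
}

#' Built-in phenotype panel: one monocytic line and four neuroblastoma lines
#'
#' Five synthetic populations emulating the structure of the holographic
#' neuroblastoma phenotyping problem: a THP-1-like monocyte class and four
#' neuroblastoma (NB) lines that fall into two super-groups,
#' NB1 = \{CHP212, SKNBE2\} and NB2 = \{SHSY5Y, SKNSH\}. Monocytes are
#' small and optically dense; NB1 cells are large, granule-rich and dense;
#' NB2 cells are smaller, optically lighter and boundary-rough. Differences
#' between the two members of each super-group are deliberately smaller
#' than the differences between super-groups, so the two NB super-groups
#' sit closer to each other than either does to the monocytes — a
#' structured, non-trivial five-class problem in which all four feature
#' groups carry signal.
#'
#' @return A named list of five [phenotype_spec()] objects
#'   (`THP1`, `CHP212`, `SKNBE2`, `SHSY5Y`, `SKNSH`).
#' @export
#' @examples
#' specs <- default_phenotypes()
#' names(specs)
default_phenotypes <- function() {
  list(
    THP1 = phenotype_spec("THP1",
      radius_mean = 4.2, radius_sd = 0.38,
      delta_n_mean = 0.052, delta_n_sd = 0.0035,
      granule_count_mean = 5, granule_radius = 0.5, granule_delta_n = 0.020,
      boundary_roughness = 0.03),
    CHP212 = phenotype_spec("CHP212",
      radius_mean = 5.8, radius_sd = 0.45,
      delta_n_mean = 0.047, delta_n_sd = 0.003,
      granule_count_mean = 12, granule_radius = 0.7, granule_delta_n = 0.022,
      boundary_roughness = 0.05),
    SKNBE2 = phenotype_spec("SKNBE2",
      radius_mean = 6.5, radius_sd = 0.45,
      delta_n_mean = 0.043, delta_n_sd = 0.003,
      granule_count_mean = 20, granule_radius = 0.7, granule_delta_n = 0.022,
      boundary_roughness = 0.09),
    SHSY5Y = phenotype_spec("SHSY5Y",
      radius_mean = 5.0, radius_sd = 0.4,
      delta_n_mean = 0.034, delta_n_sd = 0.0028,
      granule_count_mean = 7, granule_radius = 0.55, granule_delta_n = 0.018,
      boundary_roughness = 0.05),
    SKNSH = phenotype_spec("SKNSH",
      radius_mean = 5.0, radius_sd = 0.4,
      delta_n_mean = 0.034, delta_n_sd = 0.0028,
      granule_count_mean = 13, granule_radius = 0.55, granule_delta_n = 0.018,
      boundary_roughness = 0.14)
  )
}

#' Hierarchy of the five built-in classes
#'
#' The class-group map used by the hierarchical classifier: level 1
#' separates monocytes from all NB lines, level 2 separates the NB1 and
#' NB2 super-groups, level 3 resolves the leaf lines within each
#' super-group.
#'
#' @return A list with elements `monocyte`, `NB1`, `NB2` (character vectors
#'   of leaf class names).
#' @export
default_class_groups <- function() {
  list(monocyte = "THP1",
       NB1 = c("CHP212", "SKNBE2"),
       NB2 = c("SHSY5Y", "SKNSH"))
}
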
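# Shared fixtures and a memoised end-to-end pipeline run.
#
# The default-configuration pipeline run (and its seeded replicates with
# baselines) dominates the suite's runtime, so it is computed once and
# cached for every test that needs it.

.run_cache <- new.env(parent = emptyenv())

# Full pipeline report for a given master seed, with baseline models,
# computed at the package's default study scale. Memoised per seed.
report_for_seed <- function(seed) {
  key <- sprintf("seed%d", seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- run_config(seed = seed, baselines = TRUE)
    .run_cache[[key]] <- suppressMessages(run_pipeline(cfg))
  }
  .run_cache[[key]]
}

# An ideal spherical phantom: radius 5 um, RI contrast 0.04, no granules,
# no roughness. With zero spreads the draw is deterministic and exactly
# spherical, so analytic values are available in closed form.
sphere_spec <- function() {
  phenotype_spec("sphere", radius_mean = 5, radius_sd = 0,
                 delta_n_mean = 0.04, delta_n_sd = 0,
                 granule_count_mean = 0, boundary_roughness = 0)
}

sphere_phantom <- function(seed = 1L) make_phantom(sphere_spec(), seed = seed)

sphere_qpm <- function(optics = optics_config()) {
  project_qpm(sphere_phantom(), 0, optics)
}

# Peak phase of that sphere: (2 pi / lambda) * delta_n * 2 R
sphere_peak_phase <- function(optics = optics_config()) {
  4 * pi * 0.04 * 5 / optics$wavelength
}

# Binary disk / ellipse masks on a pixel grid (integer coordinates)
disk_mask <- function(radius, n = 2L * radius + 21L) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= radius^2)
}

ellipse_mask <- function(a, b, n = 2L * max(a, b) + 21L) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - ctr) / a)^2 + ((j - ctr) / b)^2 <= 1)
}

# Sierpinski carpet after k iterations (3^k x 3^k logical matrix)
sierpinski_carpet <- function(k) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(k)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m
}

# Synthetic 37-column frame-level feature table with the class structure
# the hierarchy expects: separability injected on one column per level,
# including a fractal column for the NB2 pair (L3.2 consumes fractal
# features only).
toy_feature_table <- function(cells_per_class = 10L, frames_per_cell = 5L,
                              seed = 99L, sep = 4) {
  classes <- c("THP1", "CHP212", "SKNBE2", "SHSY5Y", "SKNSH")
  feats <- feature_set("hybrid")
  set.seed(seed)
  rows <- list()
  cell_no <- 0L
  for (cl in classes) {
    for (i in seq_len(cells_per_class)) {
      cell_no <- cell_no + 1L
      x <- matrix(stats::rnorm(frames_per_cell * length(feats)),
                  frames_per_cell, length(feats),
                  dimnames = list(NULL, feats))
      if (cl == "THP1") x[, "opl_mean"] <- x[, "opl_mean"] + sep
      if (cl %in% c("CHP212", "SKNBE2")) x[, "area"] <- x[, "area"] + sep
      if (cl == "CHP212") x[, "glcm_contrast"] <- x[, "glcm_contrast"] + sep
      if (cl == "SKNBE2") x[, "glcm_contrast"] <- x[, "glcm_contrast"] - sep
      if (cl == "SHSY5Y") {
        x[, "fractal_dimension"] <- x[, "fractal_dimension"] + sep
      }
      if (cl == "SKNSH") {
        x[, "fractal_dimension"] <- x[, "fractal_dimension"] - sep
      }
      rows[[cell_no]] <- cbind(
        data.frame(cell_id = sprintf("toy%03d", cell_no), class = cl,
                   frame = seq_len(frames_per_cell)),
        as.data.frame(x))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
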
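test_that("phenotype_spec validates its arguments", {
  expect_s3_class(phenotype_spec("x", radius_mean = 5, delta_n_mean = 0.03),
                  "phenotype_spec")
  expect_error(phenotype_spec("", radius_mean = 5, delta_n_mean = 0.03),
               "name")
  expect_error(phenotype_spec("x", radius_mean = 0, delta_n_mean = 0.03),
               "radius_mean")
  expect_error(phenotype_spec("x", radius_mean = 5, delta_n_mean = 0),
               "delta_n_mean")
  expect_error(phenotype_spec("x", radius_mean = 5, delta_n_mean = 0.03,
                              boundary_roughness = 0.5),
               "boundary_roughness")
  expect_error(phenotype_spec("x", radius_mean = 5, delta_n_mean = 0.03,
                              n_views_range = c(10, 5)),
               "n_views_range")
})

test_that("default phenotype panel has five classes matching the hierarchy", {
  specs <- default_phenotypes()
  groups <- default_class_groups()
  expect_named(specs, c("THP1", "CHP212", "SKNBE2", "SHSY5Y", "SKNSH"))
  expect_setequal(unlist(groups), names(specs))
  for (sp in specs) expect_s3_class(sp, "phenotype_spec")
})

test_that("phantom generation is seed-deterministic and leaves the RNG alone", {
  spec <- default_phenotypes()$CHP212
  set.seed(123)
  before <- .Random.seed
  p1 <- make_phantom(spec, seed = 7)
  expect_identical(.Random.seed, before)
  p2 <- make_phantom(spec, seed = 7)
  p3 <- make_phantom(spec, seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1$semi_axes, p3$semi_axes))
  expect_equal(nrow(p1$granules) > 0, TRUE)
})

test_that("sphere projection matches the analytic peak phase with zero background", {
  optics <- optics_config()
  q <- sphere_qpm(optics)
  expect_s3_class(q, "qpm_image")
  expect_identical(dim(q), c(optics$qpm_size, optics$qpm_size))
  # (2 pi / lambda) * delta_n * 2 R = 4.7247 rad, pixel-grid sampling aside
  expect_equal(max(q$phase), sphere_peak_phase(optics), tolerance = 0.02 / 4.7)
  # outside the cell the phase is exactly zero (analytic chords, no taper)
  expect_identical(q$phase[1, 1], 0)
  expect_true(all(q$phase >= 0))
})

test_that("projection is linear in the refractive-index contrast", {
  optics <- optics_config()
  p1 <- sphere_phantom()
  p2 <- p1
  p2$delta_n <- 2 * p1$delta_n
  q1 <- project_qpm(p1, 0.3, optics)
  q2 <- project_qpm(p2, 0.3, optics)
  expect_equal(q2$phase, 2 * q1$phase, tolerance = 1e-12)
})

test_that("rotation conserves the integrated phase of a convex granular phantom", {
  optics <- optics_config()
  spec <- phenotype_spec("gran", radius_mean = 5, radius_sd = 0.2,
                         delta_n_mean = 0.04, granule_count_mean = 10,
                         granule_radius = 0.6, granule_delta_n = 0.02)
  ph <- make_phantom(spec, seed = 3)
  sums <- vapply(c(0, 0.7, 1.9, 3.0),
                 function(a) sum(project_qpm(ph, a, optics)$phase),
                 numeric(1))
  expect_lt(max(abs(sums - sums[1])) / sums[1], 1e-3)
})

test_that("an oversized phantom triggers a field-of-view error", {
  optics <- optics_config(qpm_size = 64L, hologram_size = 64L)
  big <- phenotype_spec("big", radius_mean = 10, delta_n_mean = 0.04)
  expect_error(project_qpm(make_phantom(big, seed = 1), 0, optics),
               "field of view")
})

test_that("roll_sequence produces monotone angles and seeded noise", {
  optics <- optics_config()
  ph <- sphere_phantom()
  sq <- roll_sequence(ph, 5, optics, seed = 2, noise_sd = 0.02)
  expect_s3_class(sq, "cell_sequence")
  expect_length(sq$frames, 5)
  expect_true(all(diff(sq$angles) > 0))
  expect_equal(sq$angles[c(1, 5)], c(0, pi))
  sq2 <- roll_sequence(ph, 5, optics, seed = 2, noise_sd = 0.02)
  expect_identical(sq$frames[[3]]$phase, sq2$frames[[3]]$phase)
  clean <- roll_sequence(ph, 3, optics, seed = 2, noise_sd = 0)
  expect_identical(clean$frames[[1]]$phase, project_qpm(ph, 0, optics)$phase)
})

test_that("encode_hologram yields a real non-negative fringe pattern", {
  optics <- optics_config(hologram_size = 256L, qpm_size = 128L)
  ph <- phenotype_spec("small", radius_mean = 3, delta_n_mean = 0.03)
  q <- project_qpm(make_phantom(ph, seed = 1), 0, optics)
  h <- encode_hologram(q, optics)
  expect_true(is.matrix(h) && is.numeric(h))
  expect_identical(dim(h), c(256L, 256L))
  expect_true(all(h >= 0))
  expect_equal(attr(h, "qpm_size"), 128L)
  expect_equal(attr(h, "carrier_freq"), optics$carrier_freq)
  bad <- optics
  bad$carrier_freq <- c(0.6, 0.1)
  expect_error(encode_hologram(q, bad), "Nyquist")
})

test_that("simulate_manifest draws per-cell view counts within range", {
  specs <- list(A = phenotype_spec("A", radius_mean = 4, delta_n_mean = 0.03,
                                   n_views_range = c(10L, 20L)),
                B = phenotype_spec("B", radius_mean = 5, delta_n_mean = 0.03,
                                   n_views_range = c(5L, 5L)))
  man <- simulate_manifest(specs, c(6L, 4L), seed = 11)
  expect_setequal(names(table(man$class)), c("A", "B"))
  nv <- tapply(man$frame, man$cell_id, max)
  cls <- tapply(man$class, man$cell_id, `[`, 1)
  expect_true(all(nv[cls == "A"] >= 10 & nv[cls == "A"] <= 20))
  expect_true(all(nv[cls == "B"] == 5))
  expect_identical(man, simulate_manifest(specs, c(6L, 4L), seed = 11))
})

test_that("make_dataset writes TIFF frames that read back losslessly", {
  optics <- optics_config(qpm_size = 96L, hologram_size = 96L)
  specs <- list(S = phenotype_spec("S", radius_mean = 3, delta_n_mean = 0.03))
  dir <- file.path(tempdir(), "qpmset-test")
  man <- make_dataset(specs, 2L, optics, seed = 5, out_dir = dir,
                      n_views = 3L, noise_sd = 0, keep_sequences = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 6L)
  seqs <- attr(man, "sequences")
  q0 <- seqs[[1]]$frames[[2]]
  back <- read_qpm(man$path[man$cell_id == seqs[[1]]$cell_id &
                            man$frame == 2], optics$pitch)
  # 32-bit float round trip: scale 32 rad over 2^23 mantissa steps
  expect_lt(max(abs(back$phase - q0$phase)), 1e-5)
  unlink(dir, recursive = TRUE)
})
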
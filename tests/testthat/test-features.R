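test_that("feature sets have the canonical sizes and layout", {
  g <- feature_groups()
  expect_named(g, c("opl", "morphology", "glcm", "fractal"))
  expect_equal(lengths(g), c(opl = 11L, morphology = 9L, glcm = 4L,
                             fractal = 13L))
  expect_length(feature_set("hybrid"), 37)
  expect_length(feature_set("conventional"), 24)
  expect_length(feature_set("fractal"), 13)
  expect_length(intersect(feature_set("conventional"),
                          feature_set("fractal")), 0)
  expect_setequal(feature_set("hybrid"),
                  c(feature_set("conventional"), feature_set("fractal")))
})

test_that("segmentation recovers the analytic disk support", {
  optics <- optics_config()
  q <- sphere_qpm(optics)
  sup <- segment_qpm(q)
  analytic_px <- pi * (5 / optics$pitch)^2
  expect_lt(abs(sum(sup) / analytic_px - 1), 0.05)
  expect_error(segment_qpm(matrix(1, 32, 32)), "no cell")
  expect_error(segment_qpm(matrix(rnorm(32 * 32, 0, 1e-4), 32)), "no cell")
})

test_that("dry mass of the 5-um sphere matches the analytic value", {
  optics <- optics_config()
  q <- sphere_qpm(optics)
  sup <- segment_qpm(q)
  f <- opl_features(q, sup)
  # m = delta_n * V / gamma = 0.04 * (4/3) pi 5^3 / 0.2 = 104.72 pg
  m_true <- 0.04 * 4 / 3 * pi * 125 / 0.2
  expect_lt(abs(f[["dry_mass"]] / m_true - 1), 0.02)
  expect_equal(f[["opl_max"]], max(q$phase))
  expect_true(all(is.finite(f)) && length(f) == 11)
})

test_that("morphology oracles: disk and 2:1 ellipse", {
  dm <- disk_mask(40L)
  f <- morphology_features(dm, pitch = 1)
  expect_gt(f[["circularity"]], 0.95)
  expect_lt(f[["circularity"]], 1.05)
  expect_equal(f[["solidity"]], 1, tolerance = 0.02)
  expect_equal(f[["eccentricity"]], 0, tolerance = 0.1)
  expect_equal(f[["extent"]], pi / 4, tolerance = 0.03)
  expect_equal(f[["max_diameter"]], 80, tolerance = 0.04)
  expect_equal(f[["min_diameter"]], 80, tolerance = 0.04)
  expect_equal(f[["area"]], pi * 40^2, tolerance = 0.02)

  em <- ellipse_mask(60L, 30L)
  fe <- morphology_features(em, pitch = 1)
  expect_equal(fe[["eccentricity"]], sqrt(1 - 0.25), tolerance = 0.02)
  expect_equal(fe[["major_axis"]], 120, tolerance = 0.02)
  expect_equal(fe[["max_diameter"]], 120, tolerance = 0.02)
  expect_equal(fe[["min_diameter"]], 60, tolerance = 0.03)

  # centroid offset: weighting the phase toward one side moves the
  # weighted centroid away from the binary one
  ph <- matrix(0, nrow(dm), ncol(dm))
  ph[dm] <- 1
  ph[seq_len(nrow(dm) / 2), ] <- ph[seq_len(nrow(dm) / 2), ] * 3
  fd <- morphology_features(dm, pitch = 1, phase = ph)
  expect_gt(fd[["norm_centroid_dist"]], 0.1)
  expect_equal(f[["norm_centroid_dist"]], 0)
})

test_that("GLCM: hand-enumerated checkerboard and anisotropic stripes", {
  n <- 32L
  cb <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
  sup <- matrix(TRUE, n, n)
  f <- glcm_features(cb, sup, glcm_config(levels = 2))
  expect_equal(f[["glcm_contrast"]], 1)
  expect_equal(f[["glcm_energy"]], 0.5)
  expect_equal(f[["glcm_correlation"]], -1)
  expect_equal(f[["glcm_homogeneity"]], 0.5)

  stripes <- outer(seq_len(n), seq_len(n), function(i, j) i %% 2)
  h <- glcm_features(stripes, sup, glcm_config(theta = 0, levels = 2))
  v <- glcm_features(stripes, sup, glcm_config(theta = 90, levels = 2))
  expect_equal(h[["glcm_contrast"]], 0)   # constant along each row
  expect_equal(v[["glcm_contrast"]], 1)   # alternates across rows

  # constant image conventions
  fc <- glcm_features(matrix(2, n, n), sup, glcm_config(levels = 8))
  expect_equal(unname(fc), c(0, 1, 1, 1))
})

test_that("box counting is exact on separable patterns", {
  full <- matrix(TRUE, 256, 256)
  bc <- box_count(full, 2^(0:7))
  expect_equal(bc$n_boxes, (256 / 2^(0:7))^2)
  fit <- fractal_fit(bc$s, bc$n_boxes)
  expect_equal(fit$dimension, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  line <- matrix(FALSE, 256, 256)
  line[128, ] <- TRUE
  bl <- box_count(line, 2^(0:7))
  expect_equal(bl$n_boxes, 256 / 2^(0:7))
  expect_equal(fractal_fit(bl$s, bl$n_boxes)$dimension, 1, tolerance = 1e-10)
  expect_true(all(diff(bl$n_boxes) <= 0))
  expect_error(box_count(matrix(FALSE, 8, 8)), "empty")
})

test_that("Sierpinski carpet dimension equals log 8 / log 3", {
  carpet <- sierpinski_carpet(5)           # 243 x 243
  bc <- box_count(carpet, 3^(0:4))
  fit <- fractal_fit(bc$s, bc$n_boxes)
  expect_equal(fit$dimension, log(8) / log(3), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("fractal_fit agrees with a brute-force lm on noisy counts", {
  set.seed(12)
  scales <- 2^(0:7)
  counts <- round(1000 * (1 / scales)^1.6 * exp(rnorm(8, 0, 0.05))) + 1
  fit <- fractal_fit(scales, counts)
  ref <- stats::lm(log(counts) ~ log(1 / scales))
  expect_equal(fit$dimension, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(fit$rmse, sqrt(mean(residuals(ref)^2)), tolerance = 1e-10)
})

test_that("lacunarity separates homogeneous, random and clustered patterns", {
  full <- matrix(TRUE, 128, 128)
  expect_equal(lacunarity(full)$index, 0, tolerance = 1e-12)

  set.seed(21)
  n_fg <- round(0.1 * 128^2)
  rand <- matrix(FALSE, 128, 128)
  rand[sample(128^2, n_fg)] <- TRUE
  clus <- matrix(FALSE, 128, 128)
  side <- floor(sqrt(n_fg))
  clus[seq_len(side), seq_len(side)] <- TRUE

  l_rand <- lacunarity(rand)
  l_clus <- lacunarity(clus)
  at4 <- function(l) l$per_scale$lambda[l$per_scale$s == 4]
  expect_gt(at4(l_clus), at4(l_rand))
  expect_gt(l_clus$index, l_rand$index)
})

test_that("pad_and_maps centres the QPM on a 256 grid and derives hole maps", {
  q <- sphere_qpm(optics_config())
  sup <- segment_qpm(q)
  maps <- pad_and_maps(q, sup)
  expect_s3_class(maps, "support_maps")
  expect_identical(dim(maps$qpm), c(256L, 256L))
  expect_equal(sum(maps$support), sum(sup))
  expect_true(any(maps$hole_support))
  expect_true(all(maps$qpm[!maps$support] < max(maps$qpm)))
  expect_error(pad_and_maps(matrix(1, 300, 300), matrix(TRUE, 300, 300)),
               "larger than")
})

test_that("fractal_features returns 13 values and guards an empty hole map", {
  q <- sphere_qpm(optics_config())
  sup <- segment_qpm(q)
  f <- fractal_features(pad_and_maps(q, sup))
  expect_length(f, 13)
  expect_named(f, feature_groups()$fractal)
  expect_true(all(is.finite(f)))
  # a filled disk on the padded grid: slope between line-like and plane-like
  # (box counts saturate at the coarsest scales, pulling the fit below 2)
  expect_gt(f[["fractal_dimension"]], 1.3)
  expect_lt(f[["fractal_dimension"]], 2.05)

  empty_holes <- pad_and_maps(q, sup, grad_threshold = 1.5)
  expect_false(any(empty_holes$hole_support))
  expect_warning(fe <- fractal_features(empty_holes), "hole")
  expect_equal(unname(fe[c("vertex_density", "vertex_lacunarity_index")]),
               c(0, 0))
})

test_that("extract_features yields the deterministic 37-vector", {
  optics <- optics_config()
  spec <- default_phenotypes()$SKNSH
  q <- roll_sequence(make_phantom(spec, seed = 5), 1, optics, seed = 5,
                     noise_sd = 0.02)$frames[[1]]
  f1 <- extract_features(q)
  f2 <- extract_features(q)
  expect_identical(f1, f2)
  expect_length(f1, 37)
  expect_identical(names(f1), feature_set("hybrid"))
  expect_true(all(is.finite(f1)))
})

test_that("extract_features_batch assembles the frame table", {
  optics <- optics_config()
  specs <- default_phenotypes()[c("THP1", "SHSY5Y")]
  man <- make_dataset(specs, 1L, optics, seed = 9, n_views = 2L,
                      keep_sequences = TRUE, write_images = FALSE)
  tab <- extract_features_batch(attr(man, "sequences"))
  expect_equal(nrow(tab), 4)
  expect_identical(names(tab)[1:3], c("cell_id", "class", "frame"))
  expect_setequal(unique(tab$class), c("THP1", "SHSY5Y"))
  expect_true(all(vapply(tab[feature_set("hybrid")], is.numeric, logical(1))))
})
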
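test_that("tamura matches its definition and rejects zero-mean input", {
  expect_equal(tamura(matrix(c(0, 2), 1, 2)), 1)           # sd 1, mean 1
  expect_equal(tamura(matrix(5, 4, 4)), 0)
  expect_error(tamura(matrix(0, 3, 3)), "mean")
})

test_that("angular-spectrum propagation is unitary and invertible", {
  set.seed(4)
  f0 <- complex_field(matrix(complex(real = rnorm(64 * 64),
                                     imaginary = rnorm(64 * 64)), 64, 64),
                      pitch = 0.5, wavelength = 0.532)
  f1 <- propagate(f0, 40)
  expect_equal(f1$z, 40)
  # band-limited content only: energy conserved to numerical precision
  expect_equal(sum(Mod(f1$field)^2), sum(Mod(f0$field)^2), tolerance = 1e-9)
  f2 <- propagate(f1, -40)
  expect_equal(f2$field, f0$field, tolerance = 1e-9)
  expect_identical(propagate(f0, 0), f0)
})

test_that("autofocus finds the refocusing distance and breaks ties at |z| min", {
  optics <- optics_config(qpm_size = 64L, hologram_size = 64L)
  ph <- phenotype_spec("s", radius_mean = 2.5, delta_n_mean = 0.03)
  q <- project_qpm(make_phantom(ph, seed = 1), 0, optics)
  f0 <- complex_field(exp(1i * q$phase), optics$pitch, optics$wavelength)
  defocused <- propagate(f0, 30)
  zb <- autofocus(defocused, z_grid = seq(-50, 50, by = 5))
  expect_equal(zb, -30)
  # a plane wave is in focus everywhere: all Tamura values tie, pick z = 0
  plane <- complex_field(matrix(1 + 0i, 32, 32), 0.5, 0.532)
  expect_equal(autofocus(plane, z_grid = c(-10, 0, 10)), 0)
  expect_error(autofocus(plane), "grid")
})

test_that("unwrap_phase output differs from the input by exact 2*pi multiples", {
  set.seed(8)
  smooth <- outer(seq(0, 6, length.out = 80), seq(0, 8, length.out = 80), `+`)
  wrapped <- (smooth + pi) %% (2 * pi) - pi
  un <- unwrap_phase(wrapped)
  k <- (un - wrapped) / (2 * pi)
  expect_equal(k, round(k), tolerance = 1e-9)
  # smooth field recovered up to a constant 2*pi*k offset
  d <- un - smooth
  expect_lt(max(d) - min(d), 1e-9)
})

test_that("unwrap_phase recovers a steep spherical cap", {
  q <- sphere_qpm(optics_config(qpm_size = 128L, hologram_size = 128L))
  wrapped <- (q$phase + pi) %% (2 * pi) - pi
  un <- unwrap_phase(wrapped)
  d <- un - q$phase
  expect_lt(max(d) - min(d), 1e-9)
})

test_that("demodulation flags a hologram without an off-axis carrier", {
  flat <- matrix(1, 64, 64)
  expect_error(demodulate(flat, pitch = 0.125, wavelength = 0.532),
               "not off-axis")
})

test_that("the full hologram round trip reconstructs the phase map", {
  optics <- optics_config(qpm_size = 128L, hologram_size = 256L)
  ph <- phenotype_spec("cell", radius_mean = 4, delta_n_mean = 0.035,
                       granule_count_mean = 5, granule_radius = 0.5)
  q <- project_qpm(make_phantom(ph, seed = 2), 0.4, optics)
  h <- encode_hologram(q, optics)
  ref <- encode_hologram(qpm_image(matrix(0, 128, 128), optics$pitch), optics)
  rec <- reconstruct_qpm(h, recon_config(), reference = ref)
  expect_s3_class(rec, "qpm_image")
  expect_identical(dim(rec), dim(q))
  rmse <- sqrt(mean((rec$phase - q$phase)^2))
  expect_lt(rmse, 0.08)   # hard-mask filtering at a modest grid size
  # reconstruction is sign-correct: n > n0 gives positive phase
  expect_gt(max(rec$phase), 0.9 * max(q$phase))
})

test_that("recon_config validates inputs and denoising variants run", {
  expect_error(recon_config(filter_radius = -1), "filter_radius")
  expect_error(recon_config(z_range = c(5, -5)))
  optics <- optics_config(qpm_size = 64L, hologram_size = 128L)
  q <- project_qpm(make_phantom(
    phenotype_spec("s", radius_mean = 2, delta_n_mean = 0.02), 1), 0, optics)
  h <- encode_hologram(q, optics)
  for (dn in c("median", "gaussian")) {
    rec <- reconstruct_qpm(h, recon_config(denoise = dn))
    expect_identical(dim(rec), c(64L, 64L))
  }
})
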
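test_that("time-bandwidth relation and on-resonance normalization hold", {
  for (T in c(0.33, 0.66, 1.32, 2.5)) {
    for (shape in c("plain_sinc", "filtered_sinc")) {
      p <- excitation_pulse(shape, T)
      expect_identical(p$bandwidth_khz * p$time_fwhm_ms, 2)
      expect_identical(excitation_response(p, 0), 1)
    }
  }
  # the two hardware pulses map to the narrow/broad bandwidth pair
  expect_equal(excitation_pulse("plain_sinc", 1.32)$bandwidth_khz,
               1.5152, tolerance = 1e-3)
  expect_equal(excitation_pulse("filtered_sinc", 0.66)$bandwidth_khz,
               3.0303, tolerance = 1e-3)
})

test_that("narrow pulse suppresses and broad pulse excites a 1.2 kHz species", {
  narrow <- excitation_pulse("plain_sinc", 1.32)
  broad <- excitation_pulse("filtered_sinc", 0.66)
  expect_lt(excitation_response(narrow, 1.2), 0.1)
  expect_gt(excitation_response(broad, 1.2), 0.5)
  # Gaussian response formula at FWHM bandwidth, evaluated independently
  B <- broad$bandwidth_khz
  expect_equal(excitation_response(broad, 1.2),
               exp(-4 * log(2) * (1.2 / B)^2), tolerance = 1e-12)
  expect_equal(excitation_response(broad, 1.2), 0.64740, tolerance = 1e-4)
})

test_that("plain-sinc profile is a flat-top passband with steep roll-off", {
  for (T in c(0.5, 1, 1.32, 2)) {
    p <- excitation_pulse("plain_sinc", T)
    B <- p$bandwidth_khz
    for (f in seq(B / 2, 3 * B, length.out = 7))
      expect_lte(excitation_response(p, f), 0.5)
    for (f in seq(0, B / 4, length.out = 7))
      expect_gte(excitation_response(p, f), 0.9)
    # symmetric in the offset sign
    expect_equal(excitation_response(p, -0.8 * B),
                 excitation_response(p, 0.8 * B))
  }
})

test_that("sphere voxelization matches brute-force centre enumeration", {
  g <- voxel_grid(c(20, 20, 20), c(1, 1, 1))
  # radius below half the voxel pitch, centred on a voxel centre: 1 voxel
  m1 <- voxelize_sphere(g, c(10.5, 10.5, 10.5), 0.4)
  expect_identical(sum(m1), 1L)
  expect_true(m1[11, 11, 11])

  # 5 mm sphere: count within 10% of its continuum volume
  m5 <- voxelize_sphere(g, c(10, 10, 10), 5)
  expect_lt(abs(sum(m5) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.1)
  # brute-force enumeration oracle over all voxel centres
  cnt <- 0L
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if ((i - 0.5 - 10)^2 + (j - 0.5 - 10)^2 + (k - 0.5 - 10)^2 <= 25)
      cnt <- cnt + 1L
  }
  expect_identical(sum(m5), cnt)

  # translation by exactly one voxel pitch shifts the mask by one voxel
  m <- voxelize_sphere(g, c(8, 10, 10), 3)
  mt <- voxelize_sphere(g, c(9, 10, 10), 3)
  expect_identical(mt[2:20, , ], m[1:19, , ])

  expect_error(voxelize_sphere(g, c(100, 100, 100), 2), "no voxel centre")
})

test_that("noise-free images conserve spins per compartment exactly", {
  offres <- off_resonance_compartment(c(16, 8, 16), 3, offset_khz = 1.2,
                                      spin_density_spins_per_uL = 1e15)
  spec <- simple_phantom(n_cells = 7e5, spins_per_cell = 1.3e11,
                         off_resonance = offres)
  acq <- acquisition_params(noise_sd = 0, gain = 2.5e-12, seed = 4)
  ph <- generate_fluorine_image(spec, acq)
  vol <- voxel_volume_uL(spec$grid)
  expect_identical(sum(ph$image$values[ph$masks$pellet_1]),
                   2.5e-12 * 7e5 * 1.3e11)
  expect_equal(sum(ph$image$values[ph$masks$reference]),
               2.5e-12 * 2.6e16 * vol * sum(ph$masks$reference),
               tolerance = 1e-12)
  resp <- excitation_response(acq$pulse, 1.2)
  expect_equal(sum(ph$image$values[ph$masks$off_resonance]),
               2.5e-12 * 1e15 * vol * resp * sum(ph$masks$off_resonance),
               tolerance = 1e-12)
  # everything outside the compartments is exactly zero
  expect_identical(unique(ph$image$values[background_of(ph)]), 0)
})

test_that("image generation is bit-deterministic and rejects bad input", {
  spec <- simple_phantom()
  acq <- acquisition_params(noise_sd = 80, seed = 42)
  a <- generate_fluorine_image(spec, acq)
  b <- generate_fluorine_image(spec, acq)
  expect_identical(a$image$values, b$image$values)
  c <- generate_fluorine_image(spec, acquisition_params(noise_sd = 80,
                                                        seed = 43))
  expect_false(identical(a$image$values, c$image$values))

  expect_error(acquisition_params(noise_sd = -1), "nonnegative")
  # overlapping pellet and reference tube
  bad <- phantom_spec(voxel_grid(c(32, 32, 16)),
                      pellet_spec(c(24, 16, 16), 2, 1e5, 1e11),
                      reference = reference_tube_spec(c(24, 16, 16), 1.5, 24))
  expect_error(generate_fluorine_image(bad, acq), "overlap")
})

test_that("signal-free magnitude voxels follow a Rayleigh law", {
  g <- voxel_grid(c(64, 64, 32), c(1, 1, 1))
  spec <- phantom_spec(g, pellet_spec(c(32, 32, 16), 2, 0, 1e11))
  sigma <- 50
  ph <- generate_fluorine_image(spec, acquisition_params(noise_sd = sigma,
                                                         gain = 1e-12,
                                                         seed = 99))
  v <- as.vector(ph$image$values)
  expect_gte(length(v), 1e5)
  ks <- suppressWarnings(
    stats::ks.test(v, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
  # Rayleigh mode is sigma: histogram peak near sigma
  expect_equal(sqrt(mean(v^2) / 2), sigma, tolerance = 0.02)
})

test_that("proton companion image is a two-level body map plus noise", {
  spec <- simple_phantom()
  ph <- generate_proton_image(spec, acquisition_params(noise_sd = 0,
                                                       seed = 1))
  expect_identical(sort(unique(as.vector(ph$image$values))),
                   c(0, spec$body$intensity))
  a <- generate_proton_image(spec, acquisition_params(noise_sd = 10, seed = 7))
  b <- generate_proton_image(spec, acquisition_params(noise_sd = 10, seed = 7))
  expect_identical(a$image$values, b$image$values)

  bad <- phantom_spec(spec$grid, spec$pellets,
                      body = list(center_mm = c(-50, -50, -50),
                                  semiaxes_mm = c(1, 1, 1), intensity = 1))
  expect_error(generate_proton_image(bad, acquisition_params(seed = 1)),
               "body ellipsoid")
})

test_that("pellet series reproduces the dilution layout", {
  series <- build_pellet_series(spins_per_cell = 1.5e11)
  expect_length(series, 6)
  expect_identical(vapply(series, function(s) s$pellets[[1]]$n_cells,
                          numeric(1)),
                   c(2e5, 4e5, 6e5, 8e5, 1e6, 2e6))
  # identical geometry and reference across the series
  geo <- lapply(series, function(s)
    list(s$pellets[[1]]$center_mm, s$pellets[[1]]$radius_mm, s$reference))
  for (i in 2:6) expect_identical(geo[[i]], geo[[1]])

  expect_length(build_pellet_series(5e5, spins_per_cell = 1e11), 1)

  draws <- withr::with_seed(21, sample_loading(200))
  expect_true(all(draws >= 8.2e10 & draws <= 2.4e11))
})
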
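test_that("autofluorescence subtraction clamps at zero", {
  shg <- matrix(c(5, 3, 1, 0), 2)
  expect_equal(subtract_autofluorescence(shg, matrix(0, 2, 2)), shg)
  expect_equal(subtract_autofluorescence(shg, shg), matrix(0, 2, 2))
  af <- matrix(c(1, 4, 0, 2), 2)
  expect_equal(subtract_autofluorescence(shg, af),
               matrix(c(4, 0, 1, 0), 2))
  expect_error(subtract_autofluorescence(shg, matrix(0, 3, 3)), "shape")
})

test_that("integrated density sums foreground intensity", {
  expect_equal(integrated_density(matrix(0, 8, 8))$integrated_density, 0)
  u <- matrix(2.5, 10, 10)
  d <- integrated_density(u, threshold = 0)
  expect_equal(d$integrated_density, 2.5 * 100)
  expect_equal(d$area_fraction, 1)
  # doubling fiber count increases density (monotone in content)
  f1 <- render_fiber_field(fiber_field_params(n_fibers = 10, noise_sd = 0,
                                              seed = 31))
  f2 <- render_fiber_field(fiber_field_params(n_fibers = 20, noise_sd = 0,
                                              seed = 31))
  expect_gt(integrated_density(f2$image, 0.1)$integrated_density,
            integrated_density(f1$image, 0.1)$integrated_density)
})

test_that("FFT alignment separates isotropic noise from parallel stripes", {
  with_seed_local(8, {
    ars <- replicate(20, fft_alignment(matrix(runif(96 * 96), 96, 96)))
  })
  expect_true(all(ars < 1.1))
  expect_true(all(ars >= 1))
  stripes <- matrix(sin(seq(0, 24 * pi, length.out = 128)), 128, 128)
  expect_gt(fft_alignment(stripes), 5)
  expect_error(fft_alignment(matrix(1, 64, 64)), "constant")
})

test_that("FFT alignment is scale-invariant and 90-degree-rotation-invariant", {
  f <- fixture_single_fiber
  a <- fft_alignment(f$image)
  expect_equal(fft_alignment(f$image * 7.3), a, tolerance = 1e-9)
  rot90 <- t(f$image)[ncol(f$image):1, ]
  expect_equal(fft_alignment(rot90), a, tolerance = 1e-6)
})

test_that("alignment aspect ratio increases with orientation concentration", {
  ars <- vapply(c(0, 2, 8), function(k) {
    f <- render_fiber_field(fiber_field_params(
      image_size = 256, n_fibers = 40, kappa = k, mean_angle_deg = 20,
      length_mean = 100, length_sd = 15, width_mean = 4, noise_sd = 0.01,
      seed = 100 + k))
    fft_alignment(f$image)
  }, numeric(1))
  expect_true(all(diff(ars) > 0))
})

test_that("orientation histogram finds the fiber angle and is equivariant", {
  f <- render_fiber_field(fiber_field_params(
    image_size = 256, n_fibers = 12, kappa = 1e6, mean_angle_deg = 30,
    length_mean = 120, length_sd = 10, width_mean = 4, noise_sd = 0.01,
    seed = 5))
  oh <- orientation_histogram(f$image, bin_deg = 2)
  expect_lte(abs(oh$mode_deg - 30), 2 + 1e-9)
  # rotating the image by +10 degrees shifts the mode by +10
  rot <- EBImage::imageData(EBImage::rotate(EBImage::Image(f$image), 10,
                                            bg.col = 0))
  oh2 <- orientation_histogram(rot, bin_deg = 2)
  shift <- (oh2$mode_deg - oh$mode_deg + 90) %% 180 - 90
  expect_lte(abs(shift - 10), 2 + 1e-9)
  expect_error(orientation_histogram(f$image, bin_deg = 7), "divide")
  expect_error(orientation_histogram(matrix(0, 64, 64)), "foreground")
})

test_that("isotropic fields produce a flat orientation histogram", {
  agg <- 0
  for (s in 1:20) {
    fi <- render_fiber_field(fiber_field_params(
      image_size = 192, n_fibers = 30, kappa = 0, length_mean = 80,
      length_sd = 10, width_mean = 4, noise_sd = 0.01, seed = s))
    agg <- agg + orientation_histogram(fi$image, bin_deg = 10)$histogram$weight
  }
  expect_lt(max(agg), 2 * mean(agg))
})

test_that("fiber tracer recovers single, wavy and crossing fibers", {
  expect_equal(nrow(trace_fibers(matrix(0, 64, 64))), 0)
  # one straight 200 x 6 px fiber
  tr <- trace_fibers(fixture_single_fiber$image, min_length_px = 30)
  expect_equal(nrow(tr), 1)
  expect_lt(abs(tr$length_px - 200) / 200, 0.05)
  expect_lt(abs(tr$width_px - 6) / 6, 0.20)
  expect_gt(tr$straightness, 0.99)
  expect_lt(abs(tr$angle_deg - 30), 3)
  # two crossing fibers stay separable
  fa <- render_fiber_field(fiber_field_params(256, 1, 1e6, 30, 180, 0, 5, 0,
                                              0, 0, 0.002, seed = 21))
  fb <- render_fiber_field(fiber_field_params(256, 1, 1e6, -40, 180, 0, 5, 0,
                                              0, 0, 0.002, seed = 22))
  expect_gte(nrow(trace_fibers(pmax(fa$image, fb$image))), 2)
})

test_that("traced straightness is bounded by 1 and tracks the rendered sinuosity", {
  amp <- waviness_for_sinuosity(1.2)
  f <- render_fiber_field(fiber_field_params(
    image_size = 256, n_fibers = 1, kappa = 1e6, mean_angle_deg = 10,
    length_mean = 160, length_sd = 0, width_mean = 5, width_sd = 0,
    waviness_amp = amp, noise_sd = 0.003, seed = 5))
  expect_equal(f$fibers$straightness, 1 / 1.2, tolerance = 1e-9)
  tr <- trace_fibers(f$image)
  expect_equal(nrow(tr), 1)
  expect_lt(abs(tr$straightness - 1 / 1.2), 0.03)
  expect_true(all(tr$straightness <= 1))
})

test_that("straight fraction applies the 1/1.08 cutoff strictly", {
  fibers <- tibble::tibble(straightness = c(1, 1 / 1.08, 0.8333))
  expect_equal(straight_fraction(fibers), 100 / 3, tolerance = 1e-9)
  at_threshold <- tibble::tibble(straightness = 1 / 1.08)
  expect_equal(straight_fraction(at_threshold), 0)
  expect_error(straight_fraction(fibers[0, ]), "no fibers")
})

test_that("summarize_image composes the metrics deterministically", {
  f <- fixture_single_fiber
  s1 <- summarize_image(f$image)
  s2 <- summarize_image(f$image)
  expect_identical(s1, s2)
  expect_equal(s1$n_fibers, 1)
  expect_equal(s1$straight_threshold, 1 / 1.08)
  expect_error(summarize_image(matrix(1, 32, 32)), "64")
  # autofluorescence channel reduces the density
  af <- matrix(0.2, nrow(f$image), ncol(f$image))
  s3 <- summarize_image(f$image, autofluor = af, threshold = 0.3)
  expect_lt(s3$integrated_density, s1$integrated_density)
})

test_that("batch summaries read TIFFs in stable filename order", {
  dir <- tmp_dir()
  for (i in c(3, 1, 2)) {
    f <- render_fiber_field(fiber_field_params(image_size = 128,
                                               n_fibers = 6,
                                               length_mean = 60,
                                               seed = i))
    write_image_tiff(f$image, file.path(dir, sprintf("img_%d.tif", i)))
  }
  res <- summarize_images(list.files(dir, full.names = TRUE))
  expect_equal(res$file, sprintf("img_%d.tif", 1:3))
  expect_equal(nrow(res), 3)
})
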
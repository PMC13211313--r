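# Spectrum model: normalization, rendering, HSQC reconstruction.

test_that("min-max normalization follows its contract", {
  g <- ppm_grid(0, 2, 3)
  s <- spectrum_1d("H1", g, c(0, 2, 4))
  expect_equal(normalize_instance(s)$intensities, c(0, 0.5, 1))
  s2 <- spectrum_1d("H1", g, c(0, 0.5, 1))
  expect_equal(normalize_instance(s2)$intensities, c(0, 0.5, 1))
  expect_warning(z <- normalize_instance(spectrum_1d("H1", g, c(7, 7, 7))),
                 "constant")
  expect_equal(z$intensities, c(0, 0, 0))
})

test_that("normalization is idempotent and affine-invariant", {
  set.seed(1)
  g <- ppm_grid(0, 10, 50)
  for (i in 1:20) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    n1 <- normalize_instance(spectrum_1d("H1", g, x))
    n2 <- normalize_instance(spectrum_1d("H1", g, a * x + b))
    expect_equal(n1$intensities, n2$intensities, tolerance = 1e-12)
    expect_equal(normalize_instance(n1)$intensities, n1$intensities)
    expect_equal(min(n1$intensities), 0)
    expect_equal(max(n1$intensities), 1)
  }
})

test_that("1D rendering places and normalizes Gaussian lines", {
  g <- ppm_grid(0, 10, 2001)
  s <- render_peaklist_1d(peaklist_1d("H1", 2.0, 1), g, line_sigma = 0.05)
  pts <- grid_points(g)
  expect_equal(which.max(s$intensities), which.min(abs(pts - 2.0)))
  expect_equal(max(s$intensities), 1)
  # two equal distant peaks: two equal unit maxima, lower in between
  s2 <- render_peaklist_1d(peaklist_1d("H1", c(2, 8), c(1, 1)), g,
                           line_sigma = 0.05)
  i1 <- which.min(abs(pts - 2)); i2 <- which.min(abs(pts - 8))
  expect_equal(s2$intensities[i1], 1)
  expect_equal(s2$intensities[i2], 1)
  expect_lt(s2$intensities[which.min(abs(pts - 5))], 1e-6)
})

test_that("rendering matches a brute-force two-Gaussian evaluation", {
  g <- ppm_grid(0.9, 1.1, 401)
  sig <- 0.01
  s <- render_peaklist_1d(peaklist_1d("H1", c(1.0, 1.001), c(1, 1)), g,
                          line_sigma = sig, exact = TRUE)
  # independent double loop
  pts <- grid_points(g)
  ref <- numeric(length(pts))
  for (j in seq_along(pts)) {
    for (pk in c(1.0, 1.001)) {
      ref[j] <- ref[j] + exp(-(pts[j] - pk)^2 / (2 * sig^2))
    }
  }
  ref <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_equal(s$intensities, ref, tolerance = 1e-12)
})

test_that("rendering is linear in peak intensities before normalization", {
  pts <- grid_points(ppm_grid(0, 10, 500))
  y1 <- nmr2mol:::.deposit_gaussians(pts, c(2, 5), c(1, 2), 0.1)
  y2 <- nmr2mol:::.deposit_gaussians(pts, c(2, 5), c(3, 6), 0.1)
  expect_equal(3 * y1, y2, tolerance = 1e-12)
})

test_that("empty peak list yields a zero spectrum with a warning", {
  expect_warning(s <- render_peaklist_1d(peaklist_1d("H1")), "empty")
  expect_true(all(s$intensities == 0))
  expect_false(s$normalized)
})

test_that("HSQC reconstruction deposits, broadens and compresses", {
  hg <- ppm_grid(0, 12, 64); cg <- ppm_grid(0, 200, 64)
  s <- reconstruct_hsqc(peaklist_hsqc(3.0, 50.0, 1), hg, cg, h_sigma = 0.3)
  M <- s$intensities
  jc <- which.min(abs(grid_points(cg) - 50))
  expect_true(all(M[, -jc] == 0))
  expect_equal(max(M), 1)
  expect_equal(which.max(M[, jc]), which.min(abs(grid_points(hg) - 3.0)))
  # pre-normalization ratio of weak/strong maxima equals 0.001^0.3
  # (grids chosen so both peak centres lie exactly on grid points)
  hg2 <- ppm_grid(0, 12, 61); cg2 <- ppm_grid(0, 200, 51)
  s2 <- reconstruct_hsqc(peaklist_hsqc(c(2, 8), c(32, 152), c(1, 0.001)),
                         hg2, cg2, h_sigma = 0.3, power = 0.3)
  M2 <- s2$intensities
  j150 <- which.min(abs(grid_points(cg2) - 152))
  # normalized strong max is 1 and min is 0, so the weak column maximum IS
  # the pre-normalization ratio 0.001^0.3
  expect_equal(max(M2[, j150]), 0.001^0.3, tolerance = 1e-9)
  # power = 1 reproduces the unrescaled reconstruction
  sa <- reconstruct_hsqc(peaklist_hsqc(c(2, 8), c(30, 150), c(1, 0.4)),
                         hg, cg, h_sigma = 0.3, power = 1)
  raw <- matrix(0, 64, 64)
  hp <- grid_points(hg)
  raw[, which.min(abs(grid_points(cg) - 30))] <- exp(-(hp - 2)^2 / (2 * 0.3^2))
  raw[, which.min(abs(grid_points(cg) - 150))] <-
    0.4 * exp(-(hp - 8)^2 / (2 * 0.3^2))
  raw <- raw / max(raw)
  expect_equal(sa$intensities, raw, tolerance = 1e-6)
})

test_that("power compression preserves the intensity ranking", {
  set.seed(3)
  hg <- ppm_grid(0, 12, 32); cg <- ppm_grid(0, 200, 32)
  pk <- peaklist_hsqc(runif(6, 1, 11), runif(6, 10, 190), runif(6, 0.05, 1))
  s1 <- reconstruct_hsqc(pk, hg, cg, h_sigma = 0.3, power = 1)
  sp <- reconstruct_hsqc(pk, hg, cg, h_sigma = 0.3, power = 0.3)
  expect_identical(order(s1$intensities), order(sp$intensities))
})

test_that("peaks outside both grids are dropped with a warning", {
  hg <- ppm_grid(0, 12, 16); cg <- ppm_grid(0, 200, 16)
  expect_warning(s <- reconstruct_hsqc(peaklist_hsqc(c(3, 20), c(50, 300),
                                                     c(1, 1)), hg, cg),
                 "dropped")
  expect_warning(z <- reconstruct_hsqc(peaklist_hsqc(), hg, cg), "empty")
  expect_true(all(z$intensities == 0))
})

test_that("reference/solvent windows zero out", {
  g <- ppm_grid(0, 10, 1001)
  s <- render_peaklist_1d(peaklist_1d("H1", c(1.0, 7.26), c(1, 1)), g,
                          line_sigma = 0.005)
  z <- zero_shift_windows(s)
  pts <- grid_points(g)
  expect_true(all(z$intensities[pts >= 7.24 & pts <= 7.28] == 0))
  expect_gt(max(z$intensities[pts > 0.9 & pts < 1.1]), 0.9)
})
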
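# Local evidence scores and candidate re-ranking.

test_that("uniform and empty spectra give the boundary scores", {
  g <- ppm_grid(0, 10, 200)
  ones <- spectrum_1d("H1", g, rep(1, 200), normalized = TRUE)
  expect_equal(evidence_score_1d(ones, c(1, 5, 9.5), 0.2), 1)
  zero <- spectrum_1d("H1", g, rep(0, 200), normalized = TRUE)
  expect_equal(evidence_score_1d(zero, c(2, 3), 0.2), 0)
  expect_error(evidence_score_1d(ones, numeric(0), 0.2), "empty")
  raw <- spectrum_1d("H1", g, runif(200))
  expect_error(evidence_score_1d(raw, 1, 0.2), "normalized")
})

test_that("1D score rewards shifts near real intensity and matches the
           brute-force sum", {
  g <- ppm_grid(0, 10, 1000)
  spec <- render_peaklist_1d(peaklist_1d("H1", 2.0, 1), g, line_sigma = 0.05)
  s_on <- evidence_score_1d(spec, 2.0, 0.2, exact = TRUE)
  s_off <- evidence_score_1d(spec, 8.0, 0.2, exact = TRUE)
  expect_gt(s_on, s_off)
  # independent double summation
  brute <- function(y, pts, shifts, sigma) {
    tot <- 0
    for (s in shifts) {
      num <- 0; den <- 0
      for (j in seq_along(pts)) {
        k <- exp(-(pts[j] - s)^2 / (2 * sigma^2))
        num <- num + k * y[j]; den <- den + k
      }
      tot <- tot + num / den
    }
    tot / length(shifts)
  }
  pts <- grid_points(g)
  expect_equal(s_on, brute(spec$intensities, pts, 2.0, 0.2),
               tolerance = 1e-9)
  expect_equal(s_off, brute(spec$intensities, pts, 8.0, 0.2),
               tolerance = 1e-9)
  # truncated default agrees with the exact mode to high precision
  expect_equal(evidence_score_1d(spec, 2.0, 0.2), s_on, tolerance = 1e-9)
})

test_that("appending a dead-region shift strictly lowers a positive score", {
  g <- ppm_grid(0, 10, 1000)
  spec <- render_peaklist_1d(peaklist_1d("H1", c(1.5, 3.2), c(2, 1)), g,
                             line_sigma = 0.03)
  base <- evidence_score_1d(spec, c(1.5, 3.2), 0.1)
  worse <- evidence_score_1d(spec, c(1.5, 3.2, 8.5), 0.1)
  expect_gt(base, 0)
  expect_lt(worse, base)
})

test_that("score is invariant to positive rescaling before normalization", {
  g <- ppm_grid(0, 10, 500)
  set.seed(2)
  x <- abs(rnorm(500))
  s1 <- normalize_instance(spectrum_1d("H1", g, x))
  s2 <- normalize_instance(spectrum_1d("H1", g, 37 * x))
  expect_equal(evidence_score_1d(s1, c(2, 5), 0.2),
               evidence_score_1d(s2, c(2, 5), 0.2), tolerance = 1e-12)
})

test_that("HSQC score matches brute force and is local", {
  hg <- ppm_grid(0, 12, 64); cg <- ppm_grid(0, 200, 64)
  spec <- reconstruct_hsqc(peaklist_hsqc(3.0, 50.0, 1), hg, cg,
                           h_sigma = 0.3)
  on <- evidence_score_hsqc(spec, cbind(3.0, 50.0), 0.2, 2.0, exact = TRUE)
  off <- evidence_score_hsqc(spec, cbind(3.0, 120.0), 0.2, 2.0, exact = TRUE)
  expect_gt(on, off)
  brute2 <- function(M, hp, cp, pairs, sh, sc) {
    tot <- 0
    for (i in seq_len(nrow(pairs))) {
      num <- 0; den <- 0
      for (a in seq_along(hp)) for (b in seq_along(cp)) {
        k <- exp(-(hp[a] - pairs[i, 1])^2 / (2 * sh^2)) *
          exp(-(cp[b] - pairs[i, 2])^2 / (2 * sc^2))
        num <- num + k * M[a, b]; den <- den + k
      }
      tot <- tot + num / den
    }
    tot / nrow(pairs)
  }
  expect_equal(on, brute2(spec$intensities, grid_points(hg), grid_points(cg),
                          cbind(3.0, 50.0), 0.2, 2.0), tolerance = 1e-9)
})

test_that("toy predictor mirrors the generator's shifts deterministically", {
  p1 <- toy_shift_predictor("CCO")
  p2 <- toy_shift_predictor("CCO")
  expect_identical(p1, p2)
  expect_identical(nrow(p1$c), 2L)
  expect_identical(nrow(p1$h), 3L)
  sa <- assign_toy_shifts("CCO")
  expect_identical(p1$c$shift, sa$c$shift)
  expect_error(toy_shift_predictor("C(C"), "invalid")
})

test_that("re-ranking promotes the spectrum-consistent candidate", {
  # true molecule among C4H10O isomers, planted at source rank 5
  truth <- "CCCCO"
  decoys <- c("CC(C)CO", "CCC(C)O", "CC(C)(C)O", "CCOCC")
  pool <- data.frame(smiles = c(decoys, truth),
                     log_prob = c(-1, -1.5, -2, -2.5, -3),
                     source_rank = 1:5, stringsAsFactors = FALSE)
  spectra <- simulate_record(truth, modalities = "C13", noise_sd = 0, seed = 1)
  rr <- rerank_candidates(pool, spectra)
  expect_identical(rr$smiles[1], truth)
  expect_true(all(c("evidence_score", "rerank") %in% names(rr)))
  # single candidate: order unchanged, score populated
  one <- rerank_candidates(pool[1, ], spectra)
  expect_identical(one$smiles, pool$smiles[1])
  expect_true(is.finite(one$evidence_score))
})

test_that("ties keep log-probability order and failures rank last", {
  truth <- "CCCO"
  spectra <- simulate_record(truth, modalities = "C13", noise_sd = 0, seed = 1)
  pool <- data.frame(smiles = c(truth, truth, truth),
                     log_prob = c(-1, -2, -3),
                     source_rank = 1:3, stringsAsFactors = FALSE)
  rr <- rerank_candidates(pool, spectra)
  expect_identical(rr$log_prob, c(-1, -2, -3))
  bad_predictor <- function(s) {
    if (s == "CCCO") stop("no prediction")
    assign_toy_shifts(s)
  }
  pool2 <- data.frame(smiles = c(truth, "CC(C)O"), log_prob = c(-1, -2),
                      source_rank = 1:2, stringsAsFactors = FALSE)
  expect_warning(rr2 <- rerank_candidates(pool2, spectra,
                                          predictor = bad_predictor),
                 "scored")
  expect_identical(rr2$smiles[2], truth)      # failure ranked last, kept
  expect_identical(rr2$evidence_score[2], -Inf)
})
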
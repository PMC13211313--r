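# Toy molecule grammar, shift rules, spectrum simulation and dataset splits.

test_that("molecule generation is deterministic, bounded and unique", {
  m1 <- generate_toy_molecules(40, seed = 7, heavy_range = c(5, 9))
  m2 <- generate_toy_molecules(40, seed = 7, heavy_range = c(5, 9))
  expect_identical(m1, m2)
  expect_true(all(m1$heavy_atoms >= 5 & m1$heavy_atoms <= 9))
  expect_false(any(duplicated(m1$smiles)))
  expect_true(all(smiles_is_valid(m1$smiles)))
  # canonical dedup: every SMILES already is its own canonical form
  expect_identical(canonicalize_nonstereo(m1$smiles), m1$smiles)
})

test_that("environment counting matches molecular symmetry", {
  sa <- assign_toy_shifts("CCO")
  expect_identical(nrow(sa$h), 3L)   # CH3, CH2, OH
  expect_identical(nrow(sa$c), 2L)
  expect_identical(nrow(sa$hc), 2L)
  sb <- assign_toy_shifts("c1ccccc1")
  expect_identical(nrow(sb$h), 1L)
  expect_identical(nrow(sb$c), 1L)
  expect_equal(sb$h$weight, 6)
  expect_equal(sb$c$weight, 6)
  expect_error(assign_toy_shifts("CCS"), "element")
})

test_that("shift rule table agrees with an independent implementation", {
  # independent flat reimplementation of the sp3-carbon rules for simple
  # unbranched molecules (no rings, no carbonyls)
  indep_ethane <- function() {
    # each carbon: 1 C neighbour, 3 H; second shell = 0
    c_shift <- 6 + 9.4 * 1
    h_shift <- 0.23 + 0.47 * 1
    list(c = c_shift, h = h_shift)
  }
  sa <- assign_toy_shifts("CC")
  ref <- indep_ethane()
  expect_equal(sa$c$shift, ref$c)
  expect_equal(sa$h$shift, ref$h)
  expect_equal(sa$c$weight, 2)
  expect_equal(sa$h$weight, 6)
  # propane: terminal CH3 (1C nbr, second shell 1) and central CH2 (2 C nbr)
  sb <- assign_toy_shifts("CCC")
  ref_end <- 6 + 9.4 * 1 + 0.9 * 1
  ref_mid <- 6 + 9.4 * 2
  expect_setequal(round(sb$c$shift, 6), round(c(ref_end, ref_mid), 6))
})

test_that("simulation is deterministic and sparse", {
  r1 <- simulate_record("CCO", modalities = c("H1", "C13"), noise_sd = 0,
                        seed = 5)
  r2 <- simulate_record("CCO", modalities = c("H1", "C13"), noise_sd = 0,
                        seed = 5)
  expect_identical(r1$H1$intensities, r2$H1$intensities)
  expect_identical(r1$C13$intensities, r2$C13$intensities)
  # noisy simulation is still seed-deterministic
  n1 <- simulate_record("CCO", modalities = "H1", noise_sd = 0.01, seed = 9)
  n2 <- simulate_record("CCO", modalities = "H1", noise_sd = 0.01, seed = 9)
  expect_identical(n1$H1$intensities, n2$H1$intensities)
  # sparsity: few 13C grid points carry signal for small molecules
  mols <- generate_toy_molecules(15, seed = 11, heavy_range = c(5, 9))
  frac <- vapply(mols$smiles, function(s) {
    sp <- simulate_record(s, modalities = "C13", noise_sd = 0, seed = 1)
    mean(sp$C13$intensities > 0.01)
  }, numeric(1))
  expect_lt(mean(frac), 0.05)
})

test_that("a molecule with no C-H pairs gives an empty HSQC", {
  expect_warning(r <- simulate_record("OC(=O)O", modalities = "HSQC",
                                      noise_sd = 0, seed = 1),
                 "empty")
  expect_true(all(r$HSQC$intensities == 0))
})

test_that("HSQC cross-peaks coincide with assigned shift pairs", {
  sa <- assign_toy_shifts("CCO")
  expect_true(all(sa$hc$h %in% sa$h$shift))
  expect_true(all(sa$hc$c %in% sa$c$shift))
})

test_that("largest-remainder split hits the exact ratios", {
  expect_identical(nmr2mol:::.largest_remainder(1000, c(7, 2, 1)),
                   c(700L, 200L, 100L))
  expect_identical(nmr2mol:::.largest_remainder(13, c(7, 2, 1)),
                   c(9L, 3L, 1L))
  expect_identical(sum(nmr2mol:::.largest_remainder(17, c(7, 2, 1))), 17L)
})

test_that("build_dataset writes disjoint reproducible splits", {
  d1 <- file.path(tempdir(), "bd1"); d2 <- file.path(tempdir(), "bd2")
  m1 <- build_dataset(13, d1, seed = 5, modalities = "H1", noise_sd = 0,
                      heavy_range = c(5, 8))
  m2 <- build_dataset(13, d2, seed = 5, modalities = "H1", noise_sd = 0,
                      heavy_range = c(5, 8))
  sizes <- vapply(m1, function(m) length(m$records), integer(1))
  expect_identical(unname(sizes), c(9L, 3L, 1L))
  smi <- lapply(m1, function(m) vapply(m$records, `[[`, character(1), "smiles"))
  expect_length(intersect(smi$train, smi$valid), 0L)
  expect_length(intersect(smi$train, smi$test), 0L)
  # same seed, same molecules and same spectra bytes
  expect_identical(smi$train,
                   vapply(m2$train$records, `[[`, character(1), "smiles"))
  s1 <- read_spectrum(m1$train$records[[1]]$files$H1)
  s2 <- read_spectrum(m2$train$records[[1]]$files$H1)
  expect_identical(s1$intensities, s2$intensities)
  # manifests re-read losslessly
  rr <- read_manifest(file.path(d1, "train.jsonl"))
  expect_identical(vapply(rr$records, `[[`, character(1), "smiles"), smi$train)
})
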
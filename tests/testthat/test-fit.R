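# Optimization: schedule, loss masking, training determinism, fine-tuning
# guards, and the S3 interface surface.

test_that("learning-rate schedule warms up linearly then decays by cosine", {
  expect_equal(lr_at_step(0, 3e-4, 100, 1000), 0)
  expect_equal(lr_at_step(100, 3e-4, 100, 1000), 3e-4)
  expect_equal(lr_at_step(50, 3e-4, 100, 1000), 1.5e-4)
  expect_equal(lr_at_step(1000, 3e-4, 100, 1000), 0)
  expect_equal(lr_at_step(550, 3e-4, 100, 1000), 3e-4 * 0.5 *
                 (1 + cos(pi * 0.5)), tolerance = 1e-12)
  expect_equal(lr_at_step(5000, 3e-4, 100, 1000), 0)  # clamp past the end
  # continuity at the junction and non-negativity everywhere
  lrs <- vapply(0:1000, lr_at_step, numeric(1), 3e-4, 100, 1000)
  expect_true(all(lrs >= 0))
  expect_lt(abs(lr_at_step(101, 3e-4, 100, 1000) -
                  lr_at_step(99, 3e-4, 100, 1000)), 1e-5)
})

test_that("loss and gradients ignore formula-prefix and pad positions", {
  logits <- matrix(rnorm(8 * 5), 8, 5)
  targets <- c(NA, NA, 2L, 4L, NA, 1L, 0L, NA)
  ce <- nmr2mol:::.ce_fwd_bwd(logits, targets)
  expect_true(all(ce$dlogits[is.na(targets), ] == 0))
  # changing logits at masked rows leaves the loss unchanged
  logits2 <- logits
  logits2[1, ] <- rnorm(5)
  expect_equal(nmr2mol:::.ce_fwd_bwd(logits2, targets)$loss, ce$loss)
})

test_that("training is deterministic and records its history", {
  mols <- generate_toy_molecules(16, seed = 21, heavy_range = c(5, 7))
  grids <- list(H1 = ppm_grid(0, 10, 20))
  man <- memory_manifest(mols, seed = 2, grids = grids, line_sigma_h = 0.3)
  cfg <- tiny_cfg(modalities = "H1")
  ctrl <- nmr2mol_control(lr_peak = 1e-3, warmup_steps = 2, epochs = 2,
                          batch_size = 8, seed = 3)
  f1 <- nmr2mol(man, config = cfg, control = ctrl, grids = grids)
  f2 <- nmr2mol(man, config = cfg, control = ctrl, grids = grids)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(nmr2mol:::.tree_unlist(f1$params),
                   nmr2mol:::.tree_unlist(f2$params))
  expect_s3_class(f1, "nmr2mol")
  expect_identical(nrow(f1$history), 2L)
  expect_output(print(f1), "transformer")
  expect_type(coef(f1), "list")
  f <- tempfile(fileext = ".rds")
  save_checkpoint(f1, f)
  expect_s3_class(load_checkpoint(f), "nmr2mol")
})

test_that("fine-tuning guards its vocabulary and zero epochs is identity", {
  mols <- generate_toy_molecules(12, seed = 31, heavy_range = c(5, 7))
  grids <- list(H1 = ppm_grid(0, 10, 20))
  man <- memory_manifest(mols, seed = 2, grids = grids, line_sigma_h = 0.3)
  cfg <- tiny_cfg(modalities = "H1")
  ctrl <- nmr2mol_control(lr_peak = 1e-3, warmup_steps = 2, epochs = 1,
                          batch_size = 6, seed = 3)
  fit <- nmr2mol(man, config = cfg, control = ctrl, grids = grids)
  ft0 <- finetune(fit, man, control = nmr2mol_control(lr_peak = 1e-4,
                                                      epochs = 0L,
                                                      warmup_steps = 1L))
  expect_identical(nmr2mol:::.tree_unlist(ft0$params),
                   nmr2mol:::.tree_unlist(fit$params))
  # a corpus with tokens outside the vocabulary is refused
  man2 <- man
  man2$records[[1]]$smiles <- "CCS"
  man2$records[[1]]$formula <- "C2H6S"
  expect_error(finetune(fit, man2), "missing tokens")
})

test_that("warmup longer than the schedule is rejected", {
  mols <- generate_toy_molecules(10, seed = 41, heavy_range = c(5, 7))
  man <- memory_manifest(mols, seed = 2, grids = list(H1 = ppm_grid(0, 10, 20)),
                         line_sigma_h = 0.3)
  expect_error(
    nmr2mol(man, config = tiny_cfg(modalities = "H1"),
            control = nmr2mol_control(epochs = 1, batch_size = 10,
                                      warmup_steps = 500),
            grids = list(H1 = ppm_grid(0, 10, 20))),
    "warmup")
})
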
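# Desk-scale trained-model fixture shared by the end-to-end tests.
# Built lazily once per test session: a 2,000-record noiseless 1H toy
# dataset, the d=128 / 2+2-layer model trained on its training split, and a
# 200-record evaluation of beam candidates on the validation split.

.fixture_env <- new.env(parent = emptyenv())

fixture_config <- function() {
  nmr2mol_config(d_model = 128L, n_encoder_layers = 2L, n_decoder_layers = 2L,
                 n_heads = 4L, ff_dim = 256L, patch_len_1d = 200L,
                 patch_dropout_rate = 0.5, max_decode_len = 64L,
                 modalities = "H1")
}

fixture_dataset <- function() {
  if (!is.null(.fixture_env$mans)) return(.fixture_env$mans)
  mols <- generate_toy_molecules(2000, seed = 42)
  sizes <- nmr2mol:::.largest_remainder(2000, c(7, 2, 1))
  splits <- rep(c("train", "valid", "test"), times = sizes)
  mans <- lapply(c(train = "train", valid = "valid", test = "test"),
                 function(sp) {
                   memory_manifest(mols[splits == sp, , drop = FALSE],
                                   split = sp, seed = 42, modalities = "H1",
                                   noise_sd = 0)
                 })
  .fixture_env$mans <- mans
  mans
}

fixture_model <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  mans <- fixture_dataset()
  ctrl <- nmr2mol_control(lr_peak = 1e-3, warmup_steps = 100L, epochs = 15L,
                          batch_size = 32L, seed = 42L)
  .fixture_env$fit <- nmr2mol(mans$train, mans$valid, config = fixture_config(),
                              control = ctrl)
  .fixture_env$fit
}

# beam-candidate evaluation of the fixture model on 100 validation records
fixture_eval <- function() {
  if (!is.null(.fixture_env$report)) return(.fixture_env$report)
  mans <- fixture_dataset()
  sub <- mans$valid
  sub$records <- sub$records[seq_len(100)]
  .fixture_env$report <- evaluate_topk(fixture_model(), sub,
                                       k_list = c(1L, 5L, 10L),
                                       beam_width = 10L)
  .fixture_env$report
}

fixture_valid_targets <- function(n = 100L) {
  mans <- fixture_dataset()
  vapply(mans$valid$records[seq_len(n)], `[[`, character(1), "smiles")
}
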
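# Shared test fixtures, built in code.

# tiny vocabulary handy for model-shape tests
tiny_vocab <- function() {
  toks <- c("<pad>", "<bos>", "<eos>", "<unk>", "<fpad>",
            "C", "O", "N", "c", "1", "(", ")", "=", "Cl", "Br", "F",
            "H", "2", "3", "4", "5", "6", "7", "8", "9", "0")
  ids <- seq_along(toks) - 1L
  names(ids) <- toks
  nmr2mol:::.new_vocab(ids)
}

tiny_cfg <- function(...) {
  nmr2mol_config(d_model = 16L, n_encoder_layers = 1L, n_decoder_layers = 1L,
                 n_heads = 2L, ff_dim = 32L, patch_len_1d = 5L,
                 patch_size_2d = 4L, patch_dropout_rate = 0.5,
                 max_decode_len = 48L, ...)
}

tiny_grids <- function() {
  nmr2mol:::.full_grids(list(H1 = ppm_grid(0, 10, 20),
                             C13 = ppm_grid(0, 200, 20),
                             HSQC_H = ppm_grid(0, 10, 8),
                             HSQC_C = ppm_grid(0, 200, 8)))
}

# In-memory manifest (records carry spectra directly, no files) for fast
# training tests.
memory_manifest <- function(mols, split = "train", seed = 1L,
                            modalities = "H1", noise_sd = 0, grids = list(),
                            ...) {
  recs <- lapply(seq_len(nrow(mols)), function(i) {
    list(smiles = mols$smiles[i], formula = mols$formula[i],
         heavy_atoms = mols$heavy_atoms[i], files = list(),
         spectra = simulate_record(mols$smiles[i], modalities = modalities,
                                   noise_sd = noise_sd, grids = grids,
                                   seed = seed + 13L * i, ...))
  })
  structure(list(split = split, seed = as.integer(seed), records = recs),
            class = "dataset_manifest")
}

# random patch_tokens stream for dropout tests
random_patch_tokens <- function(n, d = 8L, seed = 1L) {
  set.seed(seed)
  structure(list(X = matrix(rnorm(n * d), n, d),
                 modality = rep("H1", n), position = seq_len(n)),
            class = "patch_tokens")
}
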
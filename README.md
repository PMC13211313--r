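# nmr2mol — spectrum-to-structure elucidation from raw multimodal NMR

`nmr2mol` is an R package for end-to-end molecular structure elucidation
from raw NMR spectra. It is aimed at computational chemists and method
developers who want a complete, desk-scale, fully inspectable implementation
of the raw-spectrum transformer approach: no peak picking, no multiplicity
symbols — the model reads dense intensity vectors (1D ¹H and ¹³C) and 2D
HSQC intensity matrices directly and writes SMILES strings.

## The model

Spectra live on discrete chemical-shift grids: a 1D spectrum is a length-10,000
intensity vector *y*(δ), an HSQC spectrum a 256×256 matrix over (δ_H, δ_C).
Each spectrum is min–max normalized per instance to [0, 1], cut into
non-overlapping patches (contiguous 1D segments; flattened 2D squares),
projected into a shared latent space by a modality-specific linear embedding
with learnable positional embeddings, and concatenated across modalities
into a single token stream. During training, *patch dropout* removes a fixed
fraction of the fused tokens uniformly at random (exactly
round((1−r)·n) survive); at inference all patches are kept. A pre-norm
transformer encoder processes the stream, and an autoregressive transformer
decoder generates the SMILES token sequence through cross-attention,
conditioned additionally on a molecular-formula prompt written into a fixed
16-token prefix of the decoder input. Training minimizes cross-entropy over
SMILES positions only (prefix and padding masked), with AdamW under a linear
warmup (default 10,000 steps) + cosine-decay schedule from a peak learning
rate of 3×10⁻⁴. Accuracy is exact match of canonical, non-stereochemical
SMILES; beam search yields top-*k* candidate lists.

Candidates are post-processed in two steps:

1. **Filtering** — chemically invalid SMILES and candidates whose Hill
   formula (implicit hydrogens included) disagrees with the known formula
   are dropped; duplicates that canonicalize to one molecule are collapsed;
   up to 100 molecules are retained.
2. **Re-ranking by local spectral evidence** — given predicted shifts
   {s_i} for a candidate (from any shift predictor; a deterministic
   rule-table predictor ships with the package), the score is the mean over
   shifts of the Gaussian-kernel weighted local average intensity,

   S = (1/N) Σ_i [ Σ_j K(δ_j − s_i) y(δ_j) / Σ_j K(δ_j − s_i) ],

   with bandwidth σ set per nucleus (defaults σ_H = 0.2 ppm,
   σ_C = 2.0 ppm). The score is bounded in [0, 1] and rewards structures
   whose predicted shifts sit on observed intensity. HSQC uses the separable
   2D kernel on a power-0.3 compressed reconstruction.

Because no deep-learning framework is available to R here, the transformer,
its backpropagation and AdamW are implemented in base R over BLAS; a
finite-difference gradient check in the test suite pins the implementation
down.

A deterministic toy simulator (fragment-grammar molecules, additive shift
rules, Gaussian line rendering) makes the whole pipeline trainable in
minutes on one CPU, so every claim in the test suite is reproducible from
scratch.

## Worked example

```r
library(nmr2mol)

# 1. a 120-molecule toy dataset, 7:2:1 split, 1H-only, noiseless
mans <- build_dataset(120, tempfile("toy"), seed = 7,
                      modalities = "H1", noise_sd = 0)

# 2. train a small model
fit <- nmr2mol(mans$train, mans$valid,
               config = nmr2mol_config(d_model = 64, patch_len_1d = 100),
               control = nmr2mol_control(lr_peak = 1e-3, warmup_steps = 20,
                                         epochs = 10, batch_size = 16,
                                         seed = 1))
print(fit)
#> Spectrum-to-structure transformer (H1)
#>   d_model 64, 2+2 layers, 4 heads, 251,226 parameters
#>   trained 10 epochs (60 steps); final train loss 1.5355, best valid loss 1.5569

# 3. predict candidates for a held-out record
rec <- mans$test$records[[1]]
spectra <- lapply(rec$files, read_spectrum)
cands <- predict(fit, spectra, rec$formula, beam_width = 10,
                 type = "candidates")
head(cands[, c("smiles", "log_prob", "is_valid", "formula_ok")])
#>   smiles  log_prob is_valid formula_ok
#> 1        -2.977868    FALSE      FALSE
#> 2      C -3.638395    FALSE      FALSE
#> 3     CC -4.338205     TRUE      FALSE
#> 4    CCC -5.034636     TRUE      FALSE
#> 5  CCCCC -6.180758     TRUE      FALSE
#> 6 CCCCCC -6.913692     TRUE      FALSE

# 4. filter to valid, formula-consistent molecules and re-rank by
#    chemical-shift evidence
kept <- filter_candidates(cands, rec$formula)
rerank_candidates(kept, spectra)
```

A model this small, trained for only 60 steps, has not learned the mapping
yet: its beams are short alkane stubs, none formula-consistent, so the
filtered list is empty. That is the honest output at this budget — the
loss falling from ~3.1 to ~1.5 shows optimization working. The test suite
trains the same architecture properly (2,000 records, 15 epochs) and
reaches validation top-1 exact-match accuracy far above the permuted-target
chance level, and the acceptance script does the same at 1,000 records. The printed candidate table shows beam-ranked SMILES with their
cumulative log-probabilities and the validity/formula flags that the filter
uses; `rerank_candidates` appends the evidence score in [0, 1] and the new
rank.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/nmr2mol.R simulate --n 1000 --seed 7 --out toydata
Rscript inst/cli/nmr2mol.R train --data toydata --out model.rds --epochs 15
Rscript inst/cli/nmr2mol.R evaluate --model model.rds --manifest toydata/test.jsonl
```

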
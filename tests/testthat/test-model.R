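# Model mechanics: patchify, fusion, patch dropout, encoder/decoder
# contracts and the gradient check anchoring the hand-written backprop.

test_that("1D patchify partitions and inverts losslessly", {
  x <- rnorm(10000)
  p <- patchify_1d(x, 50L)
  expect_identical(dim(p), c(200L, 50L))
  expect_identical(unpatchify_1d(p), x)
  p1 <- patchify_1d(x, 10000L)
  expect_identical(nrow(p1), 1L)
  expect_identical(as.vector(p1), x)
  expect_error(patchify_1d(x, 300L), "does not divide")
})

test_that("2D patchify partitions and inverts losslessly", {
  M <- matrix(rnorm(256 * 256), 256, 256)
  p <- patchify_2d(M, 16L)
  expect_identical(dim(p), c(256L, 256L))
  expect_identical(unpatchify_2d(p, 256L, 256L, 16L), M)
  p1 <- patchify_2d(M, 256L)
  expect_identical(nrow(p1), 1L)
  expect_error(patchify_2d(M, 100L), "does not divide")
  # first patch is the top-left block flattened row-major
  expect_identical(p[1, 1:16], M[1, 1:16])
})

test_that("fusion concatenates modality streams in config order", {
  cfg <- tiny_cfg(modalities = c("H1", "C13", "HSQC"))
  grids <- tiny_grids()
  vocab <- tiny_vocab()
  params <- init_params(cfg, vocab, grids, seed = 2)
  ph <- matrix(runif(4 * 5), 4, 5)    # 20-point grid, patch 5
  pc <- matrix(runif(4 * 5), 4, 5)
  p2 <- matrix(runif(4 * 16), 4, 16)  # 8x8 grid, patch 4
  fused <- embed_and_fuse(list(H1 = ph, C13 = pc, HSQC = p2), params, cfg)
  expect_identical(nrow(fused$X), 12L)
  expect_identical(fused$modality, rep(c("H1", "C13", "HSQC"), each = 4))
  single <- embed_and_fuse(list(H1 = ph), params, cfg)
  expect_identical(single$X, fused$X[1:4, ])
  # projections are modality-specific: swapping spectra changes the output
  swapped <- embed_and_fuse(list(H1 = pc, C13 = ph, HSQC = p2), params, cfg)
  expect_false(isTRUE(all.equal(swapped$X, fused$X)))
})

test_that("patch dropout keeps an exact uniform subset in training only", {
  tok <- random_patch_tokens(40)
  expect_identical(patch_dropout(tok, 0, TRUE)$X, tok$X)
  expect_identical(patch_dropout(tok, 0.7, FALSE)$X, tok$X)
  set.seed(4)
  kept <- patch_dropout(tok, 0.5, TRUE)
  expect_identical(nrow(kept$X), 20L)
  idx <- attr(kept, "kept")
  expect_identical(idx, sort(idx))            # order preserved
  expect_identical(kept$position, tok$position[idx])
  expect_identical(kept$X, tok$X[idx, ])
  expect_error(patch_dropout(tok, 1.0, TRUE), "rate")
})

test_that("encoder output has the right shape and is deterministic", {
  cfg <- tiny_cfg(modalities = "H1")
  vocab <- tiny_vocab()
  grids <- tiny_grids()
  params <- init_params(cfg, vocab, grids, seed = 7)
  X <- matrix(rnorm(4 * cfg$d_model), 4, cfg$d_model)
  e1 <- nmr2mol:::.encoder_stack_fwd(params, cfg, X, 1L, 4L)$Y
  e2 <- nmr2mol:::.encoder_stack_fwd(params, cfg, X, 1L, 4L)$Y
  expect_identical(dim(e1), c(4L, 16L))
  expect_identical(e1, e2)
  # permutation equivariance: positions travel with the tokens
  perm <- c(3L, 1L, 4L, 2L)
  ep <- nmr2mol:::.encoder_stack_fwd(params, cfg, X[perm, ], 1L, 4L)$Y
  expect_equal(ep, e1[perm, ], tolerance = 1e-12)
})

test_that("decoder respects causality, the prompt and the memory", {
  cfg <- tiny_cfg(modalities = "H1")
  vocab <- tiny_vocab()
  params <- init_params(cfg, vocab, tiny_grids(), seed = 8)
  M <- matrix(rnorm(4 * cfg$d_model), 4, cfg$d_model)
  ids <- matrix(c(5L, 6L, 1L, 5L, 7L, 5L), 1, 6)
  l0 <- nmr2mol:::.decoder_stack_fwd(params, cfg, ids, M, 1L, 4L)$logits
  # changing a future token leaves earlier logits unchanged
  ids2 <- ids; ids2[1, 6] <- 9L
  l1 <- nmr2mol:::.decoder_stack_fwd(params, cfg, ids2, M, 1L, 4L)$logits
  expect_equal(l0[1:5, ], l1[1:5, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(l0[6, ], l1[6, ])))
  # changing the formula prefix changes later logits
  ids3 <- ids; ids3[1, 1] <- 8L
  l2 <- nmr2mol:::.decoder_stack_fwd(params, cfg, ids3, M, 1L, 4L)$logits
  expect_false(isTRUE(all.equal(l0[6, ], l2[6, ])))
  # cross-attention is live: zeroed memory changes the logits
  l3 <- nmr2mol:::.decoder_stack_fwd(params, cfg, ids, M * 0, 1L, 4L)$logits
  expect_false(isTRUE(all.equal(l0, l3)))
  expect_error(nmr2mol:::.decoder_stack_fwd(params, cfg,
                                            matrix(0L, 1, 60), M, 1L, 4L),
               "max_decode_len")
})

test_that("adding a modality only adds its embedding parameters", {
  vocab <- tiny_vocab(); grids <- tiny_grids()
  p1 <- init_params(tiny_cfg(modalities = "H1"), vocab, grids, seed = 1)
  p2 <- init_params(tiny_cfg(modalities = c("H1", "C13")), vocab, grids,
                    seed = 1)
  extra <- length(nmr2mol:::.tree_unlist(p2)) -
    length(nmr2mol:::.tree_unlist(p1))
  emb <- p2$embed$C13
  expect_identical(extra, length(nmr2mol:::.tree_unlist(emb)))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- nmr2mol_config(d_model = 8L, n_encoder_layers = 2L,
                        n_decoder_layers = 2L, n_heads = 2L, ff_dim = 16L,
                        patch_len_1d = 5L, patch_size_2d = 4L,
                        patch_dropout_rate = 0.5, max_decode_len = 12L,
                        modalities = c("H1", "HSQC"))
  grids <- tiny_grids()
  vocab <- tiny_vocab()
  params <- init_params(cfg, vocab, grids, seed = 5)
  B <- 2L
  batch <- list(
    patch_mats = list(H1 = matrix(runif(B * 4 * 5), B * 4, 5),
                      HSQC = matrix(runif(B * 4 * 16), B * 4, 16)),
    kept = list(sort(sample.int(8, 5)), sort(sample.int(8, 5))),
    dec_ids = matrix(sample(0:9, B * 7, TRUE), B, 7),
    targets = matrix(c(NA, NA, sample(0:9, 5, TRUE),
                       NA, sample(0:9, 6, TRUE)), B, 7, byrow = TRUE))
  out <- nmr2mol:::.train_step_fwd_bwd(params, cfg, batch, grids)
  flatp <- nmr2mol:::.tree_unlist(params)
  flatg <- nmr2mol:::.tree_unlist(out$grads)
  loss_at <- function(vec) {
    p2 <- nmr2mol:::.tree_relist(params, vec)$node
    nmr2mol:::.train_step_fwd_bwd(p2, cfg, batch, grids,
                                  want_grad = FALSE)$loss
  }
  idx <- sample(seq_along(flatp), 60)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    v1 <- flatp; v1[i] <- v1[i] + eps
    v2 <- flatp; v2[i] <- v2[i] - eps
    (loss_at(v1) - loss_at(v2)) / (2 * eps)
  }, numeric(1))
  ana <- flatg[idx]
  rel <- abs(num - ana) / pmax(abs(num) + abs(ana), 1e-8)
  # almost all coordinates agree tightly; a few may sit near the ReLU kink
  # where the finite difference itself is biased at this step size
  expect_gte(mean(rel < 1e-3), 0.95)
  expect_lt(max(rel), 0.05)
})
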
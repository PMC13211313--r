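# Patch-based multimodal encoder and formula-prompted autoregressive decoder:
# configuration, parameter initialization, patchify/unpatchify, modality
# embedding + concatenation fusion, patch dropout, and the full batched
# forward/backward pass used by training.

#' Model configuration
#'
#' @param d_model latent width (divisible by `n_heads`).
#' @param n_encoder_layers,n_decoder_layers transformer depth.
#' @param n_heads attention heads.
#' @param ff_dim feed-forward width.
#' @param patch_len_1d contiguous 1D patch length (must divide the 1D grid).
#' @param patch_size_2d square 2D patch edge (must divide both HSQC dims).
#' @param patch_dropout_rate fraction of fused patch tokens removed during
#'   training (in `[0, 1)`); disabled at inference.
#' @param max_decode_len maximum decoder sequence length, counting the
#'   formula prefix.
#' @param modalities ordered character vector, subset of
#'   `c("H1", "C13", "HSQC")`; fixes the fusion order.
#' @return an object of class `nmr2mol_config`.
#' @export
nmr2mol_config <- function(d_model = 128L, n_encoder_layers = 2L,
                           n_decoder_layers = 2L, n_heads = 4L,
                           ff_dim = 256L, patch_len_1d = 50L,
                           patch_size_2d = 16L, patch_dropout_rate = 0.5,
                           max_decode_len = 64L, modalities = c("H1")) {
  stopifnot(d_model %% n_heads == 0,
            patch_dropout_rate >= 0, patch_dropout_rate < 1,
            all(modalities %in% c("H1", "C13", "HSQC")),
            length(modalities) >= 1L, !anyDuplicated(modalities))
  structure(list(d_model = as.integer(d_model),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
                 patch_len_1d = as.integer(patch_len_1d),
                 patch_size_2d = as.integer(patch_size_2d),
                 patch_dropout_rate = patch_dropout_rate,
                 max_decode_len = as.integer(max_decode_len),
                 modalities = modalities),
            class = "nmr2mol_config")
}

#' @export
print.nmr2mol_config <- function(x, ...) {
  cat(sprintf(paste0("<nmr2mol_config d=%d, enc %d / dec %d layers, %d heads, ",
                     "ff %d, patch 1D %d / 2D %d, dropout %.2f, modalities %s>\n"),
              x$d_model, x$n_encoder_layers, x$n_decoder_layers, x$n_heads,
              x$ff_dim, x$patch_len_1d, x$patch_size_2d, x$patch_dropout_rate,
              paste(x$modalities, collapse = "+")))
  invisible(x)
}

#' Cut a 1D spectrum into contiguous patches
#'
#' @param spec a [spectrum_1d()] or plain numeric vector.
#' @param patch_len patch length; must divide the number of points exactly
#'   (no implicit padding).
#' @return matrix with one patch per row, in ascending grid order;
#'   [unpatchify_1d()] inverts it exactly.
#' @export
patchify_1d <- function(spec, patch_len) {
  x <- if (inherits(spec, "spectrum_1d")) spec$intensities else spec
  n <- length(x)
  if (n %% patch_len != 0)
    stop(sprintf("patch_len %d does not divide spectrum length %d", patch_len, n))
  matrix(x, ncol = patch_len, byrow = TRUE)
}

#' Invert [patchify_1d()]
#' @param patches matrix of patches (one per row).
#' @return numeric vector.
#' @export
unpatchify_1d <- function(patches) as.vector(t(patches))

#' Cut a 2D spectrum into flattened square patches
#'
#' Patches are taken in row-major patch-grid order and each is flattened
#' row-major, so [unpatchify_2d()] is an exact inverse.
#'
#' @param spec a [spectrum_hsqc()] or plain matrix.
#' @param patch_size square patch edge; must divide both dimensions.
#' @return matrix with one flattened patch per row.
#' @export
patchify_2d <- function(spec, patch_size) {
  M <- if (inherits(spec, "spectrum_hsqc")) spec$intensities else spec
  H <- nrow(M); W <- ncol(M); p <- patch_size
  if (H %% p != 0 || W %% p != 0)
    stop(sprintf("patch_size %d does not divide matrix dims %d x %d", p, H, W))
  pr <- H %/% p; pc <- W %/% p
  out <- matrix(0, pr * pc, p * p)
  k <- 0L
  for (r in seq_len(pr)) {
    for (cidx in seq_len(pc)) {
      k <- k + 1L
      block <- M[((r - 1L) * p + 1L):(r * p), ((cidx - 1L) * p + 1L):(cidx * p)]
      out[k, ] <- as.vector(t(block))
    }
  }
  out
}

#' Invert [patchify_2d()]
#' @param patches matrix of flattened patches.
#' @param H,W original matrix dimensions.
#' @param patch_size square patch edge used in [patchify_2d()].
#' @return the reconstructed `H x W` matrix.
#' @export
unpatchify_2d <- function(patches, H, W, patch_size) {
  p <- patch_size
  pr <- H %/% p; pc <- W %/% p
  M <- matrix(0, H, W)
  k <- 0L
  for (r in seq_len(pr)) {
    for (cidx in seq_len(pc)) {
      k <- k + 1L
      M[((r - 1L) * p + 1L):(r * p), ((cidx - 1L) * p + 1L):(cidx * p)] <-
        matrix(patches[k, ], p, p, byrow = TRUE)
    }
  }
  M
}

# patch counts per modality under a config (given the grids in use)
.patch_count <- function(cfg, modality, grids) {
  if (modality == "HSQC") {
    H <- grids$HSQC_H$n_points; W <- grids$HSQC_C$n_points
    (H %/% cfg$patch_size_2d) * (W %/% cfg$patch_size_2d)
  } else {
    grids[[modality]]$n_points %/% cfg$patch_len_1d
  }
}

.patch_dim <- function(cfg, modality) {
  if (modality == "HSQC") cfg$patch_size_2d^2 else cfg$patch_len_1d
}

#' Initialize model parameters
#'
#' @param cfg an [nmr2mol_config()].
#' @param vocab a `vocabulary`.
#' @param grids named list of grids per modality axis (defaults used where
#'   missing).
#' @param seed RNG seed for the initialization draw.
#' @return a nested parameter list (the tree walked by the optimizer).
#' @export
init_params <- function(cfg, vocab, grids = NULL, seed = 1L) {
  grids <- .full_grids(grids)
  d <- cfg$d_model
  V <- vocab$size
  .with_seed(seed, {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    attn_p <- function() list(Wq = rn(d, d), Wk = rn(d, d),
                              Wv = rn(d, d), Wo = rn(d, d))
    ln_p <- function() list(g = rep(1, d), b = numeric(d))
    ffn_p <- function() list(W1 = rn(d, cfg$ff_dim), W2 = rn(cfg$ff_dim, d))
    embed <- list()
    for (m in cfg$modalities) {
      embed[[m]] <- list(W = rn(.patch_dim(cfg, m), d), b = numeric(d),
                         pos = rn(.patch_count(cfg, m, grids), d))
    }
    enc_layers <- lapply(seq_len(cfg$n_encoder_layers), function(i)
      list(ln1 = ln_p(), attn = attn_p(), ln2 = ln_p(), ffn = ffn_p()))
    dec_layers <- lapply(seq_len(cfg$n_decoder_layers), function(i)
      list(ln1 = ln_p(), self = attn_p(), ln2 = ln_p(), cross = attn_p(),
           ln3 = ln_p(), ffn = ffn_p()))
    list(embed = embed,
         enc = list(layers = enc_layers, ln_f = ln_p()),
         dec = list(tok = rn(V, d), pos = rn(cfg$max_decode_len, d),
                    layers = dec_layers, ln_f = ln_p(),
                    out = list(W = rn(d, V), b = numeric(V))))
  })
}

.full_grids <- function(grids = NULL) {
  g <- list(H1 = default_grid("H1"), C13 = default_grid("C13"),
            HSQC_H = default_grid("HSQC_H"), HSQC_C = default_grid("HSQC_C"))
  if (!is.null(grids)) for (n in names(grids)) g[[n]] <- grids[[n]]
  g
}

#' Embed per-modality patches and fuse into one token stream
#'
#' Each modality's patches pass through that modality's own linear projection
#' and learnable positional table; the embedded sequences are concatenated
#' along the sequence dimension in the configured modality order.
#'
#' @param patches named list (one matrix of patches per modality present).
#' @param params model parameters from [init_params()].
#' @param cfg an [nmr2mol_config()].
#' @return a `patch_tokens` object: embedding matrix `X` (n_tokens x d),
#'   `modality` tags and within-modality `position` indices per token.
#' @export
embed_and_fuse <- function(patches, params, cfg) {
  stopifnot(all(names(patches) %in% cfg$modalities))
  Xs <- list(); mods <- character(0); poss <- integer(0)
  for (m in cfg$modalities) {
    if (is.null(patches[[m]])) next
    P <- patches[[m]]
    emb <- params$embed[[m]]
    if (ncol(P) != nrow(emb$W))
      stop(sprintf("modality %s: patch width %d does not match embedding (%d)",
                   m, ncol(P), nrow(emb$W)))
    if (nrow(P) != nrow(emb$pos))
      stop(sprintf("modality %s: %d patches but positional table has %d rows",
                   m, nrow(P), nrow(emb$pos)))
    X <- sweep(P %*% emb$W, 2L, emb$b, "+") + emb$pos
    Xs[[m]] <- X
    mods <- c(mods, rep(m, nrow(P)))
    poss <- c(poss, seq_len(nrow(P)))
  }
  if (!length(Xs)) stop("no modality present")
  structure(list(X = do.call(rbind, Xs), modality = mods, position = poss),
            class = "patch_tokens")
}

#' Patch dropout over the fused token stream
#'
#' In training mode, keeps exactly `round((1 - rate) * n)` tokens chosen
#' uniformly without replacement across the whole fused stream (jointly
#' across modalities), preserving the original order and position indices of
#' the survivors. At inference (`training = FALSE`) it is the identity.
#'
#' @param tokens a `patch_tokens` object (post-fusion).
#' @param rate dropout rate in `[0, 1)`.
#' @param training logical.
#' @return a `patch_tokens` object (possibly with fewer tokens) with a
#'   `kept` attribute giving the surviving indices.
#' @export
patch_dropout <- function(tokens, rate, training = TRUE) {
  stopifnot(inherits(tokens, "patch_tokens"))
  if (rate < 0 || rate >= 1) stop("patch dropout rate must be in [0, 1)")
  n <- nrow(tokens$X)
  if (!training || rate == 0) {
    attr(tokens, "kept") <- seq_len(n)
    return(tokens)
  }
  n_keep <- round((1 - rate) * n)
  keep <- sort(sample.int(n, n_keep))
  out <- structure(list(X = tokens$X[keep, , drop = FALSE],
                        modality = tokens$modality[keep],
                        position = tokens$position[keep]),
                   class = "patch_tokens")
  attr(out, "kept") <- keep
  out
}

# ---------------------------------------------------------------------------
# Batched forward/backward. A batch is a list of samples, each with
# `patches` (named list per modality) and `dec_ids` (0-based decoder input
# ids, all the same length within a batch) and `targets` (0-based, NA masked).

.encoder_stack_fwd <- function(params, cfg, X, B, T) {
  caches <- vector("list", cfg$n_encoder_layers)
  for (l in seq_len(cfg$n_encoder_layers)) {
    cc <- .enc_block_fwd(params$enc$layers[[l]], X, B, T, cfg$n_heads)
    caches[[l]] <- cc
    X <- cc$Y
  }
  fin <- .ln_fwd(X, params$enc$ln_f$g, params$enc$ln_f$b)
  list(Y = fin$Y, caches = caches, fin = fin)
}

.encoder_stack_bwd <- function(dY, fwd, params, cfg, grads) {
  fb <- .ln_bwd(dY, fwd$fin, params$enc$ln_f$g)
  grads$enc$ln_f$g <- grads$enc$ln_f$g + fb$dg
  grads$enc$ln_f$b <- grads$enc$ln_f$b + fb$db
  dX <- fb$dX
  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    bb <- .enc_block_bwd(dX, fwd$caches[[l]], params$enc$layers[[l]])
    grads$enc$layers[[l]] <- .tree_add(grads$enc$layers[[l]], bb$grads)
    dX <- bb$dX
  }
  list(dX = dX, grads = grads)
}

.decoder_stack_fwd <- function(params, cfg, ids_mat, M, B, Tm,
                               shared_kv = FALSE, cross_kvs = NULL) {
  Td <- ncol(ids_mat)
  if (Td > cfg$max_decode_len)
    stop(sprintf("decoder input length %d exceeds max_decode_len %d",
                 Td, cfg$max_decode_len))
  flat_ids <- as.vector(t(ids_mat)) + 1L   # row-major: sample-by-sample
  X <- params$dec$tok[flat_ids, , drop = FALSE] +
    params$dec$pos[rep(seq_len(Td), B), , drop = FALSE]
  caches <- vector("list", cfg$n_decoder_layers)
  for (l in seq_len(cfg$n_decoder_layers)) {
    cc <- .dec_block_fwd(params$dec$layers[[l]], X, M, B, Td, Tm, cfg$n_heads,
                         shared_kv = shared_kv,
                         cross_kv = cross_kvs[[l]])
    caches[[l]] <- cc
    X <- cc$Y
  }
  fin <- .ln_fwd(X, params$dec$ln_f$g, params$dec$ln_f$b)
  lo <- .lin_fwd(fin$Y, params$dec$out$W)
  logits <- lo$Y + rep(params$dec$out$b, each = nrow(lo$Y))
  list(logits = logits, caches = caches, fin = fin, lo = lo,
       flat_ids = flat_ids, Td = Td)
}

.decoder_stack_bwd <- function(dlogits, fwd, params, cfg, B, grads) {
  ob <- .lin_bwd(dlogits, fwd$lo, params$dec$out$W)
  grads$dec$out$W <- grads$dec$out$W + ob$dW
  grads$dec$out$b <- grads$dec$out$b + colSums(dlogits)
  fb <- .ln_bwd(ob$dX, fwd$fin, params$dec$ln_f$g)
  grads$dec$ln_f$g <- grads$dec$ln_f$g + fb$dg
  grads$dec$ln_f$b <- grads$dec$ln_f$b + fb$db
  dX <- fb$dX
  dM <- NULL
  for (l in rev(seq_len(cfg$n_decoder_layers))) {
    bb <- .dec_block_bwd(dX, fwd$caches[[l]], params$dec$layers[[l]])
    grads$dec$layers[[l]] <- .tree_add(grads$dec$layers[[l]], bb$grads)
    dX <- bb$dX
    dM <- if (is.null(dM)) bb$dM else dM + bb$dM
  }
  # embedding gradients: scatter-add by token id and by position
  Td <- fwd$Td
  gtok <- rowsum(dX, group = fwd$flat_ids)
  rows <- as.integer(rownames(gtok))
  grads$dec$tok[rows, ] <- grads$dec$tok[rows, , drop = FALSE] + gtok
  gpos <- rowsum(dX, group = rep(seq_len(Td), B))
  grads$dec$pos[seq_len(Td), ] <- grads$dec$pos[seq_len(Td), , drop = FALSE] + gpos
  list(dM = dM, grads = grads)
}

# Full training-step forward/backward over a prepared batch.
# batch: list(
#   patch_mats: named list per modality of (B*P_m) x patch_dim stacked raw
#               patches (every sample present in every configured modality),
#   kept: integer vector of kept fused-token indices per sample (same count
#         K for all samples; list of length B),
#   dec_ids: B x Td matrix of 0-based decoder input ids,
#   targets: B x Td matrix of 0-based target ids with NA at masked positions)
.train_step_fwd_bwd <- function(params, cfg, batch, grids, want_grad = TRUE,
                                smooth = 0) {
  B <- nrow(batch$dec_ids)
  # per-modality embedding of all patches
  P_m <- vapply(cfg$modalities, function(m) .patch_count(cfg, m, grids), integer(1))
  names(P_m) <- cfg$modalities
  emb_caches <- list()
  Es <- list()
  for (m in cfg$modalities) {
    Xp <- batch$patch_mats[[m]]
    lw <- .lin_fwd(Xp, params$embed[[m]]$W)
    E <- lw$Y + rep(params$embed[[m]]$b, each = nrow(lw$Y)) +
      params$embed[[m]]$pos[rep(seq_len(P_m[[m]]), B), , drop = FALSE]
    emb_caches[[m]] <- lw
    Es[[m]] <- E
  }
  # fuse per sample in modality order, then apply the kept-token selection
  P_tot <- sum(P_m)
  offs <- cumsum(c(0L, P_m[-length(P_m)])); names(offs) <- cfg$modalities
  K <- length(batch$kept[[1]])
  stopifnot(all(vapply(batch$kept, length, integer(1)) == K))
  kept_all <- unlist(batch$kept)                    # fused indices, 1-based
  sel_mod <- findInterval(kept_all - 1L, offs)      # modality block per token
  within <- kept_all - offs[sel_mod]
  sel_rows <- (rep(seq_len(B), each = K) - 1L) * P_m[sel_mod] + within
  X <- matrix(0, B * K, cfg$d_model)
  for (m_i in seq_along(cfg$modalities)) {
    m <- cfg$modalities[m_i]
    pick <- which(sel_mod == m_i)
    if (length(pick)) X[pick, ] <- Es[[m]][sel_rows[pick], , drop = FALSE]
  }
  enc <- .encoder_stack_fwd(params, cfg, X, B, K)
  dec <- .decoder_stack_fwd(params, cfg, batch$dec_ids, enc$Y, B, K)
  ce <- .ce_fwd_bwd(dec$logits, as.vector(t(batch$targets)),
                    want_grad = want_grad, smooth = smooth)
  if (!want_grad) return(list(loss = ce$loss))
  grads <- .tree_zero_like(params)
  db <- .decoder_stack_bwd(ce$dlogits, dec, params, cfg, B, grads)
  grads <- db$grads
  eb <- .encoder_stack_bwd(db$dM, enc, params, cfg, grads)
  grads <- eb$grads
  dX <- eb$dX
  # scatter the encoder-input gradient back through the fused selection
  for (m_i in seq_along(cfg$modalities)) {
    m <- cfg$modalities[m_i]
    pick <- which(sel_mod == m_i)
    if (!length(pick)) next
    dE <- matrix(0, B * P_m[[m]], cfg$d_model)
    gsub <- rowsum(dX[pick, , drop = FALSE], group = sel_rows[pick])
    rows <- as.integer(rownames(gsub))
    dE[rows, ] <- gsub
    lb <- .lin_bwd(dE, emb_caches[[m]], params$embed[[m]]$W)
    grads$embed[[m]]$W <- grads$embed[[m]]$W + lb$dW
    grads$embed[[m]]$b <- grads$embed[[m]]$b + colSums(dE)
    gpos <- rowsum(dE, group = rep(seq_len(P_m[[m]]), B))
    grads$embed[[m]]$pos <- grads$embed[[m]]$pos + gpos
  }
  list(loss = ce$loss, grads = grads)
}

# Inference-time encoding of one sample's spectra (no patch dropout).
.encode_sample <- function(params, cfg, spectra, grids) {
  patches <- list()
  for (m in cfg$modalities) {
    if (is.null(spectra[[m]])) stop("missing modality for encoding: ", m)
    patches[[m]] <- if (m == "HSQC") {
      patchify_2d(spectra[[m]], cfg$patch_size_2d)
    } else {
      patchify_1d(spectra[[m]], cfg$patch_len_1d)
    }
  }
  tok <- embed_and_fuse(patches, params, cfg)
  enc <- .encoder_stack_fwd(params, cfg, tok$X, 1L, nrow(tok$X))
  enc$Y
}

# Precompute each decoder layer's cross-attention keys/values for a fixed
# encoder memory (reused across all beam-search steps).
.memory_kvs <- function(params, cfg, memory) {
  lapply(seq_len(cfg$n_decoder_layers), function(l) {
    p <- params$dec$layers[[l]]$cross
    list(K = memory %*% p$Wk, V = memory %*% p$Wv)
  })
}

# Next-token log-probabilities for a set of decoder prefixes sharing one
# encoder memory (rows = prefixes). `prefixes` is a list of 0-based id
# vectors, all the same length.
.next_logprobs <- function(params, cfg, memory, prefixes, cross_kvs = NULL) {
  B <- length(prefixes)
  Td <- length(prefixes[[1]])
  ids <- do.call(rbind, prefixes)
  dec <- .decoder_stack_fwd(params, cfg, ids, memory, B, nrow(memory),
                            shared_kv = TRUE, cross_kvs = cross_kvs)
  # last position of each sample
  rows <- (seq_len(B)) * Td
  L <- dec$logits[rows, , drop = FALSE]
  L <- L - apply(L, 1L, max)
  L - log(rowSums(exp(L)))
}
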
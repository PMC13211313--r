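# Optimization: learning-rate schedule (linear warmup + cosine decay), AdamW,
# the nmr2mol() fitting function, fine-tuning and the S3 model interface.

#' Training control parameters
#'
#' Defaults follow the standard protocol for this model family: AdamW with a
#' peak learning rate of 3e-4 reached by linear warmup over 10 000 steps,
#' then cosine decay to zero over the full schedule.
#'
#' @param lr_peak peak learning rate.
#' @param warmup_steps linear warmup length in optimizer steps.
#' @param total_steps full schedule length; `NULL` means `epochs` times the
#'   number of batches per epoch.
#' @param epochs passes over the training manifest.
#' @param batch_size records per optimizer step.
#' @param seed RNG seed covering shuffling, patch dropout and initialization.
#' @param weight_decay AdamW decoupled weight decay (weight matrices only).
#' @param betas AdamW moment coefficients.
#' @param eps AdamW denominator floor.
#' @param label_smoothing cross-entropy label smoothing (0 disables).
#' @return an object of class `nmr2mol_control`.
#' @export
nmr2mol_control <- function(lr_peak = 3e-4, warmup_steps = 10000L,
                            total_steps = NULL, epochs = 30L,
                            batch_size = 32L, seed = 1L,
                            weight_decay = 0.01, betas = c(0.9, 0.98),
                            eps = 1e-8, label_smoothing = 0) {
  stopifnot(lr_peak > 0, warmup_steps >= 1, epochs >= 0, batch_size >= 1,
            label_smoothing >= 0, label_smoothing < 1)
  structure(list(lr_peak = lr_peak, warmup_steps = as.integer(warmup_steps),
                 total_steps = if (is.null(total_steps)) NULL else as.integer(total_steps),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), weight_decay = weight_decay,
                 betas = betas, eps = eps, label_smoothing = label_smoothing),
            class = "nmr2mol_control")
}

#' Learning rate at a given optimizer step
#'
#' Linear warmup from 0 to `lr_peak` over `warmup_steps`, then cosine decay
#' to 0 at `total_steps`:
#' `lr_peak * 0.5 * (1 + cos(pi * (step - warmup) / (total - warmup)))`.
#' Steps beyond `total_steps` clamp to the final (zero) value. Continuous at
#' the warmup/cosine junction and non-negative everywhere.
#'
#' @param step optimizer step (0-based at schedule start).
#' @param lr_peak,warmup_steps,total_steps schedule parameters.
#' @return learning rate.
#' @export
lr_at_step <- function(step, lr_peak = 3e-4, warmup_steps = 10000L,
                       total_steps = 100000L) {
  stopifnot(step >= 0, warmup_steps <= total_steps)
  if (step <= warmup_steps) return(lr_peak * step / warmup_steps)
  if (step >= total_steps) return(0)
  lr_peak * 0.5 * (1 + cos(pi * (step - warmup_steps) / (total_steps - warmup_steps)))
}

# -- data preparation --------------------------------------------------------

.load_record_spectra <- function(rec) {
  if (!is.null(rec$spectra)) return(rec$spectra)
  lapply(rec$files, read_spectrum)
}

# Pre-tokenize and pre-patchify a manifest into a training-ready list.
.prepare_dataset <- function(manifest, cfg, vocab, grids) {
  lapply(manifest$records, function(rec) {
    spectra <- .load_record_spectra(rec)
    patches <- list()
    for (m in cfg$modalities) {
      if (is.null(spectra[[m]]))
        stop("record '", rec$smiles, "' is missing modality ", m)
      patches[[m]] <- if (m == "HSQC") {
        patchify_2d(spectra[[m]], cfg$patch_size_2d)
      } else {
        patchify_1d(spectra[[m]], cfg$patch_len_1d)
      }
    }
    prefix <- vocab_encode(vocab, tokenize_formula(rec$formula), strict = TRUE)
    smi <- vocab_encode(vocab, tokenize_smiles(rec$smiles), strict = TRUE)
    list(smiles = rec$smiles, formula = rec$formula, patches = patches,
         prefix = prefix, smi_ids = smi)
  })
}

# Assemble one padded batch from prepared records.
.make_batch <- function(recs, cfg, vocab, n_fused, keep_k) {
  B <- length(recs)
  bos <- .special_id(vocab, .BOS)
  eos <- .special_id(vocab, .EOS)
  pad <- .special_id(vocab, .PAD)
  lens <- vapply(recs, function(r) length(r$smi_ids), integer(1))
  P <- length(recs[[1]]$prefix)
  Td <- P + 1L + max(lens)
  dec_ids <- matrix(pad, B, Td)
  targets <- matrix(NA_integer_, B, Td)
  for (b in seq_len(B)) {
    r <- recs[[b]]
    L <- lens[b]
    dec_ids[b, 1:P] <- r$prefix
    dec_ids[b, P + 1L] <- bos
    if (L > 0) {
      dec_ids[b, (P + 2L):(P + 1L + L)] <- r$smi_ids
      targets[b, (P + 1L):(P + L)] <- r$smi_ids
    }
    targets[b, P + 1L + L] <- eos
  }
  patch_mats <- list()
  for (m in cfg$modalities)
    patch_mats[[m]] <- do.call(rbind, lapply(recs, function(r) r$patches[[m]]))
  kept <- lapply(seq_len(B), function(b) {
    if (keep_k >= n_fused) seq_len(n_fused) else sort(sample.int(n_fused, keep_k))
  })
  list(patch_mats = patch_mats, kept = kept, dec_ids = dec_ids, targets = targets)
}

.adamw_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

# Decoupled weight-decay mask: decay applies to weight matrices only (not
# biases, layer norms or embedding tables' positional offsets is fine to
# decay; standard practice decays all 2-D weights).
.decay_mask <- function(params) {
  rec <- function(a) {
    if (is.list(a)) unlist(lapply(a, rec), use.names = FALSE)
    else rep(if (is.matrix(a)) 1 else 0, length(a))
  }
  rec(params)
}

.adamw_update <- function(flat_p, flat_g, st, lr, ctrl, mask) {
  st$t <- st$t + 1L
  b1 <- ctrl$betas[1]; b2 <- ctrl$betas[2]
  st$m <- b1 * st$m + (1 - b1) * flat_g
  st$v <- b2 * st$v + (1 - b2) * flat_g^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  flat_p <- flat_p - lr * (mhat / (sqrt(vhat) + ctrl$eps) +
                             ctrl$weight_decay * mask * flat_p)
  list(p = flat_p, st = st)
}

# Mean masked loss over a prepared dataset (no dropout, no grads).
.dataset_loss <- function(params, cfg, prepared, vocab, grids, n_fused,
                          batch_size, smooth = 0) {
  tot <- 0; nb <- 0
  idx <- seq_along(prepared)
  for (start in seq(1, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1, length(idx))]
    batch <- .make_batch(prepared[sel], cfg, vocab, n_fused, keep_k = n_fused)
    out <- .train_step_fwd_bwd(params, cfg, batch, grids, want_grad = FALSE,
                               smooth = smooth)
    tot <- tot + out$loss; nb <- nb + 1
  }
  tot / nb
}

#' Fit a spectrum-to-structure transformer
#'
#' Trains the patch-based encoder + formula-prompted autoregressive decoder
#' on a toy dataset manifest by AdamW with warmup + cosine learning-rate
#' decay. The cross-entropy loss is computed only over SMILES positions; the
#' formula prefix and padding are masked out. When a validation manifest is
#' given, the parameters with the best validation loss are retained.
#'
#' @param train_manifest a `dataset_manifest` for training.
#' @param valid_manifest optional `dataset_manifest` for validation-based
#'   checkpoint selection.
#' @param config an [nmr2mol_config()].
#' @param control an [nmr2mol_control()].
#' @param vocab optional pre-built `vocabulary`; default builds one from the
#'   given manifests.
#' @param grids optional named list of grids (see [default_grid()]).
#' @param params optional initial parameters (used by [finetune()]).
#' @param quiet suppress per-epoch progress lines.
#' @return an object of class `nmr2mol` with components `params`, `config`,
#'   `vocab`, `grids`, `control` and `history` (one row per epoch: step, lr,
#'   training loss, validation loss).
#' @export
nmr2mol <- function(train_manifest, valid_manifest = NULL,
                    config = nmr2mol_config(), control = nmr2mol_control(),
                    vocab = NULL, grids = NULL, params = NULL, quiet = TRUE) {
  stopifnot(inherits(train_manifest, "dataset_manifest"))
  cfg <- config; ctrl <- control
  if (ctrl$epochs < 1) stop("training needs epochs >= 1")
  grids <- .full_grids(grids)
  if (is.null(vocab)) {
    mans <- list(train_manifest)
    if (!is.null(valid_manifest)) mans <- c(mans, list(valid_manifest))
    vocab <- build_vocab(mans)
  }
  n_fused <- sum(vapply(cfg$modalities, function(m) .patch_count(cfg, m, grids),
                        integer(1)))
  keep_k <- round((1 - cfg$patch_dropout_rate) * n_fused)
  n <- length(train_manifest$records)
  steps_per_epoch <- ceiling(n / ctrl$batch_size)
  total_steps <- if (is.null(ctrl$total_steps)) ctrl$epochs * steps_per_epoch
                 else ctrl$total_steps
  if (ctrl$warmup_steps > total_steps)
    stop("warmup_steps exceeds total_steps; shorten warmup for this schedule")
  .with_seed(ctrl$seed, {
    prepared <- .prepare_dataset(train_manifest, cfg, vocab, grids)
    prepared_val <- if (!is.null(valid_manifest))
      .prepare_dataset(valid_manifest, cfg, vocab, grids) else NULL
    if (is.null(params)) params <- init_params(cfg, vocab, grids,
                                               seed = ctrl$seed + 1L)
    flat_p <- .tree_unlist(params)
    mask <- .decay_mask(params)
    st <- .adamw_state(length(flat_p))
    history <- NULL
    best <- list(loss = Inf, flat = flat_p)
    gstep <- 0L
    for (ep in seq_len(ctrl$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = ctrl$batch_size)) {
        sel <- ord[start:min(start + ctrl$batch_size - 1, n)]
        batch <- .make_batch(prepared[sel], cfg, vocab, n_fused, keep_k)
        out <- .train_step_fwd_bwd(params, cfg, batch, grids,
                                   smooth = ctrl$label_smoothing)
        if (!is.finite(out$loss))
          stop(sprintf("training diverged: non-finite loss at step %d", gstep))
        gstep <- gstep + 1L
        lr <- lr_at_step(gstep, ctrl$lr_peak, ctrl$warmup_steps, total_steps)
        up <- .adamw_update(flat_p, .tree_unlist(out$grads), st, lr, ctrl, mask)
        flat_p <- up$p; st <- up$st
        params <- .tree_relist(params, flat_p)$node
        ep_loss <- ep_loss + out$loss; nb <- nb + 1
      }
      vl <- if (!is.null(prepared_val)) {
        .dataset_loss(params, cfg, prepared_val, vocab, grids, n_fused,
                      ctrl$batch_size, smooth = ctrl$label_smoothing)
      } else NA_real_
      if (!is.na(vl) && vl < best$loss) best <- list(loss = vl, flat = flat_p)
      history <- rbind(history,
                       data.frame(epoch = ep, step = gstep,
                                  lr = lr_at_step(gstep, ctrl$lr_peak,
                                                  ctrl$warmup_steps, total_steps),
                                  train_loss = ep_loss / nb, valid_loss = vl))
      if (!quiet)
        message(sprintf("epoch %d/%d  step %d  train %.4f  valid %s",
                        ep, ctrl$epochs, gstep, ep_loss / nb,
                        if (is.na(vl)) "-" else sprintf("%.4f", vl)))
    }
    if (is.finite(best$loss)) params <- .tree_relist(params, best$flat)$node
    structure(list(params = params, config = cfg, vocab = vocab,
                   grids = grids, control = ctrl, history = history,
                   best_valid = if (is.finite(best$loss)) best$loss else NA_real_,
                   call = match.call()),
              class = "nmr2mol")
  })
}

#' Fine-tune a fitted model on a small manifest
#'
#' Continues training all weights from the given model's parameters with a
#' lower default peak learning rate (3e-5) and a short schedule, the
#' adaptation recipe for bridging a simulation-trained model to
#' distribution-shifted (e.g. experimental-style) spectra. The model's
#' vocabulary must cover the new corpus; missing tokens raise an error.
#'
#' @param object a fitted `nmr2mol` model.
#' @param train_manifest manifest of adaptation records.
#' @param valid_manifest optional validation manifest.
#' @param control an [nmr2mol_control()]; defaults to `lr_peak = 3e-5`,
#'   10 epochs, immediate warmup.
#' @return a fitted `nmr2mol` model.
#' @export
finetune <- function(object, train_manifest, valid_manifest = NULL,
                     control = nmr2mol_control(lr_peak = 3e-5, epochs = 10L,
                                               warmup_steps = 1L)) {
  stopifnot(inherits(object, "nmr2mol"))
  toks <- character(0)
  mans <- c(list(train_manifest),
            if (!is.null(valid_manifest)) list(valid_manifest))
  for (man in mans) for (r in man$records)
    toks <- c(toks, tokenize_smiles(r$smiles), tokenize_formula(r$formula))
  missing <- setdiff(unique(toks), names(object$vocab$token_to_id))
  if (length(missing))
    stop("vocabulary does not cover the fine-tuning corpus; missing tokens: ",
         paste(missing, collapse = " "))
  if (control$epochs == 0L) return(object)
  nmr2mol(train_manifest, valid_manifest, config = object$config,
          control = control, vocab = object$vocab, grids = object$grids,
          params = object$params)
}

# -- S3 interface ------------------------------------------------------------

#' @export
print.nmr2mol <- function(x, ...) {
  np <- length(.tree_unlist(x$params))
  cat(sprintf("Spectrum-to-structure transformer (%s)\n",
              paste(x$config$modalities, collapse = "+")))
  cat(sprintf("  d_model %d, %d+%d layers, %d heads, %s parameters\n",
              x$config$d_model, x$config$n_encoder_layers,
              x$config$n_decoder_layers, x$config$n_heads,
              format(np, big.mark = ",")))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs (%d steps); final train loss %.4f%s\n",
                last$epoch, last$step, last$train_loss,
                if (!is.na(x$best_valid))
                  sprintf(", best valid loss %.4f", x$best_valid) else ""))
  }
  invisible(x)
}

#' @export
summary.nmr2mol <- function(object, ...) {
  print(object)
  cat("\nPer-epoch history (last 5):\n")
  h <- object$history
  print(utils::tail(h, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.nmr2mol <- function(object, ...) object$params

#' @export
plot.nmr2mol <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "masked cross-entropy",
                 ylim = range(c(h$train_loss, h$valid_loss), na.rm = TRUE), ...)
  if (any(!is.na(h$valid_loss)))
    graphics::lines(h$epoch, h$valid_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "valid"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Predict molecular structures from spectra
#'
#' Encodes the given spectra, runs beam search conditioned on the
#' molecular-formula prompt, and returns either the top structure or the full
#' candidate list.
#'
#' @param object a fitted `nmr2mol` model.
#' @param spectra named list of spectra covering the model's modalities.
#' @param formula molecular formula prompt (Hill notation).
#' @param beam_width beam search width.
#' @param type `"smiles"` for the single best (filtered) structure,
#'   `"candidates"` for the full candidate data frame.
#' @param cap candidate retention cap applied when filtering.
#' @param ... unused.
#' @return a character scalar (`type = "smiles"`; `NA` if no candidate
#'   survives filtering) or a candidate data frame.
#' @export
predict.nmr2mol <- function(object, spectra, formula, beam_width = 10L,
                            type = c("smiles", "candidates"), cap = 100L, ...) {
  type <- match.arg(type)
  cands <- generate_candidates(object, spectra, formula, beam_width = beam_width)
  if (type == "candidates") return(cands)
  kept <- filter_candidates(cands, formula, cap = cap)
  if (!nrow(kept)) return(NA_character_)
  kept$smiles[1]
}
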
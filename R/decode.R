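# Beam-search candidate generation, validity/formula filtering and top-k
# exact-match evaluation.

#' Beam search over an autoregressive next-token model
#'
#' Standard beam search by cumulative log-probability (no length
#' normalization by default). `next_fn` maps a list of 0-based id prefixes to
#' a matrix of next-token log-probabilities (one row per prefix), which makes
#' the routine usable both with the fitted transformer decoder and with
#' hand-built toy decoders in tests. Sequences end at `eos_id` or at
#' `max_len` tokens; the returned sequences are distinct, sorted by total
#' log-probability (ties broken lexicographically on the token-id sequence
#' for reproducibility).
#'
#' @param next_fn function(list of integer vectors) -> matrix of log-probs.
#' @param width beam width (>= 1); `width = 1` is greedy decoding.
#' @param eos_id 0-based end-of-sequence id.
#' @param max_len maximum number of generated tokens.
#' @param length_normalize divide final scores by sequence length (off by
#'   default; provided for experimentation).
#' @return data frame with list-column `ids` (generated ids, without EOS) and
#'   column `log_prob`, ordered best-first.
#' @export
beam_search <- function(next_fn, width, eos_id, max_len,
                        length_normalize = FALSE) {
  if (width < 1) stop("beam width must be >= 1")
  beams <- list(list(ids = integer(0), score = 0))
  finished <- list()
  for (step in seq_len(max_len)) {
    if (!length(beams)) break
    lp <- next_fn(lapply(beams, `[[`, "ids"))
    cand_scores <- numeric(0); cand_parent <- integer(0); cand_tok <- integer(0)
    for (b in seq_along(beams)) {
      cand_scores <- c(cand_scores, beams[[b]]$score + lp[b, ])
      cand_parent <- c(cand_parent, rep(b, ncol(lp)))
      cand_tok <- c(cand_tok, seq_len(ncol(lp)) - 1L)
    }
    ord <- order(cand_scores, decreasing = TRUE)
    ord <- ord[seq_len(min(width, length(ord)))]
    new_beams <- list()
    for (k in ord) {
      seq_ids <- c(beams[[cand_parent[k]]]$ids, cand_tok[k])
      entry <- list(ids = seq_ids, score = cand_scores[k])
      if (cand_tok[k] == eos_id) {
        entry$ids <- seq_ids[-length(seq_ids)]
        finished <- c(finished, list(entry))
      } else {
        new_beams <- c(new_beams, list(entry))
      }
    }
    beams <- new_beams
  }
  all <- c(finished, beams)   # unfinished beams rank by their running score
  if (!length(all)) return(data.frame(log_prob = numeric(0)))
  scores <- vapply(all, `[[`, numeric(1), "score")
  if (length_normalize)
    scores <- scores / pmax(vapply(all, function(x) length(x$ids), integer(1)), 1L)
  keys <- vapply(all, function(x) paste(x$ids, collapse = ","), character(1))
  ord <- order(-scores, keys)
  all <- all[ord]; scores <- scores[ord]; keys <- keys[ord]
  dup <- duplicated(keys)
  all <- all[!dup]; scores <- scores[!dup]
  out <- data.frame(log_prob = scores[seq_len(min(width, length(all)))])
  out$ids <- lapply(all[seq_len(nrow(out))], `[[`, "ids")
  out
}

#' Generate SMILES candidates for one spectra record
#'
#' Encodes the spectra (patch dropout disabled), then beam-searches the
#' decoder conditioned on the formula prompt.
#'
#' @param object a fitted `nmr2mol` model.
#' @param spectra named list of spectra covering the model's modalities.
#' @param formula molecular formula prompt.
#' @param beam_width beam width.
#' @param max_new maximum generated SMILES tokens (default: the decoder
#'   budget left after the prompt).
#' @return a candidate data frame: `smiles`, `log_prob`, `source_rank`,
#'   `is_valid`, `formula_ok` — ordered by log-probability (non-increasing).
#' @export
generate_candidates <- function(object, spectra, formula, beam_width = 10L,
                                max_new = NULL) {
  stopifnot(inherits(object, "nmr2mol"))
  cfg <- object$config; vocab <- object$vocab
  memory <- .encode_sample(object$params, cfg, spectra, object$grids)
  kvs <- .memory_kvs(object$params, cfg, memory)
  prefix <- vocab_encode(vocab, tokenize_formula(formula), strict = FALSE)
  bos <- .special_id(vocab, .BOS)
  head_ids <- c(prefix, bos)
  if (is.null(max_new)) max_new <- cfg$max_decode_len - length(head_ids) - 1L
  next_fn <- function(id_list) {
    prefixes <- lapply(id_list, function(ids) c(head_ids, ids))
    .next_logprobs(object$params, cfg, memory, prefixes, cross_kvs = kvs)
  }
  res <- beam_search(next_fn, width = beam_width,
                     eos_id = .special_id(vocab, .EOS), max_len = max_new)
  smiles <- vapply(res$ids, function(ids) {
    if (!length(ids)) return("")
    detokenize(vocab_decode(vocab, ids))
  }, character(1))
  valid <- smiles_is_valid(smiles)
  fok <- rep(FALSE, length(smiles))
  fok[valid] <- mol_formula(smiles[valid]) == formula
  data.frame(smiles = smiles, log_prob = res$log_prob,
             source_rank = seq_along(smiles), is_valid = valid,
             formula_ok = fok, stringsAsFactors = FALSE)
}

#' Filter a candidate list by validity and formula consistency
#'
#' Drops chemically invalid SMILES, drops candidates whose full Hill formula
#' (implicit hydrogens included) differs from the target, collapses
#' duplicates that canonicalize to the same non-stereo molecule (keeping the
#' highest log-probability occurrence), preserves order, and truncates to the
#' retention cap (up to 100 molecules by default). Idempotent.
#'
#' @param cands candidate data frame from [generate_candidates()] (columns
#'   `smiles`, `log_prob`; other columns preserved).
#' @param formula target molecular formula.
#' @param cap maximum number of molecules retained (>= 1).
#' @return the filtered data frame, with a `canonical` column added.
#' @export
filter_candidates <- function(cands, formula, cap = 100L) {
  stopifnot(is.data.frame(cands), cap >= 1)
  if (!nrow(cands)) return(cbind(cands, canonical = character(0)))
  canon <- if ("canonical" %in% names(cands)) cands$canonical
           else canonicalize_nonstereo(cands$smiles)
  keep <- !is.na(canon)
  if (any(keep)) {
    f <- mol_formula(canon[keep])
    keep[keep] <- !is.na(f) & f == formula
  }
  out <- cands[keep, , drop = FALSE]
  out$canonical <- canon[keep]
  if (nrow(out)) {
    # collapse molecule-level duplicates, keeping the best log_prob
    # occurrence of each molecule; survivor order follows the input order
    keep_idx <- vapply(split(seq_len(nrow(out)), out$canonical), function(ix) {
      ix[which.max(out$log_prob[ix])]
    }, integer(1))
    out <- out[sort(unname(keep_idx)), , drop = FALSE]
  }
  rownames(out) <- NULL
  utils::head(out, cap)
}

#' Top-k exact-match evaluation over a manifest
#'
#' For each record, generates beam candidates, canonicalizes them to
#' non-stereo form, collapses duplicates at the molecule level and scores a
#' hit at `k` when the target's canonical string appears among the first `k`
#' distinct molecules. Also reports the chemical-validity fraction of top-1
#' outputs. Evaluation depends only on the candidate and target strings.
#'
#' @param object a fitted `nmr2mol` model.
#' @param manifest a `dataset_manifest`.
#' @param k_list accuracy ranks (default `c(1, 5, 10)`).
#' @param beam_width beam width (must be >= `max(k_list)`).
#' @param targets optional character vector overriding the manifest's target
#'   SMILES (used for permutation controls).
#' @param progress print a dot per record.
#' @return an `eval_report`: list with `accuracy` (named by k), `validity`,
#'   `n_evaluated`, and the per-record candidate lists.
#' @export
evaluate_topk <- function(object, manifest, k_list = c(1L, 5L, 10L),
                          beam_width = max(k_list), targets = NULL,
                          progress = FALSE) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (!length(manifest$records)) stop("empty manifest")
  if (beam_width < max(k_list)) stop("beam_width must be >= max(k_list)")
  n <- length(manifest$records)
  if (is.null(targets))
    targets <- vapply(manifest$records, `[[`, character(1), "smiles")
  target_canon <- canonicalize_nonstereo(targets)
  hits <- matrix(FALSE, n, length(k_list))
  top1_valid <- logical(n)
  cand_lists <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- manifest$records[[i]]
    spectra <- .load_record_spectra(rec)
    cands <- generate_candidates(object, spectra, rec$formula,
                                 beam_width = beam_width)
    canon <- canonicalize_nonstereo(cands$smiles)
    top1_valid[i] <- isTRUE(cands$is_valid[1])
    mols <- unique(canon[!is.na(canon)])
    for (j in seq_along(k_list)) {
      # rank molecules by first appearance among beams
      hits[i, j] <- target_canon[i] %in% utils::head(mols, k_list[j])
    }
    cands$canonical <- canon
    cand_lists[[i]] <- cands
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  acc <- colMeans(hits)
  names(acc) <- paste0("top", k_list)
  structure(list(accuracy = acc, validity = mean(top1_valid), n_evaluated = n,
                 candidates = cand_lists),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report n=%d, validity %.3f | %s>\n", x$n_evaluated,
              x$validity,
              paste(sprintf("%s %.3f", names(x$accuracy), x$accuracy),
                    collapse = ", ")))
  invisible(x)
}
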
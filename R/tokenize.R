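# Chemistry-aware tokenization of SMILES strings and molecular formulas,
# and vocabulary management.

# Special tokens. Ids are contiguous from 0; specials occupy 0..4.
.SPECIALS <- c("<pad>", "<bos>", "<eos>", "<unk>", "<fpad>")
.PAD <- "<pad>"; .BOS <- "<bos>"; .EOS <- "<eos>"; .UNK <- "<unk>"
.FPAD <- "<fpad>"  # formula-prompt padding

# Fixed capacity of the molecular-formula prefix region in the decoder input.
# 16 tokens cover all Hill formulas in the 5-35 heavy-atom regime.
.FORMULA_PREFIX_LEN <- 16L

#' Formula-prefix capacity
#' @return integer; the fixed number of decoder positions reserved for the
#'   molecular-formula prompt.
#' @export
formula_prefix_len <- function() .FORMULA_PREFIX_LEN

#' Tokenize a SMILES string at the atom level
#'
#' Splits a SMILES string into atom-level and syntax tokens with the standard
#' regular-expression convention: bracket atoms (e.g. `[NH4+]`) are single
#' tokens, two-letter halogens (`Cl`, `Br`) are single tokens, ring-bond
#' labels, bonds, parentheses and digits are single tokens. Concatenating the
#' tokens reproduces the input exactly.
#'
#' @param s a single non-empty SMILES string.
#' @return character vector of tokens.
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  mt <- .match_all_tokens(s)
  if (is.null(mt) || !mt$ok) {
    pos <- if (is.null(mt)) 1L else mt$pos
    stop(sprintf("cannot tokenize SMILES at position %d: '%s'",
                 pos, substr(s, pos, pos)))
  }
  mt$tokens
}

#' Reassemble tokens into a string
#' @param tokens character vector of tokens.
#' @return the concatenated string.
#' @export
detokenize <- function(tokens) paste(tokens, collapse = "")

#' Tokenize a molecular formula into the fixed-length prompt
#'
#' A Hill-notation formula is split into alternating element-symbol tokens and
#' single-digit tokens (counts above 9 are split into digits; counts of 1 that
#' are absent from the formula text are not materialized). The result is
#' padded with the dedicated prompt-padding token to the fixed prefix
#' capacity; formulas exceeding the capacity raise an error rather than being
#' truncated.
#'
#' @param formula Hill-notation formula string, e.g. `"C9H10O2"`.
#' @param pad_to prefix capacity (default [formula_prefix_len()]).
#' @return character vector of length `pad_to`.
#' @export
tokenize_formula <- function(formula, pad_to = formula_prefix_len()) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  starts <- as.integer(m); lens <- attr(m, "match.length")
  if (starts[1] != 1L || sum(lens) != nchar(formula))
    stop("unparseable formula: ", formula)
  toks <- character(0)
  for (k in seq_along(starts)) {
    piece <- substr(formula, starts[k], starts[k] + lens[k] - 1L)
    el <- sub("[0-9]*$", "", piece)
    digits <- sub("^[A-Za-z]+", "", piece)
    toks <- c(toks, el, if (nzchar(digits)) strsplit(digits, "")[[1]])
  }
  if (length(toks) > pad_to)
    stop(sprintf("formula '%s' needs %d tokens but the prefix capacity is %d",
                 formula, length(toks), pad_to))
  c(toks, rep(.FPAD, pad_to - length(toks)))
}

.new_vocab <- function(ids) {
  stopifnot(!is.null(names(ids)))
  nms <- names(ids)
  ids <- as.integer(ids)
  names(ids) <- nms
  tok2id <- sort(ids)
  if (!identical(unname(tok2id), seq_along(tok2id) - 1L))
    stop("vocabulary ids must be contiguous from 0")
  if (!all(.SPECIALS %in% names(tok2id)))
    stop("vocabulary is missing special tokens")
  structure(list(token_to_id = tok2id,
                 id_to_token = names(tok2id),
                 size = length(tok2id)),
            class = "vocabulary")
}

#' Build a vocabulary from dataset manifests
#'
#' The vocabulary is the union of the special tokens, all SMILES tokens and
#' all formula-prompt tokens observed in the given manifests, with stable
#' (lexicographic after specials) id assignment so repeated builds agree.
#'
#' @param manifests one `dataset_manifest` or a list of them.
#' @return an object of class `vocabulary`.
#' @export
build_vocab <- function(manifests) {
  if (inherits(manifests, "dataset_manifest")) manifests <- list(manifests)
  stopifnot(length(manifests) >= 1L)
  toks <- character(0)
  n_rec <- 0L
  for (m in manifests) {
    stopifnot(inherits(m, "dataset_manifest"))
    for (r in m$records) {
      n_rec <- n_rec + 1L
      toks <- c(toks, tokenize_smiles(r$smiles), tokenize_formula(r$formula))
    }
  }
  if (n_rec == 0L) stop("empty corpus: no records in manifests")
  toks <- sort(unique(setdiff(toks, .SPECIALS)))
  ids <- seq_len(length(.SPECIALS) + length(toks)) - 1L
  names(ids) <- c(.SPECIALS, toks)
  .new_vocab(ids)
}

#' Encode tokens to integer ids
#'
#' Tokens missing from the vocabulary map to the unknown-token id with a
#' warning (robust inference); use `strict = TRUE` to fail fast instead
#' (training-data builds).
#'
#' @param vocab a `vocabulary`.
#' @param tokens character vector.
#' @param strict error instead of warning on unknown tokens.
#' @return integer vector of ids (0-based).
#' @export
vocab_encode <- function(vocab, tokens, strict = FALSE) {
  stopifnot(inherits(vocab, "vocabulary"))
  ids <- vocab$token_to_id[tokens]
  miss <- is.na(ids)
  if (any(miss)) {
    if (strict)
      stop("tokens missing from vocabulary: ",
           paste(unique(tokens[miss]), collapse = " "))
    warning("unknown token(s) mapped to <unk>: ",
            paste(unique(tokens[miss]), collapse = " "))
    ids[miss] <- vocab$token_to_id[[.UNK]]
  }
  unname(ids)
}

#' Decode integer ids back to tokens
#' @param vocab a `vocabulary`.
#' @param ids integer vector of 0-based ids.
#' @return character vector of tokens.
#' @export
vocab_decode <- function(vocab, ids) {
  stopifnot(inherits(vocab, "vocabulary"), all(ids >= 0), all(ids < vocab$size))
  vocab$id_to_token[ids + 1L]
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d tokens (%d specials)>\n", x$size, length(.SPECIALS)))
  invisible(x)
}

# id helpers used throughout the model code
.special_id <- function(vocab, token) unname(vocab$token_to_id[[token]])
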
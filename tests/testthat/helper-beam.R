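# Toy Markov decoder and exhaustive-enumeration oracle for beam-search
# tests.

# A memoryless toy decoder over 3 tokens {A=0, B=1, EOS=2}: the next-token
# distribution depends only on the previous token. Transition rows must sum
# to 1.
toy_next_fn <- function(P, bos_row) {
  function(id_list) {
    t(vapply(id_list, function(ids) {
      row <- if (!length(ids)) bos_row else P[ids[length(ids)] + 1L, ]
      log(row)
    }, numeric(3)))
  }
}

# exhaustive enumeration of all sequences up to max_len, ranked by total
# log-probability (the brute-force oracle)
enumerate_sequences <- function(P, bos_row, max_len) {
  res <- list()
  recurse <- function(ids, lp) {
    if (length(ids) && ids[length(ids)] == 2L) {
      res[[length(res) + 1L]] <<- list(ids = ids[-length(ids)], lp = lp)
      return()
    }
    if (length(ids) == max_len) {
      res[[length(res) + 1L]] <<- list(ids = ids, lp = lp)
      return()
    }
    row <- if (!length(ids)) bos_row else P[ids[length(ids)] + 1L, ]
    for (tok in 0:2) recurse(c(ids, tok), lp + log(row[tok + 1L]))
  }
  recurse(integer(0), 0)
  keys <- vapply(res, function(x) paste(x$ids, collapse = ","), character(1))
  lps <- vapply(res, `[[`, numeric(1), "lp")
  ord <- order(-lps, keys)
  res <- res[ord][!duplicated(keys[ord])]
  res
}

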
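# Cheminformatics kernel: SMILES validity, canonicalization, formulas and
# molecular graphs. Built on OpenBabel (ChemmineOB/ChemmineR). OpenBabel is
# lenient and silently repairs some malformed SMILES, so chemical validity is
# enforced here by an explicit syntactic + valence layer before OpenBabel is
# asked to canonicalize.

# Atom-level tokenizer pattern following the Molecular Transformer convention:
# bracket atoms are single tokens, two-letter halogens are single tokens,
# %-ring closures are single tokens.
.SMILES_REGEX <- paste0(
  "(\\[[^\\]]+\\]|Br|Cl|Si|Se|se|B|C|N|O|S|P|F|I|b|c|n|o|s|p|",
  "\\(|\\)|\\.|=|#|-|\\+|\\\\|/|:|~|@|\\?|>|\\*|\\$|%[0-9]{2}|[0-9])"
)

# Standard valences used for implicit-hydrogen assignment on organic-subset
# atoms (smallest valence >= bond-order sum is chosen, as in SMILES rules).
.VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

.match_all_tokens <- function(s) {
  m <- gregexpr(.SMILES_REGEX, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # tokens must tile the string with no gaps
  if (starts[1] != 1L) return(list(ok = FALSE, pos = 1L))
  end_prev <- 0L
  for (k in seq_along(starts)) {
    if (starts[k] != end_prev + 1L) return(list(ok = FALSE, pos = end_prev + 1L))
    end_prev <- starts[k] + lens[k] - 1L
  }
  if (end_prev != nchar(s)) return(list(ok = FALSE, pos = end_prev + 1L))
  list(ok = TRUE, tokens = substring(s, starts, starts + lens - 1L))
}

.smiles_syntax_ok <- function(s) {
  if (!nzchar(s)) return(FALSE)
  mt <- .match_all_tokens(s)
  if (is.null(mt) || !mt$ok) return(FALSE)
  toks <- mt$tokens
  # balanced parentheses
  depth <- 0L
  for (t in toks) {
    if (t == "(") depth <- depth + 1L
    if (t == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
  }
  if (depth != 0L) return(FALSE)
  # every ring-closure label must appear an even number of times
  ring <- toks[grepl("^[0-9]$|^%[0-9]{2}$", toks)]
  if (length(ring) && any(table(ring) %% 2L != 0L)) return(FALSE)
  TRUE
}

.ob_canonical <- function(s) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
    error = function(e) ""
  )
  out <- gsub("[\t\r\n ].*$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Returns the kekulized heavy-atom graph (elements, bond list with orders,
#' implicit hydrogen counts) used by the toy shift assigner, the formula
#' calculator and the valence check. Aromatic rings arrive kekulized from the
#' OpenBabel conversion.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements `elements` (character vector), `bonds`
#'   (integer matrix with columns `i`, `j`, `order`), `n_h` (implicit hydrogen
#'   count per heavy atom), `adj` (adjacency list), or `NULL` if the string is
#'   not a valid molecule.
#' @export
parse_mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!.smiles_syntax_ok(smiles)) return(NULL)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) return(NULL)
  ab <- tryCatch(ChemmineR::atomblock(sdf[[1]]), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  if (!is.null(bb) && !is.matrix(bb)) bb <- matrix(bb, nrow = 1)
  if (!is.null(bb) && nrow(bb) > 0L && ncol(bb) >= 3L) {
    bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  } else {
    bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "order")))
  }
  bracket <- grepl("\\[", smiles)
  bond_sum <- integer(n)
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      if (i > n || j > n || o < 1L || o > 3L) return(NULL)
      bond_sum[i] <- bond_sum[i] + o
      bond_sum[j] <- bond_sum[j] + o
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  n_h <- integer(n)
  for (a in seq_len(n)) {
    el <- elements[a]
    val <- .VALENCES[[el]]
    if (is.null(val)) {
      if (el == "H") next  # explicit hydrogens from bracket atoms
      return(NULL)         # element outside the supported organic subset
    }
    fit <- val[val >= bond_sum[a]]
    if (!length(fit)) {
      # valence violation; tolerated only for bracket atoms (charges etc.),
      # which OpenBabel has already vetted
      if (!bracket) return(NULL)
      fit <- bond_sum[a]
    }
    n_h[a] <- fit[1] - bond_sum[a]
  }
  list(elements = elements, bonds = bonds, n_h = n_h, adj = adj)
}

#' Test SMILES strings for chemical validity
#'
#' A string is valid when it tokenizes under the atom-level pattern, has
#' balanced parentheses and paired ring-bond labels, parses to a non-empty
#' molecule, and respects standard valences on the organic element subset
#' (B, C, N, O, F, Si, P, S, Cl, Br, I).
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector.
#' @export
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) !is.null(parse_mol_graph(s)), logical(1),
         USE.NAMES = FALSE)
}

#' Canonical non-stereochemical SMILES
#'
#' Strips stereo descriptors (`/`, `\\`, `@`, `@@`) and returns the canonical
#' SMILES of the remaining constitution, so that any two spellings of the same
#' molecular constitution map to one string. Invalid inputs map to `NA`, which
#' downstream candidate filtering treats as "invalid".
#'
#' @param smiles character vector.
#' @return character vector; `NA_character_` where the input is not a valid
#'   molecule.
#' @export
canonicalize_nonstereo <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    s2 <- gsub("@", "", gsub("[/\\\\]", "", s), fixed = TRUE)
    # empty brackets like [] after stripping cannot occur; [CH] forms remain
    if (!smiles_is_valid(s2)) return(NA_character_)
    .ob_canonical(s2)
  }, character(1), USE.NAMES = FALSE)
}

#' Hill-notation molecular formula
#'
#' Computes the molecular formula (including implicit hydrogens) in Hill order:
#' carbon first, hydrogen second, all other elements alphabetically.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of formulas; `NA` for invalid inputs.
#' @export
mol_formula <- function(smiles) {
  vapply(smiles, function(s) {
    g <- parse_mol_graph(s)
    if (is.null(g)) return(NA_character_)
    tab <- table(g$elements)
    nh <- sum(g$n_h) + sum(g$elements == "H")
    counts <- as.list(tab[names(tab) != "H"])
    if (nh > 0) counts[["H"]] <- nh
    els <- names(counts)
    ord <- if ("C" %in% els) {
      c("C", intersect("H", els), sort(setdiff(els, c("C", "H"))))
    } else {
      sort(els)
    }
    paste(vapply(ord, function(el) {
      k <- as.integer(counts[[el]])
      paste0(el, if (k > 1L) k else "")
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Heavy-atom count of a molecule
#'
#' @param smiles character vector of SMILES.
#' @return integer vector of non-hydrogen atom counts (`NA` for invalid input).
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    g <- parse_mol_graph(s)
    if (is.null(g)) return(NA_integer_)
    sum(g$elements != "H")
  }, integer(1), USE.NAMES = FALSE)
}
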
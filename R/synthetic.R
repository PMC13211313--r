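# Deterministic toy molecule/spectrum generator. A fragment grammar over
# C/N/O/halogen chains, rings and carbonyls produces valid molecules; a
# documented additive rule table assigns 1H/13C chemical shifts per
# topologically distinct atom environment; spectra are rendered onto the
# dense-grid convention so that every downstream stage is trainable and
# testable without external data.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# -- fragment grammar ---------------------------------------------------------

# Recursively grow a molecule as a tree of fragments under a heavy-atom
# budget held in `env$left`. Serialization puts every child in parentheses,
# which is always valid SMILES.
.grow_fragment <- function(env, parent) {
  if (env$left <= 0L) return(NULL)
  hetero_parent <- parent %in% c("O", "N", "C=O")
  r <- stats::runif(1)
  if (!hetero_parent && env$left >= 6L && r < 0.14) {
    env$left <- env$left - 6L
    sub <- if (stats::runif(1) < 0.4) .grow_fragment(env, "ring") else NULL
    if (is.null(sub)) return("c1ccccc1")
    return(sprintf("c1ccc(%s)cc1", sub))
  }
  if (!hetero_parent && env$left >= 6L && r < 0.20) {
    env$left <- env$left - 6L
    sub <- if (stats::runif(1) < 0.4) .grow_fragment(env, "ring") else NULL
    if (is.null(sub)) return("C1CCCCC1")
    return(sprintf("C1CCC(%s)CC1", sub))
  }
  # atom nodes; heteroatoms and carbonyls never chain onto each other
  pool <- if (hetero_parent) c("C") else c("C", "O", "N", "C=O", "X")
  wts <- if (hetero_parent) 1 else c(0.62, 0.12, 0.08, 0.10, 0.08)
  type <- sample(pool, 1L, prob = wts)
  if (type == "X") {
    env$left <- env$left - 1L
    return(sample(c("F", "Cl", "Br"), 1L, prob = c(0.4, 0.45, 0.15)))
  }
  if (type == "O") {
    env$left <- env$left - 1L
    child <- if (stats::runif(1) < 0.45) .grow_fragment(env, "O") else NULL
    return(if (is.null(child)) "O" else sprintf("O%s", child))
  }
  if (type == "N") {
    env$left <- env$left - 1L
    child <- if (stats::runif(1) < 0.4) .grow_fragment(env, "N") else NULL
    return(if (is.null(child)) "N" else sprintf("N%s", child))
  }
  if (type == "C=O") {
    env$left <- env$left - 2L
    child <- if (stats::runif(1) < 0.75) .grow_fragment(env, "C=O") else NULL
    return(if (is.null(child)) "C=O" else sprintf("C(=O)%s", child))
  }
  # plain sp3 carbon with 0-2 children
  env$left <- env$left - 1L
  k <- sample(0:2, 1L, prob = c(0.30, 0.50, 0.20))
  kids <- character(0)
  for (i in seq_len(k)) {
    ch <- .grow_fragment(env, "C")
    if (!is.null(ch)) kids <- c(kids, ch)
  }
  if (!length(kids)) return("C")
  paste0("C", paste0("(", kids, ")", collapse = ""))
}

.random_molecule <- function(heavy_range) {
  target <- min(heavy_range[2], max(heavy_range[1], 4L + stats::rpois(1L, 6)))
  env <- new.env()
  env$left <- target
  # backbone: a short carbon chain, each position optionally substituted
  backlen <- sample(2:4, 1L)
  env$left <- env$left - backlen
  parts <- character(backlen)
  for (i in seq_len(backlen)) {
    subs <- character(0)
    n_sub <- sample(0:2, 1L, prob = c(0.45, 0.40, 0.15))
    for (s in seq_len(n_sub)) {
      ch <- .grow_fragment(env, "C")
      if (!is.null(ch)) subs <- c(subs, ch)
    }
    parts[i] <- if (length(subs)) paste0("C", paste0("(", subs, ")", collapse = "")) else "C"
  }
  paste(parts, collapse = "")
}

#' Generate unique toy molecules
#'
#' Draws molecules from a deterministic fragment grammar over C/N/O/halogen
#' acyclic chains, benzene and cyclohexane rings, carbonyls, ethers and
#' amines; filters by heavy-atom count; and deduplicates by canonical
#' non-stereochemical SMILES. Fully reproducible given the seed.
#'
#' @param n number of unique molecules required.
#' @param seed integer RNG seed.
#' @param heavy_range `c(min, max)` heavy-atom bounds (default the 5-35 corpus
#'   convention).
#' @return a data frame with columns `smiles` (canonical), `formula` (Hill)
#'   and `heavy_atoms`.
#' @export
generate_toy_molecules <- function(n, seed = 1L, heavy_range = c(5L, 35L)) {
  stopifnot(n > 0, length(heavy_range) == 2, heavy_range[1] <= heavy_range[2])
  .with_seed(seed, {
    seen <- character(0)
    out_smiles <- character(0)
    attempts <- 0L
    max_attempts <- 400L * n
    while (length(out_smiles) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      raw <- .random_molecule(heavy_range)
      can <- canonicalize_nonstereo(raw)
      if (is.na(can) || can %in% seen) next
      ha <- heavy_atom_count(can)
      if (is.na(ha) || ha < heavy_range[1] || ha > heavy_range[2]) next
      seen <- c(seen, can)
      out_smiles <- c(out_smiles, can)
    }
    if (length(out_smiles) < n)
      stop(sprintf("grammar yielded only %d unique molecules in range (wanted %d)",
                   length(out_smiles), n))
    data.frame(smiles = out_smiles,
               formula = mol_formula(out_smiles),
               heavy_atoms = heavy_atom_count(out_smiles),
               stringsAsFactors = FALSE)
  })
}

# -- atom environments and the toy shift rule table ---------------------------

# Atoms that survive iterative leaf pruning lie on cycles.
.ring_atoms <- function(g) {
  n <- length(g$elements)
  if (n == 0L || nrow(g$bonds) == 0L) return(logical(n))
  deg <- integer(n)
  adj <- lapply(g$adj, function(x) x)
  for (a in seq_len(n)) deg[a] <- length(adj[[a]])
  alive <- rep(TRUE, n)
  repeat {
    leaves <- which(alive & deg <= 1L)
    if (!length(leaves)) break
    for (a in leaves) {
      alive[a] <- FALSE
      for (b in adj[[a]]) if (alive[b]) deg[b] <- deg[b] - 1L
      deg[a] <- 0L
    }
  }
  alive
}

# Per-atom structural features feeding both the equivalence classes and the
# shift rules.
.atom_features <- function(g) {
  n <- length(g$elements)
  ring <- .ring_atoms(g)
  bond_to <- function(a) {
    if (!nrow(g$bonds)) return(NULL)
    sel <- g$bonds[, 1] == a | g$bonds[, 2] == a
    if (!any(sel)) return(NULL)
    b <- g$bonds[sel, , drop = FALSE]
    partner <- ifelse(b[, 1] == a, b[, 2], b[, 1])
    cbind(partner = partner, order = b[, 3])
  }
  feats <- vector("list", n)
  for (a in seq_len(n)) {
    bt <- bond_to(a)
    partners <- if (is.null(bt)) integer(0) else bt[, 1]
    orders <- if (is.null(bt)) integer(0) else bt[, 2]
    els <- g$elements[partners]
    carbonyl <- g$elements[a] == "C" && any(els == "O" & orders == 2L)
    ring_sp2 <- ring[a] && any(orders == 2L & ring[partners])
    feats[[a]] <- list(
      element = g$elements[a], n_h = g$n_h[a], ring = ring[a],
      ring_sp2 = ring_sp2, carbonyl = carbonyl,
      partners = partners, orders = orders,
      n_c = sum(els == "C"), n_o1 = sum(els == "O" & orders == 1L),
      n_o2 = sum(els == "O" & orders == 2L), n_n = sum(els == "N"),
      n_hal = sum(els %in% c("F", "Cl", "Br", "I")),
      max_order = if (length(orders)) max(orders) else 0L,
      second_shell = sum(vapply(partners, function(p) {
        max(length(g$adj[[p]]) - 1L, 0L)
      }, integer(1))))
  }
  feats
}

# Morgan-style refinement: initial label from local features, then 4 rounds of
# neighborhood relabelling. Atoms sharing the final label are treated as one
# topologically equivalent environment.
.atom_classes <- function(g, feats) {
  n <- length(g$elements)
  lab <- vapply(seq_len(n), function(a) {
    f <- feats[[a]]
    paste(f$element, f$n_h, f$ring, f$ring_sp2, f$carbonyl,
          f$n_c, f$n_o1, f$n_o2, f$n_n, f$n_hal, sep = "|")
  }, character(1))
  for (iter in 1:4) {
    lab <- vapply(seq_len(n), function(a) {
      f <- feats[[a]]
      nb <- paste(sort(paste0(f$orders, ":", lab[f$partners])), collapse = ",")
      paste0(lab[a], "{", nb, "}")
    }, character(1))
    lab <- as.character(match(lab, sort(unique(lab))))
  }
  as.integer(match(lab, unique(lab)))
}

# The additive shift rule table. Values are deterministic functions of local
# structure only (no randomness); they aim for the right chemical
# neighbourhoods, not literature accuracy.
.c_shift_rule <- function(f) {
  if (f$element != "C") return(NA_real_)
  if (f$carbonyl) {
    if (f$n_o1 > 0) return(171 - 3 * f$n_n)
    if (f$n_n > 0) return(168)
    if (f$n_h > 0) return(201)
    return(206)
  }
  if (f$ring_sp2)
    return(128 + 9 * f$n_o1 + 5 * f$n_n + 1.5 * f$n_hal + 1.2 * max(f$n_c - 2, 0))
  if (f$max_order == 3L) return(75)
  if (f$max_order == 2L) return(124 + 5 * (f$n_c - 1))
  6 + 9.4 * f$n_c + 43 * f$n_o1 + 25 * f$n_n + 12 * f$n_hal + 0.9 * f$second_shell
}

.h_shift_rule <- function(f, feats) {
  if (f$n_h == 0L) return(NA_real_)
  if (f$element == "C") {
    if (f$carbonyl) return(9.7)
    if (f$ring_sp2) return(7.26 + 0.2 * max(f$n_c - 2, 0) + 0.3 * f$n_n + 0.25 * f$n_o1)
    if (f$max_order == 3L) return(2.5)
    if (f$max_order == 2L) return(5.3 + 0.2 * (f$n_c - 1))
    return(0.23 + 0.47 * f$n_c + 2.6 * f$n_o1 + 1.6 * f$n_n + 2.0 * f$n_hal +
             0.08 * f$second_shell)
  }
  if (f$element == "O") {
    nb <- f$partners
    if (length(nb) && any(vapply(nb, function(p) feats[[p]]$carbonyl, logical(1))))
      return(11.2)
    if (length(nb) && any(vapply(nb, function(p) feats[[p]]$ring_sp2, logical(1))))
      return(5.0)
    return(2.6)
  }
  if (f$element == "N") {
    nb <- f$partners
    if (length(nb) && any(vapply(nb, function(p) feats[[p]]$carbonyl, logical(1))))
      return(7.5)
    if (length(nb) && any(vapply(nb, function(p) feats[[p]]$ring_sp2, logical(1))))
      return(3.8)
    return(1.5)
  }
  NA_real_
}

#' Assign toy chemical shifts to a molecule
#'
#' Computes topologically distinct atom environments (Morgan-style
#' neighbourhood refinement on the heavy-atom graph) and assigns each
#' environment a 1H and/or 13C shift from a fixed additive rule table: base
#' value per environment class (sp3 CH3 ~0.9/15, aromatic CH ~7.3/128,
#' carbonyl ~200, ...) plus fixed increments per alpha-substituent class.
#' Fully deterministic; serves as this package's pluggable stand-in for an
#' external shift predictor.
#'
#' @param smiles a valid SMILES string (or a one-row data frame with a
#'   `smiles` column, as produced by [generate_toy_molecules()]).
#' @return a list of class `shift_assignment` with data frames `h` (`shift`,
#'   `weight` = number of equivalent hydrogens), `c` (`shift`, `weight` =
#'   number of equivalent carbons) and `hc` (`h`, `c`, `weight`) for HSQC
#'   cross-peaks of C-H-bearing environments.
#' @export
assign_toy_shifts <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles[1]
  g <- parse_mol_graph(smiles)
  if (is.null(g)) stop("invalid SMILES: ", smiles)
  bad <- setdiff(unique(g$elements), c("C", "N", "O", "F", "Cl", "Br", "I", "H"))
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = " "))
  feats <- .atom_features(g)
  cls <- .atom_classes(g, feats)
  h <- data.frame(shift = numeric(0), weight = numeric(0))
  cc <- data.frame(shift = numeric(0), weight = numeric(0))
  hc <- data.frame(h = numeric(0), c = numeric(0), weight = numeric(0))
  for (k in unique(cls)) {
    members <- which(cls == k)
    f <- feats[[members[1]]]
    cs <- .c_shift_rule(f)
    hs <- .h_shift_rule(f, feats)
    if (!is.na(cs))
      cc <- rbind(cc, data.frame(shift = cs, weight = length(members)))
    if (!is.na(hs))
      h <- rbind(h, data.frame(shift = hs, weight = f$n_h * length(members)))
    if (f$element == "C" && f$n_h > 0L && !is.na(cs) && !is.na(hs))
      hc <- rbind(hc, data.frame(h = hs, c = cs, weight = f$n_h * length(members)))
  }
  structure(list(h = h, c = cc, hc = hc, smiles = smiles),
            class = "shift_assignment")
}

#' Simulate spectra for one molecule
#'
#' Renders the molecule's toy shift assignment onto the dense-grid convention:
#' 1D spectra via Gaussian lines with environment multiplicities as peak
#' intensities, HSQC via cross-peak deposition with 1H broadening and
#' power-0.3 dynamic-range compression. Optional additive Gaussian noise
#' (default sd 0.005 on the normalized scale) is followed by
#' re-normalization. Deterministic given the seed.
#'
#' @param smiles molecule (SMILES string or one-row data frame).
#' @param modalities subset of `c("H1", "C13", "HSQC")`.
#' @param noise_sd additive noise standard deviation (0 disables noise).
#' @param seed RNG seed for the noise draw.
#' @param grids optional named list of grids (`H1`, `C13`, `HSQC_H`, `HSQC_C`).
#' @param line_sigma_h,line_sigma_c 1D Gaussian line widths (ppm); varying
#'   them emulates acquisition-condition shifts between datasets.
#' @param hsqc_h_sigma HSQC 1H broadening (ppm).
#' @return named list of spectra (`spectrum_1d` / `spectrum_hsqc`).
#' @export
simulate_record <- function(smiles, modalities = c("H1", "C13", "HSQC"),
                            noise_sd = 0.005, seed = 1L, grids = list(),
                            line_sigma_h = 0.01, line_sigma_c = 0.1,
                            hsqc_h_sigma = 0.05) {
  stopifnot(all(modalities %in% c("H1", "C13", "HSQC")))
  if (is.data.frame(smiles)) smiles <- smiles$smiles[1]
  shifts <- assign_toy_shifts(smiles)
  gr <- function(name) if (!is.null(grids[[name]])) grids[[name]] else default_grid(name)
  out <- list()
  .with_seed(seed, {
    add_noise <- function(spec) {
      if (noise_sd <= 0) return(spec)
      x <- spec$intensities + stats::rnorm(length(spec$intensities), 0, noise_sd)
      spec$intensities <- if (is.matrix(spec$intensities))
        matrix(x, nrow(spec$intensities)) else x
      spec$normalized <- FALSE
      normalize_instance(spec)
    }
    if ("H1" %in% modalities) {
      pl <- peaklist_1d("H1", shifts$h$shift, shifts$h$weight)
      out$H1 <- add_noise(render_peaklist_1d(pl, gr("H1"), line_sigma_h))
    }
    if ("C13" %in% modalities) {
      pl <- peaklist_1d("C13", shifts$c$shift, shifts$c$weight)
      out$C13 <- add_noise(render_peaklist_1d(pl, gr("C13"), line_sigma_c))
    }
    if ("HSQC" %in% modalities) {
      pl <- peaklist_hsqc(shifts$hc$h, shifts$hc$c, shifts$hc$weight)
      out$HSQC <- add_noise(reconstruct_hsqc(pl, gr("HSQC_H"), gr("HSQC_C"),
                                             h_sigma = hsqc_h_sigma))
    }
  })
  out
}

#' Build a split toy dataset on disk
#'
#' Generates `n` unique molecules, simulates the requested modalities for
#' each, writes one spectrum file per record and modality, and splits records
#' into train/valid/test manifests at the given ratio by largest-remainder
#' rounding. Splits are disjoint by canonical SMILES (every molecule is
#' unique, and each goes to exactly one split).
#'
#' @param n number of records (>= 10).
#' @param out_dir output directory (created if needed).
#' @param ratio split ratio (default `c(7, 2, 1)`).
#' @param seed RNG seed controlling molecules, noise and split order.
#' @param modalities spectra to simulate per record.
#' @param noise_sd per-spectrum additive noise sd.
#' @param heavy_range heavy-atom bounds for the grammar.
#' @param ... further simulation arguments passed to [simulate_record()]
#'   (e.g. `line_sigma_h` for distribution-shifted sets).
#' @return named list of three `dataset_manifest` objects (`train`, `valid`,
#'   `test`), each also written as `<split>.jsonl` under `out_dir`.
#' @export
build_dataset <- function(n, out_dir, ratio = c(7, 2, 1), seed = 1L,
                          modalities = c("H1", "C13", "HSQC"),
                          noise_sd = 0.005, heavy_range = c(5L, 35L), ...) {
  stopifnot(n >= 10, length(ratio) == 3, all(ratio > 0))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  mols <- generate_toy_molecules(n, seed = seed, heavy_range = heavy_range)
  sizes <- .largest_remainder(n, ratio)
  split_of <- rep(c("train", "valid", "test"), times = sizes)
  manifests <- list()
  for (sp in c("train", "valid", "test")) {
    idx <- which(split_of == sp)
    recs <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      spectra <- simulate_record(mols$smiles[i], modalities = modalities,
                                 noise_sd = noise_sd,
                                 seed = seed + (7919L * i) %% 1000000L, ...)
      files <- list()
      for (m in names(spectra)) {
        f <- file.path(out_dir, sprintf("rec_%05d_%s.rds", i, m))
        write_spectrum(spectra[[m]], f)
        files[[m]] <- f
      }
      recs[[k]] <- list(smiles = mols$smiles[i], formula = mols$formula[i],
                        heavy_atoms = mols$heavy_atoms[i], files = files)
    }
    man <- structure(list(split = sp, seed = as.integer(seed), records = recs),
                     class = "dataset_manifest")
    write_manifest(man, file.path(out_dir, paste0(sp, ".jsonl")))
    manifests[[sp]] <- man
  }
  manifests
}

# Largest-remainder apportionment of n into parts proportional to ratio.
.largest_remainder <- function(n, ratio) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- n - sum(base)
  frac <- q - base
  ord <- order(frac, decreasing = TRUE)
  extra <- integer(length(ratio))
  if (rem > 0) extra[ord[seq_len(rem)]] <- 1L
  as.integer(base + extra)
}

#' @export
print.shift_assignment <- function(x, ...) {
  cat(sprintf("<shift_assignment '%s': %d 1H, %d 13C environments, %d HSQC pairs>\n",
              x$smiles, nrow(x$h), nrow(x$c), nrow(x$hc)))
  invisible(x)
}
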
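# Seeded synthetic data and the brute-force oracles every strategy is
# tested against.  All randomness flows through an explicit seed; RNG
# state is restored on exit so calls never disturb the caller's stream.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Specification for a batch of random sequences
#'
#' @param n_sequences Number of sequences.
#' @param length Length (scalar) or inclusive range `c(lo, hi)`.
#' @param gc_content Probability mass on `{G, C}`, split evenly;
#'   `P(A) = P(U)` share the rest.
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(n_sequences, length, gc_content = 0.5, seed = 1L) {
  dp_assert(n_sequences >= 1, "dpfold_domain", "n_sequences must be >= 1")
  length <- as.integer(length)
  dp_assert(all(length >= 1), "dpfold_domain", "length must be >= 1")
  dp_assert(length(length) <= 2, "dpfold_domain",
            "length must be a scalar or a range c(lo, hi)")
  dp_assert(gc_content >= 0 && gc_content <= 1, "dpfold_domain",
            "gc_content must lie in [0, 1]")
  structure(list(n_sequences = as.integer(n_sequences), length = length,
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate random RNA sequences from a spec
#'
#' Residues are i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(U) = (1 - gc)/2`; fully deterministic under the spec's
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @return List of [rna_sequence()] objects, ids `sim_1`, `sim_2`, ...
#' @export
random_sequences <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  gc <- spec$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_sequences), function(k) {
      len <- if (length(spec$length) == 2)
        sample(spec$length[1]:spec$length[2], 1) else spec$length
      rna_sequence(paste(sample(RNA_ALPHABET, len, replace = TRUE, prob = probs),
                         collapse = ""),
                   id = paste0("sim_", k))
    })
  })
}

#' Enumerate every valid secondary structure of a sequence
#'
#' The complete set of pair sets satisfying unique pairing, nestedness,
#' the hairpin-span rule and chemical pairing — the oracle space all
#' four strategies are checked against.  Interval decomposition by the
#' partner of the rightmost base makes the enumeration duplicate-free by
#' construction.
#'
#' @param seq An [rna_sequence()].
#' @param cfg A [fold_config()].
#' @param cap Refuse sequences longer than this (combinatorial
#'   explosion guard; default 16).
#' @return List of [secondary_structure()] objects (always includes the
#'   empty structure).
#' @export
enumerate_structures <- function(seq, cfg = fold_config(), cap = 16L) {
  n <- seq$n
  dp_assert(n <= cap, "dpfold_domain",
            sprintf("n = %d exceeds the enumeration cap %d", n, cap))
  theta <- pairing_matrix(seq, cfg)
  memo <- new.env(parent = emptyenv())
  # returns list of 2-column pair matrices over [i, j]
  enum <- function(i, j) {
    if (j - i < cfg$min_span) return(list(matrix(integer(0), ncol = 2)))
    k <- paste0(i, ",", j)
    if (!is.null(memo[[k]])) return(memo[[k]])
    out <- enum(i, j - 1L)                    # j unpaired
    for (p in i:(j - cfg$min_span)) {
      if (!theta[p, j]) next
      left <- if (p - 1L >= i) enum(i, p - 1L) else list(matrix(integer(0), ncol = 2))
      inner <- enum(p + 1L, j - 1L)
      for (L in left) for (In in inner) {
        out[[length(out) + 1L]] <- rbind(L, c(p, j), In)
      }
    }
    memo[[k]] <- out
    out
  }
  lapply(enum(1L, n), function(p) secondary_structure(n, p))
}

#' Perturb a reference structure to a chosen TP/FP/FN composition
#'
#' Removes `n_drop` randomly chosen reference pairs and adds `n_add`
#' random valid non-reference pairs, keeping the result a valid
#' structure.  The confusion of the result against `ref` then has
#' `fn >= n_drop` and `fp = n_add`.
#'
#' @param ref Reference [secondary_structure()].
#' @param n_drop Pairs to delete (`<= |ref|`).
#' @param n_add Valid foreign pairs to insert.
#' @param seed Integer seed.
#' @param cfg A [fold_config()].
#' @param seq Optional sequence restricting additions to chemically
#'   allowed pairs.
#' @return A valid [secondary_structure()].
#' @section Errors: an impossible addition budget signals
#'   `dpfold_perturbation`.
#' @export
perturb_structure <- function(ref, n_drop, n_add, seed = 1L,
                              cfg = fold_config(), seq = NULL) {
  dp_assert(n_drop >= 0 && n_drop <= n_pairs(ref), "dpfold_domain",
            "n_drop must lie in [0, |ref.pairs|]")
  dp_assert(n_add >= 0, "dpfold_domain", "n_add must be >= 0")
  n <- ref$n
  ref_keys <- if (n_pairs(ref) == 0) character(0) else
    paste(ref$pairs[, 1], ref$pairs[, 2])
  with_seed(seed, {
    kept <- ref$pairs
    if (n_drop > 0) {
      kept <- kept[-sample(nrow(kept), n_drop), , drop = FALSE]
    }
    # candidate additions: admissible, not in the reference
    cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cand <- cand[cand[, 2] - cand[, 1] >= cfg$min_span, , drop = FALSE]
    if (!is.null(seq)) {
      ok <- cfg$pair_matrix[cbind(seq$code[cand[, 1]], seq$code[cand[, 2]])]
      cand <- cand[ok, , drop = FALSE]
    }
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% ref_keys), , drop = FALSE]
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    added <- 0L
    cur <- kept
    for (r in seq_len(nrow(cand))) {
      if (added == n_add) break
      trial <- rbind(cur, cand[r, ])
      s <- secondary_structure(n, trial)
      if (structure_is_valid(s, cfg, seq)) {
        cur <- trial
        added <- added + 1L
      }
    }
    if (added < n_add)
      dp_error("dpfold_perturbation",
               sprintf("could only add %d of %d requested pairs", added, n_add))
    secondary_structure(n, cur)
  })
}

# -- brute-force oracles --------------------------------------------------

#' Oracle: maximum pair count by exhaustive enumeration
#'
#' @inheritParams enumerate_structures
#' @return Integer maximum number of pairs over all valid structures.
#' @export
oracle_max_pairs <- function(seq, cfg = fold_config(), cap = 16L) {
  max(vapply(enumerate_structures(seq, cfg, cap), n_pairs, integer(1)))
}

#' Oracle: minimum loop-decomposition energy by exhaustive enumeration
#'
#' @inheritParams enumerate_structures
#' @param em An [energy_model()].
#' @return Minimum of [loop_decomposition_energy()] over all valid
#'   structures (0 for the empty structure is always a candidate).
#' @export
oracle_min_energy <- function(seq, cfg = fold_config(),
                              em = default_energy_model(), cap = 16L) {
  min(vapply(enumerate_structures(seq, cfg, cap),
             loop_decomposition_energy, numeric(1), seq = seq, em = em))
}

#' Oracle: optimal non-crossing stem-subset energy
#'
#' Brute force over all subsets of the enumerated stem pool whose pair
#' union is a valid structure (disjoint, non-crossing).
#'
#' @inheritParams oracle_min_energy
#' @return Minimum total stem energy (0 for the empty subset).
#' @export
oracle_stem_min_energy <- function(seq, cfg = fold_config(),
                                   em = default_energy_model()) {
  pool <- enumerate_stems(seq, cfg, em)
  m <- nrow(pool)
  best <- 0
  if (m == 0) return(best)
  plist <- lapply(seq_len(m), function(r) stem_pairs(pool[r, ]))
  # depth-first over subsets, pruning any branch whose partial union is
  # already invalid (supersets of an invalid union stay invalid)
  recurse <- function(r, pairs, energy) {
    if (r > m) {
      if (energy < best) best <<- energy
      return(invisible(NULL))
    }
    recurse(r + 1L, pairs, energy)  # skip stem r
    cand <- rbind(pairs, plist[[r]])
    if (!anyDuplicated(as.vector(cand)) &&
        structure_is_valid(secondary_structure(seq$n, cand), cfg)) {
      recurse(r + 1L, cand, energy + pool$energy[r])
    }
  }
  recurse(1L, matrix(integer(0), ncol = 2), 0)
  best
}

#' Oracle: partition function and pair probabilities by enumeration
#'
#' Sums Boltzmann weights `exp(-sum(E_pair)/RT)` over the enumerated
#' structure space.
#'
#' @inheritParams oracle_min_energy
#' @return `list(q = , p = )`: the partition function and the `n` x `n`
#'   pair-probability matrix.
#' @export
oracle_partition <- function(seq, cfg = fold_config(),
                             em = toy_energy_model(pair_energy = 0), cap = 16L) {
  structs <- enumerate_structures(seq, cfg, cap)
  n <- seq$n
  w <- vapply(structs, function(s) {
    if (n_pairs(s) == 0) return(1)
    e <- sum(vapply(seq_len(n_pairs(s)), function(r)
      em$pair_energy(seq, s$pairs[r, 1], s$pairs[r, 2]), numeric(1)))
    exp(-e / cfg$rt)
  }, numeric(1))
  q <- sum(w)
  p <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    s <- structs[[k]]
    if (n_pairs(s) == 0) next
    idx <- s$pairs
    p[idx] <- p[idx] + w[k]
    p[idx[, 2:1, drop = FALSE]] <- p[idx[, 2:1, drop = FALSE]] + w[k]
  }
  list(q = q, p = p / q)
}
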
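# Boltzmann-ensemble mode: a pair-level partition function over exactly
# the structure space the other strategies search.  Per-pair energies
# E_pair come from the energy model; the Boltzmann weight of a structure
# is exp(-sum(E_pair)/RT).
#
#   Q(i, j)  = Q(i, j-1) + sum_{k : theta(k, j)} Q(i, k-1) * Qb(k, j)
#   Qb(k, j) = exp(-E_pair(k, j)/RT) * Q(k+1, j-1)
# with Q = 1 on empty intervals.  With E_pair == 0, Q(1, n) counts the
# valid structures exactly.
#
# Numerical safety: for long sequences the tables are computed in a
# per-nucleotide rescaled form Q'(i, j) = Q(i, j) * s^(j - i + 1); the
# recurrences are invariant under this substitution (each pair weight
# absorbs s^2, each unpaired base one factor of s) and all probability
# ratios cancel the scale exactly.  The reported `q` is the natural-scale
# value when representable and `log_q` is always exact.

#' Partition-function folding strategy
#'
#' @param seq An [rna_sequence()].
#' @param cfg A [fold_config()] (`rt` is taken from here).
#' @param em An [energy_model()] supplying `pair_energy`.
#' @return A [fold_strategy()] with tables `Q`, `Qb`.  The
#'   `prediction_result` carries extras `probabilities` (the base-pair
#'   probability matrix), `q` (natural scale; `NA` if rescaled out of
#'   range) and `log_q`.
#' @export
partition_strategy <- function(seq, cfg = fold_config(), em = default_energy_model()) {
  n <- seq$n
  theta <- pairing_matrix(seq, cfg)
  rt <- cfg$rt
  # per-nucleotide scale: 1 at desk sizes, < 1 for long sequences where
  # the unscaled ensemble sum would overflow double precision
  scale_s <- if (n > 300) 0.5 else 1
  log_s <- log(scale_s)
  # scaled pair weights w'(i, j) = exp(-E_pair/RT) * s^2
  wt <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (theta[i, j])
    wt[i, j] <- exp(-em$pair_energy(seq, i, j) / rt) * scale_s^2

  fill_cell <- function(state, i, j) {
    if (i == j) {
      dp_set(state, "Qb", i, j, 0)
      dp_set(state, "Q", i, j, scale_s)
      return(invisible(NULL))
    }
    qb <- if (theta[i, j]) wt[i, j] * dp_cell(state, "Q", i + 1L, j - 1L) else 0
    dp_set(state, "Qb", i, j, qb)
    q <- dp_cell(state, "Q", i, j - 1L) * scale_s
    ks <- which(theta[, j])
    ks <- ks[ks >= i]
    if (length(ks) > 0) {
      # Qb(i, j) was written just above, so every Qb(k, j) is available
      qleft <- vapply(ks, function(k) dp_cell(state, "Q", i, k - 1L), numeric(1))
      qbk <- vapply(ks, function(k) dp_cell(state, "Qb", k, j), numeric(1))
      q <- q + sum(qleft * qbk)
    }
    if (!is.finite(q))
      dp_error("dpfold_engine_invariant",
               "partition function overflow despite rescaling")
    dp_set(state, "Q", i, j, q)
  }

  traceback <- function(state) {
    P <- pair_probabilities(state)
    qs <- dp_cell(state, "Q", 1L, n)
    state$extras <- list(
      probabilities = P,
      q = if (scale_s == 1) qs else exp(log(qs) - n * log_s),
      log_q = log(qs) - n * log_s
    )
    threshold_structure(P, cfg)
  }

  fold_strategy(
    name = "partition",
    new_state = function() {
      st <- dp_allocate(n, tables = c(Q = 1, Qb = 0), audit = cfg$audit)
      st$scale_s <- scale_s
      st$theta <- theta
      st
    },
    fill_cell = fill_cell,
    final_score = function(state) dp_cell(state, "Q", 1L, n),
    traceback = traceback,
    rescore = NULL  # ensemble mode: no single-structure objective
  )
}

#' Fill the partition-function tables
#'
#' @inheritParams partition_strategy
#' @return A `dp_state` with tables `Q` (unconstrained partition function
#'   over `[i, j]`) and `Qb` (partition function given `(i, j)` paired).
#' @examples
#' st <- partition_fill(validate_sequence("GAAAC"), em = toy_energy_model(pair_energy = 0))
#' st$Q[1, 5]  # 2: the empty structure and {(1,5)}
#' @export
partition_fill <- function(seq, cfg = fold_config(), em = default_energy_model()) {
  dp_fill_state(seq, partition_strategy(seq, cfg, em), cfg)
}

#' Base-pair probabilities from a filled partition state
#'
#' Outside completion of the inside tables: `P(i, j)` is the Boltzmann
#' mass of all structures containing `(i, j)`, divided by `Q(1, n)`.
#' The outer sum decomposes by the pair directly enclosing `(i, j)`; all
#' rescaling factors cancel exactly.
#'
#' @param state State from [partition_fill()].
#' @return Symmetric `n` x `n` matrix of probabilities in `[0, 1]`.
#' @export
pair_probabilities <- function(state) {
  n <- state$n
  Qm <- state$Q; Qbm <- state$Qb
  s <- state$scale_s
  qtot <- Qm[1, n]
  # empty-interval-safe scaled lookup
  qq <- function(i, j) if (j < i) 1 else Qm[i, j]
  P <- matrix(0, n, n)
  for (d in (n - 1L):1L) {
    for (i in seq_len(n - d)) {
      j <- i + d
      if (Qbm[i, j] <= 0) next
      acc <- qq(1, i - 1L) * qq(j + 1L, n) / qtot
      if (i > 1L && j < n) {
        for (k in seq_len(i - 1L)) {
          ls <- (j + 1L):n
          ls <- ls[P[k, ls] > 0]
          if (length(ls) == 0) next
          # Q(j+1, l-1) is the empty interval (= 1) when l = j + 1
          q_right <- ifelse(ls - 1L < j + 1L, 1, Qm[cbind(j + 1L, pmax(ls - 1L, j + 1L))])
          acc <- acc + sum(P[k, ls] * qq(k + 1L, i - 1L) * q_right /
                             Qm[cbind(k + 1L, ls - 1L)])
        }
      }
      P[i, j] <- P[j, i] <- Qbm[i, j] * acc
    }
  }
  P
}

#' Structure from thresholded pair probabilities
#'
#' Greedily selects pairs with probability above the threshold in
#' decreasing probability order, skipping any that would violate
#' [check_structure()].  At the default threshold 0.5 at most one partner
#' per base can qualify, so the selection is conflict-free up to
#' crossings.
#'
#' @param P Pair-probability matrix (as from [pair_probabilities()]).
#' @param cfg A [fold_config()] (`pair_prob_threshold`, `min_span`).
#' @return A valid [secondary_structure()].
#' @export
threshold_structure <- function(P, cfg = fold_config()) {
  n <- nrow(P)
  idx <- which(upper.tri(P) & P > cfg$pair_prob_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(secondary_structure(n))
  ord <- order(-P[idx], idx[, 1], idx[, 2])  # by prob, ties by position
  idx <- idx[ord, , drop = FALSE]
  chosen <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(idx))) {
    cand <- rbind(chosen, idx[r, ])
    s <- secondary_structure(n, cand)
    if (structure_is_valid(s, cfg)) chosen <- cand
  }
  secondary_structure(n, chosen)
}
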
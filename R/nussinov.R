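# Maximum base-pairing DP.  M(i, j) is the maximum number of pairs on
# the subsequence i..j; each cell is the max over four cases:
#   (1) i unpaired:              M(i+1, j)
#   (2) j unpaired:              M(i, j-1)
#   (3) i paired with j:         M(i+1, j-1) + 1, when theta(i, j)
#   (4) bifurcation:             max_k M(i, k) + M(k+1, j), i <= k < j
# theta(i, j) folds in both chemistry (can_pair) and the hairpin-span
# rule (j - i >= min_span) so that traceback can never emit a structure
# check_structure() would reject.  Ties break in case order (1)-(4),
# then smallest split point k.

#' Nussinov maximum base-pairing strategy
#'
#' @param seq An [rna_sequence()].
#' @param cfg A [fold_config()].
#' @return A [fold_strategy()].
#' @export
nussinov_strategy <- function(seq, cfg = fold_config()) {
  n <- seq$n
  theta <- pairing_matrix(seq, cfg)

  fill_cell <- function(state, i, j) {
    if (i == j) { dp_set(state, "M", i, j, 0); return(invisible(NULL)) }
    best <- dp_cell(state, "M", i + 1L, j)                    # case 1
    best <- max(best, dp_cell(state, "M", i, j - 1L))          # case 2
    if (theta[i, j])                                           # case 3
      best <- max(best, dp_cell(state, "M", i + 1L, j - 1L) + 1)
    if (j - i >= 2L) {                                         # case 4
      ks <- (i + 1L):(j - 1L)  # k = i duplicates case 1
      splits <- dp_vec(state, "M", rep(i, length(ks)), ks) +
        dp_vec(state, "M", ks + 1L, rep(j, length(ks)))
      best <- max(best, splits)
    }
    dp_set(state, "M", i, j, best)
  }

  traceback <- function(state) {
    eqv <- function(a, b) a == b
    pairs <- matrix(integer(0), ncol = 2)
    stack <- list(c(1L, n))
    while (length(stack) > 0) {
      iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- iv[1]; j <- iv[2]
      if (j <= i) next
      v <- dp_cell(state, "M", i, j)
      if (v == 0) next
      if (eqv(v, dp_cell(state, "M", i + 1L, j))) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j)
      } else if (eqv(v, dp_cell(state, "M", i, j - 1L))) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
      } else if (theta[i, j] && eqv(v, dp_cell(state, "M", i + 1L, j - 1L) + 1)) {
        pairs <- rbind(pairs, c(i, j))
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      } else {
        done <- FALSE
        for (k in (i + 1L):(j - 1L)) {
          if (eqv(v, dp_cell(state, "M", i, k) + dp_cell(state, "M", k + 1L, j))) {
            stack[[length(stack) + 1L]] <- c(i, k)
            stack[[length(stack) + 1L]] <- c(k + 1L, j)
            done <- TRUE
            break
          }
        }
        if (!done)
          dp_error("dpfold_engine_invariant",
                   sprintf("nussinov traceback stuck at (%d,%d)", i, j))
      }
    }
    secondary_structure(n, pairs)
  }

  fold_strategy(
    name = "nussinov",
    new_state = function() dp_allocate(n, tables = c(M = 0), audit = cfg$audit),
    fill_cell = fill_cell,
    final_score = function(state) dp_cell(state, "M", 1L, n),
    traceback = traceback,
    rescore = function(s) n_pairs(s),
    score_tol = 0
  )
}

#' Fill the Nussinov matrix
#'
#' Runs the engine's span-ordered fill and returns the state (table `M`).
#'
#' @inheritParams nussinov_strategy
#' @return A `dp_state` with table `M`.
#' @examples
#' st <- nussinov_fill(validate_sequence("GGGAAAACCC"))
#' st$M[1, 10]  # 3
#' @export
nussinov_fill <- function(seq, cfg = fold_config()) {
  dp_fill_state(seq, nussinov_strategy(seq, cfg), cfg)
}

#' Trace back a filled Nussinov state
#'
#' @param state State from [nussinov_fill()].
#' @inheritParams nussinov_strategy
#' @return A [secondary_structure()] with `M(1, n)` pairs.
#' @export
nussinov_traceback <- function(state, seq, cfg = fold_config()) {
  nussinov_strategy(seq, cfg)$traceback(state)
}
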
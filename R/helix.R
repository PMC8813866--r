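# Helix/stem-region DP: enumerate every stem region into an auxiliary
# stem pool, then minimize total stem energy over stem placements and
# interval splits.
#
#   E(i, j) = 0                                  when j - i < base span
#   E(i, j) = min( H(i, j, k).energy + E(i+k, j-k)  over pool stems
#                                                   starting at i, ending at j;
#                  E(i, k) + E(k+1, j)              over splits i < k < j )
#
# The base-case span threshold is 2 * (min_stem_len - 1) + min_span — at
# the defaults (3 pairs, span 4) exactly 8, the smallest window that
# admits a minimum-length helix around a legal hairpin.

helix_base_span <- function(cfg) 2L * (cfg$min_stem_len - 1L) + cfg$min_span

#' Enumerate all stem regions of a sequence
#'
#' A stem region `H(i, j, k)` is a run of `k` consecutively stacked pairs
#' `(i+t, j-t)`, `t = 0..k-1`, whose innermost pair still satisfies the
#' hairpin-span rule.  All maximal and shorter stems with
#' `k >= min_stem_len` are listed, each carrying the sum of its `k - 1`
#' stacking energies; ordering is deterministic by `(i, j, k)`.
#'
#' @param seq An [rna_sequence()].
#' @param cfg A [fold_config()] (`min_stem_len`, `min_span`,
#'   `allowed_pairs`).
#' @param em An [energy_model()] supplying the stack energies.
#' @return A data frame with columns `i`, `j`, `k`, `energy`.
#' @examples
#' enumerate_stems(validate_sequence("GGGAAAACCC"))
#' @export
enumerate_stems <- function(seq, cfg = fold_config(), em = default_energy_model()) {
  n <- seq$n
  theta <- pairing_matrix(seq, cfg)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || !theta[i, j]) next
      # extend inward while pairs remain chemically possible and legal
      kmax <- 0L
      t <- 0L
      while (i + t < j - t && theta[i + t, j - t]) {
        kmax <- t + 1L
        t <- t + 1L
      }
      if (kmax < cfg$min_stem_len) next
      for (k in cfg$min_stem_len:kmax) {
        steps <- if (k >= 2) 0:(k - 2L) else integer(0)
        energy <- sum(vapply(steps, function(tt) em$stack(seq, i + tt, j - tt),
                             numeric(1)))
        out[[length(out) + 1L]] <- c(i = i, j = j, k = k, energy = energy)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      energy = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$i, df$j, df$k), , drop = FALSE]
}

# Pairs (as a 2-column matrix) covered by one stem row.
stem_pairs <- function(st) {
  t <- 0:(st[["k"]] - 1L)
  cbind(st[["i"]] + t, st[["j"]] - t)
}

#' Helix-based folding strategy
#'
#' @inheritParams enumerate_stems
#' @return A [fold_strategy()] with table `E` and a stem-pool auxiliary
#'   storage.
#' @export
helix_strategy <- function(seq, cfg = fold_config(), em = default_energy_model()) {
  n <- seq$n
  pool <- enumerate_stems(seq, cfg, em)
  base_span <- helix_base_span(cfg)
  # stems indexed by their outer (i, j) for O(1) lookup during fill
  key <- function(i, j) paste0(i, ",", j)
  by_ij <- split(seq_len(nrow(pool)), paste0(pool$i, ",", pool$j))

  cell_options <- function(state, i, j) {
    # list of candidate (value, kind, payload); deterministic order:
    # stems by ascending k, then splits by ascending k
    opts <- list()
    rows <- by_ij[[key(i, j)]]
    if (!is.null(rows)) {
      for (r in rows) {
        k <- pool$k[r]
        v <- pool$energy[r] + dp_cell(state, "E", i + k, j - k)
        opts[[length(opts) + 1L]] <- list(value = v, kind = "stem", row = r)
      }
    }
    # split range is i <= k < j: allowing k = i (single-base left flank)
    # closes a boundary gap — without it a stem starting at i + 1 and
    # ending exactly at j could never be isolated, while the mirrored
    # right-flank trim (k = j - 1) is always available
    for (k in i:(j - 1L)) {
      v <- dp_cell(state, "E", i, k) + dp_cell(state, "E", k + 1L, j)
      opts[[length(opts) + 1L]] <- list(value = v, kind = "split", k = k)
    }
    opts
  }

  fill_cell <- function(state, i, j) {
    if (j - i < base_span) { dp_set(state, "E", i, j, 0); return(invisible(NULL)) }
    opts <- cell_options(state, i, j)
    dp_set(state, "E", i, j, min(vapply(opts, `[[`, numeric(1), "value")))
  }

  sel <- new.env(parent = emptyenv())  # stems chosen by the last traceback
  sel$rows <- integer(0)

  traceback <- function(state) {
    sel$rows <- integer(0)
    pairs <- matrix(integer(0), ncol = 2)
    stack <- list(c(1L, n))
    while (length(stack) > 0) {
      iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- iv[1]; j <- iv[2]
      if (j <= i || j - i < base_span) next
      v <- dp_cell(state, "E", i, j)
      opts <- cell_options(state, i, j)
      done <- FALSE
      for (o in opts) {
        if (feq(v, o$value)) {
          if (o$kind == "stem") {
            st <- pool[o$row, ]
            sel$rows <- c(sel$rows, o$row)
            pairs <- rbind(pairs, stem_pairs(st))
            stack[[length(stack) + 1L]] <- c(st$i + st$k, st$j - st$k)
          } else {
            stack[[length(stack) + 1L]] <- c(i, o$k)
            stack[[length(stack) + 1L]] <- c(o$k + 1L, j)
          }
          done <- TRUE
          break
        }
      }
      if (!done) dp_error("dpfold_engine_invariant",
                          sprintf("helix traceback stuck at (%d,%d)", i, j))
    }
    secondary_structure(n, pairs)
  }

  rescore <- function(s) {
    # total energy of the stems selected by the last traceback; the stem
    # decomposition of a bare pair set is ambiguous where two selected
    # stems abut, so the selection itself is the scored object
    if (length(sel$rows) == 0) return(0)
    chosen <- do.call(rbind, lapply(sel$rows, function(r) stem_pairs(pool[r, ])))
    dp_assert(nrow(chosen) == n_pairs(s) &&
                all(chosen[order(chosen[, 1]), , drop = FALSE] == s$pairs),
              "dpfold_engine_invariant",
              "selected stems do not reproduce the traced structure")
    sum(pool$energy[sel$rows])
  }

  fold_strategy(
    name = "helix",
    new_state = function() dp_allocate(
      n, tables = c(E = 0),
      aux = list(kind = "stem_pool_op", payload = pool),
      audit = cfg$audit),
    fill_cell = fill_cell,
    final_score = function(state) dp_cell(state, "E", 1L, n),
    traceback = traceback,
    rescore = rescore,
    score_tol = 1e-9
  )
}

#' Fill the helix DP table
#'
#' @inheritParams helix_strategy
#' @return A `dp_state` with table `E` and the stem pool in `aux`.
#' @export
helix_fill <- function(seq, cfg = fold_config(), em = default_energy_model()) {
  dp_fill_state(seq, helix_strategy(seq, cfg, em), cfg)
}

#' Trace back a filled helix state
#'
#' @param state State from [helix_fill()].
#' @inheritParams helix_strategy
#' @return A [secondary_structure()] formed by the selected stems.
#' @export
helix_traceback <- function(state, seq, cfg = fold_config(),
                            em = default_energy_model()) {
  helix_strategy(seq, cfg, em)$traceback(state)
}
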
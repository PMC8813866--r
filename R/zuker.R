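# Minimum free energy DP over a pluggable loop-energy model.
#
#   W(i, j): optimal energy of i..j, any pairing status.  W(i, i) = 0 and
#     W 0-extends over short spans (the empty structure is always
#     admissible, so W <= 0 whenever the model offers nothing better).
#   V(i, j): optimal energy given (i, j) paired; "forbidden" (+Inf) when
#     the residues cannot pair or j - i < min_span.
#     V = min(E1 hairpin, E2 stack + V(i+1, j-1),
#             E3 interior/bulge closing (ip, jp) with
#                (ip - i) + (j - jp) > 2 and loop size <= cap,
#             E4 multibranch: a + min_k WM(i+1, k) + WM(k+1, j-1)).
#   WM(i, j): multibranch segment holding >= 1 branch, with affine
#     per-branch (b) and per-unpaired (c) costs:
#     WM = min(WM(i, j-1) + c, WM(i+1, j) + c, V(i, j) + b,
#              min_k WM(i, k) + WM(k+1, j)).
# At a = b = c = 0 the multibranch table reduces to "W restricted to
# paired content", recovering the bare two-segment split formulation.
# Ties break in the order written above, then smallest split point.

FLOAT_TOL <- 1e-9

feq <- function(a, b) {
  (is.infinite(a) && is.infinite(b) && sign(a) == sign(b)) ||
    (is.finite(a) && is.finite(b) && abs(a - b) <= FLOAT_TOL * max(1, abs(a), abs(b)))
}

# Admissible interior/bulge closings (ip, jp) for an exterior pair (i, j):
# i < ip < jp < j, (ip - i) + (j - jp) > 2 (excludes the stack case), and
# unpaired size (ip - i - 1) + (j - jp - 1) <= cap.
interior_closings <- function(i, j, cap) {
  out <- NULL
  ip_max <- j - 2L
  for (ip in (i + 1L):ip_max) {
    left <- ip - i - 1L
    if (left > cap) break
    jp_lo <- max(ip + 1L, j - 1L - (cap - left))
    jp_hi <- j - 1L
    if (jp_lo > jp_hi) next
    jps <- jp_lo:jp_hi
    jps <- jps[(ip - i) + (j - jps) > 2L]
    if (length(jps) > 0) out <- rbind(out, cbind(ip, jps))
  }
  out
}

#' Zuker minimum free energy strategy
#'
#' @param seq An [rna_sequence()].
#' @param cfg A [fold_config()]; `max_interior_size` caps the
#'   interior-loop scan (use `Inf` for exactness).
#' @param em An [energy_model()].
#' @return A [fold_strategy()] with tables `W`, `V`, `WM`.
#' @export
zuker_strategy <- function(seq, cfg = fold_config(), em = default_energy_model()) {
  n <- seq$n
  theta <- pairing_matrix(seq, cfg)
  cap <- cfg$max_interior_size
  a <- em$multiloop_a; b <- em$multiloop_b; cc <- em$multiloop_c

  v_cases <- function(state, i, j) {
    # returns the four case values (E1..E4); Inf where inadmissible
    e1 <- em$hairpin(seq, i, j)
    e2 <- if (j - i >= 2L)
      em$stack(seq, i, j) + dp_cell(state, "V", i + 1L, j - 1L) else Inf
    e3 <- Inf
    if (j - i >= 3L) {
      cl <- interior_closings(i, j, cap)
      if (!is.null(cl) && nrow(cl) > 0) {
        vs <- dp_vec(state, "V", cl[, 1], cl[, 2])
        fin <- which(is.finite(vs))
        for (k in fin) {
          e <- em$internal(seq, i, j, cl[k, 1], cl[k, 2]) + vs[k]
          if (e < e3) e3 <- e
        }
      }
    }
    e4 <- Inf
    if (j - i >= 3L) {
      ks <- (i + 1L):(j - 2L)
      wmL <- dp_vec(state, "WM", rep(i + 1L, length(ks)), ks)
      wmR <- dp_vec(state, "WM", ks + 1L, rep(j - 1L, length(ks)))
      e4 <- a + suppressWarnings(min(wmL + wmR))
    }
    c(e1, e2, e3, e4)
  }

  fill_cell <- function(state, i, j) {
    d <- j - i
    if (d == 0L) {
      dp_set(state, "V", i, j, Inf)
      dp_set(state, "WM", i, j, Inf)
      dp_set(state, "W", i, j, 0)
      return(invisible(NULL))
    }
    if (d < cfg$min_span) {
      # no pair fits: pairing tables forbidden, W holds the empty structure
      dp_set(state, "V", i, j, Inf)
      dp_set(state, "WM", i, j, Inf)
      dp_set(state, "W", i, j, 0)
      return(invisible(NULL))
    }
    v <- if (theta[i, j]) min(v_cases(state, i, j)) else Inf
    dp_set(state, "V", i, j, v)

    wm <- min(dp_cell(state, "WM", i, j - 1L) + cc,
              dp_cell(state, "WM", i + 1L, j) + cc,
              v + b)
    ks <- i:(j - 1L)
    wm_split <- dp_vec(state, "WM", rep(i, length(ks)), ks) +
      dp_vec(state, "WM", ks + 1L, rep(j, length(ks)))
    wm <- suppressWarnings(min(wm, wm_split))
    dp_set(state, "WM", i, j, wm)

    w <- min(v, dp_cell(state, "W", i + 1L, j), dp_cell(state, "W", i, j - 1L))
    if (d >= 3L) {
      ks <- (i + 1L):(j - 2L)
      w_split <- dp_vec(state, "W", rep(i, length(ks)), ks) +
        dp_vec(state, "W", ks + 1L, rep(j, length(ks)))
      w <- min(w, w_split)
    }
    dp_set(state, "W", i, j, w)
  }

  traceback <- function(state) {
    pairs <- matrix(integer(0), ncol = 2)
    tasks <- list(list(t = "W", i = 1L, j = n))
    push <- function(t, i, j) tasks[[length(tasks) + 1L]] <<- list(t = t, i = i, j = j)
    while (length(tasks) > 0) {
      tk <- tasks[[length(tasks)]]; tasks[[length(tasks)]] <- NULL
      i <- tk$i; j <- tk$j
      if (j <= i) next
      d <- j - i
      if (tk$t == "W") {
        if (d < cfg$min_span) next
        v <- dp_cell(state, "W", i, j)
        if (feq(v, dp_cell(state, "V", i, j))) { push("V", i, j); next }
        if (feq(v, dp_cell(state, "W", i + 1L, j))) { push("W", i + 1L, j); next }
        if (feq(v, dp_cell(state, "W", i, j - 1L))) { push("W", i, j - 1L); next }
        done <- FALSE
        if (d >= 3L) for (k in (i + 1L):(j - 2L)) {
          if (feq(v, dp_cell(state, "W", i, k) + dp_cell(state, "W", k + 1L, j))) {
            push("W", i, k); push("W", k + 1L, j); done <- TRUE; break
          }
        }
        if (!done) dp_error("dpfold_engine_invariant",
                            sprintf("zuker W traceback stuck at (%d,%d)", i, j))
      } else if (tk$t == "V") {
        v <- dp_cell(state, "V", i, j)
        pairs <- rbind(pairs, c(i, j))
        cases <- v_cases(state, i, j)
        if (feq(v, cases[1])) next                                   # hairpin
        if (feq(v, cases[2])) { push("V", i + 1L, j - 1L); next }    # stack
        if (is.finite(cases[3])) {                                   # interior
          cl <- interior_closings(i, j, cap)
          done <- FALSE
          for (k in seq_len(nrow(cl))) {
            ip <- cl[k, 1]; jp <- cl[k, 2]
            vin <- dp_cell(state, "V", ip, jp)
            if (is.finite(vin) && feq(v, em$internal(seq, i, j, ip, jp) + vin)) {
              push("V", ip, jp); done <- TRUE; break
            }
          }
          if (done) next
        }
        if (is.finite(cases[4])) {                                   # multibranch
          done <- FALSE
          for (k in (i + 1L):(j - 2L)) {
            e <- a + dp_cell(state, "WM", i + 1L, k) + dp_cell(state, "WM", k + 1L, j - 1L)
            if (feq(v, e)) { push("WM", i + 1L, k); push("WM", k + 1L, j - 1L); done <- TRUE; break }
          }
          if (done) next
        }
        dp_error("dpfold_engine_invariant",
                 sprintf("zuker V traceback stuck at (%d,%d)", i, j))
      } else {  # WM
        v <- dp_cell(state, "WM", i, j)
        if (feq(v, dp_cell(state, "WM", i, j - 1L) + cc)) { push("WM", i, j - 1L); next }
        if (feq(v, dp_cell(state, "WM", i + 1L, j) + cc)) { push("WM", i + 1L, j); next }
        if (feq(v, dp_cell(state, "V", i, j) + b)) { push("V", i, j); next }
        done <- FALSE
        for (k in i:(j - 1L)) {
          e <- dp_cell(state, "WM", i, k) + dp_cell(state, "WM", k + 1L, j)
          if (is.finite(e) && feq(v, e)) { push("WM", i, k); push("WM", k + 1L, j); done <- TRUE; break }
        }
        if (!done) dp_error("dpfold_engine_invariant",
                            sprintf("zuker WM traceback stuck at (%d,%d)", i, j))
      }
    }
    secondary_structure(n, pairs)
  }

  fold_strategy(
    name = "zuker",
    new_state = function() {
      st <- dp_allocate(n, tables = c(W = 0, V = Inf, WM = Inf),
                        aux = list(kind = "free_energy_op", payload = em),
                        audit = cfg$audit)
      st
    },
    fill_cell = fill_cell,
    final_score = function(state) dp_cell(state, "W", 1L, n),
    traceback = traceback,
    rescore = function(s) loop_decomposition_energy(s, seq, em),
    score_tol = 1e-9
  )
}

#' Fill the Zuker W/V/WM tables
#'
#' @inheritParams zuker_strategy
#' @return A `dp_state` with tables `W`, `V`, `WM`.
#' @export
zuker_fill <- function(seq, cfg = fold_config(), em = default_energy_model()) {
  dp_fill_state(seq, zuker_strategy(seq, cfg, em), cfg)
}

#' Trace back a filled Zuker state
#'
#' @param state State from [zuker_fill()].
#' @inheritParams zuker_strategy
#' @return A [secondary_structure()] whose [loop_decomposition_energy()]
#'   equals `W(1, n)` within 1e-9.
#' @export
zuker_traceback <- function(state, seq, cfg = fold_config(),
                            em = default_energy_model()) {
  zuker_strategy(seq, cfg, em)$traceback(state)
}

#' Score a structure by its loop decomposition
#'
#' Independent of the DP: classifies every loop of a valid nested
#' structure (hairpin; stack; interior/bulge; multibranch with affine
#' `a + b * branches + c * unpaired`) and sums the model energies.
#' Exterior bases are free.  Used as the oracle scorer in tests and for
#' traceback verification.
#'
#' @param s A valid [secondary_structure()].
#' @param seq The underlying [rna_sequence()].
#' @param em An [energy_model()].
#' @return Total energy (0 for the empty structure).
#' @export
loop_decomposition_energy <- function(s, seq, em) {
  m <- n_pairs(s)
  if (m == 0) return(0)
  p <- unname(s$pairs)  # sorted by i; nested (colnames stripped: single
                        # element extraction would otherwise name scalars)
  # parent of each pair = tightest enclosing pair
  parent <- integer(m)
  for (k in seq_len(m)) {
    enc <- which(p[, 1] < p[k, 1] & p[, 2] > p[k, 2])
    parent[k] <- if (length(enc) == 0) 0L
                 else enc[which.min(p[enc, 2] - p[enc, 1])]
  }
  total <- 0
  for (k in seq_len(m)) {
    i <- p[k, 1]; j <- p[k, 2]
    ch <- which(parent == k)
    nch <- length(ch)
    if (nch == 0) {
      total <- total + em$hairpin(seq, i, j)
    } else if (nch == 1) {
      ip <- p[ch, 1]; jp <- p[ch, 2]
      if (ip == i + 1 && jp == j - 1) {
        total <- total + em$stack(seq, i, j)
      } else {
        total <- total + em$internal(seq, i, j, ip, jp)
      }
    } else {
      unpaired <- (j - i - 1) - sum(p[ch, 2] - p[ch, 1] + 1)
      total <- total + em$multiloop_a + em$multiloop_b * nch +
        em$multiloop_c * unpaired
    }
  }
  total
}
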
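#' Construct a secondary structure
#'
#' A secondary structure is a set of base pairs `(i, j)`, `i < j`, over a
#' sequence of length `n`.  Constructor normalizes ordering (pairs sorted
#' by `i`); validity against the three structural rules is checked by
#' [check_structure()].
#'
#' @param n Sequence length.
#' @param pairs Two-column integer matrix of `(i, j)` pairs (or `NULL` /
#'   0-row matrix for the empty structure).
#' @return An object of class `secondary_structure` with fields `n` and
#'   `pairs` (2-column matrix, sorted by `i`, columns `i`, `j`).
#' @export
secondary_structure <- function(n, pairs = NULL) {
  n <- as.integer(n)
  dp_assert(length(n) == 1L && !is.na(n) && n >= 1L, "dpfold_domain",
            "n must be a positive integer")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
    # orient i < j, then sort by i
    flip <- pairs[, 1] > pairs[, 2]
    pairs[flip, ] <- pairs[flip, 2:1]
    dp_assert(all(pairs[, 1] < pairs[, 2]), "dpfold_domain",
              "a base cannot pair with itself")
    dp_assert(all(pairs >= 1L & pairs <= n), "dpfold_domain",
              "pair index out of range [1, n]")
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(list(n = n, pairs = pairs), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> n = %d, %d pair(s)\n", x$n, nrow(x$pairs)))
  if (nrow(x$pairs) > 0)
    cat(" ", paste(sprintf("(%d,%d)", x$pairs[, 1], x$pairs[, 2]), collapse = " "), "\n")
  invisible(x)
}

n_pairs <- function(s) nrow(s$pairs)

#' Folding configuration
#'
#' Collects the knobs shared by all folding strategies.
#'
#' @param min_span Minimum `j - i` for any base pair; the default 4 leaves
#'   at least 3 unpaired hairpin bases.  Note the two common conventions
#'   (`j - i >= 4` vs "hairpin loop length >= 4", which differ by one) are
#'   both reachable through this knob.
#' @param algorithm One of `"nussinov"`, `"zuker"`, `"helix"`,
#'   `"partition"`.
#' @param output_mode `"pair_intervals"` (the structure) or `"pair_count"`.
#' @param allowed_pairs Unordered residue pairs that may bind; the default
#'   is Watson-Crick plus wobble.
#' @param energy_params Optional path to a JSON energy-parameter file (see
#'   [read_energy_params()]).
#' @param rt Thermodynamic scale RT in kcal/mol (default 0.616, ~37 C);
#'   used by the partition strategy.
#' @param pair_prob_threshold Probability cut-off for the partition
#'   strategy's structure output, in (0, 1]. Default 0.5, which guarantees
#'   at most one partner per base can qualify.
#' @param min_stem_len Minimum helix length in pairs for the helix
#'   strategy's stem pool (default 3).
#' @param max_interior_size Cap on interior/bulge loop size scanned by the
#'   Zuker recursion (default 30; use `Inf` for exactness).
#' @param audit Record a cell-level read/write log during DP fill (slow;
#'   for invariant checking).
#' @return An object of class `fold_config`.
#' @export
fold_config <- function(min_span = 4L,
                        algorithm = c("nussinov", "zuker", "helix", "partition"),
                        output_mode = c("pair_intervals", "pair_count"),
                        allowed_pairs = c("GC", "AU", "UG"),
                        energy_params = NULL,
                        rt = 0.616,
                        pair_prob_threshold = 0.5,
                        min_stem_len = 3L,
                        max_interior_size = 30,
                        audit = FALSE) {
  algorithm <- match.arg(algorithm)
  output_mode <- match.arg(output_mode)
  min_span <- as.integer(min_span)
  dp_assert(min_span >= 1L, "dpfold_domain", "min_span must be >= 1")
  dp_assert(rt > 0, "dpfold_domain", "rt must be positive")
  dp_assert(pair_prob_threshold > 0 && pair_prob_threshold <= 1,
            "dpfold_domain", "pair_prob_threshold must lie in (0, 1]")
  dp_assert(min_stem_len >= 1L, "dpfold_domain", "min_stem_len must be >= 1")
  structure(
    list(min_span = min_span, algorithm = algorithm, output_mode = output_mode,
         allowed_pairs = allowed_pairs,
         pair_matrix = build_pair_matrix(allowed_pairs),
         energy_params = energy_params, rt = rt,
         pair_prob_threshold = pair_prob_threshold,
         min_stem_len = as.integer(min_stem_len),
         max_interior_size = max_interior_size,
         audit = isTRUE(audit)),
    class = "fold_config"
  )
}

#' Check a secondary structure against the three structural rules
#'
#' Rule 1: no position occurs in more than one pair.  Rule 2: no two pairs
#' cross (pseudoknot-free).  Rule 3: every pair satisfies
#' `j - i >= min_span`.  If a sequence is supplied, every pair must also
#' be chemically allowed.
#'
#' @param s A [secondary_structure()].
#' @param cfg A [fold_config()] (supplies `min_span` and the allowed-pair
#'   set).
#' @param seq Optional [rna_sequence()]; enables the chemistry check.
#' @return `s`, invisibly unchanged, if valid.
#' @section Errors: `dpfold_multiple_pairing`, `dpfold_pseudoknot`,
#'   `dpfold_hairpin_span`, `dpfold_chemistry` — each a classed condition.
#' @examples
#' cfg <- fold_config()
#' check_structure(secondary_structure(10, cbind(c(1, 2, 3), c(10, 9, 8))), cfg)
#' @export
check_structure <- function(s, cfg = fold_config(), seq = NULL) {
  stopifnot(inherits(s, "secondary_structure"))
  p <- s$pairs
  dp_assert(all(p >= 1L & p <= s$n), "dpfold_domain",
            "pair index out of range [1, n]")
  if (anyDuplicated(as.vector(p)))
    dp_error("dpfold_multiple_pairing",
             "a base is paired with two or more bases at the same time")
  if (any(p[, 2] - p[, 1] < cfg$min_span)) {
    k <- which(p[, 2] - p[, 1] < cfg$min_span)[1]
    dp_error("dpfold_hairpin_span",
             sprintf("pair (%d,%d) violates j - i >= %d", p[k, 1], p[k, 2],
                     cfg$min_span))
  }
  m <- nrow(p)
  if (m > 1) {
    for (a in seq_len(m - 1)) {
      i <- p[a, 1]; j <- p[a, 2]
      g <- p[(a + 1):m, 1]; h <- p[(a + 1):m, 2]
      # pairs sorted by i so i < g always; crossing iff i < g < j < h
      if (any(g < j & j < h))
        dp_error("dpfold_pseudoknot",
                 sprintf("pairs (%d,%d) and (%d,%d) cross (pseudoknot)",
                         i, j, g[which(g < j & j < h)[1]],
                         h[which(g < j & j < h)[1]]))
    }
  }
  if (!is.null(seq)) {
    dp_assert(seq$n == s$n, "dpfold_domain", "sequence/structure length mismatch")
    if (m > 0) {
      ok <- cfg$pair_matrix[cbind(seq$code[p[, 1]], seq$code[p[, 2]])]
      if (!all(ok)) {
        k <- which(!ok)[1]
        dp_error("dpfold_chemistry",
                 sprintf("residues at (%d,%d) cannot pair", p[k, 1], p[k, 2]))
      }
    }
  }
  invisible(s)
}

# TRUE/FALSE version used by greedy construction paths.
structure_is_valid <- function(s, cfg, seq = NULL) {
  tryCatch({ check_structure(s, cfg, seq); TRUE },
           dpfold_error = function(e) FALSE)
}
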
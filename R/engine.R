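# The generic DP-engine contract shared by all four folding strategies:
# triangular state allocation, a single span-ordered fill schedule,
# final-score extraction from cell (1, n), traceback, and output-mode
# dispatch.  Strategies only supply per-cell recurrences and a traceback
# rule; the engine owns the loop and can audit every cell access.

#' Allocate a triangular DP state
#'
#' A `dp_state` holds one or more upper-triangular n x n score tables
#' (cells `(i, j)` with `i <= j` are addressable), an auxiliary-storage
#' slot, and an optional access log.  Unset cells hold `NA`; reading an
#' unset cell through the accessors signals `dpfold_engine_invariant`.
#'
#' @param n Sequence length (>= 1).
#' @param tables Named numeric vector: table names mapped to their
#'   empty-interval value (the value returned when reading `j < i`, e.g.
#'   0 for a maximization table, 1 for a partition function).
#' @param aux Auxiliary storage: `list(kind = , payload = )` with kind one
#'   of `"matrix_op"`, `"stem_pool_op"`, `"free_energy_op"`, `"none"`.
#' @param audit Record an ordered read/write log (slow; testing only).
#' @return An environment of class `dp_state`.
#' @export
dp_allocate <- function(n, tables = c(main = 0), aux = list(kind = "none", payload = NULL),
                        audit = FALSE) {
  n <- as.integer(n)
  dp_assert(length(n) == 1L && !is.na(n) && n >= 1L, "dpfold_domain",
            "n must be >= 1")
  stopifnot(is.numeric(tables), !is.null(names(tables)))
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$tables <- names(tables)
  st$empty <- as.list(tables)
  for (nm in names(tables)) st[[nm]] <- matrix(NA_real_, n, n)
  st$aux <- aux
  st$audit <- isTRUE(audit)
  st$log <- if (audit) list() else NULL
  class(st) <- c("dp_state", "environment")
  st
}

#' @export
print.dp_state <- function(x, ...) {
  cat(sprintf("<dp_state> n = %d, tables: %s, aux: %s\n",
              x$n, paste(x$tables, collapse = ", "), x$aux$kind))
  invisible(x)
}

# Number of addressable (i <= j) cells.
dp_n_cells <- function(state) state$n * (state$n + 1) / 2

log_access <- function(state, type, tbl, i, j) {
  if (state$audit)
    state$log[[length(state$log) + 1L]] <-
      list(type = type, table = tbl, i = as.integer(i), j = as.integer(j))
  invisible(NULL)
}

# Scalar cell read; j < i returns the table's empty-interval value.
dp_cell <- function(state, tbl, i, j) {
  if (j < i) return(state$empty[[tbl]])
  v <- state[[tbl]][i, j]
  if (is.na(v))
    dp_error("dpfold_engine_invariant",
             sprintf("read of unset cell %s(%d,%d)", tbl, i, j))
  log_access(state, "read", tbl, i, j)
  v
}

# Parallel vector read over (ii[k], jj[k]); no empty intervals allowed.
dp_vec <- function(state, tbl, ii, jj) {
  if (length(ii) == 0L) return(numeric(0))
  v <- state[[tbl]][cbind(ii, jj)]
  if (anyNA(v)) {
    k <- which(is.na(v))[1]
    dp_error("dpfold_engine_invariant",
             sprintf("read of unset cell %s(%d,%d)", tbl, ii[k], jj[k]))
  }
  if (state$audit) for (k in seq_along(ii)) log_access(state, "read", tbl, ii[k], jj[k])
  v
}

dp_set <- function(state, tbl, i, j, value) {
  state[[tbl]][i, j] <- value
  log_access(state, "write", tbl, i, j)
  invisible(NULL)
}

#' Construct a folding strategy object
#'
#' The engine contract: `new_state()` allocates the tables and auxiliary
#' storage; `fill_cell(state, i, j)` computes cell `(i, j)` reading only
#' already-written cells (the engine schedules spans `d = j - i` from 0
#' upward); `final_score(state)` reads the answer from cell `(1, n)`;
#' `traceback(state)` reconstructs a [secondary_structure()];
#' `rescore(structure)` (optional) recomputes the objective of a traced
#' structure for the traceback-consistency check.
#'
#' @param name Strategy name.
#' @param new_state,fill_cell,final_score,traceback,rescore Closures as
#'   described above (`rescore` may be `NULL`).
#' @param score_tol Tolerance for `rescore` vs `final_score` (0 for
#'   integer objectives).
#' @return An object of class `fold_strategy`.
#' @export
fold_strategy <- function(name, new_state, fill_cell, final_score, traceback,
                          rescore = NULL, score_tol = 1e-9) {
  structure(list(name = name, new_state = new_state, fill_cell = fill_cell,
                 final_score = final_score, traceback = traceback,
                 rescore = rescore, score_tol = score_tol),
            class = "fold_strategy")
}

# Span-ordered fill: all spans d = j - i from 0 to n - 1.
dp_fill_state <- function(seq, strategy, cfg) {
  state <- strategy$new_state()
  n <- state$n
  for (d in 0:(n - 1L)) {
    for (i in seq_len(n - d)) {
      strategy$fill_cell(state, i, i + d)
    }
  }
  # every addressable cell of every table must now be set
  for (tbl in state$tables) {
    m <- state[[tbl]]
    if (anyNA(m[upper.tri(m, diag = TRUE)]))
      dp_error("dpfold_engine_invariant",
               sprintf("fill left unset cells in table %s", tbl))
  }
  state
}

#' Run a folding strategy through the generic engine
#'
#' Validates nothing about the sequence itself (callers construct it via
#' [validate_sequence()]); fills all cells in increasing span order,
#' extracts the final score from cell `(1, n)`, runs traceback, checks
#' the traced structure with [check_structure()], and — when the strategy
#' supplies a `rescore` rule — verifies that re-scoring the structure
#' reproduces the final score.
#'
#' @param seq An [rna_sequence()].
#' @param strategy A [fold_strategy()] (or name understood by
#'   [get_strategy()]).
#' @param cfg A [fold_config()].
#' @param em An [energy_model()] (ignored by the Nussinov strategy).
#' @return An object of class `prediction_result`: fields `seq`,
#'   `algorithm`, `score`, `structure`, `state`, plus strategy extras
#'   (the partition strategy adds `probabilities`, `q`, `log_q`).
#' @export
dp_run <- function(seq, strategy, cfg = fold_config(), em = default_energy_model()) {
  stopifnot(inherits(seq, "rna_sequence"))
  if (is.character(strategy)) strategy <- get_strategy(strategy, seq, cfg, em)
  state <- dp_fill_state(seq, strategy, cfg)
  score <- strategy$final_score(state)
  structure_ <- strategy$traceback(state)
  check_structure(structure_, cfg, seq)
  if (!is.null(strategy$rescore)) {
    re <- strategy$rescore(structure_)
    if (!isTRUE(abs(re - score) <= strategy$score_tol))
      dp_error("dpfold_engine_invariant",
               sprintf("traceback re-score %g != final score %g", re, score))
  }
  res <- list(seq = seq, algorithm = strategy$name, score = score,
              structure = structure_, state = state)
  if (!is.null(state$extras)) res <- c(res, state$extras)
  class(res) <- "prediction_result"
  res
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s | %s | score = %g | %d pair(s)\n",
              x$seq$id, x$algorithm, x$score, n_pairs(x$structure)))
  cat(" ", write_dotbracket(x$seq, x$structure), "\n")
  invisible(x)
}

#' Look up a folding strategy by name
#'
#' @param name `"nussinov"`, `"zuker"`, `"helix"` or `"partition"`.
#' @param seq,cfg,em Passed to the strategy constructor.
#' @return A [fold_strategy()].
#' @export
get_strategy <- function(name, seq, cfg = fold_config(), em = default_energy_model()) {
  switch(name,
         nussinov = nussinov_strategy(seq, cfg),
         zuker = zuker_strategy(seq, cfg, em),
         helix = helix_strategy(seq, cfg, em),
         partition = partition_strategy(seq, cfg, em),
         dp_error("dpfold_domain", sprintf("unknown algorithm '%s'", name)))
}

#' Predict a secondary structure in one call
#'
#' @param x An [rna_sequence()] or a raw character string (validated with
#'   defaults).
#' @param algorithm Strategy name; defaults to `cfg$algorithm`.
#' @param cfg A [fold_config()].
#' @param em An [energy_model()]; defaults to [default_energy_model()]
#'   (honouring `cfg$energy_params` when set).
#' @return A `prediction_result`.
#' @examples
#' predict_structure("GGGAAAACCC", algorithm = "nussinov")
#' @export
predict_structure <- function(x, algorithm = NULL, cfg = fold_config(),
                              em = NULL) {
  if (is.character(x)) x <- validate_sequence(x)
  if (!is.null(algorithm)) cfg$algorithm <- algorithm
  if (is.null(em)) {
    em <- if (!is.null(cfg$energy_params)) read_energy_params(cfg$energy_params)
          else default_energy_model()
  }
  dp_run(x, cfg$algorithm, cfg, em)
}

#' Render a prediction result in an output mode
#'
#' `pair_count` prints the number of pairs; `pair_intervals` prints the
#' sorted pair list, dot-bracket string, or CT table per `format`.
#'
#' @param result A `prediction_result`.
#' @param mode `"pair_count"` or `"pair_intervals"`.
#' @param format For `pair_intervals`: `"pairs"`, `"dotbracket"` or
#'   `"ct"`.
#' @return Character vector of output lines.
#' @export
emit <- function(result, mode = c("pair_intervals", "pair_count"),
                 format = c("pairs", "dotbracket", "ct")) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  s <- result$structure
  if (mode == "pair_count") return(as.character(n_pairs(s)))
  switch(format,
         pairs = if (n_pairs(s) == 0) "" else
           paste(sprintf("(%d,%d)", s$pairs[, 1], s$pairs[, 2]), collapse = " "),
         dotbracket = write_dotbracket(result$seq, s),
         ct = write_ct(result$seq, s))
}
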
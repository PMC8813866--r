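# Pluggable loop-energy model.  No published nearest-neighbor table is
# bundled; the default model uses documented heuristic values (pair-type
# dependent stacks, logarithmic loop-length penalties) and every function
# is replaceable, either programmatically or via a JSON parameter file.

#' Construct a loop-energy model
#'
#' A set of total, finite energy functions over their admissible index
#' ranges, in kcal/mol:
#' \describe{
#'   \item{hairpin(seq, i, j)}{energy of the hairpin loop closed by
#'     `(i, j)`.}
#'   \item{stack(seq, i, j)}{energy of stacking `(i, j)` on
#'     `(i+1, j-1)`.}
#'   \item{internal(seq, i, j, ip, jp)}{energy of the interior/bulge loop
#'     between closing pairs `(i, j)` and `(ip, jp)`.}
#'   \item{pair_energy(seq, i, j)}{per-pair energy used by the
#'     pair-level partition function.}
#' }
#' plus affine multiloop parameters `multiloop_a` (closing penalty),
#' `multiloop_b` (per branch), `multiloop_c` (per unpaired base) and the
#' thermodynamic scale `rt`.
#'
#' @param hairpin,stack,internal,pair_energy Functions as above.
#' @param multiloop_a,multiloop_b,multiloop_c Affine multiloop terms.
#' @param rt RT in kcal/mol.
#' @param name Label used in printing.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(hairpin, stack, internal, pair_energy = NULL,
                         multiloop_a = 0, multiloop_b = 0, multiloop_c = 0,
                         rt = 0.616, name = "custom") {
  stopifnot(is.function(hairpin), is.function(stack), is.function(internal))
  if (is.null(pair_energy)) pair_energy <- function(seq, i, j) 0
  structure(list(hairpin = hairpin, stack = stack, internal = internal,
                 pair_energy = pair_energy,
                 multiloop_a = multiloop_a, multiloop_b = multiloop_b,
                 multiloop_c = multiloop_c, rt = rt, name = name),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> %s (a = %g, b = %g, c = %g, RT = %g)\n",
              x$name, x$multiloop_a, x$multiloop_b, x$multiloop_c, x$rt))
  invisible(x)
}

#' Constant-valued toy energy model
#'
#' Every loop class maps to one constant — the workhorse of the oracle
#' test suites, where exact brute-force rescoring must be possible.
#'
#' @param hairpin,stack,internal Constant energies per loop occurrence.
#' @param pair_energy Constant per-pair energy (partition mode).
#' @inheritParams energy_model
#' @return An [energy_model()].
#' @examples
#' toy_energy_model(hairpin = -1)  # every hairpin scores -1
#' @export
toy_energy_model <- function(hairpin = -1, stack = 0, internal = 0,
                             pair_energy = 0,
                             multiloop_a = 0, multiloop_b = 0, multiloop_c = 0,
                             rt = 0.616) {
  force(hairpin); force(stack); force(internal); force(pair_energy)
  energy_model(
    hairpin = function(seq, i, j) hairpin,
    stack = function(seq, i, j) stack,
    internal = function(seq, i, j, ip, jp) internal,
    pair_energy = function(seq, i, j) pair_energy,
    multiloop_a = multiloop_a, multiloop_b = multiloop_b,
    multiloop_c = multiloop_c, rt = rt,
    name = sprintf("toy(h=%g,s=%g,l=%g)", hairpin, stack, internal)
  )
}

# Heuristic bond strengths: GC = 3 H-bonds, AU = 2, GU (wobble) = 1.
pair_strength_matrix <- function() {
  m <- matrix(0, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  m["G", "C"] <- m["C", "G"] <- 3
  m["A", "U"] <- m["U", "A"] <- 2
  m["G", "U"] <- m["U", "G"] <- 1
  m
}

#' Default heuristic energy model
#'
#' A simple, fully documented stand-in for published nearest-neighbor
#' tables (which are not bundled): stack energy is minus the mean bond
#' strength of the two stacked pairs (GC = 3, AU = 2, GU = 1 kcal/mol),
#' hairpin and interior/bulge loops pay size-dependent logarithmic
#' penalties, and multiloops use a small affine cost.  Intended as a
#' sensible default for exercising the machinery, not as a calibrated
#' thermodynamic parameterization.
#'
#' @param rt RT in kcal/mol (default 0.616 at 37 C).
#' @return An [energy_model()].
#' @export
default_energy_model <- function(rt = 0.616) {
  strength <- pair_strength_matrix()
  energy_model(
    hairpin = function(seq, i, j) {
      size <- j - i - 1
      4.5 + 1.75 * rt * log(size / 3)
    },
    stack = function(seq, i, j) {
      -(strength[seq$code[i], seq$code[j]] +
          strength[seq$code[i + 1], seq$code[j - 1]]) / 2
    },
    internal = function(seq, i, j, ip, jp) {
      size <- (ip - i - 1) + (j - jp - 1)
      1.5 + 1.1 * rt * log1p(size)
    },
    pair_energy = function(seq, i, j) -strength[seq$code[i], seq$code[j]],
    multiloop_a = 3.4, multiloop_b = 0.4, multiloop_c = 0.1,
    rt = rt, name = "default-heuristic"
  )
}

#' Read an energy model from a JSON parameter file
#'
#' Recognized top-level keys (all optional; omitted keys fall back to the
#' default heuristic model): `stack` (object mapping two unordered pair
#' types, e.g. `"GC/CG"`, to an energy), `hairpin` (array of energies for
#' loop sizes 3, 4, ...; longer loops extrapolate logarithmically from
#' the last entry), `interior` (same, for total unpaired sizes 1, 2,
#' ...), `multiloop_a`, `multiloop_b`, `multiloop_c`, `rt`,
#' `pair_energy` (object mapping pair type, e.g. `"GC"`, to an energy).
#'
#' @param path JSON file path.
#' @return An [energy_model()].
#' @export
read_energy_params <- function(path) {
  dp_assert(file.exists(path), "dpfold_io", sprintf("file not found: %s", path))
  cfgj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rt <- if (!is.null(cfgj$rt)) cfgj$rt else 0.616
  base <- default_energy_model(rt = rt)

  pair_key <- function(seq, i, j)
    paste0(RNA_ALPHABET[seq$code[i]], RNA_ALPHABET[seq$code[j]])
  norm_keys <- function(tab) {
    # "GC/CG" style keys expand to both orientations; "GC" covers GC only
    out <- list()
    for (k in names(tab)) for (kk in strsplit(k, "/", fixed = TRUE)[[1]])
      out[[kk]] <- tab[[k]]
    out
  }

  # each table gets its own name: the closures all share this frame, so
  # reusing one variable would silently rebind earlier functions
  stack_fun <- base$stack
  if (!is.null(cfgj$stack)) {
    stack_tab <- norm_keys(as.list(cfgj$stack))
    stack_fun <- function(seq, i, j) {
      v <- stack_tab[[pair_key(seq, i, j)]]
      if (is.null(v))
        dp_error("dpfold_domain",
                 sprintf("no stack entry for pair type %s", pair_key(seq, i, j)))
      v
    }
  }
  hairpin_fun <- base$hairpin
  if (!is.null(cfgj$hairpin)) {
    hairpin_tab <- as.numeric(cfgj$hairpin)  # sizes 3, 4, ...
    hairpin_fun <- function(seq, i, j) {
      size <- j - i - 1
      k <- size - 2L
      if (k <= length(hairpin_tab)) hairpin_tab[max(k, 1L)]
      else hairpin_tab[length(hairpin_tab)] +
        1.75 * rt * log(size / (length(hairpin_tab) + 2))
    }
  }
  interior_fun <- base$internal
  if (!is.null(cfgj$interior)) {
    interior_tab <- as.numeric(cfgj$interior)  # total unpaired sizes 1, 2, ...
    interior_fun <- function(seq, i, j, ip, jp) {
      size <- (ip - i - 1) + (j - jp - 1)
      if (size <= length(interior_tab)) interior_tab[size]
      else interior_tab[length(interior_tab)] +
        1.1 * rt * log(size / length(interior_tab))
    }
  }
  pair_fun <- base$pair_energy
  if (!is.null(cfgj$pair_energy)) {
    pair_tab <- norm_keys(as.list(cfgj$pair_energy))
    pair_fun <- function(seq, i, j) {
      v <- pair_tab[[pair_key(seq, i, j)]]
      if (is.null(v)) 0 else v
    }
  }
  energy_model(
    hairpin = hairpin_fun, stack = stack_fun, internal = interior_fun,
    pair_energy = pair_fun,
    multiloop_a = if (!is.null(cfgj$multiloop_a)) cfgj$multiloop_a else base$multiloop_a,
    multiloop_b = if (!is.null(cfgj$multiloop_b)) cfgj$multiloop_b else base$multiloop_b,
    multiloop_c = if (!is.null(cfgj$multiloop_c)) cfgj$multiloop_c else base$multiloop_c,
    rt = rt, name = sprintf("file:%s", basename(path))
  )
}
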
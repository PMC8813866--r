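# RNA alphabet used throughout; integer codes speed up table lookups.
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Construct an RNA sequence object
#'
#' An `rna_sequence` is a validated residue string over `{A, C, G, U}` with
#' an identifier and 1-based inclusive indexing `i` in `[1, n]`.
#'
#' @param residues Character scalar of residues (already normalized).
#' @param id Identifier label.
#' @return An object of class `rna_sequence` with fields `id`, `residues`,
#'   `n` (length) and `code` (integer encoding A=1, C=2, G=3, U=4).
#' @seealso [validate_sequence()] for parsing raw, possibly messy input.
#' @export
rna_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  code <- match(chars, RNA_ALPHABET)
  if (anyNA(code)) {
    pos <- which(is.na(code))[1]
    dp_error("dpfold_invalid_residue",
             sprintf("invalid residue '%s' at position %d", chars[pos], pos),
             position = pos, residue = chars[pos])
  }
  structure(
    list(id = as.character(id), residues = residues,
         n = length(chars), code = code),
    class = "rna_sequence"
  )
}

#' @export
print.rna_sequence <- function(x, ...) {
  res <- if (x$n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<rna_sequence> %s (n = %d)\n  %s\n", x$id, x$n, res))
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) x$n

#' Validate (and optionally normalize) a raw sequence string
#'
#' Preprocessing step run before every folding algorithm: strips
#' whitespace, optionally upcases and rewrites T to U, then checks that
#' every residue lies in `{A, C, G, U}`.
#'
#' @param raw Raw character scalar.
#' @param normalize_t Rewrite `T`/`t` to `U` before validation (DNA-style
#'   input convenience). Default `TRUE`.
#' @param to_upper Accept lowercase input and upcase it. Default `TRUE`.
#' @param id Identifier attached to the resulting sequence.
#' @return An [rna_sequence()].
#' @section Errors: empty input signals `dpfold_empty_sequence`; a residue
#'   outside the alphabet after normalization signals
#'   `dpfold_invalid_residue` carrying the offending `position`.
#' @examples
#' validate_sequence("ACGU")
#' validate_sequence("acgt")   # normalized to "ACGU"
#' @export
validate_sequence <- function(raw, normalize_t = TRUE, to_upper = TRUE,
                              id = "seq") {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- gsub("[[:space:]]+", "", raw)
  if (nchar(s) == 0L)
    dp_error("dpfold_empty_sequence", "sequence is empty after whitespace stripping")
  if (to_upper) s <- toupper(s)
  if (normalize_t) s <- chartr("Tt", "Uu", s)
  rna_sequence(s, id = id)
}

# 4x4 logical lookup built from an unordered pair spec like c("GC","AU","UG")
build_pair_matrix <- function(allowed_pairs) {
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  for (p in allowed_pairs) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    if (!(a %in% RNA_ALPHABET) || !(b %in% RNA_ALPHABET))
      dp_error("dpfold_domain", sprintf("allowed pair '%s' contains a non-RNA residue", p))
    m[a, b] <- TRUE
    m[b, a] <- TRUE  # closed under symmetry: pairs are unordered
  }
  m
}

#' Can two residues form a base pair?
#'
#' The default allowed set is Watson-Crick (`GC`, `AU`) plus the `GU`
#' wobble pair, read as unordered, so `can_pair` is symmetric in its
#' arguments.
#'
#' @param a,b Single residues in `{A, C, G, U}`.
#' @param allowed_pairs Character vector of unordered allowed pairs.
#' @return Logical scalar.
#' @examples
#' can_pair("G", "C")  # TRUE
#' can_pair("U", "G")  # TRUE (wobble)
#' can_pair("A", "A")  # FALSE
#' @export
can_pair <- function(a, b, allowed_pairs = c("GC", "AU", "UG")) {
  stopifnot(a %in% RNA_ALPHABET, b %in% RNA_ALPHABET)
  build_pair_matrix(allowed_pairs)[a, b]
}

# Pairing indicator matrix theta: theta[i,j] is TRUE iff residues i and j
# may pair AND j - i >= min_span.  Shared by all four strategies so they
# explore exactly the same structure space.
pairing_matrix <- function(seq, cfg) {
  n <- seq$n
  pm <- cfg$pair_matrix
  th <- matrix(FALSE, n, n)
  if (n >= 2) {
    idx <- which(upper.tri(th), arr.ind = TRUE)
    ok <- (idx[, 2] - idx[, 1] >= cfg$min_span) &
      pm[cbind(seq$code[idx[, 1]], seq$code[idx[, 2]])]
    th[idx[ok, , drop = FALSE]] <- TRUE
  }
  th
}
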
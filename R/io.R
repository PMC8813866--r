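# Readers/writers for the three interchange formats.  All writers emit
# deterministic, byte-stable text for fixed input.

#' Read RNA sequences from a FASTA file
#'
#' Multi-record FASTA via Biostrings; every record is passed through
#' [validate_sequence()], so DNA-style `T` and lowercase input are
#' normalized by default.
#'
#' @param path File path.
#' @param normalize_t,to_upper Passed to [validate_sequence()].
#' @return List of [rna_sequence()] objects.
#' @export
read_fasta <- function(path, normalize_t = TRUE, to_upper = TRUE) {
  dp_assert(file.exists(path), "dpfold_io", sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(set))
  ids <- sub("[[:space:]].*$", "", ids)  # first token of the header
  lapply(seq_along(set), function(k) {
    validate_sequence(as.character(set[[k]]), normalize_t = normalize_t,
                      to_upper = to_upper, id = ids[k])
  })
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs An [rna_sequence()] or list of them.
#' @param path File path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    starts <- seq(1L, s$n, by = width)
    c(paste0(">", s$id),
      substring(s$residues, starts, pmin(starts + width - 1L, s$n)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a plain text file (one sequence per line)
#'
#' @inheritParams read_fasta
#' @return List of [rna_sequence()] objects with ids `line_1`, `line_2`, ...
#' @export
read_seq_lines <- function(path, normalize_t = TRUE, to_upper = TRUE) {
  dp_assert(file.exists(path), "dpfold_io", sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(k) {
    validate_sequence(lines[k], normalize_t = normalize_t,
                      to_upper = to_upper, id = paste0("line_", k))
  })
}

# -- dot-bracket ----------------------------------------------------------

#' Write a structure in dot-bracket notation
#'
#' @param seq An [rna_sequence()].
#' @param s A [secondary_structure()] over the same length.
#' @return A single character string of `.`, `(` and `)`.
#' @export
write_dotbracket <- function(seq, s) {
  dp_assert(seq$n == s$n, "dpfold_domain", "sequence/structure length mismatch")
  chars <- rep(".", s$n)
  if (nrow(s$pairs) > 0) {
    chars[s$pairs[, 1]] <- "("
    chars[s$pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Parse a dot-bracket string into a secondary structure
#'
#' Only `.`, `(` and `)` are accepted — the notation is pseudoknot-free by
#' construction.
#'
#' @param text Dot-bracket string.
#' @return A [secondary_structure()].
#' @section Errors: unbalanced brackets or foreign characters signal
#'   `dpfold_parse`.
#' @examples
#' read_dotbracket("(((....)))")
#' @export
read_dotbracket <- function(text) {
  chars <- strsplit(trimws(text), "", fixed = TRUE)[[1]]
  dp_assert(length(chars) > 0, "dpfold_parse", "empty dot-bracket string")
  if (!all(chars %in% c(".", "(", ")")))
    dp_error("dpfold_parse",
             sprintf("illegal dot-bracket character '%s'",
                     chars[which(!chars %in% c(".", "(", ")"))[1]]))
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (length(open) == 0)
        dp_error("dpfold_parse", sprintf("unbalanced ')' at position %d", k))
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0)
    dp_error("dpfold_parse", sprintf("unbalanced '(' at position %d", open[1]))
  secondary_structure(length(chars), pairs)
}

# -- Vienna-style record: >id / sequence / dot-bracket --------------------

#' Read a Vienna-style file (header, sequence, dot-bracket)
#'
#' @param path File path to a three-line record (`>id`, sequence,
#'   structure); multiple records may follow each other.
#' @return List of `list(seq = rna_sequence, structure = secondary_structure)`.
#' @export
read_vienna <- function(path) {
  dp_assert(file.exists(path), "dpfold_io", sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  k <- 1L
  while (k <= length(lines)) {
    dp_assert(startsWith(lines[k], ">"), "dpfold_parse",
              "expected '>' header line in Vienna record")
    dp_assert(k + 2L <= length(lines), "dpfold_parse", "truncated Vienna record")
    id <- sub("^>", "", sub("[[:space:]].*$", "", lines[k]))
    sq <- validate_sequence(lines[k + 1L], id = id)
    st <- read_dotbracket(lines[k + 2L])
    dp_assert(st$n == sq$n, "dpfold_parse",
              sprintf("record %s: structure length != sequence length", id))
    out[[length(out) + 1L]] <- list(seq = sq, structure = st)
    k <- k + 3L
  }
  out
}

#' Write a Vienna-style record
#'
#' @inheritParams write_dotbracket
#' @return Character vector of three lines.
#' @export
write_vienna <- function(seq, s) {
  c(paste0(">", seq$id), seq$residues, write_dotbracket(seq, s))
}

# -- CT (connectivity table) ---------------------------------------------

#' Write a structure as CT text
#'
#' Six-column convention: index, residue, index-1, index+1, pairing
#' partner (0 if unpaired), index.  First line is `n` and the sequence id.
#'
#' @inheritParams write_dotbracket
#' @return Character vector of lines.
#' @export
write_ct <- function(seq, s) {
  dp_assert(seq$n == s$n, "dpfold_domain", "sequence/structure length mismatch")
  partner <- integer(s$n)
  if (nrow(s$pairs) > 0) {
    partner[s$pairs[, 1]] <- s$pairs[, 2]
    partner[s$pairs[, 2]] <- s$pairs[, 1]
  }
  res <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  i <- seq_len(s$n)
  c(sprintf("%d %s", s$n, seq$id),
    sprintf("%d %s %d %d %d %d", i, res, i - 1L,
            ifelse(i == s$n, 0L, i + 1L), partner, i))
}

#' Read CT text into a sequence and structure
#'
#' @param text Character vector of CT lines (or a single string with
#'   newlines).
#' @return `list(seq = rna_sequence, structure = secondary_structure)`.
#' @section Errors: partner asymmetry (`partner[partner[i]] != i`) or a
#'   malformed table signals `dpfold_parse`.
#' @export
read_ct <- function(text) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text))]
  dp_assert(length(text) >= 1L, "dpfold_parse", "empty CT input")
  head_tok <- strsplit(trimws(text[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(head_tok[1]))
  dp_assert(!is.na(n) && n >= 1L, "dpfold_parse", "CT header must start with n")
  id <- if (length(head_tok) >= 2) head_tok[2] else "ct_seq"
  dp_assert(length(text) == n + 1L, "dpfold_parse",
            sprintf("CT body has %d rows, expected %d", length(text) - 1L, n))
  rows <- strsplit(trimws(text[-1]), "[[:space:]]+")
  dp_assert(all(lengths(rows) >= 6L), "dpfold_parse", "CT rows need 6 columns")
  tab <- do.call(rbind, rows)
  idx <- as.integer(tab[, 1])
  dp_assert(identical(idx, seq_len(n)), "dpfold_parse", "CT indices must be 1..n")
  partner <- as.integer(tab[, 5])
  dp_assert(all(!is.na(partner) & partner >= 0L & partner <= n),
            "dpfold_parse", "CT partner column out of range")
  paired <- which(partner > 0L)
  if (any(partner[partner[paired]] != paired))
    dp_error("dpfold_parse", "CT partner column is asymmetric")
  if (any(partner[paired] == paired))
    dp_error("dpfold_parse", "CT row pairs a base with itself")
  sq <- validate_sequence(paste(tab[, 2], collapse = ""), id = id)
  dp_assert(sq$n == n, "dpfold_parse", "CT residue count != header n")
  up <- paired[partner[paired] > paired]  # each pair once, i < j
  st <- secondary_structure(n, cbind(up, partner[up]))
  list(seq = sq, structure = st)
}
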
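# Shared helpers: seeded sequence batches and the toy energy models the
# oracle suites run under.

rs <- function(s, id = "t") validate_sequence(s, id = id)

# a batch of random sequences with lengths drawn from `lengths`
seeded_seqs <- function(n, lengths, seed, gc = 0.5) {
  random_sequences(simulation_spec(
    n_sequences = n,
    length = if (length(lengths) == 1) lengths else range(lengths),
    gc_content = gc, seed = seed))
}

# three toy models exercised by the Zuker oracle suites: plain negative,
# mixed-sign with affine multiloop costs, and stack-dominated
toy_models <- function() list(
  toy_energy_model(hairpin = -1, stack = 0, internal = 0),
  toy_energy_model(hairpin = -1, stack = -2, internal = 0.5,
                   multiloop_a = 1, multiloop_b = 0.5, multiloop_c = 0.1),
  toy_energy_model(hairpin = 2, stack = -3, internal = -0.5,
                   multiloop_a = -1, multiloop_b = 0.2, multiloop_c = 0)
)

# configuration with the interior-loop cap disabled (exact Zuker)
cfg_exact <- function(...) fold_config(max_interior_size = Inf, ...)

# exhaustive Nussinov check for one length: every sequence over {A,C,G,U}^n
# is reduced to its pairability fingerprint (which admissible (i, j) can
# pair) — both M(1, n) and the enumeration oracle depend on the sequence
# only through that fingerprint, so checking one representative per
# fingerprint class is exhaustive over all 4^n sequences.  Returns the
# number of classes checked (or -1 on any disagreement).
exhaustive_nussinov_classes <- function(n, cfg = fold_config()) {
  codes <- as.matrix(expand.grid(rep(list(1:4), n)))
  pm <- cfg$pair_matrix
  span_idx <- which(outer(seq_len(n), seq_len(n),
                          function(i, j) j - i >= cfg$min_span),
                    arr.ind = TRUE)
  if (nrow(span_idx) == 0) {
    keys <- rep(0, nrow(codes))
  } else {
    bits <- sapply(seq_len(nrow(span_idx)), function(b) {
      pm[cbind(codes[, span_idx[b, 1]], codes[, span_idx[b, 2]])]
    })
    keys <- as.vector(bits %*% 2^(seq_len(ncol(bits)) - 1))
  }
  reps <- codes[!duplicated(keys), , drop = FALSE]
  for (r in seq_len(nrow(reps))) {
    sq <- rna_sequence(paste(RNA_ALPHABET_chars[reps[r, ]], collapse = ""))
    st <- nussinov_fill(sq, cfg)
    if (st$M[1, n] != oracle_max_pairs(sq, cfg)) return(-1L)
  }
  nrow(reps)
}

RNA_ALPHABET_chars <- c("A", "C", "G", "U")
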
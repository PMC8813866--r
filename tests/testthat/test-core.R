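test_that("validate_sequence normalizes and rejects as specified", {
  s <- validate_sequence("ACGU")
  expect_s3_class(s, "rna_sequence")
  expect_equal(s$n, 4L)
  expect_equal(s$residues, "ACGU")

  expect_equal(validate_sequence("acgt")$residues, "ACGU")
  expect_equal(validate_sequence("  GG AA\ncc ")$residues, "GGAACC")

  err <- tryCatch(validate_sequence("ACGX"), dpfold_invalid_residue = identity)
  expect_s3_class(err, "dpfold_invalid_residue")
  expect_equal(err$position, 4L)

  expect_error(validate_sequence("   "), class = "dpfold_empty_sequence")
  # ambiguity codes are rejected, not skipped
  expect_error(validate_sequence("ACGN"), class = "dpfold_invalid_residue")
  # strict mode: T is not silently accepted
  expect_error(validate_sequence("ACGT", normalize_t = FALSE),
               class = "dpfold_invalid_residue")
})

test_that("can_pair covers Watson-Crick + wobble and is symmetric", {
  expect_true(can_pair("G", "C"))
  expect_true(can_pair("U", "G"))
  expect_true(can_pair("A", "U"))
  expect_false(can_pair("A", "A"))
  expect_false(can_pair("A", "C"))
  for (a in c("A", "C", "G", "U")) for (b in c("A", "C", "G", "U"))
    expect_identical(can_pair(a, b), can_pair(b, a))
})

test_that("check_structure enforces the three structural rules", {
  cfg <- fold_config()
  good <- secondary_structure(9, cbind(c(1, 2, 3), c(9, 8, 7)))
  expect_identical(check_structure(good, cfg), good)

  expect_error(check_structure(secondary_structure(9, cbind(c(1, 4), c(6, 9))), cfg),
               class = "dpfold_pseudoknot")
  expect_error(check_structure(secondary_structure(9, cbind(c(1, 1), c(9, 8))), cfg),
               class = "dpfold_multiple_pairing")
  expect_error(check_structure(secondary_structure(9, cbind(1, 4)), cfg),
               class = "dpfold_hairpin_span")
  # chemistry check only with a sequence
  sq <- rs("AAAAAAAAA")
  expect_error(check_structure(secondary_structure(9, cbind(1, 9)), cfg, sq),
               class = "dpfold_chemistry")
  # min_span is configurable: (1,4) legal at min_span 3
  expect_silent(check_structure(secondary_structure(9, cbind(1, 4)),
                                fold_config(min_span = 3)))
})

test_that("check_structure rejects every corrupting mutation of enumerated structures", {
  cfg <- fold_config()
  sq <- seeded_seqs(1, 12, seed = 71, gc = 0.6)[[1]]
  structs <- enumerate_structures(sq, cfg)
  nonempty <- Filter(function(s) nrow(s$pairs) > 0, structs)
  expect_gt(length(nonempty), 0)
  for (s in structs) expect_silent(check_structure(s, cfg, sq))
  for (s in nonempty[seq_len(min(10, length(nonempty)))]) {
    # duplicate a position
    bad <- rbind(s$pairs, c(s$pairs[1, 1], s$pairs[1, 2] - 1L))
    expect_error(check_structure(secondary_structure(s$n, bad), cfg),
                 class = "dpfold_error")
    # shrink a pair below the span rule
    bad2 <- s$pairs
    bad2[1, ] <- c(bad2[1, 1], bad2[1, 1] + cfg$min_span - 1L)
    expect_error(check_structure(secondary_structure(s$n, bad2), cfg),
                 class = "dpfold_error")
  }
})

test_that("dot-bracket parsing matches the bracket structure and errors on imbalance", {
  s <- read_dotbracket("(((....)))")
  expect_equal(s$pairs, matrix(c(1L, 2L, 3L, 10L, 9L, 8L), ncol = 2,
                               dimnames = list(NULL, c("i", "j"))))
  expect_equal(nrow(read_dotbracket("..........")$pairs), 0L)
  expect_error(read_dotbracket("((.)"), class = "dpfold_parse")
  expect_error(read_dotbracket (".))"), class = "dpfold_parse")
  expect_error(read_dotbracket("..[x]"), class = "dpfold_parse")
})

test_that("FASTA, dot-bracket and CT round-trip on seeded instances", {
  cfg <- fold_config()
  seqs <- seeded_seqs(6, c(8, 16), seed = 42, gc = 0.6)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  back <- read_fasta(fa)
  expect_equal(length(back), length(seqs))
  for (k in seq_along(seqs)) {
    expect_equal(back[[k]]$residues, seqs[[k]]$residues)
    expect_equal(back[[k]]$id, seqs[[k]]$id)
  }
  for (sq in seqs) {
    structs <- enumerate_structures(sq, cfg)
    pick <- structs[[length(structs)]]  # a maximally decorated member
    db <- write_dotbracket(sq, pick)
    expect_equal(read_dotbracket(db)$pairs, pick$pairs)
    ct <- write_ct(sq, pick)
    rt <- read_ct(ct)
    expect_equal(rt$seq$residues, sq$residues)
    expect_equal(rt$structure$pairs, pick$pairs)
  }
})

test_that("CT parser follows the 6-column convention and flags asymmetry", {
  sq <- rs("GGGAAAACCC", id = "hairpin")
  s <- read_dotbracket("(((....)))")
  ct <- write_ct(sq, s)
  expect_equal(ct[1], "10 hairpin")
  expect_equal(ct[2], "1 G 0 2 10 1")   # index, residue, i-1, i+1, partner, index
  expect_equal(ct[11], "10 C 9 0 1 10")
  bad <- ct
  bad[2] <- "1 G 0 2 9 1"  # partner says 9, row 9 disagrees
  expect_error(read_ct(bad), class = "dpfold_parse")
  expect_error(read_ct(c("3 x", "1 A 0 2 0 1")), class = "dpfold_parse")
})

test_that("vienna records round-trip", {
  sq <- rs("GGGAAAACCC", id = "v1")
  s <- read_dotbracket("(((....)))")
  f <- tempfile()
  writeLines(write_vienna(sq, s), f)
  rec <- read_vienna(f)
  expect_equal(length(rec), 1L)
  expect_equal(rec[[1]]$seq$residues, sq$residues)
  expect_equal(rec[[1]]$structure$pairs, s$pairs)
})
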
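test_that("dp_allocate owns the triangular cell space", {
  expect_equal(dpfold:::dp_n_cells(dp_allocate(1)), 1)
  expect_equal(dpfold:::dp_n_cells(dp_allocate(5)), 15)
  expect_error(dp_allocate(0), class = "dpfold_domain")
  st <- dp_allocate(4, tables = c(main = 0))
  expect_error(dpfold:::dp_cell(st, "main", 1, 3), class = "dpfold_engine_invariant")
  expect_equal(dpfold:::dp_cell(st, "main", 3, 1), 0)  # empty interval value
})

test_that("no strategy reads a cell before it is written (access audit)", {
  seqs <- seeded_seqs(3, c(6, 10), seed = 9, gc = 0.6)
  em <- toy_energy_model(hairpin = -1, stack = -1, pair_energy = -1)
  for (sq in seqs) {
    for (alg in c("nussinov", "zuker", "helix", "partition")) {
      cfg <- fold_config(audit = TRUE, algorithm = alg)
      strat <- get_strategy(alg, sq, cfg, em)
      state <- dpfold:::dp_fill_state(sq, strat, cfg)
      written <- character(0)
      ok <- TRUE
      for (entry in state$log) {
        key <- paste(entry$table, entry$i, entry$j)
        if (entry$type == "write") written <- c(written, key)
        else if (!(key %in% written)) { ok <- FALSE; break }
      }
      expect_true(ok, label = sprintf("%s on %s: read-before-write", alg, sq$id))
      expect_gt(length(state$log), 0)
    }
  }
})

test_that("dp_run delegates: score equals the strategy's answer cell", {
  sq <- rs("GGGAAAACCC")
  res <- dp_run(sq, "nussinov")
  expect_equal(res$score, nussinov_fill(sq)$M[1, 10])
  expect_equal(res$score, 3)
})

test_that("n = 1 sequences yield the base score and an empty structure", {
  sq <- rs("G")
  for (alg in c("nussinov", "zuker", "helix")) {
    res <- dp_run(sq, alg, em = toy_energy_model())
    expect_equal(res$score, 0)
    expect_equal(nrow(res$structure$pairs), 0L)
  }
  resp <- dp_run(sq, "partition", em = toy_energy_model(pair_energy = 0))
  expect_equal(resp$score, 1)  # only the empty structure
  expect_equal(nrow(resp$structure$pairs), 0L)
})

test_that("emit output modes agree with each other", {
  res <- dp_run(rs("GGGAAAACCC"), "nussinov")
  expect_equal(emit(res, "pair_count"), "3")
  expect_equal(emit(res, "pair_intervals", "pairs"), "(1,10) (2,9) (3,8)")
  expect_equal(emit(res, "pair_intervals", "dotbracket"), "(((....)))")
  expect_equal(length(strsplit(emit(res, "pair_intervals", "pairs"), " ")[[1]]),
               as.integer(emit(res, "pair_count")))
  empty <- dp_run(rs("AAAA"), "nussinov")
  expect_equal(emit(empty, "pair_count"), "0")
  expect_equal(emit(empty, "pair_intervals", "pairs"), "")
})

test_that("output-mode equivalence holds on seeded sequences", {
  for (sq in seeded_seqs(10, c(8, 20), seed = 33, gc = 0.55)) {
    res <- dp_run(sq, "nussinov")
    ints <- emit(res, "pair_intervals", "pairs")
    k <- if (nzchar(ints)) length(strsplit(ints, " ")[[1]]) else 0L
    expect_equal(as.integer(emit(res, "pair_count")), k)
  }
})
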
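test_that("stem enumeration finds exactly the legal stems", {
  expect_equal(nrow(enumerate_stems(rs("AAAAAAAA"))), 0L)
  expect_equal(nrow(enumerate_stems(rs("GAAAC"))), 0L)  # max helix length 1 < 3
  pool <- enumerate_stems(rs("GGGAAAACCC"), em = toy_energy_model(stack = -1))
  expect_equal(nrow(pool), 1L)
  expect_equal(unlist(pool[1, ]), c(i = 1, j = 10, k = 3, energy = -2))
  # maximal-and-shorter: the (1,12) 4-run lists both k = 3 and k = 4,
  # and offset starts (1,11), (2,11), (2,12) carry their own 3-runs
  pool2 <- enumerate_stems(rs("GGGGAAAACCCC"), em = toy_energy_model(stack = -1))
  expect_equal(pool2$i, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(pool2$j, c(11L, 12L, 12L, 11L, 12L))
  expect_equal(pool2$k, c(3L, 3L, 4L, 3L, 3L))
  expect_equal(pool2$energy, c(-2, -2, -3, -2, -2))
})

test_that("base case: E(i,j) = 0 whenever the window is below the base span", {
  sq <- seeded_seqs(1, 16, seed = 13, gc = 0.7)[[1]]
  st <- helix_fill(sq, em = toy_energy_model(stack = -1))
  base <- dpfold:::helix_base_span(fold_config())
  expect_equal(base, 8L)
  for (i in 1:sq$n) for (j in i:sq$n)
    if (j - i < base) expect_equal(st$E[i, j], 0)
})

test_that("single-stem case fills and traces exactly", {
  sq <- rs("GGGAAAACCC")
  em <- toy_energy_model(stack = -1)
  st <- helix_fill(sq, em = em)
  expect_equal(st$E[1, 10], -2)
  tb <- helix_traceback(st, sq, em = em)
  expect_equal(tb$pairs, matrix(c(1L, 2L, 3L, 10L, 9L, 8L), ncol = 2,
                                dimnames = list(NULL, c("i", "j"))))
  expect_equal(nrow(helix_traceback(helix_fill(rs("AAAAAAAAAA"), em = em),
                                    rs("AAAAAAAAAA"), em = em)$pairs), 0L)
})

test_that("E never exceeds 0 when all stem energies are <= 0", {
  em <- toy_energy_model(stack = -1)
  for (sq in seeded_seqs(8, c(8, 16), seed = 19, gc = 0.6)) {
    st <- helix_fill(sq, em = em)
    expect_true(all(st$E[upper.tri(st$E, diag = TRUE)] <= 0))
  }
})

test_that("E(1,n) equals the brute-force stem-subset optimum", {
  cfg <- fold_config()
  ems <- list(toy_energy_model(stack = -1), toy_energy_model(stack = -2.5))
  for (sq in seeded_seqs(25, c(8, 14), seed = 47, gc = 0.65)) {
    for (em in ems) {
      st <- helix_fill(sq, cfg, em)
      expect_equal(st$E[1, sq$n], oracle_stem_min_energy(sq, cfg, em),
                   tolerance = 1e-9, label = sq$residues)
    }
  }
})

test_that("traceback yields valid structures whose stems re-score to E(1,n)", {
  cfg <- fold_config()
  em <- toy_energy_model(stack = -1)
  for (sq in seeded_seqs(25, c(8, 20), seed = 53, gc = 0.65)) {
    res <- dp_run(sq, "helix", cfg, em)  # dp_run enforces the re-score contract
    expect_silent(check_structure(res$structure, cfg, sq))
  }
})
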
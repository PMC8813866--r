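test_that("base cases: W(i,i) = 0 and forbidden sentinels hold", {
  sq <- seeded_seqs(1, 10, seed = 3)[[1]]
  st <- zuker_fill(sq, em = toy_energy_model())
  for (i in 1:sq$n) expect_equal(st$W[i, i], 0)
  # short spans: pairing forbidden, W 0-extends
  cfg <- fold_config()
  for (i in 1:(sq$n - 1)) for (j in (i + 1):sq$n) {
    if (j - i < cfg$min_span) {
      expect_equal(st$V[i, j], Inf)
      expect_equal(st$W[i, j], 0)
    }
  }
  # V is forbidden wherever the residues cannot pair
  th <- dpfold:::pairing_matrix(sq, cfg)
  for (i in 1:(sq$n - 1)) for (j in (i + 1):sq$n)
    if (!th[i, j]) expect_equal(st$V[i, j], Inf)
})

test_that("toy single-hairpin case folds exactly", {
  sq <- rs("GAAAC")
  em <- toy_energy_model(hairpin = -1)
  st <- zuker_fill(sq, em = em)
  expect_equal(st$W[1, 5], -1)
  tb <- zuker_traceback(st, sq, em = em)
  expect_equal(tb$pairs, matrix(c(1L, 5L), 1, 2, dimnames = list(NULL, c("i", "j"))))
  # no allowed pairs: empty structure at W = 0
  sq2 <- rs("AAAAA")
  st2 <- zuker_fill(sq2, em = em)
  expect_equal(st2$W[1, 5], 0)
  expect_equal(nrow(zuker_traceback(st2, sq2, em = em)$pairs), 0L)
})

test_that("loop decomposition classifies hairpin, stack, interior, multiloop", {
  em <- toy_energy_model(hairpin = -1, stack = -1, internal = 0.25,
                         multiloop_a = 2, multiloop_b = 0.5, multiloop_c = 0.1)
  sq <- rs("GGGAAAACCC")
  expect_equal(loop_decomposition_energy(secondary_structure(10), sq, em), 0)
  expect_equal(loop_decomposition_energy(
    secondary_structure(5, cbind(1, 5)), rs("GAAAC"), em), -1)
  # nested helix: hairpin(3,8) + stack(2,9) + stack(1,10)
  s3 <- secondary_structure(10, cbind(c(1, 2, 3), c(10, 9, 8)))
  expect_equal(loop_decomposition_energy(s3, sq, em), -3)
  # bulge: (1,10) encloses (3,9) -> interior term
  sb <- secondary_structure(10, cbind(c(1, 3), c(10, 9)))
  expect_equal(loop_decomposition_energy(sb, sq, em), 0.25 - 1)
  # multiloop closed by (1,14) with children (2,7), (8,13):
  # a + 2b + c*0, children are hairpins
  sm <- secondary_structure(14, cbind(c(1, 2, 8), c(14, 7, 13)))
  expect_equal(loop_decomposition_energy(sm, rs(strrep("A", 14)), em),
               2 + 2 * 0.5 + 0 - 2)
})

test_that("with a zero model the optimum is 0 (empty structure)", {
  em0 <- toy_energy_model(hairpin = 0, stack = 0, internal = 0)
  for (sq in seeded_seqs(5, c(6, 12), seed = 11)) {
    st <- zuker_fill(sq, cfg_exact(), em0)
    expect_equal(st$W[1, sq$n], 0)
  }
})

test_that("W(1,n) equals the brute-force loop-decomposition minimum", {
  cfg <- cfg_exact()
  models <- toy_models()
  for (sq in seeded_seqs(12, c(6, 12), seed = 37, gc = 0.6)) {
    for (em in models) {
      st <- zuker_fill(sq, cfg, em)
      expect_equal(st$W[1, sq$n], oracle_min_energy(sq, cfg, em),
                   tolerance = 1e-9, label = paste(sq$residues, em$name))
    }
  }
})

test_that("traceback re-scores to W(1,n) on seeded sequences", {
  cfg <- cfg_exact()
  for (sq in seeded_seqs(25, c(6, 20), seed = 41, gc = 0.55)) {
    for (em in toy_models()) {
      st <- zuker_fill(sq, cfg, em)
      tb <- zuker_traceback(st, sq, cfg, em)
      expect_silent(check_structure(tb, cfg, sq))
      expect_equal(loop_decomposition_energy(tb, sq, em), st$W[1, sq$n],
                   tolerance = 1e-9, label = paste(sq$residues, em$name))
    }
  }
})

test_that("an energy-parameter file drives the fold", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    stack = list(`GC/CG` = -3, `AU/UA` = -2, `GU/UG` = -1),
    hairpin = c(1.5, 1.2, 1.0, 0.9),
    interior = c(1, 1.2, 1.4),
    multiloop_a = 2, multiloop_b = 0.4, multiloop_c = 0.1,
    rt = 0.616), f, auto_unbox = TRUE)
  em <- read_energy_params(f)
  sq <- rs("GGGGAAAACCCC")
  st <- zuker_fill(sq, cfg_exact(), em)
  expect_equal(st$W[1, sq$n], oracle_min_energy(sq, cfg_exact(), em),
               tolerance = 1e-9)
})
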
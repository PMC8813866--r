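ss <- function(n, ...) secondary_structure(n, rbind(...))

test_that("confusion counts are exact set arithmetic", {
  ref <- ss(12, c(1, 12), c(2, 11), c(3, 10))
  expect_error(confusion(ss(10, c(1, 10)), ref), class = "dpfold_domain")

  cc <- confusion(ref, ref)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(3, 0, 0))

  cc2 <- confusion(secondary_structure(12), ss(12, c(1, 12), c(2, 11), c(3, 10), c(4, 9)))
  expect_equal(c(cc2$tp, cc2$fn), c(0, 4))

  cc3 <- confusion(ss(10, c(1, 10), c(2, 9)), ss(10, c(1, 10), c(3, 8)))
  expect_equal(c(cc3$tp, cc3$fp, cc3$fn), c(1, 1, 1))
  # all-pairs universe: U = C(10,2) = 45
  expect_equal(cc3$tn, 45 - 3)
  # admissible universe shrinks with the sequence
  sq <- rs("GGGAAAACCC")
  cc4 <- confusion(ss(10, c(1, 10), c(2, 9)), ss(10, c(1, 10), c(3, 8)), seq = sq)
  expect_equal(cc4$tn, sum(dpfold:::pairing_matrix(sq, fold_config())) - 3)
  # marginals tie out to the pair counts
  expect_equal(cc3$tp + cc3$fn, 2)
  expect_equal(cc3$tp + cc3$fp, 2)
})

test_that("X and Y are the standard ratios with NA (not NaN) when undefined", {
  c1 <- list(tp = 3, fp = 0, fn = 1, tn = 10)
  expect_equal(sensitivity(c1), 0.75)
  expect_equal(specificity(c1), 1.0)
  c0 <- list(tp = 0, fp = 0, fn = 0, tn = 10)
  expect_true(is.na(sensitivity(c0)))
  expect_true(is.na(specificity(c0)))
  expect_false(is.nan(sensitivity(c0)))
})

test_that("mcc_full hits the documented extremes and centre", {
  expect_equal(mcc_full(list(tp = 5, tn = 5, fp = 0, fn = 0)), 1)
  expect_equal(mcc_full(list(tp = 0, tn = 0, fp = 3, fn = 4)), -1)
  expect_equal(mcc_full(list(tp = 1, tn = 1, fp = 1, fn = 1)), 0)
  expect_true(is.na(mcc_full(list(tp = 0, fp = 0, fn = 3, tn = 9))))
  # printed-denominator variant: its (FN+FP) term vanishes at a perfect
  # prediction, so the variant is undefined exactly where the standard
  # formula attains 1 — one reason to read it as a typesetting slip
  expect_true(is.na(mcc_full(list(tp = 5, tn = 5, fp = 0, fn = 0),
                             printed_variant = TRUE)))
  c_mid <- list(tp = 4, tn = 6, fp = 2, fn = 1)
  expect_false(isTRUE(all.equal(mcc_full(c_mid), mcc_full(c_mid, printed_variant = TRUE))))
})

test_that("mcc_simple is sqrt(X*Y) with its boundary behaviour", {
  expect_equal(round(mcc_simple(0.61, 0.63), 2), 0.62)
  expect_equal(mcc_simple(1, 1), 1)
  expect_equal(mcc_simple(0, 0.8), 0)
  expect_gte(mcc_simple(0.3, 0.7), 0)
  # equals 1 iff both are 1
  expect_lt(mcc_simple(1, 0.999), 1)
})

test_that("perturbed structures land on the requested confusion composition", {
  cfg <- fold_config()
  sq <- seeded_seqs(1, 16, seed = 83, gc = 0.7)[[1]]
  structs <- enumerate_structures(sq, cfg)
  sizes <- vapply(structs, function(s) nrow(s$pairs), integer(1))
  ref <- structs[[which.max(sizes)]]
  expect_gte(max(sizes), 2)

  same <- perturb_structure(ref, 0, 0, seed = 1, cfg = cfg, seq = sq)
  cc <- confusion(same, ref, seq = sq, cfg = cfg)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(nrow(ref$pairs), 0, 0))

  gone <- perturb_structure(ref, nrow(ref$pairs), 0, seed = 2, cfg = cfg, seq = sq)
  expect_equal(confusion(gone, ref, seq = sq, cfg = cfg)$tp, 0)

  pert <- perturb_structure(ref, 1, 1, seed = 3, cfg = cfg, seq = sq)
  ccp <- confusion(pert, ref, seq = sq, cfg = cfg)
  expect_gte(ccp$fn, 1)
  expect_equal(ccp$fp, 1)
  expect_silent(check_structure(pert, cfg, sq))
  # determinism
  pert2 <- perturb_structure(ref, 1, 1, seed = 3, cfg = cfg, seq = sq)
  expect_equal(pert$pairs, pert2$pairs)
})

test_that("evaluate_structures renders NA metrics as NA, never 0", {
  rep <- evaluate_structures(secondary_structure(10), secondary_structure(10))
  expect_true(is.na(rep$x) && is.na(rep$y) && is.na(rep$mcc_simple))
  expect_equal(dpfold:::fmt_metric(rep$x), "NA")
})
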
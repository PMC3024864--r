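test_that("the canonical feature list is 32 + 15 + 18 in fixed order", {
  nm <- feature_names()
  expect_length(nm, 65L)
  expect_length(feature_names("triplet"), 32L)
  expect_length(feature_names("base_pair"), 15L)
  expect_length(feature_names("thermodynamic"), 18L)
  expect_identical(nm, c(feature_names("triplet"), feature_names("base_pair"),
                         feature_names("thermodynamic")))
  expect_identical(sum(feature_groups() == "triplet"), 32L)
  expect_identical(sum(feature_groups() == "base_pair"), 15L)
  expect_identical(sum(feature_groups() == "thermodynamic"), 18L)
})

test_that("triplet features classify windows and sum to one", {
  tf <- triplet_features("AAAAA", ".....")
  expect_equal(unname(tf[["A..."]]), 1)
  expect_equal(sum(tf), 1)

  tf2 <- triplet_features("GGGAAAACCC", "(((....)))")
  # hand enumeration of the 8 windows (brackets collapsed to '(')
  expect_equal(unname(tf2[["G((("]]), 1 / 8)
  expect_equal(unname(tf2[["G((."]]), 1 / 8)
  expect_equal(unname(tf2[["A(.."]]), 1 / 8)
  expect_equal(unname(tf2[["A..."]]), 2 / 8)
  expect_equal(unname(tf2[["A..("]]), 1 / 8)
  expect_equal(unname(tf2[["C.(("]]), 1 / 8)
  expect_equal(unname(tf2[["C((("]]), 1 / 8)
  expect_equal(sum(tf2), 1)

  set.seed(3)
  for (rep in 1:10) {
    seq <- random_rna(sample(10:60, 1))
    expect_equal(sum(triplet_features(seq, fold_mfe(seq)$structure)), 1)
  }
  expect_error(triplet_features("AC", ".."), "length >= 3")
})

test_that("base-pair features match hand computation on the GC hairpin", {
  rec <- sequence_record("h", "GGGAAAACCC")
  fold <- partition_function(rec)
  stats <- structure_stats(rec, fold$structure)
  bp <- base_pair_features(rec, stats, fold)
  expect_equal(unname(bp[["dP"]]), 0.3)
  expect_equal(unname(bp[["Avg_BP_Stem"]]), 3)
  expect_equal(unname(bp[["|G-C|/L"]]), 0.3)
  expect_equal(unname(bp[["|A-U|/L"]]), 0)
  expect_equal(unname(bp[["dP/n_loops"]]), 0.3)
  expect_equal(unname(bp[["%(G-C)/n_loops"]]), 1)
  expect_equal(unname(bp[["%(A-U)/n_loops"]]), 0)
  expect_equal(unname(bp[["G/C_ratio"]]), 1)
  expect_equal(unname(bp[["%C+G"]]), 60)
  expect_equal(unname(bp[["Diversity"]]), fold$diversity)
})

test_that("degenerate denominators resolve to zero", {
  rec <- sequence_record("a", "AAAAAAAA")  # no C, no pairs
  fold <- partition_function(rec)
  stats <- structure_stats(rec, fold$structure)
  bp <- base_pair_features(rec, stats, fold)
  expect_true(all(is.finite(bp)))
  expect_equal(unname(bp[["dP"]]), 0)
  expect_equal(unname(bp[["G/C_ratio"]]), 0)
  expect_equal(unname(bp[["Avg_BP_Stem"]]), 0)
  expect_equal(unname(bp[["dP/n_loops"]]), 0)
})

test_that("multi-loop features shrink as the loop count grows", {
  # same dP, one loop vs two loops
  one <- sequence_record("one", "GGGGAAAACCCCAAAAAAAAAAA")
  two <- sequence_record("two", two_branch_seq)
  f_one <- partition_function(one)
  s_one <- structure_stats(one, f_one$structure)
  expect_identical(s_one$n_loops, 1L)
  bp_one <- base_pair_features(one, s_one, f_one)
  f_two <- partition_function(two)
  s_two <- structure_stats(two, two_branch_struct)
  bp_two <- base_pair_features(two, s_two,
                               structure(list(diversity = 0), class = "fold_result"))
  # with n_loops = 2 the loop-normalized dP is exactly half of dP
  expect_equal(unname(bp_two[["dP/n_loops"]]), unname(bp_two[["dP"]]) / 2)
  expect_equal(unname(bp_one[["dP/n_loops"]]), unname(bp_one[["dP"]]))
})

test_that("thermodynamic features match hand computation on the GC hairpin", {
  rec <- sequence_record("h", "GGGAAAACCC")
  model <- energy_model()
  fold <- partition_function(rec, model)
  stats <- structure_stats(rec, fold$structure)
  null <- null_statistics(rec, model, n = 10, seed = 2)
  th <- thermo_features(rec, stats, fold, null, model = model)
  expect_equal(unname(th[["dG"]]), -0.9)
  expect_equal(unname(th[["MFEI_1"]]), -0.9 / 60)
  expect_equal(unname(th[["MFEI_2"]]), -0.9)
  expect_equal(unname(th[["MFEI_3"]]), -0.9)
  expect_equal(unname(th[["MFEI_4"]]), -3)
  expect_equal(unname(th[["NEFE"]]), fold$efe / 10)
  expect_equal(unname(th[["Diff"]]), abs(fold$mfe - fold$efe) / 10)
  expect_equal(unname(th[["Freq"]]), fold$freq)
  # dH: two GC/GC stacks in a 3-bp helix, Xia GG stack = -13.39
  expect_equal(unname(th[["dH"]]), 2 * -13.39)
  expect_equal(unname(th[["dS"]]),
               (2 * -13.39 - (-9)) * 1000 / model$temperature)
  expect_equal(unname(th[["dH/L"]]), th[["dH"]] / 10)
})

test_that("MFEI_3/MFEI_4 denominators can be swapped by configuration", {
  rec <- sequence_record("h", "GGGAAAACCC")
  fold <- partition_function(rec)
  stats <- structure_stats(rec, fold$structure)
  null <- null_statistics(rec, n = 5, seed = 1)
  default <- thermo_features(rec, stats, fold, null)
  swapped <- thermo_features(rec, stats, fold, null, mfei34 = "swapped")
  expect_equal(unname(default[["MFEI_3"]]), unname(swapped[["MFEI_4"]]))
  expect_equal(unname(default[["MFEI_4"]]), unname(swapped[["MFEI_3"]]))
})

test_that("unpairable inputs yield the documented degenerate thermo vector", {
  rec <- sequence_record("a", "AAAAAAAAAA")
  fold <- partition_function(rec)
  stats <- structure_stats(rec, fold$structure)
  null <- null_statistics(rec, n = 3, seed = 1)
  th <- thermo_features(rec, stats, fold, null)
  expect_equal(unname(th[["dG"]]), 0)
  expect_equal(unname(th[c("MFEI_1", "MFEI_2", "MFEI_3", "MFEI_4")]),
               c(0, 0, 0, 0))
  expect_equal(unname(th[["Freq"]]), 1)
  expect_equal(unname(th[["NEFE"]]), 0)
  expect_equal(unname(th[["Diff"]]), 0)
  expect_equal(unname(th[["z-score_MFE"]]), 0)
  expect_equal(unname(th[["p-value_MFE"]]), 1)
})

test_that("extract_all returns a finite, deterministic 65-vector", {
  rec <- sequence_record("h", "GGGGGCCAAAACAAAAGGCCCCC")
  v1 <- extract_all(rec, n_shuffles = 10, seed = 4)
  v2 <- extract_all(rec, n_shuffles = 10, seed = 4)
  expect_length(v1, 65L)
  expect_identical(names(v1), feature_names())
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)
})

test_that("batch extraction is order-invariant and round-trips via TSV", {
  set.seed(17)
  recs <- list(make_hairpin(id = "h1"), make_pseudo(id = "p1"),
               make_hairpin(id = "h2"))
  fm <- extract_features(recs, labels = c(1L, -1L, 1L), n_shuffles = 5,
                         seed = 10)
  # same records in different order: each id keeps its feature row
  fm_perm <- extract_features(recs[c(2, 3, 1)],
                              labels = c(-1L, 1L, 1L), n_shuffles = 5,
                              seed = 10)
  expect_equal(fm$x["p1", ], fm_perm$x["p1", ])

  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(fm, path)
  back <- read_feature_tsv(path)
  expect_identical(back$ids, fm$ids)
  expect_identical(back$labels, fm$labels)
  expect_equal(back$x, fm$x, tolerance = 1e-9)
  expect_identical(colnames(back$x), feature_names())
})
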
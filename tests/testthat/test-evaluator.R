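# tolerance matching, confusion counts and the metric suite

test_that("the frequency acceptance interval is Y +/- 0.6 Y, clipped to [0, 1]", {
  expect_equal(acceptance_interval(0.2), c(0.08, 0.32))
  expect_equal(acceptance_interval(1.0), c(0.4, 1.0))
  expect_equal(acceptance_interval(0.5, tolerance_rule(freq_tol_factor = 0)),
               c(0.5, 0.5))
  expect_error(acceptance_interval(0), "Y > 0")
})

test_that("matching honours the positional window and the frequency interval", {
  rule <- tolerance_rule()
  truth <- site_records("ref", 10L, "mod", 0.2, 50L)
  # one base off, frequency exact: a match
  m <- match_predictions(truth, site_records("ref", 11L, "mod", 0.2, 50L),
                         rule)
  expect_equal(nrow(m), 1L)
  expect_equal(m$offset, 1L)
  # same position, frequency outside [0.08, 0.32]: no match
  m2 <- match_predictions(truth, site_records("ref", 10L, "mod", 0.5, 50L),
                          rule)
  expect_equal(nrow(m2), 0L)
  # two adjacent truths, one prediction inside both intervals: one match only
  truth2 <- site_records("ref", c(10L, 11L), "mod", c(0.2, 0.22), 50L)
  m3 <- match_predictions(truth2, site_records("ref", 10L, "mod", 0.21, 50L),
                          rule)
  expect_equal(nrow(m3), 1L)
  expect_error(match_predictions(truth2[2:1, ],
                                 site_records("ref", 10L, "mod", 0.2, 50L),
                                 rule),
               "sorted")
})

test_that("matching cardinality equals the exhaustive maximum on random fixtures", {
  rule <- tolerance_rule()
  for (s in 1:200) {
    fx <- random_eval_fixture(s)
    m <- match_predictions(fx$truth, fx$pred, rule)
    expect_equal(nrow(m), brute_force_max_matching(fx$truth, fx$pred, rule),
                 info = sprintf("fixture seed %d", s))
    # one-to-one
    expect_equal(anyDuplicated(m$truth_idx), 0L)
    expect_equal(anyDuplicated(m$pred_idx), 0L)
  }
})

test_that("widening the tolerance never decreases the number of matches", {
  rules <- list(tolerance_rule(0.2, 0L), tolerance_rule(0.6, 1L),
                tolerance_rule(1.0, 2L))
  for (s in 1:50) {
    fx <- random_eval_fixture(s + 1000L)
    tp <- vapply(rules, function(r)
      nrow(match_predictions(fx$truth, fx$pred, r)), integer(1))
    expect_true(all(diff(tp) >= 0L), info = sprintf("fixture seed %d", s))
  }
})

test_that("confusion counts follow the matching and partition N", {
  rule <- tolerance_rule()
  # 2 matched, 1 stray prediction, 1 missed truth, N = 100
  truth <- site_records("ref", c(10L, 20L, 30L), "mod", c(0.2, 0.4, 0.6),
                        50L)
  pred <- site_records("ref", c(10L, 20L, 50L), "mod", c(0.2, 0.4, 0.9), 50L)
  m <- match_predictions(truth, pred, rule)
  counts <- confusion_counts(m, truth, pred, 100L)
  expect_equal(counts, c(TP = 2L, TN = 96L, FP = 1L, FN = 1L))

  # perfect predictions
  mp <- match_predictions(truth, truth, rule)
  expect_equal(confusion_counts(mp, truth, truth, 100L),
               c(TP = 3L, TN = 97L, FP = 0L, FN = 0L))

  # empty prediction set
  none <- truth[0, ]
  m0 <- match_predictions(truth, none, rule)
  expect_equal(confusion_counts(m0, truth, none, 100L),
               c(TP = 0L, TN = 97L, FP = 0L, FN = 3L))

  expect_error(confusion_counts(mp, truth, truth, 2L), "n_positions")
})

test_that("error metrics match their closed forms on fixed vectors", {
  truth <- site_records("ref", 0:2, "mod", c(0.1, 0.2, 0.3), 10L)
  pred <- site_records("ref", 0:2, "mod", c(0.2, 0.2, 0.2), 10L)
  pair <- paired_vectors(truth, pred, 3L)
  expect_equal(rmse(pair), sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(mae(pair), 0.2 / 3, tolerance = 1e-12)
  expect_equal(median_ae(pair), 0.1)
  expect_equal(max_deviation(pair), 0.1)
  expect_equal(min_deviation(pair), 0)

  # lower median on an even number of positions
  t2 <- site_records("ref", 0:1, "mod", c(0.1, 0.2), 10L)
  p2 <- site_records("ref", 0:1, "mod", c(0.3, 0.25), 10L)
  expect_equal(median_ae(paired_vectors(t2, p2, 2L)), 0.05)

  # single-position closed form: rmse = mae = |error|
  t1 <- site_records("ref", 0L, "mod", 0.4, 10L)
  p1 <- site_records("ref", 0L, "mod", 0.7, 10L)
  pair1 <- paired_vectors(t1, p1, 1L)
  expect_equal(rmse(pair1), 0.3)
  expect_equal(mae(pair1), 0.3)
  expect_equal(max_deviation(pair1), min_deviation(pair1))
})

test_that("accuracy and F1 follow their formulas including degenerate cases", {
  expect_equal(accuracy(c(TP = 200L, TN = 2100L, FP = 0L, FN = 138L), 2438L),
               2300 / 2438, tolerance = 1e-12)
  expect_equal(f1_score(c(TP = 2L, TN = 0L, FP = 1L, FN = 1L)), 2 / 3,
               tolerance = 1e-12)
  expect_equal(f1_score(c(TP = 5L, TN = 10L, FP = 0L, FN = 0L)), 1)
  expect_equal(f1_score(c(TP = 0L, TN = 10L, FP = 0L, FN = 0L)), 1)
  expect_equal(f1_score(c(TP = 0L, TN = 10L, FP = 2L, FN = 1L)), 0)
})

test_that("rmse dominates mae and the deviation range is ordered", {
  for (s in 1:50) {
    fx <- random_eval_fixture(s + 2000L)
    pair <- paired_vectors(fx$truth, fx$pred, fx$L)
    expect_gte(rmse(pair), mae(pair))
    expect_lte(min_deviation(pair), max_deviation(pair))
  }
  # both zero iff prediction equals truth
  fx <- random_eval_fixture(1L)
  pair <- paired_vectors(fx$truth, fx$truth, fx$L)
  expect_equal(rmse(pair), 0)
  expect_equal(mae(pair), 0)
})

test_that("evaluating a truth table against itself is perfect", {
  prof <- challenge_rate_profile("challenge3", seed = 3)
  truth <- profile_truth_records(prof, 50L)
  report <- evaluate_predictions(truth, truth, prof$length)
  expect_equal(report$metrics$rmse, 0)
  expect_equal(report$metrics$mae, 0)
  expect_equal(report$metrics$median_ae, 0)
  expect_equal(report$metrics$accuracy, 1)
  expect_equal(report$metrics$f1, 1)
  expect_equal(report$confusion$FN, 0L)
  expect_equal(report$confusion$FP, 0L)
})

test_that("evaluation is invariant to input row order", {
  fx <- random_eval_fixture(77L)
  shuffled_truth <- fx$truth[rev(seq_len(nrow(fx$truth))), ]
  shuffled_pred <- fx$pred[rev(seq_len(nrow(fx$pred))), ]
  a <- evaluate_predictions(fx$truth, fx$pred, fx$L)
  b <- evaluate_predictions(shuffled_truth, shuffled_pred, fx$L)
  expect_equal(a$metrics, b$metrics)
  expect_equal(a$confusion, b$confusion)
})

test_that("zero-frequency predictions assert 'unmodified' and are never false positives", {
  truth <- site_records("ref", 10L, "mod", 0.5, 50L)
  pred <- site_records("ref", c(10L, 20L), "mod", c(0.5, 0), 50L)
  report <- evaluate_predictions(truth, pred, 100L)
  expect_equal(report$confusion$FP, 0L)
  expect_equal(report$metrics$f1, 1)
})

test_that("evaluation rejects inconsistent inputs", {
  truth <- site_records("chrA", 10L, "mod", 0.5, 50L)
  predB <- site_records("chrB", 10L, "mod", 0.5, 50L)
  expect_error(evaluate_predictions(truth, predB, 100L), "mismatch")
  expect_error(evaluate_predictions(truth[0, ], predB, 100L),
               "at least one site")
})

test_that("reports serialize to JSON and read back with identical metrics", {
  fx <- random_eval_fixture(5L)
  report <- evaluate_predictions(fx$truth, fx$pred, fx$L)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$metrics$rmse, report$metrics$rmse, tolerance = 1e-12)
  expect_equal(back$metrics$f1, report$metrics$f1, tolerance = 1e-12)
  expect_equal(back$confusion$TP, report$confusion$TP)
})

test_that("full reports agree with the straight-line recomputation", {
  prof <- challenge_rate_profile("challenge1", seed = 6)
  truth <- profile_truth_records(prof, 40L)
  pred <- perturb_truth(truth, pos_jitter_prob = 0.1, freq_noise_sd = 0.03,
                        fp_rate = 0.005, fn_rate = 0.05, seed = 7,
                        reference_length = prof$length)
  pred <- pred[!duplicated(pred$start), ]
  report <- evaluate_predictions(truth, pred, prof$length)
  oracle <- straight_line_metrics(truth, pred, prof$length)
  expect_equal(report$metrics$rmse, oracle$rmse, tolerance = 1e-12)
  expect_equal(report$metrics$mae, oracle$mae, tolerance = 1e-12)
  expect_equal(report$metrics$median_ae, oracle$median_ae, tolerance = 1e-12)
  expect_equal(report$metrics$max_deviation, oracle$max_deviation,
               tolerance = 1e-12)
  expect_equal(report$metrics$min_deviation, oracle$min_deviation,
               tolerance = 1e-12)
  with(report$confusion, expect_equal(TP + TN + FP + FN, prof$length))
})
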
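test_that("confusion counts classify selected variants only", {
  # selection of 10; caller A made 8 of them (6 true, 2 false); the 2 calls
  # A missed are both true
  prof <- make_profile(list(A = 1:8, B = 1:10))
  truth <- truth_for(prof, c(rep(TRUE, 6), rep(FALSE, 2), TRUE, TRUE))
  sel <- selection_from_keys(prof, prof$variants$key)
  expect_equal(confusion_counts(prof, sel, truth, "A"),
               c(TP = 6L, FP = 2L, FN = 2L))
  # B made everything: no FNs
  expect_equal(confusion_counts(prof, sel, truth, "B"),
               c(TP = 8L, FP = 2L, FN = 0L))

  # no calls by the caller and no true variants selected: all zero
  prof2 <- make_profile(list(A = 1:2, B = 3:4))
  truth2 <- truth_for(prof2, c(FALSE, FALSE, FALSE, FALSE))
  sel2 <- selection_from_keys(prof2, c("c:3", "c:4"))
  expect_equal(confusion_counts(prof2, sel2, truth2, "A"),
               c(TP = 0L, FP = 0L, FN = 0L))

  # selected variant missing from the truth table is an error
  part <- truth_table("c", 1, TRUE)
  expect_error(confusion_counts(prof2, sel2, part, "A"), "missing from truth")
})

test_that("precision, recall and F1 follow the defining formulas with NA rules", {
  m <- precision_recall_f1(8, 2, 0)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 1.0)
  expect_equal(m$f1, 2 * 0.8 / 1.8)

  # no selected calls by the caller: precision (and hence F1) undefined
  m2 <- precision_recall_f1(0, 0, 3)
  expect_true(is.na(m2$precision))
  expect_equal(m2$recall, 0)
  expect_true(is.na(m2$f1))

  # both defined and zero: F1 is zero, not undefined
  m3 <- precision_recall_f1(0, 5, 5)
  expect_equal(m3$precision, 0)
  expect_equal(m3$recall, 0)
  expect_equal(m3$f1, 0)

  # nothing relevant selected at all
  m4 <- precision_recall_f1(0, 0, 0)
  expect_true(is.na(m4$precision) && is.na(m4$recall) && is.na(m4$f1))
})

test_that("F1 lies between precision and recall whenever defined", {
  for (case in 1:50) {
    withr::with_seed(case, {
      tp <- sample(0:10, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    })
    m <- precision_recall_f1(tp, fp, fn)
    if (!is.na(m$f1)) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("weighted precision weights groups by the caller's total calls per level", {
  # two callers; X made 100 unique calls and 50 shared with Y: the unique
  # group must weigh exactly twice the shared group
  prof <- make_profile(list(X = 1:150, Y = 101:180))
  truth <- truth_for(prof, rep(c(TRUE, FALSE), length.out = 180))
  sel <- selection_from_keys(prof, paste0("c:", c(1:20, 101:110)))
  g <- overlap_group_weights(prof, sel, truth, "X")
  expect_equal(g$level, c(1L, 2L))
  expect_equal(g$weight, c(100L, 50L))
  expect_equal(g$weight[1] / g$weight[2], 2)
  p1 <- g$precision[1]; p2 <- g$precision[2]
  expect_equal(weighted_precision(prof, sel, truth, "X"),
               (100 * p1 + 50 * p2) / 150)

  # single overlap level: weighted reduces to default precision
  uni <- make_profile(list(X = 1:30, Y = 31:40))
  truth_u <- truth_for(uni, rep(c(TRUE, TRUE, FALSE), length.out = 40))
  sel_u <- selection_from_keys(uni, paste0("c:", 1:12))
  cc <- confusion_counts(uni, sel_u, truth_u, "X")
  expect_equal(weighted_precision(uni, sel_u, truth_u, "X"),
               cc[["TP"]] / (cc[["TP"]] + cc[["FP"]]))

  # no selected calls by the caller: undefined
  expect_true(is.na(weighted_precision(uni, sel_u, truth_u, "Y")))
})

test_that("weighted precision matches the group-by-group oracle and stays convex", {
  for (case in 1:30) {
    prof <- random_profile(3, 12, seed = case + 300)
    withr::with_seed(case, {
      labels <- runif(12) < 0.6
      sel_keys <- sample(prof$variants$key, sample(3:10, 1))
    })
    truth <- truth_for(prof, labels)
    sel <- selection_from_keys(prof, sel_keys)
    for (cl in prof$callers) {
      got <- weighted_precision(prof, sel, truth, cl)
      want <- oracle_weighted_precision(prof, sel_keys, truth$labels, cl)
      expect_equal(got, want)
      g <- overlap_group_weights(prof, sel, truth, cl)
      if (nrow(g) > 0) {
        expect_gte(got, min(g$precision) - 1e-12)
        expect_lte(got, max(g$precision) + 1e-12)
      }
    }
  }
})

test_that("confusion counts and both precision modes match brute force exhaustively", {
  # every profile with up to 2 callers and 4 variants, every selection,
  # every truth assignment
  mismatches <- 0L
  n_checked <- 0L
  for (n in 1:2) for (m in 1:4) {
    for (tp in enumerate_mask_tuples(n, m)) {
      prof <- profile_from_masks(tp, n)
      keys <- prof$variants$key
      for (sel_mask in 0:(2^m - 1)) {
        sel_keys <- keys[bitwAnd(sel_mask, 2^(seq_len(m) - 1)) > 0]
        sel <- selection_from_keys(prof, sel_keys)
        for (tr_mask in 0:(2^m - 1)) {
          labels <- bitwAnd(tr_mask, 2^(seq_len(m) - 1)) > 0
          truth <- truth_for(prof, labels)
          for (cl in prof$callers) {
            ok_counts <- identical(
              confusion_counts(prof, sel, truth, cl),
              oracle_confusion(prof, sel_keys, truth$labels, cl))
            ok_wp <- isTRUE(all.equal(
              weighted_precision(prof, sel, truth, cl),
              oracle_weighted_precision(prof, sel_keys, truth$labels, cl)))
            if (!ok_counts || !ok_wp) mismatches <- mismatches + 1L
            n_checked <- n_checked + 1L
          }
        }
      }
    }
  }
  expect_gt(n_checked, 5000)
  expect_equal(mismatches, 0L)
})

test_that("evaluate_callers produces one record per caller in both modes", {
  prof <- make_profile(list(A = 1:6, B = c(4:9), C = c(1, 4, 10)))
  truth <- truth_for(prof, rep(c(TRUE, FALSE), length.out = 10))
  sel <- select_candidates(prof, 6, "equal_per_caller", seed = 4)
  for (mode in c("default", "weighted")) {
    m <- evaluate_callers(prof, sel, truth, mode = mode)
    expect_equal(m$caller, prof$callers)
    expect_true(all(m$mode == mode))
    for (i in seq_len(nrow(m))) {
      cc <- confusion_counts(prof, sel, truth, m$caller[i])
      expect_equal(c(TP = m$TP[i], FP = m$FP[i], FN = m$FN[i]), cc)
      want_p <- if (mode == "weighted")
        weighted_precision(prof, sel, truth, m$caller[i])
      else if (cc[["TP"]] + cc[["FP"]] == 0) NA_real_
      else cc[["TP"]] / (cc[["TP"]] + cc[["FP"]])
      expect_equal(m$precision[i], want_p)
    }
  }

  # caller with nothing selected carries NA scores
  skew <- make_profile(list(A = 1:8, B = 9))
  truth_s <- truth_for(skew, rep(TRUE, 9))
  sel_a <- selection_from_keys(skew, paste0("c:", 1:4))
  m <- evaluate_callers(skew, sel_a, truth_s)
  expect_true(is.na(m$precision[m$caller == "B"]))
  expect_true(is.na(m$F1[m$caller == "B"]))

  # single-level data: modes coincide
  uni <- make_profile(list(A = 1:5, B = 6:10))
  truth_u <- truth_for(uni, rep(c(TRUE, FALSE), 5))
  sel_u <- select_candidates(uni, 6, "random_rows", seed = 1)
  expect_equal(evaluate_callers(uni, sel_u, truth_u, "default")[-2],
               evaluate_callers(uni, sel_u, truth_u, "weighted")[-2])
})

test_that("full-set baselines differ only in unpredicted true mutations", {
  prof <- make_profile(list(A = 1:4, B = c(3, 4, 9)))
  # A predicts every true mutation and nothing else
  truth_all <- truth_table("c", c(1:4, 9), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  for (b in c("union", "all-mutations")) {
    m <- full_set_metrics(prof, truth_all, baseline = b)
    a <- m[m$caller == "A", ]
    expect_equal(c(a$precision, a$recall, a$F1), c(1, 1, 1))
  }

  # two mutations missed by every caller depress all-mutations recall only
  truth_miss <- truth_table("c", c(1:4, 9, 100, 101),
                            c(rep(TRUE, 4), FALSE, TRUE, TRUE))
  mu <- full_set_metrics(prof, truth_miss, baseline = "union")
  ma <- full_set_metrics(prof, truth_miss, baseline = "all-mutations")
  expect_equal(ma$TP, mu$TP)
  expect_equal(ma$precision, mu$precision)
  expect_true(all(ma$recall < mu$recall))

  # union baseline is evaluation over the full call union
  ens <- simulate_ensemble(simulation_config(
    genome_length = 1e5, n_true = 300, sensitivity = c(0.8, 0.6),
    n_fp = c(60, 40), shared_fp_fraction = 0.2, fp_pool_size = 30, seed = 8))
  full_sel <- selection_from_keys(ens$profile, ens$profile$variants$key)
  direct <- evaluate_callers(ens$profile, full_sel, ens$truth)
  via <- full_set_metrics(ens$profile, ens$truth, baseline = "union")
  expect_equal(via[names(direct)], direct)
})

test_that("F1 differences are signed, zero at identity and missing-propagating", {
  prof <- make_profile(list(A = 1:6, B = 4:9))
  truth <- truth_for(prof, rep(c(TRUE, TRUE, FALSE), 3))
  full <- full_set_metrics(prof, truth, baseline = "union")
  est <- evaluate_callers(
    prof, selection_from_keys(prof, prof$variants$key), truth)
  for (i in seq_len(nrow(est)))
    expect_equal(f1_difference(est[i, ], full[i, ]), 0)

  na_rec <- est[1, ]; na_rec$F1 <- NA_real_
  expect_true(is.na(f1_difference(na_rec, full[1, ])))
  expect_error(f1_difference(est[1, ], full[2, ]), "different callers")
})
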
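test_that("classification metrics follow the confusion table", {
  lab2 <- function(x) factor(x, levels = c("a", "b"))
  # perfect prediction
  m <- classification_metrics(lab2(rep(c("a", "b"), 10)),
                              lab2(rep(c("a", "b"), 10)))
  expect_equal(m$accuracy_pct, 100)
  expect_equal(m$ner_pct, 100)
  expect_equal(unname(m$sensitivity), c(1, 1))
  expect_equal(unname(m$precision), c(1, 1))
  # confusion [[10, 0], [2, 8]] (rows = true a/b)
  true <- lab2(rep(c("a", "b"), c(10, 10)))
  pred <- lab2(c(rep("a", 10), rep("a", 2), rep("b", 8)))
  m <- classification_metrics(true, pred)
  expect_equal(m$accuracy_pct, 90)
  expect_equal(m$sensitivity[["b"]], 0.8)
  expect_equal(m$specificity[["b"]], 1.0)
  expect_equal(m$precision[["b"]], 1.0)
  # always-predict-majority on a 60/40 split
  true <- lab2(rep(c("a", "b"), c(60, 40)))
  m <- classification_metrics(true, lab2(rep("a", 100)))
  expect_equal(m$accuracy_pct, 60)
  expect_equal(m$ner_pct, 50)
  expect_true(is.na(m$precision[["b"]]))
})

test_that("cancellation groups partition the samples with the remainder rule", {
  for (n in c(45, 48, 69, 23)) {
    local_seed(n, {
      folds <- chemoselect:::make_folds(n, 5)
      expect_equal(sort(unname(unlist(folds))), 1:n)  # disjoint and covering
      sizes <- lengths(folds)
      expect_true(max(sizes) - min(sizes) <= 1)
      expect_true(all(diff(sizes) <= 0))              # largest groups first
      expect_equal(sum(sizes), n)
    })
  }
})

test_that("repeated CV is deterministic and leak-free by construction", {
  d <- separable_fixture(seed = 130, n_proteins = 15)
  sch <- cv_scheme(n_groups = 5, n_repeats = 20, seed = 9)
  cv1 <- repeated_cv(d$values, d$labels, 2, sch)
  cv2 <- repeated_cv(d$values, d$labels, 2, sch)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  expect_identical(cv1$accuracy_pct, cv2$accuracy_pct)
  # a different seed draws different partitions (checked on a fixture whose
  # per-repeat accuracies do not saturate)
  out <- synthesize(synthetic_spec(n_proteins = 15, n_discriminant = 3,
                                   planted_fc = 1.3, seed = 133))
  dn <- subset_for_design(out$dataset, standard_designs()$long)
  cvA <- repeated_cv(dn$values, dn$labels, 2, cv_scheme(5, 20, seed = 9))
  cvB <- repeated_cv(dn$values, dn$labels, 2, cv_scheme(5, 20, seed = 10))
  expect_false(identical(cvA$per_repeat, cvB$per_repeat))
})

test_that("perfectly separated classes cross-validate at >= 99%", {
  d <- separable_fixture(seed = 131)
  cv <- repeated_cv(d$values, d$labels, 1, cv_scheme(5, 100, seed = 11))
  expect_gte(cv$accuracy_pct, 99)
  expect_gte(cv$ner_pct, 99)
})

test_that("single-class training folds trigger redraws and eventually error", {
  x <- matrix(rnorm(30), 10, 3)
  lab <- factor(rep(c("a", "b"), c(8, 2)))   # 2 minority samples, 5 groups
  # with both minority samples in one test fold the training fold keeps both
  # classes; degenerate draws are redrawn silently up to the budget
  cv <- repeated_cv(x, lab, 1, cv_scheme(5, 10, seed = 3))
  expect_true(is.finite(cv$accuracy_pct))
  lab1 <- factor(rep(c("a", "b"), c(9, 1)))  # impossible: the single b sample
  expect_error(repeated_cv(x, lab1, 1, cv_scheme(5, 5, seed = 3)),
               "training folds")
})

test_that("LV selection prefers the parsimonious model when one suffices", {
  expect_equal(select_n_lv(separable_fixture(seed = 132,
                                             n_proteins = 10)$values,
                           separable_fixture(seed = 132,
                                             n_proteins = 10)$labels,
                           cv_scheme(5, 30, seed = 5), max_lv = 1)$best_n_lv,
               1)
  # one cleanly informative variable: CV accuracy saturates for every LV
  # count and the tie rule picks the single latent variable
  best <- vapply(1:10, function(seed) local_seed(seed + 300, {
    lab <- factor(rep(c("a", "b"), each = 20))
    x <- cbind(sig = rnorm(40, sd = 0.3) + ifelse(lab == "b", 6, 0),
               noise = rnorm(40))
    select_n_lv(x, lab, cv_scheme(5, 30, seed = seed), max_lv = 2)$best_n_lv
  }), 0)
  expect_gte(mean(best == 1), 0.9)
})

test_that("backward elimination keeps an exact class indicator", {
  lab <- factor(rep(c("a", "b"), each = 10))
  x <- cbind(ind = ifelse(lab == "b", 1, -1) + 0,
             noise = local_seed(140, rnorm(20)))
  sel <- backward_eliminate(x, lab, cv_scheme(5, 20, seed = 6), max_lv = 1)
  expect_equal(sel$selected_set, "ind")
  expect_equal(sel$cv_metrics$accuracy_pct, 100)
})

test_that("the elimination trace is consistent and replayable", {
  d <- separable_fixture(seed = 141, n_proteins = 12, n_discriminant = 3)
  sch <- cv_scheme(5, 25, seed = 7)
  sel <- backward_eliminate(d$values, d$labels, sch, max_lv = 2)
  tr <- sel$trace
  # one step per variable count, down to a single variable
  expect_equal(tr$n_vars, seq(12, 1))
  # removed variables are never re-added and the partition is exact
  removed <- tr$removed[!is.na(tr$removed)]
  expect_false(anyDuplicated(removed) > 0)
  expect_setequal(c(sel$selected_set, removed[seq_len(12 - length(sel$selected_set))]),
                  colnames(d$values))
  # reported best CV accuracy is the max over logged steps
  expect_equal(sel$cv_metrics$accuracy_pct, max(tr$cv_accuracy_pct))
  # replay: refitting the selected set under the same scheme reproduces the
  # logged metrics bitwise (partitions are re-seeded identically per step)
  sub <- d$values[, sel$selected_set, drop = FALSE]
  replay <- repeated_cv(sub, d$labels,
                        min(sel$best_n_lv, ncol(sub)), sch)
  expect_identical(replay$accuracy_pct, sel$cv_metrics$accuracy_pct)
  expect_identical(replay$per_repeat, sel$cv_metrics$per_repeat)
  # fitting metrics come from the refit final model
  expect_equal(sel$fitting_metrics$accuracy_pct,
               classification_metrics(d$labels,
                                      sel$final_model$fitted_class)$accuracy_pct)
})

test_that("selection does not underperform the all-variable model", {
  d <- separable_fixture(seed = 142, n_proteins = 20, n_discriminant = 3,
                         fc = 3)
  sch <- cv_scheme(5, 25, seed = 8)
  sel <- backward_eliminate(d$values, d$labels, sch, max_lv = 2)
  all_cv <- sel$trace$cv_accuracy_pct[1]
  se <- sel$cv_metrics$accuracy_sd_pct / sqrt(sch$n_repeats)
  expect_gte(sel$cv_metrics$accuracy_pct, all_cv - se)
})

test_that("small planted panels are recovered by elimination", {
  spec <- synthetic_spec(n_proteins = 15, n_discriminant = 3, planted_fc = 2,
                         seed = 143)
  out <- synthesize(spec)
  d <- subset_for_design(out$dataset, standard_designs()$long)
  sel <- backward_eliminate(d$values, d$labels, cv_scheme(5, 25, seed = 12),
                            max_lv = 2)
  expect_true(all(out$truth$discriminant$t0_vs_t26 %in% sel$selected_set))
})

test_that("elimination requires at least two variables", {
  x <- matrix(rnorm(10), 10, 1)
  expect_error(backward_eliminate(x, factor(rep(c("a", "b"), 5)),
                                  cv_scheme(5, 5, seed = 1)),
               "at least 2")
})
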
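test_that("stratified folds partition the data evenly per class", {
  y <- rep(1:8, each = 10)
  folds <- stratified_kfold(y, 10, seed = 5)
  expect_length(folds, 10L)
  expect_equal(sort(unlist(folds)), seq_along(y))
  for (f in folds) {
    expect_equal(unname(table(y[f])), rep(1L, 8), ignore_attr = TRUE)
  }
  # unequal class sizes: per-class fold counts differ by at most one
  y2 <- rep(1:3, c(25, 31, 40))
  folds2 <- stratified_kfold(y2, 10, seed = 2)
  expect_equal(sort(unlist(folds2)), seq_along(y2))
  for (cls in 1:3) {
    per <- vapply(folds2, function(f) sum(y2[f] == cls), 1L)
    expect_lte(max(per) - min(per), 1L)
  }
  expect_identical(stratified_kfold(y, 10, seed = 5), folds)
  expect_false(identical(stratified_kfold(y, 10, seed = 6), folds))
  expect_error(stratified_kfold(rep(1:2, c(5, 20)), 10), "fewer than k")
})

test_that("single-member 'fusion' reduces to the classifier itself", {
  d <- make_planted_data(51, n_per_class = 12, n_noise = 3)
  res <- run_cv(d$X, d$y, 3, rule = "sum", k = 4, repeats = 1, seed = 7)
  expect_equal(res$accuracy, res$single_max)
  expect_equal(res$accuracy, unname(res$member_accuracy["3"]))
})

test_that("repeated CV is deterministic in the master seed", {
  d <- make_planted_data(52, n_per_class = 12, n_noise = 3)
  r1 <- run_cv(d$X, d$y, c(2, 3), rule = "ds", k = 4, repeats = 2, seed = 9)
  r2 <- run_cv(d$X, d$y, c(2, 3), rule = "ds", k = 4, repeats = 2, seed = 9)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$member_accuracy, r2$member_accuracy)
})

test_that("wide-margin data is recognised perfectly by the fused ensemble", {
  d <- make_planted_data(53, n_per_class = 12, n_noise = 0,
                         noise_sd = 0.05)
  res <- run_cv(d$X, d$y, c(3, 4, 5), rule = "ds", k = 6, repeats = 1,
                seed = 11)
  expect_equal(res$accuracy, 100)
})

test_that("group ablation drops exactly the group's columns and restores", {
  nm <- reference_selected_subset()
  X <- matrix(rnorm(20 * 9), 20, dimnames = list(NULL, nm))
  groups <- group_features_by_channel(nm)
  X_lt <- ablate_group(X, groups, "lt av")
  expect_equal(ncol(X_lt), 6L)
  expect_false(any(grepl("^lt_av", colnames(X_lt))))
  X_rt <- ablate_group(X, groups, "rt av")
  expect_equal(ncol(X_rt), 8L)
  # round trip: re-adding the stored columns reproduces X
  restored <- cbind(X_rt, X[, groups[["rt av"]], drop = FALSE])
  expect_equal(restored[, nm], X)
  expect_error(ablate_group(X, groups, "trunk a"), "unknown feature group")
  expect_error(ablate_group(X, groups, 99), "unknown feature group")
})

test_that("robustness summary reproduces published row arithmetic", {
  s <- robustness_summary(c(98.94, 98.83, 95.81, 99.70, 94.05))
  expect_equal(round(s$mean, 2), 97.47)
  expect_equal(round(s$sd, 4), 0.0216)
  s2 <- robustness_summary(c(96.55, 96.50, 94.24, 97.27, 92.60))
  expect_equal(round(s2$mean, 2), 95.43)
  expect_equal(round(s2$sd, 4), 0.0174)
  s3 <- robustness_summary(rep(90, 5))
  expect_equal(s3$mean, 90)
  expect_equal(s3$sd, 0)
  expect_error(robustness_summary(1:4), "exactly 5")
})

test_that("stage-2 selection prefers mean, then SD, then size", {
  ref <- reference_robustness_accuracies()
  summ <- setNames(lapply(seq_len(nrow(ref)), function(i)
    robustness_summary(as.numeric(ref[i, 2:6]))), ref$ensemble)
  expect_equal(stage2_select(summ), "3,4,5")
  expect_equal(stage2_select(summ["1,4"]), "1,4")
  tie <- list("1,2" = robustness_summary(c(95, 95, 95, 95, 95) + 1e-9),
              "3,4" = robustness_summary(c(97, 93, 95, 96, 94)))
  expect_equal(stage2_select(tie), "1,2")   # equal mean, smaller sd wins
  expect_error(stage2_select(list()), "no summaries")
})

test_that("stage-1 counting and tie-breaks follow the documented order", {
  tab <- data.frame(ensemble = c("a", "b"), single_max = c(90, 95),
                    vote = c(89, 94), sum = c(91, 94), ds = c(91, 96))
  counts <- gaitfuse:::stage1_counts(tab, c("vote", "sum", "ds"))
  expect_equal(counts$rule[1], "ds")
  expect_equal(counts$n_ge_single, c(2L, 1L, 0L))
  # all rules identical -> first rule in canonical order wins
  tab2 <- data.frame(ensemble = "a", single_max = 90,
                     vote = 92, sum = 92, ds = 92)
  expect_equal(gaitfuse:::stage1_counts(tab2)$rule[1], "vote")
})

test_that("stage-1 comparison runs end to end on planted data", {
  d <- make_planted_data(54, n_per_class = 12, n_noise = 2)
  s1 <- stage1_compare(d$X, d$y, list(c(2, 3), c(3, 4, 5)),
                       rules = c("vote", "sum", "ds"), k = 4, repeats = 1,
                       seed = 13)
  expect_equal(dim(s1$table), c(2L, 5L))
  expect_true(all(s1$table[-1] >= 0 & s1$table[-1] <= 100))
  expect_true(s1$best_rule %in% c("vote", "sum", "ds"))
  expect_error(stage1_compare(d$X, d$y, list(3), k = 4, seed = 1),
               "classifier ids")
})

test_that("fused ensembles degrade more gracefully than their worst member", {
  # corrupt one channel group at a time: the D-S fused accuracy should drop
  # by less than the worst member's drop in most scenarios (majority over
  # several seeds)
  good <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    d <- make_planted_data(60 + s, n_per_class = 12, n_noise = 5)
    groups <- group_features_by_channel(colnames(d$X))
    full <- run_cv(d$X, d$y, c(3, 4, 5), rule = "ds", k = 4, repeats = 1,
                   seed = 17)
    wins <- 0
    for (g in seq_along(groups)) {
      Xc <- d$X
      Xc[, groups[[g]]] <- withr::with_seed(70 + g,
        matrix(rnorm(length(groups[[g]]) * nrow(Xc), sd = 1), nrow(Xc)))
      res <- run_cv(Xc, d$y, c(3, 4, 5), rule = "ds", k = 4, repeats = 1,
                    seed = 17)
      fused_drop <- full$accuracy - res$accuracy
      worst_drop <- max(full$member_accuracy - res$member_accuracy)
      if (fused_drop < worst_drop + 1e-9) wins <- wins + 1
    }
    if (wins >= 3) good <- good + 1
  }
  expect_gte(good, ceiling(n_seeds / 2))
})
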
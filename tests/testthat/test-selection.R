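test_that("mutual information behaves at its anchor points", {
  y <- rep(1:8, each = 20)
  # a feature that encodes the label exactly carries log(8) nats
  expect_equal(mutual_information(as.numeric(y), y), log(8))
  expect_equal(mutual_information(rep(3.7, 160), y), 0)
  withr::with_seed(21, {
    f <- rnorm(160)
    obs <- mutual_information(f, y)
    null <- replicate(200, mutual_information(f, sample(y)))
    expect_lt(obs, quantile(null, 0.95) + 1e-12)
  })
  expect_error(mutual_information(rnorm(5), rep(1:5)), "at least 10")
  expect_error(mutual_information(rnorm(20), rep(1:2, 10), bins = 1),
               "bins")
})

test_that("MRMR ranks a planted informative feature first", {
  withr::with_seed(31, {
    y <- rep(1:8, each = 20)
    X <- cbind(planted = y + rnorm(160, sd = 0.05),
               matrix(rnorm(160 * 15), 160))
    expect_equal(mrmr_rank(X, y, 3)[1], 1L)
    # first pick equals the brute-force relevance argmax
    rels <- apply(X, 2, mutual_information, y = y)
    expect_equal(mrmr_rank(X, y, 1), unname(which.max(rels)))
  })
})

test_that("MRMR greedy trace equals exhaustive evaluation of the criterion", {
  withr::with_seed(32, {
    y <- rep(1:4, each = 15)
    d <- make_planted_data(1, n_per_class = 15, n_noise = 5)
    X <- d$X[seq_len(60), 1:10]
    expect_equal(mrmr_rank(X, y, 6), exhaustive_mrmr(X, y, 6))
    # redundancy penalty: with an exact duplicate of the top feature and a
    # weakly informative alternative, the duplicate is not picked second
    y2 <- rep(1:8, each = 20)
    X2 <- cbind(f1 = y2 + rnorm(160, sd = 0.05))
    X2 <- cbind(X2, dup = X2[, 1],
                weak = y2 + rnorm(160, sd = 3),
                noise = rnorm(160))
    r <- mrmr_rank(X2, y2, 2)
    expect_equal(r[1], 1L)
    expect_false(r[2] == 2L)
    expect_equal(r, exhaustive_mrmr(X2, y2, 2))
  })
})

test_that("MRMR screens the full bank without duplication", {
  fm <- small_gait_features()
  r <- mrmr_rank(as.matrix(fm[, 1:462]), fm$label, k = 100)
  expect_length(r, 100L)
  expect_equal(anyDuplicated(r), 0L)
  expect_error(mrmr_rank(as.matrix(fm[, 1:462]), fm$label, k = 463),
               "exceeds")
})

test_that("BMSF is deterministic and keeps an all-informative pair", {
  d <- make_planted_data(5, n_per_class = 12, n_noise = 5)
  X2 <- d$X[, 1:2]
  r <- bmsf_select(X2, d$y, n_rows = 16, seed = 9)
  expect_equal(r$final_subset, c(1L, 2L))
  r2 <- bmsf_select(d$X, d$y, n_rows = 16, seed = 4)
  r3 <- bmsf_select(d$X, d$y, n_rows = 16, seed = 4)
  expect_identical(r2[c("final_subset", "objective_trace", "n_iter")],
                   r3[c("final_subset", "objective_trace", "n_iter")])
  expect_error(bmsf_select(d$X[, 1, drop = FALSE], d$y), "at least 2")
})

test_that("forced subset size is honoured", {
  d <- make_planted_data(6, n_per_class = 12, n_noise = 10)
  r <- bmsf_select(d$X, d$y, n_rows = 32, seed = 2, force_size = 9)
  expect_length(r$final_subset, 9L)
  expect_equal(anyDuplicated(r$final_subset), 0L)
})

test_that("two-stage selection reports original column indices", {
  d <- make_planted_data(7, n_per_class = 12, n_noise = 20)
  res <- select_features(d$X, d$y, k_mrmr = 12, n_rows = 32, seed = 3)
  expect_true(all(res$final_subset %in% res$mrmr_ranking))
  expect_true(all(res$final_subset %in% seq_len(ncol(d$X))))
  expect_true(all(d$informative %in% res$mrmr_ranking))
})

test_that("channel grouping partitions the published subset as printed", {
  g <- group_features_by_channel(reference_selected_subset())
  expect_equal(lengths(g),
               c("rt av" = 1L, "lt av" = 3L, "lf av" = 3L,
                 "ls v" = 1L, "rt v" = 1L))
  expect_equal(sort(unlist(g, use.names = FALSE)), 1:9)
  expect_equal(group_features_by_channel("rt_av.mean"),
               list("rt av" = 1L))
  same <- group_features_by_channel(c("rt_av.mean", "rt_av.rms"))
  expect_length(same, 1L)
  expect_error(group_features_by_channel(character(0)), "non-empty")
})
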
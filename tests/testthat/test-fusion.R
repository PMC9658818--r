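test_that("score discounting produces valid mass functions", {
  m <- scores_to_mass(c(0.7, 0.3), alpha = 1)
  expect_equal(m$singleton, c(0.7, 0.3))
  expect_equal(m$theta, 0)
  m2 <- scores_to_mass(c(1, 0), alpha = 0.9)
  expect_equal(m2$singleton, c(0.9, 0))
  expect_equal(m2$theta, 0.1)
  withr::with_seed(3, {
    for (i in 1:20) {
      row <- random_simplex(8)
      a <- runif(1, 0.05, 1)
      mm <- scores_to_mass(row, a)
      expect_equal(sum(mm$singleton) + mm$theta, 1, tolerance = 1e-12)
    }
  })
  expect_error(scores_to_mass(c(0.5, 0.5), alpha = 0), "alpha")
  expect_error(scores_to_mass(c(0.5, 0.5), alpha = 1.1), "alpha")
  expect_error(scores_to_mass(c(0.9, 0.3)), "simplex")
})

test_that("Dempster combination matches hand-derived and algebraic anchors", {
  # worked conflict example: K = 0.46
  m1 <- mass_function(c(0.6, 0.4))
  m2 <- mass_function(c(0.7, 0.3))
  r <- ds_combine(m1, m2)
  expect_equal(r$singleton, c(0.42, 0.12) / 0.54, tolerance = 1e-12)
  expect_equal(r$theta, 0)

  # the vacuous mass is the neutral element
  vac <- mass_function(rep(0, 2), theta = 1)
  expect_equal(ds_combine(m1, vac)$singleton, m1$singleton)
  # commutativity
  r2 <- ds_combine(m2, m1)
  expect_equal(r$singleton, r2$singleton)
  # total conflict
  expect_error(ds_combine(mass_function(c(1, 0)), mass_function(c(0, 1))),
               class = "gaitfuse_conflict")
  expect_error(ds_combine(m1, mass_function(c(0.5, 0.5), class_ids = 3:4)),
               "different frames")
})

test_that("belief and plausibility bracket singleton support", {
  m <- mass_function(c(0.6, 0.3), theta = 0.1)
  expect_equal(bel_pl(m, 1), c(bel = 0.6, pl = 0.7))
  m0 <- mass_function(c(0.6, 0.4), theta = 0)
  bp <- bel_pl(m0, 2)
  expect_equal(bp[["bel"]], bp[["pl"]])
  vac <- mass_function(rep(0, 3), theta = 1)
  expect_equal(bel_pl(vac, 2), c(bel = 0, pl = 1))
  expect_error(bel_pl(m, 9), "unknown class")
})

test_that("D-S fusion agrees with exhaustive enumeration and is fold-stable", {
  Zu <- matrix(rep(c(0, 0, 1, 0, 0, 0, 0, 0), 3), nrow = 3, byrow = TRUE)
  expect_equal(as.integer(ds_fuse(Zu)), 3L)
  withr::with_seed(41, {
    for (i in 1:30) {
      Z <- t(replicate(3, random_simplex(8)))
      got <- ds_fuse(Z, alpha = 0.95)
      oracle <- bf_ds_fuse(Z, alpha = 0.95)
      expect_equal(as.integer(got), oracle$decision)
      expect_equal(unname(attr(got, "mass")$singleton), oracle$singleton,
                   tolerance = 1e-9)
      rev <- ds_fuse(Z[3:1, ], alpha = 0.95)
      expect_equal(unname(attr(rev, "mass")$singleton),
                   unname(attr(got, "mass")$singleton), tolerance = 1e-9)
    }
  })
})

test_that("total conflict at alpha = 1 falls back to the sum rule", {
  Z <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0.2, 0.8))
  got <- ds_fuse(Z, alpha = 1)
  expect_true(isTRUE(attr(got, "conflict_fallback")))
  expect_equal(as.integer(got), as.integer(algebraic_fuse(Z, "sum")))
  expect_error(ds_fuse(Z, alpha = 1, on_conflict = "error"),
               class = "gaitfuse_conflict")
})

test_that("majority voting requires a strict majority, else plurality", {
  expect_equal(as.integer(majority_vote(c(1, 1, 2))), 1L)
  expect_true(attr(majority_vote(c(1, 1, 2)), "majority"))
  tie <- majority_vote(c(1, 2, 3))
  expect_equal(as.integer(tie), 1L)
  expect_false(attr(tie, "majority"))
  expect_equal(as.integer(majority_vote(c(2, 2, 1, 1, 2))), 2L)
  expect_error(majority_vote(integer(0)), "no votes")
})

test_that("decision templates average training outputs and pick nearest", {
  Z0 <- rbind(c(0.8, 0.1, 0.1), c(0.6, 0.3, 0.1))
  Z1 <- rbind(c(0.1, 0.8, 0.1), c(0.2, 0.7, 0.1))
  Z1b <- rbind(c(0.3, 0.6, 0.1), c(0.0, 0.9, 0.1))
  tpl <- dt_fit(list(Z0, Z1, Z1b, Z0), c(1, 2, 2, 1), class_ids = 1:2)
  # class absent from training
  expect_error(dt_fit(list(Z0, Z1), c(1, 2), class_ids = 1:3),
               "no training samples")
  expect_equal(tpl$templates[[1]], Z0)
  expect_equal(tpl$templates[[2]], (Z1 + Z1b) / 2)
  expect_equal(dim(tpl$templates[[2]]), c(2L, 3L))

  tpl2 <- dt_fit(list(Z0, Z1), c(1, 2), class_ids = 1:2)
  expect_equal(as.integer(dt_predict(tpl2, Z0)), 1L)
  expect_equal(as.integer(dt_predict(tpl2, Z1)), 2L)
  # equidistant -> lowest class id
  mid <- (Z0 + Z1) / 2
  expect_equal(as.integer(dt_predict(tpl2, mid)), 1L)
  expect_error(dt_predict(tpl2, Z0[, 1:2]), "shape")
  withr::with_seed(43, {
    for (i in 1:30) {
      tplr <- dt_fit(lapply(1:8, function(c) t(replicate(3,
        random_simplex(8)))), 1:8, class_ids = 1:8)
      Z <- t(replicate(3, random_simplex(8)))
      expect_equal(as.integer(dt_predict(tplr, Z)),
                   bf_dt_predict(tplr$templates, Z))
    }
  })
})

test_that("algebraic rules match direct arithmetic and each other", {
  Z <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.6, 0.2))
  s <- algebraic_fuse(Z, "sum")
  expect_equal(as.integer(s), 2L)
  expect_equal(unname(attr(s, "support")), c(0.7, 0.9, 0.4))
  expect_equal(as.integer(algebraic_fuse(Z, "average")), 2L)
  # single-row degenerate case: every rule is that row's argmax
  Z1 <- matrix(c(0.1, 0.2, 0.7), nrow = 1)
  for (rule in c("sum", "average", "max", "min", "product")) {
    expect_equal(as.integer(algebraic_fuse(Z1, rule)), 3L)
  }
  expect_error(algebraic_fuse(Z, "median"), "arg")
  # one-hot member under the product rule does not annihilate everything
  Zoh <- rbind(c(1, 0, 0), c(0.4, 0.35, 0.25))
  expect_equal(as.integer(algebraic_fuse(Zoh, "product")), 1L)
})

test_that("sum and average decisions coincide on random inputs", {
  withr::with_seed(44, {
    for (i in 1:100) {
      Z <- t(replicate(sample(2:5, 1), random_simplex(8)))
      expect_equal(as.integer(algebraic_fuse(Z, "sum")),
                   as.integer(algebraic_fuse(Z, "average")))
    }
  })
})

test_that("all eight rules agree under unanimity", {
  one_hot <- function(j, m = 8) { v <- rep(0, m); v[j] <- 1; v }
  for (cls in c(1, 4, 8)) {
    Z <- t(replicate(3, one_hot(cls)))
    tpl <- dt_fit(lapply(1:8, function(c) t(replicate(3, one_hot(c)))),
                  1:8, class_ids = 1:8)
    for (rule in fusion_rules()) {
      expect_equal(fuse(Z, rule, templates = tpl), cls)
    }
  }
  expect_error(fuse(matrix(1, 1, 1), "nope"), "unknown fusion rule")
})
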
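test_that("mann_whitney matches exact enumeration on small samples", {
  r <- mann_whitney(c(10, 12, 14), c(1, 2, 3))
  expect_equal(r$u, 9)
  expect_equal(r$p, 0.1)

  # full-tie symmetry: U = n1*n2/2
  expect_equal(mann_whitney(c(5, 5), c(5, 5))$u, 2)

  # label swap maps U -> n1*n2 - U with the same p (exact branch)
  x <- c(3, 7, 9); y <- c(1, 4, 8, 12)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$u + b$u, length(x) * length(y))
  expect_equal(a$p, b$p)
})

test_that("mann_whitney large-sample approximation is sound", {
  set.seed(31)
  x <- rnorm(40, 0.8); y <- rnorm(60)
  r <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(r$u, unname(ref$statistic))
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)

  # label swap symmetry in the approximate branch too
  b <- mann_whitney(y, x)
  expect_equal(r$u + b$u, 40 * 60)
  expect_equal(r$p, b$p)
})

test_that("mann_whitney type-I error is near nominal", {
  set.seed(77)
  rej <- vapply(1:1000, function(i) {
    mann_whitney(rnorm(20), rnorm(20))$p < 0.05
  }, TRUE)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("bh_fdr applies the i*q/m step-up rule", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.9), q = 0.05, m = 4),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10))))
  # rank-1 threshold with a study-sized m
  expect_true(bh_fdr(c(0.05 / 67 - 1e-9, rep(1, 9)), q = 0.05, m = 67)[1])
  expect_false(bh_fdr(c(0.05 / 67 + 1e-9, rep(1, 9)), q = 0.05, m = 67)[1])
  expect_error(bh_fdr(c(0.1, 0.2), q = 1.5), "q must be")
})

test_that("bh_fdr flags form a prefix of the sorted p-values, monotone in q", {
  set.seed(5)
  for (i in 1:50) {
    p <- runif(30)^2
    f1 <- bh_fdr(p, q = 0.05)
    f2 <- bh_fdr(p, q = 0.20)
    ord <- order(p)
    runs <- rle(f1[ord])$values
    expect_true(length(runs) <= 2 && (length(runs) == 1 || runs[1]))
    expect_true(all(f2[f1]))  # larger q flags a superset
  }
})

test_that("marker_auc equals the pairwise win fraction", {
  expect_equal(marker_auc(c(10, 20), c(1, 2)), 1)
  expect_equal(marker_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(marker_auc(c(3, 5), c(1, 2, 4)), 5 / 6)
})

test_that("rank-formula AUC equals trapezoidal ROC integration", {
  set.seed(11)
  for (i in 1:200) {
    x <- round(rnorm(sample(3:25, 1), sample(0:2, 1)), 1)  # ties likely
    y <- round(rnorm(sample(3:25, 1)), 1)
    expect_equal(marker_auc(x, y), trapezoid_auc(x, y), tolerance = 1e-12)
  }
})

test_that("cutpoint_at_specificity picks the SN-maximal qualifying value", {
  r <- cutpoint_at_specificity(c(18, 25), 1:20, sp_target = 95)
  expect_equal(r$cut_point, 20)
  expect_equal(r$achieved_sp, 95)
  expect_equal(r$sn, 50)

  # perfectly separated up-marker: full sensitivity
  r2 <- cutpoint_at_specificity(101:120, 1:100, sp_target = 95)
  expect_equal(r2$sn, 100)

  # mirror symmetry: down-direction on negated data reproduces the up result
  r3 <- cutpoint_at_specificity(-c(18, 25), -(1:20), sp_target = 95,
                                direction = "down")
  expect_equal(r3$cut_point, -r$cut_point)
  expect_equal(r3$sn, r$sn)
  expect_equal(r3$achieved_sp, r$achieved_sp)

  expect_error(cutpoint_at_specificity(5, 1:10, sp_target = 95),
               "minimum resolvable")
})

test_that("achieved specificity is never below target on the input controls", {
  set.seed(21)
  for (i in 1:100) {
    ctrl <- round(rexp(sample(20:200, 1), 0.1), 1)
    cases <- round(rexp(sample(5:50, 1), 0.05), 1)
    sp <- sample(c(80, 90, 95), 1)
    r <- cutpoint_at_specificity(cases, ctrl, sp_target = sp)
    expect_gte(r$achieved_sp, sp)
  }
})

test_that("screen_markers summarises, flags and orients markers", {
  g <- generate_cohort(planted_config(seed = 6, n_markers = 6, n_cases = 80))
  sc <- screen_markers(g$cohort)
  expect_equal(nrow(sc), 6)
  expect_true(all(sc$achieved_sp >= 95))
  expect_true(all(sc$auc >= 0.5 & sc$auc <= 1))
  expect_true(sc$bh_significant[sc$marker == "plantA"])
  expect_equal(sc$direction[sc$marker == "plantA"], "up")
  expect_true(all(sc$cut_point >= pmin(sc$case_low, sc$control_low) &
                    sc$cut_point <= pmax(sc$case_high, sc$control_high)))
  expect_gte(attr(sc, "bh_threshold"), 0)

  # down-markers are oriented and cut mirrored
  cfgd <- planted_config(seed = 7, n_markers = 4, n_cases = 80)
  cfgd$marker_specs[[1]]$case_log_shift <- -1.2
  scd <- screen_markers(generate_cohort(cfgd)$cohort)
  expect_equal(scd$direction[scd$marker == "plantA"], "down")
})
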
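test_that("default configuration yields the study-shaped cohort", {
  g <- generate_cohort(generator_config(seed = 2))
  expect_equal(n_cases(g$cohort), 135)
  expect_equal(n_controls(g$cohort), 540)
  expect_length(g$cohort$markers, 67)
  expect_length(g$cohort$match_groups, 135)
  expect_silent(validate_cohort(g$cohort, control_ratio = 4))
})

test_that("match groups agree on sex, race, age window and draw-date block", {
  g <- generate_cohort(generator_config(n_cases = 10, seed = 5,
                                        marker_specs = default_marker_specs(10)))
  co <- g$cohort
  expect_equal(n_controls(co), 40)
  s <- co$subjects
  block <- function(d) paste(format(d, "%Y"), (as.integer(format(d, "%m")) - 1) %/% 2)
  for (case_id in names(co$match_groups)) {
    case <- s[s$subject_id == case_id, ]
    ctrl <- s[s$subject_id %in% co$match_groups[[case_id]], ]
    expect_equal(nrow(ctrl), 4)
    expect_true(all(ctrl$sex == case$sex))
    expect_true(all(ctrl$race == case$race))
    expect_true(all(abs(ctrl$age - case$age) <= 5))
    expect_true(all(block(ctrl$draw_date) == block(case$draw_date)))
  }
})

test_that("generation is deterministic: identical seed, byte-identical CSV", {
  cfg <- generator_config(n_cases = 15, seed = 42,
                          marker_specs = default_marker_specs(12))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cfg)$cohort, p1)
  write_cohort(simulate_cohort(cfg)$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted velocity slope shows up as a negative trend (OLS oracle)", {
  g <- generate_cohort(generator_config(seed = 8))
  s <- g$cohort$subjects
  cases <- s[s$status == "case", ]
  fit <- ols_oracle(cases$days_to_dx, log(cases$CA_19_9))
  expect_lt(fit$slope, 0)
  expect_lt(fit$p, 0.05)
  expect_lt(cor(cases$days_to_dx, log(cases$CA_19_9)), 0)
})

test_that("anchor correlation structure is imposed on the log scale", {
  g <- generate_cohort(generator_config(seed = 12))
  s <- g$cohort$subjects
  ctrl <- s[s$status == "control", ]
  r_cea <- cor(log(ctrl$CA_19_9), log(ctrl$CEA))
  r_null <- cor(log(ctrl$CA_19_9), log(ctrl$marker_20))
  expect_gt(r_cea, 0.7)
  expect_lt(abs(r_null), 0.15)
})

test_that("inject_duplicates embeds the configured duplicate structure", {
  cfg <- generator_config(n_cases = 20, seed = 3,
                          marker_specs = default_marker_specs(8))
  co <- generate_cohort(cfg)$cohort
  dup <- inject_duplicates(co, cfg)
  s <- dup$subjects
  links <- s[!is.na(s$duplicate_of), ]
  expect_equal(nrow(links), 17)
  src_status <- s$status[match(links$duplicate_of, s$subject_id)]
  expect_equal(sum(src_status == "case"), 7)
  expect_equal(sum(src_status == "control"), 10)
  expect_true(all(is.na(links$match_id)))

  # zero-noise limit: duplicates identical to their sources
  cfg0 <- generator_config(n_cases = 20, seed = 3, assay_cv_range = c(0, 0),
                           marker_specs = default_marker_specs(8))
  dup0 <- inject_duplicates(co, cfg0)
  s0 <- dup0$subjects
  l0 <- s0[!is.na(s0$duplicate_of), ]
  src0 <- s0[match(l0$duplicate_of, s0$subject_id), ]
  for (m in dup0$markers) expect_equal(l0[[m]], src0[[m]])
})

test_that("duplicate noise is calibrated: mean pair CV tracks its target", {
  cfg <- generator_config(n_cases = 30, seed = 1,
                          marker_specs = default_marker_specs(4),
                          n_duplicates_case = 7, n_duplicates_control = 10)
  co <- generate_cohort(cfg)$cohort
  # average observed mean CV over seeds approaches the per-marker target
  reps <- lapply(1:25, function(s) {
    d <- inject_duplicates(co, cfg, seed = s)
    list(cv = duplicate_report(d)$marker_cv$cv_mean,
         target = attr(d, "cv_targets"))
  })
  mean_cv <- rowMeans(vapply(reps, `[[`, numeric(4), "cv"))
  mean_target <- rowMeans(vapply(reps, `[[`, numeric(4), "target"))
  expect_true(all(abs(mean_cv - mean_target) < 1.0))
  expect_true(all(mean_cv >= cfg$assay_cv_range[1] - 1 &
                    mean_cv <= cfg$assay_cv_range[2] + 1))
})

test_that("a one-SD case shift is recovered by the univariate screen", {
  hits <- vapply(1:50, function(s) {
    g <- generate_cohort(planted_config(seed = s, n_markers = 5,
                                        n_cases = 135, shift1 = 1.0))
    sc <- screen_markers(g$cohort)
    sc$bh_significant[sc$marker == "plantA"]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("null cohorts keep the BH-flagged marker fraction near nominal", {
  frac <- vapply(1:50, function(s) {
    g <- generate_cohort(null_config(seed = 100 + s, n_markers = 20,
                                     n_cases = 40))
    mean(screen_markers(g$cohort)$bh_significant)
  }, 0)
  se <- sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), 0.05 + 3 * max(se, 1e-3))
})
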
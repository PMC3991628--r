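# Independent oracles and small fixtures shared across tests.

# Trapezoidal area under the empirical ROC curve ("call case if value >= t").
trapezoid_auc <- function(case_values, control_values) {
  ts <- sort(unique(c(case_values, control_values)), decreasing = TRUE)
  tpr <- c(0, vapply(ts, function(t) mean(case_values >= t), 0), 1)
  fpr <- c(0, vapply(ts, function(t) mean(control_values >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Closed-form simple linear regression (normal equations) with slope t-test.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(t), n - 2))
}

# Hand-built cohort: explicit rows, 2 markers, 2 complete match groups.
tiny_cohort <- function() {
  subjects <- data.frame(
    subject_id = c("c1", "k1", "k2", "k3", "k4",
                   "c2", "k5", "k6", "k7", "k8"),
    status = rep(c("case", rep("control", 4)), 2),
    age = c(rep(60L, 5), rep(70L, 5)),
    sex = rep(c("female", "male"), each = 5),
    race = "white",
    draw_date = as.Date("1996-03-10") + rep(c(0, 400), each = 5),
    days_to_dx = c(200, NA, NA, NA, NA, 700, NA, NA, NA, NA),
    survival_cat = c("<6mo", NA, NA, NA, NA, ">24mo", NA, NA, NA, NA),
    duplicate_of = NA_character_,
    match_id = rep(c("g1", "g2"), each = 5),
    m_alpha = c(12, 2, 3, 4, 5, 20, 6, 7, 8, 9),
    m_beta = c(100, 140, 120, 110, 130, 90, 150, 160, 170, 155),
    stringsAsFactors = FALSE)
  new_cohort(subjects, c("m_alpha", "m_beta"))
}

# Fast optimizer settings for toy problems.
quick_mconfig <- function(seed = 1, ...) {
  metropolis_config(n_iterations = 200, n_cv = 20, seed = seed, ...)
}

# Small planted-signal generator: two informative markers among `n_markers`.
planted_config <- function(seed, n_markers = 10, n_cases = 60,
                           shift1 = 1.0, shift2 = 0.8) {
  specs <- c(list(marker_spec("plantA", 3, 1, case_log_shift = shift1),
                  marker_spec("plantB", 5, 1, case_log_shift = shift2)),
             lapply(seq_len(n_markers - 2), function(i)
               marker_spec(sprintf("null_%02d", i), 4, 1)))
  generator_config(n_cases = n_cases, control_ratio = 4, marker_specs = specs,
                   anchor = "plantA", seed = seed)
}

# All-null generator for calibration tests.
null_config <- function(seed, n_markers = 30, n_cases = 40) {
  specs <- lapply(seq_len(n_markers), function(i)
    marker_spec(sprintf("null_%02d", i), 4, 1))
  generator_config(n_cases = n_cases, control_ratio = 4, marker_specs = specs,
                   anchor = "null_01", seed = seed)
}
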
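#' Mann-Whitney U test for a case/control marker comparison
#'
#' `U` counts case-over-control wins with ties scored 1/2. The two-sided
#' p-value is obtained by exact enumeration of all labelings when
#' `n1 * n2 <= 64`, and otherwise from the tie-corrected normal approximation
#' with a continuity correction of 1/2.
#'
#' @param case_values,control_values numeric concentration vectors.
#' @return list with elements `u` and `p`.
#' @export
mann_whitney <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  u_stat <- function(idx, pooled, n1) {
    rk <- rank(pooled)
    sum(rk[idx]) - n1 * (n1 + 1) / 2
  }
  pooled <- c(case_values, control_values)
  u <- u_stat(seq_len(n1), pooled, n1)
  if (n1 * n2 <= 64) {
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, u_stat, pooled = pooled, n1 = n1)
    dev <- abs(us - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-12)
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(list(u = u, p = 1))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
  }
  list(u = u, p = p)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Ranks the p-values from most to least significant and flags every p with
#' rank at or below the largest `i` such that `p(i) <= i * q / m`. `m` may
#' exceed the number of p-values supplied (the study's convention of counting
#' all comparisons performed).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q target false discovery rate in (0, 1) (default 0.05).
#' @param m total number of comparisons (default `length(p_values)`).
#' @return logical vector of flags, aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, q = 0.05, m = length(p_values)) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (m < length(p_values)) stop("m must be >= length(p_values)")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]")
  }
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- ps <= seq_along(ps) * q / m
  k <- if (any(ok)) max(which(ok)) else 0L
  flags <- logical(length(p_values))
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' The realized BH significance threshold
#'
#' Largest p-value flagged by [bh_fdr()] (0 if none) - the study-level
#' "significance was set at p < ..." number implied by the step-up rule.
#'
#' @inheritParams bh_fdr
#' @return the realized p-value threshold.
#' @export
bh_threshold <- function(p_values, q = 0.05, m = length(p_values)) {
  fl <- bh_fdr(p_values, q, m)
  if (any(fl)) max(p_values[fl]) else 0
}

#' Area under the ROC curve from the rank formula
#'
#' `auc = U / (n1 * n2)` with the case group as positives; equal to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @inheritParams mann_whitney
#' @return AUC in \[0, 1\].
#' @export
marker_auc <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  rk <- rank(c(case_values, control_values))
  (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Empirical cut-point and sensitivity at a target specificity
#'
#' For an up-marker the cut-point is the smallest observed value `v` such
#' that the fraction of controls at or above `v` does not exceed
#' `1 - sp_target/100`; a sample is called a case when its value is `>= v`.
#' For a down-marker (prolactin-like) the rule is mirrored: largest observed
#' `v` with few enough controls at or below it, calling cases at `<= v`.
#' Among qualifying values the one maximizing sensitivity is returned. The
#' achieved specificity is always at or above the target on the input
#' controls.
#'
#' @inheritParams mann_whitney
#' @param sp_target target specificity in percent, 0 < sp < 100.
#' @param direction `"up"` (cases elevated) or `"down"` (cases depressed).
#' @return list with `cut_point`, `sn` (percent of cases called),
#'   `achieved_sp` (percent of controls not called).
#' @export
cutpoint_at_specificity <- function(case_values, control_values,
                                    sp_target = 95,
                                    direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!length(control_values)) stop("controls must be non-empty")
  if (sp_target <= 0 || sp_target >= 100) stop("sp_target must be in (0, 100)")
  n_ctrl <- length(control_values)
  allowed <- floor(n_ctrl * (1 - sp_target / 100))
  if (allowed < 1) {
    stop("sp_target of ", sp_target, "% unattainable with ", n_ctrl,
         " controls; minimum resolvable specificity below 100% is ",
         round(100 * (n_ctrl - 1) / n_ctrl, 2), "%")
  }
  sgn <- if (direction == "up") 1 else -1
  cs <- sgn * case_values; ct <- sgn * control_values
  cand <- sort(unique(c(cs, ct)))
  qualifies <- vapply(cand, function(v) sum(ct >= v) <= allowed, TRUE)
  if (!any(qualifies)) {
    # all observed values fail: only a cut above every control attains SP
    v <- max(ct) + max(abs(max(ct)), 1) * 1e-9
  } else {
    v <- cand[which(qualifies)[1]]  # smallest qualifying value: maximal SN
  }
  sn <- 100 * mean(cs >= v)
  sp <- 100 * mean(ct < v)
  list(cut_point = sgn * v, sn = sn, achieved_sp = sp)
}

#' Univariate marker screen
#'
#' Per-marker case/control testing: Mann-Whitney U with BH false-discovery
#' control, group summaries, direction, AUC (reported in the discriminating
#' direction), and the cut-point/sensitivity at the target specificity.
#'
#' @param cohort an unblinded [new_cohort()] object. Duplicate aliquots are
#'   excluded.
#' @param markers markers to screen (default: full registry).
#' @param q FDR level (default 0.05).
#' @param m total comparisons for the BH rule (default `length(markers)`).
#' @param sp_target target specificity in percent (default 95).
#' @return data.frame with one row per marker: `marker, u, p, bh_significant,
#'   direction, case_low, case_high, case_mean, control_low, control_high,
#'   control_mean, cut_point, sn_at_sp, achieved_sp, auc`.
#' @export
screen_markers <- function(cohort, markers = cohort$markers, q = 0.05,
                           m = length(markers), sp_target = 95) {
  assert_unblinded(cohort, "screen_markers")
  s <- cohort$subjects[is.na(cohort$subjects$duplicate_of), ]
  is_case <- s$status == "case"
  rows <- lapply(markers, function(mk) {
    x1 <- s[[mk]][is_case]; x0 <- s[[mk]][!is_case]
    mw <- mann_whitney(x1, x0)
    auc_raw <- mw$u / (length(x1) * length(x0))
    dir <- if (auc_raw >= 0.5) "up" else "down"
    cp <- cutpoint_at_specificity(x1, x0, sp_target, dir)
    data.frame(marker = mk, u = mw$u, p = mw$p, bh_significant = NA,
               direction = dir,
               case_low = min(x1), case_high = max(x1), case_mean = mean(x1),
               control_low = min(x0), control_high = max(x0),
               control_mean = mean(x0),
               cut_point = cp$cut_point, sn_at_sp = cp$sn,
               achieved_sp = cp$achieved_sp,
               auc = max(auc_raw, 1 - auc_raw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_significant <- bh_fdr(out$p, q = q, m = m)
  attr(out, "bh_threshold") <- bh_threshold(out$p, q = q, m = m)
  attr(out, "sp_target") <- sp_target
  out
}
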
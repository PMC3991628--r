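#' Construct a log-linear scoring function
#'
#' A panel's scoring function is `SF(c) = sum_i w_i * ln(c_i)` over the panel
#' markers; a sample is diagnosed as a case when its score is at or above the
#' threshold, which is calibrated so that specificity on the calibration
#' controls is at or above `sp_target`.
#'
#' @param markers ordered marker subset.
#' @param coefficients one weight per marker.
#' @param threshold score cut-off (case if score >= threshold).
#' @param sp_target percent specificity used at calibration.
#' @return an object of class `scoring_function`.
#' @export
scoring_function <- function(markers, coefficients, threshold, sp_target = 95) {
  stopifnot(length(markers) == length(coefficients))
  structure(list(markers = markers,
                 coefficients = setNames(as.numeric(coefficients), markers),
                 threshold = threshold, sp_target = sp_target),
            class = "scoring_function")
}

#' @export
print.scoring_function <- function(x, ...) {
  cat("Scoring function: SF = ",
      paste(sprintf("%+.3f*ln(%s)", x$coefficients, x$markers), collapse = " "),
      "\n", sep = "")
  cat(sprintf("  call case if SF >= %.4f (calibrated at %.0f%% specificity)\n",
              x$threshold, x$sp_target))
  invisible(x)
}

#' Score samples with a scoring function
#'
#' @param sf a [scoring_function()].
#' @param x either a named concentration vector (pg/ml) for one sample, or an
#'   [new_cohort()] object.
#' @return for a vector, the numeric score; for a cohort, a data.frame
#'   `subject_id, score, call` where `call` is `"case"`/`"control"` under the
#'   threshold rule.
#' @export
sf_score <- function(sf, x) {
  if (inherits(x, "mmc_cohort")) {
    miss <- setdiff(sf$markers, x$markers)
    if (length(miss)) stop("cohort lacks marker(s): ", paste(miss, collapse = ", "))
    s <- as.vector(log_matrix(x, sf$markers) %*% sf$coefficients)
    return(data.frame(subject_id = x$subjects$subject_id, score = s,
                      call = ifelse(s >= sf$threshold, "case", "control"),
                      stringsAsFactors = FALSE))
  }
  miss <- setdiff(sf$markers, names(x))
  if (length(miss)) stop("missing marker(s): ", paste(miss, collapse = ", "))
  v <- as.numeric(x[sf$markers])
  if (any(v <= 0)) stop("concentrations must be positive")
  sum(sf$coefficients * log(v))
}

#' @export
predict.scoring_function <- function(object, newdata, ...) sf_score(object, newdata)

#' Calibrate a score threshold at a target specificity
#'
#' Returns the smallest threshold `t` (the rule calls a case when score
#' `>= t`) such that the fraction of calibration control scores at or above
#' `t` does not exceed `1 - sp_target/100`. Ties among control scores push the
#' threshold upward, so the achieved specificity is always at or above the
#' target on the calibration controls; if no control score qualifies, the
#' threshold lands just above the largest control score (specificity 100%).
#'
#' @param scores_controls numeric control scores.
#' @param sp_target percent specificity in (0, 100).
#' @return the threshold.
#' @export
calibrate_threshold <- function(scores_controls, sp_target = 95) {
  if (!length(scores_controls)) stop("controls must be non-empty")
  if (sp_target <= 0 || sp_target >= 100) stop("sp_target must be in (0, 100)")
  n <- length(scores_controls)
  allowed <- floor(n * (1 - sp_target / 100))
  just_above <- function(v) v + max(abs(v), 1) * 1e-9
  if (allowed < 1) return(just_above(max(scores_controls)))
  d <- sort(scores_controls, decreasing = TRUE)
  v1 <- d[allowed]
  v2 <- if (allowed < n) d[allowed + 1] else -Inf
  if (v1 > v2) return(v1)
  above <- d[d > v1]
  if (length(above)) return(min(above))
  just_above(v1)
}

#' Metropolis-Monte-Carlo optimizer configuration
#'
#' Defaults are package conventions: the method's description leaves the
#' proposal, schedule and split geometry open.
#'
#' @param n_iterations Metropolis iterations per fit (default 2000).
#' @param proposal_sd SD of the Normal single-coefficient perturbation
#'   (default 0.25).
#' @param temperature initial temperature, in percentage points of
#'   sensitivity (default 1.0).
#' @param cooling geometric decay factor per iteration (default 0.995).
#' @param n_cv number of repeated random subsampling cross-validation splits
#'   (default 500); `0` selects a resubstitution objective (train = test).
#' @param cv_test_fraction held-out fraction per split (default 1/3).
#' @param sp_target percent specificity at which sensitivity is optimized
#'   (default 95).
#' @param seed integer seed governing splits and the Metropolis walk.
#' @return a `metropolis_config` list.
#' @export
metropolis_config <- function(n_iterations = 2000, proposal_sd = 0.25,
                              temperature = 1.0, cooling = 0.995,
                              n_cv = 500, cv_test_fraction = 1 / 3,
                              sp_target = 95, seed = 1L) {
  stopifnot(n_iterations >= 1, proposal_sd > 0, temperature > 0,
            cooling > 0, cooling <= 1, n_cv >= 0,
            cv_test_fraction > 0, cv_test_fraction < 1,
            sp_target > 0, sp_target < 100)
  structure(list(n_iterations = as.integer(n_iterations),
                 proposal_sd = proposal_sd, temperature = temperature,
                 cooling = cooling, n_cv = as.integer(n_cv),
                 cv_test_fraction = cv_test_fraction,
                 sp_target = sp_target, seed = as.integer(seed)),
            class = "metropolis_config")
}

#' Model matrix and labels for panel fitting (duplicates excluded)
#' @keywords internal
#' @noRd
prep_xy <- function(cohort, panel) {
  keep <- is.na(cohort$subjects$duplicate_of)
  sub <- cohort$subjects[keep, , drop = FALSE]
  co <- cohort
  co$subjects <- sub
  list(X = log_matrix(co, panel), is_case = sub$status == "case")
}

#' Stratified subsampling splits (0-based indices for the C++ core)
#' @keywords internal
#' @noRd
make_cv_splits <- function(is_case, n_cv, test_fraction) {
  case_idx <- which(is_case) - 1L
  ctrl_idx <- which(!is_case) - 1L
  if (length(case_idx) < 2 || length(ctrl_idx) < 2) {
    stop("need at least 2 cases and 2 controls")
  }
  if (n_cv == 0) {
    return(list(list(train_ctrl = ctrl_idx, test_case = case_idx,
                     test_ctrl = ctrl_idx)))
  }
  n_tc <- max(1L, round(length(case_idx) * test_fraction))
  n_tk <- max(1L, round(length(ctrl_idx) * test_fraction))
  n_tc <- min(n_tc, length(case_idx) - 1L)
  n_tk <- min(n_tk, length(ctrl_idx) - 1L)
  lapply(seq_len(n_cv), function(i) {
    tc <- sample(case_idx, n_tc)
    tk <- sample(ctrl_idx, n_tk)
    list(train_ctrl = setdiff(ctrl_idx, tk), test_case = tc, test_ctrl = tk)
  })
}

#' Cross-validated objective of a fixed weight vector
#'
#' Reference (pure R) evaluation of the optimizer's objective: mean held-out
#' sensitivity over the splits, thresholds re-calibrated on each split's
#' training controls at `sp_target`. Used as an independent oracle for the
#' optimized search and exported for grid-search comparisons.
#'
#' @param cohort an unblinded cohort.
#' @param panel marker subset.
#' @param weights one weight per panel marker.
#' @param cfg a [metropolis_config()] (`n_cv`, `cv_test_fraction`,
#'   `sp_target`, `seed` are used).
#' @return list with mean percent `sn` and `sp` over the splits.
#' @export
panel_objective <- function(cohort, panel, weights, cfg) {
  assert_unblinded(cohort, "panel_objective")
  d <- prep_xy(cohort, panel)
  with_seed(cfg$seed, {
    splits <- make_cv_splits(d$is_case, cfg$n_cv, cfg$cv_test_fraction)
    s <- as.vector(d$X %*% weights)
    sn <- sp <- numeric(length(splits))
    for (i in seq_along(splits)) {
      spl <- splits[[i]]
      t <- calibrate_threshold(s[spl$train_ctrl + 1L], cfg$sp_target)
      sn[i] <- mean(s[spl$test_case + 1L] >= t)
      sp[i] <- mean(s[spl$test_ctrl + 1L] < t)
    }
    list(sn = 100 * mean(sn), sp = 100 * mean(sp))
  })
}

#' Fit a scoring function by Metropolis-Monte-Carlo optimization
#'
#' Starting from unit weights, one coefficient at a time is perturbed by
#' `Normal(0, proposal_sd)`; the move is accepted when the cross-validated
#' sensitivity objective improves, and otherwise with probability
#' `exp(delta / temperature)` under a geometrically cooling temperature. The
#' best-seen weights are returned with the threshold calibrated on all
#' training controls at `sp_target`. Deterministic given `cfg$seed`.
#'
#' @param cohort an unblinded cohort (>= 2 cases and >= 2 controls).
#' @param panel marker subset from the registry.
#' @param cfg a [metropolis_config()].
#' @return a [scoring_function()] with attributes `cv_sn` (best objective,
#'   percent), `cv_sp` (mean held-out specificity at the optimum).
#' @export
fit_scoring_function <- function(cohort, panel, cfg = metropolis_config()) {
  assert_unblinded(cohort, "fit_scoring_function")
  d <- prep_xy(cohort, panel)
  with_seed(cfg$seed, {
    splits <- make_cv_splits(d$is_case, cfg$n_cv, cfg$cv_test_fraction)
    fit <- .mmc_fit_cpp(d$X, splits, which(!d$is_case) - 1L, cfg$sp_target,
                        cfg$n_iterations, cfg$proposal_sd, cfg$temperature,
                        cfg$cooling, rep(1, length(panel)))
    s <- as.vector(d$X %*% fit$weights)
    thr <- calibrate_threshold(s[!d$is_case], cfg$sp_target)
    sf <- scoring_function(panel, fit$weights, thr, cfg$sp_target)
    attr(sf, "cv_sn") <- fit$objective
    attr(sf, "cv_sp") <- fit$cv_sp
    sf
  })
}

#' Repeated random subsampling cross-validation of a panel
#'
#' For each of `cfg$n_cv` stratified splits the weights are refitted on the
#' training two-thirds (Metropolis with a resubstitution inner objective), the
#' threshold is calibrated on the training controls, and sensitivity and
#' specificity are recorded on the held-out third.
#'
#' @inheritParams fit_scoring_function
#' @return data.frame with one row per replicate: `rep, sn, sp` (percent).
#' @export
cross_validate <- function(cohort, panel, cfg = metropolis_config()) {
  assert_unblinded(cohort, "cross_validate")
  d <- prep_xy(cohort, panel)
  n_cv <- max(1L, cfg$n_cv)
  with_seed(cfg$seed, {
    splits <- make_cv_splits(d$is_case, n_cv, cfg$cv_test_fraction)
    out <- lapply(seq_along(splits), function(i) {
      spl <- splits[[i]]
      test <- c(spl$test_case, spl$test_ctrl) + 1L
      train <- setdiff(seq_len(nrow(d$X)), test)
      Xtr <- d$X[train, , drop = FALSE]
      ytr <- d$is_case[train]
      inner <- list(list(train_ctrl = which(!ytr) - 1L,
                         test_case = which(ytr) - 1L,
                         test_ctrl = which(!ytr) - 1L))
      fit <- .mmc_fit_cpp(Xtr, inner, which(!ytr) - 1L, cfg$sp_target,
                          cfg$n_iterations, cfg$proposal_sd, cfg$temperature,
                          cfg$cooling, rep(1, length(panel)))
      str <- as.vector(Xtr %*% fit$weights)
      thr <- calibrate_threshold(str[!ytr], cfg$sp_target)
      ste <- as.vector(d$X[test, , drop = FALSE] %*% fit$weights)
      yte <- d$is_case[test]
      data.frame(rep = i, sn = 100 * mean(ste[yte] >= thr),
                 sp = 100 * mean(ste[!yte] < thr))
    })
    do.call(rbind, out)
  })
}

#' Exhaustive panel search with MMC optimization
#'
#' Enumerates every marker combination of each requested size, fits each with
#' the Metropolis optimizer against the shared cross-validation splits, and
#' ranks panels by cross-validated sensitivity at the target specificity. One
#' split set is drawn per call and reused across all panels so that ranking
#' differences reflect the panels, not split noise.
#'
#' @param cohort an unblinded cohort.
#' @param sizes panel sizes to enumerate (default `2:4`).
#' @param cfg a [metropolis_config()].
#' @param markers candidate registry (default: the cohort's).
#' @return object of class `panel_search`: list with `results` (data.frame
#'   `size, panel, cv_sn, cv_sp` ranked by `cv_sn` within size) and `best`
#'   (per-size [scoring_function()], thresholds calibrated on all controls).
#' @export
search_panels <- function(cohort, sizes = 2:4, cfg = metropolis_config(),
                          markers = cohort$markers) {
  assert_unblinded(cohort, "search_panels")
  if (max(sizes) > length(markers)) stop("registry smaller than max panel size")
  d <- prep_xy(cohort, markers)
  with_seed(cfg$seed, {
    splits <- make_cv_splits(d$is_case, cfg$n_cv, cfg$cv_test_fraction)
    res_list <- list()
    best <- list()
    for (k in sizes) {
      panels <- combn(length(markers), k) - 1L  # 0-based columns
      sr <- .mmc_search_cpp(d$X, panels, splits, which(!d$is_case) - 1L,
                            cfg$sp_target, cfg$n_iterations, cfg$proposal_sd,
                            cfg$temperature, cfg$cooling)
      panel_names <- apply(panels + 1L, 2, function(j)
        paste(markers[j], collapse = "+"))
      df <- data.frame(size = k, panel = panel_names,
                       cv_sn = sr$objective, cv_sp = sr$cv_sp,
                       stringsAsFactors = FALSE)
      ord <- order(-df$cv_sn)
      df <- df[ord, ]
      rownames(df) <- NULL
      res_list[[as.character(k)]] <- df
      top <- ord[1]
      top_panel <- markers[panels[, top] + 1L]
      w <- sr$weights[, top]
      s <- as.vector(d$X[, panels[, top] + 1L, drop = FALSE] %*% w)
      thr <- calibrate_threshold(s[!d$is_case], cfg$sp_target)
      sf <- scoring_function(top_panel, w, thr, cfg$sp_target)
      attr(sf, "cv_sn") <- df$cv_sn[1]
      attr(sf, "cv_sp") <- df$cv_sp[1]
      best[[as.character(k)]] <- sf
    }
    structure(list(results = do.call(rbind, res_list), best = best,
                   sp_target = cfg$sp_target),
              class = "panel_search")
  })
}

#' @export
print.panel_search <- function(x, ...) {
  cat("Exhaustive panel search (SN at", x$sp_target, "% SP)\n")
  for (k in names(x$best)) {
    sf <- x$best[[k]]
    cat(sprintf("  best %s-panel: %s  (cv SN %.1f%%, cv SP %.1f%%)\n", k,
                paste(sf$markers, collapse = "+"),
                attr(sf, "cv_sn"), attr(sf, "cv_sp")))
  }
  invisible(x)
}

#' Performance of a scoring function on a cohort, by MTD stratum
#'
#' Resubstitution-style evaluation used for the stage reports: sensitivity per
#' months-to-diagnosis stratum (specificity is computed on all controls, which
#' carry no diagnosis date), plus the score AUC.
#'
#' @param sf a [scoring_function()].
#' @param cohort an unblinded cohort (duplicates excluded).
#' @param strata strata to report (default complete / near / far).
#' @return data.frame `stratum, n_cases, n_controls, sn, sp, auc`.
#' @export
panel_performance <- function(sf, cohort,
                              strata = c("complete", "mtd_1_12", "mtd_12_35")) {
  assert_unblinded(cohort, "panel_performance")
  s <- cohort$subjects[is.na(cohort$subjects$duplicate_of), ]
  co <- cohort
  co$subjects <- s
  sc <- sf_score(sf, co)$score
  is_case <- s$status == "case"
  sp <- 100 * mean(sc[!is_case] < sf$threshold)
  out <- lapply(strata, function(st) {
    in_st <- is_case & in_mtd_stratum(s$days_to_dx, st)
    data.frame(stratum = st, n_cases = sum(in_st), n_controls = sum(!is_case),
               sn = 100 * mean(sc[in_st] >= sf$threshold), sp = sp,
               auc = marker_auc(sc[in_st], sc[!is_case]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
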
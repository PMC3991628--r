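#' McNemar chi-squared for correlated proportions
#'
#' `chi2 = (b - c)^2 / (b + c)` with no continuity correction, where `b` and
#' `c` are the discordant counts between two classifiers on the same subjects
#' (e.g. cases called by A but not B, and vice versa). The 3.841 cutoff is the
#' 95th percentile of chi-squared with 1 df.
#'
#' @param b,c non-negative discordant counts.
#' @param cutoff significance cutoff on chi2 (default 3.841).
#' @return list with `chi2` and `significant`.
#' @export
mcnemar_chi2 <- function(b, c, cutoff = 3.841) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    warning("no discordant pairs; chi2 defined as 0")
    return(list(chi2 = 0, significant = FALSE))
  }
  chi2 <- (b - c)^2 / (b + c)
  list(chi2 = chi2, significant = chi2 > cutoff)
}

#' Compare the sensitivity of two scoring functions on the same cases
#'
#' Builds the paired case-side classification table (each classifier calls
#' cases at its own threshold) and applies [mcnemar_chi2()]. Sensitivity is a
#' case-side proportion, so only true cases enter the table.
#'
#' @param sf_a,sf_b [scoring_function()] objects.
#' @param cohort an unblinded cohort.
#' @param stratum months-to-diagnosis stratum for the case set.
#' @return list with `b` (A+ B-), `c` (A- B+), `chi2`, `significant`.
#' @export
compare_sensitivity <- function(sf_a, sf_b, cohort, stratum = "complete") {
  assert_unblinded(cohort, "compare_sensitivity")
  s <- cohort$subjects[is.na(cohort$subjects$duplicate_of), ]
  co <- cohort
  co$subjects <- s
  keep <- s$status == "case" & in_mtd_stratum(s$days_to_dx, stratum)
  call_a <- sf_score(sf_a, co)$call[keep] == "case"
  call_b <- sf_score(sf_b, co)$call[keep] == "case"
  b <- sum(call_a & !call_b)
  cc <- sum(!call_a & call_b)
  c(list(b = b, c = cc), mcnemar_chi2(b, cc))
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)] / (n1*n0)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc area under the ROC curve.
#' @param n_case,n_control class sizes.
#' @return the standard error.
#' @export
hanley_mcneil_se <- function(auc, n_case, n_control) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
          (n_control - 1) * (q2 - auc^2)) / (n_case * n_control))
}

#' Correlated AUC comparison (Hanley-McNeil Z ratio)
#'
#' Compares the AUCs of two score sets measured on the same subjects:
#' `z = (A_a - A_b) / sqrt(se_a^2 + se_b^2 - 2 r se_a se_b)` with the
#' Hanley-McNeil SE for each AUC. Unless supplied, `r` is estimated as the
#' mean of the Pearson correlations between the two score vectors within
#' cases and within controls and used directly (no lookup-table mapping);
#' callers with a different convention can pass their own `r`.
#'
#' @param scores_a,scores_b per-subject scores from the two classifiers.
#' @param is_case logical vector (`TRUE` for cases).
#' @param r optional correlation between the two score sets.
#' @param cutoff |z| cutoff for significance (default 2).
#' @return list with `auc_a, auc_b, se_a, se_b, r, z, significant`.
#' @export
hanley_mcneil_z <- function(scores_a, scores_b, is_case, r = NULL, cutoff = 2) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(is_case))
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  auc_a <- marker_auc(scores_a[is_case], scores_a[!is_case])
  auc_b <- marker_auc(scores_b[is_case], scores_b[!is_case])
  se_a <- hanley_mcneil_se(auc_a, n1, n0)
  se_b <- hanley_mcneil_se(auc_b, n1, n0)
  if (is.null(r)) {
    r_case <- suppressWarnings(cor(scores_a[is_case], scores_b[is_case]))
    r_ctrl <- suppressWarnings(cor(scores_a[!is_case], scores_b[!is_case]))
    r <- mean(c(r_case, r_ctrl), na.rm = TRUE)
    if (is.nan(r)) r <- 0
  }
  denom <- sqrt(max(se_a^2 + se_b^2 - 2 * r * se_a * se_b, 0))
  z <- if (denom == 0) 0 else (auc_a - auc_b) / denom
  list(auc_a = auc_a, auc_b = auc_b, se_a = se_a, se_b = se_b, r = r, z = z,
       significant = abs(z) >= cutoff)
}

#' Pearson correlation of markers with an anchor marker, in cases
#'
#' Correlations are computed on case samples only; p-values come from the t
#' transform with n-2 df (via [stats::cor.test()]).
#'
#' @param cohort an unblinded cohort.
#' @param anchor anchor marker name (e.g. the lead tumor marker).
#' @param markers markers to correlate (default: registry minus anchor).
#' @param log_scale correlate log concentrations instead of raw
#'   (default `FALSE`).
#' @return data.frame `marker, r, r_squared, p, significant` (p <= 0.05).
#' @export
pearson_to_anchor <- function(cohort, anchor, markers = NULL,
                              log_scale = FALSE) {
  assert_unblinded(cohort, "pearson_to_anchor")
  if (!anchor %in% cohort$markers) stop("anchor not in registry: ", anchor)
  if (is.null(markers)) markers <- setdiff(cohort$markers, anchor)
  s <- cohort$subjects[is.na(cohort$subjects$duplicate_of) &
                         cohort$subjects$status == "case", ]
  if (nrow(s) < 3) stop("fewer than 3 cases")
  tx <- if (log_scale) log else identity
  a <- tx(s[[anchor]])
  rows <- lapply(markers, function(m) {
    ct <- cor.test(a, tx(s[[m]]), method = "pearson")
    data.frame(marker = m, r = unname(ct$estimate),
               r_squared = unname(ct$estimate)^2, p = ct$p.value,
               significant = ct$p.value <= 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
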
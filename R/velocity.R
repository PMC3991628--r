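#' Regress a marker's level on time to diagnosis
#'
#' Ordinary least squares of concentration (or its log) on days to diagnosis
#' among cases. Larger regressor values are further from diagnosis, so a
#' marker that rises as diagnosis approaches has a negative slope.
#'
#' @param cohort an unblinded cohort.
#' @param marker marker name.
#' @param stratum case subset: `"complete"`, `"mtd_1_12"` or `"mtd_gt_12"`
#'   (draws 12+ months before diagnosis).
#' @param log_scale regress log concentration (default `FALSE`).
#' @return list of class `velocity_fit`: `marker, stratum, slope, intercept,
#'   slope_p, n` (slope in pg/ml per day, or log units per day).
#' @export
fit_velocity <- function(cohort, marker,
                         stratum = c("complete", "mtd_1_12", "mtd_gt_12"),
                         log_scale = FALSE) {
  stratum <- match.arg(stratum)
  assert_unblinded(cohort, "fit_velocity")
  if (!marker %in% cohort$markers) stop("marker not in registry: ", marker)
  s <- cohort$subjects[is.na(cohort$subjects$duplicate_of) &
                         cohort$subjects$status == "case", ]
  keep <- in_mtd_stratum(s$days_to_dx, stratum)
  s <- s[keep, ]
  if (nrow(s) < 3) stop("fewer than 3 cases in stratum ", stratum)
  x <- s$days_to_dx
  if (length(unique(x)) < 2) stop("degenerate predictor: all days equal")
  y <- if (log_scale) log(s[[marker]]) else s[[marker]]
  if (sd(y) == 0) {
    return(structure(list(marker = marker, stratum = stratum, slope = 0,
                          intercept = y[1], slope_p = 1, n = nrow(s)),
                     class = "velocity_fit"))
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  slope_p <- if (nrow(sm) < 2 || is.na(sm[2, 4])) 1 else sm[2, 4]
  structure(list(marker = marker, stratum = stratum,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_p = slope_p, n = nrow(s)),
            class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("velocity of %s (%s, n=%d): slope %.4g per day, p = %.4g\n",
              x$marker, x$stratum, x$n, x$slope, x$slope_p))
  invisible(x)
}

#' Screen markers for non-zero velocity against time to diagnosis
#'
#' Fits [fit_velocity()] for every marker in every requested stratum and flags
#' slopes with p <= `alpha`. No multiplicity correction is applied to this
#' screen. The summary also identifies markers significant only in the far
#' (`mtd_gt_12`) stratum, the pattern of interest for early, resectable
#' disease.
#'
#' @param cohort an unblinded cohort.
#' @param markers markers to fit (default: full registry).
#' @param strata strata to fit (default complete and beyond-12-months).
#' @param alpha significance level on the slope (default 0.05).
#' @param log_scale regress log concentration (default `FALSE`).
#' @return data.frame `marker, stratum, slope, slope_p, n, significant` with
#'   the far-only marker names in `attr(, "far_only")`.
#' @export
velocity_screen <- function(cohort, markers = cohort$markers,
                            strata = c("complete", "mtd_gt_12"),
                            alpha = 0.05, log_scale = FALSE) {
  rows <- lapply(markers, function(m) {
    do.call(rbind, lapply(strata, function(st) {
      f <- fit_velocity(cohort, m, st, log_scale)
      data.frame(marker = m, stratum = st, slope = f$slope,
                 slope_p = f$slope_p, n = f$n,
                 significant = f$slope_p <= alpha, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(c("complete", "mtd_gt_12") %in% strata)) {
    sig_far <- out$marker[out$stratum == "mtd_gt_12" & out$significant]
    sig_all <- out$marker[out$stratum == "complete" & out$significant]
    attr(out, "far_only") <- setdiff(sig_far, sig_all)
  }
  out
}
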
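#' Coefficient of variation of a duplicate pair
#'
#' `CV% = 100 * s / m` with `m = (x1 + x2)/2` and the pair sample SD
#' `s = |x1 - x2| / sqrt(2)`.
#'
#' @param x1,x2 positive concentrations of the two aliquots (vectorized).
#' @return CV in percent.
#' @export
pair_cv <- function(x1, x2) {
  if (any(x1 <= 0 | x2 <= 0)) stop("concentrations must be positive")
  100 * (abs(x1 - x2) / sqrt(2)) / ((x1 + x2) / 2)
}

#' Duplicate-sample reproducibility report
#'
#' Per-marker CV range and mean over all embedded duplicate pairs, and, when a
#' scoring function is supplied, the consistency of the case/control call
#' within each pair.
#'
#' @param cohort a cohort containing duplicate links.
#' @param sf optional [scoring_function()] for diagnosis-consistency checking.
#' @return list of class `duplicate_report`: `marker_cv` (data.frame
#'   `marker, cv_min, cv_max, cv_mean, n_pairs`) and `pair_consistency`
#'   (data.frame `subject_id, duplicate_id, score, dup_score, consistent`, or
#'   `NULL` without `sf`).
#' @export
duplicate_report <- function(cohort, sf = NULL) {
  s <- cohort$subjects
  dup <- s[!is.na(s$duplicate_of), , drop = FALSE]
  if (!nrow(dup)) {
    warning("cohort contains no duplicate samples")
    return(structure(list(marker_cv = data.frame(), pair_consistency = NULL),
                     class = "duplicate_report"))
  }
  src <- s[match(dup$duplicate_of, s$subject_id), , drop = FALSE]
  marker_cv <- do.call(rbind, lapply(cohort$markers, function(m) {
    cv <- pair_cv(src[[m]], dup[[m]])
    data.frame(marker = m, cv_min = min(cv), cv_max = max(cv),
               cv_mean = mean(cv), n_pairs = length(cv),
               stringsAsFactors = FALSE)
  }))
  pair_consistency <- NULL
  if (!is.null(sf)) {
    panel_scores <- function(rows) {
      as.vector(log(as.matrix(rows[, sf$markers, drop = FALSE])) %*%
                  sf$coefficients)
    }
    sc_src <- panel_scores(src)
    sc_dup <- panel_scores(dup)
    pair_consistency <- data.frame(
      subject_id = src$subject_id, duplicate_id = dup$subject_id,
      score = sc_src, dup_score = sc_dup,
      consistent = (sc_src >= sf$threshold) == (sc_dup >= sf$threshold),
      stringsAsFactors = FALSE)
  }
  structure(list(marker_cv = marker_cv, pair_consistency = pair_consistency),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  if (!nrow(x$marker_cv)) {
    cat("Duplicate report: no duplicate pairs\n")
    return(invisible(x))
  }
  cat(sprintf("Duplicate report: %d pairs, %d markers\n",
              x$marker_cv$n_pairs[1], nrow(x$marker_cv)))
  cat(sprintf("  mean CV across markers: %.1f%% (per-marker means %.1f%%-%.1f%%)\n",
              mean(x$marker_cv$cv_mean), min(x$marker_cv$cv_mean),
              max(x$marker_cv$cv_mean)))
  if (!is.null(x$pair_consistency)) {
    cat(sprintf("  consistent diagnoses: %d / %d pairs\n",
                sum(x$pair_consistency$consistent),
                nrow(x$pair_consistency)))
  }
  invisible(x)
}
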
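#' Adjudicate blinded diagnoses against the key table
#'
#' Plays the role of the trial administrators: compares submitted calls with
#' true status and reports sensitivity, specificity and (when scores are
#' submitted) AUC per months-to-diagnosis stratum. Nothing beyond these
#' quantities is returned to the analyst.
#'
#' @param submission data.frame `subject_id, call` (`"case"`/`"control"`),
#'   optionally `score`.
#' @param key the key table from [blind()].
#' @param strata strata to report (default complete / near / far).
#' @return data.frame `stratum, n_cases, n_controls, sn, sp, auc` (`auc` is
#'   `NA` without submitted scores).
#' @export
adjudicate <- function(submission, key,
                       strata = c("complete", "mtd_1_12", "mtd_12_35")) {
  i <- match(submission$subject_id, key$subject_id)
  if (anyNA(i)) {
    stop("submission contains id(s) not in the key: ",
         paste(utils::head(submission$subject_id[is.na(i)], 5), collapse = ", "))
  }
  truth <- key$status[i]
  days <- key$days_to_dx[i]
  called_case <- submission$call == "case"
  is_case <- truth == "case"
  has_score <- "score" %in% names(submission)
  sp <- 100 * mean(!called_case[!is_case])
  out <- lapply(strata, function(st) {
    in_st <- is_case & in_mtd_stratum(days, st)
    auc <- if (has_score && any(in_st)) {
      marker_auc(submission$score[in_st], submission$score[!is_case])
    } else NA_real_
    data.frame(stratum = st, n_cases = sum(in_st), n_controls = sum(!is_case),
               sn = 100 * mean(called_case[in_st]), sp = sp, auc = auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the five-step blinded training/validation protocol
#'
#' Step 1 trains panels on an external (retrospective-style) training cohort.
#' Step 2 scores the first, blinded half of the study cohort with the step-1
#' scoring functions and adjudicates the submitted diagnoses against the key.
#' Step 3 retrains on the unblinded first half over the full registry. Step 4
#' scores the second, blinded half. Step 5 retrains on the entire unblinded
#' study cohort. Blinded halves never expose case/control status to the
#' training code: fitting on a blinded cohort raises an error, and truth is
#' consulted only inside [adjudicate()].
#'
#' @param train_cohort unblinded external training cohort (step 1).
#' @param study_cohort unblinded study cohort to be split, blinded and
#'   validated on.
#' @param cfg a [metropolis_config()]; its seed also drives the half split.
#' @param sizes panel sizes searched at each training step (default `2:3`).
#' @param split_fraction fraction of match groups in the first half
#'   (default 0.5).
#' @param strata reporting strata.
#' @return list of class `mmc_protocol` with one element per step:
#'   `step`, `trained_sfs` (training steps), `submission` and `performance`.
#' @export
run_protocol <- function(train_cohort, study_cohort, cfg = metropolis_config(),
                         sizes = 2:3, split_fraction = 0.5,
                         strata = c("complete", "mtd_1_12", "mtd_12_35")) {
  assert_unblinded(train_cohort, "run_protocol")
  assert_unblinded(study_cohort, "run_protocol")
  steps <- list()

  s1 <- search_panels(train_cohort, sizes, cfg)
  steps$step1 <- list(step = 1L, trained_sfs = s1$best,
                      performance = lapply(s1$best, panel_performance,
                                           cohort = train_cohort,
                                           strata = strata))

  halves <- split_halves(study_cohort, seed = cfg$seed,
                         fraction = split_fraction)
  ba <- blind(halves$a)
  sub2 <- lapply(s1$best, sf_score, x = ba$cohort)
  steps$step2 <- list(step = 2L, submission = sub2,
                      performance = lapply(sub2, adjudicate, key = ba$key,
                                           strata = strata))

  half_a <- unblind(ba$cohort, ba$key)
  s3 <- search_panels(half_a, sizes, cfg)
  steps$step3 <- list(step = 3L, trained_sfs = s3$best,
                      performance = lapply(s3$best, panel_performance,
                                           cohort = half_a, strata = strata))

  bb <- blind(halves$b)
  sub4 <- lapply(s3$best, sf_score, x = bb$cohort)
  steps$step4 <- list(step = 4L, submission = sub4,
                      performance = lapply(sub4, adjudicate, key = bb$key,
                                           strata = strata))

  s5 <- search_panels(study_cohort, sizes, cfg)
  steps$step5 <- list(step = 5L, trained_sfs = s5$best,
                      performance = lapply(s5$best, panel_performance,
                                           cohort = study_cohort,
                                           strata = strata))
  structure(steps, class = "mmc_protocol")
}

#' @export
print.mmc_protocol <- function(x, ...) {
  cat("Five-step blinded training/validation protocol\n")
  for (st in x) {
    cat(sprintf("Step %d (%s):\n", st$step,
                if (!is.null(st$trained_sfs)) "training" else "blinded validation"))
    for (nm in names(st$performance)) {
      perf <- st$performance[[nm]]
      cmp <- perf[perf$stratum == "complete", ]
      cat(sprintf("  %s-panel: SN %.1f%% / SP %.1f%%%s (complete set)\n", nm,
                  cmp$sn, cmp$sp,
                  if (!is.na(cmp$auc)) sprintf(" / AUC %.3f", cmp$auc) else ""))
    }
  }
  invisible(x)
}

#' Flatten protocol performance into a stage-report table
#'
#' @param protocol an [run_protocol()] result.
#' @return data.frame `step, panel, stratum, n_cases, n_controls, sn, sp, auc`.
#' @export
protocol_report <- function(protocol) {
  rows <- lapply(protocol, function(st) {
    do.call(rbind, lapply(names(st$performance), function(nm) {
      cbind(step = st$step, panel = nm, st$performance[[nm]])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
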
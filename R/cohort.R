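#' @keywords internal
COHORT_META_COLS <- c("subject_id", "status", "age", "sex", "race",
                      "draw_date", "days_to_dx", "survival_cat",
                      "duplicate_of", "match_id")

#' Run code with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct a nested case-control cohort
#'
#' A cohort bundles one row per serum sample with the marker registry and the
#' case:control matching structure. Concentrations are stored one column per
#' marker, in pg/ml, and must be strictly positive (see
#' [floor_concentrations()] for limit-of-detection handling).
#'
#' @param subjects data.frame with columns `subject_id`, `status`
#'   (`"case"`, `"control"` or `"blinded"`), `age`, `sex` (`"female"`/`"male"`),
#'   `race`, `draw_date` (`Date` or ISO-8601 string), `days_to_dx`
#'   (non-negative days between draw and diagnosis; `NA` for controls),
#'   `survival_cat` (`"<6mo"`, `"6-24mo"`, `">24mo"` or `NA`),
#'   `duplicate_of` (source `subject_id` for embedded duplicate aliquots, `NA`
#'   otherwise), `match_id` (`NA` for duplicates), plus one numeric column per
#'   marker.
#' @param markers character vector naming the marker columns (the registry).
#' @param match_groups named list mapping each case `subject_id` to the
#'   character vector of its matched control ids. Derived from `match_id`
#'   when `NULL` and the cohort is unblinded.
#' @param validate validate invariants (default `TRUE`).
#' @return An object of class `mmc_cohort`.
#' @export
new_cohort <- function(subjects, markers, match_groups = NULL, validate = TRUE) {
  stopifnot(is.data.frame(subjects), is.character(markers))
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  for (col in COHORT_META_COLS) {
    if (!col %in% names(subjects)) {
      subjects[[col]] <- if (col %in% c("age", "days_to_dx")) NA_real_ else NA_character_
    }
  }
  missing_mk <- setdiff(markers, names(subjects))
  if (length(missing_mk)) {
    stop("marker column(s) absent from subjects table: ",
         paste(missing_mk, collapse = ", "))
  }
  subjects$draw_date <- as.Date(subjects$draw_date)
  subjects <- subjects[, c(COHORT_META_COLS, markers)]
  if (is.null(match_groups) && !all(is.na(subjects$match_id)) &&
      any(subjects$status == "case")) {
    match_groups <- derive_match_groups(subjects)
  }
  x <- structure(list(subjects = subjects,
                      markers = markers,
                      match_groups = match_groups),
                 class = "mmc_cohort")
  if (validate) validate_cohort(x)
  x
}

derive_match_groups <- function(subjects) {
  s <- subjects[!is.na(subjects$match_id) & is.na(subjects$duplicate_of), ]
  out <- list()
  for (g in unique(s$match_id)) {
    rows <- s[s$match_id == g, ]
    case_id <- rows$subject_id[rows$status == "case"]
    if (length(case_id) != 1) next
    out[[case_id]] <- rows$subject_id[rows$status == "control"]
  }
  out
}

#' Validate cohort invariants
#'
#' Checks status levels, positivity of concentrations, presence of
#' days-to-diagnosis for (unblinded) cases and its absence for controls,
#' duplicate linkage, and match-group structure. Violations are reported with
#' the offending row numbers.
#'
#' @param cohort an [new_cohort()] object.
#' @param control_ratio expected controls per case within a match group
#'   (default 4); groups of other sizes must carry `attr(cohort, "incomplete")`.
#' @return `cohort`, invisibly, or an error.
#' @export
validate_cohort <- function(cohort, control_ratio = NULL) {
  s <- cohort$subjects
  problems <- character()
  bad_status <- which(!s$status %in% c("case", "control", "blinded"))
  if (length(bad_status)) {
    problems <- c(problems, paste0("invalid status at row(s) ",
                                   paste(bad_status, collapse = ", ")))
  }
  if (anyDuplicated(s$subject_id)) {
    problems <- c(problems, "duplicated subject_id values")
  }
  blinded <- all(s$status == "blinded")
  if (!blinded) {
    miss_dx <- which(s$status == "case" & is.na(s$days_to_dx))
    if (length(miss_dx)) {
      problems <- c(problems, paste0("case without days_to_dx at row(s) ",
                                     paste(miss_dx, collapse = ", ")))
    }
    ctrl_dx <- which(s$status == "control" & !is.na(s$days_to_dx))
    if (length(ctrl_dx)) {
      problems <- c(problems, paste0("control with days_to_dx at row(s) ",
                                     paste(ctrl_dx, collapse = ", ")))
    }
  }
  for (m in cohort$markers) {
    v <- s[[m]]
    if (!is.numeric(v)) {
      problems <- c(problems, paste0("marker ", m, " is not numeric"))
    } else {
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad)) {
        problems <- c(problems,
                      paste0("non-positive concentration for ", m, " at row(s) ",
                             paste(bad, collapse = ", "),
                             " (apply floor_concentrations)"))
      }
    }
  }
  dup <- which(!is.na(s$duplicate_of))
  bad_dup <- dup[!s$duplicate_of[dup] %in% s$subject_id]
  if (length(bad_dup)) {
    problems <- c(problems, paste0("duplicate_of references unknown id at row(s) ",
                                   paste(bad_dup, collapse = ", ")))
  }
  if (!is.null(cohort$match_groups)) {
    ids <- s$subject_id
    all_members <- c(names(cohort$match_groups), unlist(cohort$match_groups))
    if (anyDuplicated(all_members)) {
      problems <- c(problems, "a subject appears in two match groups")
    }
    if (!all(all_members %in% ids)) {
      problems <- c(problems, "match group references unknown subject_id")
    }
    if (!is.null(control_ratio)) {
      sizes <- lengths(cohort$match_groups)
      if (!isTRUE(attr(cohort, "incomplete")) && any(sizes != control_ratio)) {
        problems <- c(problems, paste0("match group(s) without exactly ",
                                       control_ratio, " controls: ",
                                       paste(names(sizes)[sizes != control_ratio],
                                             collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("cohort validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.mmc_cohort <- function(x, ...) {
  s <- x$subjects
  n_dup <- sum(!is.na(s$duplicate_of))
  cat("Nested case-control cohort\n")
  cat(sprintf("  samples : %d (%d cases, %d controls, %d blinded; %d duplicate aliquots)\n",
              nrow(s), n_cases(x), n_controls(x),
              sum(s$status == "blinded"), n_dup))
  cat(sprintf("  markers : %d (%s%s)\n", length(x$markers),
              paste(utils::head(x$markers, 4), collapse = ", "),
              if (length(x$markers) > 4) ", ..." else ""))
  cat(sprintf("  match groups: %s\n",
              if (is.null(x$match_groups)) "none" else length(x$match_groups)))
  invisible(x)
}

#' Number of cases / controls in a cohort
#'
#' Duplicate QC aliquots are not counted: they are repeat measurements of an
#' existing subject, not additional subjects.
#'
#' @param cohort an [new_cohort()] object.
#' @return integer count.
#' @export
n_cases <- function(cohort) {
  sum(cohort$subjects$status == "case" & is.na(cohort$subjects$duplicate_of))
}

#' @rdname n_cases
#' @export
n_controls <- function(cohort) {
  sum(cohort$subjects$status == "control" & is.na(cohort$subjects$duplicate_of))
}

#' Replace non-positive or sub-LOD concentrations
#'
#' The scoring function takes logarithms of concentrations, so values at or
#' below zero (or below an assay limit of detection) are replaced by LOD/2.
#' By default the LOD for each marker is the smallest positive value observed
#' for that marker in the cohort.
#'
#' @param cohort an [new_cohort()] object (not yet validated for positivity).
#' @param lod optional named numeric vector of per-marker limits of detection.
#' @return the cohort with floored concentrations; the number of replaced
#'   values per marker is attached as `attr(, "floored")`.
#' @export
floor_concentrations <- function(cohort, lod = NULL) {
  s <- cohort$subjects
  floored <- integer(0)
  for (m in cohort$markers) {
    v <- s[[m]]
    lim <- if (!is.null(lod) && m %in% names(lod)) lod[[m]] else {
      pos <- v[!is.na(v) & v > 0]
      if (!length(pos)) stop("no positive values for marker ", m)
      min(pos)
    }
    bad <- !is.na(v) & v < lim
    bad[!is.na(v) & v <= 0] <- TRUE
    if (any(bad)) {
      v[bad] <- lim / 2
      floored[m] <- sum(bad)
      s[[m]] <- v
    }
  }
  cohort$subjects <- s
  attr(cohort, "floored") <- floored
  cohort
}

#' Read a cohort from CSV
#'
#' Expects the dialect written by [write_cohort()]: comma-separated, UTF-8,
#' header row, one row per sample, columns `subject_id, status, age, sex,
#' race, draw_date, days_to_dx, survival_cat, duplicate_of, match_id` followed
#' by one numeric column per marker (pg/ml). Duplicate aliquots are separate
#' rows linked through `duplicate_of`.
#'
#' @param path CSV file path.
#' @param markers marker column names; default: every column after the
#'   metadata block.
#' @param floor apply [floor_concentrations()] to non-positive values
#'   (default `TRUE`).
#' @param lod optional per-marker limits of detection passed through.
#' @return an [new_cohort()] object.
#' @export
read_cohort <- function(path, markers = NULL, floor = TRUE, lod = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
  need <- setdiff(COHORT_META_COLS, names(raw))
  if (length(need)) {
    stop("schema error: missing column(s) ", paste(need, collapse = ", "))
  }
  if (is.null(markers)) markers <- setdiff(names(raw), COHORT_META_COLS)
  for (m in markers) {
    if (!is.numeric(raw[[m]])) {
      v <- suppressWarnings(as.numeric(raw[[m]]))
      if (anyNA(v) && !anyNA(raw[[m]])) {
        stop("marker column ", m, " is not parseable as numeric")
      }
      raw[[m]] <- v
    }
  }
  raw$duplicate_of[raw$duplicate_of %in% ""] <- NA_character_
  raw$match_id[raw$match_id %in% ""] <- NA_character_
  raw$survival_cat[raw$survival_cat %in% ""] <- NA_character_
  co <- new_cohort(raw, markers, validate = FALSE)
  if (floor) co <- floor_concentrations(co, lod = lod)
  validate_cohort(co)
  co
}

#' Write a cohort to CSV
#'
#' @param cohort an [new_cohort()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  s <- cohort$subjects
  s$draw_date <- format(s$draw_date, "%Y-%m-%d")
  write.csv(s, path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a cohort into two halves by match group
#'
#' Match groups travel whole, so no control is separated from its case; the
#' blinded-half training/validation protocol operates on the two returned
#' cohorts. Duplicate aliquots follow their source sample.
#'
#' @param cohort an unblinded cohort with populated match groups.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param fraction fraction of match groups assigned to the first half
#'   (default 0.5; blinded designs often use uneven halves such as a 56/79
#'   case split, hence the configurable fraction).
#' @return list with cohorts `a` and `b` partitioning the subjects.
#' @export
split_halves <- function(cohort, seed, fraction = 0.5) {
  if (nrow(cohort$subjects) == 0) stop("empty cohort")
  if (is.null(cohort$match_groups) || !length(cohort$match_groups)) {
    stop("match_groups must be populated")
  }
  gids <- names(cohort$match_groups)
  n_a <- round(length(gids) * fraction)
  n_a <- max(1L, min(length(gids) - 1L, n_a))
  pick <- with_seed(seed, sample(gids, n_a))
  take <- function(ids_a) {
    member <- cohort$subjects$match_id %in% ids_a
    # duplicates carry NA match_id; follow the source sample
    dup <- !is.na(cohort$subjects$duplicate_of)
    src_in <- cohort$subjects$duplicate_of %in%
      cohort$subjects$subject_id[member]
    member[dup] <- src_in[dup]
    subj <- cohort$subjects[member, , drop = FALSE]
    rownames(subj) <- NULL
    new_cohort(subj, cohort$markers,
               match_groups = cohort$match_groups[intersect(names(cohort$match_groups),
                                                            subj$subject_id)])
  }
  gid_of_case <- function(case_ids) {
    cohort$subjects$match_id[match(case_ids, cohort$subjects$subject_id)]
  }
  a_groups <- gid_of_case(pick)
  b_groups <- setdiff(unique(cohort$subjects$match_id[!is.na(cohort$subjects$match_id)]),
                      a_groups)
  list(a = take(a_groups), b = take(b_groups))
}

#' Blind a cohort
#'
#' Removes case/control status, days to diagnosis, survival category and the
#' match-group structure (which would identify the case within each group),
#' returning the blinded cohort plus a key table that restores the original
#' exactly via [unblind()].
#'
#' @param cohort an unblinded cohort.
#' @return list with elements `cohort` (blinded) and `key` (data.frame
#'   `subject_id, status, days_to_dx, survival_cat` with the match groups
#'   stashed as an attribute).
#' @export
blind <- function(cohort) {
  s <- cohort$subjects
  key <- data.frame(subject_id = s$subject_id,
                    status = s$status,
                    days_to_dx = s$days_to_dx,
                    survival_cat = s$survival_cat,
                    match_id = s$match_id,
                    stringsAsFactors = FALSE)
  attr(key, "match_groups") <- cohort$match_groups
  s$status <- "blinded"
  s$days_to_dx <- NA_real_
  s$survival_cat <- NA_character_
  s$match_id <- NA_character_
  cohort$subjects <- s
  cohort$match_groups <- NULL
  list(cohort = cohort, key = key)
}

#' Unblind a cohort using its key table
#'
#' @param cohort a blinded cohort from [blind()].
#' @param key the matching key table.
#' @return the restored unblinded cohort.
#' @export
unblind <- function(cohort, key) {
  s <- cohort$subjects
  i <- match(s$subject_id, key$subject_id)
  if (anyNA(i)) stop("key table does not cover all subjects")
  s$status <- key$status[i]
  s$days_to_dx <- key$days_to_dx[i]
  s$survival_cat <- key$survival_cat[i]
  s$match_id <- key$match_id[i]
  cohort$subjects <- s
  cohort$match_groups <- attr(key, "match_groups")
  validate_cohort(cohort)
  cohort
}

#' Stop unless a cohort is unblinded
#' @keywords internal
#' @noRd
assert_unblinded <- function(cohort, what = "this operation") {
  if (any(cohort$subjects$status == "blinded")) {
    stop(what, " requires an unblinded cohort; blinded samples present. ",
         "Unblind with the key table after adjudication.", call. = FALSE)
  }
  invisible(cohort)
}

#' Months-to-diagnosis strata
#'
#' MTD = floor(days_to_dx / 30.44). The near stratum (`mtd_1_12`) covers draws
#' taken under 365 days before diagnosis; the far stratum (`mtd_12_35`,
#' equivalently `mtd_gt_12`) covers 365 to 1064 days; `complete` is their
#' union.
#'
#' @param days_to_dx numeric vector of days between draw and diagnosis.
#' @param stratum one of `"complete"`, `"mtd_1_12"`, `"mtd_12_35"`,
#'   `"mtd_gt_12"`.
#' @return logical vector: membership in the stratum (`FALSE` for `NA` days).
#' @export
in_mtd_stratum <- function(days_to_dx, stratum = c("complete", "mtd_1_12",
                                                   "mtd_12_35", "mtd_gt_12")) {
  stratum <- match.arg(stratum)
  d <- days_to_dx
  ok <- !is.na(d)
  switch(stratum,
         complete = ok & d < 1065,
         mtd_1_12 = ok & d < 365,
         mtd_12_35 = ok & d >= 365 & d < 1065,
         mtd_gt_12 = ok & d >= 365 & d < 1065)
}

#' Months to diagnosis from days
#' @param days_to_dx numeric vector of days.
#' @return integer months, `floor(days / 30.44)`.
#' @export
months_to_dx <- function(days_to_dx) floor(days_to_dx / 30.44)

#' Extract the log-concentration matrix for a marker panel
#' @keywords internal
#' @noRd
log_matrix <- function(cohort, panel) {
  missing_mk <- setdiff(panel, cohort$markers)
  if (length(missing_mk)) {
    stop("marker(s) not in registry: ", paste(missing_mk, collapse = ", "))
  }
  m <- as.matrix(cohort$subjects[, panel, drop = FALSE])
  if (any(m <= 0, na.rm = TRUE)) {
    stop("non-positive concentrations; apply floor_concentrations() first")
  }
  log(m)
}
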
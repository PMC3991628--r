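#' Describe one simulated serum marker
#'
#' Markers are log-normal: `log(conc) ~ Normal(log_mean_control, log_sd)` in
#' controls. Cases add `case_log_shift` (negative for markers depressed in
#' cases, prolactin-like) plus `velocity_slope * (days_to_dx - centre)` so
#' that markers rising before diagnosis have negative slopes against
#' days-to-diagnosis. `corr_with_anchor` imposes a Pearson correlation of the
#' log level with the anchor marker's noise through a shared latent factor.
#'
#' @param name marker name.
#' @param log_mean_control mean of log concentration (log pg/ml) in controls.
#' @param log_sd standard deviation of log concentration (> 0).
#' @param case_log_shift additive case effect, log units (default 0).
#' @param velocity_slope log-units per day of days-to-diagnosis (default 0).
#' @param corr_with_anchor correlation in \[-1, 1\] with the anchor marker's
#'   latent noise (default 0).
#' @return a `marker_spec` list.
#' @export
marker_spec <- function(name, log_mean_control, log_sd,
                        case_log_shift = 0, velocity_slope = 0,
                        corr_with_anchor = 0) {
  stopifnot(log_sd > 0, abs(corr_with_anchor) <= 1)
  structure(list(name = name, log_mean_control = log_mean_control,
                 log_sd = log_sd, case_log_shift = case_log_shift,
                 velocity_slope = velocity_slope,
                 corr_with_anchor = corr_with_anchor),
            class = "marker_spec")
}

#' Default 67-marker specification set
#'
#' Eight named informative markers (seven elevated in cases, prolactin
#' depressed) with case shifts calibrated so their single-marker AUCs fall in
#' the 0.52-0.66 band typical of prediagnostic serum markers, six of them with
#' a negative level-versus-time-to-diagnosis slope, CEA and CA 125 correlated
#' with the CA 19-9 anchor, AGRP carrying a velocity trend without a level
#' shift, and null filler markers to a registry of `n_markers`.
#'
#' @param n_markers registry size (default 67).
#' @return list of [marker_spec()] objects.
#' @export
default_marker_specs <- function(n_markers = 67) {
  shift_for_auc <- function(auc, sd) sqrt(2) * qnorm(auc) * sd
  vel <- -1.5e-3
  named <- list(
    marker_spec("CA_19_9",  2.5, 1.4, shift_for_auc(0.656, 1.4), vel, 0),
    marker_spec("CEA",      7.5, 1.2, shift_for_auc(0.525, 1.2), vel, 0.83),
    marker_spec("CA_125",   3.0, 1.1, shift_for_auc(0.574, 1.1), vel, 0.73),
    marker_spec("NSE",      8.2, 0.9, shift_for_auc(0.577, 0.9), 0, 0),
    marker_spec("IL_8",     1.9, 0.7, shift_for_auc(0.596, 0.7), vel, 0),
    marker_spec("bHCG",    -0.9, 0.6, shift_for_auc(0.579, 0.6), 0, 0),
    marker_spec("CEACAM1",  7.0, 0.5, shift_for_auc(0.535, 0.5), 0, 0),
    marker_spec("prolactin", 10.5, 0.9, -shift_for_auc(0.570, 0.9), vel, 0),
    marker_spec("AGRP",     4.6, 0.8, 0, vel, 0)
  )
  n_fill <- n_markers - length(named)
  if (n_fill < 0) return(named[seq_len(n_markers)])
  fill <- lapply(seq_len(n_fill), function(i) {
    marker_spec(sprintf("marker_%02d", i + length(named)),
                log_mean_control = 2 + (i %% 7),
                log_sd = 0.6 + 0.1 * (i %% 8))
  })
  c(named, fill)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_cases number of cases (default 135).
#' @param control_ratio matched controls per case (default 4).
#' @param marker_specs list of [marker_spec()]; default [default_marker_specs()].
#' @param anchor name of the anchor marker for `corr_with_anchor`
#'   (default `"CA_19_9"`).
#' @param n_duplicates_case,n_duplicates_control embedded duplicate aliquots
#'   (defaults 7 and 10).
#' @param assay_cv_range percent interval for per-marker assay CV targets
#'   (default `c(1.0, 7.8)`).
#' @param days_range half-open range of days-to-diagnosis sampled uniformly
#'   (default `c(30, 1065)`).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_cases = 135, control_ratio = 4,
                             marker_specs = default_marker_specs(),
                             anchor = "CA_19_9",
                             n_duplicates_case = 7, n_duplicates_control = 10,
                             assay_cv_range = c(1.0, 7.8),
                             days_range = c(30, 1065),
                             seed = 1L) {
  stopifnot(n_cases >= 1, control_ratio >= 1,
            all(assay_cv_range >= 0), all(assay_cv_range <= 100),
            assay_cv_range[1] <= assay_cv_range[2],
            days_range[1] >= 0, days_range[2] > days_range[1])
  structure(list(n_cases = as.integer(n_cases),
                 control_ratio = as.integer(control_ratio),
                 marker_specs = marker_specs, anchor = anchor,
                 n_duplicates_case = as.integer(n_duplicates_case),
                 n_duplicates_control = as.integer(n_duplicates_control),
                 assay_cv_range = assay_cv_range,
                 days_range = days_range, seed = as.integer(seed)),
            class = "generator_config")
}

#' Read / write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return [generator_config()] object ([read_generator_config()]); `path`
#'   invisibly ([write_generator_config()]).
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y$marker_specs, function(s) do.call(marker_spec, s))
  generator_config(n_cases = y$n_cases %||% 135,
                   control_ratio = y$control_ratio %||% 4,
                   marker_specs = if (length(specs)) specs else default_marker_specs(),
                   anchor = y$anchor %||% "CA_19_9",
                   n_duplicates_case = y$n_duplicates_case %||% 7,
                   n_duplicates_control = y$n_duplicates_control %||% 10,
                   assay_cv_range = unlist(y$assay_cv_range) %||% c(1.0, 7.8),
                   days_range = unlist(y$days_range) %||% c(30, 1065),
                   seed = y$seed %||% 1L)
}

#' @rdname read_generator_config
#' @param config a [generator_config()] object.
#' @export
write_generator_config <- function(config, path) {
  y <- unclass(config)
  y$marker_specs <- lapply(y$marker_specs, unclass)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a matched nested case-control cohort
#'
#' Draws `n_cases` cases, each with `control_ratio` controls agreeing on sex,
#' race, age within 5 years, and calendar 2-month draw-date block (blocks
#' anchored at January 1). Case days-to-diagnosis are uniform on
#' `days_range`. Log concentrations follow the [marker_spec()] model with the
#' anchor-correlation structure imposed through a shared latent Gaussian
#' factor. The returned ground truth records the per-marker shifts, slopes and
#' correlations plus each sample's latent (noise-free) concentrations, for
#' parameter-recovery testing.
#'
#' @param config a [generator_config()].
#' @return list with elements `cohort` ([new_cohort()]) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  specs <- config$marker_specs
  markers <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(markers)) stop("duplicate marker names in specs")
  rho <- vapply(specs, `[[`, 0, "corr_with_anchor")
  a_idx <- match(config$anchor, markers)
  if (any(rho != 0) && is.na(a_idx)) {
    stop("anchor marker ", config$anchor, " not in specs")
  }
  with_seed(config$seed, {
    nc <- config$n_cases
    r <- config$control_ratio
    n <- nc * (r + 1)

    case_age <- sample(55:74, nc, replace = TRUE)
    case_sex <- sample(c("male", "female"), nc, replace = TRUE,
                       prob = c(0.58, 0.42))
    case_race <- sample(c("white", "black", "asian", "hispanic", "other"),
                        nc, replace = TRUE,
                        prob = c(0.89, 0.05, 0.03, 0.02, 0.01))
    draw_year <- sample(1994:2001, nc, replace = TRUE)
    draw_block <- sample(0:5, nc, replace = TRUE)  # 2-month blocks from Jan 1
    rand_date_in_block <- function(year, block, m) {
      start <- as.Date(sprintf("%d-%02d-01", year, 2 * block + 1))
      end <- as.Date(ifelse(block == 5, sprintf("%d-01-01", year + 1),
                            sprintf("%d-%02d-01", year, 2 * block + 3)))
      start + floor(runif(m) * as.integer(end - start))
    }
    case_date <- rand_date_in_block(draw_year, draw_block, nc)
    days_dx <- floor(runif(nc, config$days_range[1], config$days_range[2]))
    surv <- sample(c("<6mo", "6-24mo", ">24mo"), nc, replace = TRUE,
                   prob = c(0.48, 0.37, 0.15))

    id <- sprintf("S%05d", seq_len(n))
    gid <- sprintf("G%04d", seq_len(nc))
    case_rows <- data.frame(subject_id = id[seq_len(nc)], status = "case",
                            age = case_age, sex = case_sex, race = case_race,
                            draw_date = case_date, days_to_dx = days_dx,
                            survival_cat = surv,
                            duplicate_of = NA_character_, match_id = gid,
                            stringsAsFactors = FALSE)
    ctrl_idx <- rep(seq_len(nc), each = r)
    ctrl_age <- vapply(ctrl_idx, function(i) {
      lo <- max(55L, case_age[i] - 5L); hi <- min(74L, case_age[i] + 5L)
      sample(seq(lo, hi), 1L)
    }, 0L)
    ctrl_rows <- data.frame(subject_id = id[nc + seq_len(nc * r)],
                            status = "control", age = ctrl_age,
                            sex = case_sex[ctrl_idx], race = case_race[ctrl_idx],
                            draw_date = rand_date_in_block(draw_year[ctrl_idx],
                                                           draw_block[ctrl_idx],
                                                           nc * r),
                            days_to_dx = NA_real_,
                            survival_cat = NA_character_,
                            duplicate_of = NA_character_,
                            match_id = gid[ctrl_idx],
                            stringsAsFactors = FALSE)
    subjects <- rbind(case_rows, ctrl_rows)

    is_case <- subjects$status == "case"
    days_c <- ifelse(is_case, subjects$days_to_dx, 0)
    centre <- mean(config$days_range)
    z <- matrix(rnorm(n * length(specs)), n, length(specs))
    conc <- matrix(NA_real_, n, length(specs),
                   dimnames = list(NULL, markers))
    latent <- conc
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      noise <- if (rho[j] != 0 && j != a_idx) {
        rho[j] * z[, a_idx] + sqrt(1 - rho[j]^2) * z[, j]
      } else {
        z[, j]
      }
      mu <- sp$log_mean_control + is_case * sp$case_log_shift +
        is_case * sp$velocity_slope * (days_c - centre)
      latent[, j] <- exp(mu)
      conc[, j] <- exp(mu + sp$log_sd * noise)
    }
    subjects <- cbind(subjects, as.data.frame(conc))
    mg <- split(ctrl_rows$subject_id, ctrl_idx)
    names(mg) <- case_rows$subject_id
    cohort <- new_cohort(subjects, markers, match_groups = mg)
    truth <- list(markers = markers,
                  case_log_shift = vapply(specs, `[[`, 0, "case_log_shift"),
                  velocity_slope = vapply(specs, `[[`, 0, "velocity_slope"),
                  corr_with_anchor = rho,
                  anchor = config$anchor,
                  latent = latent)
    list(cohort = cohort, truth = truth)
  })
}

#' Embed duplicate QC aliquots into a cohort
#'
#' Adds duplicate rows for randomly chosen cases and controls. The duplicate's
#' concentrations are the source sample's values perturbed multiplicatively by
#' `exp(Normal(0, sigma_m))`, with `sigma_m` calibrated so the expected
#' duplicate-pair CV equals a per-marker target drawn uniformly from
#' `assay_cv_range` (so with the zero interval the duplicates are exact
#' copies). Duplicates share the source's covariates and are linked through
#' `duplicate_of`; they belong to no match group.
#'
#' @param cohort an [new_cohort()] object.
#' @param config a [generator_config()] (duplicate counts, CV range).
#' @param seed integer seed (default `config$seed + 1`).
#' @return the cohort with duplicate rows appended; per-marker CV targets are
#'   attached as `attr(, "cv_targets")`.
#' @export
inject_duplicates <- function(cohort, config, seed = config$seed + 1L) {
  s <- cohort$subjects
  cases <- s$subject_id[s$status == "case" & is.na(s$duplicate_of)]
  ctrls <- s$subject_id[s$status == "control" & is.na(s$duplicate_of)]
  if (length(cases) < config$n_duplicates_case ||
      length(ctrls) < config$n_duplicates_control) {
    stop("insufficient subjects for requested duplicate counts")
  }
  with_seed(seed, {
    pick <- c(sample(cases, config$n_duplicates_case),
              sample(ctrls, config$n_duplicates_control))
    cv_target <- runif(length(cohort$markers),
                       config$assay_cv_range[1], config$assay_cv_range[2])
    names(cv_target) <- cohort$markers
    sigma <- cv_target * sqrt(pi) / 100  # E[pair CV%] = 100*sigma/sqrt(pi)
    src <- s[match(pick, s$subject_id), , drop = FALSE]
    dup <- src
    dup$subject_id <- paste0(src$subject_id, "_dup")
    dup$duplicate_of <- src$subject_id
    dup$match_id <- NA_character_
    for (k in seq_along(cohort$markers)) {
      m <- cohort$markers[k]
      dup[[m]] <- src[[m]] * exp(rnorm(nrow(dup), 0, sigma[k]))
    }
    rownames(dup) <- NULL
    cohort$subjects <- rbind(s, dup)
    attr(cohort, "cv_targets") <- cv_target
    validate_cohort(cohort)
    cohort
  })
}

#' Generate a cohort with embedded duplicates
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [inject_duplicates()].
#'
#' @inheritParams generate_cohort
#' @return list with elements `cohort` and `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- generate_cohort(config)
  g$cohort <- inject_duplicates(g$cohort, config)
  g
}

#' Write generator ground truth as JSON
#'
#' Stores the per-marker true shifts, slopes and anchor correlations (the
#' latent concentration matrix is omitted for size).
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth[c("markers", "case_log_shift", "velocity_slope",
                 "corr_with_anchor", "anchor")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
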
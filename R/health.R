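#' Score larval health observations
#'
#' The larval health index sums four observed categories: activity
#' (0 = none ... 3 = active without stimulation), cocoon formation
#' (0 = none, 0.5 = partial, 1 = full), melanisation (0 = complete
#' melanisation ... 4 = none) and survival (0 = dead, 2 = alive). A fully
#' healthy larva scores 10, the rubric minimum is 0. Category values are
#' validated against their enumerated levels; dead larvae may carry any
#' values in the other categories (the rubric does not couple them).
#'
#' @param activity,cocoon,melanisation,survival Category values (vectors are
#'   recycled to a common length).
#' @return Numeric score(s) in \[0, 10\].
#' @export
score_observation <- function(activity, cocoon, melanisation, survival) {
  n <- max(length(activity), length(cocoon), length(melanisation), length(survival))
  activity <- rep_len(activity, n)
  cocoon <- rep_len(cocoon, n)
  melanisation <- rep_len(melanisation, n)
  survival <- rep_len(survival, n)
  check_levels <- function(x, levels, what) {
    bad <- !x %in% levels
    if (any(bad)) {
      stop(sprintf("invalid %s value %s (allowed: %s)", what,
                   x[bad][1], paste(levels, collapse = ", ")), call. = FALSE)
    }
  }
  check_levels(activity, 0:3, "activity")
  check_levels(cocoon, c(0, 0.5, 1), "cocoon")
  check_levels(melanisation, 0:4, "melanisation")
  check_levels(survival, c(0, 2), "survival")
  activity + cocoon + melanisation + survival
}

#' @rdname score_observation
#' @param obs A health-observation table with the four category columns.
#' @return `score_health()` returns `obs` with a `score` column appended.
#' @export
score_health <- function(obs) {
  obs$score <- score_observation(obs$activity, obs$cocoon,
                                 obs$melanisation, obs$survival)
  tibble::as_tibble(obs)
}

#' Aggregate health scores per group and time
#'
#' Observer scores are combined by arithmetic mean per larva; group
#' summaries are the mean and sample SD of these per-larva scores. Observer
#' concordance is the mean absolute difference between the two observers'
#' scores for the same larva (NA when a single observer scored the cell);
#' any larva whose observers disagree by more than `flag_threshold` points
#' raises a warning.
#'
#' @param obs A health-observation table (columns `larva_id`, `group`,
#'   `time_h`, `observer_id` and the four categories).
#' @param flag_threshold Discordance (points) beyond which a warning is
#'   emitted (default 2).
#' @return A tibble with one row per group x time: `n_larvae`, `mean_score`,
#'   `sd_score`, `observer_mad`, `max_disagreement`.
#' @export
aggregate_health <- function(obs, flag_threshold = 2) {
  obs <- score_health(obs)
  per_larva <- obs |>
    dplyr::group_by(.data$group, .data$time_h, .data$larva_id) |>
    dplyr::summarise(
      larva_score = mean(.data$score),
      disagreement = if (dplyr::n() >= 2) max(.data$score) - min(.data$score) else NA_real_,
      .groups = "drop"
    )
  n_flagged <- sum(per_larva$disagreement > flag_threshold, na.rm = TRUE)
  if (n_flagged > 0) {
    warning(sprintf("%d larva-time cell(s) with observer disagreement > %g points",
                    n_flagged, flag_threshold), call. = FALSE)
  }
  per_larva |>
    dplyr::group_by(.data$group, .data$time_h) |>
    dplyr::summarise(
      n_larvae = dplyr::n(),
      mean_score = mean(.data$larva_score),
      sd_score = stats::sd(.data$larva_score),
      observer_mad = if (all(is.na(.data$disagreement))) NA_real_
                     else mean(abs(.data$disagreement), na.rm = TRUE),
      max_disagreement = if (all(is.na(.data$disagreement))) NA_real_
                         else max(.data$disagreement, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Survival proportion per group and time
#'
#' A larva counts as alive at a time point when any observer recorded
#' survival = 2 there (observer disagreement on survival is warned about).
#' If a larva appears to return from the dead across consecutive times a
#' warning is raised; the recorded values are reported unchanged.
#'
#' @param obs A health-observation table.
#' @return A tibble per group x time: `n_larvae`, `n_alive`,
#'   `survival_fraction` in \[0, 1\].
#' @export
survival_fraction <- function(obs) {
  if (!"survival" %in% names(obs)) stop("survival column required", call. = FALSE)
  per_larva <- obs |>
    dplyr::group_by(.data$group, .data$time_h, .data$larva_id) |>
    dplyr::summarise(
      alive = any(.data$survival == 2),
      disagree = length(unique(.data$survival)) > 1,
      .groups = "drop"
    )
  if (any(per_larva$disagree)) {
    warning(sprintf("%d larva-time cell(s) with observers disagreeing on survival",
                    sum(per_larva$disagree)), call. = FALSE)
  }
  resurrect <- per_larva |>
    dplyr::arrange(.data$time_h) |>
    dplyr::group_by(.data$group, .data$larva_id) |>
    dplyr::summarise(res = any(diff(as.integer(.data$alive)) > 0), .groups = "drop")
  if (any(resurrect$res)) {
    warning(sprintf("%d larva(e) recorded dead then alive at a later time",
                    sum(resurrect$res)), call. = FALSE)
  }
  per_larva |>
    dplyr::group_by(.data$group, .data$time_h) |>
    dplyr::summarise(
      n_larvae = dplyr::n(),
      n_alive = sum(.data$alive),
      survival_fraction = mean(.data$alive),
      .groups = "drop"
    )
}
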
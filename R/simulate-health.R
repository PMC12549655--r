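#' Category distributions for simulated larval health observations
#'
#' A health profile fixes, for one experimental group, the sampling
#' distribution of each scored category of the larval health index and the
#' per-interval survival probability. Category levels follow the scoring
#' rubric: activity 0/1/2/3, cocoon formation 0/0.5/1, melanisation 0--4
#' (4 = no melanisation), survival 0 (dead) / 2 (alive).
#'
#' @param activity Probability vector over activity levels 0..3.
#' @param cocoon Probability vector over cocoon levels 0, 0.5, 1.
#' @param melanisation Probability vector over melanisation levels 0..4.
#' @param p_survive Probability a larva alive at the previous observation is
#'   still alive at the next one (survival is generated as a monotone
#'   per-larva process, so cohort survival never increases over time).
#'
#' @return An object of class `health_profile`.
#' @export
health_profile <- function(activity = c(0, 0, 0.2, 0.8),
                           cocoon = c(0.1, 0.2, 0.7),
                           melanisation = c(0, 0, 0, 0.2, 0.8),
                           p_survive = 1) {
  check_probs <- function(p, k, what) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("%s must be %d non-negative probabilities summing to 1",
                   what, k), call. = FALSE)
    }
  }
  check_probs(activity, 4, "activity")
  check_probs(cocoon, 3, "cocoon")
  check_probs(melanisation, 5, "melanisation")
  if (p_survive < 0 || p_survive > 1) stop("p_survive must be in [0,1]", call. = FALSE)
  structure(list(activity = activity, cocoon = cocoon,
                 melanisation = melanisation, p_survive = p_survive),
            class = "health_profile")
}

#' @rdname health_profile
#' @details `health_profile_healthy()` puts all mass on the maximal level of
#'   every category (the profile of an untroubled cohort: every observation
#'   scores 10); `health_profile_dead()` is the rubric minimum.
#' @export
health_profile_healthy <- function() {
  health_profile(activity = c(0, 0, 0, 1), cocoon = c(0, 0, 1),
                 melanisation = c(0, 0, 0, 0, 1), p_survive = 1)
}

#' @rdname health_profile
#' @export
health_profile_dead <- function() {
  health_profile(activity = c(1, 0, 0, 0), cocoon = c(1, 0, 0),
                 melanisation = c(1, 0, 0, 0, 0), p_survive = 0)
}

#' Simulate scored health observations for every experimental group
#'
#' Generates one record per larva x observation time x observer. Latent
#' category states are drawn per larva and time from the group's
#' [health_profile()]; both observers record the same latent state unless
#' `p_misread > 0`, in which case an observer independently re-draws a
#' category from the profile with that probability (emulating imperfect
#' inter-observer concordance). Survival is a monotone per-larva process:
#' a larva that dies stays dead, and the survival category of a dead larva
#' is 0 for both observers.
#'
#' @param design An [experiment_design()]; groups are its arms (treatments
#'   plus control).
#' @param profile A single [health_profile()] applied to every group, or a
#'   named list of profiles keyed by group label.
#' @param seed Integer seed (reproducible).
#' @param n_larvae Larvae per group (default 10).
#' @param times_h Observation times in hours (default 24, 48, 72).
#' @param n_observers Number of independent blinded observers (default 2).
#' @param p_misread Per-category probability that an observer re-draws the
#'   level instead of recording the latent state (default 0).
#'
#' @return A tibble with columns `larva_id`, `group`, `time_h`, `observer_id`,
#'   `activity`, `cocoon`, `melanisation`, `survival`.
#' @export
generate_health_observations <- function(design, profile, seed,
                                         n_larvae = 10L,
                                         times_h = c(24, 48, 72),
                                         n_observers = 2L,
                                         p_misread = 0) {
  stopifnot(inherits(design, "experiment_design"))
  groups <- design_arms(design)
  if (inherits(profile, "health_profile")) {
    profile <- stats::setNames(rep(list(profile), length(groups)), groups)
  }
  if (!all(groups %in% names(profile))) {
    stop("profile must be a health_profile or a named list covering every group",
         call. = FALSE)
  }
  for (p in profile) stopifnot(inherits(p, "health_profile"))
  set.seed(as.integer(seed))

  levels_act <- 0:3
  levels_coc <- c(0, 0.5, 1)
  levels_mel <- 0:4
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    pr <- profile[[g]]
    rows <- vector("list", n_larvae)
    for (l in seq_len(n_larvae)) {
      alive <- TRUE
      recs <- vector("list", length(times_h))
      for (ti in seq_along(times_h)) {
        if (alive) alive <- stats::runif(1) < pr$p_survive
        latent <- c(
          activity = sample(levels_act, 1, prob = pr$activity),
          cocoon = sample(levels_coc, 1, prob = pr$cocoon),
          melanisation = sample(levels_mel, 1, prob = pr$melanisation)
        )
        obs <- lapply(seq_len(n_observers), function(o) {
          a <- latent[["activity"]]
          co <- latent[["cocoon"]]
          m <- latent[["melanisation"]]
          if (p_misread > 0) {
            if (stats::runif(1) < p_misread) a <- sample(levels_act, 1, prob = pr$activity)
            if (stats::runif(1) < p_misread) co <- sample(levels_coc, 1, prob = pr$cocoon)
            if (stats::runif(1) < p_misread) m <- sample(levels_mel, 1, prob = pr$melanisation)
          }
          tibble::tibble(larva_id = sprintf("%s_L%02d", g, l), group = g,
                         time_h = times_h[ti], observer_id = o,
                         activity = a, cocoon = co, melanisation = m,
                         survival = if (alive) 2 else 0)
        })
        recs[[ti]] <- dplyr::bind_rows(obs)
      }
      rows[[l]] <- dplyr::bind_rows(recs)
    }
    out[[gi]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
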
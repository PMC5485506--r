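# Cancer detection: symptomatic (clinical) presentation and the PSA-then-
# biopsy screening episode, plus the screening-strategy catalog.

#' Screening strategy specification
#'
#' @param name Strategy label.
#' @param ages Integer vector of screening ages (empty = no screening).
#' @param surveillance Manage screen-detected localized low-grade cancer by
#'   active surveillance instead of immediate treatment.
#' @return A `ps_strategy` list.
#' @export
#' @examples
#' strategy_spec("55-69, 2y", seq(55, 69, by = 2))
strategy_spec <- function(name, ages = integer(0), surveillance = FALSE) {
  ages <- sort(unique(as.integer(ages)))
  if (length(ages) && (min(ages) < 0 || max(ages) > 120))
    stop("screening ages must lie in [0, 120]")
  out <- list(name = name, ages = ages, surveillance = isTRUE(surveillance))
  class(out) <- "ps_strategy"
  out
}

#' The evaluated screening-strategy grid
#'
#' The 14 strategies of the base-case analyses: no screening; one-time
#' screening at ages 55, 59, 64 and 69; and interval screening over the age
#' windows 55-59, 55-64 and 55-69 with 4-, 2- and 1-year intervals. Interval
#' schedules start at the window's lower bound and step by the interval,
#' truncating at the upper bound, which reproduces the published per-strategy
#' screen counts (e.g. three screens for "55-64, 4y").
#'
#' @param surveillance Apply active surveillance to every strategy.
#' @return A named list of 14 [strategy_spec()] objects.
#' @export
#' @examples
#' vapply(strategy_catalog(), function(s) length(s$ages), integer(1))
strategy_catalog <- function(surveillance = FALSE) {
  specs <- list(
    `no screening` = integer(0),
    `55y` = 55L, `59y` = 59L, `64y` = 64L, `69y` = 69L)
  for (stop_age in c(59L, 64L, 69L)) for (by in c(4L, 2L, 1L)) {
    specs[[sprintf("55-%d, %dy", stop_age, by)]] <- seq(55L, stop_age, by = by)
  }
  out <- lapply(names(specs), function(nm)
    strategy_spec(nm, specs[[nm]], surveillance = surveillance))
  names(out) <- names(specs)
  out
}

#' Annual clinical (symptomatic) detection probability
#'
#' @param state Integer state code 1..9 (latent, undiagnosed cancer).
#' @param params A `ps_params` object.
#' @return Annual detection probability.
#' @export
clinical_detection_prob <- function(state, params) {
  state <- as.integer(state)
  if (any(state < 1L | state > 9L))
    stop("clinical detection is defined only for latent cancer states (1..9)")
  unname(params$detection$clinical_detect[.STATE_KEYS[state]])
}

#' Draw clinical detection events
#'
#' @inheritParams clinical_detection_prob
#' @param n Number of independent annual draws.
#' @return Logical vector of length `n`.
#' @export
clinical_detection_draw <- function(state, params, n = 1) {
  stats::runif(n) < clinical_detection_prob(state, params)
}

# whole-episode screening sensitivity by state and age (0 for no cancer)
screen_sensitivity <- function(state, age, params) {
  ss <- params$detection$screen_sens
  grp <- ifelse(state == 0L, NA,
         ifelse(state <= 3L, "localized", "advanced"))
  agegrp <- ifelse(age < 70, "lt70", "ge70")
  out <- ifelse(is.na(grp), 0, ss[paste(grp, agegrp, sep = "_")])
  unname(out)
}

#' Simulate PSA screening episodes
#'
#' One screening episode is a PSA test followed by biopsy whenever the PSA
#' is elevated. For cancer-free men the PSA is falsely positive with
#' probability `1 - specificity` and the (perfectly specific) biopsy is
#' negative, so the episode costs a biopsy but yields no diagnosis. For men
#' with latent cancer the calibrated whole-episode sensitivity is split into
#' a PSA-positivity probability `sens / biopsy_sensitivity` and a biopsy
#' detection probability `biopsy_sensitivity`, so men with a false-negative
#' biopsy still incur its disutility.
#'
#' @param state Integer state code (0 = cancer-free, 1..9 latent cancer).
#' @param age Age at the episode (years); ages below 70 use the `<70`
#'   sensitivities.
#' @param params A `ps_params` object.
#' @param n Number of independent episodes to simulate.
#' @return A `data.frame` with logical columns `psa_positive`, `biopsy_done`,
#'   `detected`, `false_positive`.
#' @export
#' @examples
#' set.seed(1)
#' colMeans(screening_episode(0L, 60, default_parameters(), n = 1e4))
screening_episode <- function(state, age, params, n = 1) {
  state <- as.integer(state)
  if (length(state) != 1L || state < 0L || state > 9L)
    stop("`state` must be a single code in 0..9")
  det <- params$detection
  u_psa <- stats::runif(n)
  u_bx <- stats::runif(n)
  if (state == 0L) {
    pos <- u_psa < (1 - det$psa_specificity)
    data.frame(psa_positive = pos, biopsy_done = pos,
               detected = rep(FALSE, n), false_positive = pos)
  } else {
    sens <- screen_sensitivity(state, age, params)
    p_pos <- min(1, sens / det$biopsy_sensitivity)
    pos <- u_psa < p_pos
    found <- pos & u_bx < det$biopsy_sensitivity
    data.frame(psa_positive = pos, biopsy_done = pos,
               detected = found, false_positive = rep(FALSE, n))
  }
}
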
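# Experiment suite: scenario analyses, one-way sensitivity sweeps over cure
# rates and disutility preferences, and calibration of the familial risk
# factor to a target lifetime-incidence ratio.

#' Sensitivity sweep over the cure-rate multiplier
#'
#' Scales the grade-specific cure probabilities by a common factor and
#' re-evaluates the QALD gain of each screening strategy versus no
#' screening, reporting the smallest multiplier at which any screening
#' strategy reaches a non-negative gain.
#'
#' @param grid Multiplier grid (default 1.0 to 1.8 in steps of 0.1).
#' @param params Base parameter set.
#' @param strategies Strategy list (first = reference no-screening arm).
#' @param n,seed Cohort size and seed (the same seed is reused across the
#'   grid: paired comparisons).
#' @param ... Passed to [run_cohort()].
#' @return A list with `curves` (`data.frame`: multiplier, strategy,
#'   qald_gained, se) and `crossing_multiplier` (smallest grid value with a
#'   non-negative gain, `NA` if none; resolution = grid step).
#' @export
sweep_cure_multiplier <- function(grid = seq(1, 1.8, by = 0.1),
                                  params = default_parameters(),
                                  strategies = strategy_catalog(),
                                  n, seed, ...) {
  rows <- list()
  for (m in grid) {
    p <- params
    p$treatment$cure_multiplier <- m
    res <- run_cohort(p, strategies, n = n, seed = seed, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      multiplier = m, strategy = res$strategy,
      qald_gained = res$qald_gained, se = res$se_qald_gained,
      stringsAsFactors = FALSE)
  }
  curves <- do.call(rbind, rows)
  screen <- curves$strategy != strategies[[1]]$name
  pos <- curves$multiplier[screen & curves$qald_gained >= 0]
  list(curves = curves,
       crossing_multiplier = if (length(pos)) min(pos) else NA_real_)
}

#' Sensitivity sweep over disutility preferences and index age
#'
#' Varies the common multiplier on the long-term adverse-event disutility
#' weights (0 = no impairment from ED/UI/BD, 1 = base case, 2 = doubled) for
#' screening candidates of different index ages, and maps the
#' QALD-maximizing strategy at each (age, multiplier) grid point. For index
#' ages beyond 55 the strategy schedules are shifted accordingly and
#' outcomes are conditioned on being alive and undiagnosed at the index
#' age.
#'
#' @param m_grid Disutility multiplier grid.
#' @param index_ages Ages at which the screening decision is made.
#' @param params Base parameter set.
#' @param strategies Strategy list for index age 55 (first = no screening).
#' @param n,seed Cohort size and seed.
#' @param ... Passed to [run_cohort()].
#' @return A list with `grid` (age, multiplier, strategy, qald_gained) and
#'   `optimal` (one row per age and multiplier with the best strategy).
#' @export
sweep_disutility <- function(m_grid = c(0, 0.5, 1, 1.5, 2),
                             index_ages = c(55, 60, 65),
                             params = default_parameters(),
                             strategies = strategy_catalog(),
                             n, seed, ...) {
  rows <- list()
  for (age in index_ages) {
    strats <- lapply(strategies, function(s)
      strategy_spec(s$name, s$ages + (age - 55), s$surveillance))
    for (m in m_grid) {
      p <- params
      p$utilities$disutility_multiplier <- m
      res <- run_cohort(p, strats, n = n, seed = seed,
                        condition_age = age, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        index_age = age, multiplier = m, strategy = res$strategy,
        qald_gained = res$qald_gained, stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  sp <- split(grid, list(grid$index_age, grid$multiplier))
  optimal <- do.call(rbind, lapply(sp, function(g)
    g[which.max(g$qald_gained), ]))
  rownames(optimal) <- NULL
  list(grid = grid, optimal = optimal[order(optimal$index_age,
                                            optimal$multiplier), ])
}

#' Scenario analyses
#'
#' Evaluates the QALD gain of each strategy under a list of named scenarios
#' applied on top of a base parameter set.
#'
#' @param scenarios Named list of [scenario_spec()] objects.
#' @param params Base parameter set.
#' @param strategies Strategy list (first = reference).
#' @param n,seed Cohort size and seed (shared across scenarios).
#' @param ... Passed to [run_cohort()].
#' @return A `data.frame`: scenario, strategy, qald_gained, se.
#' @export
run_scenarios <- function(scenarios, params = default_parameters(),
                          strategies = strategy_catalog(), n, seed, ...) {
  rows <- list()
  for (nm in names(scenarios)) {
    p <- apply_scenario(params, scenarios[[nm]])
    res <- run_cohort(p, strategies, n = n, seed = seed, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = nm, strategy = res$strategy,
      qald_gained = res$qald_gained, se = res$se_qald_gained,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Calibrate the familial risk factor
#'
#' Finds the hazard multiplier `fr` (applied to both onset and progression)
#' for which the no-screening lifetime risk of cancer diagnosis equals
#' `target_ratio` times the average-risk (`fr = 1`) value, by bisection.
#' Every evaluation reuses the same seed, so the risk is a monotone,
#' effectively deterministic function of `fr` and the bisection is stable
#' down to Monte-Carlo resolution.
#'
#' @param target_ratio Desired lifetime-incidence ratio (2.0 for a doubled
#'   familial risk).
#' @param params Base parameter set (evaluated at `fr = 1` for the
#'   reference).
#' @param bounds Search interval for `fr`.
#' @param tol Bisection half-width at which to stop.
#' @param n,seed Cohort size per evaluation and seed.
#' @param life_table Life table for other-cause mortality.
#' @return A list: `fr` (the calibrated factor), `risk_ratio` achieved,
#'   `base_risk` and `target_risk` (percent), `evaluations`.
#' @export
calibrate_familial_factor <- function(target_ratio = 2, params = default_parameters(),
                                      bounds = c(1, 4), tol = 0.01, n, seed,
                                      life_table = synthetic_life_table()) {
  stopifnot(target_ratio >= 1, bounds[1] >= 0, bounds[2] > bounds[1])
  noscreen <- strategy_spec("no screening")
  eval_risk <- function(fr) {
    p <- params
    p$natural_history$fr <- fr
    p$natural_history$fr_on_onset <- TRUE
    p$natural_history$fr_on_progression <- TRUE
    ctx <- cohort_context(p, n, seed, life_table)
    pp <- simulate_strategy(ctx, noscreen)
    100 * mean(pp$diagnosed)
  }
  base_risk <- eval_risk(1)
  target <- target_ratio * base_risk
  evals <- 1L
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- eval_risk(lo) - target
  f_hi <- eval_risk(hi) - target
  evals <- evals + 2L
  if (f_lo > 0 || f_hi < 0)
    stop("bounds [", lo, ", ", hi, "] do not bracket the target ratio ",
         target_ratio)
  while ((hi - lo) / 2 > tol) {
    mid <- (lo + hi) / 2
    f_mid <- eval_risk(mid) - target
    evals <- evals + 1L
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  fr <- (lo + hi) / 2
  achieved <- eval_risk(fr)
  list(fr = fr, risk_ratio = achieved / base_risk, base_risk = base_risk,
       target_risk = target, achieved_risk = achieved,
       evaluations = evals + 1L)
}
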
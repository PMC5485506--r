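# Aggregation of per-person ledgers into the benefit-harm outcome table and
# contrasts against the no-screening arm.
#
# Overdiagnosis is a population-level difference: the lifetime risk of
# diagnosis with screening minus without, the no-screening arm standing for
# the world without overdiagnosis. The overdiagnosis fraction divides that
# difference by the risk of screen detection. Overtreatment applies the same
# principle to curative (RP/RT) treatment risks.

# per-strategy aggregate from the per-person ledger, optionally restricted
# to a subset mask (index-age conditioning)
.aggregate_strategy <- function(pp, subset = NULL) {
  sel <- if (is.null(subset)) rep(TRUE, length(pp$diagnosed)) else subset
  n <- sum(sel)
  pmean <- function(x) mean(x[sel])
  pse <- function(x) stats::sd(x[sel]) / sqrt(n)
  risk <- function(flag) 100 * pmean(flag)
  rse <- function(flag) 100 * sqrt(pmean(flag) * (1 - pmean(flag)) / n)
  on_as <- pp$as_flag[sel]
  data.frame(
    strategy = pp$strategy,
    n_screens = pp$n_screens,
    surveillance = pp$surveillance,
    risk_dx = risk(pp$diagnosed),
    se_risk_dx = rse(pp$diagnosed),
    risk_screen_dx = risk(pp$mode_screen),
    risk_rp = risk(pp$proc == 1L),
    risk_rt = risk(pp$proc == 2L),
    risk_curative = risk(pp$proc %in% 1:2),
    risk_pca_death = risk(pp$cause == "pca"),
    se_risk_pca_death = rse(pp$cause == "pca"),
    rp_deaths_per_10k = 1e4 * pmean(pp$cause == "rp"),
    aes_per_man = pmean(pp$ae_count),
    psa_tests_per_man = pmean(pp$psa_tests),
    false_pos_per_man = pmean(pp$fp_tests),
    screened_frac = pmean(pp$psa_tests >= 1),
    as_entrants_frac = pmean(pp$as_flag),
    as_biopsies_per_man = if (any(on_as))
      mean(pp$as_biopsies[sel][on_as]) else NA_real_,
    life_days = pmean(pp$life_days),
    se_life_days = pse(pp$life_days),
    qald = pmean(pp$qald),
    se_qald = pse(pp$qald),
    stringsAsFactors = FALSE)
}

# contrasts of one strategy against the reference (no-screening) ledger,
# paired person-by-person under common random numbers
.contrast_vs_reference <- function(pp, ref, subset = NULL) {
  sel <- if (is.null(subset)) rep(TRUE, length(pp$diagnosed)) else subset
  n <- sum(sel)
  d_life <- pp$life_days[sel] - ref$life_days[sel]
  d_qald <- pp$qald[sel] - ref$qald[sel]
  risk <- function(flag) 100 * mean(flag[sel])
  overdx <- risk(pp$diagnosed) - risk(ref$diagnosed)
  screen_dx <- risk(pp$mode_screen)
  overtx <- risk(pp$proc %in% 1:2) - risk(ref$proc %in% 1:2)
  arr <- (mean(ref$cause[sel] == "pca") - mean(pp$cause[sel] == "pca"))
  tests <- mean(pp$psa_tests[sel])
  screened <- mean(pp$psa_tests[sel] >= 1)
  data.frame(
    risk_overdx = overdx,
    overdx_frac = if (screen_dx > 0) 100 * overdx / screen_dx else NA_real_,
    risk_overtx = overtx,
    overtx_frac = if (screen_dx > 0) 100 * overtx / screen_dx else NA_real_,
    life_days_gained = mean(d_life),
    se_life_days_gained = stats::sd(d_life) / sqrt(n),
    qald_gained = mean(d_qald),
    se_qald_gained = stats::sd(d_qald) / sqrt(n),
    tests_per_death_averted = if (arr > 0) tests / arr else Inf,
    men_per_death_averted = if (arr > 0) screened / arr else Inf,
    stringsAsFactors = FALSE)
}

#' Run a cohort through a set of screening strategies
#'
#' Builds one shared cohort context (common random numbers) and evaluates
#' every strategy on it, returning the full benefit-harm outcome table with
#' Monte-Carlo standard errors and contrasts against the reference arm (the
#' first strategy, conventionally no screening).
#'
#' @inheritParams cohort_context
#' @param strategies List of [strategy_spec()] objects; the first is the
#'   comparison reference. See [strategy_catalog()].
#' @param postdx Post-diagnosis death probabilities by state code.
#' @param condition_age If non-`NULL`, restrict all aggregates to men alive
#'   and undiagnosed at this index age (the perspective of a screening
#'   candidate of that age).
#' @param keep_person Also return the per-person ledgers (memory-heavy).
#' @return A `data.frame` of class `ps_comparison`, one row per strategy,
#'   with risks in percent, counts per man, life days and quality-adjusted
#'   life days (QALDs) plus their gains versus the reference arm. Attributes
#'   `n`, `seed`, `condition_age` and `synthetic_inputs` record provenance.
#' @export
#' @examples
#' res <- run_cohort(default_parameters(),
#'                   strategy_catalog()[c("no screening", "55y")],
#'                   n = 2000, seed = 1)
#' res[, c("strategy", "risk_dx", "qald_gained")]
run_cohort <- function(params, strategies, n, seed,
                       life_table = synthetic_life_table(),
                       postdx = synthetic_postdx_rates(),
                       condition_age = NULL, keep_person = FALSE,
                       progression_first = FALSE) {
  if (inherits(strategies, "ps_strategy")) strategies <- list(strategies)
  ctx <- cohort_context(params, n, seed, life_table,
                        progression_first = progression_first)
  subset <- NULL
  if (!is.null(condition_age))
    subset <- ctx$death_oc > condition_age & ctx$clin_age > condition_age
  ref <- simulate_strategy(ctx, strategies[[1]], postdx)
  rows <- vector("list", length(strategies))
  persons <- if (keep_person) vector("list", length(strategies)) else NULL
  for (k in seq_along(strategies)) {
    pp <- if (k == 1) ref else simulate_strategy(ctx, strategies[[k]], postdx)
    rows[[k]] <- cbind(.aggregate_strategy(pp, subset),
                       .contrast_vs_reference(pp, ref, subset))
    if (keep_person) persons[[k]] <- pp
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "n_subset") <- if (is.null(subset)) n else sum(subset)
  attr(out, "condition_age") <- condition_age
  attr(out, "synthetic_inputs") <-
    isTRUE(ctx$synthetic_life_table) || isTRUE(attr(postdx, "synthetic")) ||
    "utilities.baseline" %in% params$provenance$synthetic
  attr(out, "persons") <- persons
  class(out) <- c("ps_comparison", "data.frame")
  out
}

#' Base-case benefit-harm analysis
#'
#' Evaluates the full 14-strategy grid for one population (average or
#' familial risk) with or without active surveillance, mirroring the layout
#' of the published benefit-harm tables.
#'
#' @param population `"average"` or `"familial"` (familial sets the
#'   calibrated risk factor 1.423 on onset and progression).
#' @param surveillance Manage eligible screen-detected cancers by active
#'   surveillance.
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param params Base parameter set to start from (defaults to the bundled
#'   base case; the familial flag is applied on top).
#' @param ... Passed on to [run_cohort()].
#' @return A `ps_comparison` table (see [run_cohort()]).
#' @export
run_basecase <- function(population = c("average", "familial"),
                         surveillance = FALSE, n, seed,
                         params = default_parameters(), ...) {
  population <- match.arg(population)
  if (population == "familial") params$natural_history$fr <- 1.423
  run_cohort(params, strategy_catalog(surveillance = surveillance),
             n = n, seed = seed, ...)
}

#' @export
print.ps_comparison <- function(x, ...) {
  cat(sprintf("<ps_comparison> %d strategies, n = %s, seed = %s%s\n",
              nrow(x), format(attr(x, "n"), big.mark = ","),
              attr(x, "seed"),
              if (isTRUE(attr(x, "synthetic_inputs")))
                " [synthetic life table / survival / utility inputs]" else ""))
  cols <- c("strategy", "n_screens", "risk_dx", "risk_screen_dx",
            "risk_overdx", "overdx_frac", "risk_curative", "risk_overtx",
            "risk_pca_death", "life_days_gained", "qald_gained")
  y <- as.data.frame(x)[, cols]
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
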
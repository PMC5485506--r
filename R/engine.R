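# Cohort microsimulation engine.
#
# The engine follows men from birth to death (or the 120-year horizon) in
# annual cycles. Within a cycle the event order is: (1) other-cause death,
# (2) screening episode at scheduled ages, (3) clinical detection, (4)
# diagnosis handling (treatment or active surveillance, AS biopsies), (5)
# latent progression, (6) post-diagnosis cancer death for non-cured men,
# (7) utility accrual. Deaths occur at the start of their cycle: the death
# cycle is not lived, so life years equal the death age and the terminal
# one-time weight falls on the last lived cycle.
#
# Everything is vectorized over persons. Randomness comes from (purpose,
# cycle)-keyed substreams of the base seed (see rng.R), so two strategies
# evaluated on the same context consume identical uniforms person-by-person:
# exact common random numbers. Strategy-independent draws (latent history,
# other-cause death, clinical detection, treatment and post-diagnosis
# survival inversions) live in the shared cohort context.

# subset-aware latent state lookup (rows idx; default all)
latent_state_at <- function(hist, a, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(hist$n)
  s <- integer(length(idx))
  for (k in 1:6) {
    e <- hist$entry[idx, k]
    hit <- e <= a
    s[hit] <- hist$state[idx, k][hit]
  }
  s
}

# first age at which each man's latent cancer presents clinically, with the
# state at presentation; Inf / 0 when it never presents before the horizon.
# `shift = 1` evaluates detection against the post-progression state of the
# same cycle (the progression-before-detection event-order variant).
.clinical_detection_ages <- function(hist, params, seed, max_age = 120,
                                     shift = 0L) {
  n <- hist$n
  clin_p <- unname(params$detection$clinical_detect[.STATE_KEYS])
  clin_age <- rep(Inf, n)
  clin_state <- integer(n)
  onset <- hist$entry[, 1]
  if (!any(is.finite(onset))) return(list(age = clin_age, state = clin_state))
  amin <- max(1L, as.integer(floor(min(onset[is.finite(onset)]))))
  for (a in amin:(max_age - 1)) {
    cand <- which(onset <= a + shift & !is.finite(clin_age))
    if (!length(cand)) next
    s <- latent_state_at(hist, a + shift, cand)
    keep <- s >= 1L & s <= 9L
    cand <- cand[keep]
    s <- s[keep]
    if (!length(cand)) next
    u <- substream_runif(n, seed, .PUR$clin, a)
    det <- u[cand] < clin_p[s]
    clin_age[cand[det]] <- a
    clin_state[cand[det]] <- s[det]
  }
  list(age = clin_age, state = clin_state)
}

#' Build the shared cohort context
#'
#' Samples every strategy-independent quantity once: latent trajectories,
#' other-cause death ages, clinical presentation ages, and the person-level
#' uniforms inverted for cure, peri-operative death, adverse events and
#' post-diagnosis survival. Evaluating several strategies against the same
#' context is what implements common random numbers.
#'
#' @param params A `ps_params` object.
#' @param n Cohort size.
#' @param seed Integer base seed.
#' @param life_table Life table `data.frame` (`age`, `q`); defaults to the
#'   synthetic fixture.
#' @param progression_first Evaluate detection (screening and clinical)
#'   against the post-progression state of the same cycle instead of the
#'   default detection-before-progression order; a bounding switch for the
#'   within-cycle event-order convention.
#' @return A `ps_context` list consumed by [simulate_strategy()].
#' @export
cohort_context <- function(params, n, seed,
                           life_table = synthetic_life_table(),
                           progression_first = FALSE) {
  validate_parameters(params)
  stopifnot(n >= 1, is.finite(seed))
  shift <- as.integer(isTRUE(progression_first))
  hist <- sample_latent_histories(n, seed, params)
  death_oc <- sample_other_cause_death(n, seed, life_table)
  clin <- .clinical_detection_ages(hist, params, seed, shift = shift)
  ctx <- list(
    n = n, seed = seed, params = params, shift = shift,
    hist = hist, death_oc = death_oc,
    clin_age = clin$age, clin_state = clin$state,
    u_cure = substream_runif(n, seed, .PUR$cure),
    u_periop = substream_runif(n, seed, .PUR$periop),
    u_ed = substream_runif(n, seed, .PUR$ae_ed),
    u_ui = substream_runif(n, seed, .PUR$ae_ui),
    u_bd = substream_runif(n, seed, .PUR$ae_bd),
    u_pcad = substream_runif(n, seed, .PUR$pcad),
    bu = baseline_utility(params, 0:119),
    CB = .cumulative_baseline(params),
    synthetic_life_table = isTRUE(attr(life_table, "synthetic")))
  class(ctx) <- "ps_context"
  ctx
}

# geometric inversion of the constant annual post-diagnosis death rate
.geom_years <- function(u, r) {
  out <- rep(Inf, length(u))
  k <- r >= 1
  out[k] <- 1
  k <- r > 0 & r < 1
  out[k] <- floor(log(u[k]) / log(1 - r[k])) + 1
  out
}

#' Simulate one screening strategy on a cohort context
#'
#' Runs the full per-person event sequence for `strategy` against the shared
#' context and returns the per-person outcome ledger.
#'
#' @param ctx A `ps_context` from [cohort_context()].
#' @param strategy A [strategy_spec()] object.
#' @param postdx Post-diagnosis annual cancer death probabilities by state
#'   code (see [synthetic_postdx_rates()]).
#' @return A list of per-person vectors: diagnosis (`dx_age`, `mode_screen`,
#'   `dx_state`), treatment (`treat_age`, `treat_state`, `proc`, `cured`,
#'   `periop`, `ae_count`), testing (`psa_tests`, `fp_tests`,
#'   `as_biopsies`), and survival (`death_age`, `cause`, `life_days`,
#'   `qald`).
#' @export
simulate_strategy <- function(ctx, strategy,
                              postdx = synthetic_postdx_rates()) {
  stopifnot(inherits(ctx, "ps_context"), inherits(strategy, "ps_strategy"))
  params <- ctx$params
  n <- ctx$n
  seed <- ctx$seed
  det <- params$detection
  tr <- params$treatment
  ut <- params$utilities
  bx_sens <- det$biopsy_sensitivity
  w_bx <- ut$one_time[["biopsy"]]
  max_age <- params$max_age

  screen_age <- rep(Inf, n)
  screen_state <- integer(n)
  psa_tests <- integer(n)
  fp_tests <- integer(n)
  ev_i <- list(); ev_a <- list(); ev_w <- list()
  add_events <- function(i, a, w) {
    if (!length(i)) return(invisible())
    k <- length(ev_i) + 1L
    ev_i[[k]] <<- i
    ev_a[[k]] <<- rep_len(a, length(i))
    ev_w[[k]] <<- rep_len(w, length(i))
    invisible()
  }

  ## (2) screening episodes at scheduled ages
  for (a in strategy$ages) {
    elig <- ctx$death_oc > a & ctx$clin_age > a & !is.finite(screen_age)
    if (det$participation < 1) {
      u_part <- substream_runif(n, seed, .PUR$psa + 2L, a)
      elig <- elig & u_part < det$participation
    }
    idx <- which(elig)
    if (!length(idx)) next
    psa_tests[idx] <- psa_tests[idx] + 1L
    s <- latent_state_at(ctx$hist, a + ctx$shift, idx)
    u_psa <- substream_runif(n, seed, .PUR$psa, a)
    u_bx <- substream_runif(n, seed, .PUR$biopsy, a)
    free <- idx[s == 0L]
    pos0 <- free[u_psa[free] < 1 - det$psa_specificity]
    fp_tests[pos0] <- fp_tests[pos0] + 1L
    add_events(pos0, a, w_bx)
    has_ca <- s >= 1L & s <= 9L
    canc <- idx[has_ca]
    sc <- s[has_ca]
    if (length(canc)) {
      sens <- screen_sensitivity(sc, a, params)
      pos <- u_psa[canc] < pmin(1, sens / bx_sens)
      bio <- canc[pos]
      add_events(bio, a, w_bx)
      hit <- u_bx[bio] < bx_sens
      found <- bio[hit]
      screen_age[found] <- a
      screen_state[found] <- sc[pos][hit]
    }
  }

  ## (3)-(4) diagnosis: screening always precedes clinical presentation
  ## (eligibility required clin_age > a, so screen_age < clin_age when set)
  dx_age <- pmin(screen_age, ctx$clin_age)
  diagnosed <- is.finite(dx_age) & dx_age < ctx$death_oc & dx_age <= max_age - 1
  dx_age[!diagnosed] <- Inf
  mode_screen <- diagnosed & screen_age <= ctx$clin_age
  dx_state <- ifelse(mode_screen, screen_state, ctx$clin_state)
  dx_state[!diagnosed] <- 0L

  ## (4) treatment or active surveillance
  as_flag <- diagnosed & strategy$surveillance & mode_screen & dx_state == 1L
  treat_age <- ifelse(diagnosed & !as_flag, dx_age, Inf)
  treat_state <- ifelse(diagnosed & !as_flag, dx_state, 0L)
  as_biopsies <- integer(n)
  if (any(as_flag)) {
    interval <- params$surveillance$interval
    as_max <- params$surveillance$max_age
    untreated <- as_flag
    a0 <- as.integer(min(dx_age[as_flag])) + 1L
    if (a0 <= as_max) for (a in a0:as_max) {
      due <- untreated & dx_age < a & (a - dx_age) %% interval == 0 &
        a < ctx$death_oc & a < ctx$clin_age
      idx <- which(due)
      if (!length(idx)) next
      as_biopsies[idx] <- as_biopsies[idx] + 1L
      add_events(idx, a, w_bx)
      s <- latent_state_at(ctx$hist, a + ctx$shift, idx)
      grade <- (s - 1L) %% 3L + 1L
      u <- substream_runif(n, seed, .PUR$asbx, a)
      hit <- grade >= 2L & u[idx] < bx_sens
      trig <- idx[hit]
      treat_age[trig] <- a
      treat_state[trig] <- s[hit]
      untreated[trig] <- FALSE
    }
    # beyond the biopsy window (or between biopsies) clinical presentation
    # remains the treatment trigger
    rem <- which(untreated & is.finite(ctx$clin_age) &
                   ctx$clin_age < ctx$death_oc & ctx$clin_age <= max_age - 1)
    treat_age[rem] <- ctx$clin_age[rem]
    treat_state[rem] <- ctx$clin_state[rem]
  }
  treated <- is.finite(treat_age)

  ## treatment draws (person-level shared streams)
  stage <- integer(n); grade <- integer(n)
  stage[treated] <- (treat_state[treated] - 1L) %/% 3L + 1L
  grade[treated] <- (treat_state[treated] - 1L) %% 3L + 1L
  periop <- treated & stage == 1L & ctx$u_periop < tr$rp_periop_mortality
  cure_p <- rep(0, n)
  lr <- treated & stage <= 2L
  cure_p[lr] <- pmin(1, tr$cure_by_grade[grade[lr]] * tr$cure_multiplier)
  cure_p[treated & stage == 3L] <- tr$cure_distant
  cured <- treated & !periop & ctx$u_cure < cure_p
  risk_ed <- ifelse(stage == 1L, tr$ae_risk$RP[["ED"]], tr$ae_risk$RT[["ED"]])
  risk_ui <- ifelse(stage == 1L, tr$ae_risk$RP[["UI"]], tr$ae_risk$RT[["UI"]])
  risk_bd <- ifelse(stage == 1L, tr$ae_risk$RP[["BD"]], tr$ae_risk$RT[["BD"]])
  curable <- treated & stage <= 2L & !periop
  ed <- curable & ctx$u_ed < risk_ed
  ui <- curable & ctx$u_ui < risk_ui
  bd <- curable & ctx$u_bd < risk_bd
  ae_count <- as.integer(ed) + as.integer(ui) + as.integer(bd)
  ae_f <- .ae_factor(stage == 1L, ed, ui, bd, params)

  # one-time treatment weights (periop deaths never live the cycle)
  rp_i <- which(curable & stage == 1L)
  rt_i <- which(curable & stage == 2L)
  add_events(rp_i, treat_age[rp_i], ut$one_time[["RP"]])
  add_events(rt_i, treat_age[rt_i], ut$one_time[["RT"]])

  ## (6) post-diagnosis cancer death (from the cycle after treatment)
  pca_age <- rep(Inf, n)
  nc <- which(treated & !cured & !periop)
  if (length(nc)) {
    r <- as.numeric(postdx)[treat_state[nc]]
    pca_age[nc] <- treat_age[nc] + .geom_years(ctx$u_pcad[nc], r)
  }
  nt <- which(!treated)
  pca_age[nt] <- pmin(pca_age[nt], ctx$hist$untreated_death[nt])

  ## death assembly
  death_age <- pmin(ctx$death_oc, ifelse(periop, treat_age, Inf),
                    pca_age, max_age)
  cause <- rep("horizon", n)
  cause[death_age < max_age & death_age == ctx$death_oc] <- "oc"
  k <- death_age < max_age & cause == "horizon"
  cause[k & periop & death_age == treat_age] <- "rp"
  cause[k & cause == "horizon" & death_age == pca_age] <- "pca"
  pca_death <- cause == "pca"
  add_events(which(pca_death), death_age[pca_death] - 1,
             ut$one_time[["terminal"]])

  ## (7) quality-adjusted survival
  dpy <- params$days_per_year
  qaly <- ctx$CB[death_age + 1]
  # distant-stage (palliative) men live at the distant-state utility
  dist_flag <- treated & stage == 3L & !periop
  di <- which(dist_flag & death_age > treat_age)
  if (length(di))
    qaly[di] <- qaly[di] +
      ut$distant_clinical * (death_age[di] - treat_age[di]) -
      (ctx$CB[death_age[di] + 1] - ctx$CB[treat_age[di] + 1])
  # chronic adverse-event window
  ae_flag <- curable & ae_f < 1
  ai <- which(ae_flag)
  if (length(ai)) {
    wend <- pmin(treat_age[ai] + tr$ae_duration, death_age[ai])
    qaly[ai] <- qaly[ai] +
      (ae_f[ai] - 1) * (ctx$CB[wend + 1] - ctx$CB[treat_age[ai] + 1])
  }
  # one-time events, grouped by (person, cycle) so same-cycle weights
  # combine multiplicatively
  if (length(ev_i)) {
    i <- unlist(ev_i); a <- unlist(ev_a); w <- unlist(ev_w)
    keep <- a < death_age[i]
    i <- i[keep]; a <- a[keep]; w <- w[keep]
    if (length(i)) {
      key <- (i - 1) * (max_age + 1) + a
      lw <- rowsum(log(w), key)
      keys <- as.numeric(rownames(lw))
      ki <- keys %/% (max_age + 1) + 1
      ka <- keys %% (max_age + 1)
      u_c <- ctx$bu[ka + 1]
      dsel <- dist_flag[ki] & ka >= treat_age[ki]
      u_c[dsel] <- ut$distant_clinical
      asel <- ae_flag[ki] & ka >= treat_age[ki] &
        ka < treat_age[ki] + tr$ae_duration
      u_c[asel] <- u_c[asel] * ae_f[ki[asel]]
      adj <- u_c * (exp(lw[, 1]) - 1)
      padj <- rowsum(adj, ki)
      pid <- as.numeric(rownames(padj))
      qaly[pid] <- qaly[pid] + padj[, 1]
    }
  }
  life_days <- death_age * dpy
  qald <- pmin(pmax(qaly * dpy, 0), life_days)

  list(strategy = strategy$name, n_screens = length(strategy$ages),
       surveillance = strategy$surveillance,
       diagnosed = diagnosed, mode_screen = mode_screen,
       dx_age = dx_age, dx_state = dx_state,
       as_flag = as_flag, as_biopsies = as_biopsies,
       treated = treated, treat_age = treat_age, treat_state = treat_state,
       proc = stage, cured = cured, periop = periop,
       ae_count = ae_count,
       psa_tests = psa_tests, fp_tests = fp_tests,
       death_age = death_age, cause = cause,
       life_days = life_days, qald = qald)
}

#' Simulate one man
#'
#' Convenience wrapper running the cohort engine with `n = 1`; useful for
#' tracing a single trajectory reproducibly.
#'
#' @inheritParams cohort_context
#' @param strategy A [strategy_spec()].
#' @param postdx Post-diagnosis death probabilities by state.
#' @return The per-person ledger of [simulate_strategy()] with scalar fields.
#' @export
simulate_person <- function(params, strategy, seed,
                            life_table = synthetic_life_table(),
                            postdx = synthetic_postdx_rates()) {
  ctx <- cohort_context(params, 1L, seed, life_table)
  simulate_strategy(ctx, strategy, postdx)
}
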
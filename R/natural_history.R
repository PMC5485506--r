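# Latent disease trajectories.
#
# A trajectory is the sequence of latent states a man would traverse absent
# any intervention: onset (exit from "no cancer" into localized/G<7), then up
# to four stage/grade progressions, and possibly the terminal exit from
# distant/G>7. Sojourn times in each state follow the state's mixture-cure
# Weibull exit distribution, discretized to annual cycles via the exact
# conditional per-cycle probability. The familial risk factor scales the
# onset hazard when `fr_on_onset` and the progression hazards when
# `fr_on_progression`.

.fr_effective <- function(nh) {
  c(onset = if (nh$fr_on_onset) nh$fr else 1,
    progression = if (nh$fr_on_progression) nh$fr else 1)
}

# survivor tables S_fr(0..tmax): list(no_cancer = vector, states = matrix).
# For the default "discrete" convention this is the exact fr-scaled mixture
# survivor; for "pointwise" it is the product of per-cycle survival under the
# midpoint-hazard probabilities, so both conventions feed the same sampler.
.survivor_tables <- function(params, tmax = 121) {
  nh <- params$natural_history
  fr <- .fr_effective(nh)
  one <- function(exit, frx) {
    if (identical(nh$cycle_method, "pointwise")) {
      q <- cycle_exit_probability(exit, frx, 0:(tmax - 1), "pointwise")
      c(1, cumprod(1 - q))
    } else {
      .survivor_table(exit, frx, tmax)
    }
  }
  list(no_cancer = one(nh$exit$no_cancer, fr[["onset"]]),
       states = vapply(.STATE_KEYS, function(k)
         one(nh$exit[[k]], fr[["progression"]]), numeric(tmax + 1)))
}

# vectorized destination-state rule (s in 1..9)
.next_state_vec <- function(s, ub, split_vec) {
  stage <- (s - 1L) %/% 3L + 1L
  grade <- (s - 1L) %% 3L + 1L
  out <- integer(length(s))
  out[s == 9L] <- 10L
  k <- s >= 1L & s <= 8L
  stage_move <- grade == 3L | ub < split_vec[pmax(s, 1L)]
  stage_move[stage == 3L] <- FALSE
  out[k] <- ifelse(stage_move[k], s[k] + 3L, s[k] + 1L)
  out
}

# Sample n complete latent trajectories from substreams of `seed`.
# Returns entry/state matrices (n x 6 slots; slot 1 = onset into state 1,
# slot 6 can only be the untreated-death exit), plus onset and untreated
# cancer death ages (Inf when the event does not occur by the horizon).
sample_latent_histories <- function(n, seed, params) {
  nh <- params$natural_history
  S <- .survivor_tables(params)
  split_vec <- .stage_split_vector(nh)
  u0 <- substream_runif(n, seed, .PUR$latent_soj, 0L)
  onset <- sample_sojourn(u0, S$no_cancer)
  entry <- matrix(Inf, n, 6)
  state <- matrix(0L, n, 6)
  entry[, 1] <- onset
  state[, 1] <- 1L
  for (k in 1:5) {
    us <- substream_runif(n, seed, .PUR$latent_soj, k)
    ub <- substream_runif(n, seed, .PUR$latent_br, k)
    s <- state[, k]
    active <- is.finite(entry[, k]) & s >= 1L & s <= 9L
    soj <- rep(Inf, n)
    for (code in sort(unique(s[active]))) {
      idx <- active & s == code
      soj[idx] <- sample_sojourn(us[idx], S$states[, code])
    }
    nxt <- .next_state_vec(s, ub, split_vec)
    entry[, k + 1] <- ifelse(active, entry[, k] + soj, Inf)
    state[, k + 1] <- nxt
  }
  untreated_death <- ifelse(state[, 6] == 10L & is.finite(entry[, 6]),
                            entry[, 6], Inf)
  list(entry = entry, state = state, onset = onset,
       untreated_death = untreated_death, n = n)
}

#' Sample one latent disease trajectory
#'
#' Reference single-person sampler: walks annual cycles with
#' [cycle_exit_probability()] draws and resolves exits with
#' [next_latent_state()]. The cohort engine uses an equivalent vectorized
#' inverse-CDF sampler; this readable version is the one to study (and the
#' one the tests compare the engine against).
#'
#' @param params A `ps_params` object.
#' @param max_age Horizon in years (default 120).
#' @return A `data.frame` with one row per transition: `age`, `from`, `to`
#'   (state labels). Zero rows if onset does not occur before `max_age`.
#' @export
#' @examples
#' set.seed(1)
#' sample_latent_history(default_parameters())
sample_latent_history <- function(params, max_age = params$max_age) {
  stopifnot(max_age <= 120)
  nh <- params$natural_history
  fr <- .fr_effective(nh)
  trans <- list()
  state <- 0L
  tis <- 0L
  for (age in 1:max_age) {
    exit <- if (state == 0L) nh$exit$no_cancer else nh$exit[[.STATE_KEYS[state]]]
    frx <- if (state == 0L) fr[["onset"]] else fr[["progression"]]
    if (stats::runif(1) < cycle_exit_probability(exit, frx, tis,
                                                 nh$cycle_method)) {
      nxt <- next_latent_state(state, stats::runif(1), params)
      trans[[length(trans) + 1L]] <-
        data.frame(age = age, from = state_label(state),
                   to = state_label(nxt), stringsAsFactors = FALSE)
      if (nxt == 10L) break
      state <- nxt
      tis <- 0L
    } else {
      tis <- tis + 1L
    }
  }
  if (!length(trans))
    return(data.frame(age = integer(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  do.call(rbind, trans)
}
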
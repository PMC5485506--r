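# Per-cycle utility model.
#
# A lived cycle's utility starts from the age-specific baseline; men living
# with clinically detected distant cancer use the distant-state utility
# (0.6) in place of the baseline; long-term treatment adverse events
# multiply in as (1 - m * (1 - u_ae)) each, where m is the disutility
# preference multiplier; short-term events (biopsy, RP, RT, terminal
# disease) multiply the cycle's utility by their one-time relative weights.

baseline_utility <- function(params, age) {
  bt <- params$utilities$baseline
  idx <- findInterval(pmin(age, max(bt$age)), bt$age)
  bt$utility[pmax(idx, 1L)]
}

#' Utility of one annual cycle
#'
#' @param age Age during the cycle, years.
#' @param params A `ps_params` object.
#' @param clinical_distant Living with clinically detected distant cancer
#'   (replaces the age baseline by the distant-state utility).
#' @param active_aes Character vector of active long-term adverse events as
#'   `"procedure:event"`, e.g. `c("RP:ED", "RP:UI")`.
#' @param one_time_events Character vector of this-cycle events among
#'   `"biopsy"`, `"RP"`, `"RT"`, `"terminal"` (repeats allowed, e.g. two
#'   biopsies).
#' @return Utility in `[0, 1]`.
#' @export
#' @examples
#' p <- default_parameters()
#' annual_utility(62, p, one_time_events = c("RP", "biopsy"))
annual_utility <- function(age, params, clinical_distant = FALSE,
                           active_aes = character(0),
                           one_time_events = character(0)) {
  ut <- params$utilities
  u <- if (clinical_distant) ut$distant_clinical else baseline_utility(params, age)
  m <- ut$disutility_multiplier
  for (ae in active_aes) {
    parts <- strsplit(ae, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(ut$ae_utility) ||
        !parts[2] %in% names(ut$ae_utility[[parts[1]]]))
      stop("unknown adverse-event key: ", ae)
    u_ae <- ut$ae_utility[[parts[1]]][[parts[2]]]
    u <- u * max(0, min(1, 1 - m * (1 - u_ae)))
  }
  for (ev in one_time_events) {
    if (!ev %in% names(ut$one_time)) stop("unknown one-time event key: ", ev)
    u <- u * ut$one_time[[ev]]
  }
  max(0, min(1, u))
}

# effective multiplicative AE utility factor for a person, given drawn events
# (logical vectors) and the disutility multiplier
.ae_factor <- function(proc_is_rp, ed, ui, bd, params) {
  ut <- params$utilities
  m <- ut$disutility_multiplier
  f_of <- function(u_ae) pmax(0, pmin(1, 1 - m * (1 - u_ae)))
  aeu <- ut$ae_utility
  f <- rep(1, length(ed))
  for (ev in c("ED", "UI", "BD")) {
    drawn <- switch(ev, ED = ed, UI = ui, BD = bd)
    u_ev <- ifelse(proc_is_rp, aeu$RP[[ev]], aeu$RT[[ev]])
    f <- f * ifelse(drawn, f_of(u_ev), 1)
  }
  f
}

# cumulative baseline quality-adjusted years: CB[a + 1] = sum of baseline
# utilities over cycles 0..a-1
.cumulative_baseline <- function(params, max_age = 120) {
  c(0, cumsum(baseline_utility(params, 0:(max_age - 1))))
}
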
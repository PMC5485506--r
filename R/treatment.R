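# Treatment at diagnosis and active-surveillance eligibility.
#
# Treatment is homogeneous and stage-specific: radical prostatectomy (RP)
# for localized, radiotherapy (RT) for regional, androgen deprivation (ADT,
# palliative) for distant disease. Curative treatment succeeds with a
# grade-specific probability (scaled by the cure multiplier); RP carries a
# small peri-operative mortality; RP/RT can cause long-term erectile
# dysfunction (ED), urinary incontinence (UI) and bowel dysfunction (BD).

.PROCS <- c("RP", "RT", "ADT")

procedure_for_stage <- function(stage) .PROCS[stage]

#' Simulate treatment at diagnosis
#'
#' Draws cure, peri-operative death and adverse events for men diagnosed in
#' a given state. Cure probabilities apply to localized/regional disease by
#' grade, scaled by `cure_multiplier` and clamped to `[0, 1]`; distant
#' disease is never cured. Adverse events are drawn independently per
#' (procedure, event) and persist `ae_duration` years.
#'
#' @param state Integer state code 1..9 at treatment.
#' @param params A `ps_params` object.
#' @param n Number of independent treatment draws.
#' @return A `data.frame` with columns `procedure` (`"RP"/"RT"/"ADT"`),
#'   `cured`, `periop_death`, `ED`, `UI`, `BD`.
#' @export
#' @examples
#' set.seed(1)
#' colMeans(treat_at_diagnosis(1L, default_parameters(), n = 1e4)[-1])
treat_at_diagnosis <- function(state, params, n = 1) {
  state <- as.integer(state)
  if (length(state) != 1L || state < 1L || state > 9L)
    stop("`state` must be a single diagnosed cancer state code in 1..9")
  tr <- params$treatment
  stage <- state_stage(state)
  grade <- state_grade(state)
  proc <- procedure_for_stage(stage)
  periop <- if (proc == "RP")
    stats::runif(n) < tr$rp_periop_mortality else rep(FALSE, n)
  cure_p <- if (proc == "ADT") tr$cure_distant else
    min(1, tr$cure_by_grade[[grade]] * tr$cure_multiplier)
  cured <- !periop & stats::runif(n) < cure_p
  if (proc %in% c("RP", "RT")) {
    risk <- tr$ae_risk[[proc]]
    ed <- !periop & stats::runif(n) < risk[["ED"]]
    ui <- !periop & stats::runif(n) < risk[["UI"]]
    bd <- !periop & stats::runif(n) < risk[["BD"]]
  } else {
    ed <- ui <- bd <- rep(FALSE, n)
  }
  data.frame(procedure = rep(proc, n), cured = cured, periop_death = periop,
             ED = ed, UI = ui, BD = bd, stringsAsFactors = FALSE)
}

#' Active-surveillance eligibility
#'
#' Men are managed by active surveillance instead of immediate treatment iff
#' surveillance is enabled and the cancer is screen-detected, localized and
#' low grade (Gleason < 7). All other diagnoses are treated immediately.
#'
#' @param mode Diagnosis mode, `"screen"` or `"clinical"`.
#' @param state Integer state code at diagnosis.
#' @param params A `ps_params` object.
#' @return Logical.
#' @export
surveillance_eligible <- function(mode, state, params) {
  params$surveillance$enabled & mode == "screen" & as.integer(state) == 1L
}
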
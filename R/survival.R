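# Other-cause mortality (period life table) and post-diagnosis cancer
# survival (pluggable annual death probabilities).

#' Read a period life table from CSV
#'
#' Expects a header and two columns, `age` and `q` (annual probability of
#' death). Ages must be contiguous from 0; ages beyond the table reuse the
#' last tabulated `q`; the engine enforces its 120-year horizon regardless.
#'
#' @param file Path to the CSV.
#' @return A validated `data.frame` with columns `age`, `q`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(synthetic_life_table(), f, row.names = FALSE)
#' lt <- read_life_table(f)
read_life_table <- function(file) {
  lt <- utils::read.csv(file)
  if (!all(c("age", "q") %in% names(lt)))
    stop("life table must have columns 'age' and 'q'")
  bad <- which(!is.finite(lt$q) | lt$q < 0 | lt$q > 1)
  if (length(bad))
    stop("life table row ", bad[1], " (age ", lt$age[bad[1]],
         "): q must be a probability in [0,1]")
  if (lt$age[1] != 0 || any(diff(lt$age) != 1)) {
    gap <- which(diff(lt$age) != 1)
    stop("life table ages must be contiguous from 0 (problem near row ",
         if (length(gap)) gap[1] + 1 else 1, ")")
  }
  if (max(lt$age) < 100)
    stop("life table must extend to age 100 or beyond")
  lt[c("age", "q")]
}

# annual q extended to ages 0..119 (+ certain death at the horizon)
.lt_q_vector <- function(life_table, max_age = 120) {
  q <- life_table$q[match(0:(max_age - 1), life_table$age)]
  last <- life_table$q[nrow(life_table)]
  q[is.na(q)] <- last
  q
}

# inverse-CDF sample of other-cause death ages (age at start of death cycle);
# survivors of all 120 cycles get death age 120 (the horizon)
sample_other_cause_death <- function(n, seed, life_table, max_age = 120) {
  q <- .lt_q_vector(life_table, max_age)
  S <- cumprod(1 - q)                  # S[a] = P(alive after cycle a-1)
  u <- substream_runif(n, seed, .PUR$oc)
  # death age = number of cycles survived = #{a : S[a] > u}
  max_age - findInterval(u, rev(S))
}

#' Post-diagnosis cancer death draw probability
#'
#' Annual probability that a diagnosed, not-cured man dies of prostate
#' cancer, given the stage/grade state at treatment. The default model is
#' the synthetic constant-rate fixture ([synthetic_postdx_rates()]); cured
#' men are never at risk.
#'
#' @param state Integer state code 1..9 at treatment.
#' @param cured Logical; cured men have probability 0.
#' @param postdx Rates vector as returned by [synthetic_postdx_rates()].
#' @return Annual death probability.
#' @export
postdx_death_prob <- function(state, cured = FALSE, postdx = synthetic_postdx_rates()) {
  stopifnot(all(state >= 1L & state <= 9L))
  ifelse(cured, 0, as.numeric(postdx)[state])
}
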
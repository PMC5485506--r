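# Disease-state coding and the latent progression lattice.
#
# Latent prostate cancer occupies one of 9 states on a stage x grade lattice:
# stage in {localized, regional, distant}, grade in {G<7, G=7, G>7}. State 0
# is "no cancer"; code 10 marks exit from (distant, G>7), interpreted as death
# from untreated cancer. Stage and grade never regress.

.STAGES <- c("localized", "regional", "distant")
.GRADES <- c("G<7", "G=7", "G>7")

#' Disease state codes
#'
#' Cancer states are encoded as `(stage - 1) * 3 + grade` with stage
#' 1 = localized, 2 = regional, 3 = distant and grade 1 = `G<7`, 2 = `G=7`,
#' 3 = `G>7`; 0 encodes "no cancer" and 10 death from untreated cancer.
#'
#' @return Named integer vector mapping state labels (e.g.
#'   `"localized/G<7"`) to codes 1..9.
#' @export
#' @examples
#' pca_states()
pca_states <- function() {
  codes <- 1:9
  names(codes) <- paste(rep(.STAGES, each = 3), rep(.GRADES, 3), sep = "/")
  codes
}

state_stage <- function(code) {
  ifelse(code >= 1L & code <= 9L, (code - 1L) %/% 3L + 1L, NA_integer_)
}

state_grade <- function(code) {
  ifelse(code >= 1L & code <= 9L, (code - 1L) %% 3L + 1L, NA_integer_)
}

state_label <- function(code) {
  lab <- rep(NA_character_, length(code))
  lab[code == 0L] <- "none"
  lab[code == 10L] <- "dead-untreated-pca"
  k <- code >= 1L & code <= 9L
  lab[k] <- names(pca_states())[code[k]]
  lab
}

# stage-progression probability on exit, by state code; NA where the move is
# forced (grade G>7 always progresses in stage; distant always in grade,
# except distant/G>7 which exits to untreated cancer death)
.stage_split_vector <- function(nh) {
  sp <- nh$stage_split
  c(sp[["localized_Glt7"]], sp[["localized_Geq7"]], 1,
    sp[["regional_Glt7"]], sp[["regional_Geq7"]], 1,
    0, 0, NA)
}

#' Next latent state on exit
#'
#' Resolves the destination of a state exit. From `(localized|regional,
#' G<7|G=7)` the exit is a stage progression (same grade) with the printed
#' stage-split probability and a grade progression (same stage) otherwise;
#' from `(localized|regional, G>7)` it is always a stage progression; from
#' `(distant, G<7|G=7)` always a grade progression; the exit from
#' `(distant, G>7)` is death from untreated cancer. The exit from "no cancer"
#' enters the lattice at `(localized, G<7)`.
#'
#' @param state Integer state code (0 = no cancer, 1..9 cancer states).
#' @param split_draw Uniform draw in `[0,1]` deciding stage vs grade moves.
#' @param params A parameter set (see [default_parameters()]).
#' @return Integer code of the destination state.
#' @export
#' @examples
#' p <- default_parameters()
#' next_latent_state(pca_states()[["localized/G<7"]], 0.10, p) # -> regional/G<7
next_latent_state <- function(state, split_draw, params) {
  state <- as.integer(state)
  if (length(state) != 1L || is.na(state) || state < 0L || state > 9L)
    stop("`state` must be a single code in 0..9 (latent cancer or no cancer)")
  if (state == 0L) return(1L)
  stage <- state_stage(state); grade <- state_grade(state)
  if (stage == 3L && grade == 3L) return(10L)
  split <- .stage_split_vector(params$natural_history)[state]
  stage_move <- if (is.na(split)) FALSE else (grade == 3L || split_draw < split)
  if (stage < 3L && stage_move) state + 3L else state + 1L
}
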
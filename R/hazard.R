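# Mixture-cure Weibull exit-time machinery.
#
# Each latent state's exit time follows a mixture-cure Weibull distribution:
# a fraction p of occupants is at risk of exiting, with Weibull(shape a,
# scale b) exit times; the remaining 1 - p never exit. The familial risk
# factor fr scales the hazard, so the survivor function of the scaled process
# is S(t)^fr where S(t) = 1 - p * (1 - exp(-(t/b)^a)).

#' Mixture-cure Weibull exit hazard
#'
#' Continuous-time hazard of leaving a latent state after `t` years in it:
#' \deqn{h(t) = fr \; \frac{p\,(a/b)(t/b)^{a-1} e^{-(t/b)^a}}
#'   {1 - p\,(1 - e^{-(t/b)^a})}}
#' where `p` is the fraction at risk of exiting, `a` the Weibull shape,
#' `b` the Weibull scale (years) and `fr` the familial risk factor.
#'
#' @param exit Numeric vector `c(p, scale, shape)` (or a list with those
#'   names) describing the state's exit distribution.
#' @param fr Familial risk factor (non-negative hazard multiplier).
#' @param t Time in state, years (vectorized, `t >= 0`).
#' @return Non-negative hazard per year. For `shape < 1` the hazard at
#'   `t = 0` is `Inf` (the Weibull density pole); for `shape > 1` it is 0.
#' @export
#' @examples
#' mixture_hazard(c(0.838, 80.427, 8.448), fr = 1, t = 60)
mixture_hazard <- function(exit, fr = 1, t) {
  ex <- .as_exit(exit)
  stopifnot(fr >= 0, all(t >= 0))
  p <- ex[1]; b <- ex[2]; a <- ex[3]
  z <- (t / b)^a
  # (t/b)^(a-1) at t = 0: 0 for a > 1, 1/b-scaled pole for a < 1
  base <- (a / b) * (t / b)^(a - 1)
  if (p == 1) {
    h <- fr * base
  } else {
    # denominator written as (1-p)/E + p with E = exp(-z): stable for large t
    h <- fr * p * base / ((1 - p) * exp(z) + p)
  }
  h[t == 0 & a < 1] <- Inf
  h
}

# survivor function of the fr-scaled mixture: S_fr(t) = S(t)^fr
mixture_survivor <- function(exit, fr = 1, t) {
  ex <- .as_exit(exit)
  p <- ex[1]; b <- ex[2]; a <- ex[3]
  (1 - p * (1 - exp(-(t / b)^a)))^fr
}

#' Per-cycle exit probability
#'
#' Converts the continuous mixture-cure hazard into the probability of
#' leaving the state during annual cycle `t` (from `t` to `t + 1` years in
#' state). The default `"discrete"` method is exact: it is the conditional
#' probability `1 - (S(t+1)/S(t))^fr` implied by the mixture survivor
#' function with the familial factor applied on the hazard scale. The
#' `"pointwise"` method instead evaluates the continuous hazard at the cycle
#' midpoint and truncates at 1.
#'
#' @inheritParams mixture_hazard
#' @param t Integer cycle index (years already spent in state), `t >= 0`.
#' @param method `"discrete"` (default) or `"pointwise"`.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' cycle_exit_probability(c(0.449, 2.041, 8.431), fr = 1, t = 0:5)
cycle_exit_probability <- function(exit, fr = 1, t,
                                   method = c("discrete", "pointwise")) {
  method <- match.arg(method)
  stopifnot(fr >= 0, all(t >= 0))
  if (method == "discrete") {
    s0 <- mixture_survivor(exit, fr = 1, t)
    s1 <- mixture_survivor(exit, fr = 1, t + 1)
    q <- 1 - (s1 / s0)^fr
  } else {
    q <- pmin(1, mixture_hazard(exit, fr, t + 0.5))
  }
  pmin(pmax(q, 0), 1)
}

.as_exit <- function(exit) {
  if (is.list(exit)) exit <- c(exit$p, exit$scale, exit$shape)
  exit <- as.numeric(exit)
  if (length(exit) != 3 || anyNA(exit))
    stop("`exit` must supply p, scale and shape")
  if (exit[1] < 0 || exit[1] > 1) stop("exit fraction p must be in [0, 1]")
  if (exit[2] <= 0) stop("Weibull scale must be positive")
  if (exit[3] <= 0) stop("Weibull shape must be positive")
  exit
}

# S_fr(t) at t = 0..tmax for one state; used by the samplers
.survivor_table <- function(exit, fr, tmax) {
  mixture_survivor(exit, fr = fr, t = 0:tmax)
}

# Inverse-CDF sojourn sampling. S is the fr-scaled survivor at t = 0..Tmax
# (S[1] = 1, non-increasing). Returns integer sojourns in 1..Tmax, or Inf if
# the exit falls beyond Tmax (censored at the horizon / cured fraction).
sample_sojourn <- function(u, S) {
  tmax <- length(S) - 1L
  inc <- rev(S[-1])                       # S_fr(Tmax..1), non-decreasing
  n_le <- findInterval(u, inc)            # t with S_fr(t) <= u
  soj <- (tmax - n_le) + 1
  soj[soj > tmax] <- Inf
  soj
}
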
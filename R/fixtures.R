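# Synthetic stand-ins for the three external model inputs that are not
# printed in any parameter table: the period life table for other-cause
# mortality, the post-diagnosis cancer survival model, and the age-specific
# baseline utility table. All three are clearly labeled synthetic; swapping
# in real tables changes numbers, not code paths.

#' Synthetic period life table (Gompertz-Makeham)
#'
#' Annual all-cause death probabilities
#' `q(age) = 1 - exp(-(A + B * c^age))`, a Gompertz-Makeham schedule. The
#' defaults are tuned so that survival from birth to age 55 is about 0.93 and
#' period life expectancy about 78 years, the ballpark of a recent Western
#' European male life table. This is a synthetic approximation, not official
#' life-table data; for exact reproduction of published results substitute a
#' real national male life table via [read_life_table()].
#'
#' @param A Makeham (age-independent) hazard component, `>= 0`.
#' @param B Gompertz baseline hazard, `> 0` (unless building a zero-mortality
#'   table with `A = B = 0` for analytic tests).
#' @param c Gompertz rate of aging, `> 1`.
#' @param max_age Last tabulated age; `q` is forced to 1 there.
#' @return A `data.frame` with columns `age` (0..`max_age`) and `q`, carrying
#'   attribute `synthetic = TRUE`.
#' @export
#' @examples
#' lt <- synthetic_life_table()
#' prod(1 - lt$q[lt$age < 55]) # survival to age 55, about 0.93
synthetic_life_table <- function(A = 4e-4, B = 3e-5, c = 1.10, max_age = 120) {
  stopifnot(A >= 0, B >= 0, c > 1 || B == 0, max_age >= 100)
  age <- 0:max_age
  q <- 1 - exp(-(A + B * c^age))
  q <- pmin(pmax(q, 0), 1)
  q[length(q)] <- 1
  lt <- data.frame(age = age, q = q)
  attr(lt, "synthetic") <- TRUE
  lt
}

#' Synthetic post-diagnosis cancer survival model
#'
#' Constant annual probabilities of dying from prostate cancer for diagnosed,
#' not-cured men, by stage and grade at treatment. Registry-derived
#' conditional survival (the input the model is designed to take) is not
#' printed in any parameter table, so these are plausible synthetic
#' magnitudes ordered `distant > regional > localized` and `G>7 > G=7 > G<7`;
#' they are not registry estimates.
#'
#' @param rates Named numeric vector of 9 annual death probabilities, one per
#'   stage/grade state (names as in [pca_states()] with `/` replaced by the
#'   defaults shown below). Override to plug in a real survival model.
#' @return Numeric vector of length 9 (indexed by state code 1..9) with
#'   attribute `synthetic = TRUE`.
#' @export
#' @examples
#' synthetic_postdx_rates()
synthetic_postdx_rates <- function(rates = c(
    localized_Glt7 = 0.005, localized_Geq7 = 0.015, localized_Ggt7 = 0.04,
    regional_Glt7 = 0.02, regional_Geq7 = 0.05, regional_Ggt7 = 0.10,
    distant_Glt7 = 0.20, distant_Geq7 = 0.25, distant_Ggt7 = 0.30)) {
  stopifnot(length(rates) == 9, all(rates >= 0), all(rates <= 1))
  r <- as.numeric(rates)
  names(r) <- names(rates)
  attr(r, "synthetic") <- TRUE
  r
}

#' Synthetic age-specific baseline utility table
#'
#' Piecewise-linear general-population male utilities: 1.00 up to age 35,
#' declining linearly to 0.78 at age 90 and constant thereafter. The model's
#' documented input is an age-specific table spanning 1 to 0.78 whose exact
#' values are not printed, so this interpolation is a synthetic stand-in.
#'
#' @param max_age Last tabulated age.
#' @return A `data.frame` with columns `age` and `utility`, attribute
#'   `synthetic = TRUE`.
#' @export
#' @examples
#' head(synthetic_utility_table())
synthetic_utility_table <- function(max_age = 120) {
  age <- 0:max_age
  u <- ifelse(age <= 35, 1,
       ifelse(age >= 90, 0.78, 1 - (1 - 0.78) * (age - 35) / (90 - 35)))
  ut <- data.frame(age = age, utility = u)
  attr(ut, "synthetic") <- TRUE
  ut
}

#' Write the synthetic fixture tables to CSV
#'
#' Emits `life_table_synthetic.csv`, `postdx_rates_synthetic.csv` and
#' `utility_table_synthetic.csv` into `dir`.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lt <- synthetic_life_table()
  pr <- synthetic_postdx_rates()
  ut <- synthetic_utility_table()
  paths <- file.path(dir, c("life_table_synthetic.csv",
                            "postdx_rates_synthetic.csv",
                            "utility_table_synthetic.csv"))
  utils::write.csv(lt, paths[1], row.names = FALSE)
  utils::write.csv(data.frame(state = names(pr), rate = as.numeric(pr)),
                   paths[2], row.names = FALSE)
  utils::write.csv(ut, paths[3], row.names = FALSE)
  invisible(paths)
}
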
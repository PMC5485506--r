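# Independent deterministic cohort oracle: propagates occupancy mass over
# (latent state, time-in-state) in annual cycles with the same per-cycle
# probabilities the parameters imply, no screening. Written directly from
# the model description, independently of the sampling engine.

cohort_oracle <- function(params, life_table = synthetic_life_table(),
                          postdx = synthetic_postdx_rates()) {
  q_oc <- prostasim:::.lt_q_vector(life_table)
  nh <- params$natural_history
  states <- c("no_cancer", prostasim:::.STATE_KEYS)
  qx <- sapply(states, function(k)
    cycle_exit_probability(nh$exit[[k]], nh$fr, 0:120, nh$cycle_method))
  clin <- c(0, unname(params$detection$clinical_detect[prostasim:::.STATE_KEYS]))
  splitv <- prostasim:::.stage_split_vector(nh)
  tr <- params$treatment
  occ <- matrix(0, 10, 122)  # rows: no-cancer + 9 states; cols: tis 0..121
  occ[1, 1] <- 1
  cured_mass <- 0
  noncured <- rep(0, 9)
  dead_pca <- dead_rp <- dx_total <- 0
  for (a in 0:119) {
    qa <- q_oc[a + 1]
    occ <- occ * (1 - qa)
    cured_mass <- cured_mass * (1 - qa)
    noncured <- noncured * (1 - qa)
    d <- noncured * as.numeric(postdx)
    dead_pca <- dead_pca + sum(d)
    noncured <- noncured - d
    for (s in 2:10) {
      det <- occ[s, ] * clin[s]
      mass <- sum(det)
      if (mass > 0) {
        occ[s, ] <- occ[s, ] - det
        dx_total <- dx_total + mass
        code <- s - 1
        stage <- (code - 1) %/% 3 + 1
        grade <- (code - 1) %% 3 + 1
        periop <- if (stage == 1) tr$rp_periop_mortality else 0
        dead_rp <- dead_rp + mass * periop
        mass <- mass * (1 - periop)
        cure_p <- if (stage == 3) tr$cure_distant else
          min(1, tr$cure_by_grade[[grade]] * tr$cure_multiplier)
        cured_mass <- cured_mass + mass * cure_p
        noncured[code] <- noncured[code] + mass * (1 - cure_p)
      }
    }
    newocc <- matrix(0, 10, 122)
    for (s in 1:10) {
      ex <- occ[s, 1:121] * qx[1:121, s]
      newocc[s, 2:122] <- occ[s, 1:121] - ex
      tot_ex <- sum(ex)
      if (tot_ex > 0) {
        if (s == 1) {
          newocc[2, 1] <- newocc[2, 1] + tot_ex
        } else {
          code <- s - 1
          if (code == 9) {
            dead_pca <- dead_pca + tot_ex  # untreated terminal exit
          } else {
            stage <- (code - 1) %/% 3 + 1
            grade <- (code - 1) %% 3 + 1
            sp <- if (stage == 3) 0 else if (grade == 3) 1 else splitv[code]
            if (sp > 0)
              newocc[1 + code + 3, 1] <- newocc[1 + code + 3, 1] + tot_ex * sp
            if (sp < 1)
              newocc[1 + code + 1, 1] <- newocc[1 + code + 1, 1] + tot_ex * (1 - sp)
          }
        }
      }
    }
    occ <- newocc
  }
  list(dx_risk = 100 * dx_total, pca_death_risk = 100 * dead_pca,
       rp_deaths_per_10k = 1e4 * dead_rp)
}

# direct transcription of the continuous mixture-cure hazard formula,
# independent of the package's algebra
hazard_transcription <- function(p, b, a, fr, t) {
  fr * (p * ((a / b) * (t / b)^(a - 1) * exp(-(t / b)^a))) /
    (1 - p * (1 - exp(-(t / b)^a)))
}
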
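# Deterministic substream seeding.
#
# The engine draws every random quantity from a substream identified by
# (base seed, purpose, cycle). Substream seeds are derived with an integer
# LCG hash computed exactly in double arithmetic (all intermediates < 2^53),
# so a run is reproducible from the base seed alone and two strategies that
# consume the same (purpose, cycle) stream see identical uniforms for every
# person -- the common-random-numbers contract.

# purpose ids (cycle component is 0 for person-level streams)
.PUR <- list(
  oc          = 1L,   # other-cause death inversion
  latent_soj  = 10L,  # + slot index 0..5: sojourn-time draws
  latent_br   = 20L,  # + slot index 1..5: stage-vs-grade branch draws
  clin        = 30L,  # per-cycle clinical detection
  psa         = 40L,  # per-cycle PSA positivity
  biopsy      = 41L,  # per-cycle diagnostic biopsy
  cure        = 50L,  # cure at treatment
  periop      = 51L,  # peri-operative RP death
  ae_ed       = 52L,
  ae_ui       = 53L,
  ae_bd       = 54L,
  asbx        = 60L,  # per-cycle active-surveillance biopsy
  pcad        = 70L   # post-diagnosis survival inversion
)

.M31 <- 2147483647

substream_seed <- function(seed, purpose, cycle = 0L) {
  h <- as.double(seed) %% .M31
  h <- (h * 69069 + as.double(purpose)) %% .M31
  h <- (h * 69069 + as.double(cycle)) %% .M31
  as.integer(h)
}

# n uniforms from the (seed, purpose, cycle) substream, indexed by person
substream_runif <- function(n, seed, purpose, cycle = 0L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, purpose, cycle))
  stats::runif(n)
}
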
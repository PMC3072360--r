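# Shared, lazily computed synthetic ensembles. The heavy simulations (10+10
# single-state cells, 10 transition recordings; 900 frames each) are reused
# across the module tests and the acceptance suite.

md_cache <- new.env(parent = emptyenv())

# canonical study-condition seed sets
ENSEMBLE_SEEDS <- list(idling = 1000 + 1:10, treadmilling = 1100 + 1:10)
TRANSITION_SEEDS <- 7000 + 1:10

ensemble_data <- function() {
  if (is.null(md_cache$ens)) {
    sim <- function(state, seeds) lapply(seeds, function(s)
      simulate_roundness_series(synthetic_params(state, seed = s), feret = FALSE))
    ser <- list(idling = sim("idling", ENSEMBLE_SEEDS$idling),
                treadmilling = sim("treadmilling", ENSEMBLE_SEEDS$treadmilling))
    md_cache$ens <- list(
      series = ser,
      measures = lapply(ser, function(g) lapply(g, measure_battery))
    )
  }
  md_cache$ens
}

transition_data <- function() {
  if (is.null(md_cache$tra)) {
    runs <- lapply(TRANSITION_SEEDS, function(s) {
      rs <- simulate_roundness_series(synthetic_params("transition", seed = s),
                                      feret = FALSE)
      sc <- morlet_cwt(rs)
      tp <- transition_profile(sc)
      sw <- attr(rs, "truth")$t_switch
      list(series = rs, change_point = tp$change_point,
           slow_pre = mean(tp$slow_band[1:sw]),
           slow_post = mean(tp$slow_band[(sw + 1):rs$n]),
           t_switch = sw)
    })
    md_cache$tra <- runs
  }
  md_cache$tra
}
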
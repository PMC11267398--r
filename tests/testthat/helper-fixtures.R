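## shared fixtures: everything is generated in code at test time

## short trial: 2 h baseline in two 1 h blocks + 1 h recovery, 5/5 cycles
tiny_protocol <- function(...) {
  protocol_schedule(baseline_hours = 2, n_baseline_blocks = 2,
                    recovery_hours = 1, sample_interval_s = 60, ...)
}

tiny_design <- function(n_pairs = 2, n_social_recovery = 1, seed = 1, ...) {
  study_design(n_pairs = n_pairs, n_social_recovery = n_social_recovery,
               seed = seed, ...)
}

## noiseless effects with no biological variation: truth is deterministic
clean_effects <- function(...) {
  effect_config(trace_noise_sd = 0,
                process_cv = list(pair = 0, routine = 0, mmr = 0, k = 0),
                ...)
}

## MO2 series sampled from an exponential recovery R + (M - R) e^(-k t);
## t_mid_s measured on a trial clock with the chase ending at chase_end_s
decay_series <- function(R, M, k_per_h, chase_end_s = 0, cycle_min = 5,
                         hours = 6) {
  mids <- seq(cycle_min * 60 / 2, hours * 3600, by = cycle_min * 2 * 60)
  t_s <- chase_end_s + mids
  data.frame(t_mid_s = t_s,
             mo2 = R + (M - R) * exp(-k_per_h * mids / 3600),
             qc_pass = TRUE,
             period_index = seq_along(mids))
}

## balanced status x treatment metric data with known cell means,
## no pair/fish variance unless sd > 0
balanced_metric_data <- function(cell_means, n_per_cell = 4, sd = 0,
                                 seed = 1) {
  grid <- expand.grid(status = c("dominant", "subordinate"),
                      treatment = c("social", "isolation"),
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  grid$pair_id <- paste0("P", grid$rep)
  grid$fish_id <- paste0(grid$pair_id, "_", substr(grid$status, 1, 1),
                         "_", substr(grid$treatment, 1, 1))
  mu <- cell_means[cbind(grid$status, grid$treatment)]
  set.seed(seed)
  grid$value <- mu + rnorm(nrow(grid), 0, sd)
  grid$mass_g <- 8 + rnorm(nrow(grid), 0, 0.5)
  grid
}
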
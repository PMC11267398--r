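#' True (noise-free) metabolic rate of one fish
#'
#' The deterministic oxygen-consumption process underlying the simulator.
#' During baseline, MO2 is the allometric routine level modulated by the
#' circadian light cycle and any status x treatment baseline multiplier.
#' During recovery it decays single-exponentially from the fish's maximum
#' towards its treatment-matched routine level:
#' `R + (MMR - R) * exp(-k * (t - chase_end))`.
#'
#' @param t_s time since trial start (seconds); vectorized.
#' @param mass_g body mass (g).
#' @param status `"dominant"` or `"subordinate"`.
#' @param treatment treatment in force at `t_s` (`"social"`/`"isolation"`);
#'   scalar or vector matching `t_s`.
#' @param phase `"baseline"` or `"recovery"`; scalar or vector.
#' @param effects an [effect_config()].
#' @param protocol a [protocol_schedule()].
#' @param chase_end_s chase end time (seconds); required when any phase is
#'   `"recovery"`.
#' @param fish_mult named multipliers `c(routine=, mmr=, k=)` carrying
#'   biological variation (all 1 for the population-typical fish).
#' @return MO2 in umol O2 h^-1.
#' @export
#' @examples
#' p <- protocol_schedule(); e <- effect_config()
#' true_mo2(3600, 8, "dominant", "social", "baseline", e, p)
true_mo2 <- function(t_s, mass_g, status, treatment, phase, effects, protocol,
                     chase_end_s = NULL,
                     fish_mult = c(routine = 1, mmr = 1, k = 1)) {
  stopifnot(status %in% STATUSES, all(treatment %in% CONDITIONS),
            all(phase %in% c("baseline", "recovery")))
  n <- length(t_s)
  treatment <- rep_len(treatment, n)
  phase <- rep_len(phase, n)
  base_level <- effects$allometric_coefficient *
    mass_g^effects$allometric_exponent * effects$routine_level *
    fish_mult[["routine"]]
  R <- base_level * effects$baseline_mult[status, treatment]
  out <- numeric(n)

  is_base <- phase == "baseline"
  if (any(is_base)) {
    nf <- effects$circadian_night_fraction
    circ <- nf + (1 - nf) * light_intensity(t_s[is_base], protocol)
    out[is_base] <- R[is_base] * circ
  }
  is_rec <- !is_base
  if (any(is_rec)) {
    if (is.null(chase_end_s)) {
      config_error("configuration error: chase_end_s is required for recovery-phase MO2")
    }
    mmr <- base_level / fish_mult[["routine"]] *
      effects$mmr_multiplier[status, treatment[is_rec]] * fish_mult[["mmr"]]
    k <- effects$recovery_rate_k[status, treatment[is_rec]] * fish_mult[["k"]]
    dt_h <- pmax(0, t_s[is_rec] - chase_end_s) / 3600
    out[is_rec] <- R[is_rec] + (mmr - R[is_rec]) * exp(-k * dt_h)
  }
  out
}

## draw the lognormal biological multipliers for one fish (deterministic
## in (seed, pair_id, fish_id) so any subset of a study reproduces)
draw_fish_effects <- function(fish, effects, seed) {
  cv <- effects$process_cv
  pair_mult <- with_seed(substream_seed(seed, "pair", fish$pair_id),
                         rlnorm(1, 0, cv$pair))
  with_seed(substream_seed(seed, "fish", fish$fish_id), {
    c(routine = pair_mult * rlnorm(1, 0, cv$routine),
      mmr = pair_mult * rlnorm(1, 0, cv$mmr),
      k = rlnorm(1, 0, cv$k))
  })
}

## effective chamber volume (L): chamber minus fish-displaced volume
effective_volume <- function(chamber_volume_l, mass_g, density_g_ml = 1) {
  v <- chamber_volume_l - mass_g / density_g_ml / 1000
  if (any(v <= 0)) {
    config_error("configuration error: effective chamber volume must be positive")
  }
  v
}

#' Simulate the raw O2 trace of one fish
#'
#' Applies the chamber observation model to the fish's true MO2 process:
#' within each sealed measure period the O2 concentration declines linearly
#' at rate `true_mo2(midpoint) / V_eff` (umol L^-1 h^-1) from the
#' saturation value, plus i.i.d. Gaussian reading noise; each flush restores
#' the chamber to saturation. Identical seeds give identical traces.
#'
#' @param fish one row of a [study_design()] table (data.frame or list).
#' @param schedule a [build_schedule()] table.
#' @param effects an [effect_config()].
#' @param protocol the [protocol_schedule()] used to build `schedule`.
#' @param seed integer seed; fish-specific sub-streams are derived from it.
#' @param include_flush also emit readings during flush periods (constant at
#'   saturation plus noise). Default `FALSE`: flush samples carry no
#'   information for slope fitting.
#' @return a long `data.frame`: `fish_id`, `pair_id`, `status`, `treatment`,
#'   `phase` (`"baseline-social"`, `"baseline-isolation"`, `"recovery"`),
#'   `period_index`, `period_kind`, `time_s`, `o2_umol_per_L`.
#' @export
simulate_trace <- function(fish, schedule, effects, protocol, seed,
                           include_flush = FALSE) {
  fish <- as.list(fish)
  v_eff <- effective_volume(fish$chamber_volume_l, fish$mass_g,
                            effects$fish_density_g_ml)
  fm <- draw_fish_effects(fish, effects, seed)
  a <- schedule_anchors(protocol)
  blocks <- block_treatments(fish$treatment_order, protocol$n_baseline_blocks)

  per <- schedule[if (include_flush) TRUE else schedule$kind == "measure", ,
                  drop = FALSE]
  treat <- ifelse(is.na(per$block), fish$recovery_condition, blocks[per$block])
  phase_lab <- ifelse(per$phase == "recovery", "recovery",
                      paste0("baseline-", treat))
  sim_phase <- ifelse(per$phase == "recovery", "recovery", "baseline")
  rate <- true_mo2(per$mid_s, fish$mass_g, fish$status, treat, sim_phase,
                   effects, protocol, chase_end_s = a$chase_end_s,
                   fish_mult = fm) / v_eff

  dt <- protocol$sample_interval_s
  offs <- seq(0, protocol$cycle_measure_min * 60 - dt, by = dt)
  n_s <- length(offs)
  n_p <- nrow(per)
  idx <- rep(seq_len(n_p), each = n_s)
  rel <- rep(offs, times = n_p)
  is_meas <- per$kind[idx] == "measure"
  o2 <- effects$o2_saturation_umol_l -
    ifelse(is_meas, rate[idx] * rel / 3600, 0)
  noise <- with_seed(substream_seed(seed, "trace", fish$fish_id),
                     rnorm(length(o2), 0, effects$trace_noise_sd))
  data.frame(fish_id = fish$fish_id,
             pair_id = fish$pair_id,
             status = fish$status,
             treatment = treat[idx],
             phase = phase_lab[idx],
             period_index = per$period_index[idx],
             period_kind = per$kind[idx],
             time_s = per$start_s[idx] + rel,
             o2_umol_per_L = o2 + noise,
             stringsAsFactors = FALSE)
}

#' Simulate a full paired study
#'
#' One trace per fish plus a ground-truth table recording every fish's true
#' resting, routine and maximum MO2 and recovery rate. Truth rows are keyed
#' by fish x treatment; maximum MO2 and k are populated only for the
#' treatment matching the fish's recovery condition.
#'
#' @param design a [study_design()] table.
#' @param protocol a [protocol_schedule()].
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @param include_flush passed to [simulate_trace()].
#' @return list with elements `trace` (row-bound traces) and `truth`.
#' @export
#' @examples
#' p <- protocol_schedule(baseline_hours = 2, recovery_hours = 1,
#'                        sample_interval_s = 60)
#' s <- simulate_study(study_design(n_pairs = 2, n_social_recovery = 1),
#'                     p, effect_config(), seed = 1)
#' nrow(s$truth)
simulate_study <- function(design, protocol, effects, seed,
                           include_flush = FALSE) {
  validate_design(design)
  schedule <- build_schedule(protocol)
  traces <- vector("list", nrow(design))
  truths <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    fish <- design[i, ]
    traces[[i]] <- simulate_trace(fish, schedule, effects, protocol, seed,
                                  include_flush = include_flush)
    truths[[i]] <- fish_truth(fish, effects, seed)
  }
  list(trace = do.call(rbind, traces),
       truth = do.call(rbind, truths))
}

## ground-truth metabolic levels for one fish, one row per treatment
fish_truth <- function(fish, effects, seed) {
  fish <- as.list(fish)
  fm <- draw_fish_effects(fish, effects, seed)
  base_level <- effects$allometric_coefficient *
    fish$mass_g^effects$allometric_exponent * effects$routine_level *
    fm[["routine"]]
  routine <- base_level * effects$baseline_mult[fish$status, CONDITIONS]
  resting <- routine * effects$circadian_night_fraction
  rec <- fish$recovery_condition
  mmr <- k <- rep(NA_real_, 2)
  names(mmr) <- names(k) <- CONDITIONS
  mmr[rec] <- effects$allometric_coefficient *
    fish$mass_g^effects$allometric_exponent * effects$routine_level *
    effects$mmr_multiplier[fish$status, rec] * fm[["mmr"]]
  k[rec] <- effects$recovery_rate_k[fish$status, rec] * fm[["k"]]
  data.frame(fish_id = fish$fish_id, pair_id = fish$pair_id,
             status = fish$status, mass_g = fish$mass_g,
             treatment = CONDITIONS,
             recovery_condition = rec,
             resting_true = resting, routine_true = routine,
             mmr_true = unname(mmr), k_true = unname(k),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate endpoint values directly (bypassing trace synthesis)
#'
#' Draws one endpoint value per fish straight from the generator truth plus
#' lognormal pair, fish and measurement variation — the fast route for
#' error-rate and power simulations at the metric level.
#'
#' @param design a [study_design()] table.
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @param response `"max_mo2"` (maximum MO2) or `"routine_mo2"`.
#' @param measurement_cv lognormal sd of the measurement error.
#' @return a `data.frame` with `fish_id`, `pair_id`, `status`, `treatment`
#'   (the recovery condition), `mass_g` and `value`.
#' @export
simulate_metric_table <- function(design, effects, seed,
                                  response = c("max_mo2", "routine_mo2"),
                                  measurement_cv = 0.05) {
  response <- match.arg(response)
  validate_design(design)
  n <- nrow(design)
  base <- effects$allometric_coefficient *
    design$mass_g^effects$allometric_exponent * effects$routine_level
  mult <- vapply(seq_len(n), function(i) {
    if (response == "max_mo2") {
      effects$mmr_multiplier[design$status[i], design$recovery_condition[i]]
    } else {
      effects$baseline_mult[design$status[i], design$recovery_condition[i]]
    }
  }, numeric(1))
  cv <- effects$process_cv
  bio_sd <- if (response == "max_mo2") cv$mmr else cv$routine
  with_seed(substream_seed(seed, "metric", response), {
    pair_mult <- rlnorm(n / 2, 0, cv$pair)[match(design$pair_id,
                                                 unique(design$pair_id))]
    value <- base * mult * pair_mult * rlnorm(n, 0, bio_sd) *
      rlnorm(n, 0, measurement_cv)
    data.frame(fish_id = design$fish_id, pair_id = design$pair_id,
               status = design$status, treatment = design$recovery_condition,
               mass_g = design$mass_g, value = value,
               stringsAsFactors = FALSE)
  })
}
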
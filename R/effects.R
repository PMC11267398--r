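STATUSES <- c("dominant", "subordinate")
CONDITIONS <- c("social", "isolation")

#' Generator truth: effect configuration
#'
#' Collects every parameter of the simulated metabolic process. The
#' baseline (pre-chase) oxygen-consumption rate of a fish of mass `m` grams
#' is `allometric_coefficient * m^allometric_exponent * routine_level`,
#' modulated over the day by a smoothed circadian square wave that drops to
#' `circadian_night_fraction` of the daytime level overnight. After the
#' exhaustive chase, the rate starts at the fish's maximum
#' (`mmr_multiplier` times its routine level, by status and recovery
#' condition) and decays single-exponentially back towards the
#' treatment-matched routine level at rate `recovery_rate_k` (per hour).
#'
#' Biological variation is lognormal: a pair-level multiplier shared by
#' both fish of a pair, and fish-level multipliers on routine level,
#' maximum level and recovery rate (`process_cv`). Observation noise is
#' i.i.d. Gaussian on each O2 reading (`trace_noise_sd`).
#'
#' With all default multipliers the configuration is the *null* scenario:
#' dominants and subordinates differ only through their masses.
#'
#' @param allometric_coefficient routine MO2 of a 1 g fish
#'   (umol O2 h^-1 g^-b).
#' @param allometric_exponent allometric mass exponent `b`.
#' @param routine_level multiplier on the allometric baseline.
#' @param circadian_night_fraction overnight fraction of the daytime
#'   routine level, in (0, 1).
#' @param mmr_multiplier 2x2 matrix (status x recovery condition) of
#'   maximum-MO2 multipliers relative to routine; a scalar is recycled.
#' @param recovery_rate_k 2x2 matrix (status x recovery condition) of
#'   exponential recovery rates (h^-1); a scalar is recycled.
#' @param baseline_mult 2x2 matrix (status x treatment) of baseline-level
#'   multipliers; a scalar is recycled.
#' @param process_cv list of lognormal sds: `pair` (shared level), `routine`,
#'   `mmr`, `k` (fish level).
#' @param trace_noise_sd Gaussian sd of a single O2 reading (umol O2 L^-1).
#' @param o2_saturation_umol_l chamber O2 concentration at each flush end
#'   (umol O2 L^-1; 27 C freshwater default — the value cancels out of MO2).
#' @param fish_density_g_ml body density used for the effective-volume
#'   correction (g mL^-1).
#' @return an object of class `effect_config`.
#' @seealso [paper_scenario()], [scenario_config()]
#' @export
effect_config <- function(allometric_coefficient = 10,
                          allometric_exponent = 0.8,
                          routine_level = 1,
                          circadian_night_fraction = 0.7,
                          mmr_multiplier = 6,
                          recovery_rate_k = 1.5,
                          baseline_mult = 1,
                          process_cv = list(pair = 0.05, routine = 0.05,
                                            mmr = 0.05, k = 0.05),
                          trace_noise_sd = 0.15,
                          o2_saturation_umol_l = 247,
                          fish_density_g_ml = 1) {
  as_grid <- function(x, cols) {
    if (length(x) == 1) x <- matrix(x, 2, 2)
    stopifnot(is.matrix(x), all(dim(x) == c(2, 2)))
    dimnames(x) <- list(STATUSES, cols)
    x
  }
  e <- list(allometric_coefficient = allometric_coefficient,
            allometric_exponent = allometric_exponent,
            routine_level = routine_level,
            circadian_night_fraction = circadian_night_fraction,
            mmr_multiplier = as_grid(mmr_multiplier, CONDITIONS),
            recovery_rate_k = as_grid(recovery_rate_k, CONDITIONS),
            baseline_mult = as_grid(baseline_mult, CONDITIONS),
            process_cv = modifyList(list(pair = 0.05, routine = 0.05,
                                         mmr = 0.05, k = 0.05), process_cv),
            trace_noise_sd = trace_noise_sd,
            o2_saturation_umol_l = o2_saturation_umol_l,
            fish_density_g_ml = fish_density_g_ml)
  class(e) <- "effect_config"
  validate_effects(e)
  e
}

validate_effects <- function(e) {
  stopifnot(inherits(e, "effect_config"))
  if (e$allometric_coefficient <= 0 || e$routine_level <= 0) {
    config_error("configuration error: metabolic level parameters must be positive")
  }
  if (e$circadian_night_fraction <= 0 || e$circadian_night_fraction >= 1) {
    config_error("configuration error: circadian_night_fraction must be in (0, 1)")
  }
  if (any(e$mmr_multiplier <= 0) || any(e$baseline_mult <= 0)) {
    config_error("configuration error: all effect multipliers must be positive")
  }
  if (any(e$recovery_rate_k <= 0)) {
    config_error("configuration error: recovery rates k must be positive")
  }
  if (e$trace_noise_sd < 0) {
    config_error("configuration error: trace_noise_sd must be non-negative")
  }
  invisible(e)
}

#' Calibrate subordinate-social effects to target observed percentages
#'
#' The pipeline measures maximum MO2 as the largest single-period rate
#' after the chase. Under single-exponential recovery the first measure
#' period (midpoint `t1 = cycle_measure_min / 2` after the chase ends) is
#' the largest, so the *measured* maximum is
#' `R * (1 + (mu - 1) * exp(-k * t1))`, attenuated below the true peak
#' `mu * R` by an amount that depends on the recovery rate `k`. Likewise
#' the measured time to 50% aerobic-scope recovery is `t1 + ln(2) / k`
#' (the threshold is defined from the measured maximum, which shifts the
#' analytic crossing by exactly `t1`).
#'
#' This function inverts that measurement model: given the dominant-side
#' baselines (`mmr_base`, `k_base`) and the target *observed* percentages
#' (a relative deficit in measured maximum MO2 and a relative excess in
#' measured recovery time for subordinates in the social condition), it
#' returns the subordinate-social multiplier and recovery rate that make
#' the pipeline's expected output hit the targets.
#'
#' @param protocol a [protocol_schedule()] (supplies `t1`).
#' @param mmr_base maximum-MO2 multiplier of all unaffected cells.
#' @param k_base recovery rate (h^-1) of all unaffected cells.
#' @param mmr_deficit target fractional deficit in measured maximum MO2
#'   (e.g. 0.07 for 7% lower).
#' @param as50_excess target fractional excess in measured time to 50%
#'   aerobic-scope recovery (e.g. 0.65 for 65% longer).
#' @return list with `mmr_multiplier_sub_social` and `k_sub_social`.
#' @export
calibrate_paper_effects <- function(protocol = protocol_schedule(),
                                    mmr_base = 6, k_base = 1.5,
                                    mmr_deficit = 0.07, as50_excess = 0.65) {
  t1_h <- protocol$cycle_measure_min / 2 / 60
  as50_d_h <- t1_h + log(2) / k_base
  as50_s_h <- (1 + as50_excess) * as50_d_h
  if (as50_s_h <= t1_h) {
    config_error("configuration error: target recovery time is shorter than the first measure period")
  }
  k_s <- log(2) / (as50_s_h - t1_h)
  m_d <- 1 + (mmr_base - 1) * exp(-k_base * t1_h)
  m_s <- (1 - mmr_deficit) * m_d
  mu_s <- 1 + (m_s - 1) / exp(-k_s * t1_h)
  if (mu_s <= 1) {
    config_error("configuration error: target deficit leaves no post-chase elevation")
  }
  list(mmr_multiplier_sub_social = mu_s, k_sub_social = k_s)
}

#' The packaged study scenario
#'
#' An [effect_config()] whose subordinate-social cells are calibrated (via
#' [calibrate_paper_effects()]) so that the full pipeline recovers, in
#' expectation, a 7% deficit in measured maximum MO2 and a 65% excess in
#' measured time to 50% aerobic-scope recovery for subordinates relative
#' to their dominants when the pair is in visual contact, together with the
#' pooled aerobic-scope deficit those parameters imply (about 4%).
#'
#' @param protocol a [protocol_schedule()].
#' @param mmr_deficit,as50_excess target observed percentages (fractions).
#' @param ... further arguments passed to [effect_config()].
#' @return an `effect_config`.
#' @export
#' @examples
#' e <- paper_scenario()
#' e$mmr_multiplier
paper_scenario <- function(protocol = protocol_schedule(),
                           mmr_deficit = 0.07, as50_excess = 0.65, ...) {
  base <- effect_config(...)
  cal <- calibrate_paper_effects(protocol,
                                 mmr_base = base$mmr_multiplier["dominant", "social"],
                                 k_base = base$recovery_rate_k["dominant", "social"],
                                 mmr_deficit = mmr_deficit,
                                 as50_excess = as50_excess)
  base$mmr_multiplier["subordinate", "social"] <- cal$mmr_multiplier_sub_social
  base$recovery_rate_k["subordinate", "social"] <- cal$k_sub_social
  attr(base, "targets") <- list(mmr_deficit_social = mmr_deficit,
                                as50_excess_social = as50_excess)
  validate_effects(base)
  base
}

#' The null scenario: no status or treatment effects
#'
#' @param ... arguments passed to [effect_config()].
#' @return an `effect_config` in which dominants and subordinates differ
#'   only by mass.
#' @export
null_scenario <- function(...) effect_config(...)
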
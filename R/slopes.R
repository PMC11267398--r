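#' Quality-control configuration for slope extraction
#'
#' @param r2_min minimum coefficient of determination for a period to pass
#'   QC (default 0.90).
#' @param mixing_window_s readings collected within this many seconds of
#'   the start of a measure period are discarded before slope fitting
#'   (chamber mixing; default 30 s).
#' @param min_points minimum retained readings per period (default 3);
#'   periods with fewer are flagged and excluded.
#' @param background_rate constant background (microbial) oxygen
#'   consumption subtracted from every fish rate (umol O2 h^-1; default 0 —
#'   hook only, no blank-chamber correction is modelled).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(r2_min = 0.90, mixing_window_s = 30, min_points = 3,
                      background_rate = 0) {
  stopifnot(r2_min >= 0, r2_min <= 1, mixing_window_s >= 0, min_points >= 3)
  structure(list(r2_min = r2_min, mixing_window_s = mixing_window_s,
                 min_points = min_points, background_rate = background_rate),
            class = "qc_config")
}

#' Ordinary least-squares slope of one measure period
#'
#' Fits O2 concentration against time by OLS after discarding the mixing
#' window. When the retained readings have zero variance (a perfectly flat
#' period) the slope is 0 and, by declared convention, r^2 is 0.
#'
#' @param time_s reading times (seconds; any origin).
#' @param o2 O2 concentrations (umol O2 L^-1).
#' @param mixing_window_s discard readings within this window of the first
#'   reading (seconds).
#' @param min_points minimum retained readings.
#' @return a one-row `data.frame`: `slope` (umol O2 L^-1 h^-1), `r2`,
#'   `n_points`, `ok` (FALSE when fewer than `min_points` remain — slope
#'   and r2 are then `NA`).
#' @export
#' @examples
#' fit_period_slope(seq(0, 270, 30), 247 - 4 * seq(0, 270, 30) / 3600,
#'                  mixing_window_s = 0)
fit_period_slope <- function(time_s, o2, mixing_window_s = 30,
                             min_points = 3) {
  keep <- time_s - min(time_s) >= mixing_window_s
  t_h <- time_s[keep] / 3600
  y <- o2[keep]
  n <- length(y)
  if (n < min_points) {
    return(data.frame(slope = NA_real_, r2 = NA_real_, n_points = n,
                      ok = FALSE))
  }
  tc <- t_h - mean(t_h)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  sxy <- sum(tc * yc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
  data.frame(slope = slope, r2 = r2, n_points = n, ok = TRUE)
}

#' Convert a concentration slope to a whole-animal rate
#'
#' `MO2 = -slope * V_eff - background`, with effective volume
#' `V_eff = chamber_volume - mass / density` (fish body density 1 g mL^-1
#' by default). Negative results are permitted here; QC downstream flags
#' them.
#'
#' @param slope O2 concentration slope (umol O2 L^-1 h^-1).
#' @param chamber_volume_l chamber volume (L).
#' @param mass_g fish mass (g).
#' @param density_g_ml fish body density (g mL^-1).
#' @param background_rate constant background rate subtracted
#'   (umol O2 h^-1).
#' @return MO2 in umol O2 h^-1.
#' @export
#' @examples
#' slope_to_mo2(-10, chamber_volume_l = 1.5, mass_g = 0)  # 15
slope_to_mo2 <- function(slope, chamber_volume_l, mass_g, density_g_ml = 1,
                         background_rate = 0) {
  v_eff <- effective_volume(chamber_volume_l, mass_g, density_g_ml)
  -slope * v_eff - background_rate
}

#' Extract a quality-controlled MO2 series from raw traces
#'
#' Fits one OLS slope per sealed measure period (vectorized over all fish
#' and periods), converts slopes to whole-animal rates via the effective
#' chamber volume, and applies QC: a period passes when its r^2 reaches
#' `r2_min`, its rate is non-negative and enough readings remain after the
#' mixing-window discard. Failing periods are retained in the output with
#' `qc_pass = FALSE` so downstream stages can exclude them.
#'
#' @param trace a trace table as produced by [simulate_trace()] /
#'   [simulate_study()] (flush rows, if present, are ignored).
#' @param meta fish metadata with `fish_id`, `mass_g`, `chamber_volume_l`
#'   (a [study_design()] table works).
#' @param protocol the [protocol_schedule()] the trace follows (supplies
#'   the measure-period length for midpoint timing).
#' @param qc a [qc_config()].
#' @return a `data.frame` with one row per fish x measure period:
#'   `fish_id`, `pair_id`, `status`, `treatment`, `phase`, `period_index`,
#'   `t_mid_s`, `slope`, `r2`, `n_points`, `mo2` (umol O2 h^-1) and
#'   `qc_pass`; ordered by fish and time. Attribute `qc_counts` reports
#'   per-fish totals, passes and negative rates. A warning is raised for
#'   any fish with more than 50% of periods failing QC.
#' @export
extract_mo2_series <- function(trace, meta, protocol, qc = qc_config()) {
  stopifnot(all(c("fish_id", "period_index", "period_kind", "time_s",
                  "o2_umol_per_L") %in% names(trace)))
  dt <- as.data.table(trace)[period_kind == "measure"]
  if (nrow(dt) == 0) config_error("configuration error: trace has no measure periods")
  dt[, t0 := min(time_s), by = .(fish_id, period_index)]
  dt[, rel_s := time_s - t0]
  n_all <- dt[, .(t_start = t0[1]), by = .(fish_id, period_index)]
  dt <- dt[rel_s >= qc$mixing_window_s]
  dt[, tx := time_s / 3600]
  ## centre within period before forming cross-products: numerically stable
  ## and makes the grouped sums eligible for data.table's fast paths
  dt[, `:=`(txc = tx - mean(tx),
            o2c = o2_umol_per_L - mean(o2_umol_per_L)),
     by = .(fish_id, period_index)]
  dt[, `:=`(pxx = txc^2, pxy = txc * o2c, pyy = o2c^2)]
  grp <- dt[, .(n_points = .N,
                sxx = sum(pxx), sxy = sum(pxy), syy = sum(pyy),
                phase = data.table::first(phase),
                treatment = data.table::first(treatment),
                pair_id = data.table::first(pair_id),
                status = data.table::first(status)),
            by = .(fish_id, period_index)]
  grp <- merge(grp, n_all, by = c("fish_id", "period_index"))
  grp[, slope := ifelse(n_points >= qc$min_points & sxx > 0, sxy / sxx, NA_real_)]
  grp[, r2 := ifelse(is.na(slope), NA_real_, ifelse(syy > 0, sxy^2 / (sxx * syy), 0))]
  grp[, t_mid_s := t_start + protocol$cycle_measure_min * 60 / 2]

  m <- as.data.table(meta)[, .(fish_id, mass_g, chamber_volume_l)]
  grp <- merge(grp, m, by = "fish_id")
  grp[, mo2 := -slope * effective_volume(chamber_volume_l, mass_g) -
        qc$background_rate]
  grp[, qc_pass := !is.na(slope) & r2 >= qc$r2_min & mo2 >= 0]
  setorder(grp, fish_id, t_mid_s)

  counts <- grp[, .(n_periods = .N, n_pass = sum(qc_pass),
                    n_negative = sum(!is.na(mo2) & mo2 < 0)), by = fish_id]
  bad <- counts[n_pass < n_periods / 2]
  if (nrow(bad)) {
    warning(sprintf("more than 50%% of measure periods failed QC for: %s",
                    paste(bad$fish_id, collapse = ", ")), call. = FALSE)
  }
  log_line("extract", c(n_periods = sum(counts$n_periods),
                        n_pass = sum(counts$n_pass),
                        n_negative = sum(counts$n_negative)))
  out <- as.data.frame(grp[, .(fish_id, pair_id, status, treatment, phase,
                               period_index, t_mid_s, slope, r2, n_points,
                               mo2, qc_pass)])
  attr(out, "qc_counts") <- as.data.frame(counts)
  out
}
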
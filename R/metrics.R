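#' Metric-computation configuration
#'
#' @param resting_n number of lowest overnight rates averaged for resting
#'   MO2 (default 10).
#' @param routine_n number of consecutive post-sunrise periods averaged for
#'   routine MO2 (default 5).
#' @param routine_delay_min minutes after lights reach full intensity at
#'   which the routine window is anchored (default 30).
#' @param max_window_min post-chase search window for maximum MO2
#'   (default 60 min).
#' @param sustained_n number of consecutive sub-threshold periods required
#'   to declare a recovery-threshold crossing (default 1: first crossing).
#' @param routine10_margin fractional margin over routine for long-term
#'   recovery (default 0.10: within 10% of routine).
#' @param as50_fraction fraction of aerobic scope for the short-term
#'   recovery landmark (default 0.5).
#' @return a list of class `metric_config`.
#' @export
metric_config <- function(resting_n = 10, routine_n = 5,
                          routine_delay_min = 30, max_window_min = 60,
                          sustained_n = 1, routine10_margin = 0.10,
                          as50_fraction = 0.5) {
  stopifnot(resting_n >= 1, routine_n >= 1, max_window_min > 0,
            sustained_n >= 1, routine10_margin > 0, as50_fraction > 0,
            as50_fraction < 1)
  structure(list(resting_n = resting_n, routine_n = routine_n,
                 routine_delay_min = routine_delay_min,
                 max_window_min = max_window_min, sustained_n = sustained_n,
                 routine10_margin = routine10_margin,
                 as50_fraction = as50_fraction),
            class = "metric_config")
}

## QC-passing rows of a series, ordered by time
qc_rows <- function(series) {
  s <- series[series$qc_pass & is.finite(series$mo2), , drop = FALSE]
  s[order(s$t_mid_s), , drop = FALSE]
}

#' Resting MO2: mean of the lowest overnight rates
#'
#' @param series an MO2 series `data.frame` (`t_mid_s`, `mo2`, `qc_pass`)
#'   for one fish.
#' @param night_window `c(start_s, end_s)` of the dark phase of the
#'   treatment block.
#' @param n number of lowest values averaged (default 10).
#' @return resting MO2 (umol O2 h^-1).
#' @export
#' @examples
#' s <- data.frame(t_mid_s = 1:12, mo2 = 1:12, qc_pass = TRUE)
#' resting_mo2(s, c(0, 13))  # mean(1:10) = 5.5
resting_mo2 <- function(series, night_window, n = 10) {
  s <- qc_rows(series)
  night <- s$mo2[s$t_mid_s >= night_window[1] & s$t_mid_s < night_window[2]]
  if (length(night) < n) {
    stop(sprintf("resting MO2: only %d overnight QC-passing periods (need %d)",
                 length(night), n), call. = FALSE)
  }
  mean(sort(night)[seq_len(n)])
}

#' Routine MO2: mean of consecutive post-sunrise periods
#'
#' Averages the first `n` consecutive QC-passing measure periods whose
#' midpoints lie at or after the anchor time (30 min after lights reach
#' full intensity, by default of the calling pipeline). If a QC failure
#' interrupts the window, the window slides forward to the first run of
#' `n` consecutive passing periods.
#'
#' @param series an MO2 series `data.frame` for one fish; must contain
#'   `period_index` so consecutiveness can be checked.
#' @param anchor_s anchor time (seconds on the trial clock).
#' @param n number of consecutive periods (default 5).
#' @return routine MO2 (umol O2 h^-1).
#' @export
routine_mo2 <- function(series, anchor_s, n = 5) {
  s <- series[order(series$t_mid_s), , drop = FALSE]
  s <- s[s$t_mid_s >= anchor_s, , drop = FALSE]
  pass <- s$qc_pass & is.finite(s$mo2)
  if (sum(pass) < n) {
    stop("routine MO2: no run of consecutive QC-passing periods after anchor",
         call. = FALSE)
  }
  ## schedule step between adjacent measure periods (2 when flushes
  ## interleave, 1 otherwise)
  step <- min(diff(sort(unique(series$period_index))))
  for (i in seq_len(nrow(s) - n + 1)) {
    win <- seq(i, i + n - 1)
    if (all(pass[win]) && all(diff(s$period_index[win]) == step)) {
      return(mean(s$mo2[win]))
    }
  }
  stop("routine MO2: no run of consecutive QC-passing periods after anchor",
       call. = FALSE)
}

#' Maximum MO2 within the post-chase search window
#'
#' @param series an MO2 series `data.frame` for one fish (recovery phase
#'   rows are selected by time).
#' @param chase_end_s chase end time (seconds on the trial clock).
#' @param window_min search-window length after the chase (default 60 min).
#' @return the largest single-period MO2 in the window (umol O2 h^-1).
#' @export
max_mo2 <- function(series, chase_end_s, window_min = 60) {
  s <- qc_rows(series)
  w <- s$mo2[s$t_mid_s >= chase_end_s &
               s$t_mid_s <= chase_end_s + window_min * 60]
  if (!length(w)) {
    stop("maximum MO2: no QC-passing periods in the post-chase window",
         call. = FALSE)
  }
  max(w)
}

#' Aerobic scope
#'
#' The difference between maximum and routine MO2. Negative values are
#' allowed (and flagged by [compute_metrics()]).
#'
#' @param max_mo2,routine_mo2 the two endpoint values (umol O2 h^-1).
#' @return aerobic scope (umol O2 h^-1).
#' @export
#' @examples
#' aerobic_scope(100, 60)  # 40
aerobic_scope <- function(max_mo2, routine_mo2) {
  stopifnot(is.finite(max_mo2), is.finite(routine_mo2))
  max_mo2 - routine_mo2
}

## first time the series drops to <= threshold, linearly interpolated
## between bracketing period midpoints; 0 when the first point is already
## below; NA when never reached. sustained_n requires a run of consecutive
## sub-threshold periods; the crossing is interpolated into the first.
threshold_crossing <- function(t_s, mo2, threshold, sustained_n = 1) {
  below <- mo2 <= threshold
  if (!any(below)) return(NA_real_)
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= sustained_n)
  if (!length(hit)) return(NA_real_)
  i <- starts[hit[1]]
  if (i == 1) return(0)
  t1 <- t_s[i - 1]; y1 <- mo2[i - 1]
  t2 <- t_s[i]; y2 <- mo2[i]
  if (y1 == y2) return(t2)
  t1 + (y1 - threshold) / (y1 - y2) * (t2 - t1)
}

#' Time to 50% aerobic-scope recovery
#'
#' Elapsed time from the end of the chase until MO2 first falls to
#' `routine + as50_fraction * aerobic_scope`, linearly interpolated between
#' bracketing period midpoints. Censored at the end of the recovery window
#' when the threshold is never reached.
#'
#' @param series an MO2 series `data.frame` for one fish.
#' @param routine treatment-matched routine MO2 (umol O2 h^-1).
#' @param as aerobic scope (umol O2 h^-1); must be positive.
#' @param chase_end_s chase end time (seconds on the trial clock).
#' @param recovery_end_s end of the recovery window (seconds).
#' @param sustained_n consecutive sub-threshold periods required.
#' @param as50_fraction fraction of aerobic scope (default 0.5).
#' @return list with `minutes` (time in minutes; the censoring limit when
#'   censored) and `censored` (logical; also `TRUE` with `minutes = NA`
#'   when `as <= 0` makes the metric undefined).
#' @export
time_to_as50 <- function(series, routine, as, chase_end_s, recovery_end_s,
                         sustained_n = 1, as50_fraction = 0.5) {
  limit_min <- (recovery_end_s - chase_end_s) / 60
  if (!is.finite(as) || as <= 0) {
    return(list(minutes = NA_real_, censored = TRUE))
  }
  s <- qc_rows(series)
  s <- s[s$t_mid_s >= chase_end_s & s$t_mid_s <= recovery_end_s, , drop = FALSE]
  cross <- threshold_crossing(s$t_mid_s, s$mo2,
                              routine + as50_fraction * as, sustained_n)
  if (is.na(cross)) {
    list(minutes = limit_min, censored = TRUE)
  } else {
    list(minutes = max(0, (cross - chase_end_s) / 60), censored = FALSE)
  }
}

#' Time to within 10% of routine MO2
#'
#' Elapsed time from the end of the chase until MO2 first falls to
#' `(1 + margin) * routine` (margin 0.10 by default), interpolated as in
#' [time_to_as50()]; censorable at the recovery-window end.
#'
#' @inheritParams time_to_as50
#' @param margin fractional margin over routine (default 0.10).
#' @return list with `minutes` and `censored`.
#' @export
time_to_routine10 <- function(series, routine, chase_end_s, recovery_end_s,
                              sustained_n = 1, margin = 0.10) {
  stopifnot(is.finite(routine), routine > 0)
  limit_min <- (recovery_end_s - chase_end_s) / 60
  s <- qc_rows(series)
  s <- s[s$t_mid_s >= chase_end_s & s$t_mid_s <= recovery_end_s, , drop = FALSE]
  cross <- threshold_crossing(s$t_mid_s, s$mo2, (1 + margin) * routine,
                              sustained_n)
  if (is.na(cross)) {
    list(minutes = limit_min, censored = TRUE)
  } else {
    list(minutes = max(0, (cross - chase_end_s) / 60), censored = FALSE)
  }
}

#' Excess post-exercise oxygen consumption
#'
#' Trapezoidal integral of `max(MO2 - routine, 0)` over the recovery
#' window, from the chase end to the earlier of the first return to routine
#' (interpolated) and the window end. The integration grid is the observed
#' QC-passing period midpoints; the interval between the chase end and the
#' first midpoint (half a measure period) is not extrapolated.
#'
#' @inheritParams time_to_as50
#' @return list with `epoc` (umol O2) and `flagged` (`TRUE` when every
#'   recovery period is already at or below routine, giving 0).
#' @export
epoc <- function(series, routine, chase_end_s, recovery_end_s) {
  s <- qc_rows(series)
  s <- s[s$t_mid_s >= chase_end_s & s$t_mid_s <= recovery_end_s, , drop = FALSE]
  if (nrow(s) < 2) {
    stop("EPOC: need at least 2 QC-passing recovery periods", call. = FALSE)
  }
  t_h <- (s$t_mid_s - chase_end_s) / 3600
  y <- s$mo2
  if (all(y <= routine)) {
    return(list(epoc = 0, flagged = TRUE))
  }
  cross <- threshold_crossing(s$t_mid_s, y, routine, sustained_n = 1)
  if (!is.na(cross) && cross > 0) {
    keep <- s$t_mid_s < cross
    t_h <- c(t_h[keep], (cross - chase_end_s) / 3600)
    y <- c(y[keep], routine)
  }
  excess <- pmax(y - routine, 0)
  area <- sum(diff(t_h) * (head(excess, -1) + tail(excess, -1)) / 2)
  list(epoc = area, flagged = FALSE)
}

#' Compute the seven endpoints for every fish of a study
#'
#' Resting and routine MO2 are computed per treatment block (two rows per
#' fish); the stressor endpoints (maximum MO2, aerobic scope, the two
#' recovery times and EPOC) once per fish, labelled with the recovery
#' condition and using the treatment-matched routine as their baseline.
#'
#' @param mo2_series output of [extract_mo2_series()] (all fish).
#' @param design the [study_design()] table.
#' @param protocol the [protocol_schedule()].
#' @param opts a [metric_config()].
#' @return a tidy long `data.frame`: `fish_id`, `pair_id`, `status`,
#'   `treatment`, `metric`, `value`, `censored`, `flagged`. Censored
#'   recovery times carry the window limit as `value` with
#'   `censored = TRUE`. Attribute `notes` counts censored and flagged
#'   records.
#' @export
compute_metrics <- function(mo2_series, design, protocol,
                            opts = metric_config()) {
  validate_design(design)
  a <- schedule_anchors(protocol)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    fish <- design[i, ]
    s <- mo2_series[mo2_series$fish_id == fish$fish_id, , drop = FALSE]
    if (!nrow(s)) {
      stop(sprintf("no MO2 records for fish %s", fish$fish_id), call. = FALSE)
    }
    blocks <- block_treatments(fish$treatment_order, protocol$n_baseline_blocks)
    rows <- list()
    routine_by_tr <- c(social = NA_real_, isolation = NA_real_)
    for (b in seq_along(blocks)) {
      tr <- blocks[b]
      rest <- resting_mo2(s, a$night_windows[b, ], n = opts$resting_n)
      rout <- routine_mo2(s, a$lights_full_s[b] + opts$routine_delay_min * 60,
                          n = opts$routine_n)
      routine_by_tr[tr] <- rout
      rows[[length(rows) + 1]] <- data.frame(
        treatment = tr, metric = c("resting_mo2", "routine_mo2"),
        value = c(rest, rout), censored = FALSE, flagged = FALSE)
    }
    rec <- fish$recovery_condition
    rout_m <- routine_by_tr[[rec]]
    mx <- max_mo2(s, a$chase_end_s, window_min = opts$max_window_min)
    as_val <- aerobic_scope(mx, rout_m)
    t50 <- time_to_as50(s, rout_m, as_val, a$chase_end_s, a$recovery_end_s,
                        sustained_n = opts$sustained_n,
                        as50_fraction = opts$as50_fraction)
    t10 <- time_to_routine10(s, rout_m, a$chase_end_s, a$recovery_end_s,
                             sustained_n = opts$sustained_n,
                             margin = opts$routine10_margin)
    ep <- epoc(s, rout_m, a$chase_end_s, a$recovery_end_s)
    rows[[length(rows) + 1]] <- data.frame(
      treatment = rec,
      metric = c("max_mo2", "aerobic_scope", "time_to_as50",
                 "time_to_routine10", "epoc"),
      value = c(mx, as_val, t50$minutes, t10$minutes, ep$epoc),
      censored = c(FALSE, FALSE, t50$censored, t10$censored, FALSE),
      flagged = c(FALSE, as_val < 0, FALSE, FALSE, ep$flagged))
    fr <- do.call(rbind, rows)
    fr <- cbind(data.frame(fish_id = fish$fish_id, pair_id = fish$pair_id,
                           status = fish$status, stringsAsFactors = FALSE),
                fr)
    out[[i]] <- fr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_cens <- sum(res$censored)
  n_flag <- sum(res$flagged)
  if (n_cens) log_line("metrics", c(censored = n_cens))
  if (n_flag) log_line("metrics", c(flagged = n_flag))
  attr(res, "notes") <- list(n_censored = n_cens, n_flagged = n_flag)
  res
}
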
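#' Protocol schedule for a paired respirometry trial
#'
#' Describes the timing of an intermittent-flow respirometry trial: a
#' baseline split into equal treatment blocks, an exhaustive chase plus air
#' exposure at the end of baseline, and a recovery phase, all cycled through
#' alternating measure/flush periods under a fixed photoperiod.
#'
#' The trial clock starts at lights-on of day 1, so every baseline block and
#' the recovery phase each begin at a simulated sunrise. Defaults encode the
#' study protocol: 5 min measure / 5 min flush cycles, a 48 h baseline in
#' two 24 h blocks, a 3 min chase plus 1 min air exposure at 48 h, 6 h of
#' recovery, and a 13:11 light:dark photoperiod with a 30 min sunrise ramp.
#'
#' @param cycle_measure_min length of a sealed measurement period (minutes).
#' @param cycle_flush_min length of a flush period (minutes).
#' @param baseline_hours total baseline duration (hours), split into
#'   `n_baseline_blocks` equal treatment blocks.
#' @param n_baseline_blocks number of baseline treatment blocks.
#' @param recovery_hours post-chase recovery duration (hours).
#' @param photoperiod_light_h hours of light per 24 h day.
#' @param sunrise_ramp_min minutes over which light ramps up at sunrise
#'   (and down at sunset).
#' @param chase_duration_min chase duration (minutes).
#' @param air_exposure_min air exposure following the chase (minutes).
#' @param sample_interval_s spacing of O2 readings within a measure period
#'   (seconds).
#' @param lights_on_clock_h wall-clock hour of lights-on (metadata only; the
#'   trial clock is anchored at lights-on).
#' @return an object of class `protocol_schedule` (a validated list).
#' @seealso [build_schedule()], [schedule_anchors()]
#' @export
#' @examples
#' p <- protocol_schedule()
#' sum(build_schedule(p)$kind == "measure")  # 324
protocol_schedule <- function(cycle_measure_min = 5,
                              cycle_flush_min = 5,
                              baseline_hours = 48,
                              n_baseline_blocks = 2,
                              recovery_hours = 6,
                              photoperiod_light_h = 13,
                              sunrise_ramp_min = 30,
                              chase_duration_min = 3,
                              air_exposure_min = 1,
                              sample_interval_s = 30,
                              lights_on_clock_h = 8) {
  p <- list(cycle_measure_min = cycle_measure_min,
            cycle_flush_min = cycle_flush_min,
            baseline_hours = baseline_hours,
            n_baseline_blocks = n_baseline_blocks,
            recovery_hours = recovery_hours,
            photoperiod_light_h = photoperiod_light_h,
            sunrise_ramp_min = sunrise_ramp_min,
            chase_duration_min = chase_duration_min,
            air_exposure_min = air_exposure_min,
            sample_interval_s = sample_interval_s,
            lights_on_clock_h = lights_on_clock_h)
  class(p) <- "protocol_schedule"
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "protocol_schedule"))
  num <- c("cycle_measure_min", "cycle_flush_min", "baseline_hours",
           "recovery_hours", "photoperiod_light_h", "sunrise_ramp_min",
           "chase_duration_min", "air_exposure_min", "sample_interval_s")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0) {
      config_error("configuration error: '%s' must be a single non-negative number", f)
    }
  }
  if (p$cycle_measure_min <= 0) {
    config_error("configuration error: measure periods must have positive length")
  }
  if (p$photoperiod_light_h <= 0 || p$photoperiod_light_h >= 24) {
    config_error("configuration error: photoperiod_light_h must be in (0, 24)")
  }
  cycle_min <- p$cycle_measure_min + p$cycle_flush_min
  block_min <- p$baseline_hours * 60 / p$n_baseline_blocks
  for (seg in c(baseline_block = block_min, recovery = p$recovery_hours * 60)) {
    if (abs(seg / cycle_min - round(seg / cycle_min)) > 1e-9) {
      config_error(paste0("configuration error: phase length (%.1f min) is not a ",
                          "whole multiple of the %.1f min measure+flush cycle"),
                   seg, cycle_min)
    }
  }
  if (p$sample_interval_s > 0 &&
      p$cycle_measure_min * 60 / p$sample_interval_s < 3) {
    config_error("configuration error: fewer than 3 O2 samples per measure period")
  }
  invisible(p)
}

#' Light intensity over the trial clock
#'
#' Smoothed square-wave photoperiod: intensity ramps linearly from 0 to 1
#' over `sunrise_ramp_min` at lights-on, holds at 1, ramps back to 0 ending
#' exactly at lights-off, and is 0 overnight. The trial clock starts at
#' lights-on, so `t_s %% 86400` is time-of-day.
#'
#' @param t_s time since trial start (seconds); vectorized.
#' @param protocol a [protocol_schedule()].
#' @return light intensity in `[0, 1]`.
#' @export
light_intensity <- function(t_s, protocol) {
  L <- protocol$photoperiod_light_h
  r <- protocol$sunrise_ramp_min / 60
  tod <- (t_s / 3600) %% 24
  f <- numeric(length(tod))
  if (r > 0) {
    up <- tod < r
    f[up] <- tod[up] / r
    full <- tod >= r & tod <= L - r
    f[full] <- 1
    down <- tod > L - r & tod < L
    f[down] <- (L - tod[down]) / r
  } else {
    f[tod < L] <- 1
  }
  f
}

#' Enumerate the measure/flush periods of a trial
#'
#' Expands a [protocol_schedule()] into an ordered table of contiguous,
#' non-overlapping periods covering the baseline blocks and the recovery
#' phase. The chase plus air exposure occupies the gap between the end of
#' baseline and the start of recovery and contains no periods.
#'
#' @param protocol a [protocol_schedule()].
#' @return a `data.frame` with one row per period: `phase`
#'   (`"baseline_block1"`, `"baseline_block2"`, ..., `"recovery"`), `block`
#'   (baseline block number, `NA` in recovery), `kind` (`"measure"` or
#'   `"flush"`), `period_index` (over all periods), `measure_index` (over
#'   measure periods only, `NA` for flushes), `start_s`, `end_s`, `mid_s`
#'   and `lights` (light intensity at the period midpoint).
#' @export
build_schedule <- function(protocol) {
  validate_protocol(protocol)
  m_s <- protocol$cycle_measure_min * 60
  f_s <- protocol$cycle_flush_min * 60
  cyc <- m_s + f_s
  block_s <- protocol$baseline_hours * 3600 / protocol$n_baseline_blocks

  seg <- function(start_s, dur_s, phase, block) {
    n <- round(dur_s / cyc)
    if (n == 0) return(NULL)
    st <- start_s + (seq_len(n) - 1) * cyc
    rows <- list(
      data.frame(phase = phase, block = block, kind = "measure",
                 start_s = st, end_s = st + m_s, stringsAsFactors = FALSE))
    if (f_s > 0) {
      rows[[2]] <- data.frame(phase = phase, block = block, kind = "flush",
                              start_s = st + m_s, end_s = st + cyc,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  parts <- list()
  for (b in seq_len(protocol$n_baseline_blocks)) {
    parts[[b]] <- seg((b - 1) * block_s, block_s,
                      paste0("baseline_block", b), b)
  }
  a <- schedule_anchors(protocol)
  parts[[length(parts) + 1]] <-
    seg(a$recovery_start_s, protocol$recovery_hours * 3600, "recovery", NA)
  out <- do.call(rbind, parts)
  out <- out[order(out$start_s, out$kind == "flush"), , drop = FALSE]
  out$period_index <- seq_len(nrow(out))
  out$measure_index <- NA_integer_
  mi <- out$kind == "measure"
  out$measure_index[mi] <- seq_len(sum(mi))
  out$mid_s <- (out$start_s + out$end_s) / 2
  out$lights <- light_intensity(out$mid_s, protocol)
  rownames(out) <- NULL
  out
}

#' Timing anchors derived from a protocol
#'
#' @param protocol a [protocol_schedule()].
#' @return a list: `block_starts_s`, `baseline_end_s`, `chase_start_s`,
#'   `chase_end_s` (= recovery start, after chase + air exposure),
#'   `recovery_start_s`, `recovery_end_s`, `lights_full_s` (per-block time
#'   at which lights reach full intensity), and `night_windows` (per-block
#'   `cbind(start, end)` of the dark phase).
#' @export
schedule_anchors <- function(protocol) {
  block_s <- protocol$baseline_hours * 3600 / protocol$n_baseline_blocks
  starts <- (seq_len(protocol$n_baseline_blocks) - 1) * block_s
  baseline_end <- protocol$baseline_hours * 3600
  chase_end <- baseline_end +
    (protocol$chase_duration_min + protocol$air_exposure_min) * 60
  L_s <- protocol$photoperiod_light_h * 3600
  list(block_starts_s = starts,
       baseline_end_s = baseline_end,
       chase_start_s = baseline_end,
       chase_end_s = chase_end,
       recovery_start_s = chase_end,
       recovery_end_s = chase_end + protocol$recovery_hours * 3600,
       lights_full_s = starts + protocol$sunrise_ramp_min * 60,
       night_windows = cbind(start = starts + L_s,
                             end = starts + pmin(86400, block_s)))
}
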
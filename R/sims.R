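#' Replicate-study recovery of the injected effect sizes
#'
#' Simulates `n_reps` independent paired studies from a scenario
#' configuration, runs the full pipeline (trace synthesis -> slope
#' extraction -> endpoints) on each, and summarises three within-pair
#' percentage contrasts:
#'
#' * `pct_mmr_social` — mean over social-recovery pairs of
#'   `100 * (1 - max_mo2[sub] / max_mo2[dom])`;
#' * `pct_as_pooled` — the same aerobic-scope contrast averaged over *all*
#'   pairs (both recovery conditions);
#' * `pct_as50_social` — mean over social-recovery pairs of
#'   `100 * (t_as50[sub] / t_as50[dom] - 1)`, censored times dropped.
#'
#' @param n_reps number of replicate studies (>= 1).
#' @param seed integer base seed; replicate `i` uses a derived sub-stream.
#' @param config a [scenario_config()] (default: the packaged paper
#'   scenario).
#' @param sample_interval_s optional override of the within-period sampling
#'   interval, e.g. 60 s for faster replicate sweeps.
#' @return a `data.frame` with one row per replicate (`rep`, the three
#'   percentages) plus attribute `summary`: mean and Monte-Carlo standard
#'   error of each column.
#' @export
effect_recovery_study <- function(n_reps, seed,
                                  config = scenario_config("paper_scenario"),
                                  sample_interval_s = NULL) {
  stopifnot(n_reps >= 1)
  protocol <- config$protocol
  if (!is.null(sample_interval_s)) {
    protocol$sample_interval_s <- sample_interval_s
    validate_protocol(protocol)
  }
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- substream_seed(seed, "rep", i)
    design <- do.call(study_design, c(config$design, list(seed = rep_seed)))
    sim <- simulate_study(design, protocol, config$effects, seed = rep_seed)
    mo2 <- suppressMessages(
      extract_mo2_series(sim$trace, design, protocol, config$qc))
    met <- suppressMessages(
      compute_metrics(mo2, design, protocol, config$metrics))
    rows[[i]] <- cbind(rep = i, pair_effect_percentages(met, design))
  }
  out <- do.call(rbind, rows)
  sm <- vapply(c("pct_mmr_social", "pct_as_pooled", "pct_as50_social"),
               function(cl) {
                 x <- out[[cl]][is.finite(out[[cl]])]
                 c(mean = mean(x), mc_se = sd(x) / sqrt(length(x)))
               }, numeric(2))
  attr(out, "summary") <- t(sm)
  out
}

## within-pair percentage contrasts of one study's metric table
pair_effect_percentages <- function(metrics, design) {
  w <- metrics[metrics$metric %in% c("max_mo2", "aerobic_scope",
                                     "time_to_as50"), , drop = FALSE]
  rec <- design[design$status == "dominant",
                c("pair_id", "recovery_condition")]
  get <- function(metric, status) {
    x <- w[w$metric == metric & w$status == status, ]
    v <- x$value
    v[x$censored] <- NA_real_
    v[match(rec$pair_id, x$pair_id)]
  }
  soc <- rec$recovery_condition == "social"
  ratio <- function(metric) get(metric, "subordinate") / get(metric, "dominant")
  data.frame(
    pct_mmr_social = 100 * mean(1 - ratio("max_mo2")[soc], na.rm = TRUE),
    pct_as_pooled = 100 * mean(1 - ratio("aerobic_scope"), na.rm = TRUE),
    pct_as50_social = 100 * mean(ratio("time_to_as50")[soc] - 1, na.rm = TRUE))
}

#' Empirical type-I error of the Type-III interaction test
#'
#' Simulates `n_reps` metric-level studies under a null configuration (all
#' status and treatment multipliers equal), fits the endpoint model
#' (status, treatment, their interaction, centred log mass, pair random
#' intercept) to each, and reports the fraction of replicates whose
#' Type-III status-by-treatment F test rejects at `alpha`.
#'
#' @param n_reps number of replicate studies.
#' @param seed integer base seed.
#' @param effects a null [effect_config()] (default [null_scenario()]).
#' @param design_args arguments for [study_design()] (defaults: 16 pairs,
#'   9/7 recovery split).
#' @param response endpoint simulated, see [simulate_metric_table()].
#' @param alpha nominal level (default 0.05).
#' @return a list: `rate` (rejection fraction), `n` (replicates used),
#'   `p_values`.
#' @export
interaction_type1_sim <- function(n_reps, seed, effects = null_scenario(),
                                  design_args = list(n_pairs = 16,
                                                     n_social_recovery = 9),
                                  response = "max_mo2", alpha = 0.05) {
  stopifnot(n_reps >= 1)
  pvals <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- substream_seed(seed, "nullrep", i)
    design <- do.call(study_design, c(design_args, list(seed = rep_seed)))
    d <- simulate_metric_table(design, effects, seed = rep_seed,
                               response = response)
    tab <- tryCatch({
      f <- fit_lmm(d, random = "pair")
      type3_anova(f)
    }, error = function(e) NULL)
    if (!is.null(tab)) {
      pvals[i] <- tab$p[tab$term == "status:treatment"]
    }
  }
  ok <- is.finite(pvals)
  list(rate = mean(pvals[ok] < alpha), n = sum(ok), p_values = pvals)
}
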
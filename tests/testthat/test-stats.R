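test_that("partial eta-squared reproduces published F/df conversions", {
  ## every (F, df) triple from the summary table whose printed effect size
  ## round-trips at printed precision (two rows with rounded denominator
  ## dfs are excluded: they do not reproduce from the printed values)
  cases <- list(
    list(0.01, 32, 0.001, 3, "le"), list(0.11, 32, 0.003, 3, "eq"),
    list(6.35, 25, 0.20, 2, "eq"), list(0.02, 64, 0.001, 3, "le"),
    list(1.38, 48, 0.03, 2, "eq"), list(1.29, 48, 0.03, 2, "eq"),
    list(11.65, 61, 0.16, 2, "eq"), list(8.63, 18, 0.32, 2, "eq"),
    list(0.30, 16, 0.02, 2, "eq"), list(113.65, 19, 0.86, 2, "eq"),
    list(6.17, 23, 0.21, 2, "eq"), list(50.04, 27, 0.65, 2, "eq"),
    list(1.91, 29, 0.06, 2, "eq"), list(0.41, 16, 0.02, 2, "eq"),
    list(6.84, 16, 0.30, 2, "eq"), list(0.82, 27, 0.03, 2, "eq"),
    list(0.80, 27, 0.03, 2, "eq"), list(1.39, 27, 0.05, 2, "eq"),
    list(1.18, 27, 0.04, 2, "eq"), list(0.07, 27, 0.003, 3, "eq"),
    list(0.23, 26, 0.009, 3, "eq"), list(0.14, 16, 0.009, 3, "eq"),
    list(4.44, 16, 0.22, 2, "eq"), list(9.78, 31, 0.24, 2, "eq"))
  for (cs in cases) {
    got <- partial_eta_squared(cs[[1]], 1, cs[[2]])
    if (cs[[5]] == "eq") {
      expect_equal(round(got, cs[[4]]), cs[[3]])
    } else {
      expect_lt(got, cs[[3]])  # printed as "<0.001"
    }
  }
  expect_equal(partial_eta_squared(0, 1, 20), 0)
  ## increasing in F, decreasing in df_den
  expect_true(all(diff(partial_eta_squared(c(1, 2, 5, 50), 1, 20)) > 0))
  expect_true(all(diff(partial_eta_squared(3, 1, c(10, 20, 40))) < 0))
})

test_that("zero between-group variance reduces mixed fixed effects to OLS", {
  d <- balanced_metric_data(matrix(c(100, 93, 95, 96), 2, 2,
                                   dimnames = list(c("dominant", "subordinate"),
                                                   c("social", "isolation"))),
                            n_per_cell = 6, sd = 1, seed = 2)
  ## remove all pair-level signal so the variance component sits exactly at
  ## its zero boundary
  d$value <- d$value - ave(d$value, d$pair_id) + mean(d$value)
  f <- fit_lmm(d, random = "pair")
  expect_true(f$singular)
  ols <- lm(value ~ status * treatment + log_mass_c,
            data = socresp:::prepare_model_frame(d),
            contrasts = list(status = "contr.sum", treatment = "contr.sum"))
  expect_equal(unname(lme4::fixef(f$fit)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("a constant response gives zero slopes", {
  d <- balanced_metric_data(matrix(50, 2, 2,
                                   dimnames = list(c("dominant", "subordinate"),
                                                   c("social", "isolation"))))
  f <- fit_lmm(d, random = "pair")
  fe <- lme4::fixef(f$fit)
  expect_equal(unname(fe[-1]), rep(0, length(fe) - 1), tolerance = 1e-10)
  expect_equal(unname(fe[1]), 50)
})

test_that("mixed-model estimation recovers a large injected effect", {
  ## simulation oracle: mean status-effect estimate over replicates within
  ## 3 Monte-Carlo SEs of the injected multiplier
  e <- effect_config(mmr_multiplier = matrix(c(6, 6, 4.8, 4.8), 2, 2,
                                             byrow = TRUE))
  est <- vapply(1:200, function(i) {
    d <- study_design(seed = i, mass_sdlog = 0.02,
                      pair_mass_ratio_sdlog = 0.02)
    tab <- simulate_metric_table(d, e, seed = i)
    f <- fit_lmm(tab, random = "pair")
    ## status coded sum-to-zero: dominant +1; effect = 2 * coefficient
    2 * unname(lme4::fixef(f$fit)["status1"])
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  ## analytic expectation of the dominant-subordinate gap at mean mass:
  ## (6 - 4.8) * a * m^b * E[lognormal noise] with near-constant masses
  gap_true <- 1.2 * 10 * exp(0.8 * log(8.5)) * exp(0.5 * 3 * 0.05^2)
  expect_lt(abs(mean(est) - gap_true), 3 * se + 0.01 * gap_true)
})

test_that("singularity fallback walks the ladder and is a no-op otherwise", {
  ## zero fish-level variance in repeated measures forces fish-in-pair
  ## down to pair-only (or further); provenance records the reduction
  set.seed(9)
  pairs <- paste0("P", 1:8)
  d <- expand.grid(pair_id = pairs, status = c("dominant", "subordinate"),
                   treatment = c("social", "isolation"),
                   stringsAsFactors = FALSE)
  d$fish_id <- paste0(d$pair_id, "_", substr(d$status, 1, 1))
  pair_eff <- setNames(rnorm(8, 0, 6), pairs)
  noise <- rnorm(nrow(d), 0, 1)
  ## remove each fish's average residual: the fish-level variance component
  ## is then exactly at the zero boundary while pair variance stays positive
  noise <- noise - ave(noise, d$fish_id)
  d$value <- 100 + pair_eff[d$pair_id] + noise
  d$mass_g <- 8
  d$log_mass_c <- 0
  f0 <- fit_lmm(d, random = "fish_in_pair")
  f <- singularity_fallback(f0)
  expect_true(f0$singular)
  expect_match(f$provenance, "reduced")
  expect_true(f$random %in% c("pair", "none"))
  expect_true(all(names(f$ladder)[1] == "fish_in_pair"))
  ## non-singular fit: unchanged
  fp <- fit_lmm(d, random = "pair")
  if (!fp$singular) {
    expect_identical(singularity_fallback(fp)$provenance,
                     "initial fit retained")
  }
})

test_that("with all variances zero the stack collapses to classical ANOVA", {
  d <- balanced_metric_data(matrix(c(100, 93, 95, 96), 2, 2,
                                   dimnames = list(c("dominant", "subordinate"),
                                                   c("social", "isolation"))),
                            n_per_cell = 8, sd = 2, seed = 5)
  d$mass_g <- 8  # drop the covariate's influence: constant mass
  d$value <- d$value - ave(d$value, d$pair_id) + mean(d$value)
  f <- singularity_fallback(fit_lmm(d, random = "pair"))
  expect_identical(f$random, "none")
  tab <- type3_anova(f)
  ## classical two-way ANOVA oracle on the balanced design (Type III equals
  ## sequential sums of squares when balanced)
  oracle <- anova(lm(value ~ status * treatment,
                     data = socresp:::prepare_model_frame(d),
                     contrasts = list(status = "contr.sum",
                                      treatment = "contr.sum")))
  for (term in c("status", "treatment", "status:treatment")) {
    i <- match(term, tab$term)
    expect_equal(tab$F[i], oracle[term, "F value"], tolerance = 1e-8)
    expect_equal(tab$df_den[i], oracle["Residuals", "Df"])
  }
})

test_that("type-III tests isolate a pure interaction on balanced data", {
  cm <- matrix(c(100, 90, 90, 100), 2, 2,
               dimnames = list(c("dominant", "subordinate"),
                               c("social", "isolation")))
  d <- balanced_metric_data(cm, n_per_cell = 6, sd = 0.01, seed = 3)
  d$mass_g <- 8
  f <- singularity_fallback(fit_lmm(d, random = "pair"))
  tab <- type3_anova(f)
  get <- function(t) tab$F[match(t, tab$term)]
  ## orthogonality: main-effect estimates vanish while the interaction F
  ## is numerically huge (reported finite, not infinite)
  fe <- if (inherits(f$fit, "lm")) coef(f$fit) else lme4::fixef(f$fit)
  expect_lt(abs(unname(fe["status1"])), 0.05)
  expect_lt(abs(unname(fe["treatment1"])), 0.05)
  expect_gt(get("status:treatment"), 1e4 * max(get("status"), get("treatment"), 1))
})

test_that("marginal-mean contrasts estimate cell differences with Tukey adjustment", {
  cm <- matrix(c(100, 93, 97, 96), 2, 2,
               dimnames = list(c("dominant", "subordinate"),
                               c("social", "isolation")))
  d <- balanced_metric_data(cm, n_per_cell = 6, sd = 1e-8, seed = 8)
  d$mass_g <- 8
  f <- fit_lmm(d, random = "none")
  ct <- emm_contrasts(f)
  i <- grep("^dominant social - subordinate social$", ct$contrast)
  expect_length(i, 1)
  expect_equal(ct$estimate[i], 7, tolerance = 1e-6)
  ## all-equal cells: every adjusted p at 1 (noise centred within cells so
  ## the cell means are exactly equal)
  d2 <- balanced_metric_data(matrix(80, 2, 2,
                                    dimnames = dimnames(cm)),
                             n_per_cell = 6, sd = 3, seed = 12)
  d2$mass_g <- 8
  cell <- paste(d2$status, d2$treatment)
  d2$value <- d2$value - ave(d2$value, cell) + 80
  ct2 <- emm_contrasts(fit_lmm(d2, random = "none"))
  expect_true(all(ct2$p_adj > 0.999))
  expect_true(all(abs(ct2$estimate) < 1e-10))
  ## adjusted p never below raw p over random fits
  for (s in 1:5) {
    d3 <- balanced_metric_data(cm, n_per_cell = 5, sd = 6, seed = 100 + s)
    ct3 <- emm_contrasts(fit_lmm(d3, random = "none"))
    expect_true(all(ct3$p_adj >= ct3$p_raw - 1e-12))
  }
})

test_that("endpoint models use the spec'd random structures and drop censored rows", {
  p <- protocol_schedule(sample_interval_s = 60)
  cfg <- scenario_config("paper_scenario")
  d <- study_design(n_pairs = 8, n_social_recovery = 4, seed = 14)
  s <- simulate_study(d, p, cfg$effects, seed = 14)
  mo2 <- extract_mo2_series(s$trace, d, p, cfg$qc)
  met <- compute_metrics(mo2, d, p, cfg$metrics)
  res <- analyze_metrics(met, d)
  ms <- res$model_summaries
  expect_setequal(unique(ms$term),
                  c("status", "treatment", "log_mass_c", "status:treatment"))
  expect_true(all(ms$eta_p2 >= 0 & ms$eta_p2 < 1))
  expect_true(all(ms$p >= 0 & ms$p <= 1, na.rm = TRUE))
  ## repeated endpoints start from fish-within-pair, single-measure from pair
  expect_true(all(ms$random[ms$response %in% c("max_mo2", "aerobic_scope",
                                               "epoc")] %in%
                    c("pair", "none")))
  expect_identical(nrow(res$fits$resting_mo2$data), 32L)  # 16 fish x 2 blocks
  expect_identical(names(res$fits$resting_mo2$ladder)[1], "fish_in_pair")
})
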
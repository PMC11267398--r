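RANDOM_LADDER <- c("fish_in_pair", "pair", "none")

#' Partial eta-squared from an F statistic
#'
#' `eta_p^2 = (F * df_num) / (F * df_num + df_den)`: the proportion of
#' effect-plus-residual variance attributable to a model term.
#'
#' @param f F statistic (>= 0); vectorized.
#' @param df_num,df_den numerator and denominator degrees of freedom.
#' @return partial eta-squared in `[0, 1)`.
#' @export
#' @examples
#' round(partial_eta_squared(8.63, 1, 18), 2)    # 0.32
#' round(partial_eta_squared(113.65, 1, 19), 2)  # 0.86
partial_eta_squared <- function(f, df_num, df_den) {
  ## Satterthwaite denominator dfs are fractional and can drop below 1 in
  ## very small designs; only non-positive values are invalid
  stopifnot(all(f >= 0), all(df_num >= 1), all(df_den > 0))
  f * df_num / (f * df_num + df_den)
}

#' Fit the status x treatment linear mixed model for one endpoint
#'
#' Gaussian LMM fitted by REML with fixed effects status, treatment, their
#' interaction and centred natural-log body mass, under sum-to-zero factor
#' coding (required for meaningful Type-III tests). The random structure is
#' one rung of the ladder fish-within-pair -> pair-only -> none; the last
#' rung is an ordinary least-squares fit.
#'
#' @param data a `data.frame` with columns `value`, `status`, `treatment`,
#'   `mass_g` (or `log_mass_c`), `pair_id` and `fish_id`. Rows with missing
#'   `value` are dropped (complete-case).
#' @param random `"fish_in_pair"` (`(1|pair_id/fish_id)`), `"pair"`
#'   (`(1|pair_id)`) or `"none"`.
#' @return a list of class `socresp_fit`: `fit` (a `lmerModLmerTest` or
#'   `lm`), `random` (structure used), `singular` (logical), `n` (rows
#'   used), `data`.
#' @export
fit_lmm <- function(data, random = c("fish_in_pair", "pair", "none")) {
  random <- match.arg(random)
  d <- prepare_model_frame(data)
  ## a constant body mass would alias the covariate against the intercept;
  ## drop it for such degenerate inputs rather than fitting a rank-deficient
  ## design
  rhs <- if (sd(d$log_mass_c) > 1e-10) {
    "status * treatment + log_mass_c"
  } else {
    "status * treatment"
  }
  if (random == "none") {
    fit <- lm(as.formula(paste("value ~", rhs)), data = d,
              contrasts = list(status = "contr.sum", treatment = "contr.sum"))
    singular <- FALSE
  } else {
    re <- if (random == "fish_in_pair") "(1 | pair_id / fish_id)" else "(1 | pair_id)"
    fit <- lmerTest::lmer(as.formula(paste("value ~", rhs, "+", re)),
                          data = d, REML = TRUE,
                          contrasts = list(status = "contr.sum",
                                           treatment = "contr.sum"),
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
    singular <- lme4::isSingular(fit)
  }
  structure(list(fit = fit, random = random, singular = singular,
                 n = nrow(d), data = d),
            class = "socresp_fit")
}

prepare_model_frame <- function(data) {
  req <- c("value", "status", "treatment", "pair_id", "fish_id")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    config_error("configuration error: model data is missing columns: %s",
                 paste(miss, collapse = ", "))
  }
  d <- as.data.frame(data)
  if (!"log_mass_c" %in% names(d)) {
    if (!"mass_g" %in% names(d)) {
      config_error("configuration error: model data needs 'mass_g' or 'log_mass_c'")
    }
    lm_ <- log(d$mass_g)
    d$log_mass_c <- lm_ - mean(lm_, na.rm = TRUE)
  }
  d <- d[is.finite(d$value), , drop = FALSE]
  d$status <- factor(d$status, levels = STATUSES)
  d$treatment <- factor(d$treatment, levels = CONDITIONS)
  d$pair_id <- factor(d$pair_id)
  d$fish_id <- factor(d$fish_id)
  for (f in c("status", "treatment")) {
    if (nlevels(droplevels(d[[f]])) < 2) {
      config_error("configuration error: factor '%s' has fewer than 2 observed levels", f)
    }
  }
  d
}

#' Reduce the random structure of a singular fit
#'
#' Walks the ladder fish-within-pair -> pair-only -> none, refitting until
#' the fit is no longer singular (a variance component at the zero
#' boundary) or the ladder is exhausted. Non-singular fits are returned
#' unchanged. All fits along the way are retained for side-by-side
#' comparison (the with/without-random-effect check used for the
#' time-to-10%-routine endpoint).
#'
#' @param fitted a `socresp_fit` from [fit_lmm()].
#' @return a `socresp_fit` with extra fields `provenance` (character note)
#'   and `ladder` (list of all fits tried, named by structure).
#' @export
singularity_fallback <- function(fitted) {
  stopifnot(inherits(fitted, "socresp_fit"))
  ladder <- list()
  ladder[[fitted$random]] <- fitted
  cur <- fitted
  while (cur$singular && cur$random != "none") {
    nxt <- RANDOM_LADDER[match(cur$random, RANDOM_LADDER) + 1]
    cur <- fit_lmm(cur$data, random = nxt)
    ladder[[nxt]] <- cur
  }
  cur$provenance <- if (identical(cur$random, fitted$random)) {
    "initial fit retained"
  } else {
    sprintf("singular fit: random structure reduced %s -> %s",
            fitted$random, cur$random)
  }
  if (!identical(cur$provenance, "initial fit retained")) {
    log_line("stats", c(fallback = paste0(fitted$random, "->", cur$random)))
  }
  cur$ladder <- ladder
  cur
}

#' Type-III F tests for a fitted model
#'
#' Per-term marginal (Type-III) F tests under sum-to-zero contrasts:
#' Satterthwaite denominator degrees of freedom for mixed fits, residual
#' degrees of freedom for the fixed-effects-only fallback. Partial
#' eta-squared is attached per term.
#'
#' @param fitted a `socresp_fit`.
#' @return a `data.frame`: `term`, `F`, `df_num`, `df_den`, `p`, `eta_p2`,
#'   plus `random` and `singular` describing the fit.
#' @export
type3_anova <- function(fitted) {
  stopifnot(inherits(fitted, "socresp_fit"))
  fit <- fitted$fit
  if (inherits(fit, "lmerModLmerTest")) {
    tab <- as.data.frame(anova(fit, type = 3, ddf = "Satterthwaite"))
    out <- data.frame(term = rownames(tab), F = tab[["F value"]],
                      df_num = tab$NumDF, df_den = tab$DenDF,
                      p = tab[["Pr(>F)"]], stringsAsFactors = FALSE)
  } else {
    tab <- car::Anova(fit, type = 3)
    tab <- as.data.frame(tab)
    keep <- !rownames(tab) %in% c("(Intercept)", "Residuals")
    df_den <- tab["Residuals", "Df"]
    out <- data.frame(term = rownames(tab)[keep], F = tab[keep, "F value"],
                      df_num = tab[keep, "Df"], df_den = df_den,
                      p = tab[keep, "Pr(>F)"], stringsAsFactors = FALSE)
  }
  if (any(!is.finite(out$F))) {
    config_error("configuration error: rank-deficient design; aliased terms: %s",
                 paste(out$term[!is.finite(out$F)], collapse = ", "))
  }
  out$eta_p2 <- partial_eta_squared(out$F, out$df_num, out$df_den)
  out$random <- fitted$random
  out$singular <- fitted$singular
  rownames(out) <- NULL
  out
}

#' Tukey-adjusted pairwise contrasts of the status x treatment cells
#'
#' Estimated marginal means of the four status x treatment cells at the
#' mean (centred) log body mass, with all pairwise contrasts adjusted by
#' the studentized-range (Tukey) method.
#'
#' @param fitted a `socresp_fit` whose model contains the interaction.
#' @return a `data.frame`: `contrast`, `estimate`, `SE`, `df`, `p_adj`,
#'   `p_raw` (unadjusted, for reference).
#' @export
emm_contrasts <- function(fitted) {
  stopifnot(inherits(fitted, "socresp_fit"))
  cells <- table(fitted$data$status, fitted$data$treatment)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    config_error("configuration error: empty design cell: %s x %s",
                 rownames(cells)[empty[1, 1]], colnames(cells)[empty[1, 2]])
  }
  em <- emmeans::emmeans(fitted$fit, ~ status * treatment)
  tuk <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "none"))
  data.frame(contrast = as.character(tuk$contrast), estimate = tuk$estimate,
             SE = tuk$SE, df = tuk$df, p_adj = tuk$p.value,
             p_raw = raw$p.value, stringsAsFactors = FALSE)
}

#' Fit all endpoint models of a study
#'
#' One model per endpoint: repeated-measures endpoints (resting and routine
#' MO2; one value per fish per treatment block) start from the
#' fish-within-pair random structure, single-measure endpoints from
#' pair-only, and each is reduced by [singularity_fallback()] if singular.
#' Censored recovery times enter as missing (complete-case). Tukey
#' contrasts are computed for every endpoint.
#'
#' @param metrics the long table from [compute_metrics()].
#' @param design the [study_design()] table (supplies body mass).
#' @param alpha significance level recorded in the notes (default 0.05).
#' @return a list: `model_summaries` (row-bound [type3_anova()] tables with
#'   a `response` column), `contrasts` (row-bound [emm_contrasts()] tables),
#'   `fits` (named list of `socresp_fit`), `notes` (censoring counts,
#'   fallbacks).
#' @export
analyze_metrics <- function(metrics, design, alpha = 0.05) {
  mass <- design[, c("fish_id", "mass_g")]
  responses <- unique(metrics$metric)
  summaries <- list()
  contrasts <- list()
  fits <- list()
  notes <- list(alpha = alpha, dropped_censored = 0L, fallbacks = character())
  for (resp in responses) {
    m <- metrics[metrics$metric == resp, , drop = FALSE]
    n_cens <- sum(m$censored)
    if (n_cens) {
      notes$dropped_censored <- notes$dropped_censored + n_cens
      log_line("stats", c(response = resp, dropped_censored = n_cens))
      m <- m[!m$censored, , drop = FALSE]
    }
    d <- merge(m, mass, by = "fish_id")
    start <- if (resp %in% c("resting_mo2", "routine_mo2")) "fish_in_pair" else "pair"
    f0 <- fit_lmm(d, random = start)
    f <- singularity_fallback(f0)
    if (!identical(f$provenance, "initial fit retained")) {
      notes$fallbacks <- c(notes$fallbacks,
                           setNames(f$provenance, resp))
    }
    tab <- type3_anova(f)
    tab <- cbind(response = resp, tab, stringsAsFactors = FALSE)
    ct <- emm_contrasts(f)
    ct <- cbind(response = resp, ct, stringsAsFactors = FALSE)
    summaries[[resp]] <- tab
    contrasts[[resp]] <- ct
    fits[[resp]] <- f
  }
  list(model_summaries = do.call(rbind, c(summaries, make.row.names = FALSE)),
       contrasts = do.call(rbind, c(contrasts, make.row.names = FALSE)),
       fits = fits, notes = notes)
}
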
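scenario_keys <- function() {
  list(top = c("name", "design", "protocol", "effects", "targets", "qc",
               "metrics"),
       design = setdiff(names(formals(study_design)), "seed"),
       protocol = names(formals(protocol_schedule)),
       effects = names(formals(effect_config)),
       qc = names(formals(qc_config)),
       metrics = names(formals(metric_config)),
       targets = c("mmr_deficit_social", "as50_excess_social"))
}

#' Load and validate a scenario configuration
#'
#' Reads a hierarchical key-value (YAML) scenario file — either one of the
#' packaged scenarios (`"paper_scenario"`, `"null_scenario"`) or a path —
#' validates every key before any stage runs, and materialises the
#' component configurations. Non-zero effect `targets` are converted into
#' calibrated subordinate-social multipliers via
#' [calibrate_paper_effects()].
#'
#' @param scenario scenario name or path to a YAML file.
#' @return a list of class `run_config`: `name`, `design` (argument list
#'   for [study_design()]), `protocol`, `effects`, `qc`, `metrics`,
#'   `targets`.
#' @export
#' @examples
#' cfg <- scenario_config("paper_scenario")
#' cfg$effects$mmr_multiplier
scenario_config <- function(scenario = "paper_scenario") {
  path <- if (file.exists(scenario)) {
    scenario
  } else {
    system.file("scenarios", paste0(scenario, ".yaml"), package = "socresp")
  }
  if (!nzchar(path) || !file.exists(path)) {
    config_error("configuration error: unknown scenario '%s'", scenario)
  }
  raw <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      config_error("configuration error: unknown key(s) in %s: %s",
                   where, paste(bad, collapse = ", "))
    }
  }
  keys <- scenario_keys()
  check_keys(raw, keys$top, "scenario")
  for (section in c("design", "protocol", "effects", "qc", "metrics",
                    "targets")) {
    check_keys(raw[[section]] %||% list(), keys[[section]], section)
  }

  protocol <- do.call(protocol_schedule, raw$protocol %||% list())
  targets <- modifyList(list(mmr_deficit_social = 0, as50_excess_social = 0),
                        raw$targets %||% list())
  effects <- if (targets$mmr_deficit_social > 0 ||
                 targets$as50_excess_social > 0) {
    do.call(paper_scenario,
            c(list(protocol = protocol,
                   mmr_deficit = targets$mmr_deficit_social,
                   as50_excess = targets$as50_excess_social),
              raw$effects %||% list()))
  } else {
    do.call(effect_config, raw$effects %||% list())
  }
  structure(list(name = raw$name %||% basename(path),
                 design = raw$design %||% list(),
                 protocol = protocol,
                 effects = effects,
                 qc = do.call(qc_config, raw$qc %||% list()),
                 metrics = do.call(metric_config, raw$metrics %||% list()),
                 targets = targets),
            class = "run_config")
}

#' Validate trace and metadata tables
#'
#' Schema, pairing, time-ordering and unit checks on a raw trace table and
#' its fish metadata. Problems are *returned*, not raised, so callers can
#' decide what is fatal.
#'
#' @param trace a trace table (see [simulate_trace()] for the dialect).
#' @param meta a fish metadata table ([study_design()] dialect).
#' @return a `data.frame` of diagnostics (`check`, `id`, `message`); zero
#'   rows when everything is well-formed.
#' @export
validate_inputs <- function(trace, meta) {
  diag <- list()
  add <- function(check, id, message) {
    diag[[length(diag) + 1]] <<- data.frame(check = check, id = id,
                                            message = message,
                                            stringsAsFactors = FALSE)
  }
  trace_cols <- c("fish_id", "pair_id", "status", "treatment", "phase",
                  "period_index", "period_kind", "time_s", "o2_umol_per_L")
  miss <- setdiff(trace_cols, names(trace))
  if (length(miss)) {
    add("schema", "trace", paste("missing columns:", paste(miss, collapse = ", ")))
  }
  meta_cols <- c("fish_id", "pair_id", "status", "mass_g", "chamber_volume_l")
  miss <- setdiff(meta_cols, names(meta))
  if (length(miss)) {
    add("schema", "meta", paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (length(diag)) return(do.call(rbind, diag))

  for (p in unique(meta$pair_id)) {
    st <- sort(meta$status[meta$pair_id == p])
    if (!identical(st, c("dominant", "subordinate"))) {
      add("pairing", p, "pair must hold exactly one dominant and one subordinate")
    }
  }
  for (f in unique(trace$fish_id)) {
    ts <- trace$time_s[trace$fish_id == f]
    if (any(diff(ts) <= 0)) {
      add("monotonic_time", f, "time_s must be strictly increasing within fish")
    }
  }
  bad_o2 <- !is.finite(trace$o2_umol_per_L) | trace$o2_umol_per_L < 0
  if (any(bad_o2)) {
    add("units", "trace", sprintf("%d non-finite or negative O2 readings",
                                  sum(bad_o2)))
  }
  if (any(meta$mass_g <= 0)) add("units", "meta", "non-positive mass")
  if (any(meta$chamber_volume_l - meta$mass_g / 1000 <= 0)) {
    add("units", "meta", "effective chamber volume non-positive")
  }
  unknown <- setdiff(unique(trace$fish_id), meta$fish_id)
  if (length(unknown)) {
    add("schema", "trace", paste("fish without metadata:",
                                 paste(unknown, collapse = ", ")))
  }
  if (length(diag)) do.call(rbind, diag) else
    data.frame(check = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Run the full pipeline and write a reproducible report bundle
#'
#' simulate -> extract -> metrics -> stats, with any subset of stages;
#' later stages read the CSVs written by earlier runs into the same output
#' directory, so a stats-only rerun on saved metrics reproduces identical
#' summaries. Outputs are plain CSV plus a YAML run manifest (seed,
#' configuration, QC attrition, censoring counts, singularity fallbacks).
#' Identical scenario + seed give byte-identical outputs.
#'
#' @param scenario scenario name or YAML path (see [scenario_config()]).
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "extract", "metrics", "stats")`, in pipeline order.
#' @param write_trace write the (large) raw trace CSV (default TRUE when
#'   the simulate stage runs).
#' @return invisibly, a list with the stage outputs and file paths.
#' @export
run_pipeline <- function(scenario = "paper_scenario", seed = 1,
                         outdir = tempfile("socresp_run_"),
                         stages = c("simulate", "extract", "metrics", "stats"),
                         write_trace = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  config <- scenario_config(scenario)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(trace = file.path(outdir, "trace.csv"),
                truth = file.path(outdir, "truth.csv"),
                design = file.path(outdir, "design.csv"),
                mo2 = file.path(outdir, "mo2_series.csv"),
                metrics = file.path(outdir, "metrics.csv"),
                summaries = file.path(outdir, "model_summaries.csv"),
                contrasts = file.path(outdir, "contrasts.csv"),
                manifest = file.path(outdir, "manifest.yaml"))
  out <- list(config = config, paths = paths)
  manifest <- list(scenario = config$name, seed = seed,
                   stages = stages,
                   targets = config$targets,
                   design = config$design)

  run_stage <- function(name, f) {
    log_line(name, c(status = "start"))
    tryCatch(f(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ## stage isolation: when a serialized copy exists, consume it rather than
  ## the in-memory object, so a stage rerun from saved files reproduces the
  ## first run byte for byte
  load_or <- function(obj, path) {
    if (file.exists(path)) {
      as.data.frame(data.table::fread(path))
    } else {
      obj %||% config_error("configuration error: missing stage input '%s'",
                            basename(path))
    }
  }

  if ("simulate" %in% stages) {
    res <- run_stage("simulate", function() {
      design <- do.call(study_design, c(config$design, list(seed = seed)))
      sim <- simulate_study(design, config$protocol, config$effects, seed)
      data.table::fwrite(design, paths$design)
      data.table::fwrite(sim$truth, paths$truth)
      if (write_trace) data.table::fwrite(sim$trace, paths$trace)
      list(design = design, trace = sim$trace, truth = sim$truth)
    })
    out[names(res)] <- res
  }
  if ("extract" %in% stages) {
    res <- run_stage("extract", function() {
      trace <- load_or(out$trace, paths$trace)
      design <- load_or(out$design, paths$design)
      diags <- validate_inputs(trace, design)
      if (nrow(diags)) {
        stop(paste("input diagnostics:",
                   paste(diags$check, diags$message, collapse = "; ")))
      }
      mo2 <- extract_mo2_series(trace, design, config$protocol, config$qc)
      data.table::fwrite(mo2, paths$mo2)
      list(design = design, mo2 = mo2, qc_counts = attr(mo2, "qc_counts"))
    })
    out[c("design", "mo2")] <- res[c("design", "mo2")]
    manifest$qc_summary <- list(n_periods = sum(res$qc_counts$n_periods),
                                n_pass = sum(res$qc_counts$n_pass),
                                n_negative = sum(res$qc_counts$n_negative))
  }
  if ("metrics" %in% stages) {
    res <- run_stage("metrics", function() {
      mo2 <- load_or(out$mo2, paths$mo2)
      design <- load_or(out$design, paths$design)
      met <- compute_metrics(mo2, design, config$protocol, config$metrics)
      data.table::fwrite(met, paths$metrics)
      list(design = design, metrics = met, notes = attr(met, "notes"))
    })
    out[c("design", "metrics")] <- res[c("design", "metrics")]
    manifest$metric_notes <- res$notes
  }
  if ("stats" %in% stages) {
    res <- run_stage("stats", function() {
      met <- load_or(out$metrics, paths$metrics)
      design <- load_or(out$design, paths$design)
      st <- analyze_metrics(met, design)
      data.table::fwrite(st$model_summaries, paths$summaries)
      data.table::fwrite(st$contrasts, paths$contrasts)
      st
    })
    out$stats <- res
    manifest$stat_notes <- list(dropped_censored = res$notes$dropped_censored,
                                fallbacks = as.list(res$notes$fallbacks))
  }
  yaml::write_yaml(manifest, paths$manifest)
  log_line("pipeline", c(status = "done", outdir = outdir))
  invisible(out)
}
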
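# Orchestration: design -> simulate -> cost -> trial fits -> decode ->
# infer, as one reproducible run driven by a serializable config.

# 32-bit FNV-1a hash of a config's YAML form, for stamping outputs
config_hash <- function(config) {
  plain <- lapply(unclass(config),
                  function(x) if (is.list(x)) unclass(x) else x)
  bytes <- utf8ToInt(yaml::as.yaml(plain))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# per-stage seed derivation: fixed offsets from the master seed keep
# stages independently re-runnable
stage_seed <- function(seed, stage) {
  offs <- c(design = 1L, cohort = 2L, neural = 3L, boot = 4L, perm = 5L,
            modelsel = 6L, compare = 7L)
  (as.integer(seed) + 1000003L * offs[[stage]]) %% 2147483647L
}

#' Default pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_participants cohort size.
#' @param n_blocks blocks per session.
#' @param n_neural participants for whom a neural dataset is simulated and
#'   decoded (0 disables the decoding and combined-model stages).
#' @param n_boot bootstrap iterations for the inference stage.
#' @param n_perm scrambled-label permutations (0 disables).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param params,nparams generator parameter lists; defaults are
#'   [synth_params()] / [neural_synth_params()] with the matching sizes.
#' @return list of class `pm_config`.
#' @export
pm_config <- function(seed = 1L, n_participants = 78L, n_blocks = 6L,
                      n_neural = 2L, n_boot = 2000L, n_perm = 0L,
                      out_dir = NULL, params = NULL, nparams = NULL) {
  if (is.null(params))
    params <- synth_params(n_participants = n_participants,
                           n_blocks = n_blocks, seed = stage_seed(seed, "cohort"))
  if (is.null(nparams)) nparams <- neural_synth_params()
  structure(list(seed = as.integer(seed), n_participants = n_participants,
                 n_blocks = n_blocks, n_neural = n_neural,
                 n_boot = n_boot, n_perm = n_perm, out_dir = out_dir,
                 params = params, nparams = nparams),
            class = "pm_config")
}

write_stage <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(obj))
    write_events(obj, file.path(out_dir, paste0(name, ".tsv")))
  else
    jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Generates the session design, simulates the cohort, computes baselines,
#' PM costs, trial summaries and per-trial polynomial fits, optionally
#' simulates and decodes neural data for the first `n_neural` participants,
#' and runs the bootstrap inference linking PM cost slope (and, when
#' available, PM intention evidence) to PM accuracy. All outputs are pure
#' functions of `(config, seed)`; stage tables and a summary report are
#' written to `config$out_dir` when set, stamped with the config hash.
#'
#' @param config a [pm_config()].
#' @return list of class `pm_run`: `design`, `cohort`, `behavior` (the
#'   [pm_cost_pipeline()] list), `fits`, `proportions`, `inference`,
#'   `neural` (per-participant EV tables, or `NULL`), `comparison`,
#'   `report`.
#' @export
run_pipeline <- function(config = pm_config()) {
  stopifnot(inherits(config, "pm_config"))
  stamp <- list(config_hash = config_hash(config), seed = config$seed)

  design <- generate_session(config$n_blocks,
                             seed = stage_seed(config$seed, "design"))
  cohort <- simulate_cohort(config$params, design = design)
  behavior <- pm_cost_pipeline(cohort)
  fits <- fit_cohort_trials(behavior$costed_probes)
  proportions <- best_fit_proportions(fits)

  neural <- NULL
  trials <- behavior$trials
  if (config$n_neural > 0L) {
    nseed <- stage_seed(config$seed, "neural")
    templates <- class_templates(config$nparams, nseed)
    ev_tabs <- lapply(seq_len(min(config$n_neural,
                                  config$n_participants)), function(i) {
      pr <- cohort$probes[cohort$probes$participant == i, , drop = FALSE]
      ds <- simulate_neural(pr, config$nparams, seed = nseed + i,
                            templates = templates)
      loc <- simulate_localizer(config$nparams, templates,
                                seed = nseed + i)
      cv <- crossvalidate(ds, loc)
      ev <- pm_intention_evidence(cv, pr)
      cbind(participant = i, ev$trials,
            accuracy = cv$accuracy, stringsAsFactors = FALSE)
    })
    neural <- do.call(rbind, ev_tabs)
    trials <- merge(trials, neural[, c("participant", "trial", "mean_ev")],
                    by = c("participant", "trial"), all.x = TRUE,
                    sort = FALSE)
  }

  enough <- all(vapply(c("dec", "inc"), function(dd) {
    sum(trials$direction == dd & !is.na(trials$cost_slope) &
          !is.na(trials$pm_hit)) >= 30
  }, TRUE)) && config$n_participants >= 4
  inference <- if (enough)
    slope_accuracy_model(trials, n_iter = config$n_boot,
                         seed = stage_seed(config$seed, "boot"))
  comparison <- NULL
  n_ev_participants <- if (is.null(neural)) 0L
                       else length(unique(neural$participant))
  if (n_ev_participants >= 8L)
    comparison <- compare_predictor_models(
      trials[!is.na(trials$mean_ev), , drop = FALSE],
      n_iter = min(config$n_boot, 1000L),
      seed = stage_seed(config$seed, "compare"))

  report <- list(
    stamp = stamp,
    n_participants = config$n_participants,
    n_trials = nrow(trials),
    prop_excluded = mean(trials$excluded),
    condition_slopes = behavior$condition_slopes,
    cost_trend_ms_per_level = behavior$cost_trend,
    best_fit_cohort = proportions$cohort,
    coefficients = if (!is.null(inference)) inference$coefficients)

  out <- structure(list(design = design, cohort = cohort,
                        behavior = behavior, fits = fits,
                        proportions = proportions, inference = inference,
                        neural = neural, comparison = comparison,
                        report = report, config = config),
                   class = "pm_run")
  if (!is.null(config$out_dir)) {
    write_stage(design, config$out_dir, "design")
    write_stage(cohort$probes, config$out_dir, "probes")
    write_stage(behavior$trials, config$out_dir, "trials")
    write_stage(fits, config$out_dir, "trial_fits")
    if (!is.null(neural)) write_stage(neural, config$out_dir, "pm_ev")
    write_stage(report, config$out_dir, "report")
    write_stage(as.list(unclass(config$params)), config$out_dir, "params")
  }
  out
}

#' @export
print.pm_run <- function(x, ...) {
  r <- x$report
  cat("pmflex run", r$stamp$config_hash, "seed", r$stamp$seed, "\n")
  cat(sprintf("%d participants, %d trials (%.1f%% excluded)\n",
              r$n_participants, r$n_trials, 100 * r$prop_excluded))
  cat("condition mean PM cost slopes (ms/s):\n")
  print(r$condition_slopes, digits = 3)
  if (!is.null(x$inference)) print(x$inference)
  invisible(x)
}

#' Validate a probe-level event table
#'
#' Schema and range checks for event tables consumed by the cost pipeline:
#' required columns, difficulty in 1-15, RT within the response window
#' (0, 1.9] seconds, probe indices consistent with `n_probes`.
#'
#' @param events a probe-level data.frame.
#' @return invisibly `TRUE` if clean, otherwise a data.frame of violations
#'   (`row`, `problem`), also printed.
#' @export
validate_events <- function(events) {
  required <- c("block", "trial", "probe", "condition", "pm_type",
                "difficulty_level")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  probs <- list()
  bad <- which(!(events$difficulty_level %in% 1:15))
  if (length(bad))
    probs[[length(probs) + 1L]] <-
      data.frame(row = bad, problem = "difficulty_level outside 1-15")
  if ("rt" %in% names(events)) {
    bad <- which(!is.na(events$rt) & (events$rt <= 0 | events$rt > 1.9))
    if (length(bad))
      probs[[length(probs) + 1L]] <-
        data.frame(row = bad, problem = "rt outside the (0, 1.9] s window")
  }
  bad <- which(!(events$condition %in% pm_conditions))
  if (length(bad))
    probs[[length(probs) + 1L]] <-
      data.frame(row = bad, problem = "unknown condition")
  if ("n_probes" %in% names(events)) {
    bad <- which(events$probe > events$n_probes | events$probe < 1)
    if (length(bad))
      probs[[length(probs) + 1L]] <-
        data.frame(row = bad, problem = "probe index outside 1..n_probes")
  }
  if (!length(probs)) return(invisible(TRUE))
  out <- do.call(rbind, probs)
  out <- out[order(out$row), , drop = FALSE]
  rownames(out) <- NULL
  out
}
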
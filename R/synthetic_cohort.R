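# Synthetic cohort generator. Behavioral sessions are produced from a
# latent proactive-control strategy trace theta in [0,1]: theta drifts
# linearly within a trial at a condition-specific rate (with per-trial
# jitter), expresses itself as an additive RT cost on PM trials whose
# magnitude is attenuated at harder difficulty levels, and sets the hit
# probability for the PM target at its reappearance on the final probe.

#' Synthetic cohort parameters
#'
#' Ground-truth parameters of the behavioral generator. Defaults emulate
#' the descriptive structure of the difficulty-ramped dual-task paradigm:
#' baseline RT rises and ongoing-task accuracy falls roughly linearly from
#' the easiest to the hardest search level; the proactive RT cost is about
#' 0.15 s at full engagement on easy search and is attenuated to near zero
#' at the hardest level; strategy drifts upward on decreasing-difficulty
#' trials, downward (more steeply) on increasing trials and mildly upward
#' on fixed trials as target expectancy grows.
#'
#' @param rt_base_easy,rt_base_hard baseline correct-response RT (s) at
#'   difficulty levels 1 and 15; interpolated linearly in between.
#' @param acc_easy,acc_hard ongoing-task accuracy at levels 1 and 15.
#' @param cost_amplitude proactive RT cost (s) at full engagement
#'   (`theta = 1`) on the easiest level.
#' @param cost_difficulty_decay attenuation of the expressed cost with
#'   level: `decay(level) = max(0, 1 - cost_difficulty_decay*(level-1)/14)`.
#' @param theta0 initial strategy at trial start, in `[0, 1]`.
#' @param drift_inc,drift_dec,drift_fix mean strategy change per probe by
#'   trial direction.
#' @param drift_sd per-trial Gaussian jitter of the drift around its
#'   condition mean (trial-to-trial strategy variability).
#' @param pm_slope_gain,pm_intercept logit coefficients of hit probability
#'   on strategy at target onset.
#' @param reactive_floor hit probability floor supplied by reactive,
#'   cue-triggered retrieval when no proactive engagement remains.
#' @param rt_noise_sd residual RT noise (s).
#' @param n_participants cohort size.
#' @param n_blocks blocks per session.
#' @param seed master seed.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(rt_base_easy = 0.70, rt_base_hard = 1.25,
                         acc_easy = 0.97, acc_hard = 0.62,
                         cost_amplitude = 0.2, cost_difficulty_decay = 1,
                         theta0 = 0.3,
                         drift_inc = -0.08, drift_dec = 0.04,
                         drift_fix = 0.03, drift_sd = 0.05,
                         pm_slope_gain = 4, pm_intercept = -1.4,
                         reactive_floor = 0.45,
                         rt_noise_sd = 0.15,
                         n_participants = 78L, n_blocks = 6L, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$rt_base_easy < p$rt_base_hard, p$rt_base_hard < 1.9,
            p$acc_easy >= 0, p$acc_easy <= 1,
            p$acc_hard >= 0, p$acc_hard <= 1,
            p$theta0 >= 0, p$theta0 <= 1,
            p$reactive_floor >= 0, p$reactive_floor <= 1,
            p$rt_noise_sd >= 0, p$n_participants >= 1)
  class(p) <- "synth_params"
  p
}

#' Neural generator parameters
#'
#' @param n_features number of synthetic features (voxels), at least 4.
#' @param snr template-to-noise amplitude ratio (unit Gaussian noise).
#' @param coupling shift of the PM-target class template with the trial
#'   mean strategy, `coupling * (theta_bar - 0.5)`.
#' @param tr sampling interval in seconds (one sample per 2 s probe).
#' @param lag_trs hemodynamic label shift in samples.
#' @return list of class `neural_synth_params`.
#' @export
neural_synth_params <- function(n_features = 40L, snr = 1, coupling = 0.5,
                                tr = 2, lag_trs = 2L) {
  stopifnot(n_features >= 4, snr >= 0)
  structure(list(n_features = as.integer(n_features), snr = snr,
                 coupling = coupling, tr = tr,
                 lag_trs = as.integer(lag_trs)),
            class = "neural_synth_params")
}

level_interp <- function(level, easy, hard, n_levels = 15) {
  easy + (level - 1) / (n_levels - 1) * (hard - easy)
}

cost_decay <- function(level, decay, n_levels = 15) {
  pmax(0, 1 - decay * (level - 1) / (n_levels - 1))
}

direction_of <- function(condition) {
  ifelse(condition == "fixed", "fix",
         ifelse(condition %in% c("inc_easy", "inc_mid"), "inc", "dec"))
}

# truncated-at-left normal draw, vectorized; values beyond the response
# deadline are reported as omissions by the caller
rnorm_left_trunc <- function(n, mean, sd, lower = 0.3, max_redraws = 20L) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_redraws)) {
    bad <- which(x <= lower)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
  }
  pmax(x, lower + 1e-6)
}

#' Simulate one participant's session
#'
#' Applies the latent-strategy generator to a probe-level design. Non-PM
#' probe RTs are baseline plus noise; PM-trial probe RTs add the expressed
#' proactive cost `theta * cost_amplitude * decay(level)`. Ongoing-task
#' correctness is Bernoulli in the level-interpolated accuracy. RTs are
#' truncated below at 300 ms; draws beyond the 1.9 s response deadline are
#' recorded as omissions (no response, counted incorrect). On PM trials the
#' target reappears on the final probe and is hit with probability
#' `reactive_floor + (1 - reactive_floor) *
#'  plogis(pm_intercept + pm_slope_gain * theta_final)`;
#' a hit preempts the ongoing-task response on that probe.
#'
#' @param design probe-level design from [generate_session()].
#' @param params [synth_params()].
#' @param seed participant-level seed.
#' @return list with `probes` (design columns plus `theta`, `rt`,
#'   `response`, `og_correct`, `omitted`) and `trials` (per-trial summary
#'   with `theta_final`, `theta_mean`, `pm_hit`).
#' @export
simulate_participant <- function(design, params = synth_params(), seed = 1L) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(seed)
  d <- design
  n <- nrow(d)
  dir <- direction_of(d$condition)
  drift_mean <- c(inc = params$drift_inc, dec = params$drift_dec,
                  fix = params$drift_fix)[dir]
  trial_ids <- unique(d$trial)
  jit <- stats::rnorm(length(trial_ids), 0, params$drift_sd)
  names(jit) <- as.character(trial_ids)
  drift <- drift_mean + jit[as.character(d$trial)]
  theta <- pmin(1, pmax(0, 0.0 + params$theta0 + drift * (d$probe - 1)))

  lev <- d$difficulty_level
  base <- level_interp(lev, params$rt_base_easy, params$rt_base_hard)
  is_pm_trial <- d$pm_type != "none"
  cost <- ifelse(is_pm_trial,
                 theta * params$cost_amplitude *
                   cost_decay(lev, params$cost_difficulty_decay),
                 0)
  rt <- rnorm_left_trunc(n, base + cost, params$rt_noise_sd)
  omitted <- rt > 1.9
  acc <- level_interp(lev, params$acc_easy, params$acc_hard)
  og_correct <- stats::rbinom(n, 1L, acc) == 1L
  og_correct[omitted] <- FALSE
  rt[omitted] <- NA_real_
  response <- ifelse(omitted, "none", "og")

  # PM target reappears on the final probe of PM trials
  fin <- which(is_pm_trial & d$is_final_probe)
  theta_final <- theta[fin]
  p_hit <- params$reactive_floor + (1 - params$reactive_floor) *
    stats::plogis(params$pm_intercept + params$pm_slope_gain * theta_final)
  hit <- stats::rbinom(length(fin), 1L, p_hit) == 1L
  response[fin][hit] <- "pm"
  rt[fin][hit] <- NA_real_        # PM response preempts the OG response
  og_correct[fin][hit] <- NA

  probes <- cbind(d, data.frame(theta = theta, rt = rt,
                                response = response,
                                og_correct = og_correct,
                                omitted = omitted,
                                stringsAsFactors = FALSE))

  first <- !duplicated(d$trial)
  trials <- data.frame(
    block = d$block[first], trial = d$trial[first],
    condition = d$condition[first], direction = dir[first],
    pm_type = d$pm_type[first], is_catch = d$is_catch[first],
    n_probes = d$n_probes[first],
    stringsAsFactors = FALSE)
  trials$theta_final <- NA_real_
  trials$theta_mean <- tapply(theta, d$trial, mean)[as.character(trials$trial)]
  trials$pm_hit <- NA
  m <- match(d$trial[fin], trials$trial)
  trials$theta_final[m] <- theta_final
  trials$pm_hit[m] <- hit
  rownames(trials) <- NULL
  list(probes = probes, trials = trials)
}

#' Simulate a full cohort
#'
#' Runs [simulate_participant()] for each participant with seeds derived
#' from the master seed. All participants share the session design (trial
#' lengths are predetermined in the paradigm), which is generated from the
#' master seed when not supplied.
#'
#' @param params [synth_params()].
#' @param design optional probe-level design shared by the cohort.
#' @return list of class `pm_cohort` with pooled `probes` and `trials`
#'   tables carrying a `participant` column, plus the `design` and
#'   `params`.
#' @export
simulate_cohort <- function(params = synth_params(), design = NULL) {
  if (params$n_participants < 1) stop("'n_participants' must be >= 1")
  if (is.null(design))
    design <- generate_session(params$n_blocks, seed = params$seed)
  set.seed(params$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, params$n_participants)
  sims <- lapply(seq_len(params$n_participants), function(i) {
    s <- simulate_participant(design, params, seed = seeds[i])
    s$probes$participant <- i
    s$trials$participant <- i
    s
  })
  structure(list(
    probes = do.call(rbind, lapply(sims, `[[`, "probes")),
    trials = do.call(rbind, lapply(sims, `[[`, "trials")),
    design = design, params = params), class = "pm_cohort")
}

#' @export
print.pm_cohort <- function(x, ...) {
  cat("Synthetic PM cohort:", max(x$probes$participant), "participants,",
      length(unique(x$design$block)), "blocks,",
      nrow(x$trials) / max(x$probes$participant), "trials each\n")
  invisible(x)
}

#' Class templates for the neural generator
#'
#' One template pattern per class (face, scene, og, rest), standard normal
#' entries, drawn deterministically from the seed. Shared templates let a
#' task dataset and a localizer dataset be generated coherently.
#' @param nparams [neural_synth_params()].
#' @param seed integer seed.
#' @return 4 x n_features matrix with rownames `face, scene, og, rest`.
#' @export
class_templates <- function(nparams, seed = 1L) {
  set.seed(seed)
  t <- matrix(stats::rnorm(4L * nparams$n_features), nrow = 4L)
  rownames(t) <- c("face", "scene", "og", "rest")
  t
}

mvpa_classes <- c("face", "scene", "og", "rest")

# Build the event timeline for one participant's probe table: per trial a
# 2-sample encoding period (unlabeled), the probe samples (class = PM
# target category, or "og" on non-PM trials), then rest samples, with a
# 1-sample guard adjacent to the next trial onset.
neural_timeline <- function(probes, rest_samples = 4L) {
  rows <- list()
  for (b in unique(probes$block)) {
    pb <- probes[probes$block == b, , drop = FALSE]
    tl <- list(data.frame(event = "rest", trial = NA_integer_,
                          run = b, usable = c(TRUE, TRUE, FALSE),
                          is_final_probe = FALSE, theta_bar = NA_real_,
                          target = NA_character_,
                          stringsAsFactors = FALSE))
    for (tr in unique(pb$trial)) {
      pt <- pb[pb$trial == tr, , drop = FALSE]
      np <- nrow(pt)
      cls <- if (pt$pm_type[1] == "none") "og" else pt$pm_type[1]
      tb <- if ("theta" %in% names(pt)) mean(pt$theta) else NA_real_
      enc <- data.frame(event = "encoding", trial = tr, run = b,
                        usable = FALSE, is_final_probe = FALSE,
                        theta_bar = tb, target = cls,
                        stringsAsFactors = FALSE)[rep(1, 2), ]
      prb <- data.frame(event = cls, trial = tr, run = b, usable = TRUE,
                        is_final_probe = seq_len(np) == np, theta_bar = tb,
                        target = cls, stringsAsFactors = FALSE)
      rst <- data.frame(event = "rest", trial = tr, run = b,
                        usable = c(rep(TRUE, rest_samples - 1L), FALSE),
                        is_final_probe = FALSE, theta_bar = NA_real_,
                        target = NA_character_, stringsAsFactors = FALSE)
      tl[[length(tl) + 1L]] <- rbind(enc, prb, rst)
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, tl)
  }
  out <- do.call(rbind, rows)
  out$sample <- seq_len(nrow(out))
  out
}

#' Simulate a neural dataset from behavioral probes
#'
#' Produces a time-point by feature matrix sampled once per 2 s probe.
#' Each sample carries the template of the event happening `lag_trs`
#' samples earlier (the hemodynamic lag), scaled by `snr`, plus unit
#' Gaussian noise; on PM-trial probe samples the PM-target class template
#' is additionally shifted by `coupling * (theta_bar - 0.5)`. Class labels
#' are the event labels shifted forward by `lag_trs` samples so that they
#' align with the lagged signal. Samples from encoding periods, a 1-sample
#' rest guard adjacent to each trial onset, and run lead-ins are flagged
#' unusable; final probes of each trial are flagged for exclusion from
#' classifier training.
#'
#' @param probes one participant's probe table (or probe-level design).
#' @param nparams [neural_synth_params()].
#' @param seed integer seed.
#' @param templates optional template matrix from [class_templates()];
#'   drawn from `seed` when missing.
#' @param localizer logical flag marking the dataset as localizer data
#'   (always placed in the training set by [crossvalidate()]).
#' @return list of class `neural_dataset` with `X` (samples x features),
#'   `events` (per-sample metadata: shifted `label`, `run`, `trial`,
#'   `usable`, `in_training`, `theta_bar`, `target`), `tr`, `lag_trs`.
#' @export
simulate_neural <- function(probes, nparams = neural_synth_params(),
                            seed = 1L, templates = NULL, localizer = FALSE) {
  if ("participant" %in% names(probes) &&
      length(unique(probes$participant)) > 1L)
    stop("'probes' must belong to a single participant; subset the cohort")
  if (is.null(templates)) templates <- class_templates(nparams, seed)
  set.seed(seed + 1L)
  tl <- neural_timeline(probes)
  n <- nrow(tl)
  lag <- nparams$lag_trs
  shift <- function(v, fill = NA) c(rep(fill, lag), v[seq_len(n - lag)])
  # the BOLD-like signal at sample t reflects the event lag_trs earlier
  lag_event <- shift(tl$event)
  lag_theta <- shift(tl$theta_bar)
  X <- matrix(stats::rnorm(n * nparams$n_features), nrow = n)
  ev_class <- match(lag_event, mvpa_classes)  # NA for encoding/lead-in
  sig <- !is.na(ev_class)
  X[sig, ] <- X[sig, ] + nparams$snr * templates[ev_class[sig], ]
  pmrow <- which(lag_event %in% c("face", "scene"))
  if (length(pmrow))
    X[pmrow, ] <- X[pmrow, ] +
      nparams$coupling * (lag_theta[pmrow] - 0.5) *
      templates[lag_event[pmrow], ]
  events <- data.frame(
    sample = tl$sample,
    run = tl$run,                       # runs change slowly; keep unshifted
    label = shift(tl$event),
    trial = shift(tl$trial),
    usable = shift(tl$usable, FALSE) & !is.na(shift(tl$event)) &
      shift(tl$event, "encoding") != "encoding",
    is_final_probe = shift(tl$is_final_probe, FALSE),
    theta_bar = shift(tl$theta_bar),
    target = shift(tl$target),
    stringsAsFactors = FALSE)
  events$in_training <- events$usable & !events$is_final_probe
  structure(list(X = X, events = events, tr = nparams$tr,
                 lag_trs = lag, localizer = localizer,
                 templates = templates),
            class = "neural_dataset")
}

#' Simulate a balanced localizer dataset
#'
#' Mini-block localizer with equal numbers of face, scene, ongoing-task and
#' rest samples, generated from the same class templates as the task data.
#'
#' @param nparams [neural_synth_params()].
#' @param templates template matrix shared with the task dataset.
#' @param seed integer seed.
#' @param n_per_class usable samples per class.
#' @param run run identifier (keep distinct from task runs).
#' @return a `neural_dataset` with `localizer = TRUE`.
#' @export
simulate_localizer <- function(nparams = neural_synth_params(),
                               templates = NULL, seed = 1L,
                               n_per_class = 40L, run = "loc1") {
  if (is.null(templates)) templates <- class_templates(nparams, seed)
  set.seed(seed + 2L)
  lab <- sample(rep(mvpa_classes, n_per_class))
  n <- length(lab)
  X <- matrix(stats::rnorm(n * nparams$n_features), nrow = n) +
    nparams$snr * templates[match(lab, mvpa_classes), ]
  events <- data.frame(sample = seq_len(n), run = run, label = lab,
                       trial = NA_integer_, usable = TRUE,
                       is_final_probe = FALSE, theta_bar = NA_real_,
                       target = NA_character_, in_training = TRUE,
                       stringsAsFactors = FALSE)
  structure(list(X = X, events = events, tr = nparams$tr,
                 lag_trs = nparams$lag_trs, localizer = TRUE,
                 templates = templates),
            class = "neural_dataset")
}
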
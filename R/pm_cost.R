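# Behavioral strategy metrics: response filtering, difficulty-by-practice
# RT baselines, per-probe PM cost, within-trial PM cost slope, exclusions.

#' Drop anticipatory responses
#'
#' Removes probe rows with RT strictly below the cutoff (responses faster
#' than 300 ms are considered carried over from the preceding response
#' window); rows with no RT (omissions, PM responses) are kept. The number
#' of removed rows is attached as attribute `n_removed` and messaged.
#'
#' @param probes probe-level table with an `rt` column in seconds.
#' @param min_rt cutoff in seconds; RTs equal to the cutoff are kept.
#' @return the filtered table.
#' @export
filter_responses <- function(probes, min_rt = 0.3) {
  if (!"rt" %in% names(probes)) stop("'probes' must have an 'rt' column")
  drop <- !is.na(probes$rt) & probes$rt < min_rt
  out <- probes[!drop, , drop = FALSE]
  if (any(drop)) message("filter_responses: removed ", sum(drop),
                         " responses faster than ", min_rt * 1000, " ms")
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Default early/late block split
#'
#' Early = first `floor(B/2)` blocks, late = the rest: blocks 1-3 vs 4-6
#' for a six-block session and 1-2 vs 3-5 for a five-block session.
#' @param blocks vector of block identifiers.
#' @return named character vector mapping block -> `"early"`/`"late"`.
#' @export
default_block_split <- function(blocks) {
  b <- sort(unique(blocks))
  n_early <- floor(length(b) / 2)
  stats::setNames(ifelse(seq_along(b) <= n_early, "early", "late"),
                  as.character(b))
}

#' Difficulty-by-practice RT baselines
#'
#' Mean ongoing-task RT on non-PM-trial probes at each difficulty level,
#' separately for the early and late halves of the session (practice
#' effects shrink RTs over blocks). With all 15 levels observed in both
#' bins this yields 30 baseline cells per participant. Only correct
#' responses enter by default; `correct_only = FALSE` mirrors the
#' all-responses control analysis. Apply [filter_responses()] first.
#'
#' @param probes filtered probe table (may hold several participants).
#' @param block_split mapping of block to bin as from
#'   [default_block_split()]; computed per participant when `NULL`.
#' @param correct_only use only correct ongoing-task responses.
#' @return data.frame `participant`, `difficulty_level`, `bin`, `mean_rt`,
#'   `n_obs`, one row per difficulty level visited by the session and
#'   practice bin; cells with no usable observation carry `n_obs = 0` and
#'   an `NA` mean (see [probe_costs()] for the fallback).
#' @export
compute_baselines <- function(probes, block_split = NULL,
                              correct_only = TRUE) {
  if (!"participant" %in% names(probes)) probes$participant <- 1L
  np <- probes[probes$pm_type == "none" & !is.na(probes$rt), , drop = FALSE]
  if (correct_only) np <- np[np$og_correct %in% TRUE, , drop = FALSE]
  if (nrow(np) == 0L) stop("no usable non-PM probes to build baselines from")
  all_np <- probes[probes$pm_type == "none", , drop = FALSE]
  out <- lapply(split(np, np$participant), function(d) {
    bs <- if (is.null(block_split)) default_block_split(d$block) else block_split
    d$bin <- bs[as.character(d$block)]
    agg <- stats::aggregate(rt ~ difficulty_level + bin, data = d,
                            FUN = mean)
    cnt <- stats::aggregate(rt ~ difficulty_level + bin, data = d,
                            FUN = length)
    # one cell per difficulty level the session visited x practice bin;
    # cells with no usable observation are kept, flagged by n_obs = 0
    lev <- sort(unique(
      all_np$difficulty_level[all_np$participant == d$participant[1]]))
    grid <- expand.grid(difficulty_level = lev, bin = sort(unique(bs)),
                        stringsAsFactors = FALSE)
    m <- match(paste(grid$difficulty_level, grid$bin),
               paste(agg$difficulty_level, agg$bin))
    data.frame(participant = d$participant[1],
               difficulty_level = grid$difficulty_level, bin = grid$bin,
               mean_rt = agg$rt[m],
               n_obs = ifelse(is.na(m), 0L, cnt$rt[m]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-probe PM cost
#'
#' Cost = ongoing-task RT on a PM-trial probe minus the baseline mean RT at
#' the same difficulty level and practice bin. Probes whose baseline cell
#' is empty fall back to the same-level mean from the other practice bin
#' (flagged in `baseline_fallback`); if that is empty too, the cost is NA.
#'
#' @param probes filtered probe table.
#' @param baselines output of [compute_baselines()].
#' @param block_split as in [compute_baselines()]; must match.
#' @param correct_only restrict to correct ongoing-task responses.
#' @return PM-trial probe rows with `bin`, `cost` (s), `baseline_fallback`.
#' @export
probe_costs <- function(probes, baselines, block_split = NULL,
                        correct_only = TRUE) {
  if (!"participant" %in% names(probes)) probes$participant <- 1L
  pm <- probes[probes$pm_type != "none", , drop = FALSE]
  out <- lapply(split(pm, pm$participant), function(d) {
    bs <- if (is.null(block_split)) default_block_split(d$block) else block_split
    d$bin <- bs[as.character(d$block)]
    bl <- baselines[baselines$participant == d$participant[1], , drop = FALSE]
    key <- paste(d$difficulty_level, d$bin)
    m <- match(key, paste(bl$difficulty_level, bl$bin))
    base <- bl$mean_rt[m]
    other <- ifelse(d$bin == "early", "late", "early")
    m2 <- match(paste(d$difficulty_level, other),
                paste(bl$difficulty_level, bl$bin))
    fallback <- is.na(base) & !is.na(bl$mean_rt[m2])
    base[fallback] <- bl$mean_rt[m2][fallback]
    d$baseline_fallback <- fallback
    d$cost <- d$rt - base
    if (correct_only) d$cost[!(d$og_correct %in% TRUE)] <- NA_real_
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-trial PM cost slope
#'
#' The difference between the mean PM cost over the final three probes
#' before the target reappearance (probes `n-3 .. n-1`; the final probe
#' itself is excluded) and the mean over the first three probes, divided by
#' the number of probes in the trial and by the probe duration, expressed
#' in ms/s. Positive slopes mark a shift toward proactive control. Windows
#' are defined on calendar probe positions; only probes with a usable cost
#' contribute, and at least `min_window_n` usable costs are required per
#' window. Trials shorter than 7 probes have overlapping windows and get an
#' undefined slope.
#'
#' @param cost per-probe costs (s) of one trial, in probe order.
#' @param probe probe indices matching `cost`.
#' @param n_probes total probes in the trial.
#' @param probe_duration_s probe duration (2 s).
#' @param min_window_n minimum usable costs per window (1 by default; set
#'   3 to require complete windows).
#' @return slope in ms/s, or NA with attribute `reason`.
#' @export
cost_slope <- function(cost, probe, n_probes, probe_duration_s = 2,
                       min_window_n = 1L) {
  if (n_probes < 7L)
    return(structure(NA_real_, reason = "windows overlap (n_probes < 7)"))
  w1 <- cost[probe <= 3L]
  w2 <- cost[probe >= n_probes - 3L & probe <= n_probes - 1L]
  w1 <- w1[!is.na(w1)]
  w2 <- w2[!is.na(w2)]
  if (length(w1) < min_window_n || length(w2) < min_window_n)
    return(structure(NA_real_, reason = "too few usable costs in a window"))
  1000 * ((mean(w2) - mean(w1)) / n_probes) / probe_duration_s
}

# within-trial slope of raw OG RT, same convention (ms/s)
rt_slope <- function(rt, probe, n_probes, probe_duration_s = 2) {
  cost_slope(rt, probe, n_probes, probe_duration_s)
}

#' Trial-level strategy summary
#'
#' Computes per-trial ongoing-task accuracy, mean PM cost, PM cost slope
#' and covariates, applies the 50% accuracy exclusion (trials where the
#' participant performed the ongoing task below chance are unreliable), and
#' aggregates the classic descriptives: the per-participant per-level mean
#' cost profile, condition-wise mean slopes, and the pooled linear trend of
#' cost on difficulty level.
#'
#' @param costed_probes output of [probe_costs()] (PM-trial probes), or the
#'   full filtered probe table (non-PM rows are used for covariates only).
#' @param trials trial table (e.g. from [simulate_cohort()]) carrying
#'   `participant`, `trial`, `condition`, `direction`, `pm_type`,
#'   `n_probes` and, when available, `pm_hit`.
#' @param accuracy_threshold exclusion threshold on ongoing-task accuracy.
#' @param min_window_n passed to [cost_slope()].
#' @return list with `trials` (trial summaries incl. `excluded`),
#'   `level_costs` (participant x level mean cost, s), `condition_slopes`
#'   (mean slope by direction, ms/s), `cost_trend` (pooled lm coefficient
#'   of cost in ms on level).
#' @export
summarize_trials <- function(costed_probes, trials,
                             accuracy_threshold = 0.5, min_window_n = 1L) {
  cp <- costed_probes[costed_probes$pm_type != "none", , drop = FALSE]
  if (!"participant" %in% names(cp)) cp$participant <- 1L
  key <- paste(cp$participant, cp$trial)
  sp <- split(cp, key)
  sum_one <- function(d) {
    np <- d$n_probes[1]
    # OG accuracy over probes where an OG response was expected (final
    # probes answered with a PM response are excluded)
    og <- d[is.na(d$og_correct) == FALSE, , drop = FALSE]
    og_acc <- if (nrow(og)) mean(og$og_correct) else NA_real_
    sl <- cost_slope(d$cost, d$probe, np, min_window_n = min_window_n)
    data.frame(participant = d$participant[1], trial = d$trial[1],
               og_accuracy = og_acc,
               mean_cost = mean(d$cost, na.rm = TRUE),
               cost_slope = as.numeric(sl),
               mean_og_rt = mean(d$rt, na.rm = TRUE),
               og_rt_slope = as.numeric(rt_slope(d$rt, d$probe, np)),
               stringsAsFactors = FALSE)
  }
  smry <- do.call(rbind, lapply(sp, sum_one))
  tr <- merge(trials, smry, by = c("participant", "trial"),
              all.x = FALSE, sort = FALSE)
  tr$excluded <- !is.na(tr$og_accuracy) &
    tr$og_accuracy < accuracy_threshold
  tr$exclusion_reason <- ifelse(tr$excluded, "og_accuracy_below_chance", "")
  keep <- tr[!tr$excluded, , drop = FALSE]

  cp_keep <- cp[!(paste(cp$participant, cp$trial) %in%
                    paste(tr$participant[tr$excluded],
                          tr$trial[tr$excluded])), , drop = FALSE]
  lc <- stats::aggregate(cost ~ participant + difficulty_level,
                         data = cp_keep, FUN = mean, na.rm = TRUE)
  names(lc)[names(lc) == "cost"] <- "mean_cost"

  cs <- stats::aggregate(cost_slope ~ direction, data = keep, FUN = mean,
                         na.rm = TRUE)
  names(cs)[names(cs) == "cost_slope"] <- "mean_slope"

  trend <- stats::coef(stats::lm(I(1000 * cost) ~ difficulty_level,
                                 data = cp_keep))[["difficulty_level"]]

  list(trials = tr, level_costs = lc, condition_slopes = cs,
       cost_trend = trend)
}

#' End-to-end behavioral metrics for a cohort
#'
#' Convenience wrapper: RT filter, per-participant baselines, per-probe
#' costs, trial summaries.
#'
#' @param cohort a `pm_cohort` (or list with `probes` and `trials`).
#' @param correct_only restrict baselines and costs to correct responses.
#' @param min_window_n passed to [cost_slope()].
#' @return the [summarize_trials()] list, plus `baselines` and
#'   `costed_probes`.
#' @export
pm_cost_pipeline <- function(cohort, correct_only = TRUE,
                             min_window_n = 1L) {
  probes <- suppressMessages(filter_responses(cohort$probes))
  baselines <- compute_baselines(probes, correct_only = correct_only)
  costed <- probe_costs(probes, baselines, correct_only = correct_only)
  res <- summarize_trials(costed, cohort$trials,
                          min_window_n = min_window_n)
  res$baselines <- baselines
  res$costed_probes <- costed
  res
}
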
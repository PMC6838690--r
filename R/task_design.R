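# Deterministic generators for the difficulty parameterization, distractor
# arrays, within-trial difficulty trajectories and block/session/localizer
# designs of the difficulty-ramped visual-search dual task.

#' Trajectory condition labels
#'
#' The five within-trial difficulty conditions: increasing from the easiest
#' level, increasing from the median level, fixed at the median level,
#' decreasing from the median level, and decreasing from the hardest level.
#' @export
pm_conditions <- c("inc_easy", "inc_mid", "fixed", "dec_mid", "dec_hard")

#' PM target types
#' @export
pm_types <- c("face", "scene", "none")

# circular distance between two orientations in degrees
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Build the ordered difficulty table
#'
#' Crosses the minimum distractor-to-target angular distances with the
#' distractor orientation variances, drops every pair whose minimum distance
#' plus variance exceeds the vertical plane limit (90 degrees by default,
#' so no distractor band can cross the vertical), and assigns ordinal
#' difficulty levels. Larger minimum distance makes the distractors less
#' target-like (easier search) and smaller variance makes them more
#' homogeneous (easier rejection), so levels are assigned by descending
#' minimum distance, then ascending variance; level 1 is the easiest.
#'
#' @param min_distances minimum distractor-to-target angles, degrees.
#' @param variances maximum deviations from the minimum angle, degrees.
#' @param plane_limit pairs with `min + variance > plane_limit` are dropped.
#' @param permutation optional integer permutation re-assigning levels, for
#'   alternative orderings of the retained pairs.
#' @return data.frame with columns `level`, `min_distance`, `variance`.
#' @examples
#' nrow(build_difficulty_table())  # 15 conditions
#' @export
build_difficulty_table <- function(min_distances = c(5, 15, 25, 45, 65, 75),
                                   variances = c(10, 20, 40),
                                   plane_limit = 90,
                                   permutation = NULL) {
  if (length(min_distances) == 0L || length(variances) == 0L)
    stop("'min_distances' and 'variances' must be non-empty")
  if (any(min_distances <= 0) || any(variances <= 0) || plane_limit <= 0)
    stop("all angular parameters must be positive")
  grid <- expand.grid(min_distance = min_distances, variance = variances)
  grid <- grid[grid$min_distance + grid$variance <= plane_limit, , drop = FALSE]
  grid <- grid[order(-grid$min_distance, grid$variance), , drop = FALSE]
  if (!is.null(permutation)) {
    if (!setequal(permutation, seq_len(nrow(grid))))
      stop("'permutation' must permute 1..", nrow(grid))
    grid <- grid[order(permutation), , drop = FALSE]
  }
  rownames(grid) <- NULL
  cbind(level = seq_len(nrow(grid)), grid)
}

start_level <- function(condition, n_levels = 15L) {
  mid <- as.integer(ceiling(n_levels / 2))
  switch(condition,
    inc_easy = 1L, inc_mid = mid, fixed = mid,
    dec_mid = mid, dec_hard = n_levels,
    stop("unknown condition: ", condition))
}

#' Within-trial difficulty trajectory
#'
#' Difficulty shifts by one level per probe from the condition's starting
#' level and clamps when an endpoint (level 1 or `n_levels`) is reached;
#' the fixed condition stays at the median level throughout.
#'
#' @param condition one of [pm_conditions].
#' @param n_probes number of probes in the trial (1 to `n_levels`).
#' @param n_levels number of difficulty levels (15 by default).
#' @return integer vector of difficulty levels, one per probe.
#' @examples
#' make_trajectory("inc_easy", 10)  # 1..10
#' @export
make_trajectory <- function(condition, n_probes, n_levels = 15L) {
  condition <- match.arg(condition, pm_conditions)
  if (!is.numeric(n_probes) || n_probes < 1)
    stop("'n_probes' must be a positive integer")
  n_probes <- as.integer(n_probes)
  step <- switch(condition, inc_easy = 1L, inc_mid = 1L, fixed = 0L,
                 dec_mid = -1L, dec_hard = -1L)
  lev <- start_level(condition, n_levels) + step * (seq_len(n_probes) - 1L)
  pmin(pmax(lev, 1L), as.integer(n_levels))
}

reflect_h <- function(theta) (360 - theta) %% 360
reflect_v <- function(theta) (180 - theta) %% 360

#' Sample one visual-search arrow array
#'
#' Draws distractor orientations for a 10-slot circular array. Base
#' orientations are uniform on `[min_distance, min_distance + variance]`;
#' each is then independently reflected across the horizontal plane
#' (`theta -> 360 - theta`) and the vertical plane (`theta -> 180 - theta`)
#' with probability 0.5, which confines distractors to
#' `[5,175] U [185,355]` degrees (never horizontal, the target orientation).
#' To avoid pop-out from a repeated local change, no distractor may lie
#' within 5 degrees (circular) of the orientation shown at the same slot on
#' the previous display; offending slots are resampled, and after
#' `max_attempts` failures the constraint is relaxed for that slot with a
#' warning.
#'
#' @param spec one row of [build_difficulty_table()].
#' @param previous the previous `arrow_array` at the same slots, or `NULL`.
#' @param target_present logical; if `TRUE` one slot shows the 0-degree
#'   target and only 9 distractors are drawn.
#' @param n_slots number of display slots.
#' @param seed optional integer seed for reproducibility.
#' @param max_attempts resampling budget per slot for the 5-degree rule.
#' @return list of class `arrow_array` with `orientations` (degrees per
#'   slot), `target_present`, `target_slot`.
#' @export
sample_arrow_array <- function(spec, previous = NULL, target_present = TRUE,
                               n_slots = 10L, seed = NULL,
                               max_attempts = 100L) {
  stopifnot(is.numeric(spec$min_distance), is.numeric(spec$variance))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(previous) && length(previous$orientations) != n_slots)
    stop("'previous' must have the same slot layout")
  target_slot <- if (target_present) sample.int(n_slots, 1L) else NA_integer_
  ori <- numeric(n_slots)
  for (s in seq_len(n_slots)) {
    if (!is.na(target_slot) && s == target_slot) {
      ori[s] <- 0
      next
    }
    prev <- if (is.null(previous)) NULL else previous$orientations[s]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      th <- spec$min_distance + stats::runif(1) * spec$variance
      if (stats::runif(1) < 0.5) th <- reflect_h(th)
      if (stats::runif(1) < 0.5) th <- reflect_v(th)
      if (is.null(prev) || is.na(prev) || circ_dist(th, prev) >= 5) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      warning("anti-pop-out constraint relaxed for slot ", s,
              " after ", max_attempts, " attempts")
    ori[s] <- th
  }
  structure(list(orientations = ori, target_present = target_present,
                 target_slot = target_slot),
            class = "arrow_array")
}

# Sample 8 localizer trial lengths in [2,12] summing to `total`.
localizer_lengths <- function(total = 60L, n_trials = 8L,
                              min_len = 2L, max_len = 12L) {
  for (i in seq_len(10000L)) {
    len <- sample(seq.int(min_len, max_len), n_trials - 1L, replace = TRUE)
    last <- total - sum(len)
    if (last >= min_len && last <= max_len)
      return(sample(c(len, last)))
  }
  stop("could not compose localizer trial lengths")  # nocov
}

# Build probe-level rows for one trial.
trial_probes <- function(block, trial, condition, pm_type, n_probes,
                         is_catch, onset, probe_s = 2) {
  lev <- make_trajectory(condition, n_probes)
  data.frame(
    block = block, trial = trial, probe = seq_len(n_probes),
    onset_s = onset + probe_s * (seq_len(n_probes) - 1L),
    condition = condition, pm_type = pm_type,
    difficulty_level = lev, is_catch = is_catch,
    is_final_probe = seq_len(n_probes) == n_probes,
    n_probes = n_probes,
    stringsAsFactors = FALSE)
}

#' Generate a session design
#'
#' Each block holds 15 trials, one per combination of PM type (face, scene,
#' non-PM) and difficulty condition ([pm_conditions]), in shuffled order.
#' Five trials per block are catch trials with fewer than eight probes;
#' which combinations are catch is counterbalanced across the session in
#' spans of three blocks (over a full span every combination is catch
#' exactly once). Within each full span the three PM types share identical
#' trial-length multisets, so face, scene and non-PM probe totals are equal
#' for any number of blocks divisible by three (approximately equal
#' otherwise). PM trials end with the reappearance of the PM target on the
#' final probe.
#'
#' @param n_blocks number of blocks (6 emulates the behavioral session,
#'   5 the scanner session).
#' @param seed integer seed; the design is a deterministic function of
#'   `(n_blocks, seed)`.
#' @param catch_lengths integer probe counts available to catch trials.
#' @param main_lengths integer probe counts available to non-catch trials.
#' @return probe-level design data.frame (one row per 2 s probe) with
#'   columns `block`, `trial`, `probe`, `onset_s`, `condition`, `pm_type`,
#'   `difficulty_level`, `is_catch`, `is_final_probe`, `n_probes`.
#' @export
generate_session <- function(n_blocks, seed = 1L,
                             catch_lengths = 2:7, main_lengths = 8:15) {
  if (!is.numeric(n_blocks) || n_blocks < 1)
    stop("'n_blocks' must be a positive integer")
  n_blocks <- as.integer(n_blocks)
  stopifnot(all(catch_lengths < 8), all(main_lengths >= 8),
            all(main_lengths <= 15))
  set.seed(seed)
  combos <- expand.grid(pm_type = pm_types, condition = pm_conditions,
                        stringsAsFactors = FALSE)
  out <- vector("list", n_blocks)
  trial_id <- 0L
  onset <- 0
  block <- 0L
  while (block < n_blocks) {
    span <- min(3L, n_blocks - block)
    perm <- sample.int(15L)  # catch counterbalancing within the span
    catch_of_block <- split(perm[seq_len(5L * span)],
                            rep(seq_len(span), each = 5L))
    # shared per-type length multisets over the span (5 catch + 10 main
    # trials per type per full span)
    shared_catch <- sample(catch_lengths, 5L, replace = TRUE)
    shared_main <- sample(main_lengths, 10L, replace = TRUE)
    len_pool <- lapply(pm_types, function(p) {
      list(catch = sample(shared_catch), main = sample(shared_main))
    })
    names(len_pool) <- pm_types
    used <- list(catch = stats::setNames(rep(0L, 3), pm_types),
                 main = stats::setNames(rep(0L, 3), pm_types))
    for (b in seq_len(span)) {
      block <- block + 1L
      rows <- combos[sample.int(15L), , drop = FALSE]
      catch_idx <- catch_of_block[[b]]
      is_catch <- as.integer(rownames(rows)) %in% catch_idx
      blk <- vector("list", 15L)
      for (i in seq_len(15L)) {
        p <- rows$pm_type[i]
        if (is_catch[i]) {
          used$catch[p] <- used$catch[p] + 1L
          np <- if (span == 3L) len_pool[[p]]$catch[used$catch[p]]
                else sample(catch_lengths, 1L)
        } else {
          used$main[p] <- used$main[p] + 1L
          np <- if (span == 3L) len_pool[[p]]$main[used$main[p]]
                else sample(main_lengths, 1L)
        }
        trial_id <- trial_id + 1L
        onset <- onset + 4           # 3 s target/null cue + 1 s fixation
        blk[[i]] <- trial_probes(block, trial_id, rows$condition[i], p,
                                 np, is_catch[i], onset)
        onset <- onset + 2 * np + 8  # probes + 2 s feedback + 6 s rest
      }
      out[[block]] <- do.call(rbind, blk)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate an ongoing-task localizer design
#'
#' Arrow-search-only blocks used to harvest labeled non-PM training samples
#' for the decoder. Each block holds 60 probes split into 8 trials of
#' lengths between 2 and 12 whose difficulty increases or decreases as in
#' the main task.
#'
#' @param n_blocks number of localizer blocks (2 in the scanner protocol).
#' @param seed integer seed.
#' @return probe-level design data.frame in the [generate_session()] layout
#'   (`pm_type` is always `"none"`).
#' @export
generate_localizer_design <- function(n_blocks, seed = 1L) {
  if (!is.numeric(n_blocks) || n_blocks < 1)
    stop("'n_blocks' must be a positive integer")
  n_blocks <- as.integer(n_blocks)
  set.seed(seed)
  dynamic <- setdiff(pm_conditions, "fixed")
  out <- vector("list", n_blocks)
  trial_id <- 0L
  onset <- 0
  for (b in seq_len(n_blocks)) {
    lens <- localizer_lengths()
    conds <- sample(dynamic, 8L, replace = TRUE)
    blk <- vector("list", 8L)
    for (i in seq_len(8L)) {
      trial_id <- trial_id + 1L
      blk[[i]] <- trial_probes(b, trial_id, conds[i], "none", lens[i],
                               FALSE, onset)
      onset <- onset + 2 * lens[i] + 6  # probes + 6 s rest
    }
    out[[b]] <- do.call(rbind, blk)
  }
  res <- do.call(rbind, out)
  res$is_final_probe <- res$probe == res$n_probes
  rownames(res) <- NULL
  res
}

#' Write / read a probe-level event table
#'
#' Tab-separated event tables in the spirit of BIDS `events.tsv` files.
#' @param events a probe-level design or cohort probe table.
#' @param path file path.
#' @return `read_events` returns the data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
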
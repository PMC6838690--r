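# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

test_cohort <- function(n = 16, blocks = 4, seed = 42, ...) {
  key <- paste("cohort", n, blocks, seed, paste(c(...), collapse = "_"))
  memo(key, {
    p <- synth_params(n_participants = n, n_blocks = blocks, seed = seed, ...)
    simulate_cohort(p)
  })
}

test_behavior <- function(n = 16, blocks = 4, seed = 42, ...) {
  key <- paste("behavior", n, blocks, seed, paste(c(...), collapse = "_"))
  memo(key, pm_cost_pipeline(test_cohort(n, blocks, seed, ...)))
}

# hand-built probe table: one participant, `blocks` blocks, each with one
# non-PM and one PM trial of `n_probes` probes at the given levels
toy_probes <- function(levels, rt_non, rt_pm, blocks = 2) {
  np <- length(levels)
  one <- function(b, tr, type, rts) {
    data.frame(participant = 1L, block = b, trial = tr,
               probe = seq_len(np), condition = "dec_mid", pm_type = type,
               difficulty_level = levels, is_catch = FALSE,
               is_final_probe = seq_len(np) == np, n_probes = np,
               rt = rts, og_correct = TRUE, response = "og",
               omitted = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(blocks), function(b) {
    rbind(one(b, 2L * b - 1L, "none", rt_non),
          one(b, 2L * b, "face", rt_pm))
  }))
}

toy_trials <- function(probes) {
  first <- !duplicated(paste(probes$participant, probes$trial))
  d <- probes[first, c("participant", "block", "trial", "condition",
                       "pm_type", "is_catch", "n_probes")]
  d$direction <- ifelse(d$condition == "fixed", "fix",
                        ifelse(grepl("^inc", d$condition), "inc", "dec"))
  d$pm_hit <- ifelse(d$pm_type == "none", NA, TRUE)
  rownames(d) <- NULL
  d
}

# small neural dataset (one participant) shared across mvpa tests
test_neural <- function(snr = 1, coupling = 0.5, blocks = 3, seed = 5,
                        n_features = 30) {
  key <- paste("neural", snr, coupling, blocks, seed, n_features)
  memo(key, {
    p <- synth_params(n_participants = 1, n_blocks = blocks, seed = seed)
    des <- generate_session(blocks, seed = seed)
    sim <- simulate_participant(des, p, seed = seed + 1)
    np <- neural_synth_params(snr = snr, coupling = coupling,
                              n_features = n_features)
    tpl <- class_templates(np, seed)
    list(sim = sim,
         ds = simulate_neural(sim$probes, np, seed = seed, templates = tpl),
         loc = simulate_localizer(np, tpl, seed = seed),
         nparams = np, templates = tpl)
  })
}
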
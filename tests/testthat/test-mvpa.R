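test_that("the ANOVA screen matches aov and holds its null retention rate", {
  set.seed(3)
  n <- 120
  labels <- sample(rep(c("face", "scene", "og", "rest"), n / 4))
  X <- matrix(rnorm(n * 2000), n)
  X[, 1] <- X[, 1] + 2 * (labels == "face")  # planted separation
  keep <- screen_features(X, labels)
  expect_true(1 %in% keep)
  expect_lte(length(keep), ncol(X))
  # null features retained at about the alpha rate
  null_rate <- (length(keep) - 1) / (ncol(X) - 1)
  expect_gt(null_rate, 0.02)
  expect_lt(null_rate, 0.09)
  # per-feature p-values agree with a stats::aov oracle
  for (j in 1:3) {
    pv <- summary(aov(X[, j] ~ factor(labels)))[[1]][["Pr(>F)"]][1]
    expect_equal(j %in% keep, pv < 0.05)
  }
  Xz <- cbind(X[, 1:5], 0)
  expect_warning(screen_features(Xz, labels), "zero-variance")
})

test_that("one-vs-rest classifiers separate an easy toy problem", {
  set.seed(4)
  centers <- rbind(c(6, 0), c(0, 6), c(-6, 0), c(0, -6))
  rownames(centers) <- c("face", "scene", "og", "rest")
  lab <- rep(rownames(centers), each = 50)
  X <- centers[rep(1:4, each = 50), ] + matrix(rnorm(400, sd = 0.5), 200)
  clf <- train_ovr_classifiers(X, lab, penalty = 1)
  ev <- predict_evidence(clf, X)
  pred <- colnames(ev)[max.col(ev)]
  expect_equal(mean(pred == lab), 1)
  # evidence is probability-scale per classifier, not normalized across
  expect_false(all(abs(rowSums(ev) - 1) < 0.01))
  expect_error(train_ovr_classifiers(X[1:100, ], lab[1:100]), "rest")

  # ridge limit: a huge penalty shrinks evidence to the class base rate
  clf_big <- train_ovr_classifiers(X, lab, penalty = 1e7)
  ev_big <- predict_evidence(clf_big, X)
  expect_lt(max(abs(ev_big[, "face"] - 0.25)), 0.02)
})

test_that("a lightly penalized fit agrees with an unregularized glm oracle", {
  set.seed(6)
  n <- 2000
  X <- matrix(rnorm(n * 3), n)
  y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0.25)))
  lab <- ifelse(y == 1, "face", "scene")
  clf <- train_ovr_classifiers(X, lab, penalty = 0.01,
                               classes = c("face", "scene"))
  ridge <- as.numeric(coef(clf$models[["face"]]))
  oracle <- unname(coef(glm(y ~ X, binomial)))
  expect_equal(ridge, oracle, tolerance = 0.05)
})

test_that("cross-validation scores every usable sample exactly once", {
  fx <- test_neural(seed = 5)
  cv <- crossvalidate(fx$ds, fx$loc)
  usable <- fx$ds$events$sample[fx$ds$events$usable &
                                  !is.na(fx$ds$events$label)]
  expect_setequal(cv$evidence$sample, usable)
  expect_equal(anyDuplicated(cv$evidence$sample), 0L)
  expect_gt(cv$accuracy, 0.5)
  expect_true(all(cv$auc > 0.5, na.rm = TRUE))

  one_run <- fx$ds
  keep <- one_run$events$run == 1
  one_run$X <- one_run$X[keep, , drop = FALSE]
  one_run$events <- one_run$events[keep, , drop = FALSE]
  expect_error(crossvalidate(one_run), "single task run")
})

test_that("within-fold screening avoids the leakage of full-data screening", {
  set.seed(12)
  p <- synth_params(n_participants = 1, n_blocks = 2, seed = 13)
  des <- generate_session(2, seed = 13)
  sim <- simulate_participant(des, p, seed = 13)
  np <- neural_synth_params(snr = 0, coupling = 0, n_features = 300)
  ds <- simulate_neural(sim$probes, np, seed = 14)
  proper <- crossvalidate(ds)
  # leaky variant: screen once on all usable rows (labels included), then
  # cross-validate on the pre-selected features only
  ev <- ds$events
  rows <- ev$usable & !is.na(ev$label)
  keep <- screen_features(scale(ds$X[rows, ]), ev$label[rows])
  leaky <- ds
  leaky$X <- ds$X[, keep, drop = FALSE]
  leaked <- crossvalidate(leaky, alpha = 1)
  expect_false(isTRUE(all.equal(proper$accuracy, leaked$accuracy)))
  # on pure noise the leaky pipeline looks better than it should
  expect_gt(leaked$accuracy, proper$accuracy)
})

test_that("scrambled labels preserve run-wise class counts and chance accuracy", {
  fx <- test_neural(seed = 5)
  sb <- scrambled_baseline(fx$ds, fx$loc, n_perm = 30, seed = 2)
  expect_length(sb$accuracies, 30L)
  expect_lt(abs(sb$mean - 0.28), 0.1)  # near chance for these base rates
  expect_gt(sb$sd, 0)
  # real labels beat the scrambled distribution on signal data
  cv <- crossvalidate(fx$ds, fx$loc)
  expect_gt(cv$accuracy, quantile(sb$accuracies, 0.95))
})

test_that("PM intention evidence is the target-minus-nontarget contrast", {
  ev <- data.frame(
    sample = 1:8, run = 1, trial = rep(c(1, 2), each = 4),
    label = rep(c("face", "scene"), each = 4),
    target = rep(c("face", "scene"), each = 4),
    is_final_probe = rep(c(FALSE, FALSE, FALSE, TRUE), 2),
    face = c(0.9, 0.8, 0.7, 0.6, 0.2, 0.2, 0.2, 0.2),
    scene = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.6, 0.6, 0.6),
    og = 0.1, rest = 0.1, predicted = "face",
    stringsAsFactors = FALSE)
  dec <- structure(list(evidence = ev), class = "decoding_result")
  probes <- data.frame(trial = rep(c(1, 2), each = 4), probe = rep(1:4, 2),
                       difficulty_level = rep(c(3, 9), each = 4))
  out <- pm_intention_evidence(dec, probes)
  expect_equal(out$trials$mean_ev,
               c(mean(c(0.8, 0.6, 0.4)), mean(c(0.4, 0.4, 0.4))))
  # antisymmetry: swapping target and nontarget flips the sign exactly
  ev2 <- ev
  ev2$target <- ifelse(ev$target == "face", "scene", "face")
  out2 <- pm_intention_evidence(structure(list(evidence = ev2),
                                          class = "decoding_result"), probes)
  expect_equal(out2$trials$mean_ev, -out$trials$mean_ev)
  # equal face/scene evidence -> zero EV; constant evidence -> zero slope
  ev3 <- ev
  ev3$scene <- ev3$face
  out3 <- pm_intention_evidence(structure(list(evidence = ev3),
                                          class = "decoding_result"), probes)
  expect_equal(out3$trials$mean_ev, c(0, 0))
  expect_equal(out2$trials$ev_slope[2], 0)
  # final probe excluded by default, included on request
  expect_equal(out$trials$n_used, c(3L, 3L))
  out_f <- pm_intention_evidence(dec, probes, include_final = TRUE)
  expect_equal(out_f$trials$n_used, c(4L, 4L))
  # difficulty profile maps samples back to probe difficulty
  expect_setequal(out$by_level$difficulty_level, c(3, 9))
})
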
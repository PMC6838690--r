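# Simplified decoding stage: ANOVA feature screening, one-vs-rest
# L2-penalized logistic classifiers, leave-one-run-out cross-validation
# with localizer augmentation, scrambled-label chance calibration, and
# per-trial PM intention evidence.

#' ANOVA feature screen
#'
#' One-way F-test per feature across the four classes; features whose
#' between-class variance is significant at `alpha` are retained. Features
#' must be z-scored across all time points beforehand (the cross-validation
#' driver does this); zero-variance features are excluded with a warning.
#' The screen is refit inside each cross-validation fold on training rows
#' only, so selection never sees test data.
#'
#' @param X samples x features matrix (training rows only).
#' @param labels class label per row.
#' @param alpha retention threshold on the F-test p-value.
#' @return integer vector of retained feature indices.
#' @export
screen_features <- function(X, labels, alpha = 0.05) {
  labels <- factor(labels)
  n <- nrow(X)
  g <- nlevels(labels)
  if (g < 2L) stop("need at least two classes to screen features")
  v <- apply(X, 2, stats::var)
  zero <- v <= 0 | !is.finite(v)
  if (any(zero)) warning(sum(zero), " zero-variance feature(s) excluded")
  gm <- rowsum(X, labels) / as.vector(table(labels))
  grand <- colMeans(X)
  ssb <- colSums(as.vector(table(labels)) * (gm - rep(grand, each = g))^2)
  sst <- colSums((X - rep(grand, each = n))^2)
  ssw <- sst - ssb
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  p <- stats::pf(f, g - 1, n - g, lower.tail = FALSE)
  which(!zero & !is.na(p) & p < alpha)
}

# map the toolbox-style penalty (weight on sum of squared coefficients in
# the unnormalized loss) to glmnet's ridge lambda: glmnet minimizes
# -loglik/n + lambda/2 * ||beta||^2, so lambda = 2*penalty/n.
penalty_to_lambda <- function(penalty, n) 2 * penalty / n

#' Train one-vs-rest penalized logistic classifiers
#'
#' One binary ridge (L2) logistic classifier per class, each trained to
#' separate its class from all others. `penalty` is the weight on the
#' squared-coefficient term of the regularized logistic loss (the
#' convention of the MVPA toolboxes this emulates); it is mapped
#' internally to glmnet's per-observation lambda. The classifier's
#' evidence for a time point is its probability-scale output, so the four
#' evidence values need not sum to one across classes.
#'
#' @param X training matrix (samples x features).
#' @param labels class per row; every class in `classes` must be present.
#' @param penalty L2 penalty weight (50 by default).
#' @param classes class set and tie-break order.
#' @return list of class `ovr_classifiers`.
#' @export
train_ovr_classifiers <- function(X, labels, penalty = 50,
                                  classes = mvpa_classes) {
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls))
    stop("class absent from training data: ",
         paste(missing_cls, collapse = ", "))
  lam <- penalty_to_lambda(penalty, nrow(X))
  models <- lapply(classes, function(cl) {
    y <- as.integer(labels == cl)
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lam, standardize = FALSE)
  })
  names(models) <- classes
  structure(list(models = models, classes = classes, penalty = penalty),
            class = "ovr_classifiers")
}

#' Evidence of each class for new samples
#'
#' @param object `ovr_classifiers` from [train_ovr_classifiers()].
#' @param X samples x features matrix on the training feature set.
#' @return samples x classes matrix of probability-scale evidence.
#' @export
predict_evidence <- function(object, X) {
  ev <- vapply(object$classes, function(cl) {
    as.numeric(stats::predict(object$models[[cl]], X, type = "response"))
  }, numeric(nrow(X)))
  colnames(ev) <- object$classes
  ev
}

zscore_cols <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  scale(X, center = TRUE, scale = s)
}

rank_auc <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                 direction = "<", levels = c(FALSE, TRUE))))
}

#' Leave-one-run-out cross-validated decoding
#'
#' Task runs rotate as the held-out test set; localizer datasets (if any)
#' are always in training. Features are z-scored across all time points of
#' each dataset; the ANOVA screen and the one-vs-rest classifiers are refit
#' within each fold on training rows only. Final probes of each trial are
#' excluded from training (the PM target is on screen) but are scored at
#' test. The predicted class is the evidence argmax with ties broken by
#' the fixed class order (face, scene, og, rest).
#'
#' @param dataset a `neural_dataset` of task data.
#' @param localizer a `neural_dataset` (or list of them) of localizer data,
#'   or `NULL`.
#' @param penalty L2 penalty weight.
#' @param alpha feature-screen threshold.
#' @param folds run identifiers to hold out (defaults to all task runs;
#'   a subset gives a reduced-fold evaluation).
#' @return list of class `decoding_result`: `evidence` (per test sample:
#'   run, trial, label, evidence per class, predicted), `accuracy`,
#'   `auc` per class, `n_features` retained per fold.
#' @export
crossvalidate <- function(dataset, localizer = NULL, penalty = 50,
                          alpha = 0.05, folds = NULL) {
  stopifnot(inherits(dataset, "neural_dataset"))
  if (inherits(localizer, "neural_dataset")) localizer <- list(localizer)
  ev <- dataset$events
  runs <- unique(ev$run)
  if (length(runs) < 2L)
    stop("a single task run cannot be cross-validated; split the session ",
         "into at least two runs")
  if (is.null(folds)) folds <- runs
  X <- zscore_cols(dataset$X)
  loc_X <- NULL
  loc_lab <- character(0)
  for (l in localizer) {
    lX <- zscore_cols(l$X)
    keep <- l$events$in_training & !is.na(l$events$label)
    loc_X <- rbind(loc_X, lX[keep, , drop = FALSE])
    loc_lab <- c(loc_lab, l$events$label[keep])
  }
  out_rows <- list()
  n_feat <- integer(0)
  for (r in folds) {
    test <- which(ev$run == r & ev$usable & !is.na(ev$label))
    train <- which(ev$run != r & ev$in_training & !is.na(ev$label))
    Xtr <- rbind(X[train, , drop = FALSE], loc_X)
    ytr <- c(ev$label[train], loc_lab)
    keep <- screen_features(Xtr, ytr, alpha = alpha)
    if (length(keep) < 2L) keep <- seq_len(ncol(Xtr))
    n_feat[as.character(r)] <- length(keep)
    clf <- train_ovr_classifiers(Xtr[, keep, drop = FALSE], ytr, penalty)
    evd <- predict_evidence(clf, X[test, keep, drop = FALSE])
    pred <- mvpa_classes[max.col(evd[, mvpa_classes, drop = FALSE],
                                 ties.method = "first")]
    out_rows[[as.character(r)]] <- data.frame(
      sample = ev$sample[test], run = r, trial = ev$trial[test],
      label = ev$label[test], target = ev$target[test],
      is_final_probe = ev$is_final_probe[test],
      evd, predicted = pred, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out_rows)
  rownames(res) <- NULL
  acc <- mean(res$predicted == res$label)
  auc <- vapply(mvpa_classes, function(cl) {
    truth <- res$label == cl
    if (length(unique(truth)) < 2L) return(NA_real_)
    rank_auc(truth, res[[cl]])
  }, 0)
  structure(list(evidence = res, accuracy = acc, auc = auc,
                 n_features = n_feat),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding accuracy: %.1f%% over %d test samples\n",
              100 * x$accuracy, nrow(x$evidence)))
  cat("per-class AUC:",
      paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  invisible(x)
}

#' Scrambled-label chance calibration
#'
#' Permutes the class labels within each run (preserving run structure and
#' per-run class counts) and reruns the cross-validation pipeline, giving
#' the empirical chance distribution of decoding accuracy. For balanced
#' classes the distribution centers on 25%.
#'
#' @param dataset,localizer,penalty,alpha as in [crossvalidate()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param folds_per_perm held-out runs evaluated per permutation (1 by
#'   default to keep the calibration affordable; `NULL` for all).
#' @return list: `accuracies` (length `n_perm`), `mean`, `sd`.
#' @export
scrambled_baseline <- function(dataset, localizer = NULL, n_perm = 1000L,
                               seed = 1L, penalty = 50, alpha = 0.05,
                               folds_per_perm = 1L) {
  stopifnot(inherits(dataset, "neural_dataset"))
  set.seed(seed)
  runs <- unique(dataset$events$run)
  acc <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    d <- dataset
    for (r in runs) {
      rows <- which(d$events$run == r & !is.na(d$events$label))
      d$events$label[rows] <- sample(d$events$label[rows])
    }
    folds <- if (is.null(folds_per_perm)) runs
             else sample(runs, min(folds_per_perm, length(runs)))
    cv <- crossvalidate(d, localizer, penalty = penalty, alpha = alpha,
                        folds = folds)
    acc[i] <- cv$accuracy
  }
  list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc))
}

#' Subsample a dataset to balanced class counts
#'
#' Randomly trims usable samples so every class occurs equally often within
#' each run (useful for chance-level calibration on balanced data).
#'
#' @param dataset a `neural_dataset`.
#' @param seed integer seed.
#' @return the trimmed `neural_dataset`.
#' @export
balance_dataset <- function(dataset, seed = 1L) {
  set.seed(seed)
  ev <- dataset$events
  keep <- logical(nrow(ev))
  for (r in unique(ev$run)) {
    rows <- which(ev$run == r & ev$usable & !is.na(ev$label))
    cnt <- table(ev$label[rows])
    m <- min(cnt)
    for (cl in names(cnt)) {
      cl_rows <- rows[ev$label[rows] == cl]
      keep[sample(cl_rows, m)] <- TRUE
    }
  }
  dataset$X <- dataset$X[keep, , drop = FALSE]
  dataset$events <- ev[keep, , drop = FALSE]
  dataset
}

#' Per-trial PM intention evidence
#'
#' PM intention evidence (PM EV) at a time point is the classifier evidence
#' for the PM target's category minus the evidence for the nontarget
#' category (the other of face/scene). Defined only on PM trials; the
#' final probe (target on screen) is excluded by default, consistent with
#' its exclusion from classifier training. Reports the trial mean EV, the
#' within-trial least-squares EV slope in EV/s, and the EV-by-difficulty
#' profile.
#'
#' @param decoding a `decoding_result` from [crossvalidate()].
#' @param probes the participant's probe table (for difficulty levels).
#' @param tr sampling interval in seconds.
#' @param include_final include the target-reappearance probe.
#' @return list: `trials` (trial, target, `mean_ev`, `ev_slope`, `n_used`),
#'   `by_level` (mean EV per difficulty level), `timepoints` (per-sample
#'   EV).
#' @export
pm_intention_evidence <- function(decoding, probes, tr = 2,
                                  include_final = FALSE) {
  res <- decoding$evidence
  pm <- res[!is.na(res$target) & res$target %in% c("face", "scene") &
              res$label %in% c("face", "scene"), , drop = FALSE]
  if (!include_final) pm <- pm[!pm$is_final_probe, , drop = FALSE]
  if (nrow(pm) == 0L) stop("no PM-trial evidence samples available")
  pm$ev <- ifelse(pm$target == "face",
                  pm$face - pm$scene, pm$scene - pm$face)
  sp <- split(pm, pm$trial)
  trials <- do.call(rbind, lapply(sp, function(d) {
    slope <- if (nrow(d) >= 3L)
      unname(stats::coef(stats::lm(d$ev ~ I(d$sample * tr)))[2])
    else NA_real_
    data.frame(trial = d$trial[1], target = d$target[1],
               mean_ev = mean(d$ev), ev_slope = slope, n_used = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(trials) <- NULL
  # difficulty level of the probe generating each (lag-aligned) sample
  key <- match(paste(pm$trial, ave(pm$sample, pm$trial, FUN = seq_along)),
               paste(probes$trial, probes$probe))
  pm$difficulty_level <- probes$difficulty_level[key]
  by_level <- stats::aggregate(ev ~ difficulty_level,
                               data = pm[!is.na(pm$difficulty_level), ],
                               FUN = mean)
  names(by_level)[2] <- "mean_ev"
  list(trials = trials, by_level = by_level, timepoints = pm)
}
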
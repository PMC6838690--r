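# Participant-level bootstrap inference: logistic regressions linking PM
# cost slope (and PM intention evidence) to PM accuracy, partial
# regressions, and wAIC model comparison.

# Fast pooled logistic fit on a model matrix; flags (quasi-)separation.
logit_fit <- function(X, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 25)) sep <- TRUE
  rank_ok <- fit$rank == ncol(X)
  ll <- -fit$deviance / 2
  list(beta = beta, loglik = ll, aic = fit$deviance + 2 * ncol(X),
       separated = sep || !rank_ok,
       fitted = fit$fitted.values)
}

#' Participant-level bootstrap
#'
#' On each iteration the full participant count is resampled with
#' replacement, their trials are pooled, and `stat_fn` is applied to the
#' pooled table. Iterations where `stat_fn` signals an error or returns a
#' vector with a `separated = TRUE` attribute are dropped and counted.
#'
#' @param data trial-level data.frame with a `participant` column.
#' @param stat_fn function of a pooled data.frame returning a named
#'   numeric vector.
#' @param n_iter bootstrap iterations.
#' @param seed integer seed.
#' @param max_drop_frac abort if more than this fraction of iterations is
#'   dropped.
#' @return matrix of per-iteration statistics with attribute `n_dropped`.
#' @export
bootstrap_participants <- function(data, stat_fn, n_iter = 10000L,
                                   seed = 1L, max_drop_frac = 0.05) {
  if (!"participant" %in% names(data)) stop("'participant' column required")
  set.seed(seed)
  ids <- unique(data$participant)
  idx <- split(seq_len(nrow(data)), data$participant)
  out <- vector("list", n_iter)
  dropped <- 0L
  for (it in seq_len(n_iter)) {
    take <- sample(as.character(ids), length(ids), replace = TRUE)
    d <- data[unlist(idx[take], use.names = FALSE), , drop = FALSE]
    st <- tryCatch(stat_fn(d), error = function(e) NULL)
    if (is.null(st) || isTRUE(attr(st, "separated"))) {
      dropped <- dropped + 1L
      next
    }
    out[[it]] <- st
  }
  if (dropped > max_drop_frac * n_iter)
    stop("more than ", 100 * max_drop_frac,
         "% of bootstrap iterations dropped (", dropped, "/", n_iter, ")")
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  attr(res, "n_dropped") <- dropped
  res
}

# two-sided percentile bootstrap p-value, floored at 1/n
boot_p <- function(v) {
  n <- length(v)
  max(2 * min(mean(v <= 0), mean(v >= 0)), 1 / n)
}

boot_summary <- function(boot, point) {
  data.frame(
    term = colnames(boot),
    estimate = point[colnames(boot)],
    boot_mean = colMeans(boot),
    ci_lo = apply(boot, 2, stats::quantile, 0.025),
    ci_hi = apply(boot, 2, stats::quantile, 0.975),
    p = apply(boot, 2, boot_p),
    row.names = NULL)
}

#' Logistic link between PM cost slope and PM accuracy
#'
#' Pooled fixed-effect logistic regressions of PM hit on PM cost slope,
#' fitted separately within each trial direction, plus the
#' slope-by-direction interaction model on the directions jointly.
#' Point estimates come from the full sample; confidence intervals and
#' two-sided p-values from the participant bootstrap (percentile method).
#' Resamples with a separated or degenerate fit are dropped and counted.
#'
#' @param trials trial summaries with `participant`, `direction`,
#'   `cost_slope` (ms/s) and logical/0-1 `pm_hit`; rows with undefined
#'   slope or missing outcome are ignored.
#' @param directions the two directions entering the interaction model.
#' @param n_iter bootstrap iterations (10000 for full fidelity; smaller
#'   values trade precision for time).
#' @param seed integer seed.
#' @return list of class `pm_slope_fit`: `coefficients` (per-direction
#'   slope betas and the interaction with CI and p), `boot` (iteration
#'   draws), `n_dropped`.
#' @export
slope_accuracy_model <- function(trials, directions = c("dec", "inc"),
                                 n_iter = 2000L, seed = 1L) {
  d <- trials[!is.na(trials$cost_slope) & !is.na(trials$pm_hit) &
                trials$direction %in% directions, , drop = FALSE]
  d$pm_hit <- as.integer(d$pm_hit)
  stat <- function(dd) {
    out <- c()
    sep <- FALSE
    for (dir in directions) {
      di <- dd[dd$direction == dir, , drop = FALSE]
      if (nrow(di) < 10L || length(unique(di$pm_hit)) < 2L)
        return(structure(NA_real_, separated = TRUE))
      f <- logit_fit(cbind(1, di$cost_slope), di$pm_hit)
      sep <- sep || f$separated
      out[paste0("beta_", dir)] <- f$beta[2]
    }
    dd2 <- dd[dd$direction %in% directions, , drop = FALSE]
    dir_dec <- as.integer(dd2$direction == directions[1])
    X <- cbind(1, dd2$cost_slope, dir_dec, dd2$cost_slope * dir_dec)
    f <- logit_fit(X, dd2$pm_hit)
    sep <- sep || f$separated
    out["beta_interaction"] <- f$beta[4]
    structure(out, separated = sep)
  }
  point <- stat(d)
  boot <- bootstrap_participants(d, stat, n_iter = n_iter, seed = seed)
  res <- list(coefficients = boot_summary(boot, point), boot = boot,
              n_dropped = attr(boot, "n_dropped"))
  class(res) <- "pm_slope_fit"
  res
}

#' @export
print.pm_slope_fit <- function(x, ...) {
  cat("Bootstrap logistic regression of PM accuracy on PM cost slope\n")
  print(x$coefficients, digits = 3)
  cat("dropped iterations:", x$n_dropped, "\n")
  invisible(x)
}

#' Partial variance explained
#'
#' Residualizes the focal predictor and the outcome on a control variable
#' and reports the variance of the outcome residual explained by the focal
#' residual, i.e. how much of the outcome the focal predictor explains
#' beyond the control.
#'
#' @param data data.frame (trial- or participant-level).
#' @param outcome,focal,control column names; `control` may be a vector of
#'   columns to partial out jointly.
#' @return list with `partial_r2`, `marginal_r2` and the p-value of the
#'   focal residual term.
#' @export
partial_r2 <- function(data, outcome, focal, control) {
  d <- stats::na.omit(data[, unique(c(outcome, focal, control)),
                           drop = FALSE])
  for (v in control)
    if (stats::var(d[[v]]) == 0) stop("constant control covariate: ", v)
  ctrl <- as.matrix(d[, control, drop = FALSE])
  rf <- stats::residuals(stats::lm(d[[focal]] ~ ctrl))
  ro <- stats::residuals(stats::lm(d[[outcome]] ~ ctrl))
  fit <- stats::lm(ro ~ rf)
  marg <- summary(stats::lm(d[[outcome]] ~ d[[focal]]))$r.squared
  list(partial_r2 = summary(fit)$r.squared,
       marginal_r2 = marg,
       p = summary(fit)$coefficients["rf", "Pr(>|t|)"])
}

# candidate logistic models over slope (s), evidence (e), direction (g)
candidate_models <- function() {
  list(
    s        = function(d) cbind(1, d$cost_slope),
    e        = function(d) cbind(1, d$mean_ev),
    g        = function(d) cbind(1, d$dir_dec),
    s_g      = function(d) cbind(1, d$cost_slope, d$dir_dec,
                                 d$cost_slope * d$dir_dec),
    e_g      = function(d) cbind(1, d$mean_ev, d$dir_dec,
                                 d$mean_ev * d$dir_dec),
    s_e      = function(d) cbind(1, d$cost_slope, d$mean_ev,
                                 d$cost_slope * d$mean_ev),
    full     = function(d) {
      s <- d$cost_slope; e <- d$mean_ev; g <- d$dir_dec
      cbind(1, s, e, g, s * e, s * g, e * g, s * e * g)
    })
}

#' Compare behavioral, neural and combined predictors of PM accuracy
#'
#' Fits all candidate logistic models of PM hit on PM cost slope, mean PM
#' intention evidence and trial direction on each participant-bootstrap
#' resample; per iteration selects the best behavior-only, best
#' neural-only and the full combined model by AIC, converts the three AICs
#' to Akaike weights, and summarizes weights with medians, paired Wilcoxon
#' signed-rank tests and median weight ratios.
#'
#' @param trials trial summaries with `participant`, `direction` in
#'   `c("dec","inc")` rows used, `cost_slope`, `mean_ev`, `pm_hit`.
#' @param n_iter bootstrap iterations.
#' @param seed integer seed.
#' @return list: `median_waic`, `wilcoxon` (combined vs each single-domain
#'   model), `median_ratio`, `boot_waic` (iterations x 3), `n_dropped`.
#' @export
compare_predictor_models <- function(trials, n_iter = 1000L, seed = 1L) {
  d <- trials[trials$direction %in% c("dec", "inc") &
                !is.na(trials$cost_slope) & !is.na(trials$pm_hit), ,
              drop = FALSE]
  has_ev <- "mean_ev" %in% names(d) && any(!is.na(d$mean_ev))
  if (!has_ev)
    warning("no neural metric available; behavior-only comparison")
  else
    d <- d[!is.na(d$mean_ev), , drop = FALSE]
  d$pm_hit <- as.integer(d$pm_hit)
  d$dir_dec <- as.integer(d$direction == "dec")
  mods <- candidate_models()
  behav <- c("s", "g", "s_g")
  neur <- c("e", "g", "e_g")
  if (!has_ev) mods <- mods[behav]
  stat <- function(dd) {
    aics <- vapply(mods, function(m) {
      f <- logit_fit(m(dd), dd$pm_hit)
      if (f$separated) NA_real_ else f$aic
    }, 0)
    if (any(is.na(aics))) return(structure(NA_real_, separated = TRUE))
    if (!has_ev) {
      w <- akaike_weights(aics)
      names(w) <- names(mods)
      return(w)
    }
    three <- c(combined = aics[["full"]],
               behavior = min(aics[behav]),
               neural = min(aics[neur]))
    w <- akaike_weights(three)
    names(w) <- names(three)
    w
  }
  boot <- bootstrap_participants(d, stat, n_iter = n_iter, seed = seed)
  med <- apply(boot, 2, stats::median)
  if (!has_ev)
    return(list(median_waic = med, wilcoxon = NULL, median_ratio = NULL,
                boot_waic = boot, n_dropped = attr(boot, "n_dropped")))
  wil <- lapply(c("behavior", "neural"), function(other) {
    wt <- stats::wilcox.test(boot[, "combined"], boot[, other],
                             paired = TRUE, exact = FALSE)
    data.frame(comparison = paste0("combined_vs_", other),
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  ratio <- c(behavior = stats::median(boot[, "combined"] / boot[, "behavior"]),
             neural = stats::median(boot[, "combined"] / boot[, "neural"]))
  list(median_waic = med, wilcoxon = do.call(rbind, wil),
       median_ratio = ratio, boot_waic = boot,
       n_dropped = attr(boot, "n_dropped"))
}
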
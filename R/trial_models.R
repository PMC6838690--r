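# Per-trial polynomial model selection: least-squares fits of PM cost
# against difficulty, Gaussian-likelihood AIC/AICc, Akaike weights,
# best-fit proportions and the super-subject bootstrap selection analysis.

#' Akaike weights
#'
#' `w_i = exp(-(s_i - min(s))/2) / sum_j exp(-(s_j - min(s))/2)` over a set
#' of AIC or AICc scores; invariant to adding a constant to all scores.
#'
#' @param scores finite AIC/AICc values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(scores) {
  if (length(scores) == 0L) stop("'scores' must be non-empty")
  if (any(!is.finite(scores))) stop("'scores' must be finite")
  d <- scores - min(scores)
  w <- exp(-d / 2)
  w / sum(w)
}

# Gaussian-likelihood information criteria from a least-squares fit.
# k counts the polynomial coefficients (order + 1 incl. intercept) plus
# the error variance by default (k_extra = 1).
ls_ic <- function(rss, n, n_coef, k_extra = 1L) {
  rss <- max(rss, 1e-10)  # guard exact fits
  k <- n_coef + k_extra
  aic <- n * log(rss / n) + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  list(k = k, aic = aic, aicc = aicc)
}

#' Polynomial fits of PM cost against difficulty for one trial
#'
#' Least-squares fits of first-, second- and third-order polynomials. A
#' first-order winner indicates a fluid, graded shift of strategy within
#' the trial; a cubic winner would indicate an all-or-none flip. The
#' parameter count used in the information criteria includes the error
#' variance (`k = order + 2`); this convention only shifts all scores in a
#' comparison by a constant and can be changed via `k_extra`. Orders with
#' fewer than `order + 2` points are flagged unfit, and orders whose AICc
#' small-sample denominator `n - k - 1` is non-positive have `aicc = NA`
#' (disqualified from AICc comparisons rather than scored infinitely).
#'
#' @param cost per-probe PM costs (s); NAs are dropped.
#' @param x predictor, normally the difficulty level per probe.
#' @param orders polynomial orders to fit.
#' @param k_extra extra parameters counted beyond the coefficients.
#' @return data.frame `order`, `n`, `rss`, `k`, `aic`, `aicc`, `qualified`
#'   with AICc Akaike weights over the qualified orders in `weight`.
#' @export
fit_trial_polynomials <- function(cost, x, orders = 1:3, k_extra = 1L) {
  ok <- !is.na(cost) & !is.na(x)
  cost <- cost[ok]
  x <- x[ok]
  n <- length(cost)
  if (n < 3L) stop("too few points to fit any polynomial")
  if (length(unique(x)) < 2L)
    stop("degenerate design: constant predictor (fixed-difficulty trial?)")
  fits <- lapply(orders, function(p) {
    if (n < p + 2L || length(unique(x)) < p + 1L)
      return(data.frame(order = p, n = n, rss = NA_real_, k = NA_real_,
                        aic = NA_real_, aicc = NA_real_, qualified = FALSE))
    X <- cbind(1, stats::poly(x, degree = p))
    f <- stats::lm.fit(X, cost)
    rss <- sum(f$residuals^2)
    ic <- ls_ic(rss, n, p + 1L, k_extra)
    data.frame(order = p, n = n, rss = rss, k = ic$k, aic = ic$aic,
               aicc = ic$aicc, qualified = TRUE)
  })
  out <- do.call(rbind, fits)
  out$weight <- NA_real_
  q <- out$qualified & is.finite(out$aicc)
  if (any(q)) out$weight[q] <- akaike_weights(out$aicc[q])
  out
}

#' Fit polynomials for every dynamic trial of a cohort
#'
#' Applies [fit_trial_polynomials()] to each PM trial with varying
#' difficulty. Fixed-difficulty trials have a constant difficulty regressor
#' and are skipped (reported in attribute `n_skipped`).
#'
#' @param costed_probes PM-trial probes with `cost` (from [probe_costs()]).
#' @param predictor column used as regressor (`"difficulty_level"`).
#' @param min_points trials with fewer usable costs are skipped.
#' @return long data.frame of fits with `participant`, `trial`,
#'   `condition` prepended.
#' @export
fit_cohort_trials <- function(costed_probes, predictor = "difficulty_level",
                              min_points = 3L) {
  cp <- costed_probes[costed_probes$pm_type != "none", , drop = FALSE]
  if (!"participant" %in% names(cp)) cp$participant <- 1L
  sp <- split(cp, paste(cp$participant, cp$trial))
  skipped <- 0L
  rows <- lapply(sp, function(d) {
    x <- d[[predictor]]
    ok <- !is.na(d$cost) & !is.na(x)
    if (sum(ok) < min_points || length(unique(x[ok])) < 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    f <- fit_trial_polynomials(d$cost, x)
    cbind(participant = d$participant[1], trial = d$trial[1],
          condition = d$condition[1], f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Best-fit proportions and mean Akaike weights by order
#'
#' For each participant, the fraction of trials whose lowest AICc (or AIC)
#' belongs to each polynomial order, plus the mean Akaike weight per order;
#' cohort means with normal-approximation 95% confidence intervals.
#'
#' @param fits output of [fit_cohort_trials()].
#' @param criterion `"aicc"` or `"aic"`.
#' @return list with `by_participant` and `cohort` data.frames.
#' @export
best_fit_proportions <- function(fits, criterion = c("aicc", "aic")) {
  criterion <- match.arg(criterion)
  sp <- split(fits, paste(fits$participant, fits$trial))
  win <- lapply(sp, function(f) {
    s <- f[[criterion]]
    q <- f$qualified & is.finite(s)
    if (!any(q)) return(NULL)
    w <- akaike_weights(s[q])
    weights <- stats::setNames(rep(0, nrow(f)), f$order)
    weights[as.character(f$order[q])] <- w
    data.frame(participant = f$participant[1],
               winner = f$order[q][which.min(s[q])],
               w1 = weights[["1"]], w2 = weights[["2"]],
               w3 = weights[["3"]])
  })
  win <- do.call(rbind, win)
  per <- lapply(split(win, win$participant), function(d) {
    data.frame(participant = d$participant[1],
               n_trials = nrow(d),
               prop1 = mean(d$winner == 1), prop2 = mean(d$winner == 2),
               prop3 = mean(d$winner == 3),
               w1 = mean(d$w1), w2 = mean(d$w2), w3 = mean(d$w3))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ci <- function(v) {
    se <- stats::sd(v) / sqrt(length(v))
    c(mean = mean(v), lo = mean(v) - 1.96 * se, hi = mean(v) + 1.96 * se)
  }
  cohort <- do.call(rbind, lapply(c("prop1", "prop2", "prop3",
                                    "w1", "w2", "w3"),
                                  function(v) {
                                    data.frame(measure = v, t(ci(per[[v]])))
                                  }))
  list(by_participant = per, cohort = cohort)
}

#' Super-subject bootstrap model selection
#'
#' PM costs are z-scored within each participant, all trials are pooled
#' into one super-subject, and on each iteration `trials_per_type` trials
#' of each of the five trial types are drawn; first- to third-order
#' polynomials are fitted to the pooled probe-level sample of each type and
#' the lowest-AIC order is selected. For dynamic types the regressor is the
#' difficulty level; fixed-difficulty trials, whose level never varies, are
#' regressed on probe position instead. Reports selection fractions per
#' type and a 1-df chi-square of linear-vs-not selections against the
#' chance rate of 1/3.
#'
#' @param costed_probes PM-trial probes with `cost` and `participant`.
#' @param n_iter bootstrap iterations.
#' @param trials_per_type trials sampled per type per iteration (sampling
#'   is with replacement when a type pool is smaller, with a message).
#' @param seed integer seed.
#' @return list with `selections` (iteration x type winning order),
#'   `fractions`, `chisq` (statistic, df, p).
#' @export
bootstrap_model_selection <- function(costed_probes, n_iter = 1000L,
                                      trials_per_type = 50L, seed = 1L) {
  cp <- costed_probes[costed_probes$pm_type != "none" &
                        !is.na(costed_probes$cost), , drop = FALSE]
  if (!"participant" %in% names(cp)) cp$participant <- 1L
  # z-score within participant
  sp <- split(cp$cost, cp$participant)
  z <- lapply(sp, function(v) (v - mean(v)) / stats::sd(v))
  cp$z <- unsplit(z, cp$participant)
  cp$key <- paste(cp$participant, cp$trial)
  pools <- split(cp, cp$condition)
  idx_by_key <- lapply(pools, function(d) split(seq_len(nrow(d)), d$key))
  trial_keys <- lapply(pools, function(d) unique(d$key))
  small <- names(trial_keys)[vapply(trial_keys, length, 1L) < trials_per_type]
  if (length(small))
    message("sampling with replacement for type(s): ",
            paste(small, collapse = ", "))
  set.seed(seed)
  sel <- matrix(NA_integer_, n_iter, length(pools),
                dimnames = list(NULL, names(pools)))
  for (it in seq_len(n_iter)) {
    for (ty in names(pools)) {
      keys <- sample(trial_keys[[ty]], trials_per_type,
                     replace = length(trial_keys[[ty]]) < trials_per_type)
      d <- pools[[ty]][unlist(idx_by_key[[ty]][keys], use.names = FALSE),
                       , drop = FALSE]
      x <- if (ty == "fixed") d$probe else d$difficulty_level
      scores <- vapply(1:3, function(p) {
        X <- cbind(1, stats::poly(x, degree = p))
        f <- stats::lm.fit(X, d$z)
        ls_ic(sum(f$residuals^2), nrow(d), p + 1L)$aic
      }, 0)
      sel[it, ty] <- which.min(scores)
    }
  }
  frac <- apply(sel, 2, function(v) tabulate(v, 3) / length(v))
  rownames(frac) <- paste0("order", 1:3)
  n_sel <- length(sel)
  lin <- sum(sel == 1L)
  expd <- c(n_sel / 3, 2 * n_sel / 3)
  obs <- c(lin, n_sel - lin)
  stat <- sum((obs - expd)^2 / expd)
  list(selections = sel, fractions = frac,
       chisq = c(statistic = stat, df = 1,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE)))
}
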
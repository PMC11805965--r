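#' Build per-fish emigration event histories
#'
#' Converts a fate table into right-censored time-to-emigration records.
#' Event histories start on day zero, the tagging date. Fish whose terminal
#' event fell inside the CTR recovery window are excluded, as are fish with
#' more than `max_gaps` daily detection gaps (receiver coverage judged
#' insufficient to monitor movements). Emigration is the event; all other
#' fates are right-censored on their fate date. Because unknown fates may
#' hide emigrants, `unknown_treatment` switches unknown fish between
#' censored (`"censored"`) and events (`"emigrated"`).
#'
#' @param fates Fate tibble from [classify_fates()].
#' @param unknown_treatment `"censored"` or `"emigrated"`.
#' @param gap_counts Optional tibble `tag_id`, `n_gaps` (e.g. from
#'   [residence_index()]); fish with `n_gaps > max_gaps` are dropped.
#' @param max_gaps Maximum permitted number of daily detection gaps.
#' @return Tibble: `tag_id`, `time_days`, `event`, `fate_source`,
#'   `unknown_treatment`.
#' @export
build_event_histories <- function(fates,
                                  unknown_treatment = c("censored", "emigrated"),
                                  gap_counts = NULL, max_gaps = 1L) {
  unknown_treatment <- match.arg(unknown_treatment)
  eh <- fates |> filter(!.data$ctr_flag)
  if (!is.null(gap_counts)) {
    eh <- eh |>
      left_join(select(gap_counts, "tag_id", "n_gaps"), by = "tag_id") |>
      filter(tidyr::replace_na(.data$n_gaps, 0L) <= max_gaps)
  }
  eh |>
    transmute(
      tag_id = .data$tag_id,
      time_days = as.numeric(.data$fate_date - .data$tag_date),
      event = .data$fate == "emigrated" |
        (unknown_treatment == "emigrated" & .data$fate == "unknown"),
      fate_source = .data$fate,
      unknown_treatment = unknown_treatment) |>
    filter(.data$time_days > 0)
}

#' Product-limit (Kaplan-Meier) site-fidelity curve
#'
#' Step estimator `S(t) = prod(1 - d_i / n_i)` over event times, with
#' Greenwood variance and confidence limits on the log(-log) scale.
#' Residence quantiles (time at which a stated fraction of fish remains) are
#' read off by first crossing and are `NA` when the curve never reaches the
#' level.
#'
#' @param histories Event-history tibble ([build_event_histories()]).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `fidelity_curve`.
#' @export
product_limit <- function(histories, conf_level = 0.95) {
  sf <- survival::survfit(
    survival::Surv(time_days, event) ~ 1,
    data = histories, conf.type = "log-log", conf.int = conf_level)
  curve <- tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                  estimate = sf$surv, std_err = sf$surv * sf$std.err,
                  conf_low = sf$lower, conf_high = sf$upper)
  structure(list(estimator = "product_limit", curve = curve,
                 n = sf$n, n_events = sum(sf$n.event),
                 conf_level = conf_level,
                 unknown_treatment = if ("unknown_treatment" %in%
                                           names(histories))
                   histories$unknown_treatment[1] else NA_character_),
            class = "fidelity_curve")
}

#' Weibull parametric site-fidelity model
#'
#' Right-censored maximum-likelihood fit of a Weibull time-to-emigration
#' distribution (intercept-only accelerated-failure-time model), giving
#' `S(t) = exp(-(t/lambda)^k)` with shape `k` and scale `lambda`. Residence
#' quantiles follow `t_q = lambda * (-log q)^(1/k)`; annual fidelity is
#' `S(365)`.
#'
#' @param histories Event-history tibble.
#' @param conf_level Confidence level.
#' @return Object of class `fidelity_curve` with `shape`, `scale` and a
#'   fine-grained survival curve with delta-method confidence bands.
#' @export
fit_weibull <- function(histories, conf_level = 0.95) {
  if (sum(histories$event) < 2) {
    abort("Weibull fit needs at least 2 emigration events; check event count")
  }
  fit <- tryCatch(
    survival::survreg(survival::Surv(time_days, event) ~ 1,
                      data = histories, dist = "weibull"),
    error = function(e) abort(paste(
      "Weibull fit failed to converge (", conditionMessage(e),
      "); check the number and spread of emigration events")))
  lambda <- unname(exp(stats::coef(fit)[1]))
  k <- 1 / fit$scale
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  vc <- stats::vcov(fit)  # (intercept, log(sigma))
  tmax <- max(histories$time_days) * 2
  tt <- seq(0, tmax, length.out = 400)
  # log(-log S) = (log t - mu) / sigma; delta method in (mu, log sigma)
  mu <- stats::coef(fit)[1]; sigma <- fit$scale
  eta <- (log(pmax(tt, 1e-9)) - mu) / sigma
  g <- cbind(-1 / sigma, -eta)  # d eta / d(mu, log sigma)
  se_eta <- sqrt(pmax(rowSums((g %*% vc) * g), 0))
  surv <- exp(-exp(eta))
  lo <- exp(-exp(eta + z * se_eta)); hi <- exp(-exp(eta - z * se_eta))
  curve <- tibble(time = tt, estimate = surv, conf_low = lo, conf_high = hi)
  curve$estimate[tt == 0] <- 1
  structure(list(estimator = "weibull", curve = curve,
                 shape = k, scale = lambda,
                 n = nrow(histories), n_events = sum(histories$event),
                 conf_level = conf_level, fit = fit,
                 unknown_treatment = if ("unknown_treatment" %in%
                                           names(histories))
                   histories$unknown_treatment[1] else NA_character_),
            class = "fidelity_curve")
}

#' Evaluate a fidelity curve at given times
#'
#' @param object A `fidelity_curve`.
#' @param times Times in days.
#' @param ... Unused.
#' @return Tibble with `time`, `estimate`, `conf_low`, `conf_high`.
#' @export
predict.fidelity_curve <- function(object, times = 365, ...) {
  if (object$estimator == "weibull") {
    s <- exp(-(times / object$scale)^object$shape)
    idx <- vapply(times, function(t) {
      which.min(abs(object$curve$time - t))
    }, integer(1))
    tibble(time = times, estimate = s,
           conf_low = object$curve$conf_low[idx],
           conf_high = object$curve$conf_high[idx])
  } else {
    step_at <- function(t, col) {
      i <- findInterval(t, object$curve$time)
      c(1, object$curve[[col]])[i + 1]
    }
    tibble(time = times, estimate = step_at(times, "estimate"),
           conf_low = step_at(times, "conf_low"),
           conf_high = step_at(times, "conf_high"))
  }
}

#' Residence quantiles of a fidelity curve
#'
#' Time at which the remaining fraction first drops to `probs` (e.g. 0.5 for
#' 50% residence). `NA` when the curve never falls that far.
#'
#' @param x A `fidelity_curve`.
#' @param probs Remaining fractions.
#' @return Tibble with `prob` and `time_days`.
#' @export
residence_quantile <- function(x, probs = c(0.5, 0.4, 0.01)) {
  t_q <- vapply(probs, function(q) {
    if (x$estimator == "weibull") {
      x$scale * (-log(q))^(1 / x$shape)
    } else {
      hit <- which(x$curve$estimate <= q)
      if (length(hit) == 0) NA_real_ else x$curve$time[hit[1]]
    }
  }, numeric(1))
  tibble(prob = probs, time_days = t_q)
}

#' @export
print.fidelity_curve <- function(x, ...) {
  cat(sprintf("%s site-fidelity curve: n = %d, events = %d\n",
              x$estimator, x$n, x$n_events))
  if (x$estimator == "weibull") {
    cat(sprintf("  shape = %.3f, scale = %.1f d\n", x$shape, x$scale))
  }
  s365 <- predict(x, 365)
  cat(sprintf("  S(365) = %.3f [%.3f, %.3f]\n", s365$estimate, s365$conf_low,
              s365$conf_high))
  invisible(x)
}

#' @export
tidy.fidelity_curve <- function(x, ...) x$curve

#' @export
glance.fidelity_curve <- function(x, ...) {
  p365 <- predict(x, 365)
  rq <- residence_quantile(x)
  tibble(estimator = x$estimator, n = x$n, n_events = x$n_events,
         s365 = p365$estimate, s365_low = p365$conf_low,
         s365_high = p365$conf_high,
         t50 = rq$time_days[1], t40 = rq$time_days[2], t01 = rq$time_days[3],
         unknown_treatment = x$unknown_treatment)
}

#' Classify low-pressure days
#'
#' A day is a low-pressure day when its median atmospheric pressure lies
#' strictly below the stated lower percentile (default the 0.5th) of all
#' daily median pressures over the study window.
#'
#' @param environment Environment tibble with `date` and
#'   `atm_pressure_mbar`.
#' @param percentile Lower percentile in percent (0.5 means the 0.5th
#'   percentile).
#' @return The environment tibble with logical `low_pressure` and an
#'   attribute `threshold_mbar`.
#' @export
classify_pressure_days <- function(environment, percentile = 0.5) {
  thr <- stats::quantile(environment$atm_pressure_mbar, percentile / 100,
                         names = FALSE)
  out <- mutate(environment, low_pressure = .data$atm_pressure_mbar < thr)
  attr(out, "threshold_mbar") <- thr
  out
}

# binomial-logit IRLS; X is the model matrix
.irls_binomial <- function(X, events, trials, tol = 1e-10, maxit = 50) {
  beta <- rep(0, ncol(X))
  y <- events / trials
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- trials * mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  W <- trials * mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(W))
  vcov <- tryCatch(solve(XtWX), error = function(e) {
    abort(paste("degenerate fit: a covariate level has no (or all) events,",
                "so its coefficient is not estimable"))
  })
  ll <- sum(stats::dbinom(events, trials, mu, log = TRUE))
  list(coefficients = beta, vcov = vcov, loglik = ll, fitted = mu)
}

#' Daily emigration probability (DEP) model
#'
#' Fits a binomial logistic model of daily emigration counts: on day `i`,
#' `E_i ~ Binom(n_i, p_i)` with `logit(p_i)` linear in the day's covariates.
#' The default covariate is the binary low-pressure indicator. Candidate
#' single-covariate models are ranked by AIC and the most parsimonious
#' retained. The fit uses iteratively reweighted least squares implemented
#' in the package. Marginal emigration probabilities on regular and
#' low-pressure days come from the inverse logit of the linear predictor,
#' with confidence intervals by the delta method on the logit scale.
#'
#' @param daily_counts Tibble with one row per day: `n_risk` (fish observed),
#'   `n_emigrated`, a logical `low_pressure` column and optionally further
#'   numeric candidate covariates (e.g. `bottom_temp_C`, `tilt_deg`).
#' @param candidates Character vector of candidate covariate columns;
#'   default: every candidate present among `low_pressure`,
#'   `bottom_temp_C`, `tilt_deg`.
#' @param conf_level Confidence level for marginal probabilities.
#' @return Object of class `dep_model` with coefficients, the candidate
#'   table, and marginal probabilities `p_r`, `p_l` with CIs.
#' @export
fit_dep <- function(daily_counts, candidates = NULL, conf_level = 0.95) {
  dc <- daily_counts
  if (sum(dc$n_emigrated) == 0) {
    abort("no emigration events in the daily counts: degenerate fit")
  }
  if (any(dc$n_emigrated > dc$n_risk)) {
    abort("n_emigrated cannot exceed n_risk")
  }
  if (is.null(candidates)) {
    candidates <- intersect(c("low_pressure", "bottom_temp_C", "tilt_deg"),
                            names(dc))
  }
  fits <- lapply(candidates, function(cv) {
    X <- cbind(1, as.numeric(dc[[cv]]))
    colnames(X) <- c("(Intercept)", cv)
    .irls_binomial(X, dc$n_emigrated, dc$n_risk)
  })
  aic <- vapply(fits, function(f) 2 * length(f$coefficients) - 2 * f$loglik,
                numeric(1))
  cand_tab <- tibble(covariate = candidates, aic = aic,
                     loglik = vapply(fits, `[[`, numeric(1), "loglik")) |>
    arrange(.data$aic)
  best_i <- which.min(aic)
  best <- fits[[best_i]]
  best_cov <- candidates[best_i]

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  marginal <- NULL
  if ("low_pressure" %in% candidates) {
    f <- fits[[match("low_pressure", candidates)]]
    lev <- tibble(level = c("regular", "low"), x = c(0, 1))
    Xp <- cbind(1, lev$x)
    eta <- drop(Xp %*% f$coefficients)
    se <- sqrt(rowSums((Xp %*% f$vcov) * Xp))
    marginal <- tibble(
      level = lev$level,
      estimate = stats::plogis(eta),
      conf_low = stats::plogis(eta - z * se),
      conf_high = stats::plogis(eta + z * se))
  }
  structure(list(coefficients = best$coefficients, vcov = best$vcov,
                 loglik = best$loglik, covariate = best_cov,
                 candidates = cand_tab, marginal = marginal,
                 n_days = nrow(dc), n_events = sum(dc$n_emigrated),
                 conf_level = conf_level),
            class = "dep_model")
}

#' @export
print.dep_model <- function(x, ...) {
  cat("Daily emigration probability model (binomial logit, IRLS)\n")
  cat("  selected covariate:", x$covariate, "\n")
  if (!is.null(x$marginal)) print(x$marginal)
  invisible(x)
}

#' @export
tidy.dep_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std_error = sqrt(diag(x$vcov)))
}

#' @export
glance.dep_model <- function(x, ...) {
  out <- tibble(covariate = x$covariate, logLik = x$loglik,
                aic = min(x$candidates$aic), n_days = x$n_days,
                n_events = x$n_events)
  if (!is.null(x$marginal)) {
    out$p_regular <- x$marginal$estimate[x$marginal$level == "regular"]
    out$p_low <- x$marginal$estimate[x$marginal$level == "low"]
  }
  out
}

#' Aggregate event histories into daily at-risk/emigration counts
#'
#' @param histories Event-history tibble.
#' @param environment Environment tibble (classified with
#'   [classify_pressure_days()]), whose day 1 is tagging day 0.
#' @return One row per study day with `n_risk`, `n_emigrated` and the
#'   environment covariates.
#' @export
dep_daily_counts <- function(histories, environment) {
  days <- seq_len(nrow(environment))
  counts <- lapply(days, function(d) {
    at_risk <- sum(histories$time_days >= d)
    emig <- sum(histories$time_days == d & histories$event)
    tibble(day = d, n_risk = at_risk, n_emigrated = emig)
  })
  bind_rows(counts) |>
    bind_cols(select(environment, -dplyr::any_of(c("date")))) |>
    filter(.data$n_risk > 0)
}

#' Expected site fidelity after t days
#'
#' `S(t) = (1 - p_r)^(t - D_L) * (1 - p_l)^(D_L)`: the probability a fish is
#' still in the study area after `t` days of which `D_L` were low-pressure
#' days, given daily emigration probabilities `p_r` (regular) and `p_l`
#' (low).
#'
#' @param p_r,p_l Daily emigration probabilities on regular and low days.
#' @param t Horizon in days.
#' @param d_low Number of low-pressure days `D_L` (0 <= d_low <= t).
#' @return Expected fidelity, vectorized over `t`/`d_low`.
#' @export
project_fidelity <- function(p_r, p_l, t, d_low) {
  if (any(d_low > t)) abort("d_low cannot exceed t")
  if (any(c(p_r, p_l) <= 0) || any(c(p_r, p_l) >= 1)) {
    abort("probabilities must lie strictly in (0, 1)")
  }
  (1 - p_r)^(t - d_low) * (1 - p_l)^d_low
}
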
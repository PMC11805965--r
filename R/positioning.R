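#' Per-bin 2DRMS of calibration positions
#'
#' Computes, for known-location calibration tags, twice the distance root
#' mean squared error per integer HPE bin:
#' `2DRMS_i = 2 * sqrt(mean(dx^2 + dy^2))` with `dx`, `dy` the east-west and
#' north-south differences between estimated and known coordinates of the
#' observations in bin `i`. The upper tail of HPE values is censored before
#' binning (default upper 5%) to limit outlier influence, bins use
#' `floor(HPE)` with increment 1, and sparse bins (fewer than `min_bin_n`
#' observations) are merged into the next bin up.
#'
#' @param calibration_positions Position tibble with `x_m`, `y_m`,
#'   `known_x_m`, `known_y_m`, `hpe`, optionally a `region` column (bins are
#'   computed per region).
#' @param hpe_censor_quantile Upper HPE quantile removed before binning.
#' @param min_bin_n Minimum observations per bin before merging upward.
#' @return Tibble with `region` (if present), `hpe_bin`, `hpe_mean`, `n`,
#'   `drms2_m`.
#' @export
compute_2drms_bins <- function(calibration_positions,
                               hpe_censor_quantile = 0.95, min_bin_n = 3L) {
  cp <- calibration_positions
  if (nrow(cp) == 0 || !all(c("known_x_m", "known_y_m") %in% names(cp)) ||
      all(is.na(cp$known_x_m))) {
    abort("no calibration records with known locations: calibration unavailable")
  }
  if (!"region" %in% names(cp)) cp$region <- "all"
  cp |>
    group_by(.data$region) |>
    filter(.data$hpe <= stats::quantile(.data$hpe, hpe_censor_quantile)) |>
    mutate(hpe_bin = floor(.data$hpe)) |>
    group_by(.data$region, .data$hpe_bin) |>
    summarise(hpe_mean = mean(.data$hpe), n = dplyr::n(),
              sq = sum((.data$x_m - .data$known_x_m)^2 +
                         (.data$y_m - .data$known_y_m)^2),
              .groups = "drop_last") |>
    arrange(.data$region, .data$hpe_bin) |>
    group_modify(~ .merge_sparse_bins(.x, min_bin_n)) |>
    ungroup() |>
    mutate(drms2_m = 2 * sqrt(.data$sq / .data$n)) |>
    select("region", "hpe_bin", "hpe_mean", "n", "drms2_m")
}

# Merge bins with n < min_n into the next bin upward (last bin merges down).
.merge_sparse_bins <- function(bins, min_n) {
  repeat {
    small <- which(bins$n < min_n)
    if (length(small) == 0 || nrow(bins) == 1) break
    i <- small[1]
    j <- if (i < nrow(bins)) i + 1 else i - 1
    w <- bins$n[i] + bins$n[j]
    bins$hpe_mean[j] <- (bins$hpe_mean[i] * bins$n[i] +
                           bins$hpe_mean[j] * bins$n[j]) / w
    bins$sq[j] <- bins$sq[i] + bins$sq[j]
    bins$n[j] <- w
    bins$hpe_bin[j] <- min(bins$hpe_bin[i], bins$hpe_bin[j])
    bins <- bins[-i, ]
  }
  bins
}

#' Fit the 2DRMS-versus-HPE filtering relationship
#'
#' Regresses per-bin 2DRMS on mean HPE by ordinary least squares, comparing a
#' single pooled relationship against region-specific lines (an array-region
#' interaction). Candidate partitions are ranked by small-sample-corrected
#' AIC on the bin-level regression and the winner is retained.
#'
#' @param bins Output of [compute_2drms_bins()] (with a `region` column).
#' @param error_threshold_m Accepted position error for downstream filtering.
#' @return An object of class `drms_fit` with per-region `slope`/`intercept`,
#'   the model-comparison table, and the retained partition.
#' @export
fit_2drms <- function(bins, error_threshold_m = 20) {
  if (nrow(bins) < 2) abort("need at least 2 HPE bins to fit a line")
  if (!"region" %in% names(bins)) bins$region <- "all"
  n_regions <- dplyr::n_distinct(bins$region)
  aicc <- function(fit) {
    k <- length(stats::coef(fit)) + 1
    n <- stats::nobs(fit)
    stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  fit1 <- stats::lm(drms2_m ~ hpe_mean, data = bins)
  cand <- tibble(partition = "pooled", n_regions = 1L, aicc = aicc(fit1))
  fits <- list(pooled = fit1)
  if (n_regions > 1) {
    if (any(table(bins$region) < 2)) {
      abort("each candidate region needs at least 2 HPE bins")
    }
    fitk <- stats::lm(drms2_m ~ hpe_mean * region, data = bins)
    cand <- bind_rows(cand, tibble(partition = "by_region",
                                   n_regions = n_regions, aicc = aicc(fitk)))
    fits$by_region <- fitk
  }
  winner <- cand$partition[which.min(cand$aicc)]
  fit <- fits[[winner]]
  regions <- if (winner == "pooled") "all" else sort(unique(bins$region))
  lines <- lapply(regions, function(r) {
    b <- stats::coef(fit)
    if (winner == "pooled") {
      tibble(region = r, intercept = b[["(Intercept)"]],
             slope = b[["hpe_mean"]])
    } else {
      base <- sort(unique(bins$region))[1]
      int <- b[["(Intercept)"]] +
        if (r == base) 0 else b[[paste0("region", r)]] %||% 0
      slp <- b[["hpe_mean"]] +
        if (r == base) 0 else b[[paste0("hpe_mean:region", r)]] %||% 0
      tibble(region = r, intercept = int, slope = slp)
    }
  })
  structure(list(
    lines = bind_rows(lines),
    partition = winner,
    comparison = cand,
    model = fit,
    error_threshold_m = error_threshold_m,
    hpe_censor_quantile = 0.95
  ), class = "drms_fit")
}

#' @export
print.drms_fit <- function(x, ...) {
  cat("2DRMS ~ HPE filtering relationship (", x$partition, " partition)\n",
      sep = "")
  print(x$lines)
  invisible(x)
}

#' Predicted 2DRMS at given HPE values
#'
#' @param object A `drms_fit`.
#' @param hpe Numeric HPE values.
#' @param region Region labels (recycled); unmatched regions fall back to the
#'   first fitted line with a warning.
#' @param ... Unused.
#' @return Predicted 2DRMS in meters.
#' @export
predict.drms_fit <- function(object, hpe, region = NULL, ...) {
  ln <- object$lines
  if (is.null(region) || nrow(ln) == 1) {
    ln$intercept[1] + ln$slope[1] * hpe
  } else {
    idx <- match(region, ln$region)
    if (anyNA(idx)) {
      warn("position region not in calibration; assigned to first region line")
      idx[is.na(idx)] <- 1L
    }
    ln$intercept[idx] + ln$slope[idx] * hpe
  }
}

#' @export
tidy.drms_fit <- function(x, ...) x$lines

#' @export
glance.drms_fit <- function(x, ...) {
  tibble(partition = x$partition, n_regions = nrow(x$lines),
         r_squared = summary(x$model)$r.squared,
         aicc = min(x$comparison$aicc),
         error_threshold_m = x$error_threshold_m)
}

#' Filter positions on predicted 2DRMS
#'
#' Retains positions whose predicted 2DRMS (the calibrated region line
#' evaluated at the position's HPE) does not exceed the accepted error
#' threshold.
#'
#' @param positions Position tibble with `hpe` (and optionally `region`).
#' @param fit A `drms_fit`.
#' @param threshold_m Accepted position error in meters (default 20).
#' @return The retained positions, with attributes `retention` (fraction
#'   kept) and `n_dropped`.
#' @export
filter_positions <- function(positions, fit, threshold_m = 20) {
  reg <- if ("region" %in% names(positions)) positions$region else NULL
  pred <- predict(fit, positions$hpe, reg)
  keep <- pred <= threshold_m
  out <- positions[keep, , drop = FALSE]
  attr(out, "retention") <- mean(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Fit a logistic detection-range curve
#'
#' Maximum-likelihood fit of `p(d) = p0 / (1 + exp(steepness * (d - d50)))`
#' to Bernoulli detection trials; `d50` is the distance at which detection
#' probability halves relative to `p0`.
#'
#' @param range_trials Tibble with `distance_m` and logical `detected`.
#' @return Object of class `range_model` with `p0`, `d50_m`, `steepness`,
#'   the log-likelihood and the binned estimation table.
#' @export
estimate_range <- function(range_trials) {
  d <- range_trials$distance_m
  y <- as.numeric(range_trials$detected)
  if (all(y == 1) || all(y == 0)) {
    abort(paste("complete separation: all trials", if (all(y == 1)) "succeeded"
                else "failed", "- widen the distance span of the trials"))
  }
  nll <- function(par) {
    p0 <- stats::plogis(par[1]); d50 <- exp(par[2]); st <- exp(par[3])
    p <- pmin(pmax(p0 / (1 + exp(st * (d - d50))), 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  starts <- list(c(3, log(stats::median(d)), log(0.01)),
                 c(2, log(mean(range(d))), log(0.005)))
  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(s, nll, method = "Nelder-Mead",
                            control = list(maxit = 2000)), silent = TRUE)
    if (!inherits(opt, "try-error") &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) abort("range model failed to converge")
  brks <- seq(0, max(d) + 50, by = 50)
  est_tab <- tibble(bin = cut(d, brks), detected = y) |>
    group_by(.data$bin) |>
    summarise(trials = dplyr::n(), successes = sum(.data$detected),
              .groups = "drop")
  structure(list(p0 = stats::plogis(best$par[1]), d50_m = exp(best$par[2]),
                 steepness = exp(best$par[3]), loglik = -best$value,
                 estimation_table = est_tab, n = length(y)),
            class = "range_model")
}

#' @export
print.range_model <- function(x, ...) {
  cat(sprintf("Logistic detection range: p0 = %.3f, d50 = %.1f m, steepness = %.4f (n = %d)\n",
              x$p0, x$d50_m, x$steepness, x$n))
  invisible(x)
}

#' @export
tidy.range_model <- function(x, ...) {
  tibble(term = c("p0", "d50_m", "steepness"),
         estimate = c(x$p0, x$d50_m, x$steepness))
}

#' @export
glance.range_model <- function(x, ...) {
  tibble(p0 = x$p0, d50_m = x$d50_m, steepness = x$steepness,
         logLik = x$loglik, nobs = x$n)
}

#' @export
predict.range_model <- function(object, distance_m, ...) {
  detection_probability(distance_m, object$p0, object$d50_m, object$steepness)
}

#' Centers of activity from binned detections
#'
#' Removes spurious detections (a detection with no other detection of the
#' same tag within 60 minutes either side), then averages the distinct
#' detecting receivers' coordinates per (tag, time bin). Bins supported by
#' fewer than `min_receivers` distinct receivers are dropped, except on each
#' tag's final detection date, where bins with at least one receiver are
#' retained (emigrating fish move fast and are detected sparsely on their
#' last day); retained sub-threshold bins are flagged by `below_min`.
#'
#' @param detections Detection tibble.
#' @param receivers Receiver tibble supplying coordinates.
#' @param bin_minutes COA bin width in minutes; must divide 1440 (30 for
#'   fine-scale work, 240 for movement/dispersal summaries).
#' @param min_receivers Distinct receivers required per bin (default 3).
#' @param spurious_window_min Isolation window for the spurious-detection
#'   rule (default 60).
#' @return COA tibble: `tag_id`, `bin_start`, `bin_minutes`, `x_m`, `y_m`,
#'   `n_receivers`, `n_detections`, `mean_depth_m`, `below_min`.
#' @export
compute_coas <- function(detections, receivers, bin_minutes = 30,
                         min_receivers = 3L, spurious_window_min = 60) {
  if (1440 %% bin_minutes != 0) abort("bin_minutes must divide 1440")
  det <- detections |>
    inner_join(select(receivers, "receiver_id", "x_m", "y_m"),
               by = "receiver_id") |>
    arrange(.data$tag_id, .data$timestamp)
  if (!"depth_m" %in% names(det)) det$depth_m <- NA_real_

  det <- det |>
    group_by(.data$tag_id) |>
    mutate(
      gap_prev = as.numeric(difftime(.data$timestamp, lag(.data$timestamp),
                                     units = "mins")),
      gap_next = as.numeric(difftime(lead(.data$timestamp), .data$timestamp,
                                     units = "mins")),
      spurious = (is.na(.data$gap_prev) | .data$gap_prev > spurious_window_min) &
        (is.na(.data$gap_next) | .data$gap_next > spurious_window_min)
    ) |>
    filter(!.data$spurious) |>
    ungroup()
  if (nrow(det) == 0) {
    return(tibble(tag_id = character(), bin_start = as.POSIXct(character(),
                                                               tz = "UTC"),
                  bin_minutes = numeric(), x_m = numeric(), y_m = numeric(),
                  n_receivers = integer(), n_detections = integer(),
                  mean_depth_m = numeric(), below_min = logical()))
  }

  bin_s <- bin_minutes * 60
  coas <- det |>
    mutate(bin_start = as.POSIXct(
      floor(as.numeric(.data$timestamp) / bin_s) * bin_s,
      tz = "UTC", origin = "1970-01-01")) |>
    group_by(.data$tag_id, .data$bin_start) |>
    summarise(
      x_m = mean(.data$x_m[!duplicated(.data$receiver_id)]),
      y_m = mean(.data$y_m[!duplicated(.data$receiver_id)]),
      n_receivers = dplyr::n_distinct(.data$receiver_id),
      n_detections = dplyr::n(),
      mean_depth_m = mean(.data$depth_m, na.rm = TRUE),
      .groups = "drop")

  final_date <- det |>
    group_by(.data$tag_id) |>
    summarise(final_date = as.Date(max(.data$timestamp)), .groups = "drop")
  coas |>
    left_join(final_date, by = "tag_id") |>
    mutate(below_min = .data$n_receivers < min_receivers) |>
    filter(!.data$below_min | as.Date(.data$bin_start) == .data$final_date) |>
    mutate(bin_minutes = bin_minutes,
           mean_depth_m = ifelse(is.nan(.data$mean_depth_m), NA_real_,
                                 .data$mean_depth_m)) |>
    select("tag_id", "bin_start", "bin_minutes", "x_m", "y_m", "n_receivers",
           "n_detections", "mean_depth_m", "below_min")
}

#' Residence index and daily detection gaps
#'
#' The residence index for a fish is its number of detection days divided by
#' the inclusive detection period (days from first to last detection day,
#' endpoints counted), so continuous presence gives RI = 1. Gaps are maximal
#' runs of zero-detection days strictly inside the detection period.
#'
#' @param detections Detection tibble (any table with `tag_id` and
#'   `timestamp`).
#' @return One row per tag: `first_day`, `last_day`, `detection_days`,
#'   `period_days`, `ri`, `n_gaps`, `max_gap_days`.
#' @export
residence_index <- function(detections) {
  detections |>
    mutate(day = as.Date(.data$timestamp)) |>
    group_by(.data$tag_id) |>
    summarise(
      first_day = min(.data$day), last_day = max(.data$day),
      detection_days = dplyr::n_distinct(.data$day), .groups = "drop") |>
    mutate(period_days = as.integer(.data$last_day - .data$first_day) + 1L,
           ri = .data$detection_days / .data$period_days) |>
    left_join(
      detection_gaps(detections) |>
        summarise(n_gaps = dplyr::n(),
                  max_gap_days = max(.data$gap_days, 0L),
                  .by = "tag_id"),
      by = "tag_id") |>
    mutate(n_gaps = tidyr::replace_na(.data$n_gaps, 0L),
           max_gap_days = tidyr::replace_na(.data$max_gap_days, 0L))
}

#' @rdname residence_index
#' @export
detection_gaps <- function(detections) {
  detections |>
    mutate(day = as.Date(.data$timestamp)) |>
    distinct(.data$tag_id, .data$day) |>
    arrange(.data$tag_id, .data$day) |>
    group_by(.data$tag_id) |>
    mutate(gap_days = as.integer(.data$day - lag(.data$day)) - 1L) |>
    filter(!is.na(.data$gap_days), .data$gap_days > 0) |>
    transmute(tag_id = .data$tag_id,
              gap_start = .data$day - .data$gap_days,
              gap_end = .data$day - 1L,
              gap_days = .data$gap_days) |>
    ungroup()
}
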
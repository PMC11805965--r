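#' Simulation configuration
#'
#' Builds the configuration object for the synthetic-telemetry generator. The
#' defaults emulate a fine-scale acoustic positioning study of site-attached
#' reef fish: a regular receiver grid (600 m spacing), logistic detection-range
#' decay with a 50% range of 346 m for fish-specification tags, 60-180 s
#' random interpulse delays, Ornstein-Uhlenbeck residency around home-site
#' centroids with occasional centroid shifts, daily competing risks of
#' emigration (strongly elevated on low-atmospheric-pressure days), natural
#' mortality, capture removal and predation, and triangulation error whose
#' per-axis standard deviation is proportional to a right-skewed HPE draw.
#'
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param n_fish Number of tagged fish.
#' @param study_days Length of the tracking window in days.
#' @param array Grid layout: `n_rows`, `n_cols`, `spacing_m`.
#' @param range_model Logistic detection curve
#'   `p(d) = p0 / (1 + exp(steepness * (d - d50_m)))`.
#' @param movement OU residency: stationary SD about the centroid
#'   (`centroid_sd_m`), track step (`step_minutes`), OU relaxation time
#'   (`tau_minutes`), daily centroid-shift probability (`shift_prob_per_day`),
#'   and `n_centroids_max`.
#' @param transmission Uniform interpulse delay bounds in seconds.
#' @param hazards Daily event probabilities; emigration hazard is multiplied
#'   by `low_pressure_multiplier` on low-pressure days.
#' @param pressure Daily environment: probability a day is a low-pressure day
#'   and the mean/SD of regular and low daily pressure (mbar).
#' @param position_error `hpe_shape`/`hpe_scale` of the Gamma HPE draw and
#'   `error_per_hpe_m`, the per-axis error SD per HPE unit.
#' @param predation Predator-carried run: sustained speed (m/s) and duration
#'   (h) with full-water-column depth excursions.
#' @param emigration_speed_mps Speed of the directed off-array emigration run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_fish = 20L,
                       study_days = 120L,
                       array = list(),
                       range_model = list(),
                       movement = list(),
                       transmission = list(),
                       hazards = list(),
                       pressure = list(),
                       position_error = list(),
                       predation = list(),
                       emigration_speed_mps = 0.8) {
  merge_block <- function(defaults, user) utils::modifyList(defaults, user)
  cfg <- list(
    seed = as.integer(seed), n_fish = as.integer(n_fish),
    study_days = as.integer(study_days),
    array = merge_block(list(n_rows = 7L, n_cols = 7L, spacing_m = 600), array),
    range_model = merge_block(list(p0 = 0.97, d50_m = 346, steepness = 0.012),
                              range_model),
    movement = merge_block(list(centroid_sd_m = 40, step_minutes = 10,
                                tau_minutes = 60, shift_prob_per_day = 0.004,
                                n_centroids_max = 7L), movement),
    transmission = merge_block(list(delay_min_s = 60, delay_max_s = 180),
                               transmission),
    hazards = merge_block(list(base_emigration_per_day = 4e-4,
                               low_pressure_multiplier = 175,
                               mortality_per_day = 2e-4,
                               capture_per_day = 2e-4,
                               predation_per_day = 1e-4), hazards),
    pressure = merge_block(list(low_day_prob = 0.005, regular_mbar = 1016,
                                low_mbar = 1004, sd_mbar = 2), pressure),
    position_error = merge_block(list(hpe_shape = 2, hpe_scale = 1.7,
                                      error_per_hpe_m = 1.2), position_error),
    predation = merge_block(list(speed_mps = 0.9, duration_h = 3), predation),
    emigration_speed_mps = emigration_speed_mps
  )
  stopifnot(cfg$transmission$delay_min_s < cfg$transmission$delay_max_s,
            cfg$range_model$d50_m > 0, cfg$range_model$p0 > 0,
            cfg$range_model$p0 <= 1)
  rates <- unlist(cfg$hazards[c("base_emigration_per_day", "mortality_per_day",
                                "capture_per_day", "predation_per_day")])
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(cfg, class = "sim_config")
}

#' Logistic detection-probability curve
#'
#' @param d Distance in meters.
#' @param p0 Close-range detection probability.
#' @param d50_m Distance at which probability halves.
#' @param steepness Logistic steepness per meter.
#' @return Detection probability, same length as `d`.
#' @export
detection_probability <- function(d, p0 = 0.97, d50_m = 346,
                                  steepness = 0.012) {
  p0 / (1 + exp(steepness * (d - d50_m)))
}

#' Simulate a regular receiver grid
#'
#' @param config A [sim_config()].
#' @return A receiver tibble in the canonical `receivers` schema, with the
#'   grid anchored at (0, 0).
#' @export
simulate_array <- function(config) {
  a <- config$array
  if (a$spacing_m <= 0) abort("array spacing must be positive")
  if (a$n_rows < 2 || a$n_cols < 2) abort("array grid needs at least 2x2")
  grid <- expand.grid(col = seq_len(a$n_cols) - 1, row = seq_len(a$n_rows) - 1)
  tibble(
    receiver_id = sprintf("R%02d", seq_len(nrow(grid))),
    x_m = grid$col * a$spacing_m,
    y_m = grid$row * a$spacing_m,
    deploy_date = as.Date("2021-01-01"),
    recover_date = as.Date("2021-01-01") + config$study_days,
    station_name = sprintf("S%02d", seq_len(nrow(grid))),
    array_label = "synthetic",
    habitat_label = NA_character_
  )
}

#' Habitat polygons aligned to a simulated array
#'
#' Builds a small habitat map matching the simulated grid: a hard-bottom (HB)
#' rectangle over most of the interior, a narrow ledge strip along one flank,
#' and a point-like artificial-reef (AR) patch; sand is the complement.
#'
#' @param receivers Receiver tibble from [simulate_array()].
#' @return A tibble of class `habitat_map` with `habitat_label` and a
#'   `polygon` list-column of closed (x, y) rings.
#' @export
simulate_habitat <- function(receivers) {
  xr <- range(receivers$x_m); yr <- range(receivers$y_m)
  w <- diff(xr); h <- diff(yr)
  rect <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
  }
  hb <- rect(xr[1] + 0.15 * w, yr[1] + 0.15 * h, xr[1] + 0.70 * w, yr[1] + 0.85 * h)
  ledge <- rect(xr[1] + 0.80 * w, yr[1] + 0.20 * h, xr[1] + 0.86 * w, yr[1] + 0.80 * h)
  ar_c <- c(xr[1] + 0.75 * w, yr[1] + 0.10 * h)
  ar <- rect(ar_c[1] - 15, ar_c[2] - 15, ar_c[1] + 15, ar_c[2] + 15)
  structure(
    tibble(habitat_label = c("HB", "ledge", "AR"),
           polygon = list(hb, ledge, ar)),
    class = c("habitat_map", "tbl_df", "tbl", "data.frame"))
}

#' Simulate the daily environmental series
#'
#' Each day is independently a low-pressure day with probability
#' `pressure$low_day_prob`; daily median pressure is drawn about the regular
#' or low mean. Bottom temperature follows a seasonal sinusoid and receiver
#' tilt is white noise, giving the covariate-selection machinery genuinely
#' uninformative competitors.
#'
#' @param config A [sim_config()].
#' @return Environment tibble (canonical schema) with an extra logical
#'   `true_low` column recording the generator's own day labels.
#' @export
simulate_environment <- function(config) {
  set.seed(config$seed + 1L)
  p <- config$pressure
  days <- seq_len(config$study_days)
  low <- stats::runif(length(days)) < p$low_day_prob
  mbar <- ifelse(low, stats::rnorm(length(days), p$low_mbar, p$sd_mbar / 2),
                 stats::rnorm(length(days), p$regular_mbar, p$sd_mbar))
  tibble(
    date = as.Date("2021-01-01") + days - 1,
    atm_pressure_mbar = mbar,
    bottom_temp_C = 22 + 5 * sin(2 * pi * days / 365) +
      stats::rnorm(length(days), 0, 0.3),
    tilt_deg = stats::rnorm(length(days), 5, 1),
    true_low = low
  )
}

# One fish's track: day-resolution competing risks + within-day OU steps.
.simulate_one_track <- function(fish_id, config, receivers, env_low) {
  mv <- config$movement
  hz <- config$hazards
  dt_s <- mv$step_minutes * 60
  phi <- exp(-mv$step_minutes / mv$tau_minutes)
  innov_sd <- mv$centroid_sd_m * sqrt(1 - phi^2)
  steps_per_day <- as.integer(round(1440 / mv$step_minutes))
  xr <- range(receivers$x_m); yr <- range(receivers$y_m)
  # home sites sit well inside the array so edge exits are unambiguous
  margin <- 1.5 * config$array$spacing_m
  new_centroid <- function() {
    c(stats::runif(1, xr[1] + margin, xr[2] - margin),
      stats::runif(1, yr[1] + margin, yr[2] - margin))
  }

  centroid <- new_centroid()
  centroids <- list(list(x = centroid[1], y = centroid[2], start_day = 1))
  pos <- centroid + stats::rnorm(2, 0, mv$centroid_sd_m)
  depth <- 35
  t0 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")

  fate <- "survived"; event_day <- config$study_days
  xs <- ys <- ds <- vector("list", config$study_days)
  ts <- vector("list", config$study_days)
  dead <- FALSE

  # piecewise-straight run through waypoints at constant speed
  run_path <- function(start, waypoints, speed) {
    px <- start[1]; py <- start[2]; rx <- ry <- numeric(0)
    for (w in waypoints) {
      vec <- w - c(px, py); dist <- sqrt(sum(vec^2))
      ns <- max(1L, ceiling(dist / (speed * dt_s)))
      rx <- c(rx, px + vec[1] * seq_len(ns) / ns)
      ry <- c(ry, py + vec[2] * seq_len(ns) / ns)
      px <- w[1]; py <- w[2]
    }
    cbind(rx, ry)
  }
  exit_point <- function(from) {
    edges <- c(from[1] - xr[1], xr[2] - from[1], from[2] - yr[1], yr[2] - from[2])
    switch(which.min(edges),
           c(xr[1] - 2500, from[2]), c(xr[2] + 2500, from[2]),
           c(from[1], yr[1] - 2500), c(from[1], yr[2] + 2500))
  }

  for (day in seq_len(config$study_days)) {
    n <- steps_per_day
    tt <- t0 + ((day - 1) * 86400 + seq_len(n) * dt_s)

    if (dead) {  # stationary tag keeps transmitting at the death site
      xs[[day]] <- rep(pos[1], n); ys[[day]] <- rep(pos[2], n)
      ds[[day]] <- depth + stats::rnorm(n, 0, 0.05)
      ts[[day]] <- tt
      next
    }

    # daily competing risks (first event wins, sampled jointly)
    p_e <- min(hz$base_emigration_per_day *
                 if (env_low[day]) hz$low_pressure_multiplier else 1, 0.99)
    probs <- c(emigrated = p_e, mortality = hz$mortality_per_day,
               predated = hz$predation_per_day, captured = hz$capture_per_day)
    u <- stats::runif(1)
    cum <- cumsum(probs)
    ev <- if (u < cum[length(cum)]) names(probs)[which(u < cum)[1]] else NA

    if (!is.na(ev)) { fate <- ev; event_day <- day }

    if (stats::runif(1) < mv$shift_prob_per_day &&
        length(centroids) < mv$n_centroids_max && is.na(ev)) {
      centroid <- new_centroid()
      centroids[[length(centroids) + 1]] <-
        list(x = centroid[1], y = centroid[2], start_day = day)
    }

    ex <- stats::rnorm(n, 0, innov_sd); ey <- stats::rnorm(n, 0, innov_sd)
    x <- as.numeric(stats::filter(ex, phi, "recursive",
                                  init = pos[1] - centroid[1])) + centroid[1]
    y <- as.numeric(stats::filter(ey, phi, "recursive",
                                  init = pos[2] - centroid[2])) + centroid[2]
    dstep <- stats::rnorm(n, 0, 0.4)
    d <- depth + cumsum(dstep)
    d <- 38 - abs((d %% 76) - 38)  # reflect into [0, 38]

    if (!is.na(ev)) {
      frac <- stats::runif(1, 0.2, 0.8)
      k <- max(1L, as.integer(floor(frac * n)))
      if (ev == "captured") {
        x <- x[seq_len(k)]; y <- y[seq_len(k)]
        d <- d[seq_len(k)]; tt <- tt[seq_len(k)]
      } else if (ev == "mortality") {
        x[k:n] <- x[k]; y[k:n] <- y[k]
        d[k:n] <- d[k] + stats::rnorm(n - k + 1, 0, 0.05)
        dead <- TRUE
      } else if (ev == "emigrated") {
        run <- run_path(c(x[k], y[k]), list(exit_point(c(x[k], y[k]))),
                        config$emigration_speed_mps)
        ridx <- seq_len(nrow(run))
        x <- c(x[seq_len(k)], run[, 1]); y <- c(y[seq_len(k)], run[, 2])
        d <- c(d[seq_len(k)], rep(d[k], nrow(run)))
        tt <- c(tt[seq_len(k)], tt[k] + dt_s * ridx)
      } else if (ev == "predated") {
        # shark-like: fast meander across the array interior, then exit
        run_len <- config$predation$duration_h * 3600 *
          config$predation$speed_mps
        leg <- 0.4 * min(diff(xr), diff(yr))
        n_wp <- max(2L, ceiling(run_len / leg))
        wps <- lapply(seq_len(n_wp), function(i) {
          c(stats::runif(1, xr[1] + margin, xr[2] - margin),
            stats::runif(1, yr[1] + margin, yr[2] - margin))
        })
        wps[[length(wps) + 1]] <- exit_point(wps[[length(wps)]])
        run <- run_path(c(x[k], y[k]), wps, config$predation$speed_mps)
        ridx <- seq_len(nrow(run))
        x <- c(x[seq_len(k)], run[, 1]); y <- c(y[seq_len(k)], run[, 2])
        d <- c(d[seq_len(k)],
               19 + 18.5 * sin(2 * pi * ridx * dt_s / 10800))
        tt <- c(tt[seq_len(k)], tt[k] + dt_s * ridx)
      }
    }

    xs[[day]] <- x; ys[[day]] <- y; ds[[day]] <- d; ts[[day]] <- tt
    if (!is.na(ev) && ev != "mortality") break
    pos <- c(x[length(x)], y[length(y)]); depth <- d[length(d)]
  }

  kept <- which(!vapply(xs, is.null, logical(1)))
  track <- tibble(
    tag_id = fish_id,
    timestamp = as.POSIXct(unlist(ts[kept]), tz = "UTC",
                           origin = "1970-01-01"),
    x = unlist(xs[kept]), y = unlist(ys[kept]), depth = unlist(ds[kept]))
  cent <- bind_rows(lapply(centroids, as_tibble)) |>
    mutate(tag_id = fish_id, centroid_id = dplyr::row_number(), .before = 1)
  list(track = track,
       fate = tibble(tag_id = fish_id, true_fate = fate,
                     event_day = event_day, tag_date = as.Date("2021-01-01")),
       centroids = cent)
}

#' Simulate true fish tracks with competing terminal fates
#'
#' Each fish performs a 2-D Ornstein-Uhlenbeck walk about its current home
#' centroid, with Bernoulli daily centroid shifts. Each day it is exposed to
#' competing risks: emigration (hazard multiplied on low-pressure days,
#' executed as a directed run off the array), mortality (the tag becomes
#' stationary with near-zero depth variance but keeps transmitting),
#' predation (a fast, full-water-column run off the array) and capture
#' (transmissions stop instantly).
#'
#' @param config A [sim_config()].
#' @param receivers Receiver tibble ([simulate_array()]).
#' @param environment Environment tibble ([simulate_environment()]); its
#'   `true_low` column drives the emigration hazard.
#' @return A list of class `true_track_set`: `tracks` (step-resolution
#'   positions/depths), `fates` (true fate and event day per fish) and
#'   `centroids` (true centroid history).
#' @export
simulate_tracks <- function(config, receivers, environment) {
  set.seed(config$seed + 2L)
  env_low <- if ("true_low" %in% names(environment)) environment$true_low
             else rep(FALSE, config$study_days)
  fish_ids <- sprintf("F%03d", seq_len(config$n_fish))
  sims <- lapply(seq_along(fish_ids), function(i) {
    .simulate_one_track(fish_ids[i], config, receivers, env_low)
  })
  structure(list(
    tracks = bind_rows(lapply(sims, `[[`, "track")),
    fates = bind_rows(lapply(sims, `[[`, "fate")),
    centroids = bind_rows(lapply(sims, `[[`, "centroids"))
  ), class = "true_track_set")
}

#' Simulate detections and triangulated positions from true tracks
#'
#' Transmissions occur at independent Uniform(delay_min, delay_max) intervals.
#' Each receiver detects a transmission independently with the logistic range
#' probability at its distance. Transmissions detected by at least
#' `min_receivers` receivers yield a position record: the true location plus
#' isotropic Gaussian error with per-axis SD `error_per_hpe_m * HPE`, with
#' HPE drawn from the configured Gamma distribution.
#'
#' @param tracks A `true_track_set` from [simulate_tracks()].
#' @param receivers Receiver tibble.
#' @param config A [sim_config()].
#' @param min_receivers Receivers required for a position solution (default 3).
#' @return A list with `detections` and `positions` tibbles in the canonical
#'   schemas.
#' @export
simulate_detections <- function(tracks, receivers, config, min_receivers = 3L) {
  set.seed(config$seed + 3L)
  tr <- config$transmission
  rm_ <- config$range_model
  pe <- config$position_error
  rx <- receivers$x_m; ry <- receivers$y_m
  det_out <- list(); pos_out <- list()

  for (id in unique(tracks$tracks$tag_id)) {
    path <- tracks$tracks[tracks$tracks$tag_id == id, ]
    t_start <- as.numeric(path$timestamp[1])
    t_end <- as.numeric(path$timestamp[nrow(path)])
    span <- t_end - t_start
    n_tx <- ceiling(span / tr$delay_min_s) + 1
    gaps <- stats::runif(n_tx, tr$delay_min_s, tr$delay_max_s)
    tx_t <- t_start + cumsum(gaps)
    tx_t <- tx_t[tx_t <= t_end]
    if (length(tx_t) == 0) next
    pt <- as.numeric(path$timestamp)
    tx_x <- stats::approx(pt, path$x, tx_t)$y
    tx_y <- stats::approx(pt, path$y, tx_t)$y
    tx_d <- stats::approx(pt, path$depth, tx_t)$y

    # beyond 8 logistic widths past d50 detection is numerically impossible
    d_cut <- rm_$d50_m + 8 / rm_$steepness
    n <- length(tx_t)
    chunk <- 20000L
    for (s in seq(1, n, by = chunk)) {
      idx <- s:min(s + chunk - 1, n)
      near <- which(rx >= min(tx_x[idx]) - d_cut & rx <= max(tx_x[idx]) + d_cut &
                      ry >= min(tx_y[idx]) - d_cut & ry <= max(tx_y[idx]) + d_cut)
      if (length(near) == 0) next
      dx <- outer(tx_x[idx], rx[near], "-"); dy <- outer(tx_y[idx], ry[near], "-")
      dist <- sqrt(dx^2 + dy^2)
      p <- detection_probability(dist, rm_$p0, rm_$d50_m, rm_$steepness)
      hit <- matrix(stats::runif(length(p)) < p, nrow = length(idx))
      wh <- which(hit, arr.ind = TRUE)
      if (nrow(wh) > 0) {
        det_out[[length(det_out) + 1]] <- tibble(
          tag_id = id,
          receiver_id = receivers$receiver_id[near][wh[, 2]],
          timestamp = as.POSIXct(tx_t[idx][wh[, 1]], tz = "UTC",
                                 origin = "1970-01-01"),
          depth_m = tx_d[idx][wh[, 1]])
      }
      n_det <- rowSums(hit)
      ok <- which(n_det >= min_receivers)
      if (length(ok) > 0) {
        hpe <- stats::rgamma(length(ok), shape = pe$hpe_shape,
                             scale = pe$hpe_scale)
        sd_m <- pe$error_per_hpe_m * hpe
        pos_out[[length(pos_out) + 1]] <- tibble(
          tag_id = id,
          timestamp = as.POSIXct(tx_t[idx][ok], tz = "UTC",
                                 origin = "1970-01-01"),
          x_m = tx_x[idx][ok] + stats::rnorm(length(ok), 0, sd_m),
          y_m = tx_y[idx][ok] + stats::rnorm(length(ok), 0, sd_m),
          hpe = hpe,
          depth_m = tx_d[idx][ok])
      }
    }
  }
  detections <- if (length(det_out)) arrange(bind_rows(det_out), .data$tag_id,
                                             .data$timestamp) else
    tibble(tag_id = character(), receiver_id = character(),
           timestamp = as.POSIXct(character(), tz = "UTC"),
           depth_m = numeric())
  positions <- if (length(pos_out)) arrange(bind_rows(pos_out), .data$tag_id,
                                            .data$timestamp) else
    tibble(tag_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
           x_m = numeric(), y_m = numeric(), hpe = numeric(),
           depth_m = numeric())
  list(detections = detections, positions = positions)
}

#' Simulate known-location calibration positions
#'
#' Emulates fixed reference/sync tags: each site produces position solutions
#' at its known location plus isotropic Gaussian error with per-axis SD
#' `error_per_hpe_m * HPE`. A per-site `error_per_hpe_m` column in `sites`
#' lets error scale differ across array regions.
#'
#' @param config A [sim_config()].
#' @param sites Tibble with `station`, `x_m`, `y_m`, optional `region` and
#'   `error_per_hpe_m`. Default: one site at the array centre.
#' @param n_per_site Position solutions per site.
#' @return A calibration position tibble (canonical `positions` schema plus
#'   `region`), with `known_x_m`/`known_y_m` filled.
#' @export
simulate_calibration <- function(config, sites = NULL, n_per_site = 2000L) {
  set.seed(config$seed + 4L)
  pe <- config$position_error
  if (is.null(sites)) {
    a <- config$array
    sites <- tibble(station = "REF1",
                    x_m = (a$n_cols - 1) * a$spacing_m / 2,
                    y_m = (a$n_rows - 1) * a$spacing_m / 2,
                    region = "A",
                    error_per_hpe_m = pe$error_per_hpe_m)
  }
  if (!"region" %in% names(sites)) sites$region <- "A"
  if (!"error_per_hpe_m" %in% names(sites)) {
    sites$error_per_hpe_m <- pe$error_per_hpe_m
  }
  out <- lapply(seq_len(nrow(sites)), function(i) {
    hpe <- stats::rgamma(n_per_site, shape = pe$hpe_shape, scale = pe$hpe_scale)
    sd_m <- sites$error_per_hpe_m[i] * hpe
    tibble(
      tag_id = sites$station[i],
      timestamp = as.POSIXct("2021-01-01", tz = "UTC") +
        seq_len(n_per_site) * 600,
      x_m = sites$x_m[i] + stats::rnorm(n_per_site, 0, sd_m),
      y_m = sites$y_m[i] + stats::rnorm(n_per_site, 0, sd_m),
      hpe = hpe,
      known_x_m = sites$x_m[i], known_y_m = sites$y_m[i],
      region = sites$region[i])
  })
  bind_rows(out)
}

#' Simulate detection-range Bernoulli trials
#'
#' @param config A [sim_config()].
#' @param n Number of trials.
#' @param d_max Maximum trial distance (default three halving distances).
#' @return Tibble with `distance_m` and logical `detected`.
#' @export
simulate_range_trials <- function(config, n = 5000L, d_max = NULL) {
  set.seed(config$seed + 5L)
  rm_ <- config$range_model
  if (is.null(d_max)) d_max <- 3 * rm_$d50_m
  d <- stats::runif(n, 0, d_max)
  p <- detection_probability(d, rm_$p0, rm_$d50_m, rm_$steepness)
  tibble(distance_m = d, detected = stats::runif(n) < p)
}

#' Run the full synthetic-telemetry generator
#'
#' @param config A [sim_config()].
#' @return A list with `receivers`, `habitat`, `environment`, `tracks`
#'   (a `true_track_set`), `detections` and `positions`.
#' @export
simulate_telemetry <- function(config = sim_config()) {
  receivers <- simulate_array(config)
  habitat <- simulate_habitat(receivers)
  environment <- simulate_environment(config)
  tracks <- simulate_tracks(config, receivers, environment)
  det <- simulate_detections(tracks, receivers, config)
  list(receivers = receivers, habitat = habitat, environment = environment,
       tracks = tracks, detections = det$detections,
       positions = det$positions)
}
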
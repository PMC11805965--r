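#' Per-step movement distances and rates
#'
#' Rate is the distance between successive positions divided by the elapsed
#' time. The corrected rate assumes worst-case position error by shortening
#' each distance by twice the accepted position error (floored at zero)
#' before dividing, to vet rates that exceed the species' reported maximum.
#'
#' @param positions Position tibble (`tag_id`, `timestamp`, `x_m`, `y_m`).
#' @param error_threshold_m Accepted position error (default 20 m).
#' @param rate_flag_mps Rates above this are flagged (default 0.75 m/s, the
#'   maximum reported for the study species).
#' @return Tibble of steps: `tag_id`, `t0`, `t1`, `distance_m`, `dt_s`,
#'   `rate_mps`, `corrected_rate_mps`, `flagged`. Zero-duration steps are
#'   skipped with a warning.
#' @export
movement_rates <- function(positions, error_threshold_m = 20,
                           rate_flag_mps = 0.75) {
  steps <- positions |>
    arrange(.data$tag_id, .data$timestamp) |>
    group_by(.data$tag_id) |>
    mutate(t0 = lag(.data$timestamp),
           distance_m = sqrt((.data$x_m - lag(.data$x_m))^2 +
                               (.data$y_m - lag(.data$y_m))^2),
           dt_s = as.numeric(difftime(.data$timestamp, .data$t0,
                                      units = "secs"))) |>
    ungroup() |>
    filter(!is.na(.data$dt_s))
  n_zero <- sum(steps$dt_s == 0)
  if (n_zero > 0) {
    warn(paste0("skipped ", n_zero, " zero-duration step(s)"))
    steps <- filter(steps, .data$dt_s > 0)
  }
  steps |>
    transmute(
      tag_id = .data$tag_id, t0 = .data$t0, t1 = .data$timestamp,
      distance_m = .data$distance_m, dt_s = .data$dt_s,
      rate_mps = .data$distance_m / .data$dt_s,
      corrected_rate_mps = pmax(0, .data$distance_m -
                                  2 * error_threshold_m) / .data$dt_s,
      flagged = .data$corrected_rate_mps > rate_flag_mps)
}

#' Detect long-distance movements
#'
#' A long-distance movement (LDM) is a pair of locations more than
#' `min_dist_m` apart within any rolling `window_h`-hour window. Qualifying
#' pairs whose time spans overlap are merged into a single event (one
#' traverse is one event); the event reports the maximum pairwise distance
#' and its endpoints. An event is emigration-associated when it runs into
#' the fish's final location (the fish is never seen on-array afterwards).
#'
#' @param locations Tibble with `tag_id`, `timestamp` (or `bin_start`),
#'   `x_m`, `y_m`: filtered positions or 4-h COAs.
#' @param window_h Window length in hours (default 48).
#' @param min_dist_m Distance threshold in meters (default 2000).
#' @param source Label recorded on events (`"positions"` or `"coa_4h"`).
#' @return Tibble of LDM events: `tag_id`, `start`, `end`, `start_x`,
#'   `start_y`, `end_x`, `end_y`, `max_distance_m`, `source`,
#'   `emigration_associated`.
#' @export
detect_ldm <- function(locations, window_h = 48, min_dist_m = 2000,
                       source = "positions") {
  ts_col <- if ("timestamp" %in% names(locations)) "timestamp" else "bin_start"
  out <- list()
  for (id in unique(locations$tag_id)) {
    loc <- locations[locations$tag_id == id, ]
    loc <- loc[order(loc[[ts_col]]), ]
    tt <- as.numeric(loc[[ts_col]]); x <- loc$x_m; y <- loc$y_m
    n <- length(tt)
    if (n < 2) next
    w_s <- window_h * 3600
    pairs <- list()
    j_hi <- 1L
    for (i in seq_len(n - 1)) {
      while (j_hi < n && tt[j_hi + 1] - tt[i] <= w_s) j_hi <- j_hi + 1L
      if (j_hi <= i) next
      js <- (i + 1):j_hi
      d <- sqrt((x[js] - x[i])^2 + (y[js] - y[i])^2)
      hit <- js[d > min_dist_m]
      if (length(hit) > 0) {
        pairs[[length(pairs) + 1]] <- tibble(i = i, j = hit,
                                             d = d[d > min_dist_m])
      }
    }
    if (length(pairs) == 0) next
    pairs <- bind_rows(pairs) |>
      mutate(t_start = tt[.data$i], t_end = tt[.data$j]) |>
      arrange(.data$t_start)
    # merge pairs whose [t_start, t_end] spans overlap into events
    ev_id <- integer(nrow(pairs)); cur <- 1L; ev_id[1] <- 1L
    cur_end <- pairs$t_end[1]
    for (r in seq_len(nrow(pairs))[-1]) {
      if (pairs$t_start[r] <= cur_end) {
        ev_id[r] <- cur
        cur_end <- max(cur_end, pairs$t_end[r])
      } else {
        cur <- cur + 1L; ev_id[r] <- cur; cur_end <- pairs$t_end[r]
      }
    }
    pairs$event <- ev_id
    last_t <- tt[n]
    ev <- pairs |>
      group_by(.data$event) |>
      mutate(ev_end = max(.data$t_end)) |>
      slice_max(.data$d, n = 1, with_ties = FALSE) |>
      ungroup() |>
      transmute(
        tag_id = id,
        start = as.POSIXct(tt[.data$i], tz = "UTC", origin = "1970-01-01"),
        end = as.POSIXct(tt[.data$j], tz = "UTC", origin = "1970-01-01"),
        start_x = x[.data$i], start_y = y[.data$i],
        end_x = x[.data$j], end_y = y[.data$j],
        max_distance_m = .data$d, source = source,
        emigration_associated = last_t - .data$ev_end <= w_s)
    out[[length(out) + 1]] <- ev
  }
  if (length(out) == 0) {
    return(tibble(tag_id = character(),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  start_x = numeric(), start_y = numeric(),
                  end_x = numeric(), end_y = numeric(),
                  max_distance_m = numeric(), source = character(),
                  emigration_associated = logical()))
  }
  bind_rows(out)
}

#' Assign habitat labels to points
#'
#' Point-in-polygon labels against the habitat map; points in no named
#' polygon are sand (the complement). Points outside the map's bounding box
#' are labeled sand with a warning. Where polygons overlap, the smaller
#' (more specific) habitat wins.
#'
#' @param points Tibble with `x_m`, `y_m`.
#' @param habitat_map A `habitat_map` tibble (`habitat_label`, `polygon`).
#' @return The points with a `habitat_label` column appended.
#' @export
assign_habitat <- function(points, habitat_map) {
  lab <- rep("sand", nrow(points))
  areas <- vapply(habitat_map$polygon, function(pg) {
    abs(sum(pg[-nrow(pg), 1] * pg[-1, 2] - pg[-1, 1] * pg[-nrow(pg), 2])) / 2
  }, numeric(1))
  for (i in order(areas, decreasing = TRUE)) {  # small polygons overwrite
    pg <- habitat_map$polygon[[i]]
    inside <- as.logical(mgcv::in.out(pg, cbind(points$x_m, points$y_m)))
    lab[inside] <- habitat_map$habitat_label[i]
  }
  allxy <- do.call(rbind, habitat_map$polygon)
  out_box <- points$x_m < min(allxy[, 1]) - 1e4 |
    points$x_m > max(allxy[, 1]) + 1e4 |
    points$y_m < min(allxy[, 2]) - 1e4 | points$y_m > max(allxy[, 2]) + 1e4
  if (any(out_box)) {
    warn(paste0(sum(out_box),
                " point(s) far outside the habitat map; labeled sand"))
  }
  mutate(points, habitat_label = lab)
}

#' Per-habitat summary of a numeric variable
#'
#' @param data Tibble with a `habitat_label` column.
#' @param var Column to summarize (tidy-eval).
#' @return Tibble of per-habitat `n`, `median`, `mean`, `sd`.
#' @export
habitat_summary <- function(data, var) {
  data |>
    group_by(.data$habitat_label) |>
    summarise(n = dplyr::n(),
              median = stats::median({{ var }}, na.rm = TRUE),
              mean = mean({{ var }}, na.rm = TRUE),
              sd = stats::sd({{ var }}, na.rm = TRUE), .groups = "drop")
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of the ranks; the p-value is exact for
#' small untied samples (n <= 10) and uses the large-sample approximation
#' otherwise.
#'
#' @param x,y Numeric vectors.
#' @return Tibble with `rho`, `p_value`, `n`, `method`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  exact <- n <= 10 && no_ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  tibble(rho = rho, p_value = ct$p.value, n = n,
         method = if (exact) "exact" else "approximate")
}
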
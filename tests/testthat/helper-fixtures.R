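utc <- function(x) as.POSIXct(x, tz = "UTC")

# small detection table: one tag heard by three receivers around a bin
tiny_detections <- function() {
  tibble::tibble(
    tag_id = "T1",
    receiver_id = c("R1", "R2", "R3", "R1", "R2", "R3"),
    timestamp = utc("2021-01-01 08:00:00") + c(0, 60, 120, 300, 360, 420),
    depth_m = 30)
}

tiny_receivers <- function() {
  tibble::tibble(
    receiver_id = c("R1", "R2", "R3"),
    x_m = c(0, 100, 0), y_m = c(0, 0, 100),
    deploy_date = as.Date("2020-12-01"),
    recover_date = as.Date("2021-12-01"),
    station_name = c("S1", "S2", "S3"),
    array_label = "synthetic", habitat_label = NA_character_)
}

# COA table holding a fish at a fixed spot for `days` days, `per_day` bins/day
resident_coas <- function(tag = "F1", x = 1000, y = 1000, days = 20,
                          per_day = 8, depth = 35, depth_sd = 1,
                          start = as.Date("2021-01-01")) {
  bins <- do.call(c, lapply(seq_len(days) - 1, function(d) {
    utc(format(start + d)) + seq(8 * 3600, by = 1800, length.out = per_day)
  }))
  set.seed(sum(utf8ToInt(tag)))
  tibble::tibble(
    tag_id = tag, bin_start = bins, bin_minutes = 30,
    x_m = x + stats::rnorm(length(bins), 0, 20),
    y_m = y + stats::rnorm(length(bins), 0, 20),
    n_receivers = 3L, n_detections = 6L,
    mean_depth_m = depth + stats::rnorm(length(bins), 0, depth_sd),
    below_min = FALSE)
}

grid_receivers <- function(n = 7, spacing = 600) {
  cfg <- sim_config(array = list(n_rows = n, n_cols = n, spacing_m = spacing))
  simulate_array(cfg)
}

# Poisson-binomial P(at least k successes) by dynamic programming
prob_at_least <- function(p, k) {
  f <- 1
  for (pi in p) f <- c(f, 0) * (1 - pi) + c(0, f) * pi
  sum(f[(k + 1):length(f)])
}
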
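test_that("per-bin 2DRMS evaluates the defining formula", {
  cal <- tibble::tibble(
    tag_id = "REF", timestamp = utc("2021-01-01") + 1:2,
    x_m = c(103, 104), y_m = c(104, 103), hpe = c(1.2, 1.6),
    known_x_m = 100, known_y_m = 100)
  bins <- compute_2drms_bins(cal, hpe_censor_quantile = 1, min_bin_n = 1)
  # (dx, dy) of (3,4) and (4,3): 2 * sqrt((25 + 25) / 2) = 10 m
  expect_equal(bins$drms2_m, 10)

  zero <- dplyr::mutate(cal, x_m = known_x_m, y_m = known_y_m)
  expect_equal(compute_2drms_bins(zero, 1, 1)$drms2_m, 0)

  scaled <- dplyr::mutate(cal, x_m = known_x_m + 3 * (x_m - known_x_m),
                          y_m = known_y_m + 3 * (y_m - known_y_m))
  expect_equal(compute_2drms_bins(scaled, 1, 1)$drms2_m, 30)

  expect_error(compute_2drms_bins(cal[0, ]), "calibration")
})

test_that("upper HPE tail is censored before binning", {
  set.seed(1)
  cal <- tibble::tibble(tag_id = "REF", timestamp = utc("2021-01-01") + 1:1000,
                        x_m = 0, y_m = 0, hpe = runif(1000, 0, 10),
                        known_x_m = 0, known_y_m = 0)
  bins <- compute_2drms_bins(cal, hpe_censor_quantile = 0.95)
  expect_lte(sum(bins$n), 950 + 1)
  expect_lt(max(bins$hpe_mean), 9.7)
})

test_that("calibration fit recovers a single linear error relationship", {
  cfg <- sim_config(seed = 3)
  cal <- simulate_calibration(cfg, n_per_site = 4000)
  fit <- fit_2drms(compute_2drms_bins(cal))
  expect_equal(fit$partition, "pooled")
  # isotropic Gaussian error with per-axis SD = c * HPE gives
  # 2DRMS = 2 * sqrt(2) * c * HPE
  slope_theory <- 2 * sqrt(2) * cfg$position_error$error_per_hpe_m
  expect_lt(abs(tidy(fit)$slope - slope_theory) / slope_theory, 0.05)
  expect_lt(abs(tidy(fit)$intercept), 1)
})

test_that("a two-regime array selects the region-specific relationship", {
  cfg <- sim_config(seed = 8)
  sites <- tibble::tibble(station = c("A1", "B1"), x_m = c(500, 3000),
                          y_m = c(500, 3000), region = c("A", "B"),
                          error_per_hpe_m = c(1.2, 3.6))
  cal <- simulate_calibration(cfg, sites, n_per_site = 3000)
  fit <- fit_2drms(compute_2drms_bins(cal))
  expect_equal(fit$partition, "by_region")
  expect_equal(nrow(tidy(fit)), 2)
  sl <- sort(tidy(fit)$slope)
  expect_lt(abs(sl[2] / sl[1] - 3), 0.6)
})

test_that("position filtering retains by predicted 2DRMS", {
  cfg <- sim_config(seed = 3)
  cal <- simulate_calibration(cfg, n_per_site = 4000)
  fit <- fit_2drms(compute_2drms_bins(cal))
  set.seed(10)
  pos <- tibble::tibble(tag_id = "F", timestamp = utc("2021-01-01") + 1:20000,
                        x_m = 0, y_m = 0,
                        hpe = rgamma(20000, cfg$position_error$hpe_shape,
                                     scale = cfg$position_error$hpe_scale))
  expect_equal(attr(filter_positions(pos, fit, Inf), "retention"), 1)
  keep0 <- filter_positions(pos, fit, 0)
  expect_equal(nrow(keep0), 0)
  # study conditions put roughly 86% of positions under the 20 m threshold
  ret <- attr(filter_positions(pos, fit, 20), "retention")
  expect_gt(ret, 0.83)
  expect_lt(ret, 0.89)
})

test_that("filtering lowers positional error below the unfiltered error", {
  cfg <- sim_config(seed = 12)
  cal <- simulate_calibration(cfg, n_per_site = 6000)
  fit <- fit_2drms(compute_2drms_bins(cal))
  err_all <- sqrt((cal$x_m - cal$known_x_m)^2 + (cal$y_m - cal$known_y_m)^2)
  kept <- filter_positions(cal, fit, 20)
  err_kept <- sqrt((kept$x_m - kept$known_x_m)^2 +
                     (kept$y_m - kept$known_y_m)^2)
  expect_lt(median(err_kept), median(err_all))
  # stochastic dominance at a grid of quantiles
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(quantile(err_kept, qs) <= quantile(err_all, qs)))
  expect_lt(median(err_kept), 20)
})

test_that("range estimation recovers d50 and errors on separation", {
  cfg <- sim_config(seed = 21)
  trials <- simulate_range_trials(cfg, n = 5000)
  rm_ <- estimate_range(trials)
  expect_lt(abs(rm_$d50_m - 346) / 346, 0.05)
  # p at d50 equals half the fitted p0 by construction
  expect_equal(predict(rm_, rm_$d50_m), rm_$p0 / 2)

  allyes <- tibble::tibble(distance_m = runif(100, 0, 100), detected = TRUE)
  expect_error(estimate_range(allyes), "separation")
})

test_that("range estimation is consistent as trials grow", {
  cfg <- sim_config(seed = 33)
  d_hat <- vapply(c(1000, 10000), function(n) {
    estimate_range(simulate_range_trials(sim_config(seed = 33), n))$d50_m
  }, numeric(1))
  expect_lt(abs(d_hat[2] - 346), abs(d_hat[1] - 346) + 5)
  expect_lt(abs(d_hat[2] - 346) / 346, 0.03)
})

test_that("COAs average distinct receiver coordinates per bin", {
  coas <- compute_coas(tiny_detections(), tiny_receivers(), 30)
  expect_equal(nrow(coas), 1)
  expect_equal(coas$x_m, 100 / 3, tolerance = 1e-10)
  expect_equal(coas$y_m, 100 / 3, tolerance = 1e-10)
  expect_equal(coas$n_receivers, 3L)
  expect_error(compute_coas(tiny_detections(), tiny_receivers(), 37),
               "1440")
})

test_that("a tag heard by one receiver has COAs at that receiver", {
  det <- tiny_detections()
  det$receiver_id <- "R2"
  det <- dplyr::distinct(det)
  coas <- compute_coas(det, tiny_receivers(), 30, min_receivers = 1)
  expect_true(all(coas$x_m == 100 & coas$y_m == 0))
})

test_that("sub-threshold bins survive only on the final detection date", {
  det <- dplyr::bind_rows(
    tiny_detections(),                                   # day 1: 3 receivers
    dplyr::mutate(tiny_detections()[1:2, ],              # day 2: 2 receivers
                  timestamp = timestamp + 86400),
    dplyr::mutate(tiny_detections()[1:2, ],              # day 3 (final): 2
                  timestamp = timestamp + 2 * 86400))
  coas <- compute_coas(det, tiny_receivers(), 30)
  days <- as.Date(coas$bin_start)
  expect_true(as.Date("2021-01-01") %in% days)   # full bin kept
  expect_false(as.Date("2021-01-02") %in% days)  # 2-receiver mid-study bin dropped
  expect_true(as.Date("2021-01-03") %in% days)   # final date retained
  expect_true(coas$below_min[days == as.Date("2021-01-03")])
})

test_that("the spurious-detection rule uses the 60-minute isolation window", {
  base <- utc("2021-01-01 00:00:00")
  det <- tibble::tibble(
    tag_id = "T1", receiver_id = "R1",
    timestamp = base + c(2, 3) * 3600, depth_m = 30)
  # neighbors 60 min apart: neither is spurious
  coas <- compute_coas(det, tiny_receivers(), 30, min_receivers = 1)
  expect_equal(nrow(coas), 2)
  # neighbor 90 min away: both isolated, everything removed
  det2 <- dplyr::mutate(det, timestamp = base + c(1.5, 3) * 3600)
  coas2 <- compute_coas(det2, tiny_receivers(), 30, min_receivers = 1)
  expect_equal(nrow(coas2), 0)
})

test_that("residence index counts detection days over the inclusive period", {
  base <- utc("2021-01-01 12:00:00")
  det <- tibble::tibble(tag_id = "T1", receiver_id = "R1",
                        timestamp = base + c(0, 1, 9) * 86400, depth_m = 30)
  ri <- residence_index(det)
  expect_equal(ri$detection_days, 3L)
  expect_equal(ri$period_days, 10L)
  expect_equal(ri$ri, 0.3)
  gaps <- detection_gaps(det)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$gap_days, 7L)

  daily <- tibble::tibble(tag_id = "T2", receiver_id = "R1",
                          timestamp = base + 0:99 * 86400, depth_m = 30)
  ri2 <- residence_index(daily)
  expect_equal(ri2$ri, 1)
  expect_equal(ri2$n_gaps, 0L)

  single <- det[1, ]
  expect_equal(residence_index(single)$ri, 1)
})
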
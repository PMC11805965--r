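static_pair <- function(x = 500, y = 500, gap_s = 600) {
  tibble::tibble(tag_id = "a",
                 timestamp = utc("2021-01-01 10:00:00") + c(0, gap_s),
                 x_m = x, y_m = y)
}

test_that("every UD integrates to one on its grid", {
  ud <- daily_ud(static_pair(), sigma2_m = 0.5, error_sd = 20)
  expect_equal(sum(ud$z) * ud$cell_m^2, 1, tolerance = 1e-6)
  set.seed(4)
  p <- tibble::tibble(tag_id = "a",
                      timestamp = utc("2021-01-01 08:00:00") + (0:20) * 900,
                      x_m = cumsum(rnorm(21, 0, 30)),
                      y_m = cumsum(rnorm(21, 0, 30)))
  ud2 <- daily_ud(p, sigma2_m = 1, error_sd = 20)
  expect_equal(sum(ud2$z) * ud2$cell_m^2, 1, tolerance = 1e-6)
})

test_that("a static pair with vanishing motion variance is the error kernel", {
  ud <- daily_ud(static_pair(), sigma2_m = 1e-12, error_sd = 20, cell_m = 5)
  a95 <- ud_contour(ud, 0.95)$area_m2
  a50 <- ud_contour(ud, 0.50)$area_m2
  # chi-square(2) closed forms for a bivariate Gaussian of SD 20
  expect_equal(a95, qchisq(0.95, 2) * pi * 400, tolerance = 0.02)
  expect_equal(a95 / a50, log(0.05) / log(0.5), tolerance = 0.03)
})

test_that("scaling all gaps leaves the pair weights invariant", {
  p1 <- tibble::tibble(tag_id = "a",
                       timestamp = utc("2021-01-01 08:00:00") +
                         c(0, 600, 1800),
                       x_m = c(0, 50, 100), y_m = 0)
  p2 <- dplyr::mutate(p1, timestamp = utc("2021-01-01 08:00:00") +
                        2 * c(0, 600, 1800))
  grid <- list(x = reeftrack:::.aligned_seq(-100, 200, 10),
               y = reeftrack:::.aligned_seq(-100, 100, 10))
  ud1 <- daily_ud(p1, sigma2_m = 1e-12, error_sd = 15, grid = grid)
  ud2 <- daily_ud(p2, sigma2_m = 1e-12, error_sd = 15, grid = grid)
  expect_equal(ud1$z, ud2$z, tolerance = 1e-9)
})

test_that("no eligible pair yields the no-UD marker", {
  p <- tibble::tibble(tag_id = "a",
                      timestamp = utc("2021-01-01 08:00:00") + c(0, 7200),
                      x_m = c(0, 100), y_m = 0)
  expect_null(daily_ud(p, sigma2_m = 1, error_sd = 20, max_gap_min = 60))
})

test_that("the bridge kernel matches a Monte-Carlo bridge-sampling oracle", {
  set.seed(6)
  for (rep in 1:5) {
    dt <- sample(c(900, 1800, 2700), 1)
    x1 <- runif(1, -200, 200); y1 <- runif(1, -200, 200)
    s2 <- runif(1, 0.1, 1); esd <- runif(1, 10, 25)
    p <- tibble::tibble(tag_id = "a",
                        timestamp = utc("2021-01-01 08:00:00") + c(0, dt),
                        x_m = c(0, x1), y_m = c(0, y1))
    ud <- daily_ud(p, sigma2_m = s2, error_sd = esd)
    n <- 2e5
    a <- runif(n)
    v <- a * (1 - a) * dt * s2 + esd^2
    xx <- a * x1 + rnorm(n, 0, sqrt(v))
    yy <- a * y1 + rnorm(n, 0, sqrt(v))
    half <- ud$cell_m / 2
    ix <- findInterval(xx, c(ud$x - half, max(ud$x) + half))
    iy <- findInterval(yy, c(ud$y - half, max(ud$y) + half))
    ok <- ix >= 1 & ix <= length(ud$x) & iy >= 1 & iy <= length(ud$y)
    emp <- table(factor(ix[ok], seq_along(ud$x)),
                 factor(iy[ok], seq_along(ud$y))) / n
    tv <- 0.5 * sum(abs(emp - ud$z * ud$cell_m^2))
    expect_lt(tv, 0.02)
  }
})

test_that("motion variance is recovered from position triplets", {
  set.seed(2)
  for (sig2 in c(0.5, 1.5)) {
    nt <- 1200
    tw <- cumsum(rep(300, nt))
    pos <- tibble::tibble(
      tag_id = "a", timestamp = utc("2021-01-01 00:00:00") + tw,
      x_m = cumsum(rnorm(nt, 0, sqrt(sig2 * 300))) + rnorm(nt, 0, 5),
      y_m = cumsum(rnorm(nt, 0, sqrt(sig2 * 300))) + rnorm(nt, 0, 5))
    est <- estimate_bb_sigma(pos, error_sd = 5)
    expect_lt(abs(est - sig2) / sig2, 0.3)
  }
})

test_that("tracking-duration UD averages daily surfaces and gates eligibility", {
  set.seed(8)
  mkday <- function(day, cx) {
    tibble::tibble(tag_id = "f",
                   timestamp = utc("2021-01-01 06:00:00") + (day - 1) * 86400 +
                     (0:19) * 1200,
                   x_m = cx + rnorm(20, 0, 30), y_m = rnorm(20, 0, 30))
  }
  pos <- dplyr::bind_rows(lapply(1:6, mkday, cx = 0))
  uds <- daily_uds_by_fish(pos, error_sd = 10)$f
  td <- tracking_ud(uds, min_ud_days = 5, min_mean_positions = 10)
  expect_equal(sum(td$z) * td$cell_m^2, 1, tolerance = 1e-6)
  expect_equal(td$scale, "tracking_duration")

  expect_error(tracking_ud(uds, min_ud_days = 33), "low_ud_days")
  expect_error(tracking_ud(uds, min_ud_days = 5, min_mean_positions = 50),
               "low_position_yield")

  # identical daily UDs: the average equals any one of them
  td1 <- tracking_ud(list(uds[[1]], uds[[1]], uds[[1]]), min_ud_days = 1,
                     min_mean_positions = 1)
  expect_equal(td1$z, uds[[1]]$z, tolerance = 1e-12)

  # two disjoint half-study ranges: 95% area about the sum of phase areas
  pos2 <- dplyr::bind_rows(lapply(1:6, mkday, cx = 0),
                           lapply(7:12, function(d) mkday(d, cx = 3000)))
  uds2 <- daily_uds_by_fish(pos2, error_sd = 10)$f
  td2 <- tracking_ud(uds2, min_ud_days = 5, min_mean_positions = 10)
  a_both <- ud_contour(td2, 0.95)$area_m2
  a_one <- ud_contour(td, 0.95)$area_m2
  expect_equal(a_both / (2 * a_one), 1, tolerance = 0.25)
})

test_that("contours take the densest cells first", {
  # uniform density over N cells
  z <- matrix(1, 10, 10)
  ud <- reeftrack:::new_ud_grid((0:9 + 0.5) * 10, (0:9 + 0.5) * 10, z)
  expect_equal(ud_contour(ud, 0.95)$area_m2, ceiling(0.95 * 100) * 100)
  # monotone density: contour cells are exactly the top-k
  z2 <- matrix(seq(1, 2, length.out = 100), 10, 10)
  ud2 <- reeftrack:::new_ud_grid((0:9 + 0.5) * 10, (0:9 + 0.5) * 10, z2)
  ct <- ud_contour(ud2, 0.5)
  k <- nrow(ct$cells)
  expect_equal(sort(ct$cells$density, decreasing = TRUE),
               sort(as.vector(ud2$z), decreasing = TRUE)[seq_len(k)])
  expect_error(ud_contour(ud2, 1.2), "level")
})

test_that("area95 dominates area50 and daily areas sit below tracking areas", {
  set.seed(13)
  mkday <- function(day) {
    tibble::tibble(tag_id = "f",
                   timestamp = utc("2021-01-01 06:00:00") + (day - 1) * 86400 +
                     (0:19) * 1200,
                   x_m = 60 * sin(day) + rnorm(20, 0, 35),
                   y_m = 60 * cos(day) + rnorm(20, 0, 35))
  }
  uds <- daily_uds_by_fish(dplyr::bind_rows(lapply(1:8, mkday)),
                           error_sd = 10)$f
  td <- tracking_ud(uds, min_ud_days = 5, min_mean_positions = 10)
  expect_gte(ud_contour(td, 0.95)$area_m2, ud_contour(td, 0.50)$area_m2)
  daily_areas <- vapply(uds, function(u) ud_contour(u, 0.95)$area_m2,
                        numeric(1))
  expect_lte(median(daily_areas), ud_contour(td, 0.95)$area_m2)
})

test_that("centroids and shifts mirror the occupancy timeline", {
  set.seed(5)
  mkday <- function(day, cx) {
    tibble::tibble(tag_id = "f",
                   timestamp = utc("2021-01-01 06:00:00") + (day - 1) * 86400 +
                     (0:29) * 900,
                   x_m = cx + rnorm(30, 0, 40), y_m = 500 + rnorm(30, 0, 40))
  }
  # single home range: one centroid, no shift
  pos1 <- dplyr::bind_rows(lapply(1:10, mkday, cx = 500))
  td1 <- tracking_ud(daily_uds_by_fish(pos1, error_sd = 10)$f,
                     min_ud_days = 5, min_mean_positions = 10)
  cen1 <- find_centroids(td1)
  expect_equal(nrow(cen1), 1)
  expect_equal(nrow(detect_shifts(cen1, pos1)$shifts), 0)

  # hard shift at day 11, never revisited: two centroids, one shift
  pos2 <- dplyr::bind_rows(lapply(1:10, mkday, cx = 500),
                           lapply(11:20, mkday, cx = 2500))
  td2 <- tracking_ud(daily_uds_by_fish(pos2, error_sd = 10)$f,
                     min_ud_days = 5, min_mean_positions = 10)
  cen2 <- find_centroids(td2)
  expect_equal(nrow(cen2), 2)
  sh2 <- detect_shifts(cen2, pos2)
  expect_equal(nrow(sh2$shifts), 1)
  expect_lte(abs(as.numeric(sh2$shifts$day - as.Date("2021-01-11"))), 1)

  # alternation between the two sites: two centroids but no shift
  pos3 <- dplyr::bind_rows(lapply(1:20, function(d) {
    mkday(d, cx = ifelse(d %% 2 == 0, 500, 2500))
  }))
  td3 <- tracking_ud(daily_uds_by_fish(pos3, error_sd = 10)$f,
                     min_ud_days = 5, min_mean_positions = 10)
  cen3 <- find_centroids(td3)
  expect_equal(nrow(cen3), 2)
  expect_equal(nrow(detect_shifts(cen3, pos3)$shifts), 0)
})

test_that("centroid components below the minimum area are discarded", {
  z <- matrix(1e-9, 30, 30)
  z[10:15, 10:15] <- 1           # 36-cell component
  z[25, 25] <- 4                 # dense single-cell component (100 m2)
  ud <- reeftrack:::new_ud_grid((0:29 + 0.5) * 10, (0:29 + 0.5) * 10, z,
                                scale = "tracking_duration")
  cen_all <- find_centroids(ud, level = 0.9, min_area_m2 = 100)
  expect_equal(nrow(cen_all), 2)
  cen_big <- find_centroids(ud, level = 0.9, min_area_m2 = 200)
  expect_equal(nrow(cen_big), 1)
  expect_true(all(cen_big$area_m2 >= 200))
})
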
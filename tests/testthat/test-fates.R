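test_that("stationary intervals are flagged from daily depth variability", {
  flat <- resident_coas("M1", days = 30, depth = 35, depth_sd = 0.05)
  iv <- detect_stationary(flat)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_days, 30L)
  expect_equal(iv$start_date, as.Date("2021-01-01"))

  # alternating 20/30 m within each day: SD far above 0.25 m
  wob <- resident_coas("M2", days = 30, depth_sd = 0)
  wob$mean_depth_m <- rep(c(20, 30), length.out = nrow(wob))
  expect_equal(nrow(detect_stationary(wob)), 0)

  nodepth <- dplyr::mutate(flat, mean_depth_m = NA_real_)
  expect_warning(iv3 <- detect_stationary(nodepth), "depth")
  expect_equal(nrow(iv3), 0)
})

test_that("short still spells below the minimum duration are ignored", {
  cc <- resident_coas("M3", days = 20, depth_sd = 1)
  still <- as.Date(cc$bin_start) %in% (as.Date("2021-01-05") + 0:3)
  cc$mean_depth_m[still] <- 35
  expect_equal(nrow(detect_stationary(cc)), 0)  # 4 d < 7 d minimum
})

# -- classifier scenarios on constructed tracks ------------------------------

rec7 <- grid_receivers(7, 600)  # 0..3600 square
study_end <- as.Date("2021-01-30")

# helper: append an exit run on the fish's last day
with_exit_run <- function(coas, to = c(0, 1800)) {
  last <- dplyr::slice_max(coas, bin_start, n = 1)
  run <- tibble::tibble(
    tag_id = last$tag_id,
    bin_start = last$bin_start + 1800 * (1:4),
    bin_minutes = 30,
    x_m = seq(last$x_m, to[1], length.out = 5)[-1],
    y_m = seq(last$y_m, to[2], length.out = 5)[-1],
    n_receivers = c(3L, 3L, 2L, 1L), n_detections = 4L,
    mean_depth_m = last$mean_depth_m, below_min = c(FALSE, FALSE, TRUE, TRUE))
  dplyr::bind_rows(coas, run)
}

anchor <- function() {
  # a fish detected through study end keeps the cohort window honest
  resident_coas("A0", x = 2400, y = 2400, days = 30)
}

test_that("a fish detected to the study end survives", {
  fates <- classify_fates(anchor(), NULL, rec7, study_end = study_end)
  expect_equal(fates$fate, "survived")
  expect_false(fates$ctr_flag)
})

test_that("an edge run followed by silence is emigration (criterion 1)", {
  cc <- with_exit_run(resident_coas("E1", x = 1800, y = 1800, days = 10))
  fates <- classify_fates(dplyr::bind_rows(cc, anchor()), NULL, rec7,
                          study_end = study_end)
  f <- fates[fates$tag_id == "E1", ]
  expect_equal(f$fate, "emigrated")
  expect_match(f$evidence, "criterion1")
})

test_that("an outside relocation confirms emigration (criterion 2)", {
  cc <- resident_coas("E2", x = 1800, y = 1800, days = 10)
  reloc <- tibble::tibble(tag_id = "E2",
                          timestamp = utc("2021-01-20 00:00:00"),
                          x_m = 9000, y_m = 9000, source = "glider",
                          alive = TRUE)
  fates <- classify_fates(dplyr::bind_rows(cc, anchor()), reloc, rec7,
                          study_end = study_end)
  f <- fates[fates$tag_id == "E2", ]
  expect_equal(f$fate, "emigrated")
  expect_match(f$evidence, "criterion2")
  expect_equal(f$confirmed_by, "glider")
})

test_that("a group exit with one confirmed emigrant spreads (criterion 3)", {
  confirmed <- resident_coas("G1", x = 1800, y = 1800, days = 10)
  reloc <- tibble::tibble(tag_id = "G1",
                          timestamp = utc("2021-01-25 00:00:00"),
                          x_m = -8000, y_m = 200, source = "recapture",
                          alive = FALSE)
  # second tag stops silently near the edge within 48 h: alone it is unknown
  buddy <- resident_coas("G2", x = 500, y = 900, days = 10)
  fates <- classify_fates(dplyr::bind_rows(confirmed, buddy, anchor()),
                          reloc, rec7, study_end = study_end)
  f2 <- fates[fates$tag_id == "G2", ]
  expect_equal(f2$fate, "emigrated")
  expect_match(f2$evidence, "criterion3")

  # without the confirmed partner the same fish is unknown
  alone <- classify_fates(dplyr::bind_rows(buddy, anchor()), NULL, rec7,
                          study_end = study_end)
  expect_equal(alone$fate[alone$tag_id == "G2"], "unknown")
})

test_that("an abrupt interior stop is capture removal; recapture confirms", {
  cc <- resident_coas("C1", x = 1800, y = 2400, days = 12)
  fates <- classify_fates(dplyr::bind_rows(cc, anchor()), NULL, rec7,
                          study_end = study_end)
  f <- fates[fates$tag_id == "C1", ]
  expect_equal(f$fate, "captured")
  expect_match(f$evidence, "interior")

  reloc <- tibble::tibble(tag_id = "C1",
                          timestamp = utc("2021-01-12 12:00:00"),
                          x_m = 1800, y_m = 2400, source = "recapture",
                          alive = FALSE)
  fates2 <- classify_fates(dplyr::bind_rows(cc, anchor()), reloc, rec7,
                           study_end = study_end)
  f2 <- fates2[fates2$tag_id == "C1", ]
  expect_equal(f2$fate, "captured")
  expect_equal(f2$confirmed_by, "recapture")
})

test_that("a stationary tag is mortality unless a predation run precedes it", {
  # still from the start: mortality, never predation
  dead <- resident_coas("D1", x = 1800, y = 1800, days = 25,
                        depth_sd = 0.05)
  dead$x_m <- 1800; dead$y_m <- 1800
  fates <- classify_fates(dplyr::bind_rows(dead, anchor()), NULL, rec7,
                          study_end = study_end)
  f <- fates[fates$tag_id == "D1", ]
  expect_equal(f$fate, "mortality")
  expect_equal(f$fate_date, as.Date("2021-01-01"))
  expect_true(f$ctr_flag)
})

test_that("fast shark-like runs with a sequel flag predation, without do not", {
  # resident fish with a fast excursion that keeps being detected afterwards
  cc <- resident_coas("P1", x = 1800, y = 1800, days = 20)
  burst <- as.Date(cc$bin_start) == as.Date("2021-01-05")
  cc$x_m[burst] <- seq(1800, 1800 + 1700 * sum(burst), length.out = sum(burst))
  fates <- classify_fates(dplyr::bind_rows(cc, anchor()), NULL, rec7,
                          study_end = study_end)
  expect_false(fates$fate[fates$tag_id == "P1"] == "predated")

  # same burst right before the tag leaves the array: predation
  cc2 <- resident_coas("P2", x = 1800, y = 1800, days = 10)
  tail_bins <- utc("2021-01-10 16:00:00") + 1800 * (0:5)
  run <- tibble::tibble(tag_id = "P2", bin_start = tail_bins, bin_minutes = 30,
                        x_m = 1800 + 1700 * (1:6), y_m = 1800,
                        n_receivers = 3L, n_detections = 5L,
                        mean_depth_m = c(35, 3, 36, 2, 35, 3),
                        below_min = FALSE)
  fates2 <- classify_fates(dplyr::bind_rows(cc2, run, anchor()), NULL, rec7,
                           study_end = study_end)
  f2 <- fates2[fates2$tag_id == "P2", ]
  expect_equal(f2$fate, "predated")
})

test_that("conflicting evidence raises an error naming both sources", {
  dead <- resident_coas("X1", x = 1800, y = 1800, days = 25, depth_sd = 0.05)
  reloc <- tibble::tibble(tag_id = "X1",
                          timestamp = utc("2021-01-20 00:00:00"),
                          x_m = 1800, y_m = 1800, source = "recapture",
                          alive = FALSE)
  expect_error(
    classify_fates(dplyr::bind_rows(dead, anchor()), reloc, rec7,
                   study_end = study_end),
    "conflicting")
})

test_that("every fish gets exactly one fate and CTR events are flagged", {
  cc <- dplyr::bind_rows(
    anchor(),
    with_exit_run(resident_coas("E9", x = 1800, y = 1800, days = 10)),
    resident_coas("C9", x = 1800, y = 2400, days = 12))
  fates <- classify_fates(cc, NULL, rec7, study_end = study_end)
  expect_equal(sort(unique(fates$tag_id)), sort(unique(cc$tag_id)))
  expect_equal(anyDuplicated(fates$tag_id), 0L)
  expect_true(all(fates$fate %in% c("survived", "emigrated", "mortality",
                                    "predated", "captured", "unknown")))
  expect_true(all(fates$fate_date >= fates$tag_date))
})
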
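#' Fate-rule configuration
#'
#' Thresholds for the rule-based fate classifier. The recovery window,
#' stationary depth-SD rule and group-emigration window follow standard
#' practice for surgically tagged reef fish: a 3-day capture-tagging-release
#' (CTR) recovery period, a tag declared stationary when its daily depth SD
#' stays below 0.25 m, and a 48 h window for group exits. The predation
#' envelope (sustained speed above anything reported for the study species
#' plus full-water-column use) is a heuristic and deliberately configurable.
#'
#' @param recovery_days CTR recovery window (days).
#' @param stationary_depth_sd_m Daily depth SD below which a tag is
#'   stationary.
#' @param stationary_min_days Consecutive stationary days required.
#' @param group_window_h Window for the group-emigration criterion.
#' @param edge_margin_m Distance from the array hull boundary within which a
#'   final location counts as "at the edge"; defaults to one receiver
#'   spacing when left `NULL`.
#' @param predation_speed_floor_mps Sustained COA displacement rate above
#'   which movement is outside the species envelope.
#' @param predation_min_hours Minimum sustained duration of such movement.
#' @param predation_depth_range_m Within-run depth excursion indicating
#'   full-water-column use.
#' @param sequel_window_days A predation run must be followed, within this
#'   many days, by a stationary interval or array exit.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(recovery_days = 3,
                        stationary_depth_sd_m = 0.25,
                        stationary_min_days = 7,
                        group_window_h = 48,
                        edge_margin_m = NULL,
                        predation_speed_floor_mps = 0.75,
                        predation_min_hours = 1,
                        predation_depth_range_m = 25,
                        sequel_window_days = 2) {
  structure(list(recovery_days = recovery_days,
                 stationary_depth_sd_m = stationary_depth_sd_m,
                 stationary_min_days = stationary_min_days,
                 group_window_h = group_window_h,
                 edge_margin_m = edge_margin_m,
                 predation_speed_floor_mps = predation_speed_floor_mps,
                 predation_min_hours = predation_min_hours,
                 predation_depth_range_m = predation_depth_range_m,
                 sequel_window_days = sequel_window_days),
            class = "rule_config")
}

#' Detect stationary-tag intervals from depth series
#'
#' Flags maximal runs of days whose depth standard deviation stays below the
#' stationary threshold, lasting at least `stationary_min_days`.
#'
#' @param depth_series Tibble with `tag_id`, `timestamp` (or `bin_start`) and
#'   a depth column (`depth_m` or `mean_depth_m`), at COA or finer
#'   resolution.
#' @param config A [rule_config()].
#' @return Tibble with `tag_id`, `start_date`, `end_date`, `n_days`.
#' @export
detect_stationary <- function(depth_series, config = rule_config()) {
  ts_col <- if ("timestamp" %in% names(depth_series)) "timestamp" else "bin_start"
  d_col <- if ("depth_m" %in% names(depth_series)) "depth_m" else "mean_depth_m"
  empty <- tibble(tag_id = character(), start_date = as.Date(character()),
                  end_date = as.Date(character()), n_days = integer())
  if (!d_col %in% names(depth_series) ||
      all(is.na(depth_series[[d_col]]))) {
    warn("no depth data: stationary detection unavailable")
    return(empty)
  }
  daily <- depth_series |>
    mutate(day = as.Date(.data[[ts_col]])) |>
    filter(!is.na(.data[[d_col]])) |>
    group_by(.data$tag_id, .data$day) |>
    summarise(depth_sd = stats::sd(.data[[d_col]]), n = dplyr::n(),
              .groups = "drop") |>
    filter(.data$n >= 2)
  if (nrow(daily) == 0) return(empty)
  still <- daily |>
    mutate(stat = .data$depth_sd < config$stationary_depth_sd_m) |>
    arrange(.data$tag_id, .data$day) |>
    group_by(.data$tag_id) |>
    # a run breaks on a non-stationary day or a calendar gap
    mutate(brk = !.data$stat | is.na(lag(.data$stat)) | !lag(.data$stat) |
             (.data$day - lag(.data$day)) > 1,
           run = cumsum(tidyr::replace_na(.data$brk, TRUE))) |>
    filter(.data$stat) |>
    ungroup()
  if (nrow(still) == 0) return(empty)
  still |>
    group_by(.data$tag_id, .data$run) |>
    summarise(start_date = min(.data$day), end_date = max(.data$day),
              n_days = dplyr::n(), .groups = "drop") |>
    filter(.data$n_days >= config$stationary_min_days) |>
    select(-"run")
}

# min distance from points to the boundary of the receiver convex hull;
# negative outside the hull
.dist_to_hull_boundary <- function(x, y, receivers) {
  hull_idx <- grDevices::chull(receivers$x_m, receivers$y_m)
  hx <- receivers$x_m[hull_idx]; hy <- receivers$y_m[hull_idx]
  n <- length(hx)
  seg_d <- sapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    vx <- hx[j] - hx[i]; vy <- hy[j] - hy[i]
    tt <- pmin(pmax(((x - hx[i]) * vx + (y - hy[i]) * vy) / (vx^2 + vy^2), 0), 1)
    sqrt((x - (hx[i] + tt * vx))^2 + (y - (hy[i] + tt * vy))^2)
  })
  d <- if (is.matrix(seg_d)) apply(seg_d, 1, min) else min(seg_d)
  inside <- as.logical(mgcv::in.out(cbind(c(hx, hx[1]), c(hy, hy[1])),
                                    cbind(x, y)))
  ifelse(inside, d, -d)
}

#' Detect shark-like predation movement signatures
#'
#' Flags a fish when its COA track shows a sustained run of displacement
#' rates above the configured non-study-species envelope (optionally with
#' full-water-column depth excursions), and the run is followed within a
#' short window by a stationary interval or by the fish leaving the array.
#' Fast movements by an otherwise continuously tracked fish are not flagged.
#'
#' @param coas COA tibble (from [compute_coas()]).
#' @param config A [rule_config()].
#' @param stationary Optional stationary intervals ([detect_stationary()])
#'   used as the "tag went still" sequel.
#' @return Tibble with `tag_id`, `flagged`, `run_date`, `max_rate_mps`,
#'   `depth_range_m`.
#' @export
detect_predation_signature <- function(coas, config = rule_config(),
                                       stationary = NULL) {
  ann <- coas |>
    arrange(.data$tag_id, .data$bin_start) |>
    group_by(.data$tag_id) |>
    mutate(
      dt_s = as.numeric(difftime(.data$bin_start, lag(.data$bin_start),
                                 units = "secs")),
      rate = sqrt((.data$x_m - lag(.data$x_m))^2 +
                    (.data$y_m - lag(.data$y_m))^2) / .data$dt_s,
      # water-column envelope: depth range over a rolling short window
      win_range = vapply(seq_along(.data$bin_start), function(i) {
        w <- abs(as.numeric(difftime(.data$bin_start, .data$bin_start[i],
                                     units = "hours"))) <=
          2 * config$predation_min_hours
        dd <- .data$mean_depth_m[w]
        if (all(is.na(dd))) 0 else diff(range(dd, na.rm = TRUE))
      }, numeric(1)),
      fast = (!is.na(.data$rate) &
                .data$rate > config$predation_speed_floor_mps) |
        (.data$win_range >= config$predation_depth_range_m &
           !is.na(.data$rate) &
           .data$rate > 0.25 * config$predation_speed_floor_mps),
      last_seen = max(.data$bin_start))
  fast_rows <- ann |>
    mutate(run = cumsum(!.data$fast)) |>
    filter(.data$fast) |>
    ungroup()
  if (nrow(fast_rows) == 0) {
    return(tibble(tag_id = character(), flagged = logical(),
                  run_date = as.Date(character()), max_rate_mps = numeric(),
                  depth_range_m = numeric()))
  }
  runs <- fast_rows |>
    group_by(.data$tag_id, .data$run, .data$last_seen) |>
    summarise(run_start = min(.data$bin_start), run_end = max(.data$bin_start),
              dur_h = sum(.data$dt_s) / 3600,
              max_rate_mps = max(.data$rate),
              depth_range_m = if (all(is.na(.data$mean_depth_m))) 0 else
                diff(range(.data$mean_depth_m, na.rm = TRUE)),
              .groups = "drop") |>
    filter(.data$dur_h >= config$predation_min_hours)
  if (nrow(runs) == 0) {
    return(tibble(tag_id = character(), flagged = logical(),
                  run_date = as.Date(character()), max_rate_mps = numeric(),
                  depth_range_m = numeric()))
  }
  seq_w <- config$sequel_window_days * 86400
  runs$exit_sequel <- as.numeric(difftime(runs$last_seen, runs$run_end,
                                          units = "secs")) <= seq_w
  runs$still_sequel <- FALSE
  if (!is.null(stationary) && nrow(stationary) > 0) {
    for (i in seq_len(nrow(runs))) {
      st <- stationary[stationary$tag_id == runs$tag_id[i], ]
      runs$still_sequel[i] <- any(
        abs(as.numeric(st$start_date - as.Date(runs$run_end[i]))) <=
          config$sequel_window_days)
    }
  }
  runs |>
    filter(.data$exit_sequel | .data$still_sequel) |>
    group_by(.data$tag_id) |>
    slice_min(.data$run_start, n = 1, with_ties = FALSE) |>
    ungroup() |>
    transmute(tag_id = .data$tag_id, flagged = TRUE,
              run_date = as.Date(.data$run_start),
              max_rate_mps = .data$max_rate_mps,
              depth_range_m = .data$depth_range_m)
}

#' Rule-based terminal fate classification
#'
#' Assigns each tracked fish one terminal fate from its COA track, depth
#' series, auxiliary relocations and the array geometry, in priority order:
#' recapture inside the array (captured), stationary tag not preceded by a
#' predation signature (mortality), predation signature followed by a stop or
#' exit (predated), any of three emigration criteria — (1) a final location
#' at the array edge before going silent, (2) confirmation by recapture or a
#' live glider detection outside the array, (3) membership in a group of
#' tags leaving within the group window with at least one confirmed — then
#' detection through the study end (survived), an abrupt silent stop in the
#' array interior (captured), and otherwise unknown. Events inside the CTR
#' recovery window carry `ctr_flag` and are excluded from downstream event
#' histories.
#'
#' @param coas COA tibble ([compute_coas()]); `mean_depth_m` supplies the
#'   depth series.
#' @param relocations Relocation tibble (recaptures, glider detections) or
#'   `NULL`.
#' @param receivers Receiver tibble defining the array geometry.
#' @param config A [rule_config()].
#' @param tagging Optional tibble `tag_id`, `tag_date`; defaults to each
#'   fish's first detection date.
#' @param study_end Last study date; defaults to the latest COA date.
#' @return Fate tibble: `tag_id`, `fate`, `fate_date`, `ctr_flag`,
#'   `evidence`, `confirmed_by`, `tag_date`, `last_det_date`.
#' @export
classify_fates <- function(coas, relocations = NULL, receivers,
                           config = rule_config(), tagging = NULL,
                           study_end = NULL) {
  if (is.null(config$edge_margin_m)) {
    dx <- sort(unique(receivers$x_m))
    config$edge_margin_m <- if (length(dx) > 1) min(diff(dx)) else 600
  }
  if (is.null(study_end)) study_end <- max(as.Date(coas$bin_start))

  coas <- coas |> mutate(.edge = .dist_to_hull_boundary(.data$x_m, .data$y_m,
                                                        receivers))
  per_tag <- coas |>
    group_by(.data$tag_id) |>
    arrange(.data$bin_start, .by_group = TRUE) |>
    summarise(first_det = as.Date(min(.data$bin_start)),
              last_det_date = as.Date(max(.data$bin_start)),
              edge_dist = .data$.edge[which.max(.data$bin_start)],
              # typical edge distance before the final detection day, to
              # distinguish an approach to the boundary from residency there
              prior_edge_dist = {
                pre <- .data$.edge[as.Date(.data$bin_start) <
                                     as.Date(max(.data$bin_start))]
                if (length(pre) == 0) .data$.edge[which.max(.data$bin_start)]
                else stats::median(pre)
              },
              # outward displacement within the final detection day
              final_day_outward = {
                fd <- as.Date(.data$bin_start) == as.Date(max(.data$bin_start))
                e <- .data$.edge[fd][order(.data$bin_start[fd])]
                e[1] - e[length(e)]
              },
              .groups = "drop")
  if (is.null(tagging)) {
    tagging <- tibble(tag_id = per_tag$tag_id, tag_date = per_tag$first_det)
  }
  per_tag <- left_join(per_tag, tagging, by = "tag_id")

  stationary <- suppressWarnings(detect_stationary(coas, config))
  predation <- detect_predation_signature(coas, config, stationary)

  reloc <- relocations %||%
    tibble(tag_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
           x_m = numeric(), y_m = numeric(), source = character(),
           alive = logical())
  if (nrow(reloc) > 0) {
    if (!"x_m" %in% names(reloc)) reloc$x_m <- NA_real_
    if (!"y_m" %in% names(reloc)) reloc$y_m <- NA_real_
    has_xy <- !is.na(reloc$x_m) & !is.na(reloc$y_m)
    reloc$inside <- FALSE
    if (any(has_xy)) {
      reloc$inside[has_xy] <- .dist_to_hull_boundary(
        reloc$x_m[has_xy], reloc$y_m[has_xy], receivers) > 0
    }
  } else reloc$inside <- logical(0)

  rows <- lapply(seq_len(nrow(per_tag)), function(i) {
    p <- per_tag[i, ]
    rl <- reloc[reloc$tag_id == p$tag_id, ]
    st <- stationary[stationary$tag_id == p$tag_id, ]
    pr <- predation[predation$tag_id == p$tag_id, ]
    evid <- character(); confirmed <- "none"

    recap_in <- rl[rl$source == "recapture" & rl$inside, ]
    outside_conf <- rl[!rl$inside &
                         (rl$source == "recapture" | rl$alive), ]

    if (nrow(recap_in) > 0) {
      if (nrow(st) > 0 &&
          min(st$start_date) < as.Date(min(recap_in$timestamp)) - 1) {
        abort(paste0("conflicting evidence for ", p$tag_id,
                     ": stationary interval from ", min(st$start_date),
                     " but recapture inside the array on ",
                     as.Date(min(recap_in$timestamp))))
      }
      fate <- "captured"; date <- as.Date(min(recap_in$timestamp))
      evid <- "recapture_inside"; confirmed <- "recapture"
    } else if (nrow(st) > 0 &&
               !(nrow(pr) > 0 && pr$run_date <= min(st$start_date) + 1)) {
      fate <- "mortality"; date <- min(st$start_date)
      evid <- "stationary_depth"
    } else if (nrow(pr) > 0) {
      fate <- "predated"; date <- pr$run_date
      evid <- "predation_signature"
    } else if (nrow(outside_conf) > 0 &&
               as.Date(min(outside_conf$timestamp)) >= p$last_det_date) {
      fate <- "emigrated"; date <- p$last_det_date
      evid <- "criterion2_confirmed_outside"
      confirmed <- outside_conf$source[1]
    } else if (p$last_det_date >= study_end - 1) {
      fate <- "survived"; date <- study_end
      evid <- "detected_to_study_end"
    } else if (p$edge_dist < 0.25 * config$edge_margin_m ||
               (p$final_day_outward > 0.5 * config$edge_margin_m &&
                  p$edge_dist < p$prior_edge_dist)) {
      # ended at/over the boundary, or ran outward on its last day
      fate <- "emigrated"; date <- p$last_det_date
      evid <- "criterion1_edge_exit"
    } else {
      fate <- "pending"; date <- p$last_det_date
    }
    tibble(tag_id = p$tag_id, fate = fate, fate_date = date,
           evidence = paste(evid, collapse = ";"),
           confirmed_by = confirmed, tag_date = p$tag_date,
           last_det_date = p$last_det_date, edge_dist = p$edge_dist,
           final_day_outward = p$final_day_outward)
  })
  fates <- bind_rows(rows)

  # criterion 3: tags leaving within the group window, >=1 confirmed emigrant
  pending <- fates$fate == "pending"
  if (any(pending)) {
    conf_exits <- fates$last_det_date[fates$fate == "emigrated" &
                                        fates$confirmed_by != "none"]
    for (i in which(pending)) {
      near <- abs(as.numeric(fates$last_det_date[i] - conf_exits)) * 24 <=
        config$group_window_h
      if (length(conf_exits) > 0 && any(near)) {
        fates$fate[i] <- "emigrated"
        fates$evidence[i] <- "criterion3_group_exit"
        fates$confirmed_by[i] <- "group"
      }
    }
  }
  # abrupt silent stop well inside the array: capture removal
  pending <- fates$fate == "pending"
  fates$fate[pending & fates$edge_dist > config$edge_margin_m &
               fates$final_day_outward < 0.25 * config$edge_margin_m] <-
    "captured"
  fates$evidence[fates$fate == "captured" & fates$evidence == ""] <-
    "abrupt_interior_stop"
  fates$fate[fates$fate == "pending"] <- "unknown"

  fates |>
    mutate(ctr_flag = .data$fate_date <= .data$tag_date + config$recovery_days &
             .data$fate != "survived") |>
    select("tag_id", "fate", "fate_date", "ctr_flag", "evidence",
           "confirmed_by", "tag_date", "last_det_date")
}
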
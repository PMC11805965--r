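#' Utilization-distribution grid
#'
#' Internal constructor for the 10 x 10 m UD raster. Cells are aligned to
#' multiples of the cell size so daily grids from the same fish can be
#' averaged cell-for-cell.
#'
#' @param x,y Cell-center coordinate vectors.
#' @param z Density matrix (`length(x)` rows, `length(y)` columns), per m2.
#' @param cell_m Cell edge in meters.
#' @param scale `"daily"` or `"tracking_duration"`.
#' @param tag_id,date Provenance labels.
#' @return Object of class `ud_grid`.
#' @keywords internal
new_ud_grid <- function(x, y, z, cell_m = 10, scale = "daily",
                        tag_id = NA_character_, date = as.Date(NA)) {
  z <- z / (sum(z) * cell_m^2)  # exact normalization on the grid
  structure(list(x = x, y = y, z = z, cell_m = cell_m, scale = scale,
                 tag_id = tag_id, date = date), class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("UD grid (%s): %d x %d cells of %g m, mass %.6f\n", x$scale,
              length(x$x), length(x$y), x$cell_m, sum(x$z) * x$cell_m^2))
  invisible(x)
}

.aligned_seq <- function(lo, hi, cell) {
  lo_i <- floor(lo / cell); hi_i <- ceiling(hi / cell)
  (seq(lo_i, hi_i) + 0.5) * cell
}

#' Estimate Brownian-bridge motion variance
#'
#' Leave-one-out maximum likelihood on position triplets: each interior
#' position is predicted from the Brownian bridge spanned by its neighbours,
#' and the bridge motion variance maximizing the summed Gaussian
#' log-likelihood (with endpoint and observation location error) is
#' returned.
#'
#' @param positions Tibble with `timestamp`, `x_m`, `y_m` for one fish.
#' @param error_sd Location error SD in meters (the accepted position error
#'   threshold stands in for it when unknown).
#' @param max_gap_min Maximum gap between bridge endpoints (minutes).
#' @return Motion variance `sigma2_m` in m2/s.
#' @export
estimate_bb_sigma <- function(positions, error_sd = 20, max_gap_min = 60) {
  p <- arrange(positions, .data$timestamp)
  t_s <- as.numeric(p$timestamp)
  n <- nrow(p)
  if (n < 3) return(NA_real_)
  i <- 2:(n - 1)
  g1 <- t_s[i] - t_s[i - 1]; g2 <- t_s[i + 1] - t_s[i]
  ok <- g1 <= max_gap_min * 60 & g2 <= max_gap_min * 60 & g1 > 0 & g2 > 0
  i <- i[ok]
  if (length(i) == 0) return(NA_real_)
  alpha <- (t_s[i] - t_s[i - 1]) / (t_s[i + 1] - t_s[i - 1])
  T_tot <- t_s[i + 1] - t_s[i - 1]
  mx <- (1 - alpha) * p$x_m[i - 1] + alpha * p$x_m[i + 1]
  my <- (1 - alpha) * p$y_m[i - 1] + alpha * p$y_m[i + 1]
  dx <- p$x_m[i] - mx; dy <- p$y_m[i] - my
  # location error of the observed point plus the interpolated endpoints
  err_part <- (1 + (1 - alpha)^2 + alpha^2) * error_sd^2
  nll <- function(log_s2) {
    v <- alpha * (1 - alpha) * T_tot * exp(log_s2) + err_part
    -sum(-log(2 * pi * v) - (dx^2 + dy^2) / (2 * v))
  }
  opt <- stats::optimize(nll, c(log(1e-6), log(1e4)))
  exp(opt$minimum)
}

#' Daily Brownian-bridge utilization distribution
#'
#' For one fish-day, builds the Brownian-bridge kernel for every consecutive
#' pair of positions no more than `max_gap_min` apart: along each bridge the
#' location density is Gaussian with mean interpolated between the endpoints
#' and variance `a(1-a) * dt * sigma2_m + error_sd^2` (the location-error
#' variance is carried along the whole bridge), integrated over the bridge by
#' midpoint quadrature. Pair kernels are
#' averaged with weights proportional to the time interval each encompasses,
#' and the result normalized on the 10 m grid.
#'
#' @param positions Positions for one fish and one day (`timestamp`, `x_m`,
#'   `y_m`).
#' @param sigma2_m Motion variance (m2/s), e.g. from [estimate_bb_sigma()].
#' @param error_sd Location error SD in meters (default the 20 m accepted
#'   position error).
#' @param cell_m Grid cell edge (default 10 m).
#' @param max_gap_min Maximum within-pair gap (default 60 min).
#' @param n_quad Quadrature points per bridge (default 10).
#' @param grid Optional list with `x`, `y` cell centers to force a grid.
#' @return A `ud_grid`, or `NULL` when no eligible pair exists (the no-UD
#'   marker for that day). The number of contributing positions is attached
#'   as attribute `n_positions`.
#' @export
daily_ud <- function(positions, sigma2_m, error_sd = 20, cell_m = 10,
                     max_gap_min = 60, n_quad = 10, grid = NULL) {
  p <- arrange(positions, .data$timestamp)
  t_s <- as.numeric(p$timestamp)
  dt <- diff(t_s)
  ok <- which(dt > 0 & dt <= max_gap_min * 60)
  if (length(ok) == 0) return(NULL)

  max_var <- max(dt[ok]) * sigma2_m / 4 + error_sd^2
  margin <- 3.5 * sqrt(max_var) + cell_m
  if (is.null(grid)) {
    gx <- .aligned_seq(min(p$x_m) - margin, max(p$x_m) + margin, cell_m)
    gy <- .aligned_seq(min(p$y_m) - margin, max(p$y_m) + margin, cell_m)
  } else { gx <- grid$x; gy <- grid$y }
  z <- matrix(0, length(gx), length(gy))

  a_quad <- (seq_len(n_quad) - 0.5) / n_quad
  for (k in ok) {
    w <- dt[k]
    for (a in a_quad) {
      mx <- (1 - a) * p$x_m[k] + a * p$x_m[k + 1]
      my <- (1 - a) * p$y_m[k] + a * p$y_m[k + 1]
      v <- a * (1 - a) * dt[k] * sigma2_m + error_sd^2
      z <- z + (w / n_quad) *
        outer(stats::dnorm(gx, mx, sqrt(v)), stats::dnorm(gy, my, sqrt(v)))
    }
  }
  ud <- new_ud_grid(gx, gy, z, cell_m, "daily",
                    tag_id = p$tag_id[1] %||% NA_character_,
                    date = as.Date(p$timestamp[1]))
  attr(ud, "n_positions") <- nrow(p)
  ud
}

#' Daily UDs for every fish-day of a position table
#'
#' @param positions Filtered position tibble (`tag_id`, `timestamp`, `x_m`,
#'   `y_m`).
#' @param error_sd Location error SD (m).
#' @param sigma2_m Motion variance; estimated per fish via
#'   [estimate_bb_sigma()] when `NULL`.
#' @param ... Passed to [daily_ud()].
#' @return Named list (by tag) of lists of `ud_grid` objects (days without
#'   an eligible pair are dropped).
#' @export
daily_uds_by_fish <- function(positions, error_sd = 20, sigma2_m = NULL, ...) {
  by_tag <- split(positions, positions$tag_id)
  lapply(by_tag, function(pp) {
    s2 <- sigma2_m %||% estimate_bb_sigma(pp, error_sd)
    if (is.na(s2)) return(list())
    days <- split(pp, as.Date(pp$timestamp))
    uds <- lapply(days, daily_ud, sigma2_m = s2, error_sd = error_sd, ...)
    uds[!vapply(uds, is.null, logical(1))]
  })
}

#' Tracking-duration utilization distribution
#'
#' Averages a fish's daily UD density surfaces (equal weight per day) on the
#' union grid. Fish with fewer than `min_ud_days` estimable daily UDs or a
#' mean daily position count below `min_mean_positions` are excluded (the
#' low-position-yield rule); the reason is attached to the error condition.
#'
#' @param daily_uds List of `ud_grid` objects for one fish.
#' @param min_ud_days Minimum number of UD-days (default 33).
#' @param min_mean_positions Minimum mean daily positions (default 18).
#' @return A `ud_grid` with scale `"tracking_duration"`.
#' @export
tracking_ud <- function(daily_uds, min_ud_days = 33, min_mean_positions = 18) {
  n_days <- length(daily_uds)
  if (n_days == 0) abort("ineligible: no daily UDs (reason: no_ud_days)")
  mean_pos <- mean(vapply(daily_uds, function(u) {
    attr(u, "n_positions") %||% NA_real_
  }, numeric(1)), na.rm = TRUE)
  if (n_days < min_ud_days) {
    abort(paste0("ineligible: ", n_days, " UD-days < ", min_ud_days,
                 " (reason: low_ud_days)"))
  }
  if (!is.na(mean_pos) && mean_pos < min_mean_positions) {
    abort(paste0("ineligible: mean daily positions ", round(mean_pos, 1),
                 " < ", min_mean_positions, " (reason: low_position_yield)"))
  }
  cell <- daily_uds[[1]]$cell_m
  ix_all <- lapply(daily_uds, function(u) round(u$x / cell - 0.5))
  iy_all <- lapply(daily_uds, function(u) round(u$y / cell - 0.5))
  gx <- (seq(min(unlist(ix_all)), max(unlist(ix_all))) + 0.5) * cell
  gy <- (seq(min(unlist(iy_all)), max(unlist(iy_all))) + 0.5) * cell
  z <- matrix(0, length(gx), length(gy))
  for (u in daily_uds) {
    ix <- match(round(u$x / cell - 0.5), round(gx / cell - 0.5))
    iy <- match(round(u$y / cell - 0.5), round(gy / cell - 0.5))
    z[ix, iy] <- z[ix, iy] + u$z
  }
  ud <- new_ud_grid(gx, gy, z / n_days, cell, "tracking_duration",
                    tag_id = daily_uds[[1]]$tag_id)
  attr(ud, "n_ud_days") <- n_days
  attr(ud, "mean_daily_positions") <- mean_pos
  ud
}

#' Isopleth contour of a utilization distribution
#'
#' Returns the smallest set of grid cells whose cumulative density reaches
#' the stated level (the greedy top-density set, which is optimal), with the
#' isopleth area counted by cells.
#'
#' @param ud A `ud_grid`.
#' @param level Contour level in (0, 1), e.g. 0.95.
#' @return List with `cells` (tibble `x`, `y`, `density`), `area_m2` and
#'   `level`.
#' @export
ud_contour <- function(ud, level = 0.95) {
  if (level <= 0 || level >= 1) abort("contour level must lie in (0, 1)")
  dens <- as.vector(ud$z)
  ord <- order(dens, decreasing = TRUE)
  mass <- cumsum(dens[ord]) * ud$cell_m^2
  k <- which(mass >= level)[1]
  if (is.na(k)) k <- length(ord)
  sel <- ord[seq_len(k)]
  ij <- arrayInd(sel, dim(ud$z))
  list(cells = tibble(x = ud$x[ij[, 1]], y = ud$y[ij[, 2]],
                      density = dens[sel]),
       area_m2 = k * ud$cell_m^2, level = level)
}

# 4-connected component labeling of a logical matrix (flood fill)
.label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask & lab == 0)) {
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      cel <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[cel] != 0L || !mask[cel]) next
      lab[cel] <- cur
      i <- ((cel - 1) %% nrow(mask)) + 1; j <- ((cel - 1) %/% nrow(mask)) + 1
      if (i > 1) stack <- c(stack, cel - 1)
      if (i < nrow(mask)) stack <- c(stack, cel + 1)
      if (j > 1) stack <- c(stack, cel - nrow(mask))
      if (j < ncol(mask)) stack <- c(stack, cel + nrow(mask))
    }
  }
  lab
}

#' High-use centroids of a tracking-duration UD
#'
#' Connected components of the 90% isopleth with area of at least 100 m2
#' become centroids (high-use sites).
#'
#' @param ud_td Tracking-duration `ud_grid`.
#' @param level Isopleth level (default 0.90).
#' @param min_area_m2 Minimum component area (default 100).
#' @return Tibble: `centroid_id`, `x` (density-weighted center), `y`,
#'   `area_m2`, and a `cells` list-column.
#' @export
find_centroids <- function(ud_td, level = 0.90, min_area_m2 = 100) {
  ct <- ud_contour(ud_td, level)
  mask <- matrix(FALSE, length(ud_td$x), length(ud_td$y))
  ix <- match(ct$cells$x, ud_td$x); iy <- match(ct$cells$y, ud_td$y)
  mask[cbind(ix, iy)] <- TRUE
  lab <- .label_components(mask)
  comps <- sort(unique(lab[lab > 0]))
  out <- lapply(comps, function(cc) {
    idx <- which(lab == cc, arr.ind = TRUE)
    area <- nrow(idx) * ud_td$cell_m^2
    if (area < min_area_m2) return(NULL)
    w <- ud_td$z[lab == cc]
    tibble(x = sum(ud_td$x[idx[, 1]] * w) / sum(w),
           y = sum(ud_td$y[idx[, 2]] * w) / sum(w),
           area_m2 = area,
           cells = list(tibble(x = ud_td$x[idx[, 1]], y = ud_td$y[idx[, 2]])))
  })
  out <- bind_rows(out)
  if (nrow(out) > 0) out <- mutate(out, centroid_id = dplyr::row_number(),
                                   .before = 1)
  out
}

#' Assign daily positions to centroids and detect shifts in space use
#'
#' Counts each day's positions inside each centroid's cells, then flags a
#' shift whenever a newly used centroid's first active day falls after the
#' last active day of every previously used centroid (no temporal overlap).
#' Alternating use of several centroids is not a shift.
#'
#' @param centroids Output of [find_centroids()].
#' @param positions Daily positions of the same fish.
#' @param cell_m Grid cell size used for membership (default 10).
#' @return List with `occupancy` (centroid x day counts) and `shifts`
#'   (tibble of shift events with `centroid_id` and `day`).
#' @export
detect_shifts <- function(centroids, positions, cell_m = 10) {
  if (nrow(centroids) == 0) {
    return(list(occupancy = tibble(), shifts = tibble()))
  }
  pos <- mutate(positions, day = as.Date(.data$timestamp),
                cx = (floor(.data$x_m / cell_m) + 0.5) * cell_m,
                cy = (floor(.data$y_m / cell_m) + 0.5) * cell_m)
  occ <- lapply(seq_len(nrow(centroids)), function(i) {
    cells <- centroids$cells[[i]]
    inside <- paste(pos$cx, pos$cy) %in% paste(cells$x, cells$y)
    pos[inside, ] |>
      count(.data$day, name = "n_positions") |>
      mutate(centroid_id = centroids$centroid_id[i], .before = 1)
  })
  occ <- bind_rows(occ)
  if (nrow(occ) == 0) return(list(occupancy = occ, shifts = tibble()))
  spans <- occ |>
    group_by(.data$centroid_id) |>
    summarise(first_day = min(.data$day), last_day = max(.data$day),
              .groups = "drop") |>
    arrange(.data$first_day)
  shifts <- list()
  for (i in seq_len(nrow(spans))[-1]) {
    if (spans$first_day[i] > max(spans$last_day[seq_len(i - 1)])) {
      shifts[[length(shifts) + 1]] <- tibble(
        centroid_id = spans$centroid_id[i], day = spans$first_day[i])
    }
  }
  list(occupancy = occ, shifts = bind_rows(shifts))
}
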
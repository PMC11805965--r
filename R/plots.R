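#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_step geom_ribbon
#'   geom_line geom_point geom_path coord_equal labs scale_fill_viridis_c
#'   theme_minimal geom_polygon
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot a utilization distribution
#'
#' @param object A `ud_grid`.
#' @param trim Cells below this fraction of the peak density are dropped for
#'   display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ud_grid <- function(object, trim = 1e-4, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$density <- as.vector(object$z)
  df <- df[df$density > trim * max(df$density), ]
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$density)) +
    geom_tile() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(title = paste0("Utilization distribution (", object$scale, ")"),
         x = "Easting (m)", y = "Northing (m)", fill = "Density (m⁻²)") +
    theme_minimal()
}

#' Plot a site-fidelity curve
#'
#' @param object A `fidelity_curve`.
#' @param ... Unused.
#' @return A ggplot of S(t) with its confidence band.
#' @export
autoplot.fidelity_curve <- function(object, ...) {
  cv <- object$curve
  g <- ggplot(cv, aes(x = .data$time, y = .data$estimate))
  g <- if (object$estimator == "product_limit") {
    g + geom_ribbon(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                    alpha = 0.2) + geom_step()
  } else {
    g + geom_ribbon(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                    alpha = 0.2) + geom_line()
  }
  g + labs(x = "Days since tagging", y = "Proportion remaining S(t)",
           title = paste0("Site fidelity (", object$estimator, ")")) +
    theme_minimal()
}

#' Plot fitted dispersal kernels against the empirical survival curve
#'
#' Empirical exceedance uses the Kaplan-Meier estimator on the censored
#' distances so right-censored fish contribute correctly.
#'
#' @param object A `kernel_fits`.
#' @param records The dispersal records the fits were built from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kernel_fits <- function(object, records, ...) {
  km <- survival::survfit(
    survival::Surv(max_distance_m / 1000, !censored) ~ 1,
    data = records)
  emp <- tibble(d = km$time, s = km$surv)
  dd <- seq(min(records$max_distance_m), max(records$max_distance_m),
            length.out = 200)
  fit_df <- bind_rows(lapply(names(object$fits), function(fam) {
    tibble(d = dd / 1000, s = kernel_survival(object, dd, fam), family = fam)
  }))
  ggplot(fit_df, aes(x = .data$d, y = .data$s, color = .data$family)) +
    geom_line() +
    geom_step(data = emp, aes(x = .data$d, y = .data$s),
              inherit.aes = FALSE, linetype = 2) +
    ggplot2::scale_x_log10() +
    labs(x = "Maximum dispersal (km)", y = "P(X ≥ d)",
         title = "Dispersal kernel fits vs empirical survival") +
    theme_minimal()
}

#' Per-fish review plot: COA path and depth strip
#'
#' The diagnostic view used when vetting fate assignments: the horizontal
#' COA track colored by time over the receiver array, with the depth series
#' underneath.
#'
#' @param coas COA tibble for one fish.
#' @param receivers Receiver tibble.
#' @return A list of two ggplots (`path`, `depth`).
#' @export
plot_fate_review <- function(coas, receivers) {
  path <- ggplot(coas, aes(x = .data$x_m, y = .data$y_m,
                           color = as.numeric(.data$bin_start))) +
    geom_point(data = receivers, aes(x = .data$x_m, y = .data$y_m),
               inherit.aes = FALSE, shape = 3, color = "grey50") +
    geom_path() + geom_point(size = 0.8) +
    coord_equal() +
    labs(x = "Easting (m)", y = "Northing (m)", color = "Time") +
    theme_minimal()
  depth <- ggplot(coas, aes(x = .data$bin_start, y = -.data$mean_depth_m)) +
    geom_line() +
    labs(x = NULL, y = "Depth (m)") +
    theme_minimal()
  list(path = path, depth = depth)
}
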
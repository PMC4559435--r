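#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_point
#'   geom_raster labs scale_fill_viridis_c coord_equal facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a summary-function curve
#' @param object an `ryr_curve`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ryr_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$value)) +
    geom_line() +
    labs(x = "r (µm)", y = attr(object, "statistic")) +
    theme_minimal()
}

#' Plot a Monte-Carlo envelope
#' @param object an `ryr_envelope`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ryr_envelope <- function(object, ...) {
  ggplot(object, aes(x = .data$r)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.3) +
    geom_line(aes(y = .data$observed)) +
    labs(x = "r (µm)",
         y = attr(object, "statistic"),
         title = sprintf("%s envelope (%d sims): observed %s",
                         attr(object, "statistic"), attr(object, "n_sims"),
                         attr(object, "verdict"))) +
    theme_minimal()
}

#' Plot all envelopes of a test
#' @param object an `ryr_envelopes`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ryr_envelopes <- function(object, ...) {
  df <- tidy.ryr_envelopes(object)
  ggplot(df, aes(x = .data$r)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.3) +
    geom_line(aes(y = .data$observed)) +
    facet_wrap(~.data$statistic, scales = "free_y") +
    labs(x = "r (µm)", y = "value") +
    theme_minimal()
}

#' Plot a point pattern
#' @param object an `ryr_pattern`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ryr_pattern <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_point(size = 0.8) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}

#' Plot the volume-averaged transient of a simulation
#' @param object an `ryr_sim`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ryr_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace[, c("time", "ca_mean", "f_f0")],
                            -"time")
  ggplot(df, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    facet_wrap(~.data$name, scales = "free_y") +
    labs(x = "time (ms)", y = NULL) +
    theme_minimal()
}

#' Plot a line scan
#' @param object an `ryr_linescan`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.ryr_linescan <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$position,
                     fill = .data$rendered)) +
    geom_raster() +
    scale_fill_viridis_c(name = "F/F0") +
    labs(x = "time (ms)", y = "position (µm)") +
    theme_minimal()
}

#' Plot a template cross-section with an optional pattern overlay
#' @param volume a `label_volume`.
#' @param pattern optional point pattern.
#' @param slice axial slice to draw.
#' @export
plot_template <- function(volume, pattern = NULL, slice = 1) {
  d <- dim(volume$labels)
  h <- volume$voxel_size
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$x <- (df$i - 0.5) * h[1]
  df$y <- (df$j - 0.5) * h[2]
  df$label <- factor(volume$labels[cbind(df$i, df$j, slice)],
                     levels = c(0, 1, 2),
                     labels = c("cytosol", "myofibril", "mitochondria"))
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$label)) +
    geom_raster() +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", fill = NULL) +
    theme_minimal()
  if (!is.null(pattern))
    p <- p + geom_point(data = as.data.frame(pattern),
                        aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, colour = "red", size = 0.8)
  p
}

# --- broom-style accessors -------------------------------------------------

#' Tidy an envelope test into one long tibble
#' @param x an `ryr_envelopes`.
#' @param ... ignored.
#' @exportS3Method generics::tidy
tidy.ryr_envelopes <- function(x, ...) {
  bind_rows(lapply(x, function(e) {
    tibble(statistic = attr(e, "statistic"), r = e$r, lower = e$lower,
           observed = e$observed, upper = e$upper,
           verdict = attr(e, "verdict"))
  }))
}

#' Tidy a reconstruction: the energy trace
#' @param x an `ryr_recon`.
#' @param ... ignored.
#' @exportS3Method generics::tidy
tidy.ryr_recon <- function(x, ...) {
  tibble(accept = seq_along(x$energy_trace) - 1, energy = x$energy_trace)
}

#' One-row summary of a reconstruction
#' @param x an `ryr_recon`.
#' @param ... ignored.
#' @exportS3Method generics::glance
glance.ryr_recon <- function(x, ...) {
  tibble(n_points = nrow(x$pattern), energy = x$energy,
         iterations = x$iterations, accepted = as.integer(x$accepted),
         converged = x$converged, audit_max = x$audit_max,
         mean_nn = mean(nn_distances(x$pattern)),
         sd_nn = sd(nn_distances(x$pattern)))
}

#' One-row summary of a simulation
#' @param x an `ryr_sim`.
#' @param ... ignored.
#' @exportS3Method generics::glance
glance.ryr_sim <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble(t_end = last$time, ca_mean = last$ca_mean,
         f4ca_mean = last$f4ca_mean, f_f0 = last$f_f0,
         mass_rel_err = last$mass_rel_err, n_sites = length(x$sites))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
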
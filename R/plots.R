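#' Plot a circuit trajectory
#'
#' Time series of every species (free-scaled facets) with the stimulation
#' windows shaded, the standard way these simulations are displayed.
#'
#' @param object A `circuit_trajectory`.
#' @param species Optional character vector restricting the facets.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_trajectory <- function(object, species = NULL, ...) {
  sp <- setdiff(names(object), c("time", "input"))
  if (!is.null(species)) sp <- intersect(sp, species)
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[c("time", sp)],
                              -"time", names_to = "species",
                              values_to = "level")
  long$species <- factor(long$species, levels = sp)
  sched <- trajectory_schedule(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$level))
  if (!is.null(sched)) {
    onsets <- pulse_onsets(sched)
    shade <- tibble::tibble(xmin = onsets, xmax = onsets + sched$dur_on)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6)
  }
  p +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (dimensionless)", y = "concentration") +
    ggplot2::theme_minimal()
}

#' Plot a fold-change sweep as a phase-diagram heatmap
#'
#' @param object A `sweep_grid`.
#' @param fill Which column to map to fill (default `"fc"`).
#' @param ... Unused.
#' @return A ggplot object; axes are log-scaled when the sweep used
#'   log-spaced values.
#' @export
autoplot.sweep_grid <- function(object, fill = "fc", ...) {
  axes <- attr(object, "axes", exact = TRUE)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data[[axes[1]]],
                                    y = .data[[axes[2]]],
                                    fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(fill = "log2 FC") +
    ggplot2::theme_minimal()
  for (i in 1:2) {
    vals <- unique(object[[axes[i]]])
    if (length(vals) > 2 && min(vals) > 0) {
      r <- diff(log(sort(vals)))
      if (sd(r) < 1e-8 * mean(r)) {
        p <- p + (if (i == 1) ggplot2::scale_x_log10()
                  else ggplot2::scale_y_log10())
      }
    }
  }
  p
}

#' @rdname autoplot.circuit_trajectory
#' @param traj A `circuit_trajectory`.
#' @export
plot_trajectory <- function(traj, species = NULL) {
  autoplot.circuit_trajectory(traj, species = species)
}

#' @rdname autoplot.sweep_grid
#' @param grid A `sweep_grid`.
#' @export
plot_sweep <- function(grid, fill = "fc") {
  autoplot.sweep_grid(grid, fill = fill)
}

#' One-line trajectory summary
#'
#' @param x A `circuit_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble with the circuit kind, duration, number of
#'   samples and the global output maximum.
#' @export
glance.circuit_trajectory <- function(x, ...) {
  tibble::tibble(
    circuit = trajectory_circuit(x) %||% NA_character_,
    n_samples = nrow(x),
    duration = max(x$time),
    max_output = max(x$G)
  )
}
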
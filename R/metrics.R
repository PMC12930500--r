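#' Per-stimulus output peaks
#'
#' Scores a trajectory once per stimulus interval: peak i is the maximum of
#' the output G over the dense samples in `[start_i, end_i)` (the final
#' interval includes its right endpoint, the horizon). Ties are broken by
#' the earliest time. No sub-sample refinement is applied: the integrator's
#' convergence contract bounds the sampling error, keeping the metric
#' solver-agnostic.
#'
#' @param traj A `circuit_trajectory` (or any tibble with `time` and the
#'   output column).
#' @param partition An `interval_partition`; by default rebuilt from the
#'   trajectory's stored schedule with the trajectory end as horizon.
#' @param output Name of the output column (default `"G"`).
#' @return A `peak_series`: a tibble with columns `interval`, `t_peak`,
#'   `peak`.
#' @examples
#' p <- circuit_params(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1, mu = 1)
#' simulate_protocol("habituation", p, pulse_train(3, 1, 9)) |>
#'   interval_peaks()
#' @export
interval_peaks <- function(traj, partition = NULL, output = "G") {
  stopifnot(is.data.frame(traj), "time" %in% names(traj),
            output %in% names(traj))
  if (is.null(partition)) {
    sched <- trajectory_schedule(traj)
    if (is.null(sched)) {
      stop("no stored schedule on `traj`; supply `partition` explicitly.",
           call. = FALSE)
    }
    partition <- stim_partition(sched, horizon = max(traj$time))
  }
  tmax <- max(traj$time)
  if (tmax < max(partition$end) - 1e-9) {
    stop("trajectory ends before the partition horizon.", call. = FALSE)
  }
  tt <- traj$time
  gg <- traj[[output]]
  last_i <- nrow(partition)
  rows <- purrr::pmap(partition, function(interval, start, end) {
    sel <- if (interval == last_i) tt >= start & tt <= end
           else tt >= start & tt < end
    if (!any(sel)) {
      stop(sprintf(
        "interval %d [%g, %g) contains no samples; use a finer sample_spacing.",
        interval, start, end), call. = FALSE)
    }
    k <- which(sel)[which.max(gg[sel])]
    tibble::tibble(interval = interval, t_peak = tt[k], peak = gg[k])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("peak_series", class(out))
  out
}

peaks_vector <- function(peaks) {
  if (is.data.frame(peaks)) {
    stopifnot("peak" %in% names(peaks))
    peaks$peak
  } else {
    stopifnot(is.numeric(peaks))
    as.numeric(peaks)
  }
}

new_fc_report <- function(..., components) {
  structure(list(..., components = components), class = "fold_change_report")
}

#' Log2 fold change between last and first output peaks
#'
#' The learning-strength statistic for the single-behavior circuits: the
#' log2-transformed ratio of the peak response following the final stimulus
#' to the peak response following the first stimulus. Habituation gives
#' negative values (FC = -1 means the final peak fell to half the first),
#' sensitization positive values.
#'
#' @param peaks A `peak_series` tibble (or a bare numeric vector of peak
#'   values in stimulus order) with at least two peaks; the first peak must
#'   be positive.
#' @return A `fold_change_report` with element `fc`; if the final peak is
#'   exactly zero, `fc` is `-Inf` and the report carries
#'   `degenerate = "zero_final_peak"` (with a warning), never a silent
#'   numeric.
#' @examples
#' fold_change(c(4, 2))      # fc = -1: final peak is half the first
#' fold_change(c(1, 2, 4))   # fc = 2
#' @export
fold_change <- function(peaks) {
  v <- peaks_vector(peaks)
  if (length(v) < 2L) {
    stop("need at least two peaks (one per stimulus).", call. = FALSE)
  }
  first <- v[1L]; last <- v[length(v)]
  if (first <= 0) {
    stop("fold change undefined: first-interval peak is not positive.",
         call. = FALSE)
  }
  degenerate <- NULL
  if (last == 0) {
    warning("final peak is exactly zero; fc = -Inf.", call. = FALSE)
    degenerate <- "zero_final_peak"
  }
  new_fc_report(fc = log2(last / first), degenerate = degenerate,
                components = c(first_peak = first, last_peak = last))
}

#' Sensitization and habituation fold changes of the hybrid circuit
#'
#' The hybrid circuit sensitizes first (peaks grow to an interior maximum)
#' and then habituates (peaks fall). Two fold changes characterize the two
#' phases: `fc_sens = log2(max_peak / first_peak) >= 0` and
#' `fc_hab = log2(last_peak / max_peak) <= 0`. The orientation of each
#' ratio is chosen so magnitudes match the single-behavior metric:
#' sensitization positive, habituation negative.
#'
#' @inheritParams fold_change
#' @return A `fold_change_report` with elements `fc_sens`, `fc_hab` and the
#'   index of the maximal peak.
#' @examples
#' hybrid_fold_changes(c(1, 2, 4, 2))  # fc_sens = 2, fc_hab = -1
#' @export
hybrid_fold_changes <- function(peaks) {
  v <- peaks_vector(peaks)
  if (length(v) < 2L) {
    stop("need at least two peaks (one per stimulus).", call. = FALSE)
  }
  imax <- which.max(v)
  first <- v[1L]; last <- v[length(v)]; top <- v[imax]
  if (first <= 0 || top <= 0) {
    stop("fold change undefined: compared peaks must be positive.",
         call. = FALSE)
  }
  degenerate <- NULL
  if (last == 0) {
    warning("final peak is exactly zero; fc_hab = -Inf.", call. = FALSE)
    degenerate <- "zero_final_peak"
  }
  new_fc_report(fc_sens = log2(top / first), fc_hab = log2(last / top),
                peak_argmax = imax, degenerate = degenerate,
                components = c(first_peak = first, max_peak = top,
                               last_peak = last))
}

#' Spaced-versus-massed fold change
#'
#' Quantifies the massed-spaced learning effect: the log2 ratio of the
#' global output maximum under a spaced protocol to the global output
#' maximum under the massed protocol delivering the same total on-time.
#' Positive values mean spacing enhanced the peak response.
#'
#' @param spaced A `circuit_trajectory` from the spaced protocol.
#' @param massed A `circuit_trajectory` from the massed (single-pulse)
#'   protocol. Both runs must use identical parameters and identical total
#'   on-time.
#' @param output Name of the output column (default `"G"`).
#' @return A `fold_change_report` with element `fc`.
#' @export
msl_fold_change <- function(spaced, massed, output = "G") {
  stopifnot(is.data.frame(spaced), is.data.frame(massed),
            output %in% names(spaced), output %in% names(massed))
  ps <- trajectory_params(spaced); pm <- trajectory_params(massed)
  if (!is.null(ps) && !is.null(pm) && !identical(unclass(ps), unclass(pm))) {
    stop("spaced and massed runs must use identical parameters.",
         call. = FALSE)
  }
  ss <- trajectory_schedule(spaced); sm <- trajectory_schedule(massed)
  if (!is.null(ss) && !is.null(sm)) {
    on_s <- ss$n_pulses * ss$dur_on
    on_m <- sm$n_pulses * sm$dur_on
    if (abs(on_s - on_m) > 1e-9 * max(on_s, on_m)) {
      stop("spaced and massed runs must deliver identical total on-time.",
           call. = FALSE)
    }
  }
  max_s <- max(spaced[[output]])
  max_m <- max(massed[[output]])
  if (max_m <= 0) {
    stop("fold change undefined: massed peak is not positive.",
         call. = FALSE)
  }
  new_fc_report(fc = log2(max_s / max_m), degenerate = NULL,
                components = c(spaced_peak = max_s, massed_peak = max_m))
}

#' @export
print.fold_change_report <- function(x, ...) {
  cat("<fold_change_report>\n")
  for (nm in setdiff(names(x), c("components", "degenerate"))) {
    cat(sprintf("  %s = %s\n", nm, format(x[[nm]], digits = 6)))
  }
  comps <- x$components
  cat("  components:",
      paste(names(comps), signif(comps, 6), sep = " = ", collapse = ", "),
      "\n")
  if (!is.null(x$degenerate)) cat("  degenerate:", x$degenerate, "\n")
  invisible(x)
}

#' Tidy a fold-change report
#'
#' @param x A `fold_change_report`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per fold-change statistic
#'   (columns `metric`, `estimate`). `glance()`: a one-row tibble of all
#'   statistics and compared peak values.
#' @export
tidy.fold_change_report <- function(x, ...) {
  stats <- x[setdiff(names(x), c("components", "degenerate", "peak_argmax"))]
  tibble::tibble(metric = names(stats),
                 estimate = as.numeric(unlist(stats)))
}

#' @rdname tidy.fold_change_report
#' @export
glance.fold_change_report <- function(x, ...) {
  stats <- x[setdiff(names(x), c("components", "degenerate"))]
  out <- tibble::as_tibble(as.list(unlist(stats)))
  comps <- as.list(x$components)
  dplyr::bind_cols(out, tibble::as_tibble(comps))
}

#' Write / read a fold-change report as JSON
#'
#' @param report A `fold_change_report`.
#' @param path File path.
#' @param provenance Optional named list recorded alongside the metrics
#'   (e.g. circuit, parameters, protocol).
#' @return `write_fc_report()` returns `path` invisibly; `read_fc_report()`
#'   returns the parsed list.
#' @export
write_fc_report <- function(report, path, provenance = NULL) {
  stopifnot(inherits(report, "fold_change_report"))
  payload <- list(
    statistics = report[setdiff(names(report),
                                c("components", "degenerate"))],
    components = as.list(report$components),
    degenerate = report$degenerate,
    provenance = provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fc_report
#' @export
read_fc_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
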
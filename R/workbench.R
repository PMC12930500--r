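#' Define a sweep axis
#'
#' @param name Parameter name to vary (one of `alpha`, `beta`, `gamma`,
#'   `lambda`, `mu`, `rho`, `K_out`).
#' @param from,to Range endpoints (`from < to`).
#' @param n Number of grid points (>= 2).
#' @param scale `"log"` (default, natural for rate constants spanning
#'   decades) or `"linear"`.
#' @return A `sweep_axis` object.
#' @export
sweep_axis <- function(name, from, to, n = 41, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  valid <- c("alpha", "beta", "gamma", "lambda", "mu", "rho", "K_out")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop("axis `name` must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.numeric(from), is.numeric(to), from < to, n >= 2,
            n == round(n))
  if (scale == "log" && from <= 0) {
    stop("log-scaled axes need `from` > 0.", call. = FALSE)
  }
  values <- if (scale == "log") exp(seq(log(from), log(to), length.out = n))
            else seq(from, to, length.out = n)
  structure(list(name = name, values = values, scale = scale),
            class = "sweep_axis")
}

#' Two-parameter fold-change sweep (phase diagram)
#'
#' Maps learning strength over a 2-D parameter grid: each cell overrides
#' the two axis parameters in `params`, simulates the circuit from rest
#' over `schedule`, and scores the run with the requested fold-change
#' metric. Cells where the metric is undefined (zero first peak) are
#' flagged, not silently dropped: `fc` (and `fc_hab` for the hybrid
#' metric) is `NA` and `note` records the reason.
#'
#' The whole computation is deterministic; there is no seed to set
#' anywhere in this package.
#'
#' @param circuit Circuit kind.
#' @param params Baseline `circuit_params`; axis parameters override their
#'   entries cell by cell.
#' @param schedule Stimulation protocol applied in every cell.
#' @param axis1,axis2 Two distinct [sweep_axis()] objects.
#' @param metric `"fold_change"` (last vs first peak) or `"hybrid"`
#'   (sensitization and habituation fold changes vs the highest peak).
#' @param grid Optional [simulation_grid()] shared by all cells.
#' @return A `sweep_grid`: a long-format tibble with the two axis columns,
#'   `fc` (plus `fc_hab` when `metric = "hybrid"`, in which case `fc`
#'   holds `fc_sens`), and `note`.
#' @examples
#' \donttest{
#' p <- circuit_params(alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1, mu = 1)
#' sweep_fc("habituation", p, pulse_train(5, 1, 9),
#'          sweep_axis("alpha", 0.5, 4, n = 3),
#'          sweep_axis("gamma", 0.005, 0.05, n = 3))
#' }
#' @export
sweep_fc <- function(circuit, params, schedule, axis1, axis2,
                     metric = c("fold_change", "hybrid"), grid = NULL) {
  metric <- match.arg(metric)
  circuit <- check_circuit(circuit)
  stopifnot(inherits(axis1, "sweep_axis"), inherits(axis2, "sweep_axis"))
  if (identical(axis1$name, axis2$name)) {
    stop("the two sweep axes must vary distinct parameters.", call. = FALSE)
  }
  cells <- tidyr::expand_grid(a1 = axis1$values, a2 = axis2$values)
  score <- function(a1, a2) {
    p <- params
    p[[axis1$name]] <- a1
    p[[axis2$name]] <- a2
    traj <- integrate_circuit(circuit, p, schedule, grid = grid)
    peaks <- interval_peaks(traj)
    if (peaks$peak[1L] <= 0) {
      return(tibble::tibble(fc = NA_real_,
                            fc_hab = NA_real_,
                            note = "undefined: zero first peak"))
    }
    if (metric == "hybrid") {
      r <- hybrid_fold_changes(peaks)
      tibble::tibble(fc = r$fc_sens, fc_hab = r$fc_hab, note = NA_character_)
    } else {
      r <- suppressWarnings(fold_change(peaks))
      tibble::tibble(fc = r$fc, fc_hab = NA_real_, note = NA_character_)
    }
  }
  scored <- purrr::pmap(cells, function(a1, a2) score(a1, a2))
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(scored))
  names(out)[1:2] <- c(axis1$name, axis2$name)
  if (metric != "hybrid") out$fc_hab <- NULL
  new_sweep_grid(out, circuit = circuit, metric = metric,
                 axes = c(axis1$name, axis2$name),
                 params = params, schedule = as_pulse_train(schedule))
}

new_sweep_grid <- function(tbl, circuit, metric, axes, params, schedule) {
  structure(tbl,
            class = c("sweep_grid", class(tibble::tibble())),
            circuit = circuit, metric = metric, axes = axes,
            params = params, schedule = schedule)
}

#' Massed-spaced fold-change sweep
#'
#' Maps the spacing effect over pulse count and inter-pulse delay: a fixed
#' total on-time is split into `n` pulses separated by `gap`, the full
#' circuit is simulated, and each cell stores the spaced-versus-massed
#' fold change against the shared massed reference (simulated once). The
#' massed column (`n = 1`) is identically zero by construction.
#'
#' @param params A `circuit_params` for the massed-spaced circuit.
#' @param total_on_time Total stimulus duration shared by all cells.
#' @param n_values Integer vector of pulse counts (>= 1).
#' @param gap_values Numeric vector of inter-pulse delays (>= 0).
#' @param amplitude Input amplitude.
#' @param grid Optional [simulation_grid()].
#' @return A `sweep_grid` tibble with columns `n_pulses`, `gap`, `fc`,
#'   `note`.
#' @export
sweep_msl <- function(params, total_on_time = 10, n_values = 1:10,
                      gap_values = seq(0, 200, length.out = 41),
                      amplitude = 1, grid = NULL) {
  stopifnot(all(n_values >= 1), all(n_values == round(n_values)),
            all(gap_values >= 0))
  massed <- integrate_circuit(
    "msl", params, massed_spaced(total_on_time, 1, 0, amplitude),
    grid = grid)
  massed_max <- max(massed$G)
  cells <- tidyr::expand_grid(n_pulses = as.integer(n_values),
                              gap = gap_values)
  fc_cell <- function(n_pulses, gap) {
    if (n_pulses == 1L) return(0)  # massed reference; gap has no effect
    traj <- integrate_circuit(
      "msl", params, massed_spaced(total_on_time, n_pulses, gap, amplitude),
      grid = grid)
    log2(max(traj$G) / massed_max)
  }
  fc <- purrr::pmap_dbl(cells, fc_cell)
  out <- dplyr::bind_cols(cells, tibble::tibble(fc = fc))
  out$note <- ifelse(massed_max > 0, NA_character_,
                     "undefined: zero massed peak")
  if (massed_max <= 0) out$fc <- NA_real_
  new_sweep_grid(out, circuit = "msl", metric = "msl_fc",
                 axes = c("n_pulses", "gap"), params = params,
                 schedule = NULL)
}

#' Threshold mask of a sweep grid
#'
#' Flags the cells whose fold change is beyond a given level, in the
#' direction implied by the sweep's metric: at or below the level for
#' habituation maps (`fc` is negative where learning is strong), at or
#' above it for sensitization and massed-spaced maps. A typical use is the
#' `fc = -1` contour delimiting where the final peak has fallen to at most
#' half the first.
#'
#' @param grid A `sweep_grid`.
#' @param level Finite fold-change level.
#' @param direction `"auto"` (from the sweep metadata), `"le"` or `"ge"`.
#' @return The grid tibble with an added logical column `beyond` (`NA`
#'   where `fc` is undefined).
#' @export
threshold_mask <- function(grid, level, direction = c("auto", "le", "ge")) {
  direction <- match.arg(direction)
  stopifnot(inherits(grid, "sweep_grid"), is.finite(level))
  if (direction == "auto") {
    metric <- attr(grid, "metric", exact = TRUE)
    circuit <- attr(grid, "circuit", exact = TRUE)
    direction <- if (identical(metric, "msl_fc")) "ge"
                 else if (identical(circuit, "habituation")) "le"
                 else "ge"
  }
  grid$beyond <- if (direction == "le") grid$fc <= level else grid$fc >= level
  grid
}

#' Canonical demonstration configurations
#'
#' Ready-made circuit + parameter + protocol bundles exhibiting each
#' learning behavior at its reference operating point:
#'
#' * `habituation_default` — incoherent feed-forward loop with
#'   `alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1, mu = 1`, stimulated
#'   by pulses of width 1 at period 10.
#' * `sensitization_default` — adds `rho = 1.75` on the double-repression
#'   cascade, same protocol.
#' * `hybrid_default` — hybrid circuit with `beta = 10` and output
#'   repressor half-activation `K_out = 1.5`, same protocol.
#' * `msl_spaced` / `msl_massed` — massed-spaced circuit with
#'   `alpha = 1, beta = 1, gamma = 0.01, mu = 1`; total on-time 10 either
#'   split into 5 pulses with gap 50 or delivered as one block.
#'
#' The pulse-train configurations use input amplitude 1 and 10 pulses
#' (20 for the hybrid, whose sensitization-to-habituation turnover at the
#' reference parameters occurs around pulse 13, so a longer train is
#' needed to display both phases). Pulse count and amplitude are package
#' conventions, not constants of the circuit models.
#'
#' @param name One of `"habituation_default"`, `"sensitization_default"`,
#'   `"hybrid_default"`, `"msl_spaced"`, `"msl_massed"`.
#' @param n_pulses Number of pulses for the pulse-train configurations
#'   (default 10, or 20 for the hybrid; ignored by the massed-spaced
#'   ones).
#' @return A list with elements `circuit`, `params`, `schedule`.
#' @examples
#' fx <- make_fixture("habituation_default")
#' fx$params
#' @export
make_fixture <- function(name, n_pulses = NULL) {
  fixtures <- c("habituation_default", "sensitization_default",
                "hybrid_default", "msl_spaced", "msl_massed")
  if (!is.character(name) || length(name) != 1L || !name %in% fixtures) {
    stop("unknown fixture; available: ", paste(fixtures, collapse = ", "),
         call. = FALSE)
  }
  n_pulses <- n_pulses %||% if (name == "hybrid_default") 20 else 10
  switch(name,
    habituation_default = list(
      circuit = "habituation",
      params = circuit_params(alpha = 1.5, beta = 5, gamma = 0.01,
                              lambda = 1, mu = 1),
      schedule = pulse_train(n_pulses, dur_on = 1, dur_off = 9)),
    sensitization_default = list(
      circuit = "sensitization",
      params = circuit_params(alpha = 1.5, beta = 5, gamma = 0.01,
                              lambda = 1, mu = 1, rho = 1.75),
      schedule = pulse_train(n_pulses, dur_on = 1, dur_off = 9)),
    hybrid_default = list(
      circuit = "hybrid",
      params = circuit_params(alpha = 1.5, beta = 10, gamma = 0.01,
                              lambda = 1, mu = 1, rho = 1.75, K_out = 1.5),
      schedule = pulse_train(n_pulses, dur_on = 1, dur_off = 9)),

    msl_spaced = list(
      circuit = "msl",
      params = circuit_params(alpha = 1, beta = 1, gamma = 0.01, mu = 1),
      schedule = massed_spaced(total_on_time = 10, n_pulses = 5, gap = 50)),
    msl_massed = list(
      circuit = "msl",
      params = circuit_params(alpha = 1, beta = 1, gamma = 0.01, mu = 1),
      schedule = massed_spaced(total_on_time = 10, n_pulses = 1, gap = 0)))
}

#' Run a demonstration configuration
#'
#' @param name Fixture name, see [make_fixture()].
#' @param ... Passed on to [integrate_circuit()].
#' @return A `circuit_trajectory`.
#' @export
run_fixture <- function(name, ...) {
  fx <- make_fixture(name)
  integrate_circuit(fx$circuit, fx$params, fx$schedule, ...)
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV holds the dense samples (`time,input,<species...>`, doubles
#' written so that they parse back bit-identically); the JSON sidecar holds
#' the circuit kind, parameters, schedule and grid, so the pair
#' round-trips into an equivalent `circuit_trajectory`.
#'
#' @param traj A `circuit_trajectory`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return `write_trajectory()` returns `prefix` invisibly;
#'   `read_trajectory()` returns the reconstructed `circuit_trajectory`.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  readr::write_csv(format_doubles(tibble::as_tibble(traj)),
                   paste0(prefix, ".csv"), na = "")
  sched <- trajectory_schedule(traj)
  meta <- list(
    circuit = trajectory_circuit(traj),
    params = Filter(Negate(is.null), unclass(trajectory_params(traj))),
    schedule = unclass(sched),
    grid = attr(traj, "grid", exact = TRUE),
    tool = paste0("circlearn ", as.character(utils::packageVersion("circlearn")))
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(prefix) {
  # base read.csv parses doubles with strtod, bit-exactly
  tbl <- tibble::as_tibble(utils::read.csv(paste0(prefix, ".csv"),
                                           na.strings = ""))
  # whole-valued columns (e.g. a constant input) come back integer
  tbl[] <- lapply(tbl, function(v) if (is.integer(v)) as.double(v) else v)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  params <- do.call(circuit_params, as.list(meta$params))
  sched <- do.call(pulse_train, as.list(meta$schedule))
  new_trajectory(tbl, circuit = meta$circuit, params = params,
                 schedule = sched, grid = meta$grid)
}

#' Write / read a sweep grid as CSV with JSON metadata
#'
#' The CSV is the long-format grid (axis columns plus `fc` fields);
#' undefined cells stay as empty fields with their reason in `note`. The
#' JSON sidecar carries circuit, metric, baseline parameters and protocol.
#'
#' @param grid A `sweep_grid`.
#' @param prefix Output path prefix.
#' @return `write_sweep()` returns `prefix` invisibly; `read_sweep()` the
#'   reconstructed `sweep_grid`.
#' @export
write_sweep <- function(grid, prefix) {
  stopifnot(inherits(grid, "sweep_grid"))
  readr::write_csv(format_doubles(tibble::as_tibble(grid)),
                   paste0(prefix, ".csv"), na = "")
  sched <- attr(grid, "schedule", exact = TRUE)
  meta <- list(
    circuit = attr(grid, "circuit", exact = TRUE),
    metric = attr(grid, "metric", exact = TRUE),
    axes = attr(grid, "axes", exact = TRUE),
    params = Filter(Negate(is.null),
                    unclass(attr(grid, "params", exact = TRUE))),
    schedule = if (!is.null(sched)) unclass(sched),
    tool = paste0("circlearn ", as.character(utils::packageVersion("circlearn")))
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

# Render double columns with 17 significant digits so the CSV text parses
# back to bit-identical values.
format_doubles <- function(tbl) {
  for (nm in names(tbl)) {
    if (is.double(tbl[[nm]])) {
      v <- tbl[[nm]]
      tbl[[nm]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    }
  }
  tbl
}

#' @rdname write_sweep
#' @export
read_sweep <- function(prefix) {
  tbl <- tibble::as_tibble(utils::read.csv(paste0(prefix, ".csv"),
                                           na.strings = ""))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  params <- do.call(circuit_params, as.list(meta$params))
  sched <- if (!is.null(meta$schedule)) do.call(pulse_train,
                                                as.list(meta$schedule))
  new_sweep_grid(tbl, circuit = meta$circuit, metric = meta$metric,
                 axes = meta$axes, params = params, schedule = sched)
}
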
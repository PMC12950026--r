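#' Steady-state and peak rates for the two ramp-and-hold batteries
#'
#' Runs the ten reference ramp trials (five ramp velocities to a 37-degree
#' hold, then five hold angles at 240.4 deg/s) through the afferent model and
#' extracts, per trial, the peak instantaneous rate (reciprocal of the minimum
#' inter-spike interval) and the steady-state rate (mean rate over the
#' trailing `ss_window` ms of the hold).
#'
#' @param adex [adex_params()].
#' @param gain Mechanotransduction gain (pA/deg).
#' @param dt Time step (ms).
#' @param hold_ms Hold duration (ms).
#' @param ss_window Trailing window of the hold used for the steady state (ms).
#' @return A tibble with columns `trial` (1-10), `battery`
#'   (`"velocity"`/`"hold_angle"`), `ramp_velocity`, `hold_angle`, `ss` and
#'   `peak` (Hz).
#' @export
ramp_battery_rates <- function(adex = adex_params(), gain = 50, dt = 0.25,
                               hold_ms = 500, ss_window = 100) {
  protos <- dplyr::bind_rows(
    tibble::tibble(battery = "velocity", ramp_velocity = velocity_battery(),
                   hold_angle = 37),
    tibble::tibble(battery = "hold_angle", ramp_velocity = 240.4,
                   hold_angle = hold_angle_battery())
  )
  protos$trial <- seq_len(nrow(protos))
  run_one <- function(v, ha) {
    trace <- ramp_and_hold(v, ha, hold_ms = hold_ms, dt = dt)
    spikes <- integrate_adex(hair_currents(trace, gain), adex, dt = dt)
    p <- attr(trace, "protocol")
    hold_end <- p$pre_ms + p$ramp_ms + p$hold_ms
    ss_times <- spikes$time[spikes$time > hold_end - ss_window &
                              spikes$time <= hold_end]
    ss <- if (length(ss_times) >= 2) 1000 / mean(diff(ss_times)) else 0
    tibble::tibble(ss = ss, peak = peak_rate(spikes))
  }
  rates <- purrr::map2(protos$ramp_velocity, protos$hold_angle, run_one)
  dplyr::bind_cols(protos, dplyr::bind_rows(rates)) |>
    dplyr::select("trial", "battery", "ramp_velocity", "hold_angle",
                  "ss", "peak")
}

#' Reference ramp-response table for afferent calibration
#'
#' Loads the packaged stand-in for the cockroach scapal hair-plate
#' ramp-response rates. The table is synthetic: it was constructed to match
#' the published envelope of the electrophysiological recordings (peak rates
#' 118-166 Hz across the velocity battery, peaks about 150% of steady state,
#' no tonic response at the smallest hold angle), because the original figure
#' data are not redistributable. MAE values against it calibrate the grid
#' search mechanics but are not a quantitative fit to the physiology; supply
#' your own digitised table for that.
#'
#' @return A tibble with columns `trial`, `ss` and `peak`.
#' @export
reference_rates_synthetic <- function() {
  path <- system.file("extdata", "okada_toh_reference_synthetic.csv",
                      package = "hairplate")
  tibble::as_tibble(read.csv(path))
}

new_grid_search <- function(grid, value_col, params) {
  best <- min(grid[[value_col]])
  argmin <- grid[grid[[value_col]] <= best + 1e-12, , drop = FALSE]
  structure(list(grid = grid, value = value_col, argmin = argmin,
                 params = params),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> %d cells over (%s), min %s = %.4g at %d cell(s)\n",
              nrow(x$grid), paste(x$params, collapse = ", "), x$value,
              min(x$grid[[x$value]]), nrow(x$argmin)))
  invisible(x)
}

#' @export
tidy.grid_search <- function(x, ...) x$grid

#' @export
glance.grid_search <- function(x, ...) {
  dplyr::mutate(x$argmin[1, , drop = FALSE], n_ties = nrow(x$argmin))
}

#' Pick one cell from the argmin set of a grid search
#'
#' Ties are reported in full by the search itself; this selects one cell,
#' either the lexicographically smallest (deterministic default) or a seeded
#' random choice.
#'
#' @param x A `grid_search`.
#' @param method `"lexicographic"` or `"random"`.
#' @param seed Seed for the random choice.
#' @return A one-row tibble.
#' @export
select_argmin <- function(x, method = c("lexicographic", "random"),
                          seed = NULL) {
  method <- match.arg(method)
  am <- dplyr::arrange(x$argmin,
                       dplyr::across(dplyr::all_of(x$params)))
  if (method == "lexicographic") return(am[1, , drop = FALSE])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  am[sample.int(nrow(am), 1), , drop = FALSE]
}

#' Grid search over afferent gain and adaptation increment
#'
#' Sweeps the mechanotransduction gain and the spike-triggered adaptation
#' increment `b` over a grid, scoring each cell by the mean absolute error
#' ([mae_fit()]) between the model's ramp-battery response rates and a
#' reference table.
#'
#' @param reference Tibble with columns `trial`, `ss`, `peak` for the ten
#'   ramp trials (e.g. [reference_rates_synthetic()] or a model-generated
#'   table).
#' @param gains Gain values (pA/deg).
#' @param bs Adaptation increments (pA).
#' @param adex Template [adex_params()]; `b` is overridden per cell.
#' @param dt Time step (ms).
#' @return A `grid_search` whose grid has columns `gain`, `b` and `mae`.
#' @export
grid_search_adex <- function(reference,
                             gains = seq(10, 150, length.out = 8),
                             bs = seq(50, 350, length.out = 8),
                             adex = adex_params(), dt = 0.25) {
  cells <- tidyr::expand_grid(gain = gains, b = bs)
  cells$mae <- purrr::map2_dbl(cells$gain, cells$b, function(g, b) {
    pars <- adex_params(C = adex$C, g_L = adex$g_L, E_L = adex$E_L,
                        delta_T = adex$delta_T, V_T = adex$V_T, a = adex$a,
                        tau_w = adex$tau_w, b = b)
    model <- ramp_battery_rates(pars, gain = g, dt = dt)
    mae_fit(model, reference)
  })
  new_grid_search(cells, "mae", c("gain", "b"))
}

#' Grid search over position-interneuron time constant and synaptic weight
#'
#' For each (tau, omega) cell, decodes every supplied trace with position
#' interneurons using those parameters and scores the z-normalised combined
#' signal against the z-normalised joint angle ([position_error()]); cells are
#' ranked by the MSE averaged over traces. The sensory layer is simulated once
#' per trace and reused across cells.
#'
#' @param traces A list of [joint_trace()]s, or a tibble with a `trace` list
#'   column.
#' @param taus Membrane time constants (ms).
#' @param omegas Synaptic weights (mV).
#' @param cfg Template [joint_config()]; `NULL` builds a default
#'   (non-extended) configuration per trace from its observed range.
#' @param rate_method,width Passed to [spike_rate()].
#' @return A `grid_search` whose grid has columns `tau`, `omega` and `mse`.
#' @export
grid_search_position <- function(traces, taus = c(30, 60, 120, 240),
                                 omegas = c(1, 2, 5, 10), cfg = NULL,
                                 rate_method = "isi", width = 50) {
  if (is.data.frame(traces)) traces <- traces$trace
  stopifnot(length(traces) >= 1)
  prep <- purrr::map(traces, function(tr) {
    c0 <- cfg %||% default_joint_config(range(tr$theta), extended = FALSE)
    tr <- resample_trace(tr, c0$dt)
    list(cfg = c0, trace = tr, sensory = run_sensory_layer(tr, c0))
  })
  cells <- tidyr::expand_grid(tau = taus, omega = omegas)
  cells$mse <- purrr::map2_dbl(cells$tau, cells$omega, function(tau, om) {
    errs <- purrr::map_dbl(prep, function(p) {
      cfg_cell <- p$cfg
      cfg_cell$pos_lif <- lif_params(tau = tau, omega = om)
      pos <- run_position_ins(p$sensory, cfg_cell)
      enc <- structure(list(trace = p$trace, cfg = cfg_cell,
                            pos_plus = pos$pos_plus,
                            pos_minus = pos$pos_minus),
                       class = "joint_encoding")
      position_error(enc, rate_method = rate_method, width = width)$mse
    })
    mean(errs)
  })
  new_grid_search(cells, "mse", c("tau", "omega"))
}

#' Mean velocity-interneuron rate as a function of sweep speed
#'
#' Encodes constant-velocity triangular sweeps with the extended plate and
#' velocity chain and measures, per speed, the combined mean output rate of
#' the two velocity interneurons (spikes per second over the sweep; exactly
#' one of the two is driven at any moment).
#'
#' @param speeds Sweep speeds (deg/s).
#' @param range Working range (deg).
#' @param cfg A [joint_config()] with an extended plate; default builds the
#'   standard 50-hairs-per-field encoder over `range`.
#' @param reps Full triangle cycles per speed.
#' @return A tibble with columns `speed` and `rate` (Hz), ready for
#'   [fit_rate_velocity()].
#' @export
velocity_rate_curve <- function(speeds = c(25, 50, 100, 150, 200, 300, 400),
                                range = c(0, 180), cfg = NULL, reps = 1) {
  cfg <- cfg %||% default_joint_config(range)
  sweeps <- constant_velocity_sweep(speeds, range = range, reps = reps,
                                    dt = cfg$dt)
  rate <- purrr::map_dbl(sweeps$trace, function(tr) {
    enc <- encode_joint(tr, cfg, velocity = TRUE)
    dur_s <- (tr$t[nrow(tr)] - tr$t[1]) / 1000
    (nrow(enc$vel_plus) + nrow(enc$vel_minus)) / dur_s
  })
  tibble::tibble(speed = sweeps$speed, rate = rate)
}
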
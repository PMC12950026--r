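#' Construct a spike train
#'
#' A spike train is a tibble with columns `neuron_id` and `time` (ms), carrying
#' the simulation `duration` (ms) as an attribute. Times must be strictly
#' increasing within a neuron and lie in `[0, duration]`.
#'
#' @param times Spike times (ms).
#' @param neuron_id Neuron label (recycled).
#' @param duration Simulation length (ms).
#' @return A `spike_train` tibble.
#' @export
spike_train <- function(times = numeric(), neuron_id = "n1", duration = NA_real_) {
  times <- as.numeric(times)
  out <- tibble::tibble(neuron_id = rep_len(as.character(neuron_id), length(times)),
                        time = times)
  out <- dplyr::arrange(out, .data$neuron_id, .data$time)
  bad <- dplyr::group_by(out, .data$neuron_id) |>
    dplyr::summarise(ok = all(diff(.data$time) > 0), .groups = "drop")
  if (!all(bad$ok)) stop("spike times must be strictly increasing per neuron")
  if (!is.na(duration) && length(times) &&
      (min(times) < 0 || max(times) > duration)) {
    stop("spike times must lie within [0, duration]")
  }
  attr(out, "duration") <- duration
  class(out) <- c("spike_train", class(out))
  out
}

#' @export
#' @rdname spike_train
#' @param x A `spike_train`.
train_duration <- function(x) attr(x, "duration")

check_uniform_grid <- function(t, dt = NULL) {
  if (length(t) < 2) stop("time grid needs at least two samples")
  steps <- diff(t)
  if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-8 * max(steps[1], 1)) {
    stop("time grid must be uniform and strictly increasing")
  }
  if (!is.null(dt) && abs(steps[1] - dt) > 1e-8) {
    stop(sprintf("time grid step (%g ms) does not match dt = %g ms", steps[1], dt))
  }
  steps[1]
}

#' Integrate the AdEx afferent model over an input current trace
#'
#' Solves the two AdEx equations with a fixed-step backward-difference scheme:
#' the linear leak and adaptation terms are treated implicitly and the
#' exponential spike-initiation term is evaluated at the previous step's
#' voltage, with its argument clamped at `exp_cap` to avoid overflow (the
#' clamp only shapes the supra-threshold overshoot, not spike timing at the
#' default step). A spike is recorded whenever the updated voltage exceeds
#' `V_T`; the voltage then resets to `E_L` and the adaptation current jumps by
#' `b`, producing the phasic-tonic (spike-rate-adapting) response.
#'
#' @param current A data frame with columns `t` (ms, uniform grid) and `I`
#'   (pA), or a numeric current vector combined with `dt`.
#' @param params [adex_params()].
#' @param dt Time step (ms); required when `current` is a bare vector,
#'   otherwise checked against the grid.
#' @param record_state Record the voltage and adaptation trajectories?
#' @param exp_cap Clamp on the exponential argument `(V - V_T)/delta_T`.
#' @param v_ceiling Diagnostic ceiling (mV); integration aborts if the
#'   membrane potential exceeds it despite the clamp.
#' @param neuron_id Label for the returned spike train.
#' @return A [spike_train()]; when `record_state = TRUE` it carries a `state`
#'   attribute, a tibble with columns `t`, `V` (mV) and `w` (pA).
#' @examples
#' trace <- ramp_and_hold(ramp_velocity = 980, hold_angle = 37)
#' spikes <- integrate_adex(hair_currents(trace, gain = 50))
#' nrow(spikes)
#' @export
integrate_adex <- function(current, params = adex_params(), dt = NULL,
                           record_state = FALSE, exp_cap = 20,
                           v_ceiling = 200, neuron_id = "adex") {
  stopifnot(inherits(params, "adex_params"))
  if (is.data.frame(current)) {
    if (!all(c("t", "I") %in% names(current))) {
      stop("`current` data frame needs columns `t` and `I`")
    }
    step <- check_uniform_grid(current$t, dt)
    I <- current$I
    t0 <- current$t[1]
  } else {
    if (is.null(dt)) stop("`dt` is required when `current` is a bare vector")
    step <- dt
    I <- as.numeric(current)
    t0 <- 0
  }
  if (step <= 0) stop("`dt` must be positive")
  res <- cpp_adex(I, step, params$C, params$g_L, params$E_L, params$delta_T,
                  params$V_T, params$a, params$tau_w, params$b,
                  exp_cap, v_ceiling, record_state)
  duration <- t0 + (length(I) - 1) * step
  out <- spike_train(t0 + (res$spike_steps - 1) * step, neuron_id, duration)
  attr(out, "dt") <- step
  if (record_state) {
    attr(out, "state") <- tibble::tibble(
      t = t0 + (seq_along(I) - 1) * step, V = res$V, w = res$w)
  }
  out
}

#' Integrate a LIF interneuron over weighted presynaptic spike events
#'
#' Between events the membrane potential decays toward `E_L` with time
#' constant `tau` (backward-difference update); each presynaptic event adds
#' its weight (mV), events falling in the same step summing; whenever the
#' potential exceeds `V_T` an output spike is recorded and the potential
#' resets to `E_L`.
#'
#' @param events A data frame with columns `time` (ms) and `weight` (mV), or a
#'   numeric vector of event times (each weighted by `params$omega`).
#' @param params [lif_params()].
#' @param dt Time step (ms).
#' @param duration Simulation length (ms).
#' @param record_state Record the voltage trajectory?
#' @param neuron_id Label for the returned spike train.
#' @return A [spike_train()].
#' @examples
#' # a single strong input spike fires the neuron immediately
#' integrate_lif(data.frame(time = 10, weight = 25),
#'               lif_params(tau = 5, omega = 25), duration = 50)
#' @export
integrate_lif <- function(events, params, dt = 0.25, duration,
                          record_state = FALSE, neuron_id = "lif") {
  stopifnot(inherits(params, "lif_params"))
  if (dt <= 0) stop("`dt` must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  if (is.data.frame(events)) {
    if (!all(c("time", "weight") %in% names(events))) {
      stop("`events` data frame needs columns `time` and `weight`")
    }
    times <- events$time
    weights <- events$weight
  } else {
    times <- as.numeric(events)
    weights <- rep(params$omega, length(times))
  }
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    stop("event times must lie within [0, duration]")
  }
  n <- floor(duration / dt) + 1L
  w_in <- numeric(n)
  if (length(times)) {
    idx <- pmin(pmax(round(times / dt) + 1L, 1L), n)
    for (j in seq_along(idx)) w_in[idx[j]] <- w_in[idx[j]] + weights[j]
  }
  res <- cpp_lif(w_in, dt, params$E_L, params$V_T, params$tau, record_state)
  out <- spike_train((res$spike_steps - 1) * dt, neuron_id, duration)
  attr(out, "dt") <- dt
  if (record_state) {
    attr(out, "state") <- tibble::tibble(t = (seq_len(n) - 1) * dt, V = res$V)
  }
  out
}

#' Equilibrium firing rate of the AdEx afferent under constant current
#'
#' Under sustained input the spike-triggered adaptation lengthens successive
#' inter-spike intervals until they settle at an equilibrium; this returns the
#' reciprocal of that equilibrium interval, i.e. the tonic plateau rate
#' `f_ss`. For a fully deflected hair, `I_const = 90 * gain`.
#'
#' @param params [adex_params()].
#' @param I_const Constant input current (pA).
#' @param dt Time step (ms).
#' @param settle_time Portion (ms) discarded before measuring; must allow the
#'   adaptation to equilibrate (>= 10 * tau_w recommended).
#' @param sim_time Total simulated time (ms).
#' @return Rate in Hz (0 if no spikes occur after settling).
#' @examples
#' steady_state_rate(adex_params(), I_const = 4500)
#' @export
steady_state_rate <- function(params = adex_params(), I_const, dt = 0.25,
                              settle_time = 10 * params$tau_w,
                              sim_time = settle_time + 500) {
  stopifnot(sim_time > settle_time)
  n <- floor(sim_time / dt) + 1L
  spikes <- integrate_adex(rep(I_const, n), params, dt = dt)
  late <- spikes$time[spikes$time > settle_time]
  if (length(late) < 2) return(0)
  1000 / mean(diff(late))
}
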
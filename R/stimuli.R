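#' Construct a joint-angle trace
#'
#' A joint-angle trace is a tibble with columns `t` (ms, uniform grid) and
#' `theta` (deg), with `joint`, `leg` and `source` labels kept as attributes.
#'
#' @param t Time grid (ms, uniform, strictly increasing).
#' @param theta Joint angles (deg), same length as `t`.
#' @param joint One of `"alpha"`, `"beta"`, `"gamma"` (or `NA`).
#' @param leg One of `"R1"`, `"R2"`, `"R3"`, `"L1"`, `"L2"`, `"L3"` (or `NA`).
#' @param source One of `"experimental"`, `"synthetic"`, `"protocol"`.
#' @return A `joint_trace` tibble.
#' @export
joint_trace <- function(t, theta, joint = NA_character_, leg = NA_character_,
                        source = c("protocol", "synthetic", "experimental")) {
  source <- match.arg(source)
  if (length(t) != length(theta)) stop("`t` and `theta` lengths differ")
  check_uniform_grid(t)
  if (any(!is.finite(theta))) stop("`theta` must be finite")
  if (!is.na(joint) && !joint %in% c("alpha", "beta", "gamma")) {
    stop("`joint` must be one of alpha, beta, gamma")
  }
  if (!is.na(leg) && !leg %in% c("R1", "R2", "R3", "L1", "L2", "L3")) {
    stop("`leg` must be one of R1..L3")
  }
  out <- tibble::tibble(t = as.numeric(t), theta = as.numeric(theta))
  attr(out, "joint") <- joint
  attr(out, "leg") <- leg
  attr(out, "source") <- source
  class(out) <- c("joint_trace", class(out))
  out
}

trace_dt <- function(trace) diff(trace$t[1:2])

#' Ramp-and-hold deflection protocol
#'
#' Linear ramp from `start_angle` to `hold_angle` at `ramp_velocity`, a hold,
#' and a down-ramp at the same speed, padded by pre/post rest periods. Used
#' to probe the phasic-tonic afferent response; the classic batteries are
#' five ramp velocities (980, 604, 352, 188, 96 deg/s) to a 37-degree hold,
#' and five hold angles (60, 46, 34, 23, 15 deg) at 240.4 deg/s.
#'
#' @param ramp_velocity Ramp speed (deg/s), positive. `Inf` gives a one-step
#'   jump.
#' @param hold_angle Plateau angle (deg).
#' @param start_angle Baseline angle (deg).
#' @param hold_ms Hold duration (ms).
#' @param pre_ms,post_ms Rest padding before and after (ms).
#' @param dt Time step (ms).
#' @return A [joint_trace()] with `source = "protocol"`; `theta` is the hair
#'   deflection (or joint angle) in degrees.
#' @examples
#' ramp_and_hold(980, 37)
#' @export
ramp_and_hold <- function(ramp_velocity, hold_angle, start_angle = 0,
                          hold_ms = 500, pre_ms = 50, post_ms = 100,
                          dt = 0.25) {
  if (ramp_velocity <= 0) stop("`ramp_velocity` must be positive")
  ramp_ms <- if (is.infinite(ramp_velocity)) dt
             else abs(hold_angle - start_angle) / ramp_velocity * 1000
  total <- pre_ms + ramp_ms + hold_ms + ramp_ms + post_ms
  t <- seq(0, total, by = dt)
  up0 <- pre_ms; up1 <- pre_ms + ramp_ms
  dn0 <- up1 + hold_ms; dn1 <- dn0 + ramp_ms
  theta <- dplyr::case_when(
    t < up0 ~ start_angle,
    t < up1 ~ start_angle + (t - up0) / ramp_ms * (hold_angle - start_angle),
    t < dn0 ~ hold_angle,
    t < dn1 ~ hold_angle - (t - dn0) / ramp_ms * (hold_angle - start_angle),
    TRUE ~ start_angle
  )
  out <- joint_trace(t, theta, source = "protocol")
  attr(out, "protocol") <- list(ramp_velocity = ramp_velocity,
                                hold_angle = hold_angle,
                                start_angle = start_angle,
                                pre_ms = pre_ms, hold_ms = hold_ms,
                                ramp_ms = ramp_ms)
  out
}

#' @rdname ramp_and_hold
#' @export
velocity_battery <- function() c(980, 604, 352, 188, 96)

#' @rdname ramp_and_hold
#' @export
hold_angle_battery <- function() c(60, 46, 34, 23, 15)

#' Constant-velocity triangular joint sweeps
#'
#' For each speed, a triangular wave traverses the full working range back and
#' forth at constant absolute angular velocity for at least `reps` full
#' cycles. Used to measure the rate-velocity curve of the velocity
#' interneurons.
#'
#' @param speeds Angular speeds (deg/s), all positive.
#' @param range Working range (deg), length 2 increasing.
#' @param reps Full cycles per speed.
#' @param dt Time step (ms).
#' @return A tibble with columns `speed` (deg/s) and `trace` (list of
#'   [joint_trace()]).
#' @examples
#' constant_velocity_sweep(c(100, 200), range = c(0, 180), dt = 1)
#' @export
constant_velocity_sweep <- function(speeds, range = c(0, 180), reps = 1,
                                    dt = 0.25) {
  if (any(speeds <= 0)) stop("`speeds` must be positive")
  stopifnot(length(range) == 2, range[2] > range[1], reps >= 1)
  span <- range[2] - range[1]
  make_one <- function(v) {
    half_ms <- span / v * 1000
    t <- seq(0, 2 * half_ms * reps, by = dt)
    phase <- (t %% (2 * half_ms)) / half_ms
    theta <- range[1] + span * ifelse(phase <= 1, phase, 2 - phase)
    joint_trace(t, theta, source = "protocol")
  }
  tibble::tibble(speed = as.numeric(speeds),
                 trace = purrr::map(speeds, make_one))
}

#' Synthetic gait-like joint-angle trace
#'
#' Emulates the statistical structure of motion-capture joint angles during
#' stepping: a quasi-periodic oscillation built from the fundamental stepping
#' frequency and its first harmonics with random phases, plus optional
#' low-pass-filtered Gaussian noise, soft-clipped so the trace stays strictly
#' inside the working range with smooth reversals. Sampled at the
#' motion-capture rate (5 ms, 200 Hz) by default; identical seeds give
#' byte-identical traces.
#'
#' @param duration_ms Trace length (ms).
#' @param working_range Joint working range (deg).
#' @param fundamental_hz Stepping frequency (Hz).
#' @param harmonics Relative amplitudes of the 1st..k-th harmonics.
#' @param noise_sd Noise amplitude (deg) before low-pass filtering.
#' @param noise_corner_hz Noise corner frequency (Hz).
#' @param dt Sampling step (ms).
#' @param seed Integer seed; required so runs are reproducible.
#' @param joint,leg Optional labels.
#' @return A [joint_trace()] with `source = "synthetic"`.
#' @examples
#' synthetic_gait(2000, seed = 1)
#' @export
synthetic_gait <- function(duration_ms = 5000, working_range = c(40, 140),
                           fundamental_hz = 1, harmonics = c(1, 0.4, 0.15),
                           noise_sd = 1, noise_corner_hz = 5, dt = 5,
                           seed, joint = NA_character_, leg = NA_character_) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(length(working_range) == 2, working_range[2] > working_range[1])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t <- seq(0, duration_ms, by = dt)
  ts <- t / 1000
  x <- numeric(length(t))
  phases <- runif(length(harmonics), 0, 2 * pi)
  for (k in seq_along(harmonics)) {
    x <- x + harmonics[k] * sin(2 * pi * k * fundamental_hz * ts + phases[k])
  }
  x <- x / sum(abs(harmonics))
  if (noise_sd > 0) {
    raw <- rnorm(length(t), sd = noise_sd)
    # single-pole low-pass at the corner frequency
    alpha <- exp(-2 * pi * noise_corner_hz * dt / 1000)
    sm <- numeric(length(raw)); acc <- 0
    for (i in seq_along(raw)) { acc <- alpha * acc + (1 - alpha) * raw[i]; sm[i] <- acc }
    # restore the requested amplitude after filtering
    if (sd(sm) > 0) sm <- sm * noise_sd / sd(sm)
    mid_range <- (working_range[2] - working_range[1]) / 2
    x <- x + sm / mid_range
  }
  mid <- mean(working_range)
  hw <- (working_range[2] - working_range[1]) / 2
  theta <- mid + hw * tanh(1.2 * x) # soft clip, strictly inside the range
  joint_trace(t, theta, joint = joint, leg = leg, source = "synthetic")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Resample a joint-angle trace onto a finer uniform grid
#'
#' Linear interpolation, endpoints preserved exactly; used to bring the 5 ms
#' motion-capture sampling onto the 0.25 ms simulation grid.
#'
#' @param trace A [joint_trace()].
#' @param dt_target Target step (ms).
#' @return A [joint_trace()] on the new grid.
#' @examples
#' resample_trace(synthetic_gait(1000, seed = 1), 0.25)
#' @export
resample_trace <- function(trace, dt_target = 0.25) {
  stopifnot(is.data.frame(trace), all(c("t", "theta") %in% names(trace)))
  if (dt_target <= 0) stop("`dt_target` must be positive")
  t_new <- seq(trace$t[1], trace$t[length(trace$t)], by = dt_target)
  out <- joint_trace(t_new,
                     approx(trace$t, trace$theta, xout = t_new)$y,
                     joint = attr(trace, "joint") %||% NA_character_,
                     leg = attr(trace, "leg") %||% NA_character_,
                     source = attr(trace, "source") %||% "protocol")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write joint-angle traces as long-format CSV
#'
#' Dialect: columns `time_s`, `leg`, `joint`, `angle_deg`, `trial_id`. Each
#' (trial, leg, joint) combination becomes one [joint_trace()].
#'
#' @param path CSV file path.
#' @return `read_joint_csv()`: a tibble with columns `trial_id`, `leg`,
#'   `joint` and `trace` (list of [joint_trace()]).
#' @export
read_joint_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("time_s", "leg", "joint", "angle_deg", "trial_id")
  if (!all(need %in% names(df))) {
    stop("joint CSV needs columns: ", paste(need, collapse = ", "))
  }
  df |>
    dplyr::group_by(.data$trial_id, .data$leg, .data$joint) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(trace = purrr::pmap(
      list(.data$data, .data$leg, .data$joint),
      function(d, l, j) joint_trace(d$time_s * 1000, d$angle_deg,
                                    joint = j, leg = l,
                                    source = "experimental"))) |>
    dplyr::select("trial_id", "leg", "joint", "trace")
}

#' @rdname read_joint_csv
#' @param traces Tibble as returned by `read_joint_csv()`, or a single
#'   [joint_trace()] (then `trial_id` defaults to 1).
#' @export
write_joint_csv <- function(traces, path) {
  if (is.data.frame(traces) && all(c("t", "theta") %in% names(traces))) {
    traces <- tibble::tibble(trial_id = 1L,
                             leg = attr(traces, "leg") %||% NA_character_,
                             joint = attr(traces, "joint") %||% NA_character_,
                             trace = list(traces))
  }
  long <- traces |>
    dplyr::mutate(rows = purrr::map(.data$trace, function(tr) {
      tibble::tibble(time_s = tr$t / 1000, angle_deg = tr$theta)
    })) |>
    dplyr::select(-"trace") |>
    tidyr::unnest("rows") |>
    dplyr::select("time_s", "leg", "joint", "angle_deg", "trial_id")
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
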
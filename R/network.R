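#' Configuration of the two-layer encoder for one joint
#'
#' Bundles the hair plate, the AdEx afferent parameters, the position LIF,
#' the per-hair high-pass LIF and the velocity integrator LIF, together with
#' the simulation step. The integrator weight must exceed `V_T - E_L` so that
#' every spike surviving the high-pass stage is relayed.
#'
#' @param plate A [hair_plate()].
#' @param adex [adex_params()] for the mechanosensory afferents.
#' @param pos_lif [lif_params()] of the position interneurons.
#' @param hp_lif [lif_params()] of the per-hair high-pass stage; the default
#'   is the calibrated cutoff weight (see [hp_lif_params()]).
#' @param vel_lif [lif_params()] of the velocity integrator stage.
#' @param dt Simulation step (ms).
#' @param joint,leg Optional labels.
#' @return An object of class `joint_config`.
#' @examples
#' joint_config(hair_plate(c(0, 180), n_hairs = 10, extended = TRUE))
#' @export
joint_config <- function(plate, adex = adex_params(),
                         pos_lif = position_lif_params(),
                         hp_lif = hp_lif_params(),
                         vel_lif = integrator_lif_params(),
                         dt = 0.25,
                         joint = NA_character_, leg = NA_character_) {
  stopifnot(inherits(plate, "hair_plate"), inherits(adex, "adex_params"),
            inherits(pos_lif, "lif_params"), inherits(hp_lif, "lif_params"),
            inherits(vel_lif, "lif_params"), dt > 0)
  if (vel_lif$omega <= vel_lif$V_T - vel_lif$E_L) {
    stop("velocity integrator weight must exceed V_T - E_L (one spike out per spike in)")
  }
  structure(
    list(plate = plate, adex = adex, pos_lif = pos_lif, hp_lif = hp_lif,
         vel_lif = vel_lif, dt = dt, joint = joint, leg = leg),
    class = "joint_config"
  )
}

#' Default encoder configuration for a joint's observed working range
#'
#' Builds the standard network joint encoder: an extended bi-directional plate
#' with 50 hairs per field, 0.1 degree overlaps, 50 pA/deg gain, and the
#' calibrated neuron parameters.
#'
#' @param working_range Joint working range (deg); typically the min/max of
#'   the joint's recorded angles.
#' @param n_hairs Hairs per field.
#' @param ... Passed on to [joint_config()].
#' @inheritParams hair_plate
#' @export
default_joint_config <- function(working_range, n_hairs = 50, overlap = 0.1,
                                 gain = 50, extended = TRUE, ...) {
  joint_config(hair_plate(working_range, n_hairs = n_hairs, overlap = overlap,
                          gain = gain, extended = extended), ...)
}

#' Run the mechanosensory layer for one joint
#'
#' Converts the joint-angle trace to per-hair deflections, deflections to
#' currents, and integrates one AdEx afferent per hair. Plate-level hair
#' indices run 1..n over the negative field and n+1..2n over the positive
#' field.
#'
#' @param trace A [joint_trace()] sampled at (or resampled to) `cfg$dt`.
#' @param cfg A [joint_config()].
#' @return A tibble with columns `hair` (plate index), `field`
#'   (`"neg"`/`"pos"`), `masked` (wired to position INs?) and `time` (ms),
#'   one row per spike, with attributes `duration` and `dt`.
#' @export
run_sensory_layer <- function(trace, cfg) {
  stopifnot(inherits(cfg, "joint_config"))
  dt <- check_uniform_grid(trace$t)
  if (abs(dt - cfg$dt) > 1e-8) {
    stop(sprintf("trace step (%g ms) does not match cfg$dt (%g ms); resample first",
                 dt, cfg$dt))
  }
  plate <- cfg$plate
  phi <- plate_angles(plate, trace$theta)
  I <- hair_currents(phi, plate$gain)
  n <- plate$field_neg$n_hairs
  masked <- c(plate$mask_neg, plate$mask_pos)
  fields <- rep(c("neg", "pos"), c(n, ncol(phi) - n))
  spikes <- purrr::map(seq_len(ncol(I)), function(j) {
    st <- integrate_adex(I[, j], cfg$adex, dt = dt)
    tibble::tibble(hair = j, field = fields[j], masked = masked[j],
                   time = st$time + trace$t[1])
  })
  out <- dplyr::bind_rows(spikes)
  attr(out, "duration") <- trace$t[length(trace$t)]
  attr(out, "t0") <- trace$t[1]
  attr(out, "dt") <- dt
  out
}

#' Run the position interneurons on the sensory layer output
#'
#' Each position LIF integrates all spikes from the position-wired (masked)
#' hairs of its field: `pos_minus` from the negative-orientation field (active
#' below the resting angle), `pos_plus` from the positive field.
#'
#' @param sensory Output of [run_sensory_layer()].
#' @param cfg A [joint_config()].
#' @return A list with [spike_train()] elements `pos_plus` and `pos_minus`.
#' @export
run_position_ins <- function(sensory, cfg) {
  stopifnot(inherits(cfg, "joint_config"))
  duration <- attr(sensory, "duration")
  one <- function(fld, id) {
    ev <- sensory$time[sensory$field == fld & sensory$masked]
    integrate_lif(ev - attr(sensory, "t0"), cfg$pos_lif, dt = cfg$dt,
                  duration = duration - attr(sensory, "t0"), neuron_id = id)
  }
  list(pos_plus = one("pos", "pos_plus"), pos_minus = one("neg", "pos_minus"))
}

#' Run the velocity interneuron chains on the sensory layer output
#'
#' Every hair's afferent train feeds its own high-pass LIF, whose cutoff input
#' rate lies just above the tonic afferent plateau, so only phasic bursts
#' (emitted while the joint angle sweeps across that hair's receptive field)
#' survive. Surviving spikes from all hairs of the positive field converge on
#' the `vel_plus` integrator (one output spike per input spike) and those of
#' the negative field on `vel_minus`, yielding direction-selective velocity
#' encoding across the whole working range.
#'
#' @inheritParams run_position_ins
#' @return A list with [spike_train()] elements `vel_plus` and `vel_minus`.
#' @export
run_velocity_ins <- function(sensory, cfg) {
  stopifnot(inherits(cfg, "joint_config"))
  if (!cfg$plate$extended) {
    stop("velocity interneurons require an extended bi-directional plate")
  }
  t0 <- attr(sensory, "t0")
  duration <- attr(sensory, "duration") - t0
  one <- function(fld, id) {
    hairs <- unique(sensory$hair[sensory$field == fld])
    passed <- purrr::map(hairs, function(h) {
      train <- sensory$time[sensory$hair == h] - t0
      hp <- integrate_lif(train, cfg$hp_lif, dt = cfg$dt, duration = duration)
      hp$time
    })
    integrate_lif(sort(unlist(passed)), cfg$vel_lif, dt = cfg$dt,
                  duration = duration, neuron_id = id)
  }
  list(vel_plus = one("pos", "vel_plus"), vel_minus = one("neg", "vel_minus"))
}

#' Encode one joint-angle trace with the full two-layer network
#'
#' Runs the sensory layer, the two position interneurons and the two velocity
#' chains, returning everything needed for decoding and evaluation.
#'
#' @param trace A [joint_trace()]; resampled to `cfg$dt` automatically.
#' @param cfg A [joint_config()].
#' @param velocity Run the velocity chains? (Requires an extended plate.)
#' @return An object of class `joint_encoding`: a list with elements `trace`
#'   (the resampled input), `cfg`, `sensory`, `pos_plus`, `pos_minus` and,
#'   when requested, `vel_plus`, `vel_minus`.
#' @examples
#' cfg <- default_joint_config(c(40, 140), n_hairs = 10)
#' enc <- encode_joint(synthetic_gait(1000, seed = 1), cfg)
#' glance(enc)
#' @export
encode_joint <- function(trace, cfg, velocity = cfg$plate$extended) {
  dt <- check_uniform_grid(trace$t)
  if (abs(dt - cfg$dt) > 1e-8) trace <- resample_trace(trace, cfg$dt)
  sensory <- run_sensory_layer(trace, cfg)
  pos <- run_position_ins(sensory, cfg)
  out <- c(list(trace = trace, cfg = cfg, sensory = sensory), pos)
  if (velocity) out <- c(out, run_velocity_ins(sensory, cfg))
  structure(out, class = "joint_encoding")
}

#' @export
print.joint_encoding <- function(x, ...) {
  dur <- (x$trace$t[length(x$trace$t)] - x$trace$t[1]) / 1000
  cat(sprintf("<joint_encoding> %.3g s, %d sensory spikes, pos +/-: %d/%d",
              dur, nrow(x$sensory), nrow(x$pos_plus), nrow(x$pos_minus)))
  if (!is.null(x$vel_plus)) {
    cat(sprintf(", vel +/-: %d/%d", nrow(x$vel_plus), nrow(x$vel_minus)))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.joint_encoding <- function(x, ...) {
  ins <- purrr::map(c("pos_plus", "pos_minus", "vel_plus", "vel_minus"),
                    function(nm) {
                      if (is.null(x[[nm]])) return(NULL)
                      tibble::tibble(neuron = nm, time = x[[nm]]$time)
                    })
  dplyr::bind_rows(
    tibble::tibble(neuron = paste0("hair_", x$sensory$hair),
                   time = x$sensory$time),
    dplyr::bind_rows(ins)
  )
}

#' @export
glance.joint_encoding <- function(x, ...) {
  tibble::tibble(
    duration_ms = x$trace$t[length(x$trace$t)] - x$trace$t[1],
    n_hairs = 2L * x$cfg$plate$field_neg$n_hairs,
    sensory_spikes = nrow(x$sensory),
    pos_plus_spikes = nrow(x$pos_plus),
    pos_minus_spikes = nrow(x$pos_minus),
    vel_plus_spikes = if (is.null(x$vel_plus)) NA_integer_ else nrow(x$vel_plus),
    vel_minus_spikes = if (is.null(x$vel_minus)) NA_integer_ else nrow(x$vel_minus)
  )
}

#' Encode joint-angle traces for a whole body (up to 18 joints)
#'
#' Runs the per-joint encoder independently for each (leg, joint) trace;
#' results are deterministic and independent of row order. Configurations are
#' built per joint from each trace's observed working range unless supplied.
#'
#' @param traces A tibble with columns `leg`, `joint` and `trace` (list of
#'   [joint_trace()]), e.g. from [read_joint_csv()], optionally `trial_id`.
#' @param cfgs Either `NULL` (build [default_joint_config()] per joint from
#'   the observed range), a single [joint_config()] used for all joints, or a
#'   list keyed by `"<leg>.<joint>"`.
#' @param n_hairs,velocity Passed to the default configuration/encoder.
#' @return `traces` with an added list-column `encoding`.
#' @export
simulate_body <- function(traces, cfgs = NULL, n_hairs = 50, velocity = TRUE) {
  stopifnot(is.data.frame(traces),
            all(c("leg", "joint", "trace") %in% names(traces)))
  missing_tr <- purrr::map_lgl(traces$trace, is.null)
  if (any(missing_tr)) {
    stop("missing traces for: ",
         paste(traces$leg[missing_tr], traces$joint[missing_tr],
               sep = ":", collapse = ", "))
  }
  get_cfg <- function(leg, joint, trace) {
    if (inherits(cfgs, "joint_config")) return(cfgs)
    key <- paste(leg, joint, sep = ".")
    if (!is.null(cfgs) && !is.null(cfgs[[key]])) return(cfgs[[key]])
    rng <- range(trace$theta)
    if (diff(rng) < 1) rng <- rng + c(-0.5, 0.5) # degenerate flat trace
    default_joint_config(rng, n_hairs = n_hairs, joint = joint, leg = leg)
  }
  traces |>
    dplyr::mutate(encoding = purrr::pmap(
      list(.data$leg, .data$joint, .data$trace),
      function(l, j, tr) encode_joint(tr, get_cfg(l, j, tr), velocity = velocity)
    ))
}

#' Calibrate the high-pass cutoff of the velocity chain
#'
#' Reproduces the tuning of the per-hair high-pass stage: with `tau` fixed,
#' the synaptic weight is increased along a grid — each increase lowers the
#' cutoff input rate `f_c` — and the calibration stops at the largest weight
#' for which `f_c` still sits just above the tonic plateau rate `f_ss` of a
#' fully deflected hair. Concretely, the selected weight is the largest on
#' the grid such that the high-pass LIF (i) passes no spikes when driven by
#' the settled tonic spike train of a fully deflected hair, yet (ii) passes
#' at least one spike of the phasic burst evoked by a slow reference ramp.
#' Also reports the achieved `f_c`, the lowest constant input rate that
#' elicits any output. A weight above `V_T - E_L` is degenerate (every input
#' spike passes) and is flagged.
#'
#' @param cfg A [joint_config()].
#' @param omega_grid Candidate weights (mV).
#' @param ramp_velocity Reference ramp speed (deg/s) for the phasic test.
#' @param test_ms Duration of the tonic test train (ms).
#' @return A list of class `cutoff_calibration` with elements `omega_hp`,
#'   `f_ss`, `f_c`, `degenerate` and the per-candidate `grid` tibble.
#' @export
calibrate_cutoff <- function(cfg, omega_grid = seq(9, 12, by = 0.1),
                             ramp_velocity = 50, test_ms = 2000) {
  stopifnot(inherits(cfg, "joint_config"))
  settle <- 10 * cfg$adex$tau_w
  f_ss <- steady_state_rate(cfg$adex, I_const = 90 * cfg$plate$gain,
                            dt = cfg$dt, settle_time = settle,
                            sim_time = settle + test_ms)
  # realized tonic train of a fully deflected hair, after settling
  n <- floor((settle + test_ms) / cfg$dt) + 1L
  tonic <- integrate_adex(rep(90 * cfg$plate$gain, n), cfg$adex, dt = cfg$dt)
  tonic_times <- tonic$time[tonic$time > settle] - settle
  # phasic reference: one hair deflected across its full 0-90 range slowly
  ramp <- ramp_and_hold(ramp_velocity, 90, hold_ms = 500, dt = cfg$dt)
  phasic <- integrate_adex(hair_currents(ramp, cfg$plate$gain), cfg$adex)
  dur <- train_duration(phasic)
  gap <- cfg$hp_lif$V_T - cfg$hp_lif$E_L

  try_omega <- function(om) {
    p <- lif_params(tau = cfg$hp_lif$tau, omega = om,
                    E_L = cfg$hp_lif$E_L, V_T = cfg$hp_lif$V_T)
    blocked <- nrow(integrate_lif(tonic_times, p, dt = cfg$dt,
                                  duration = test_ms)) == 0
    passes <- nrow(integrate_lif(phasic$time, p, dt = cfg$dt,
                                 duration = dur)) > 0
    tibble::tibble(omega = om, blocks_tonic = blocked, passes_phasic = passes)
  }
  grid <- dplyr::bind_rows(purrr::map(sort(omega_grid), try_omega))
  ok <- grid$blocks_tonic & grid$passes_phasic
  if (!any(ok)) {
    stop("no omega on the grid blocks the tonic rate while passing the phasic burst")
  }
  omega_hp <- grid$omega[max(which(ok))]
  # achieved cutoff: lowest constant input rate that elicits any output
  p_sel <- lif_params(tau = cfg$hp_lif$tau, omega = omega_hp,
                      E_L = cfg$hp_lif$E_L, V_T = cfg$hp_lif$V_T)
  rates <- seq(50, 1000, by = 2)
  fires <- purrr::map_lgl(rates, function(f) {
    nrow(integrate_lif(seq(0, test_ms, by = 1000 / f), p_sel, dt = cfg$dt,
                       duration = test_ms)) > 0
  })
  f_c <- if (any(fires)) rates[which(fires)[1]] else NA_real_
  structure(
    list(omega_hp = omega_hp, f_ss = f_ss, f_c = f_c,
         degenerate = omega_hp > gap, grid = grid),
    class = "cutoff_calibration"
  )
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf("<cutoff_calibration> omega = %g mV, f_ss = %.1f Hz, f_c = %.1f Hz%s\n",
              x$omega_hp, x$f_ss, x$f_c,
              if (x$degenerate) " (degenerate: passes every spike)" else ""))
  invisible(x)
}
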
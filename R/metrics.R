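#' Mean absolute error between reference and model ramp-response rates
#'
#' For the ten ramp-and-hold reference trials (five ramp velocities plus five
#' hold angles), compares the steady-state and peak spike rates of the model
#' against a reference table and averages the twenty absolute deviations.
#'
#' @param model,reference Tibbles with columns `trial`, `ss` and `peak` (Hz),
#'   one row per ramp trial, matched by `trial`.
#' @return MAE in Hz.
#' @examples
#' ref <- tibble::tibble(trial = 1:10, ss = 100, peak = 150)
#' mae_fit(dplyr::mutate(ref, ss = ss + 10, peak = peak + 10), ref) # 10 Hz
#' @export
mae_fit <- function(model, reference) {
  need <- c("trial", "ss", "peak")
  stopifnot(all(need %in% names(model)), all(need %in% names(reference)))
  if (nrow(model) != nrow(reference)) stop("trial tables differ in length")
  j <- dplyr::inner_join(model, reference, by = "trial",
                         suffix = c("_m", "_r"))
  if (nrow(j) != nrow(model)) stop("trial ids do not match")
  sum(abs(j$ss_m - j$ss_r) + abs(j$peak_m - j$peak_r)) / (2 * nrow(j))
}

#' Mean squared error between aligned (z-normalised) traces
#'
#' The squared difference averaged over time steps. With data-frame inputs the
#' traces are aligned on their shared `t` grid; with vectors they must have
#' equal length. Symmetric in its arguments.
#'
#' @param model,reference Numeric vectors, or tibbles whose first column is
#'   `t` and last column the value.
#' @return Mean squared error (dimensionless for z-normalised inputs).
#' @export
mse_traces <- function(model, reference) {
  if (is.data.frame(model) && is.data.frame(reference)) {
    vm <- names(model)[length(names(model))]
    vr <- names(reference)[length(names(reference))]
    t_shared <- intersect(round(model$t, 9), round(reference$t, 9))
    if (!length(t_shared)) stop("traces share no time points")
    m <- model[[vm]][match(t_shared, round(model$t, 9))]
    r <- reference[[vr]][match(t_shared, round(reference$t, 9))]
  } else {
    m <- as.numeric(model); r <- as.numeric(reference)
    if (length(m) != length(r)) stop("traces differ in length")
  }
  mean((m - r)^2)
}

#' Aggregate per-trace MSEs over joints and trials
#'
#' Averages per-trace mean squared errors with equal weight per trace (each
#' trace contributes its per-step mean), and tabulates group means by leg and
#' by joint for downstream statistics.
#'
#' @param results A tibble with columns `leg`, `joint`, `trial_id` (optional)
#'   and `mse`.
#' @return A list with `overall` (scalar), `by_leg`, `by_joint` and
#'   `by_leg_joint` tibbles (`mse` mean and `sd`).
#' @export
mse_table <- function(results) {
  stopifnot(all(c("leg", "joint", "mse") %in% names(results)))
  agg <- function(...) {
    results |>
      dplyr::group_by(...) |>
      dplyr::summarise(mean_mse = mean(.data$mse), sd = sd(.data$mse),
                       n = dplyr::n(), .groups = "drop")
  }
  list(overall = mean(results$mse),
       by_leg = agg(.data$leg),
       by_joint = agg(.data$joint),
       by_leg_joint = agg(.data$leg, .data$joint))
}

#' Confusion-matrix rates for the velocity interneurons
#'
#' Treats the two velocity interneurons as a binary classifier of movement
#' direction: `vel_plus` spikes during rising joint angle are true positives
#' and during falling angle false positives; `vel_minus` spikes during rising
#' angle are false negatives and during falling angle true negatives. Then
#' `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)` and
#' `ACC = (TPR + TNR) / 2`; a rate with a zero denominator is `NA`.
#'
#' @param tp,fp,fn,tn Spike counts.
#' @return A tibble with the counts and `tpr`, `tnr`, `acc`.
#' @examples
#' confusion_rates(1627811, 155707, 155167, 1689086)
#' @export
confusion_rates <- function(tp, fp, fn, tn) {
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 tpr = tpr, tnr = tnr, acc = acc)
}

#' Classify velocity-interneuron spikes against the true movement direction
#'
#' The ground-truth angular velocity is the central finite difference of the
#' joint-angle trace on the simulation grid; each spike is labelled by the
#' velocity sign at its time step. Samples with |velocity| below `zero_tol`
#' (deg/ms) are excluded from the tallies, since the direction is undefined
#' while the joint is stationary.
#'
#' @param vel_plus,vel_minus [spike_train()]s of the two velocity
#'   interneurons.
#' @param trace The [joint_trace()] that drove the encoder (simulation grid).
#' @param zero_tol Velocity magnitude (deg/ms) below which samples are
#'   excluded.
#' @return A tibble as from [confusion_rates()].
#' @export
velocity_confusion <- function(vel_plus, vel_minus, trace, zero_tol = 1e-6) {
  dt <- check_uniform_grid(trace$t)
  n <- nrow(trace)
  vel <- c(NA, (trace$theta[3:n] - trace$theta[1:(n - 2)]) / (2 * dt), NA)
  sign_at <- function(times) {
    idx <- pmin(pmax(round((times - trace$t[1]) / dt) + 1, 1), n)
    v <- vel[idx]
    v[!is.na(v) & abs(v) >= zero_tol]
  }
  vp <- sign_at(vel_plus$time)
  vm <- sign_at(vel_minus$time)
  confusion_rates(tp = sum(vp > 0), fp = sum(vp < 0),
                  fn = sum(vm > 0), tn = sum(vm < 0))
}

#' Linear fit of mean velocity-interneuron rate against sweep speed
#'
#' Ordinary least squares through the per-speed mean output rates; the slope
#' (Hz per deg/s, i.e. spikes per degree) and r-squared summarise how linearly
#' the interneurons encode angular velocity.
#'
#' @param rates A data frame with columns `speed` (deg/s) and `rate` (Hz).
#' @return An object of class `rv_fit` with `tidy()`/`glance()` methods.
#' @examples
#' fit_rate_velocity(data.frame(speed = 1:5, rate = 2 * (1:5)))
#' @export
fit_rate_velocity <- function(rates) {
  stopifnot(all(c("speed", "rate") %in% names(rates)))
  if (nrow(rates) < 3) stop("need at least 3 speeds")
  fit <- lm(rate ~ speed, data = rates)
  sst <- sum((rates$rate - mean(rates$rate))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, model = fit, data = tibble::as_tibble(rates)),
    class = "rv_fit"
  )
}

#' @export
print.rv_fit <- function(x, ...) {
  cat(sprintf("<rv_fit> rate = %.4g + %.4g * speed  (r^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
tidy.rv_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "speed"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.rv_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n = nrow(x$data))
}

#' Decode and score joint-angle (position) encoding for one trace
#'
#' Computes the combined z-normalised position signal from the two position
#' interneurons, z-normalises the (resampled) joint angle, and returns the
#' per-trace MSE together with the traces used.
#'
#' @param encoding A [encode_joint()] result.
#' @param rate_method,width Passed to [spike_rate()].
#' @return A list with `mse`, `signal` (model) and `reference` tibbles.
#' @export
position_error <- function(encoding, rate_method = "isi", width = 50) {
  stopifnot(inherits(encoding, "joint_encoding"))
  rp <- spike_rate(encoding$pos_plus, method = rate_method, width = width)
  rm <- spike_rate(encoding$pos_minus, method = rate_method, width = width)
  model <- combined_signal(rp, rm)
  ref <- tibble::tibble(t = model$t,
                        signal = znorm(encoding$trace$theta[
                          seq_len(nrow(model))]))
  list(mse = mse_traces(model, ref), signal = model, reference = ref)
}

#' Decode and score angular-velocity encoding for one trace
#'
#' As [position_error()] but for the velocity interneurons, compared against
#' the z-normalised central-difference angular velocity, optionally after
#' shifting the model response earlier by `lag_ms` to correct the encoding
#' lag.
#'
#' @param encoding A [encode_joint()] result (velocity chains present).
#' @param lag_ms Lag correction (ms), e.g. 25.
#' @inheritParams position_error
#' @return A list with `mse`, `signal` and `reference`.
#' @export
velocity_error <- function(encoding, lag_ms = 0, rate_method = "isi",
                           width = 50) {
  stopifnot(inherits(encoding, "joint_encoding"))
  if (is.null(encoding$vel_plus)) stop("encoding has no velocity interneurons")
  rp <- spike_rate(encoding$vel_plus, method = rate_method, width = width)
  rm <- spike_rate(encoding$vel_minus, method = rate_method, width = width)
  model <- combined_signal(rp, rm)
  tr <- encoding$trace
  dt <- check_uniform_grid(tr$t)
  n <- nrow(tr)
  vel <- c(0, (tr$theta[3:n] - tr$theta[1:(n - 2)]) / (2 * dt), 0)
  ref <- tibble::tibble(t = tr$t - tr$t[1], signal = znorm(vel))
  if (lag_ms != 0) model <- lag_shift(model, lag_ms)
  list(mse = mse_traces(model, ref), signal = model, reference = ref)
}
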
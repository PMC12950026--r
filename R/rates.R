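#' Instantaneous spike-rate time course
#'
#' Two estimators: `"isi"` assigns the reciprocal of each inter-spike interval
#' over that interval (sample-and-hold; zero before the first and after the
#' last spike), `"boxcar"` counts spikes in a centered window of `width` ms
#' divided by the window length.
#'
#' @param spikes A [spike_train()] (single neuron).
#' @param method `"isi"` or `"boxcar"`.
#' @param width Boxcar width (ms).
#' @param dt Output grid step (ms); defaults to the train's simulation step.
#' @param duration Trace length (ms); defaults to the train's duration.
#' @return A tibble with columns `t` (ms) and `rate` (Hz).
#' @examples
#' spike_rate(spike_train(seq(10, 90, by = 10), duration = 100), dt = 1)
#' @export
spike_rate <- function(spikes, method = c("isi", "boxcar"), width = 50,
                       dt = NULL, duration = NULL) {
  method <- match.arg(method)
  duration <- duration %||% train_duration(spikes)
  dt <- dt %||% attr(spikes, "dt") %||% 0.25
  if (is.null(duration) || is.na(duration) || duration <= 0) {
    stop("`duration` must be known and positive")
  }
  t <- seq(0, duration, by = dt)
  times <- sort(spikes$time)
  rate <- numeric(length(t))
  if (length(times) >= 2) {
    if (method == "isi") {
      isi <- diff(times)
      idx <- findInterval(t, times)
      inside <- idx >= 1 & idx < length(times)
      rate[inside] <- 1000 / isi[idx[inside]]
    } else {
      counts <- vapply(t, function(tt) {
        sum(times > tt - width / 2 & times <= tt + width / 2)
      }, numeric(1))
      rate <- counts / (width / 1000)
    }
  } else if (length(times) == 1 && method == "boxcar") {
    rate <- as.numeric(times > t - width / 2 & times <= t + width / 2) /
      (width / 1000)
  }
  tibble::tibble(t = t, rate = rate)
}

#' Peak instantaneous rate of a spike train
#'
#' The reciprocal of the minimum inter-spike interval, in Hz; 0 with fewer
#' than two spikes.
#'
#' @param spikes A [spike_train()].
#' @export
peak_rate <- function(spikes) {
  times <- sort(spikes$time)
  if (length(times) < 2) return(0)
  1000 / min(diff(times))
}

#' z-normalise a time series
#'
#' Rescales to zero mean and unit standard deviation over the trial, so that
#' traces in different units (spike rate vs joint angle) can be compared by
#' shape alone.
#'
#' @param x A numeric vector, or a data frame whose last column is the value
#'   (e.g. a rate trace or [joint_trace()]).
#' @return Same shape as `x`, z-normalised.
#' @export
znorm <- function(x) {
  if (is.data.frame(x)) {
    col <- names(x)[length(names(x))]
    x[[col]] <- znorm(x[[col]])
    return(x)
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-normalise a constant series")
  (x - mean(x)) / s
}

#' Combined antagonistic rate signal
#'
#' Subtracts the `minus` interneuron's rate from the `plus` interneuron's and
#' z-normalises the difference; the result tracks the (z-normalised) joint
#' angle or angular velocity.
#'
#' @param plus,minus Rate traces (tibbles with `t` and `rate`) on a shared
#'   grid.
#' @return A tibble with columns `t` and `signal` (z-units).
#' @export
combined_signal <- function(plus, minus) {
  if (nrow(plus) != nrow(minus) || max(abs(plus$t - minus$t)) > 1e-8) {
    stop("`plus` and `minus` must share the same time grid")
  }
  tibble::tibble(t = plus$t, signal = znorm(plus$rate - minus$rate))
}

#' Shift a trace in time to correct an encoding lag
#'
#' Shifts the value series by `dt_shift` (ms, positive = earlier; i.e. the
#' model response is moved back in time) and trims both ends to the
#' overlapping segment.
#'
#' @param trace A tibble whose first column is `t` and whose last column holds
#'   the values.
#' @param dt_shift Shift (ms); magnitude must be smaller than the trace
#'   duration.
#' @return The shifted, trimmed trace.
#' @export
lag_shift <- function(trace, dt_shift) {
  stopifnot(is.data.frame(trace), names(trace)[1] == "t")
  dt <- check_uniform_grid(trace$t)
  k <- round(dt_shift / dt)
  n <- nrow(trace)
  if (abs(k) >= n) stop("`dt_shift` exceeds the trace duration")
  if (k == 0) return(trace)
  col <- names(trace)[length(names(trace))]
  if (k > 0) {
    out <- trace[seq_len(n - k), , drop = FALSE]
    out[[col]] <- trace[[col]][(k + 1):n]
  } else {
    out <- trace[seq_len(n + k), , drop = FALSE]
    out[[col]] <- trace[[col]][seq_len(n + k)]
    out$t <- trace$t[(1 - k):n]
  }
  out
}
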
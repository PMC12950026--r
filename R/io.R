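#' Read and write spike trains as two-column CSV
#'
#' Columns `neuron_id`, `spike_time_ms`.
#'
#' @param spikes A [spike_train()] or any tibble with `neuron_id` and `time`.
#' @param path File path.
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(all(c("neuron_id", "time") %in% names(spikes)))
  write.csv(data.frame(neuron_id = spikes$neuron_id,
                       spike_time_ms = spikes$time),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param duration Simulation length (ms) to attach to the loaded train.
#' @export
read_spikes_csv <- function(path, duration = NA_real_) {
  df <- read.csv(path)
  spike_train(df$spike_time_ms, df$neuron_id, duration = duration)
}

#' Write a recorded voltage/adaptation state trace to CSV
#'
#' Columns `t_ms`, `V_mV` and (for AdEx) `w_pA`.
#'
#' @param spikes A [spike_train()] produced with `record_state = TRUE`.
#' @param path File path.
#' @export
write_state_csv <- function(spikes, path) {
  st <- attr(spikes, "state")
  if (is.null(st)) stop("no recorded state; rerun with record_state = TRUE")
  out <- data.frame(t_ms = st$t, V_mV = st$V)
  if (!is.null(st$w)) out$w_pA <- st$w
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Build joint encoder configurations from a YAML file
#'
#' The YAML maps joint keys (`"R1.alpha"`, ...) to parameter blocks; missing
#' fields fall back to the calibrated defaults. Recognised per-joint fields:
#' `working_range`, `n_hairs`, `overlap`, `gain`, `extended`, `dt`, and nested
#' `adex` / `pos_lif` / `hp_lif` / `vel_lif` parameter lists.
#'
#' @param path YAML file path.
#' @return A named list of [joint_config()]s.
#' @export
read_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(block, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    plate <- hair_plate(
      working_range = as.numeric(block$working_range %||% c(0, 180)),
      n_hairs = block$n_hairs %||% 50,
      overlap = block$overlap %||% 0.1,
      gain = block$gain %||% 50,
      extended = block$extended %||% TRUE)
    mk <- function(defaults, override) {
      if (is.null(override)) return(defaults)
      do.call(lif_params, utils::modifyList(
        list(tau = defaults$tau, omega = defaults$omega,
             E_L = defaults$E_L, V_T = defaults$V_T), override))
    }
    adex <- if (is.null(block$adex)) adex_params() else {
      do.call(adex_params, block$adex)
    }
    joint_config(plate, adex = adex,
                 pos_lif = mk(position_lif_params(), block$pos_lif),
                 hp_lif = mk(velocity_lif_params(), block$hp_lif),
                 vel_lif = mk(integrator_lif_params(), block$vel_lif),
                 dt = block$dt %||% 0.25,
                 leg = if (length(parts) == 2) parts[1] else NA_character_,
                 joint = if (length(parts) == 2) parts[2] else NA_character_)
  })
}
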
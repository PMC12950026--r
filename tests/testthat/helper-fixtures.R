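# shared fixtures: kept small so the suite stays fast

fig2a_field <- function() hair_field(5, 0, 92, overlap = 4)

# a light extended encoder for pipeline tests
small_cfg <- function(range = c(0, 180), n_hairs = 10, ...) {
  default_joint_config(range, n_hairs = n_hairs, ...)
}

constant_trace <- function(theta, duration = 1000, dt = 0.25) {
  joint_trace(seq(0, duration, by = dt), rep(theta, duration / dt + 1))
}

# independent scalar re-implementation of the receptive-field/deflection
# formulas, used as an oracle against the vectorised version
scalar_phi <- function(theta, i, n, lo, hi, ol, positive = TRUE) {
  s <- (hi - lo) / n
  rf0 <- s * (i - 1) + lo - ol / 2
  rf90 <- s * i + lo + ol / 2
  if (i == 1) rf0 <- lo
  if (i == n) rf90 <- hi
  fr <- min(max((theta - rf0) / (rf90 - rf0), 0), 1)
  if (positive) 90 * fr else 90 * (1 - fr)
}
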
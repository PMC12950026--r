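test_that("rate estimators behave on degenerate and periodic trains", {
  empty <- spike_train(numeric(), duration = 100)
  expect_true(all(spike_rate(empty, dt = 1)$rate == 0))

  periodic <- spike_train(seq(10, 990, by = 10), duration = 1000) # 100 Hz
  r <- spike_rate(periodic, dt = 1)
  interior <- r$rate[r$t >= 10 & r$t < 990] # sample-and-hold over each interval
  expect_true(all(interior == 100))
  expect_true(all(r$rate[r$t < 10 | r$t >= 990] == 0))

  # boxcar integral recovers the spike count when all windows fit the trace
  inner <- spike_train(seq(100, 900, by = 10), duration = 1000)
  rb <- spike_rate(inner, method = "boxcar", width = 50, dt = 1)
  expect_equal(sum(rb$rate) * 1 / 1000, nrow(inner), tolerance = 1e-9)

  expect_equal(peak_rate(periodic), 100)
  expect_equal(peak_rate(empty), 0)
})

test_that("z-normalisation is affine-invariant and rejects constants", {
  x <- rnorm(500, 20, 7)
  z <- znorm(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(znorm(3 * x - 11), z, tolerance = 1e-9)
  expect_error(znorm(rep(2, 10)), "constant")
})

test_that("combined signal is an antisymmetric z-scored difference", {
  t <- 0:99
  a <- tibble::tibble(t = t, rate = 50 + 10 * sin(t / 8))
  b <- tibble::tibble(t = t, rate = 30 + 5 * cos(t / 8))
  ab <- combined_signal(a, b)
  ba <- combined_signal(b, a)
  expect_equal(ab$signal, -ba$signal)
  expect_error(combined_signal(a, a), "constant")
  expect_error(combined_signal(a, b[1:50, ]), "grid")
})

test_that("combined position signal tracks a slow sinusoidal joint trace", {
  t <- seq(0, 4000, by = 0.25)
  tr <- joint_trace(t, 90 + 60 * sin(2 * pi * t / 2000))
  enc <- encode_joint(tr, small_cfg(c(20, 160), n_hairs = 20),
                      velocity = FALSE)
  pe <- position_error(enc)
  expect_gt(cor(pe$signal$signal, pe$reference$signal), 0.9)
})

test_that("ramp-table MAE matches hand-computed cases", {
  ref <- tibble::tibble(trial = 1:10, ss = seq(40, 130, by = 10),
                        peak = seq(90, 180, by = 10))
  expect_equal(mae_fit(ref, ref), 0)
  shifted <- dplyr::mutate(ref, ss = ss + 10, peak = peak + 10)
  expect_equal(mae_fit(shifted, ref), 10)
  one_off <- ref
  one_off$ss[4] <- ref$ss[4] + 4
  one_off$peak[4] <- ref$peak[4] - 6
  expect_equal(mae_fit(one_off, ref), (4 + 6) / 20)
})

test_that("trace MSE is symmetric with known algebra on z-scores", {
  z <- znorm(rnorm(2000))
  expect_equal(mse_traces(z, z), 0)
  # model = -reference: mean((2z)^2) = 4 * mean(z^2)
  expect_equal(mse_traces(-z, z), 4 * mean(z^2))
  expect_equal(mse_traces(-z, z), 4, tolerance = 0.01)
  a <- rnorm(300); b <- rnorm(300)
  expect_equal(mse_traces(a, b), mse_traces(b, a))
})

test_that("lag shifting is exact and recovers a constructed lag", {
  t <- seq(0, 100, by = 0.5)
  tr <- tibble::tibble(t = t, signal = sin(t / 5))
  expect_identical(lag_shift(tr, 0), tr)
  # shift then unshift restores the overlapped segment
  fwd <- lag_shift(tr, 10)
  back <- lag_shift(fwd, -10)
  ov <- match(back$t, tr$t)
  expect_equal(back$signal, tr$signal[ov], tolerance = 1e-12)
  # a trace lagging by k samples scores best at dt_shift = k*dt
  k <- 14
  lagged <- tibble::tibble(t = t, signal = dplyr::lag(tr$signal, k, default = 0))
  shifts <- seq(0, 20, by = 0.5)
  errs <- vapply(shifts, function(s) {
    mse_traces(lag_shift(lagged, s), tr)
  }, numeric(1))
  expect_equal(shifts[which.min(errs)], k * 0.5)
  expect_error(lag_shift(tr, 1e6), "duration")
})

test_that("confusion arithmetic reproduces the published counts and contracts", {
  cc <- confusion_rates(tp = 1627811, fp = 155707, fn = 155167, tn = 1689086)
  expect_equal(round(cc$tpr, 3), 0.913)
  expect_equal(round(cc$tnr, 3), 0.916)
  expect_equal(round(cc$acc, 3), 0.914)
  # every spike on the wrong phase
  expect_equal(confusion_rates(0, 10, 10, 0)$acc, 0)
  # no spikes at all: undefined, not zero
  none <- confusion_rates(0, 0, 0, 0)
  expect_true(is.na(none$tpr) && is.na(none$tnr) && is.na(none$acc))
})

test_that("spike-level confusion labels directions and skips zero velocity", {
  t <- seq(0, 4000, by = 1)
  tr <- joint_trace(t, c(seq(0, 100, length.out = 2001)[-2001],
                         seq(100, 100, length.out = 500),
                         seq(100, 0, length.out = 1501)))
  vp <- spike_train(c(500, 1000, 2200, 3000), "vel_plus", duration = 4000)
  vm <- spike_train(c(1500, 2800, 3500), "vel_minus", duration = 4000)
  cc <- velocity_confusion(vp, vm, tr)
  # the spike at t = 2200 falls in the flat hold and is excluded
  expect_equal(cc$tp, 2) # 500, 1000 rising
  expect_equal(cc$fp, 1) # 3000 falling
  expect_equal(cc$fn, 1) # 1500 rising
  expect_equal(cc$tn, 2) # 2800, 3500 falling
  expect_equal(cc$acc, (2 / 3 + 2 / 3) / 2)
})

test_that("rate-velocity regression handles exact and degenerate data", {
  ex <- fit_rate_velocity(data.frame(speed = c(50, 100, 200, 400),
                                     rate = 2 * c(50, 100, 200, 400)))
  expect_equal(ex$slope, 2)
  expect_equal(ex$intercept, 0, tolerance = 1e-9)
  expect_equal(ex$r_squared, 1)
  flat <- fit_rate_velocity(data.frame(speed = c(50, 100, 200), rate = 7))
  expect_equal(flat$slope, 0)
  expect_error(fit_rate_velocity(data.frame(speed = 1:2, rate = 1:2)), "3")
  td <- tidy(ex); gl <- glance(ex)
  expect_equal(td$estimate[td$term == "speed"], 2)
  expect_equal(gl$slope, 2)
})

test_that("metric implementations match brute-force recomputation on random inputs", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    # ramp-table MAE
    m <- tibble::tibble(trial = 1:10, ss = runif(10, 0, 200),
                        peak = runif(10, 0, 300))
    r <- tibble::tibble(trial = 1:10, ss = runif(10, 0, 200),
                        peak = runif(10, 0, 300))
    brute_mae <- sum(abs(m$ss - r$ss) + abs(m$peak - r$peak)) / 20
    expect_equal(mae_fit(m, r), brute_mae)
    # trace MSE
    a <- runif(n); b <- runif(n)
    expect_equal(mse_traces(a, b), sum((a - b)^2) / n)
    # confusion rates
    k <- sample(0:50, 4, replace = TRUE)
    cc <- confusion_rates(k[1], k[2], k[3], k[4])
    if (k[1] + k[3] > 0 && k[4] + k[2] > 0) {
      expect_equal(cc$acc, (k[1] / (k[1] + k[3]) + k[4] / (k[4] + k[2])) / 2)
    }
  }
})

test_that("per-group MSE aggregation produces the expected tables", {
  res <- tidyr::expand_grid(leg = c("R1", "L2"), joint = c("alpha", "beta"),
                            trial_id = 1:3)
  set.seed(2); res$mse <- runif(nrow(res))
  tab <- mse_table(res)
  expect_equal(tab$overall, mean(res$mse))
  expect_equal(nrow(tab$by_joint), 2)
  expect_equal(nrow(tab$by_leg_joint), 4)
  aj <- tab$by_joint$mean_mse[tab$by_joint$joint == "alpha"]
  expect_equal(aj, mean(res$mse[res$joint == "alpha"]))
})
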
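test_that("rest posture drives only the innermost position-wired hairs tonically", {
  # narrow joint: the overlap deflection at rest is suprathreshold
  cfg <- default_joint_config(c(0, 60))
  sens <- run_sensory_layer(constant_trace(30, duration = 2000), cfg)
  late <- sens[sens$time > 1000 & sens$masked, ]
  expect_equal(sort(unique(late$hair)), c(25, 76))
})

test_that("a joint pinned at the lower bound silences the positive masked hairs", {
  cfg <- small_cfg(c(0, 180))
  sens <- run_sensory_layer(constant_trace(0, duration = 500), cfg)
  expect_equal(sum(sens$field == "pos" & sens$masked), 0)
})

test_that("a monotone sweep across the range activates every hair", {
  cfg <- small_cfg(c(0, 180))
  n_steps <- 2000 / 0.25
  tr <- joint_trace(seq(0, 2000, by = 0.25),
                    seq(0, 180, length.out = n_steps + 1))
  sens <- run_sensory_layer(tr, cfg)
  expect_equal(sort(unique(sens$hair)), 1:20)
})

test_that("position interneurons are antagonistic", {
  cfg <- small_cfg(c(0, 180))
  # masks select disjoint hair sets
  pl <- cfg$plate
  n <- pl$field_neg$n_hairs
  neg_idx <- which(pl$mask_neg)
  pos_idx <- which(pl$mask_pos) + n
  expect_length(intersect(neg_idx, pos_idx), 0)
  # far into the positive half-range: pos_plus fires, pos_minus silent
  sens <- run_sensory_layer(constant_trace(170, duration = 1000), cfg)
  pos <- run_position_ins(sens, cfg)
  expect_gt(nrow(pos$pos_plus), 10)
  expect_equal(nrow(pos$pos_minus), 0)
})

test_that("raising the position weight raises rate and worsens the overshoot", {
  tr <- resample_trace(synthetic_gait(2500, seed = 13), 0.25)
  cfg1 <- default_joint_config(range(tr$theta), n_hairs = 20, extended = FALSE)
  sens <- run_sensory_layer(tr, cfg1)
  score <- function(om) {
    cfg <- cfg1
    cfg$pos_lif <- lif_params(tau = 120, omega = om)
    pos <- run_position_ins(sens, cfg)
    enc <- structure(list(trace = tr, cfg = cfg, pos_plus = pos$pos_plus,
                          pos_minus = pos$pos_minus),
                     class = "joint_encoding")
    c(rate = max(spike_rate(pos$pos_plus)$rate),
      mse = position_error(enc)$mse)
  }
  s1 <- score(1); s2 <- score(2)
  expect_gt(s2["rate"], s1["rate"])
  expect_gt(s2["mse"], s1["mse"])
})

test_that("velocity interneurons are direction-selective with bounded carryover", {
  cfg <- default_joint_config(c(0, 180), n_hairs = 25)
  sw <- constant_velocity_sweep(150, range = c(0, 180), dt = 0.25)$trace[[1]]
  enc <- encode_joint(sw, cfg)
  half_ms <- 180 / 150 * 1000
  rising <- function(tt) (tt %% (2 * half_ms)) < half_ms
  carry <- 3 * cfg$adex$tau_w
  since_reversal <- function(tt) tt %% half_ms
  # vel- spikes during rising phases only within the carryover window
  bad_minus <- enc$vel_minus$time[rising(enc$vel_minus$time)]
  expect_true(all(since_reversal(bad_minus) <= carry))
  bad_plus <- enc$vel_plus$time[!rising(enc$vel_plus$time)]
  expect_true(all(since_reversal(bad_plus) <= carry))
  # both directions encoded
  expect_gt(nrow(enc$vel_plus), 50)
  expect_gt(nrow(enc$vel_minus), 50)
})

test_that("a stationary joint silences the velocity interneurons after settling", {
  cfg <- default_joint_config(c(0, 180), n_hairs = 25)
  enc <- encode_joint(constant_trace(121, duration = 2000), cfg)
  settle <- 5 * cfg$adex$tau_w
  expect_equal(sum(enc$vel_plus$time > settle), 0)
  expect_equal(sum(enc$vel_minus$time > settle), 0)
})

test_that("velocity chain demands an extended plate", {
  cfg <- default_joint_config(c(0, 180), n_hairs = 10, extended = FALSE)
  sens <- run_sensory_layer(constant_trace(90, duration = 100), cfg)
  expect_error(run_velocity_ins(sens, cfg), "extended")
})

test_that("encode_joint equals the composition of the layer runners", {
  cfg <- small_cfg(c(20, 160))
  tr <- resample_trace(synthetic_gait(800, seed = 4, working_range = c(30, 150)),
                       0.25)
  enc <- encode_joint(tr, cfg)
  sens <- run_sensory_layer(tr, cfg)
  pos <- run_position_ins(sens, cfg)
  vel <- run_velocity_ins(sens, cfg)
  expect_equal(enc$sensory$time, sens$time)
  expect_equal(enc$pos_plus$time, pos$pos_plus$time)
  expect_equal(enc$vel_minus$time, vel$vel_minus$time)
})

test_that("whole-body runs have the right architecture and are order-independent", {
  legs <- c("R1", "R2", "R3", "L1", "L2", "L3")
  joints <- c("alpha", "beta", "gamma")
  grid <- tidyr::expand_grid(leg = legs, joint = joints)
  grid$trace <- purrr::pmap(grid, function(leg, joint) {
    synthetic_gait(300, seed = match(leg, legs) * 10 + match(joint, joints),
                   joint = joint, leg = leg)
  })
  body <- simulate_body(grid, n_hairs = 50, velocity = TRUE)
  expect_equal(nrow(body), 18)
  # 3 x 2 x N_h mechanosensory neurons per leg -> 1800 in total
  n_sensory <- sum(purrr::map_int(body$encoding, function(e) {
    2L * e$cfg$plate$field_neg$n_hairs
  }))
  expect_equal(n_sensory, 1800)
  # 2 position + 2 velocity INs per joint -> 36 + 36
  count_ins <- function(e, names) sum(!vapply(e[names], is.null, logical(1)))
  expect_equal(sum(purrr::map_int(body$encoding, count_ins,
                                  c("pos_plus", "pos_minus"))), 36)
  expect_equal(sum(purrr::map_int(body$encoding, count_ins,
                                  c("vel_plus", "vel_minus"))), 36)

  # permuting the rows leaves every per-joint output identical
  set.seed(1)
  shuffled <- simulate_body(grid[sample(18), ], n_hairs = 50, velocity = TRUE)
  for (i in c(1, 7, 18)) {
    key <- paste(body$leg[i], body$joint[i])
    j <- which(paste(shuffled$leg, shuffled$joint) == key)
    expect_identical(body$encoding[[i]]$sensory$time,
                     shuffled$encoding[[j]]$sensory$time)
    expect_identical(body$encoding[[i]]$vel_plus$time,
                     shuffled$encoding[[j]]$vel_plus$time)
  }

  # missing traces are reported by joint
  grid_bad <- grid
  grid_bad$trace[3] <- list(NULL)
  expect_error(simulate_body(grid_bad), paste0(grid$leg[3], ":", grid$joint[3]))
})

test_that("repeated runs are bit-identical", {
  cfg <- small_cfg(c(0, 180))
  tr <- resample_trace(synthetic_gait(600, seed = 8), 0.25)
  e1 <- encode_joint(tr, cfg)
  e2 <- encode_joint(tr, cfg)
  expect_identical(tidy(e1), tidy(e2))
})

test_that("cutoff calibration lands just above the tonic plateau", {
  cfg <- default_joint_config(c(0, 180))
  cal <- calibrate_cutoff(cfg)
  expect_equal(cal$omega_hp, 10.5)
  expect_gt(cal$f_c, cal$f_ss)
  expect_false(cal$degenerate)
  # the published table value admits tonic leakage under this scheme
  row_108 <- cal$grid[abs(cal$grid$omega - 10.8) < 1e-9, ]
  expect_false(row_108$blocks_tonic)
  # a weight above the threshold gap passes every input spike (degenerate)
  pre <- seq(0, 500, by = 3)
  out <- integrate_lif(pre, lif_params(tau = 5, omega = 25), dt = 0.25,
                       duration = 500)
  expect_equal(nrow(out), length(pre))
})

test_that("a 9 mV high-pass weight encodes low velocities only weakly", {
  cfg9 <- default_joint_config(c(0, 180), n_hairs = 25,
                               hp_lif = lif_params(tau = 5, omega = 9))
  cfg  <- default_joint_config(c(0, 180), n_hairs = 25)
  r9 <- velocity_rate_curve(speeds = c(50, 100), cfg = cfg9)
  r  <- velocity_rate_curve(speeds = c(50, 100), cfg = cfg)
  expect_true(all(r9$rate < 0.5 * r$rate))
})
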
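test_that("receptive-field edges match the worked five-hair geometry", {
  edges <- receptive_field_edges(fig2a_field())
  expect_equal(edges$rf0[1], 0)    # forced to theta_min
  expect_equal(edges$rf90[5], 92)  # forced to theta_max
  expect_equal(edges$rf0[2], 92 / 5 * 1 + 0 - 2)  # 16.4
  expect_equal(edges$rf90[2], 92 / 5 * 2 + 2)     # 38.8

  single <- receptive_field_edges(hair_field(1, 10, 50))
  expect_equal(c(single$rf0, single$rf90), c(10, 50))
})

test_that("hair deflection follows the clamped linear law", {
  f <- fig2a_field()
  edges <- receptive_field_edges(f)
  # below rf0 -> 0, above rf90 -> 90
  expect_equal(unname(hair_angles(f, -5)[1, ]), rep(0, 5))
  expect_equal(unname(hair_angles(f, 100)[1, ]), rep(90, 5))
  # hair 5 at 90 degrees: 90*(90-71.6)/20.4
  expect_equal(unname(hair_angles(f, 90)[1, 5]), 90 * (90 - 71.6) / 20.4,
               tolerance = 1e-12)
  # matches the independent scalar oracle on a grid
  for (th in seq(-10, 100, by = 7)) {
    for (i in 1:5) {
      expect_equal(unname(hair_angles(f, th)[1, i]),
                   scalar_phi(th, i, 5, 0, 92, 4), tolerance = 1e-12)
    }
  }
})

test_that("negative orientation mirrors the positive law", {
  f_neg <- hair_field(5, 0, 92, overlap = 4, orientation = "negative")
  f_mir <- hair_field(5, 180 - 92, 180, overlap = 4)
  grid <- seq(-5, 185, by = 3)
  phi_neg <- hair_angles(f_neg, grid)
  phi_mir <- hair_angles(f_mir, 180 - grid)
  # hair i of the negative field corresponds to hair n+1-i of the mirror
  for (i in 1:5) {
    expect_equal(unname(phi_neg[, i]), unname(phi_mir[, 5 + 1 - i]),
                 tolerance = 1e-9)
  }
})

test_that("randomized fields keep coverage, overlap and monotonicity", {
  set.seed(3)
  for (case in 1:50) {
    n <- sample(2:40, 1)
    lo <- runif(1, -90, 90)
    hi <- lo + runif(1, 5, 180)
    ol <- runif(1, 0, 0.9 * (hi - lo) / n)
    f <- hair_field(n, lo, hi, ol)
    e <- receptive_field_edges(f)
    # coverage: union of receptive fields is exactly [lo, hi]
    expect_equal(e$rf0[1], lo)
    expect_equal(e$rf90[n], hi)
    expect_true(all(e$rf0[-1] <= e$rf90[-n] + 1e-12)) # no gaps
    # monotone fractionation
    expect_true(all(diff(e$rf0) > 0))
    expect_true(all(diff(e$rf90) > 0))
    # adjacent interior overlaps equal the configured value
    expect_equal(e$rf90[-n] - e$rf0[-1], rep(ol, n - 1), tolerance = 1e-9)
    # saturation: non-decreasing deflection, bounded in [0, 90]
    grid <- seq(lo - 5, hi + 5, length.out = 41)
    phi <- hair_angles(f, grid)
    expect_true(all(phi >= 0 & phi <= 90))
    expect_true(all(apply(phi, 2, function(col) all(diff(col) >= -1e-12))))
  }
})

test_that("deflection-to-current conversion and gain validation", {
  expect_equal(hair_currents(0, gain = 50), 0)
  expect_equal(hair_currents(90, gain = 50), 4500) # 4.5 nA
  tr <- ramp_and_hold(980, 37)
  cur <- hair_currents(tr, gain = 50)
  expect_named(cur, c("t", "I"))
  expect_equal(max(cur$I), 37 * 50)
  expect_error(hair_currents(10, gain = 0), "positive")
  expect_error(hair_plate(c(0, 180), gain = 5), "10-150")
  expect_error(hair_plate(c(0, 180), gain = 200), "10-150")
})

test_that("plate construction reproduces the documented scenarios", {
  # opposing half-range fields with a 4-degree overlap at the 90-degree rest
  plA <- hair_plate(c(0, 180), n_hairs = 5, overlap = 4)
  expect_equal(plA$field_neg$theta_min, 0)
  expect_equal(plA$field_neg$theta_max, 92)
  expect_equal(plA$field_pos$theta_min, 88)
  expect_equal(plA$field_pos$theta_max, 180)
  expect_equal(overlap_at_rest(plA), 4)
  expect_true(all(plA$mask_neg) && all(plA$mask_pos))

  # abutting fields
  expect_equal(overlap_at_rest(hair_plate(c(0, 180), n_hairs = 5, overlap = 0)), 0)

  # extended plate: both fields span the full range
  plB <- hair_plate(c(0, 180), n_hairs = 10, overlap = 4, extended = TRUE)
  expect_equal(plB$field_pos$theta_min, 0)
  expect_equal(plB$field_neg$theta_max, 180)

  # network default: 100 hairs, 25 position-wired per field, 0.1 deg overlap
  pl <- hair_plate(c(0, 180), n_hairs = 50, extended = TRUE)
  expect_equal(pl$field_neg$n_hairs + pl$field_pos$n_hairs, 100)
  expect_equal(sum(pl$mask_neg), 25)
  expect_equal(sum(pl$mask_pos), 25)
  expect_equal(overlap_at_rest(pl), 0.1)

  expect_error(hair_plate(c(100, 0)), "increasing")
})

test_that("at rest exactly the innermost position-wired hair of each field is partially deflected", {
  pl <- hair_plate(c(0, 180), n_hairs = 50, extended = TRUE)
  phi <- plate_angles(pl, pl$resting_angle)[1, ]
  masked <- c(pl$mask_neg, pl$mask_pos)
  partial <- which(phi > 0 & phi < 90 & masked)
  # plate indices 25 (negative field) and 76 (= 26th of the positive field):
  # the 25th and 26th position-wired hairs in raster numbering
  expect_equal(unname(partial), c(25, 76))
})
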
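test_that("differentiate matches closed-form derivatives", {
  # ramp
  x <- seq(0, 1, by = 0.01)
  expect_equal(differentiate(x, 0.01), rep(1, length(x)))
  # constant
  expect_equal(differentiate(rep(5, 20), 0.01), rep(0, 20))
  # sinusoid at 1000 Hz vs analytic derivative on interior points
  t <- seq(0, 1, by = 1e-3)
  v <- differentiate(sin(2 * pi * t), 1e-3)
  truth <- 2 * pi * cos(2 * pi * t)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(v[interior] - truth[interior])), 1e-3)
  expect_error(differentiate(c(1, 2), 0.1), "at least 3")
})

test_that("amplitude normalization maps range to [-1, 1] and preserves velocity sign", {
  nm <- normalize_amplitude(c(0, 5, 10), c(-4, 0, 2))
  expect_equal(nm$x_norm, c(-1, 0, 1))
  expect_equal(nm$v_norm, c(-1, 0, 0.5))

  t <- seq(0, 1, length.out = 256)
  x <- sin(2 * pi * t)
  nm <- normalize_amplitude(x, differentiate(x, t[2]))
  expect_equal(min(nm$x_norm), -1, tolerance = 1e-9)
  expect_equal(max(nm$x_norm), 1, tolerance = 1e-9)
  expect_lte(max(abs(nm$v_norm)), 1 + 1e-9)

  # idempotence: normalizing an already-normalized pair changes nothing
  nm2 <- normalize_amplitude(nm$x_norm, nm$v_norm)
  expect_equal(nm2$x_norm, nm$x_norm, tolerance = 1e-12)
  expect_equal(nm2$v_norm, nm$v_norm, tolerance = 1e-12)

  expect_error(normalize_amplitude(rep(3, 10), 1:10), "zero range")
  expect_error(normalize_amplitude(1:10, rep(0, 10)), "identically zero")
})

test_that("phase angle follows the four-quadrant convention and unwraps", {
  expect_equal(phase_angle(1, 0), 0)
  expect_equal(phase_angle(0, 1), 90)
  # counterclockwise unit-circle trajectory, 64 points/rev over 2 revolutions
  a <- seq(0, 4 * pi, length.out = 129)
  phi <- phase_angle(cos(a), sin(a))
  expect_true(all(diff(phi) > 0))
  expect_equal(phi[129] - phi[1], 720, tolerance = 1e-6)
  expect_lt(max(abs(diff(phi))), 180)
  expect_error(phase_angle(c(1, 0), c(0, 0)), "sample 2")
})

test_that("relative phase recovers constant offsets of phase-angle series", {
  phi <- seq(0, 360, length.out = 101)
  expect_equal(relative_phase(phi, phi), rep(0, 101))
  expect_equal(relative_phase(phi + 30, phi), rep(30, 101))
  expect_error(relative_phase(phi, phi[-1]), "lengths differ")

  # sinusoids with a 45-degree offset: mean CRP within 1 degree
  # (amplitude-normalization distortion bounded)
  s <- sin_pair(45, n = 101)
  theta <- crp_phase_route(s$distal, s$proximal, s$dt)
  expect_lt(abs(mean(theta) - 45), 1)
})

test_that("direct-formula CRP matches the phase-angle route and in-phase identity", {
  t <- seq(0, 1, length.out = 300)
  x <- sin(2 * pi * t)
  expect_lt(max(abs(relative_phase_direct(x, x, t[2]))), 1e-9)

  s <- sin_pair(90, n = 500)
  theta <- relative_phase_direct(s$distal, s$proximal, s$dt)
  expect_lt(max(abs(theta - 90)), 1)

  for (delta in c(-150, -90, -45, 0, 30, 45, 90, 120, 180)) {
    s <- sin_pair(delta, n = 400)
    th_direct <- relative_phase_direct(s$distal, s$proximal, s$dt)
    th_phase <- crp_phase_route(s$distal, s$proximal, s$dt)
    expect_lt(max(abs(th_direct - th_phase)), 1e-6)
    if (abs(delta) < 180) {
      expect_lt(abs(mean(th_phase) - delta), 1)
    } else {
      expect_lt(abs(abs(mean(th_phase)) - 180), 1)
    }
  }

  # the minus-sign denominator variant does not satisfy the in-phase identity
  th_printed <- relative_phase_direct(x, x, t[2], denominator = "printed")
  expect_gt(max(abs(th_printed)), 1)
})

test_that("positive CRP slope means the distal phase angle advances faster", {
  # chirped distal against steady proximal: the sign of the CRP slope must
  # track the sign of the phase-rate difference pointwise
  t <- seq(0, 1, length.out = 800)
  dt <- t[2] - t[1]
  xd <- sin(2 * pi * (t + 0.15 * sin(2 * pi * t)))
  xp <- sin(2 * pi * t)
  pd <- normalize_amplitude(xd, differentiate(xd, dt))
  pp <- normalize_amplitude(xp, differentiate(xp, dt))
  phi_d <- phase_angle(pd$x_norm, pd$v_norm)
  phi_p <- phase_angle(pp$x_norm, pp$v_norm)
  theta <- relative_phase(phi_d, phi_p)
  slope_theta <- diff(theta)
  rate_diff <- diff(phi_d) - diff(phi_p)
  expect_equal(sign(slope_theta), sign(rate_diff))
  # unwrapping keeps adjacent jumps below 180 degrees
  expect_lt(max(abs(diff(phi_d))), 180)
  expect_lt(max(abs(diff(theta))), 180)
})

test_that("time normalization interpolates onto the 0-100% grid", {
  # linear series are reproduced exactly for any grid size
  lin <- seq(2, 8, length.out = 37)
  cyc <- time_normalize(lin, 25)
  expect_equal(cyc$values, seq(2, 8, length.out = 25), tolerance = 1e-12)
  expect_equal(cyc$cycle_fraction[1], 0)
  expect_equal(cyc$cycle_fraction[25], 100)

  # N equal to the input length is an identity
  x <- sin(seq(0, 2 * pi, length.out = 51))
  expect_equal(time_normalize(x, 51)$values, x, tolerance = 1e-12)

  # downsample then upsample a band-limited sinusoid: small interpolation error
  fine <- sin(2 * pi * seq(0, 1, length.out = 401))
  down <- time_normalize(fine, 101)
  up <- time_normalize(down$values, 401)
  expect_lt(max(abs(up$values - fine)), 1e-3)

  expect_error(time_normalize(x, 10), ">= 11")
  expect_error(time_normalize(c(1, 2, 3), 101), "at least 4")
})

test_that("crp_curve runs the per-trial pipeline end to end", {
  tr <- simulate_joint_cycle(c("ankle-knee" = 45, "knee-pelvis" = 30),
                             n_samples = 400)
  cv <- crp_curve(tr, c("ankle", "knee"))
  expect_s3_class(cv, "crp_curve")
  expect_length(cv$theta, 101)
  expect_true(all(is.finite(cv$theta)))
  expect_lt(abs(marp(cv) - 45), 1)
  # direct method agrees after time normalization
  cv2 <- crp_curve(tr, c("ankle", "knee"), method = "direct")
  expect_equal(cv$theta, cv2$theta, tolerance = 1e-6)
  expect_error(crp_curve(tr, c("ankle", "hip")), "hip")
})
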
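# Pure-sinusoid coupling with a known relative phase: the distal joint is
# delayed by `delta_deg`, so the CRP of (distal, proximal) equals +delta_deg.
sin_pair <- function(delta_deg, n = 500, cycles = 1) {
  t <- seq(0, cycles, length.out = n)
  list(
    distal = sin(2 * pi * t - delta_deg * pi / 180),
    proximal = sin(2 * pi * t),
    dt = t[2] - t[1]
  )
}

# CRP via the two-phase-angle route on raw (non-time-normalized) samples
crp_phase_route <- function(distal, proximal, dt) {
  pd <- normalize_amplitude(distal, differentiate(distal, dt))
  pp <- normalize_amplitude(proximal, differentiate(proximal, dt))
  relative_phase(phase_angle(pd$x_norm, pd$v_norm),
                 phase_angle(pp$x_norm, pp$v_norm))
}

# small deterministic cohort parameters for structural tests
tiny_params <- function(...) {
  ak <- "ankle-knee"; kp <- "knee-pelvis"
  offs <- function(a, k) stats::setNames(c(a, k), c(ak, kp))
  args <- utils::modifyList(list(
    offsets = list(
      control = list(pre = offs(20, 25), post = offs(30, 28)),
      test = list(pre = offs(20, 25), post = offs(30, 28)),
      target = list(single = offs(60, 35))
    ),
    sd_between = list(
      control = list(pre = offs(3, 3), post = offs(3, 3)),
      test = list(pre = offs(3, 3), post = offs(3, 3)),
      target = list(single = offs(6, 6))
    ),
    sd_jitter = list(
      control = list(pre = 1, post = 1),
      test = list(pre = 1, post = 1),
      target = list(single = 1)
    ),
    n_subjects = c(control = 3L, test = 3L, target = 3L),
    trials_per_subject = 3L,
    samples_per_cycle = 100L
  ), list(...))
  do.call(sim_params, args)
}

expect_tibble_equal_num <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
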
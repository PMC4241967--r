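test_that("b-value follows the pulsed-gradient formula", {
  sq <- sequence_params(g_amplitude = 30e-3, delta = 20, Delta = 35)
  # hand computation: (2.675e8 * 0.03 * 0.02)^2 * (0.035 - 0.02/3) * 1e-6
  expect_equal(b_value(sq), 729.8737, tolerance = 1e-6)
  expect_equal(b_value(sequence_params(g_amplitude = 30e-3, delta = 0,
                                       Delta = 35)), 0)
  # doubling g quadruples b
  sq2 <- sequence_params(g_amplitude = 60e-3, delta = 20, Delta = 35)
  expect_equal(b_value(sq2), 4 * b_value(sq))
  expect_error(sequence_params(g_amplitude = 30e-3, delta = 40, Delta = 35),
               "at least")
  expect_equal(b_value(sequence_params(b = 600)), 600)
})

test_that("echo attenuation and relative drop match direct arithmetic", {
  expect_equal(echo_attenuation(1, 600, 2.00e-10), exp(-0.12))
  expect_equal(round(echo_attenuation(1, 600, 2.00e-10), 4), 0.8869)
  expect_equal(round(echo_attenuation(1, 600, 2.128e-10), 4), 0.8801)
  expect_equal(echo_attenuation(0.5, 0, 2e-10), 0.5)
  expect_error(echo_attenuation(1, -1, 2e-10), "non-negative")

  expect_equal(signif(100 * relative_signal_drop(600, 2.00e-10, 2.128281e-10), 2),
               0.77)
  expect_equal(signif(100 * relative_signal_drop(600, 2.00e-10, 2.119729e-10), 2),
               0.72)
  expect_equal(relative_signal_drop(600, 2e-10, 2e-10), 0)
  # monotone increasing in b and in the diffusivity change
  drops_b <- relative_signal_drop(c(200, 600, 1000), 2e-10, 2.13e-10)
  expect_true(all(diff(drops_b) > 0))
  drops_d <- relative_signal_drop(600, 2e-10, c(2.05, 2.13, 2.3) * 1e-10)
  expect_true(all(diff(drops_d) > 0))
  # first-order Taylor check: drop ~ b * dD for small arguments
  dd <- 1e-12
  expect_equal(relative_signal_drop(600, 2e-10, 2e-10 + dd),
               600 * dd * 1e6, tolerance = 1e-3)
})

test_that("detectability uses the z/SNR threshold", {
  d <- detectable(0.0077, 400, z = 3)
  expect_true(d$detectable)
  expect_equal(d$margin, 0.0077 - 0.0075)
  expect_false(detectable(0, 400)$detectable)
  expect_false(detectable(0.0077, 100, z = 3)$detectable)
  expect_error(detectable(0.01, 0), "positive")
})

test_that("gradient schemes are unit-norm and round-trip through files", {
  sch <- gradient_scheme(30, b = 600, n_b0 = 1)
  expect_equal(nrow(sch), 31)
  nrm <- with(sch[sch$bval > 0, ], sqrt(gx^2 + gy^2 + gz^2))
  expect_equal(nrm, rep(1, 30), tolerance = 1e-9)
  expect_error(gradient_scheme_from_table(
    data.frame(bval = 600, gx = 1, gy = 1, gz = 0)), "unit")
  # two-file layout
  bv <- tempfile(); gv <- tempfile()
  write_gradient_scheme(sch, bv, gv)
  back <- read_gradient_scheme(bv, gv)
  expect_equal(unname(as.matrix(back)), unname(as.matrix(sch)),
               tolerance = 1e-12)
  # single-file four-column layout
  one <- tempfile()
  write_gradient_scheme(sch, one)
  expect_equal(unname(as.matrix(read_gradient_scheme(one))),
               unname(as.matrix(sch)), tolerance = 1e-12)
})

test_that("synthesized signals reduce to the scalar attenuation law", {
  st <- tensor_state(1e-9, 2e-10, 2e-10)
  tab <- data.frame(bval = c(0, 600, 600),
                    gx = c(0, 1, 0), gy = c(0, 0, 0), gz = c(0, 0, 1))
  sch <- gradient_scheme_from_table(tab)
  s <- synthesize_signal(st, sch, A0 = 2)      # fiber along z
  expect_equal(s[1], 2)                        # b = 0
  expect_equal(s[2], 2 * exp(-0.12))           # perpendicular -> lambda2
  expect_equal(s[3], 2 * exp(-0.6))            # parallel -> lambda1
})

test_that("tensor fitting inverts signal synthesis", {
  sch <- gradient_scheme(30)
  st <- tensor_state(1e-9, 2e-10, 2e-10)
  fit <- fit_tensor(synthesize_signal(st, sch), sch)
  expect_equal(fit$eigenvalues, as.numeric(st), tolerance = 1e-10)
  expect_equal(fit$A0, 1, tolerance = 1e-10)
  # random tensors and orientations round-trip below 1e-8 relative error
  set.seed(11)
  for (i in 1:25) {
    l <- sort(runif(3, 1e-10, 2.5e-9), decreasing = TRUE)
    st_i <- tensor_state(l[1], l[2], l[3])
    R <- random_rotation()
    fit_i <- fit_tensor(synthesize_signal(st_i, sch, axis = R), sch)
    expect_lt(max(abs(fit_i$eigenvalues - l) / l), 1e-8)
  }
  # isotropic signals fit to FA ~ 0
  iso <- fit_tensor(synthesize_signal(tensor_state(7e-10, 7e-10, 7e-10), sch),
                    sch)
  expect_lt(iso$fa, 1e-8)
})

test_that("activation pipeline closes through synthesis and refitting", {
  m <- adti_model()
  sch <- gradient_scheme(30)
  fa0 <- fit_tensor(synthesize_signal(m$inactive, sch), sch)$fa
  fa1 <- fit_tensor(synthesize_signal(m$active, sch), sch)$fa
  expect_equal((fa1 - fa0) / fa0, m$rel_change_FA, tolerance = 1e-6)
  expect_equal(signif(100 * (fa1 - fa0) / fa0, 2), -2.1)
})

test_that("fitted FA is invariant under joint rotation", {
  sch <- gradient_scheme(30)
  st <- tensor_state(1.4e-9, 4e-10, 1.5e-10)
  fa_ref <- fit_tensor(synthesize_signal(st, sch, axis = diag(3)), sch)$fa
  set.seed(3)
  for (i in 1:10) {
    R <- random_rotation()
    G <- as.matrix(sch[c("gx", "gy", "gz")]) %*% t(R)
    sch_rot <- gradient_scheme_from_table(
      data.frame(bval = sch$bval, gx = G[, 1], gy = G[, 2], gz = G[, 3]))
    fa_rot <- fit_tensor(synthesize_signal(st, sch_rot, axis = R), sch_rot)$fa
    expect_equal(fa_rot, fa_ref, tolerance = 1e-6)
  }
})

test_that("degenerate schemes and bad signals are rejected", {
  # collinear directions: rank-deficient design
  tab <- data.frame(bval = c(0, rep(600, 6)), gx = c(0, rep(1, 6)),
                    gy = 0, gz = 0)
  sch <- gradient_scheme_from_table(tab)
  expect_error(fit_tensor(rep(1, 7), sch), "degenerate")
  sch30 <- gradient_scheme(30)
  s <- synthesize_signal(tensor_state(1e-9, 2e-10, 2e-10), sch30)
  s[5] <- -0.1
  expect_warning(fit_tensor(s, sch30), "masking")
  expect_error(fit_tensor(s[-1], sch30), "length")
})
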
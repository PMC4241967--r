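test_that("fast-water fraction is flux x time over resident water", {
  fl <- total_flux(cst_bundle())
  f <- fast_water_fraction(fl, activation_params(),
                           resident_water_mass = water_mass_in_volume(3.5))
  expect_equal(signif(f, 3), 4.28e-3)
  expect_equal(fast_water_fraction(1e-6, activation_params(diffusion_time = 10),
                                   resident_water_mass = 0.01), 1e-3)
  expect_equal(fast_water_fraction(0, activation_params(),
                                   resident_water_mass = 0.01), 0)
  # exchanged water exceeding resident water is a model breakdown
  expect_error(fast_water_fraction(1, activation_params(),
                                   resident_water_mass = 0.01),
               "breakdown")
})

test_that("active perpendicular diffusivity supports both mixing modes", {
  f <- 4.276036e-3
  expect_equal(signif(d_perp_active(f, 2e-10, 3e-9, "approx"), 3), 2.13e-10)
  expect_equal(signif(d_perp_active(f, 2e-10, 3e-9, "exact"), 4), 2.12e-10)
  # the two modes differ by exactly the dropped term f * D_perp
  expect_equal(d_perp_active(f, 2e-10, 3e-9, "approx") -
                 d_perp_active(f, 2e-10, 3e-9, "exact"),
               f * 2e-10)
  expect_equal(d_perp_active(0, 2e-10, 3e-9, "approx"), 2e-10)
  expect_equal(d_perp_active(0, 2e-10, 3e-9, "exact"), 2e-10)
  expect_error(d_perp_active(1.2, 2e-10, 3e-9), "\\[0, 1\\]")
  expect_error(d_perp_active(0.1, 2e-10, 3e-9, mode = "banana"))
})

test_that("apparent diffusion coefficient is the eigenvalue mean", {
  expect_equal(d_app(tensor_state(1e-9, 2e-10, 2e-10)), 1.4e-9 / 3)
  expect_equal(d_app(tensor_state(7e-10, 7e-10, 7e-10)), 7e-10)
  m <- adti_model()
  expect_equal(signif(m$D_app_star, 3), 4.75e-10)
})

test_that("fractional anisotropy matches the axially symmetric closed form", {
  # general-eigenvalue formula vs closed form, machine precision
  for (dperp in c(1e-10, 2e-10, 5e-10)) {
    expect_equal(fractional_anisotropy(tensor_state(1e-9, dperp, dperp)),
                 fa_closed_form(1e-9, dperp), tolerance = 1e-14)
  }
  expect_equal(round(fractional_anisotropy(tensor_state(1e-9, 2e-10, 2e-10)), 3),
               0.770)
  expect_equal(round(fractional_anisotropy(
    tensor_state(1e-9, 2.128281e-10, 2.128281e-10)), 3), 0.754)
  expect_equal(fractional_anisotropy(c(5e-10, 5e-10, 5e-10)), 0)
  expect_error(fractional_anisotropy(c(0, 0, 0)), "undefined|positive")
  # FA of any positive triple lies in [0, 1)
  set.seed(7)
  for (i in 1:50) {
    l <- sort(runif(3, 1e-11, 3e-9), decreasing = TRUE)
    fa <- fractional_anisotropy(tensor_state(l[1], l[2], l[3]))
    expect_gte(fa, 0)
    expect_lt(fa, 1)
  }
})

test_that("the full activation pipeline reproduces the predicted changes", {
  m <- adti_model()
  expect_equal(signif(100 * m$rel_change_D_app, 2), 1.8)
  expect_equal(signif(100 * m$rel_change_FA, 2), -2.1)
  expect_lt(m$FA_star, m$FA)                    # anisotropy decreases
  expect_gt(m$D_app_star, m$D_app)              # mean diffusivity increases
  expect_equal(m$active[["lambda1"]], m$inactive[["lambda1"]])  # lambda1 fixed
  expect_gt(m$active[["lambda2"]], m$inactive[["lambda2"]])
  # zero channel densities: active state identical to inactive
  m0 <- adti_model(channels = channel_biophysics(rho_node = 0,
                                                 rho_unmyelinated = 0))
  expect_identical(unclass(m0$active), unclass(m0$inactive))
  expect_identical(m0$FA_star, m0$FA)
  expect_identical(m0$rel_change_FA, 0)
})

test_that("FA_star decreases and D_app_star increases monotonically in f_w*", {
  p <- activation_params()
  f_grid <- seq(0, 0.05, by = 0.005)
  dps <- vapply(f_grid, d_perp_active, numeric(1), d_perp = p$D_perp,
                d_free = p$D_free)
  fas <- vapply(dps, function(d)
    fractional_anisotropy(tensor_state(p$D_parallel, d, d)), numeric(1))
  dapps <- vapply(dps, function(d)
    d_app(tensor_state(p$D_parallel, d, d)), numeric(1))
  expect_true(all(diff(fas) < 0))
  expect_true(all(diff(dapps) > 0))
})

test_that("model object methods expose parameters, predictions and summary", {
  m <- adti_model()
  cf <- coef(m)
  expect_equal(cf[["diffusion_time"]], 35)
  expect_equal(cf[["D_perp"]], 2e-10)
  pr <- predict(m, b = 600)
  expect_equal(pr$signal_inactive, exp(-600 * 2e-10 * 1e6))
  expect_equal(signif(100 * pr$rel_drop, 2), 0.77)
  pr_par <- predict(m, b = 600, direction = "parallel")
  expect_equal(pr_par$signal_inactive, exp(-0.6))
  expect_equal(pr_par$rel_drop, 0)              # lambda1 unchanged
  s <- summary(m, b = 600, snr = 400)
  expect_true(s$detection$detectable)
  expect_output(print(s), "echo drop")
  # duty-cycle factor scales f_w* linearly
  m_half <- adti_model(params = activation_params(duty_cycle = 0.5))
  expect_equal(m_half$f_w_star, m$f_w_star / 2)
})
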
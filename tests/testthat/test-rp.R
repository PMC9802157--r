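eos <- t1_eos()
rigid <- table1_medium(E = Inf)

test_that("bubble pressure follows the vapor and polytropic-gas models", {
  pv <- forcing_spec("static", bubble = "pure_vapor")
  expect_equal(bubble_pressure(c(1e-6, 1e-4), pv, eos, 1e-4),
               c(2339, 2339))
  ncg <- forcing_spec("static", bubble = "ncg", p_g0 = 100, eta = 1.4)
  R0 <- 1e-4
  expect_equal(bubble_pressure(R0, ncg, eos, R0), 2339 + 100)
  expect_equal(bubble_pressure(R0 / 2, ncg, eos, R0),
               2339 + 100 * 2^4.2, tolerance = 1e-14)
  expect_error(bubble_pressure(0, ncg, eos, R0), "positive")
})

test_that("boundary pressure reproduces static and sinusoidal forcing", {
  st <- forcing_spec("static", rho_L = 998)
  p0 <- eos_pressure(eos, 998)
  expect_equal(boundary_pressure(c(0, 1), st, eos), c(p0, p0))
  u1 <- forcing_spec("ultrasound", rho_L = 998, p_amp = 1e6, freq = 20e3,
                     s = 1)
  u2 <- forcing_spec("ultrasound", rho_L = 998, p_amp = 1e6, freq = 20e3,
                     s = 2)
  expect_equal(boundary_pressure(0, u1, eos), p0)
  # s = 1 raises the pressure over the first quarter period (collapse
  # first); s = 2 lowers it (expansion first)
  expect_equal(boundary_pressure(1 / (4 * 20e3), u1, eos), p0 + 1e6)
  expect_equal(boundary_pressure(1 / (4 * 20e3), u2, eos), p0 - 1e6)
  expect_error(forcing_spec("ultrasound", p_amp = 1e6), "frequency")
})

test_that("beta reduces to the Darcy value in the rigid limit", {
  params <- prp_params(1e-3, 0.5e-3, rigid, eos, rho_l = 998)
  p_L <- eos_pressure(eos, 998)
  b <- beta_coefficient(p_L, eos$p_sat, params, eos)
  # independent arithmetic: k (p_L - p_sat) / (phi0 mu_l)
  expect_equal(b, 2.8811819e-5, tolerance = 1e-7)
  expect_equal(b, 1e-13 * (p_L - 2339) / (0.01 * 1e-3), tolerance = 1e-14)
})

test_that("any deformable medium reduces beta and preserves its sign", {
  p_L <- eos_pressure(eos, 998)
  pr <- prp_params(1e-3, 0.5e-3, rigid, eos)
  br <- beta_coefficient(p_L, eos$p_sat, pr, eos)
  for (E in c(1e3, 15e3, 1e6)) {
    ps <- prp_params(1e-3, 0.5e-3, table1_medium(E = E, nu = 0.45), eos,
                     rho_R = 950)
    bs <- beta_coefficient(p_L, eos$p_sat, ps, eos)
    expect_lt(bs, br)
    expect_gt(bs, 0)
    # sign follows p_L - p_B
    expect_lt(beta_coefficient(eos$p_sat, p_L, ps, eos), 0)
  }
})

test_that("closed-form collapse time has the stated limits", {
  expect_equal(collapse_time_closed_form(0.5e-3, 1e-3, 2e-5),
               (1e-3)^2 / (12 * 2e-5), tolerance = 1e-14)
  expect_equal(collapse_time_closed_form(1e-4, Inf, 2e-5),
               (1e-4)^2 / (2 * 2e-5), tolerance = 1e-14)
  # doubling beta halves the collapse time
  expect_equal(collapse_time_closed_form(1e-4, 1e-3, 4e-5),
               collapse_time_closed_form(1e-4, 1e-3, 2e-5) / 2,
               tolerance = 1e-14)
  expect_true(is.na(collapse_time_closed_form(1e-4, 1e-3, -1)))
})

test_that("integrated collapse matches the closed form to 1e-6", {
  params <- prp_params(1e-3, 0.5e-3, rigid, eos)
  spec <- static_998()
  tr <- rp_integrate(params, spec, eos, t_max = 0.01, n_out = 50)
  expect_true(attr(tr, "collapsed"))
  p_L <- eos_pressure(eos, 998)
  beta <- beta_coefficient(p_L, eos$p_sat, params, eos)
  expect_equal(rp_collapse_time(tr),
               collapse_time_closed_form(0.5e-3, 1e-3, beta),
               tolerance = 1e-6)
})

test_that("universal square-root scaling holds for L >> R0 and breaks
           for finite L", {
  spec <- static_998()
  p_L <- eos_pressure(eos, 998)
  R0 <- 1e-6
  params <- prp_params(1e3 * R0, R0, rigid, eos)
  beta <- beta_coefficient(p_L, eos$p_sat, params, eos)
  t_end <- 0.85 * R0^2 / (2 * beta)
  tr <- rp_integrate(params, spec, eos, t_max = t_end, n_out = 1500)
  that <- 2 * beta * tr$t / R0^2
  expect_lt(max(abs(tr$R / R0 - sqrt(1 - that))), 1e-3)

  # finite-size breakdown at L = 2 R0: trajectories for different beta
  # coincide on the rescaled axis but deviate from sqrt(1 - t_hat)
  rescaled <- function(scale_k) {
    med <- poroelastic_medium(E = Inf, k = 1e-13 * scale_k)
    p <- prp_params(2 * R0, R0, med, eos)
    b <- beta_coefficient(p_L, eos$p_sat, p, eos)
    t_end <- 0.95 * collapse_time_closed_form(R0, 2 * R0, b)
    trace <- rp_integrate(p, spec, eos, t_max = t_end, n_out = 400)
    list(that = 2 * b * trace$t / R0^2, Rhat = trace$R / R0)
  }
  a <- rescaled(1); b2 <- rescaled(4)
  expect_equal(a$Rhat, b2$Rhat, tolerance = 1e-6)   # scaling invariance
  expect_gt(max(abs(a$Rhat - sqrt(pmax(1 - a$that, 0)))), 0.05)
})

test_that("growth and collapse follow the pressure difference sign", {
  # p_B > p_L (gas-pressurized bubble, weak forcing): the bubble grows
  # toward the equilibrium radius where p_B = p_L, well inside the domain
  ncg <- forcing_spec("static", rho_L = 500.5, bubble = "ncg",
                      p_g0 = 5e3, eta = 1.4)
  params <- prp_params(1e-3, 1e-4, rigid, eos)
  tr <- rp_integrate(params, ncg, eos, t_max = 1e-6, n_out = 100)
  expect_gt(tr$R[100], tr$R[1])
  expect_true(all(tr$beta <= 0))
  expect_true(all(tr$R < 1e-3 & tr$R > 0))
})

test_that("non-condensable gas prevents singular collapse under
           ultrasound", {
  us <- forcing_spec("ultrasound", rho_L = 998, p_amp = 1e6, freq = 20e3,
                     s = 1, bubble = "ncg", p_g0 = 100, eta = 1.4)
  params <- prp_params(1e-3, 1e-4, rigid, eos)
  tr <- rp_integrate(params, us, eos, t_max = 2 / 20e3, n_out = 2000)
  expect_gt(min(tr$R), 0)
  expect_false(attr(tr, "collapsed"))
})

test_that("rho_R calibration recovers a known interface density", {
  med <- table1_medium(E = 15e3, nu = 0.45)
  params <- prp_params(1e-3, 0.5e-3, med, eos, rho_R = 900)
  spec <- static_998()
  tr <- rp_integrate(params, spec, eos, t_max = 1, n_out = 10)
  target <- rp_collapse_time(tr)
  fit <- calibrate_rho_R(target, params, spec, eos)
  expect_equal(fit, 900, tolerance = 1e-4)
  expect_gt(fit, eos$rho_v)
  expect_lt(fit, eos$b)
  # re-running with the calibrated value reproduces the target
  params$rho_R <- fit
  tr2 <- rp_integrate(params, spec, eos, t_max = 1, n_out = 10)
  expect_equal(rp_collapse_time(tr2), target, tolerance = 1e-6)
})
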
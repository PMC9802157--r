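eos <- t1_eos()

test_that("initial condition reproduces the step profile and its mass", {
  grid <- spherical_grid(1e-3, 256)
  R0 <- grid$L / 2
  # width -> 0 limit approaches rho_v + (rho_L - rho_v) H(r - R0)
  st <- suppressWarnings(
    initial_condition(grid, R0, eos$rho_v, 998, width = 1e-9))
  step <- ifelse(grid$centers < R0, eos$rho_v, 998)
  expect_equal(st$rho, step, tolerance = 1e-12)

  # measured radius of the smooth default profile is R0 to one cell
  sm <- initial_condition(grid, R0, eos$rho_v, 998)
  expect_lt(abs(bubble_radius(sm, eos) - R0), grid$dr)

  # total fluid mass against the analytic step-profile integral,
  # to within the mass of a width-thick interface shell
  phi0 <- 0.01
  mass <- sum(grid$vol * phi0 * sm$rho)
  mass_exact <- phi0 * (eos$rho_v * R0^3 / 3 + 998 * (grid$L^3 - R0^3) / 3)
  shell <- phi0 * (998 - eos$rho_v) * R0^2 * 4 * grid$dr
  expect_lt(abs(mass - mass_exact), 1.5 * shell)

  expect_warning(initial_condition(grid, R0, 8.8, 998, width = grid$dr / 4),
                 "under-resolved")
})

test_that("bubble radius locator handles step, uniform and tanh fields", {
  grid <- spherical_grid(1e-3, 512)
  mk <- function(rho) density_field(grid, rho)
  R0 <- 0.37e-3
  step <- ifelse(grid$centers < R0, 8.8, 998)
  expect_lt(abs(bubble_radius(mk(step), eos) - R0), grid$dr)
  expect_identical(bubble_radius(mk(rep(998, 512)), eos), 0)
  expect_identical(bubble_radius(mk(rep(8.8, 512)), eos), grid$L)
  # tanh interface centered at 0.3 L with width 0.01 L: the rho_c crossing
  # is the profile midpoint
  tanhf <- 8.8 + (998 - 8.8) * 0.5 *
    (1 + tanh((grid$centers - 0.3e-3) / (0.01e-3)))
  expect_lt(abs(bubble_radius(mk(tanhf), eos) - 0.3e-3), 1e-6)
})

test_that("uniform equilibrium is an exact fixed point of the step", {
  grid <- spherical_grid(1e-3, 64)
  med <- table1_medium(E = 15e3, nu = 0.45)
  st <- density_field(grid, rep(998, 64))
  out <- spherical_step(st, med, eos, dt = 1e-4, rho_L = 998)
  expect_true(out$converged)
  expect_equal(out$state$rho, rep(998, 64), tolerance = 1e-12)
  expect_equal(out$boundary_flux, 0, tolerance = 1e-20)
})

test_that("small perturbations decay at the spherical diffusion rate", {
  # rigid skeleton, near-uniform state: the slowest eigenmode of
  # phi0 drho/dt = div(D grad rho) on (0, L) with Dirichlet at L is
  # sin(pi r / L)/r with rate D (pi/L)^2, D = k W(rho0) / (mu(rho0) phi0)
  grid <- spherical_grid(1e-3, 256)
  med <- table1_medium(E = Inf)
  rho0 <- 800
  D <- med$k * eos_storage(eos, rho0) /
    (eos_viscosity(eos, rho0) * med$phi0)
  lam <- D * (pi / grid$L)^2
  mode <- grid$L / (pi * grid$centers) * sin(pi * grid$centers / grid$L)
  st <- density_field(grid, rho0 + 0.5 * mode)
  dt <- 1e-3
  for (i in 1:3) st <- spherical_step(st, med, eos, dt, rho0)$state
  a0 <- max(abs(st$rho - rho0))
  st <- spherical_step(st, med, eos, dt, rho0)$state
  a1 <- max(abs(st$rho - rho0))
  lam_est <- (a0 / a1 - 1) / dt      # backward-Euler decay 1/(1 + lam dt)
  expect_equal(lam_est, lam, tolerance = 0.02)
})

test_that("displacement matches the piecewise closed form for a step", {
  grid <- spherical_grid(1e-3, 128)
  med <- table1_medium(E = 15e3, nu = 0.45)
  R0 <- grid$faces[52]  # step aligned with a cell face
  rho <- ifelse(grid$centers < R0, 8.8, 998)
  st <- density_field(grid, rho)
  p_L <- eos_pressure(eos, 998)
  p_in <- eos_pressure(eos, 8.8)
  u <- displacement(st, med, eos, p_L)
  # cell-aligned step: exact cumulative quadrature gives
  #   r <= R0: u = alpha r (p_in - p_L) / (3 M)
  #   r >  R0: u = alpha R0^3 (p_in - p_L) / (3 M r^2)
  r <- u$r
  expect_true(R0 %in% grid$faces)  # step lies on a face
  exact <- ifelse(r <= R0, med$alpha * r * (p_in - p_L) / (3 * med$M),
                  med$alpha * R0^3 * (p_in - p_L) / (3 * med$M * r^2))
  expect_equal(u$u_r, exact, tolerance = 1e-12)
  expect_identical(u$u_r[1], 0)

  # uniform liquid: the two terms cancel exactly
  uu <- displacement(density_field(grid, rep(998, 128)), med, eos, p_L)
  expect_equal(uu$u_r, rep(0, 129), tolerance = 1e-15)

  # rigid medium: identically zero
  ur <- displacement(st, table1_medium(E = Inf), eos, p_L)
  expect_identical(ur$u_r, rep(0, 129))
})

test_that("discrete divergence of the displacement recovers the strain", {
  grid <- spherical_grid(1e-3, 128)
  med <- table1_medium(E = 5e3, nu = 0.3)
  set.seed(42)  # any admissible field; smooth bump plus noise
  rho <- 700 + 250 * sin(pi * grid$centers / grid$L) +
    runif(128, -5, 5)
  st <- density_field(grid, rho)
  p_L <- eos_pressure(eos, 998)
  u <- displacement(st, med, eos, p_L)$u_r
  eps <- volumetric_strain(st, med, eos, p_L)$eps_v
  r <- grid$faces
  div_u <- diff(r^2 * u) / grid$vol
  expect_equal(div_u, eps, tolerance = 1e-10)
})

test_that("collapse run conserves mass and never regrows the bubble", {
  grid <- spherical_grid(1e-3, 128)
  run <- run_collapse(table1_medium(E = 15e3, nu = 0.45), eos, grid,
                      static_998())
  expect_true(run$collapsed)
  expect_lt(max(run$trace$mass_residual, na.rm = TRUE), 1e-8)
  # monotone non-increasing radius under static overpressure
  expect_true(all(diff(run$trace$R) < grid$dr / 2))
  # once the vapor region is gone it stays gone
  gone <- which(run$trace$R == 0)
  expect_gt(length(gone), 1)
  expect_true(all(run$trace$R[min(gone):nrow(run$trace)] == 0))

  # solid skeleton is compressed in the liquid during collapse and the
  # strain vanishes at the boundary
  mid <- run$snapshots[[3]]
  ev <- volumetric_strain(mid, run$medium, eos, eos_pressure(eos, 998))
  expect_lt(min(ev$eps_v), 0)
  expect_equal(ev$eps_v[grid$n_cells], 0, tolerance = 1e-3)
  # post-collapse the fluid re-pressurizes diffusively and the skeleton
  # relaxes to an undeformed configuration; continue past collapse for a
  # few liquid diffusion times to observe it
  st <- run$state
  dt <- 2e-4
  while (st$t < run$collapse_time + 0.15) {
    out <- spherical_step(st, run$medium, eos, dt, 998)
    if (out$converged) {
      st <- out$state
      dt <- dt * 1.3
    } else dt <- dt / 2
  }
  uf <- displacement(st, run$medium, eos, eos_pressure(eos, 998))
  um <- displacement(mid, run$medium, eos, eos_pressure(eos, 998))
  expect_lt(max(abs(uf$u_r)), 0.05 * max(abs(um$u_r)))
})

test_that("collapse time is insensitive to the outer domain radius", {
  med <- table1_medium(E = 15e3, nu = 0.45)
  r1 <- pde_run(15e3, n_cells = 256)$collapse_time
  r2 <- run_collapse(med, eos, spherical_grid(2e-3, 512), static_998(),
                     R0 = 0.5e-3)$collapse_time
  expect_equal(r2, r1, tolerance = 0.01)
})

test_that("a very stiff skeleton matches the exact rigid branch", {
  grid <- spherical_grid(1e-3, 256)
  tr <- run_collapse(table1_medium(E = Inf), eos, grid,
                     static_998())$collapse_time
  ts <- run_collapse(table1_medium(E = 1e9, nu = 0.45), eos, grid,
                     static_998())$collapse_time
  expect_equal(ts, tr, tolerance = 5e-3)
})
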
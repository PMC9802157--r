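eos <- t1_eos()

test_that("cylindrical mesh carries the axisymmetric metric", {
  m <- cyl_mesh(2e-3, 3e-3, 10, 15)
  expect_equal(sum(m$vol), 0.5 * (2e-3)^2 * 3e-3, tolerance = 1e-14)
  expect_equal(m$r_faces[1], 0)
  expect_equal(m$z_faces[1], 0)
  expect_length(m$vol, 150)
  # cells in one radial column share the ring area
  expect_equal(m$vol[1], m$vol[1 + m$nr], tolerance = 1e-18)
})

test_that("uniform pressure with roller sides gives exact uniaxial
           compression", {
  med <- table1_medium(E = 5e3, nu = 0.3)
  mesh <- cyl_mesh(2e-3, 3e-3, 8, 12)
  op <- elasticity_operator(mesh, med,
                            bcs = list(bottom = "fixed", side = "roller",
                                       top = "free"))
  p0 <- 5000
  sol <- solve_elasticity(op, rep(p0, mesh$n_cells))
  nn <- (mesh$nr + 1) * (mesh$nz + 1)
  u_r <- sol$u[2 * seq_len(nn) - 1]
  u_z <- sol$u[2 * seq_len(nn)]
  node_z <- rep(mesh$z_faces, each = mesh$nr + 1)
  # uniaxial strain against the wall: u_z = alpha p z / M, u_r = 0
  expect_equal(u_z, med$alpha * p0 / med$M * node_z, tolerance = 1e-12)
  expect_lt(max(abs(u_r)), 1e-15)
  expect_equal(sol$eps_v, rep(med$alpha * p0 / med$M, mesh$n_cells),
               tolerance = 1e-10)
  expect_lt(sol$residual, 1e-8)
})

test_that("an axial linear displacement field passes the patch test", {
  med <- table1_medium(E = 7e3, nu = 0.25)
  mesh <- cyl_mesh(1e-3, 1.5e-3, 6, 9)
  op <- elasticity_operator(mesh, med,
                            bcs = list(bottom = "fixed", side = "fixed",
                                       top = "fixed"))
  a <- 2e-4  # u_r = 0, u_z = a z: uniform strain state
  nn <- (mesh$nr + 1) * (mesh$nz + 1)
  node_z <- rep(mesh$z_faces, each = mesh$nr + 1)
  exact <- numeric(2 * nn)
  exact[2 * seq_len(nn)] <- a * node_z
  sol <- solve_elasticity(op, rep(0, mesh$n_cells),
                          fixed_values = exact[op$fixed])
  expect_equal(sol$u, exact, tolerance = 1e-12)
  expect_equal(sol$eps_v, rep(a, mesh$n_cells), tolerance = 1e-10)
})

test_that("hydrostatic stress obeys the isotropic identity", {
  med <- table1_medium(E = 5e3, nu = 0.3)
  mesh <- cyl_mesh(1e-3, 1e-3, 4, 4)
  eps0 <- -0.01
  st <- coupled_state(mesh, rep(998, 16), u = numeric(50),
                      eps_v = rep(eps0, 16))
  expect_equal(hydrostatic_stress(st, med),
               rep((med$lambda + 2 * med$G / 3) * eps0, 16),
               tolerance = 1e-12)
  st0 <- coupled_state(mesh, rep(998, 16), u = numeric(50),
                       eps_v = rep(0, 16))
  expect_identical(hydrostatic_stress(st0, med), rep(0, 16))
  # total-stress variant subtracts the pore pressure
  expect_equal(hydrostatic_stress(st0, med, eos, total = TRUE),
               rep(-eos_pressure(eos, 998), 16), tolerance = 1e-12)
})

test_that("uniform equilibrium is stationary for the coupled step", {
  mesh <- cyl_mesh(1e-3, 1e-3, 8, 8)
  rho_b <- 998.2
  # rigid
  st <- coupled_state(mesh, rep(rho_b, 64))
  out <- coupled_step(st, table1_medium(E = Inf), eos, 1e-4, rho_b)
  expect_true(out$converged)
  expect_equal(out$state$rho, rep(rho_b, 64), tolerance = 1e-12)
  # deformable
  med <- table1_medium(E = 5e3, nu = 0.3)
  op <- elasticity_operator(mesh, med)
  p0 <- eos_pressure(eos, rep(rho_b, 64))
  el <- solve_elasticity(op, p0)
  sts <- coupled_state(mesh, rep(rho_b, 64), el$u, el$eps_v,
                       eps_t = el$eps_v - med$alpha * p0 / med$M)
  outs <- coupled_step(sts, med, eos, 1e-4, rho_b, op)
  expect_true(outs$converged)
  expect_equal(outs$state$rho, rep(rho_b, 64), tolerance = 1e-10)
})

test_that("every accepted step balances storage against boundary flux", {
  run <- experiment_near_wall(rigid = FALSE, scale = 2,
                              scale_geometry = TRUE)
  expect_true(run$collapsed)
  expect_lt(max(run$trace$mass_residual, na.rm = TRUE), 1e-8)
  run_r <- experiment_near_wall(rigid = TRUE, scale = 2,
                                scale_geometry = TRUE)
  expect_lt(max(run_r$trace$mass_residual, na.rm = TRUE), 1e-8)
})

test_that("rigid 2D collapse matches the 1D spherical solver away from
           the wall", {
  # spherically symmetric bubble centered 1 mm above the wall in a
  # 1 mm x 2 mm box; compare with the spherical solver on L = 1 mm
  med <- table1_medium(E = Inf)
  mesh <- cyl_mesh(1e-3, 2e-3, 32, 64)
  run2d <- run_near_wall(med, eos, mesh, rho_b = 998, R0 = 0.25e-3,
                         center_z = 1e-3)
  run1d <- run_collapse(med, eos, spherical_grid(1e-3, 256),
                        static_998(), R0 = 0.25e-3, width = 4 * mesh$dr)
  expect_true(run2d$collapsed && run1d$collapsed)
  expect_equal(run2d$collapse_time, run1d$collapse_time, tolerance = 0.25)
  # vapor volume decreases monotonically (to one-cell granularity)
  expect_true(all(diff(run2d$trace$vapor_volume) <=
                    2 * pi * max(mesh$vol)))
})

test_that("deformability slows the near-wall collapse and shifts the
           collapse point upward", {
  soft <- experiment_near_wall(rigid = FALSE, scale = 4)
  rig <- experiment_near_wall(rigid = TRUE, scale = 4)
  expect_true(soft$collapsed && rig$collapsed)
  expect_gt(soft$collapse_time, rig$collapse_time)
  expect_gt(soft$collapse_point["z"], rig$collapse_point["z"])
  # at matched t/t_c the vapor region is larger in the rigid medium
  frac <- 0.722
  vol_at <- function(run, f) {
    tr <- run$trace
    approx(tr$t / run$collapse_time, tr$vapor_volume, xout = f)$y
  }
  expect_gt(vol_at(rig, frac) / vol_at(rig, 0),
            vol_at(soft, frac) / vol_at(soft, 0))
})

test_that("near-wall collapse time is stable under mesh refinement", {
  # scaled-down geometry keeps the refinement study affordable
  coarse <- experiment_near_wall(rigid = TRUE, nr = 40, nz = 26, scale = 1,
                                 scale_geometry = FALSE,
                                 control = near_wall_control())
  fine <- experiment_near_wall(rigid = TRUE, nr = 80, nz = 52, scale = 1)
  expect_lt(abs(fine$collapse_time - coarse$collapse_time) /
              coarse$collapse_time, 0.10)
})
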
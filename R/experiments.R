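# Canned experiment runners for the study's standard scenarios.  Each is a
# deterministic function of its arguments; tests and the command-line
# interface call these.

#' Collapse-time sweep over Young's modulus (spherical bubble)
#'
#' Runs the 1D spherical PDE collapse for a set of Young's moduli (with
#' `Inf` denoting the rigid skeleton) and the reference parameters:
#' domain radius `L`, bubble radius `L/2`, boundary density 998 kg/m^3.
#' Solid deformation slows the collapse, so collapse time decreases as the
#' skeleton stiffens.
#'
#' @param E_values Young's moduli \[Pa\]; `Inf` for rigid.
#' @param nu Poisson ratio.
#' @param L domain radius \[m\].
#' @param n_cells grid resolution.
#' @param rho_L boundary density \[kg m^-3\].
#' @param control see [collapse_control()].
#' @return list with `results` (tibble `E`, `t_c`, `collapsed`) and
#'   `runs` (list of `collapse_run` objects, named by `E`).
#' @export
experiment_spherical_sweep <- function(E_values = c(5e3, 15e3, 50e3, Inf),
                                       nu = 0.45, L = 1e-3, n_cells = 1024,
                                       rho_L = 998,
                                       control = collapse_control()) {
  eos <- preset_table1()$eos
  grid <- spherical_grid(L = L, n_cells = n_cells)
  forcing <- forcing_spec("static", rho_L = rho_L)
  runs <- lapply(E_values, function(E) {
    run_collapse(table1_medium(E = E, nu = nu), eos, grid, forcing,
                 control = control)
  })
  names(runs) <- ifelse(is.finite(E_values), format(E_values), "rigid")
  list(results = tibble::tibble(
         E = E_values,
         t_c = vapply(runs, function(r) r$collapse_time, numeric(1)),
         collapsed = vapply(runs, function(r) r$collapsed, logical(1))),
       runs = runs)
}

#' Calibrate rho_R once, then compare reduced and full collapse times
#'
#' Calibrates the interface density `rho_R` of the poroelastic
#' Rayleigh--Plesset equation against a single PDE collapse run at
#' `E_cal`, then sweeps `E_values` comparing the PDE collapse time with
#' the Rayleigh--Plesset prediction using that one fixed `rho_R`.
#'
#' @param E_values Young's moduli to compare \[Pa\].
#' @param E_cal calibration modulus \[Pa\].
#' @inheritParams experiment_spherical_sweep
#' @return list with `rho_R`, `t_c_cal`, and `results` (tibble `E`,
#'   `t_c_pde`, `t_c_rp`, `rel_diff`).
#' @export
experiment_rp_comparison <- function(E_values = c(5e3, 10e3, 25e3, 50e3),
                                     E_cal = 15e3, nu = 0.45, L = 1e-3,
                                     n_cells = 1024, rho_L = 998,
                                     control = collapse_control()) {
  eos <- preset_table1()$eos
  grid <- spherical_grid(L = L, n_cells = n_cells)
  forcing <- forcing_spec("static", rho_L = rho_L)
  R0 <- L / 2

  cal_run <- run_collapse(table1_medium(E = E_cal, nu = nu), eos, grid,
                          forcing, control = control)
  if (!cal_run$collapsed) stop("calibration run did not collapse",
                               call. = FALSE)
  cal_params <- prp_params(L, R0, table1_medium(E = E_cal, nu = nu), eos,
                           rho_l = rho_L)
  rho_R <- calibrate_rho_R(cal_run$collapse_time, cal_params, forcing, eos)

  rows <- lapply(E_values, function(E) {
    med <- table1_medium(E = E, nu = nu)
    pde <- run_collapse(med, eos, grid, forcing, control = control)
    params <- prp_params(L, R0, med, eos, rho_l = rho_L, rho_R = rho_R)
    tr <- rp_integrate(params, forcing, eos,
                       t_max = 50 * cal_run$collapse_time, n_out = 10)
    t_rp <- rp_collapse_time(tr)
    tibble::tibble(E = E, t_c_pde = pde$collapse_time, t_c_rp = t_rp,
                   rel_diff = abs(t_rp - pde$collapse_time) /
                     pde$collapse_time)
  })
  list(rho_R = rho_R, t_c_cal = cal_run$collapse_time,
       results = do.call(rbind, rows))
}

#' Ultrasound-driven bubble: soft versus rigid medium
#'
#' Integrates the poroelastic Rayleigh--Plesset equation for a bubble with
#' non-condensable gas under sinusoidal boundary pressure, in a rigid and
#' in a soft medium, over `n_periods` wave periods. The soft medium
#' reduces the expansion velocity and the maximum bubble size, and the
#' collapse reaches a smaller minimum radius in the rigid medium.
#'
#' @param s phase selector: 1 collapses first, 2 expands first.
#' @param n_periods number of forcing periods to integrate.
#' @param E soft-medium Young's modulus \[Pa\].
#' @param nu Poisson ratio.
#' @param rho_R calibrated interface density \[kg m^-3\] (used by the
#'   soft-medium `beta`).
#' @param R0 initial bubble radius \[m\].
#' @param L outer radius \[m\].
#' @param p_amp wave amplitude \[Pa\].
#' @param freq wave frequency \[Hz\].
#' @param p_g0 gas pressure at `R0` \[Pa\].
#' @param eta polytropic exponent.
#' @param n_out output samples per trace.
#' @return list with `spec` and tibbles `rigid`, `soft` (class
#'   `bubble_trace`).
#' @export
experiment_ultrasound <- function(s = 1, n_periods = 2, E = 15e3, nu = 0.45,
                                  rho_R, R0 = 100e-6, L = 1e-3,
                                  p_amp = 1e6, freq = 20e3, p_g0 = 100,
                                  eta = 1.4, n_out = 4000) {
  eos <- preset_table1()$eos
  spec <- forcing_spec("ultrasound", rho_L = 998, p_amp = p_amp,
                       freq = freq, s = s, bubble = "ncg", p_g0 = p_g0,
                       eta = eta)
  t_max <- n_periods / freq
  rigid <- rp_integrate(prp_params(L, R0, table1_medium(E = Inf), eos),
                        spec, eos, t_max = t_max, n_out = n_out)
  soft <- rp_integrate(prp_params(L, R0, table1_medium(E = E, nu = nu),
                                  eos, rho_R = rho_R),
                       spec, eos, t_max = t_max, n_out = n_out)
  list(spec = spec, rigid = rigid, soft = soft)
}

#' Near-wall collapse: rigid or soft medium, optionally scaled down
#'
#' Runs the axisymmetric near-wall collapse with the reference geometry
#' (radial extent 5 mm, axial extent 6.5 mm, bubble radius 1.2 mm centered
#' 1.5 mm above the wall, outer density 998.2 kg/m^3). `scale` divides the
#' mesh resolution (and the geometry when `scale_geometry = TRUE`) for
#' quick exploratory runs.
#'
#' @param rigid run the rigid-medium variant.
#' @param E,nu soft-medium elasticity (ignored when `rigid`).
#' @param nr,nz base mesh resolution.
#' @param scale integer scale-down factor for the resolution.
#' @param scale_geometry also shrink the geometry by `scale`.
#' @param control see [near_wall_control()].
#' @return a `near_wall_run` object (see [run_near_wall()]).
#' @export
experiment_near_wall <- function(rigid = FALSE, E = 5e3, nu = 0.3,
                                 nr = 100, nz = 65, scale = 1,
                                 scale_geometry = FALSE,
                                 control = near_wall_control()) {
  eos <- preset_table1()$eos
  medium <- if (rigid) table1_medium(E = Inf) else
    table1_medium(E = E, nu = nu)
  geo <- if (scale_geometry) scale else 1
  mesh <- cyl_mesh(r_max = 5e-3 / geo, z_max = 6.5e-3 / geo,
                   nr = max(2, round(nr / scale)),
                   nz = max(2, round(nz / scale)))
  run_near_wall(medium, eos, mesh, rho_b = 998.2, R0 = 1.2e-3 / geo,
                center_z = 1.5e-3 / geo, control = control)
}
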
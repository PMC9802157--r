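# Coupled axisymmetric solver for bubble collapse near a rigid wall.
#
# Fluid:  alpha rho d(eps_v)/dt + [W(rho)/N + phi0] d(rho)/dt
#                = div( (k W/mu) grad rho )
# Solid:  div(sigma_eff) = alpha grad p
#
# Finite volumes with the cylindrical metric for the fluid (full Newton,
# conservative storage), Q1 finite elements for the solid, staggered
# fixed-point coupling per time step.  Boundary conditions: symmetry at
# the axis, zero normal Darcy flux at the wall (z = 0), imposed density
# on the outer radial and top boundaries; solid clamped at the wall,
# total-traction-free elsewhere.

# precomputed face topology and metric factors
axisym_faces <- function(mesh) {
  nr <- mesh$nr; nz <- mesh$nz
  idx <- function(i, j) (j - 1L) * nr + i
  # internal radial faces between (i,j) and (i+1,j), i = 1..nr-1
  ir <- rep(seq_len(nr - 1), nz)
  jr <- rep(seq_len(nz), each = nr - 1)
  rl <- idx(ir, jr); rr <- idx(ir + 1L, jr)
  Ar <- mesh$r_faces[ir + 1] * mesh$dz
  # internal axial faces between (i,j) and (i,j+1), j = 1..nz-1
  ia <- rep(seq_len(nr), nz - 1)
  ja <- rep(seq_len(nz - 1), each = nr)
  ad <- idx(ia, ja); au <- idx(ia, ja + 1L)
  Aa <- mesh$ring[ia]
  # Dirichlet boundary faces: outer radial (i = nr) and top (j = nz);
  # kept as two groups (the corner cell carries one face of each)
  be <- idx(nr, seq_len(nz))
  Ae <- rep(mesh$r_faces[nr + 1] * mesh$dz, nz)
  bt <- idx(seq_len(nr), nz)
  At <- mesh$ring
  list(rl = rl, rr = rr, Ar = Ar, ad = ad, au = au, Aa = Aa,
       be = be, bAe = Ae, bhe = mesh$dr / 2,
       bt = bt, bAt = At, bht = mesh$dz / 2)
}

# The coupled storage is split exactly:
#   alpha rho d(eps_v)/dt + [W/N + phi0] d(rho)/dt
#     = d/dt[ B Psi(rho) + phi0 rho ] + alpha rho d(eps_t)/dt ,
# with B = 1/N + alpha^2/M and eps_t = eps_v - alpha p / M the *nonlocal*
# part of the strain (the local pressure response alpha p/M is absorbed
# into the implicit storage, which is what makes the staggered iteration
# converge even for very soft skeletons).  The 1D phi_storage() supplies
# B Psi + phi0 rho; a rigid medium has B = 1/N (0 for incompressible
# grains) and no eps_t term.

# one backward-Euler fluid solve with frozen strain increment deps/dt
axisym_fluid_solve <- function(rho_old, phi_old, deps_dt, mesh, faces,
                               medium, eos, dt, rho_b, newton_tol, max_newton) {
  n <- mesh$n_cells
  m_b <- mobility(medium, eos, rho_b)
  eps_dom <- 1e-6
  scale <- mesh$vol * medium$phi0 * rho_b / dt
  rho <- pmin(pmax(rho_old, eps_dom), eos$b - eps_dom)
  couple_vol <- mesh$vol * medium$alpha * deps_dt   # multiplies rho

  for (it in 0:max_newton) {
    m <- mobility(medium, eos, rho)
    mp <- mobility_deriv(medium, eos, rho)
    net <- numeric(n)
    # radial faces
    Dm <- 0.5 * (m[faces$rl] + m[faces$rr])
    df <- (rho[faces$rr] - rho[faces$rl]) / mesh$dr
    Fr <- faces$Ar * Dm * df
    net[faces$rl] <- net[faces$rl] + Fr
    net[faces$rr] <- net[faces$rr] - Fr
    # axial faces
    Da <- 0.5 * (m[faces$ad] + m[faces$au])
    da <- (rho[faces$au] - rho[faces$ad]) / mesh$dz
    Fa <- faces$Aa * Da * da
    net[faces$ad] <- net[faces$ad] + Fa
    net[faces$au] <- net[faces$au] - Fa
    # Dirichlet boundary faces (outer radial, then top; the corner cell
    # receives one flux from each group)
    De <- 0.5 * (m[faces$be] + m_b)
    de <- (rho_b - rho[faces$be]) / faces$bhe
    Fbe <- faces$bAe * De * de
    net[faces$be] <- net[faces$be] + Fbe
    Dt <- 0.5 * (m[faces$bt] + m_b)
    dtp <- (rho_b - rho[faces$bt]) / faces$bht
    Fbt <- faces$bAt * Dt * dtp
    net[faces$bt] <- net[faces$bt] + Fbt

    resid <- mesh$vol * (phi_storage(medium, eos, rho) - phi_old) / dt +
      couple_vol * rho - net
    if (max(abs(resid / scale)) <= newton_tol) {
      return(list(rho = rho, converged = TRUE, iters = it,
                  boundary_flux = sum(Fbe) + sum(Fbt)))
    }
    if (it == max_newton) break

    diag_J <- mesh$vol * phi_storage_deriv(medium, eos, rho) / dt +
      couple_vol
    # flux Jacobian triplets (G = storage - net)
    dFr_l <- faces$Ar * (0.5 * mp[faces$rl] * df - Dm / mesh$dr)
    dFr_r <- faces$Ar * (0.5 * mp[faces$rr] * df + Dm / mesh$dr)
    dFa_d <- faces$Aa * (0.5 * mp[faces$ad] * da - Da / mesh$dz)
    dFa_u <- faces$Aa * (0.5 * mp[faces$au] * da + Da / mesh$dz)
    dFe_c <- faces$bAe * (0.5 * mp[faces$be] * de - De / faces$bhe)
    dFt_c <- faces$bAt * (0.5 * mp[faces$bt] * dtp - Dt / faces$bht)

    Ji <- c(seq_len(n),
            faces$rl, faces$rl, faces$rr, faces$rr,
            faces$ad, faces$ad, faces$au, faces$au,
            faces$be, faces$bt)
    Jj <- c(seq_len(n),
            faces$rl, faces$rr, faces$rr, faces$rl,
            faces$ad, faces$au, faces$au, faces$ad,
            faces$be, faces$bt)
    Jx <- c(diag_J,
            -dFr_l, -dFr_r, dFr_r, dFr_l,
            -dFa_d, -dFa_u, dFa_u, dFa_d,
            -dFe_c, -dFt_c)
    J <- Matrix::sparseMatrix(i = Ji, j = Jj, x = Jx, dims = c(n, n))
    delta <- tryCatch(as.numeric(Matrix::solve(J, -resid)),
                      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) break
    fac <- min(1, 0.3 * eos$b / max(abs(delta)))
    rho <- pmin(pmax(rho + fac * delta, eps_dom), eos$b - eps_dom)
  }
  list(rho = rho, converged = FALSE, iters = max_newton,
       boundary_flux = NA_real_)
}

#' Control settings for the axisymmetric coupled solver
#'
#' @inheritParams collapse_control
#' @param couple_tol staggered fixed-point tolerance on the volumetric
#'   strain (relative to the strain scale `alpha F(rho_b)/M`).
#' @param max_couple maximum staggered iterations per step.
#' @return a list of control settings.
#' @export
near_wall_control <- function(dt0 = 1e-7, t_max = 10, newton_tol = 1e-9,
                              max_newton = 12, couple_tol = 1e-6,
                              max_couple = 30, cfl = 0.5, grow = 1.4,
                              dt_min = 1e-16, n_snapshots = 3) {
  list(dt0 = dt0, t_max = t_max, newton_tol = newton_tol,
       max_newton = max_newton, couple_tol = couple_tol,
       max_couple = max_couple, cfl = cfl, grow = grow, dt_min = dt_min,
       n_snapshots = n_snapshots)
}

#' One staggered step of the coupled axisymmetric system
#'
#' Advances the coupled fluid--solid state by `dt` with a stabilized
#' staggered (fixed-point) scheme: the local part of the strain-rate
#' coupling, `alpha rho (alpha/M) dF(rho)/dt = (alpha^2/M) W(rho) drho/dt`,
#' is absorbed into the implicit fluid storage (the `B W` term of the
#' spherical reduction), and only the nonlocal remainder
#' `eps_t = eps_v - alpha p/M` is frozen per fixed-point pass and iterated
#' against the elasticity solve. This converges even for very soft
#' skeletons, where the raw strain-source iteration diverges. A uniform
#' equilibrium state is an exact fixed point; a rigid medium reduces to
#' the 2D analog of the pure nonlinear diffusion step. The per-step mass
#' balance (storage change plus coupling term versus net Dirichlet
#' boundary flux) holds to the solver tolerance by construction of the
#' conservative residual.
#'
#' @param state a [coupled_state()].
#' @param medium a [poroelastic_medium()].
#' @param eos a [fluid_eos()].
#' @param dt time step \[s\].
#' @param rho_b imposed density on the outer radial and top boundaries.
#' @param op an [elasticity_operator()] (required unless rigid).
#' @param faces precomputed face topology (internal; built when `NULL`).
#' @param control see [near_wall_control()].
#' @return list with `state`, `converged`, `newton_iters`, `couple_iters`,
#'   `boundary_flux`, `mass_residual`.
#' @export
coupled_step <- function(state, medium, eos, dt, rho_b, op = NULL,
                         faces = NULL, control = near_wall_control()) {
  mesh <- state$mesh
  if (is.null(faces)) faces <- axisym_faces(mesh)
  rigid <- is_rigid(medium)
  if (!rigid && is.null(op))
    stop("deformable run requires an elasticity operator", call. = FALSE)
  rho_old <- state$rho
  phi_old <- phi_storage(medium, eos, rho_old)
  eps_t_old <- if (rigid) NULL else state$eps_t
  eps_scale <- if (rigid) 1 else
    max(medium$alpha * eos_pressure(eos, rho_b) / medium$M, 1e-15)

  fail <- function(n_newton, n_couple)
    list(state = NULL, converged = FALSE, newton_iters = n_newton,
         couple_iters = n_couple, boundary_flux = NA_real_,
         mass_residual = NA_real_)

  eps_t_new <- eps_t_old
  newton_total <- 0L
  couple_iters <- 0L
  u <- NULL; eps_v <- NULL; eps_t <- NULL
  repeat {
    deps_dt <- if (rigid) rep(0, mesh$n_cells) else
      (eps_t_new - eps_t_old) / dt
    fl <- axisym_fluid_solve(rho_old, phi_old, deps_dt, mesh, faces,
                             medium, eos, dt, rho_b,
                             control$newton_tol, control$max_newton)
    newton_total <- newton_total + fl$iters
    if (!fl$converged) return(fail(newton_total, couple_iters))
    if (rigid) {
      rho <- fl$rho
      break
    }
    p <- eos_pressure(eos, fl$rho)
    el <- solve_elasticity(op, p)
    couple_iters <- couple_iters + 1L
    eps_t_next <- el$eps_v - medium$alpha * p / medium$M
    dchange <- max(abs(eps_t_next - eps_t_new)) / eps_scale
    eps_t_new <- eps_t_next
    if (dchange <= control$couple_tol) {
      # final fluid pass against the converged nonlocal strain
      deps_dt <- (eps_t_new - eps_t_old) / dt
      fl <- axisym_fluid_solve(rho_old, phi_old, deps_dt, mesh, faces,
                               medium, eos, dt, rho_b,
                               control$newton_tol, control$max_newton)
      newton_total <- newton_total + fl$iters
      if (!fl$converged) return(fail(newton_total, couple_iters))
      rho <- fl$rho; u <- el$u; eps_v <- el$eps_v; eps_t <- eps_t_new
      break
    }
    if (couple_iters >= control$max_couple)
      return(fail(newton_total, couple_iters))
  }
  dstore <- sum(mesh$vol * (phi_storage(medium, eos, rho) - phi_old))
  if (!rigid)
    dstore <- dstore + sum(mesh$vol * medium$alpha * rho * (eps_t - eps_t_old))
  denom <- sum(mesh$vol) * medium$phi0 * rho_b
  list(state = coupled_state(mesh, rho, u, eps_v, state$t + dt, eps_t),
       converged = TRUE, newton_iters = newton_total,
       couple_iters = couple_iters, boundary_flux = fl$boundary_flux,
       mass_residual = abs(dstore - fl$boundary_flux * dt) / denom)
}

#' Simulate bubble collapse near a rigid wall
#'
#' Runs the axisymmetric coupled solver for a vapor bubble of radius `R0`
#' centered on the axis at height `center_z` above a no-flow, no-slip wall
#' (`z = 0`), with the outer density imposed on the outer radial and top
#' boundaries. Collapse time is the first time at which the vapor region
#' (`rho < rho_c`) vanishes. The collapse point is the volume-weighted
#' centroid of the last non-empty vapor region. Deformability of the
#' skeleton slows the collapse and moves the collapse point away from the
#' wall relative to the rigid medium.
#'
#' @param medium a [poroelastic_medium()] (rigid `E = Inf` skips the
#'   elasticity solve entirely).
#' @param eos a [fluid_eos()].
#' @param mesh a [cyl_mesh()].
#' @param rho_b outer boundary density \[kg m^-3\] (default 998.2).
#' @param R0 initial bubble radius \[m\].
#' @param center_z bubble center height above the wall \[m\].
#' @param rho_in initial in-bubble density (default `eos$rho_v`).
#' @param width initial interface width \[m\] (default 4 radial cells).
#' @param control see [near_wall_control()].
#' @return object of class `near_wall_run`: list with `trace` (tibble:
#'   `t`, `R_eq`, `vapor_volume`, `dt`, `newton_iters`, `couple_iters`,
#'   `mass_residual`), `collapse_time`, `collapsed`, `collapse_point`
#'   (`c(r, z)` \[m\]), `snapshots`, `state`, and the configuration.
#' @export
run_near_wall <- function(medium, eos, mesh = cyl_mesh(),
                          rho_b = 998.2, R0 = 1.2e-3, center_z = 1.5e-3,
                          rho_in = eos$rho_v, width = 4 * mesh$dr,
                          control = near_wall_control()) {
  stopifnot(R0 > 0, center_z > 0, rho_b > 0, rho_b < eos$b)
  d <- sqrt(mesh$cell_r^2 + (mesh$cell_z - center_z)^2)
  rho <- rho_in + (rho_b - rho_in) * 0.5 * (1 + tanh(2 * (d - R0) / width))
  rigid <- is_rigid(medium)
  faces <- axisym_faces(mesh)
  op <- NULL
  if (!rigid) {
    op <- elasticity_operator(mesh, medium)
    p0 <- eos_pressure(eos, rho)
    el0 <- solve_elasticity(op, p0)
    state <- coupled_state(mesh, rho, el0$u, el0$eps_v, t = 0,
                           eps_t = el0$eps_v - medium$alpha * p0 / medium$M)
  } else {
    state <- coupled_state(mesh, rho, t = 0)
  }
  h <- min(mesh$dr, mesh$dz)
  Req <- equivalent_radius(state, eos)
  t_rec <- 0; R_rec <- Req; V_rec <- vapor_volume(state, eos)
  dt_rec <- NA_real_; it_rec <- NA_integer_; cp_rec <- NA_integer_
  mr_rec <- NA_real_
  collapse_time <- NA_real_
  collapse_point <- c(r = NA_real_, z = NA_real_)
  snapshots <- list(state)
  dt <- control$dt0

  repeat {
    dt <- min(dt, control$t_max - state$t)
    res <- coupled_step(state, medium, eos, dt, rho_b, op, faces, control)
    if (!res$converged) {
      dt <- dt / 2
      if (dt < control$dt_min)
        stop("time step underflow in the coupled solver", call. = FALSE)
      next
    }
    vap_prev <- state$rho < eos$rho_c
    state <- res$state
    R_new <- equivalent_radius(state, eos)
    speed <- abs(R_new - Req) / dt
    t_rec <- c(t_rec, state$t); R_rec <- c(R_rec, R_new)
    V_rec <- c(V_rec, vapor_volume(state, eos))
    dt_rec <- c(dt_rec, dt); it_rec <- c(it_rec, res$newton_iters)
    cp_rec <- c(cp_rec, res$couple_iters); mr_rec <- c(mr_rec, res$mass_residual)
    if (is.na(collapse_time) && R_new == 0) {
      collapse_time <- state$t
      w <- state$mesh$vol[vap_prev]
      collapse_point <- c(r = sum(state$mesh$cell_r[vap_prev] * w) / sum(w),
                          z = sum(state$mesh$cell_z[vap_prev] * w) / sum(w))
      break
    }
    if (state$t >= control$t_max) break
    n_solves <- res$couple_iters + 1L
    if (res$newton_iters <= 0.8 * control$max_newton * n_solves)
      dt <- dt * control$grow
    if (speed > 0) dt <- min(dt, control$cfl * h / speed)
    Req <- R_new
    if (length(snapshots) < control$n_snapshots + 1 &&
        R_new < R_rec[1] * (1 - length(snapshots) / (control$n_snapshots + 1))) {
      snapshots[[length(snapshots) + 1]] <- state
    }
  }
  snapshots[[length(snapshots) + 1]] <- state

  trace <- tibble::tibble(t = t_rec, R_eq = R_rec, vapor_volume = V_rec,
                          dt = dt_rec, newton_iters = it_rec,
                          couple_iters = cp_rec, mass_residual = mr_rec)
  class(trace) <- c("bubble_trace", class(trace))
  structure(
    list(trace = trace, collapse_time = collapse_time,
         collapsed = !is.na(collapse_time), collapse_point = collapse_point,
         snapshots = snapshots, state = state, mesh = mesh, medium = medium,
         eos = eos, rho_b = rho_b, R0 = R0, center_z = center_z),
    class = "near_wall_run"
  )
}

#' @export
print.near_wall_run <- function(x, ...) {
  cat("<near_wall_run> axisymmetric collapse near a rigid wall\n")
  cat(sprintf("  mesh %d x %d on %.3g x %.3g mm, R0 = %.3g mm at z = %.3g mm\n",
              x$mesh$nr, x$mesh$nz, 1e3 * x$mesh$r_max, 1e3 * x$mesh$z_max,
              1e3 * x$R0, 1e3 * x$center_z))
  cat(sprintf("  medium: %s\n",
              if (is_rigid(x$medium)) "rigid" else
                sprintf("E = %g Pa, nu = %g", x$medium$E, x$medium$nu)))
  if (x$collapsed) {
    cat(sprintf("  collapsed at t_c = %.4g s; collapse point z = %.3g mm\n",
                x$collapse_time, 1e3 * x$collapse_point["z"]))
  } else cat("  did not collapse within t_max\n")
  invisible(x)
}
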
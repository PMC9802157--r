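# Implicit finite-volume solver for the spherically symmetric density
# equation
#
#   [B W(rho) + phi0] d(rho)/dt = (1/r^2) d/dr ( r^2 (k W/mu) d(rho)/dr )
#
# on r in (0, L), with zero flux at r = 0 (symmetry) and Dirichlet
# rho = rho_L at r = L.  B = 1/N + alpha^2/M collects the poroelastic
# storage; B = 0 recovers pure nonlinear diffusion in a rigid skeleton.
# The storage term is discretized in conservation form through the
# antiderivative Phi(rho) = B Psi(rho) + phi0 rho (Psi' = W), so discrete
# mass balance holds to the Newton tolerance at every step.

# tridiagonal solve (Thomas algorithm); returns NULL on a vanishing pivot
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n - 1)
  dp <- numeric(n)
  piv <- diag[1]
  if (piv == 0) return(NULL)
  cp[1] <- upper[1] / piv
  dp[1] <- rhs[1] / piv
  for (i in 2:n) {
    piv <- diag[i] - lower[i - 1] * cp[i - 1]
    if (piv == 0) return(NULL)
    if (i < n) cp[i] <- upper[i] / piv
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / piv
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# d/drho of the face mobility k W(rho)/mu(rho)
mobility <- function(medium, eos, rho) {
  medium$k * eos_storage(eos, rho) / eos_viscosity(eos, rho)
}

mobility_deriv <- function(medium, eos, rho) {
  W <- eos_storage(eos, rho)
  Fp <- eos_dpressure(eos, rho)
  Fpp <- -2 * eos$C / rho^3 +
    2 * eos$C * (eos$b - eos$rho_c)^2 / (eos$rho_c^2 * (eos$b - rho)^3)
  Wp <- Fp + rho * Fpp
  mu <- eos_viscosity(eos, rho)
  raw <- eos$mu_v + (eos$mu_l - eos$mu_v) * (rho - eos$rho_v) / eos$b
  mup <- ifelse(raw > eos$mu_v & raw < eos$mu_l,
                (eos$mu_l - eos$mu_v) / eos$b, 0)
  medium$k * (Wp * mu - W * mup) / mu^2
}

phi_storage <- function(medium, eos, rho) {
  medium$B * eos_storage_integral(eos, rho) + medium$phi0 * rho
}

phi_storage_deriv <- function(medium, eos, rho) {
  medium$B * eos_storage(eos, rho) + medium$phi0
}

#' Control settings for the implicit spherical solver
#'
#' @param dt0 initial time step \[s\].
#' @param t_max maximum simulated time \[s\].
#' @param newton_tol relative Newton residual tolerance.
#' @param max_newton maximum Newton iterations before step rejection.
#' @param cfl maximum interface travel per accepted step, in cells.
#' @param grow time-step growth factor after an easy step.
#' @param dt_min smallest admissible step before the solver aborts \[s\].
#' @param collapse_cells collapse is declared when the bubble radius drops
#'   below this many cell widths.
#' @param t_after_frac fraction of the collapse time to keep integrating
#'   after the vapor region has vanished (regrowth check).
#' @param n_snapshots number of density snapshots to retain.
#' @return a list of control settings.
#' @export
collapse_control <- function(dt0 = 1e-8, t_max = 10, newton_tol = 1e-10,
                             max_newton = 12, cfl = 0.5, grow = 1.4,
                             dt_min = 1e-16, collapse_cells = 2,
                             t_after_frac = 0.05, n_snapshots = 5) {
  list(dt0 = dt0, t_max = t_max, newton_tol = newton_tol,
       max_newton = max_newton, cfl = cfl, grow = grow, dt_min = dt_min,
       collapse_cells = collapse_cells, t_after_frac = t_after_frac,
       n_snapshots = n_snapshots)
}

#' One backward-Euler step of the spherical density equation
#'
#' Advances the density field by `dt` with a full Newton solve of the
#' conservative finite-volume discretization. Face mobilities use the
#' arithmetic mean of the adjacent cell mobilities `k W/mu`; the boundary
#' face enforces `rho = rho_L` over the half cell. Densities are clipped to
#' `(eps, b - eps)` inside the iteration to respect the EOS domain.
#'
#' A uniform state `rho = rho_L` is an exact fixed point. With `B = 0`
#' (rigid skeleton) the step reduces to pure nonlinear diffusion
#' `phi0 d(rho)/dt = div(k W/mu grad rho)`.
#'
#' @param state a [density_field()].
#' @param medium a [poroelastic_medium()].
#' @param eos a [fluid_eos()].
#' @param dt time step \[s\].
#' @param rho_L boundary density at `r = L` \[kg m^-3\].
#' @param control see [collapse_control()].
#' @return list with `state` (advanced field, or `NULL` on Newton failure),
#'   `converged`, `iters`, `boundary_flux` (mass inflow through `r = L`
#'   per unit time, per steradian-free volume convention), and
#'   `mass_residual` (relative conservation defect of the step).
#' @export
spherical_step <- function(state, medium, eos, dt, rho_L,
                           control = collapse_control()) {
  g <- state$grid
  n <- g$n_cells
  dr <- g$dr
  A_int <- g$faces[2:n]^2        # internal faces between cells i, i+1
  A_bnd <- g$faces[n + 1]^2
  rho_old <- state$rho
  phi_old <- phi_storage(medium, eos, rho_old)
  m_L <- mobility(medium, eos, rho_L)
  eps_dom <- 1e-6
  scale <- g$vol * phi_storage_deriv(medium, eos, rho_L) * rho_L / dt

  rho <- pmin(pmax(rho_old, eps_dom), eos$b - eps_dom)
  converged <- FALSE
  iters <- 0L
  repeat {
    m <- mobility(medium, eos, rho)
    mp <- mobility_deriv(medium, eos, rho)
    # east flux into cell i (i = 1..n-1 internal, i = n boundary)
    D_int <- 0.5 * (m[-n] + m[-1])
    d_int <- (rho[-1] - rho[-n]) / dr
    Fe <- c(A_int * D_int * d_int,
            A_bnd * 0.5 * (m[n] + m_L) * (rho_L - rho[n]) / (dr / 2))
    resid <- g$vol * (phi_storage(medium, eos, rho) - phi_old) / dt -
      Fe + c(0, Fe[-n])
    if (max(abs(resid / scale)) <= control$newton_tol) {
      converged <- TRUE
      break
    }
    if (iters >= control$max_newton) break
    # Jacobian of the east flux wrt (rho_i, rho_{i+1})
    dFe_dl <- c(A_int * (0.5 * mp[-n] * d_int - D_int / dr),
                A_bnd * (0.5 * mp[n] * (rho_L - rho[n]) / (dr / 2) -
                           0.5 * (m[n] + m_L) / (dr / 2)))
    dFe_dr <- A_int * (0.5 * mp[-1] * d_int + D_int / dr)
    diag_J <- g$vol * phi_storage_deriv(medium, eos, rho) / dt -
      dFe_dl + c(0, dFe_dr)
    upper <- -dFe_dr                      # d resid_i / d rho_{i+1}
    lower <- dFe_dl[-n]                   # d resid_{i+1} / d rho_i = +dFe_dl
    delta <- thomas_solve(lower, diag_J, upper, -resid)
    if (is.null(delta) || any(!is.finite(delta))) break
    # damp overly large updates (interface cells move O(100) per step)
    fac <- min(1, 0.3 * eos$b / max(abs(delta)))
    rho <- pmin(pmax(rho + fac * delta, eps_dom), eos$b - eps_dom)
    iters <- iters + 1L
  }
  if (!converged)
    return(list(state = NULL, converged = FALSE, iters = iters,
                boundary_flux = NA_real_, mass_residual = NA_real_))
  bflux <- A_bnd * 0.5 * (mobility(medium, eos, rho[n]) + m_L) *
    (rho_L - rho[n]) / (dr / 2)
  dstore <- sum(g$vol * (phi_storage(medium, eos, rho) - phi_old))
  # relative to the total storage capacity of the domain (the same scale
  # that bounds the Newton residual), so quiet steps report ~0, not 0/0
  denom <- sum(g$vol) * phi_storage_deriv(medium, eos, rho_L) * rho_L
  list(state = density_field(g, rho, state$t + dt),
       converged = TRUE, iters = iters, boundary_flux = bflux,
       mass_residual = abs(dstore - bflux * dt) / denom)
}

#' Simulate spherical bubble collapse to completion
#'
#' Integrates the spherical density equation from a smoothed bubble initial
#' condition until the vapor region vanishes (or `t_max` is reached), with
#' adaptive backward-Euler stepping: the step grows geometrically after easy
#' Newton solves, is halved on Newton failure, and is capped so the bubble
#' interface travels at most `cfl` cells per step. For a static
#' overpressure the bubble radius decreases monotonically; collapse is
#' declared when it drops below `collapse_cells` cell widths, and after the
#' vapor region vanishes the fluid stays liquid (no regrowth), which the
#' returned trace makes checkable by integrating slightly past collapse.
#'
#' @param medium a [poroelastic_medium()].
#' @param eos a [fluid_eos()].
#' @param grid a [spherical_grid()].
#' @param forcing a [forcing_spec()] with `mode = "static"`; its `rho_L` is
#'   the imposed boundary density.
#' @param R0 initial bubble radius \[m\] (default `L/2`).
#' @param rho_in initial in-bubble density (default `eos$rho_v`).
#' @param width initial interface width \[m\] (default 4 cells).
#' @param control see [collapse_control()].
#' @return object of class `collapse_run`: list with `trace` (tibble of
#'   class `bubble_trace`: `t`, `R`, `dt`, `newton_iters`, `boundary_flux`,
#'   `mass_residual`), `collapse_time` (`NA` if not collapsed), `collapsed`,
#'   `snapshots` (list of [density_field()]), `state` (final field), and
#'   the run configuration.
#' @export
run_collapse <- function(medium, eos, grid, forcing = forcing_spec("static"),
                         R0 = grid$L / 2, rho_in = eos$rho_v,
                         width = 4 * grid$dr,
                         control = collapse_control()) {
  if (forcing$mode != "static")
    stop("the spherical solver supports static forcing only", call. = FALSE)
  rho_L <- forcing$rho_L
  if (!(rho_L > 0 && rho_L < eos$b))
    stop("rho_L outside (0, b)", call. = FALSE)
  state <- initial_condition(grid, R0, rho_in, rho_L, width)
  R <- bubble_radius(state, eos)

  dt <- control$dt0
  t_rec <- 0; R_rec <- R; dt_rec <- NA_real_; it_rec <- NA_integer_
  bf_rec <- NA_real_; mr_rec <- NA_real_
  collapse_time <- NA_real_
  t_zero <- NA_real_   # first time the vapor region has fully vanished
  snap_times <- numeric(0)
  snapshots <- list(state)

  repeat {
    dt <- min(dt, control$t_max - state$t)
    res <- spherical_step(state, medium, eos, dt, rho_L, control)
    if (!res$converged) {
      dt <- dt / 2
      if (dt < control$dt_min)
        stop("time step underflow: Newton failed repeatedly", call. = FALSE)
      next
    }
    R_new <- bubble_radius(res$state, eos)
    speed <- abs(R_new - R) / dt
    state <- res$state
    t_rec <- c(t_rec, state$t); R_rec <- c(R_rec, R_new)
    dt_rec <- c(dt_rec, dt); it_rec <- c(it_rec, res$iters)
    bf_rec <- c(bf_rec, res$boundary_flux); mr_rec <- c(mr_rec, res$mass_residual)

    if (is.na(collapse_time) && R_new < control$collapse_cells * grid$dr)
      collapse_time <- state$t
    if (is.na(t_zero) && R_new == 0) t_zero <- state$t
    R <- R_new

    done_collapse <- !is.na(t_zero) &&
      state$t >= t_zero + control$t_after_frac * max(collapse_time, t_zero)
    if (done_collapse || state$t >= control$t_max) break

    # adapt: growth on easy steps, interface-CFL cap
    if (res$iters <= 4) dt <- dt * control$grow
    if (speed > 0) dt <- min(dt, control$cfl * grid$dr / speed)

    # thin snapshot collection at log-spaced radii
    if (length(snapshots) < control$n_snapshots + 1 &&
        R_new < R0 * (1 - length(snapshots) / (control$n_snapshots + 1))) {
      snapshots[[length(snapshots) + 1]] <- state
      snap_times <- c(snap_times, state$t)
    }
  }
  snapshots[[length(snapshots) + 1]] <- state

  trace <- tibble::tibble(t = t_rec, R = R_rec, dt = dt_rec,
                          newton_iters = it_rec, boundary_flux = bf_rec,
                          mass_residual = mr_rec)
  class(trace) <- c("bubble_trace", class(trace))
  structure(
    list(trace = trace, collapse_time = collapse_time,
         collapsed = !is.na(collapse_time), snapshots = snapshots,
         state = state, grid = grid, medium = medium, eos = eos,
         rho_L = rho_L, R0 = R0),
    class = "collapse_run"
  )
}

#' @export
print.collapse_run <- function(x, ...) {
  cat("<collapse_run> spherical bubble collapse\n")
  cat(sprintf("  L = %g m, n_cells = %d, R0 = %g m, rho_L = %g kg/m^3\n",
              x$grid$L, x$grid$n_cells, x$R0, x$rho_L))
  if (x$collapsed) {
    cat(sprintf("  collapsed at t_c = %.6g s (%d accepted steps)\n",
                x$collapse_time, nrow(x$trace) - 1L))
  } else {
    cat("  did not collapse within t_max\n")
  }
  cat(sprintf("  max per-step mass residual: %.3g\n",
              max(x$trace$mass_residual, na.rm = TRUE)))
  invisible(x)
}
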
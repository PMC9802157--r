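# Poroelastic Rayleigh-Plesset equation
#
# In the spherically symmetric, inertia-free limit the bubble radius obeys
#
#   R dR/dt (L - R)/L = -beta,
#   beta = [ k (p_L - p_B) / (phi0 mu) ]
#          / [ 1 + (rho_l - rho_v) F'(rho_R) / (phi0 M) ],
#
# where p_L is the (possibly time-dependent) boundary pressure, p_B the
# bubble pressure, M the P-wave modulus of the skeleton (Inf for a rigid
# medium, making the denominator 1), and rho_R a representative fluid
# density at the bubble interface, calibrated once against a full PDE run.

#' Boundary/bubble forcing specification
#'
#' Describes the outer pressure boundary condition and the bubble-interior
#' pressure model. In `static` mode the boundary pressure is `F(rho_L)`;
#' in `ultrasound` mode it is
#' `p_L(t) = F(rho_L) - (-1)^s p_amp sin(2 pi f t)`, so `s = 1` raises the
#' pressure over the first half-cycle (collapse first) and `s = 2` lowers
#' it (expansion first). The bubble is either pure vapor (`p_B = p_sat`,
#' the usual assumption without non-condensable gas) or vapor plus a
#' non-condensable gas obeying the polytropic law
#' `p_B = p_sat + p_g0 (R(0)/R)^{3 eta}` at fixed gas mass.
#'
#' @param mode `"static"` or `"ultrasound"`.
#' @param rho_L boundary density \[kg m^-3\].
#' @param p_amp ultrasonic wave amplitude \[Pa\].
#' @param freq wave frequency \[Hz\] (required in ultrasound mode).
#' @param s phase selector, 1 (collapse first) or 2 (expansion first).
#' @param bubble `"pure_vapor"` or `"ncg"`.
#' @param p_g0 non-condensable gas pressure at `R = R(0)` \[Pa\].
#' @param eta polytropic exponent (1.4 for adiabatic diatomic gas).
#' @return object of class `forcing_spec`.
#' @export
forcing_spec <- function(mode = c("static", "ultrasound"), rho_L = 998,
                         p_amp = 0, freq = NA_real_, s = 1,
                         bubble = c("pure_vapor", "ncg"),
                         p_g0 = 100, eta = 1.4) {
  mode <- match.arg(mode)
  bubble <- match.arg(bubble)
  if (p_amp < 0) stop("p_amp must be non-negative", call. = FALSE)
  if (mode == "ultrasound" && !(is.finite(freq) && freq > 0))
    stop("ultrasound mode requires a positive frequency", call. = FALSE)
  if (!s %in% c(1, 2)) stop("phase selector s must be 1 or 2", call. = FALSE)
  if (bubble == "ncg" && eta < 1)
    stop("polytropic exponent eta must be >= 1", call. = FALSE)
  structure(list(mode = mode, rho_L = rho_L, p_amp = p_amp, freq = freq,
                 s = s, bubble = bubble, p_g0 = p_g0, eta = eta),
            class = "forcing_spec")
}

#' Parameters of the poroelastic Rayleigh--Plesset equation
#'
#' Collects the constituents of the effective interface diffusivity `beta`.
#' The viscosity entering `beta` is the liquid viscosity `mu_l` (the
#' derivation integrates over the liquid region at constant permeability
#' and viscosity). `rho_R`, the representative fluid density at the bubble
#' interface, defaults to `NULL` and must be supplied (or obtained with
#' [calibrate_rho_R()]) for deformable media; rigid media never use it.
#'
#' @param L outer domain radius \[m\].
#' @param R0 initial bubble radius \[m\], in `(0, L)`.
#' @param medium a [poroelastic_medium()]; supplies `phi0`, `k`, `M`.
#' @param eos a [fluid_eos()]; supplies `mu_l`, `rho_v`, and `F'`.
#' @param rho_l liquid density entering the interface jump \[kg m^-3\].
#' @param rho_R interface density for `beta` \[kg m^-3\], in `(rho_v, b)`.
#' @return object of class `prp_params`.
#' @export
prp_params <- function(L, R0, medium, eos, rho_l = 998, rho_R = NULL) {
  stopifnot(R0 > 0, R0 < L)
  if (!is.null(rho_R) && !(rho_R > eos$rho_v && rho_R < eos$b))
    stop("rho_R must lie in (rho_v, b)", call. = FALSE)
  structure(list(L = L, R0 = R0, phi0 = medium$phi0, k = medium$k,
                 mu = eos$mu_l, M = medium$M, rho_l = rho_l,
                 rho_v = eos$rho_v, rho_R = rho_R),
            class = "prp_params")
}

#' Bubble interior pressure
#'
#' @param R bubble radius \[m\]; vectorized.
#' @param spec a [forcing_spec()].
#' @param eos a [fluid_eos()].
#' @param R0 initial radius \[m\] (reference for the polytropic gas law).
#' @return pressure \[Pa\].
#' @export
bubble_pressure <- function(R, spec, eos, R0) {
  if (any(R <= 0)) stop("bubble radius must be positive", call. = FALSE)
  if (spec$bubble == "pure_vapor") {
    rep(eos$p_sat, length(R))
  } else {
    eos$p_sat + spec$p_g0 * (R0 / R)^(3 * spec$eta)
  }
}

#' Outer boundary pressure
#'
#' @param t time \[s\]; vectorized.
#' @param spec a [forcing_spec()].
#' @param eos a [fluid_eos()].
#' @return pressure \[Pa\].
#' @export
boundary_pressure <- function(t, spec, eos) {
  p0 <- eos_pressure(eos, spec$rho_L)
  if (spec$mode == "static") {
    rep(p0, length(t))
  } else {
    p0 - (-1)^spec$s * spec$p_amp * sin(2 * pi * spec$freq * t)
  }
}

#' Effective interface diffusivity beta
#'
#' \deqn{\beta = \frac{k (p_L - p_B)/(\phi_0 \mu)}
#'   {1 + (\rho_l - \rho_v) F'(\rho_R)/(\phi_0 M)}.}
#' The sign of `beta` follows the sign of `p_L - p_B`; a rigid medium
#' (`M = Inf`) reduces the denominator to 1, and any finite `M` makes the
#' soft-medium `beta` smaller in magnitude than the rigid one.
#'
#' @param p_L boundary pressure \[Pa\].
#' @param p_B bubble pressure \[Pa\].
#' @param params a [prp_params()].
#' @param eos a [fluid_eos()].
#' @return beta \[m^2 s^-1\].
#' @export
beta_coefficient <- function(p_L, p_B, params, eos) {
  num <- params$k * (p_L - p_B) / (params$phi0 * params$mu)
  if (!is.finite(params$M)) return(num)
  if (is.null(params$rho_R))
    stop("rho_R is required for a deformable medium; see calibrate_rho_R()",
         call. = FALSE)
  num / (1 + (params$rho_l - params$rho_v) *
           eos_dpressure(eos, params$rho_R) / (params$phi0 * params$M))
}

#' Closed-form collapse time for constant beta
#'
#' Integrating `R dR (L - R)/L = -beta dt` from `R0` to 0 gives
#' `t_c = (R0^2/2 - R0^3/(3 L)) / beta`. For `R0 = L/2` this is
#' `L^2/(12 beta)`; for `L -> Inf` it tends to the classic diffusive limit
#' `R0^2/(2 beta)`.
#'
#' @param R0 initial bubble radius \[m\].
#' @param L outer radius \[m\] (may be `Inf`).
#' @param beta constant effective diffusivity \[m^2 s^-1\].
#' @return collapse time \[s\], or `NA` when `beta <= 0` (no collapse).
#' @export
collapse_time_closed_form <- function(R0, L, beta) {
  if (beta <= 0) return(NA_real_)
  (R0^2 / 2 - R0^3 / (3 * L)) / beta
}

#' Integrate the poroelastic Rayleigh--Plesset equation
#'
#' Solves `dR/dt = -beta L / (R (L - R))` with `beta` re-evaluated from the
#' instantaneous boundary pressure `p_L(t)` and bubble pressure `p_B(R)`.
#' Pure-vapor runs stop at the collapse event `R = R_min` (the equation is
#' singular at `R = 0`); non-condensable gas keeps `min R > 0` so the full
#' span is integrated. A stiff-capable implicit integrator (`lsoda` with
#' root finding) is used: ultrasound runs are stiff near the minimum
#' radius.
#'
#' @param params a [prp_params()].
#' @param spec a [forcing_spec()].
#' @param eos a [fluid_eos()].
#' @param t_max integration span \[s\].
#' @param n_out number of output times.
#' @param r_min_frac event threshold `R_min = r_min_frac * R0`.
#' @param rtol,atol solver tolerances.
#' @return tibble of class `bubble_trace` with columns `t`, `R`, `p_L`,
#'   `p_B`, `beta`; attributes `collapse_time` (`NA` if no event) and
#'   `collapsed`.
#' @export
rp_integrate <- function(params, spec, eos, t_max, n_out = 2000,
                         r_min_frac = 1e-4, rtol = 1e-9, atol = NULL) {
  R0 <- params$R0
  L <- params$L
  if (is.null(atol)) atol <- 1e-12 * R0
  rhs <- function(t, y, parms) {
    R <- min(max(y[1], 1e-12 * R0), L * (1 - 1e-12))
    pL <- boundary_pressure(t, spec, eos)
    pB <- bubble_pressure(R, spec, eos, R0)
    b <- beta_coefficient(pL, pB, params, eos)
    list(-b * L / (R * (L - R)))
  }
  rootfun <- if (spec$bubble == "pure_vapor") {
    function(t, y, parms) y[1] - r_min_frac * R0
  } else NULL
  times <- seq(0, t_max, length.out = n_out)
  sol <- deSolve::lsoda(c(R = R0), times, rhs, parms = NULL,
                        rtol = rtol, atol = atol, events = NULL,
                        rootfunc = rootfun, maxsteps = 1e5)
  t <- sol[, 1]; R <- sol[, 2]
  collapsed <- !is.null(rootfun) && attr(sol, "istate")[1] == 3
  collapse_time <- if (collapsed) t[length(t)] else NA_real_
  pL <- boundary_pressure(t, spec, eos)
  pB <- bubble_pressure(pmax(R, 1e-12 * R0), spec, eos, R0)
  out <- tibble::tibble(t = t, R = R, p_L = pL, p_B = pB,
                        beta = beta_coefficient(pL, pB, params, eos))
  class(out) <- c("bubble_trace", class(out))
  attr(out, "collapse_time") <- collapse_time
  attr(out, "collapsed") <- collapsed
  out
}

#' Collapse time from a Rayleigh--Plesset integration
#'
#' @param trace a trace returned by [rp_integrate()].
#' @return collapse time \[s\] or `NA`.
#' @export
rp_collapse_time <- function(trace) attr(trace, "collapse_time")

#' Calibrate the interface density rho_R against one PDE run
#'
#' The representative interface density `rho_R` entering `beta` is not
#' predicted by the reduced model; it is fixed by matching the
#' Rayleigh--Plesset collapse time to the collapse time of a single
#' high-fidelity PDE simulation (one finite Young's modulus), and the
#' calibrated value is then reused unchanged for all other parameter sets.
#' The collapse time increases monotonically with `rho_R` on the liquid
#' branch, so a bracketed scalar root solve suffices.
#'
#' @param t_c_target collapse time of the reference PDE run \[s\].
#' @param params a [prp_params()] for the matching geometry/medium
#'   (finite `M`); its `rho_R` is ignored.
#' @param spec a static [forcing_spec()].
#' @param eos a [fluid_eos()].
#' @param bracket search interval for `rho_R` \[kg m^-3\]; default spans
#'   `(rho_c, b)`, the branch on which `F'` is increasing.
#' @param tol relative tolerance on the matched collapse time.
#' @return calibrated `rho_R` \[kg m^-3\].
#' @export
calibrate_rho_R <- function(t_c_target, params, spec, eos,
                            bracket = c(eos$rho_c, eos$b * (1 - 1e-6)),
                            tol = 1e-10) {
  if (!is.finite(params$M))
    stop("calibration requires a deformable medium (finite M)", call. = FALSE)
  t_cap <- 1e3 * t_c_target
  tc_of <- function(rho_R) {
    p <- params; p$rho_R <- rho_R
    tr <- rp_integrate(p, spec, eos, t_max = t_cap, n_out = 10)
    tc <- rp_collapse_time(tr)
    if (is.na(tc)) t_cap else tc   # no collapse within the cap: overshoot
  }
  f <- function(rho_R) tc_of(rho_R) - t_c_target
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo * fhi > 0)
    stop("no rho_R in the bracket reproduces the target collapse time",
         call. = FALSE)
  uniroot(f, lower = bracket[1], upper = bracket[2],
          f.lower = flo, f.upper = fhi,
          tol = tol * (bracket[2] - bracket[1]))$root
}
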
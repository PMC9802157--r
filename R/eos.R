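#' Smoothed barotropic liquid--vapor equation of state
#'
#' Constructs the single-component liquid--vapor equation of state
#' \deqn{F(\rho) = p_{sat} + C\left(\frac{1}{\rho_c} - \frac{1}{\rho}\right)
#'   + C\,\frac{b-\rho_c}{\rho_c^2}\,\frac{\rho-\rho_c}{b-\rho},}
#' a smoothed barotropic law spanning the vapor, mixture and liquid branches.
#' `p_sat` is the saturation pressure, `rho_c` the density of minimum sound
#' speed (where `2C/rho_c` is the fluid bulk modulus), and `1/b` the fluid
#' covolume, so that the liquid stiffness diverges as the density approaches
#' `b`. The predicted squared sound speed `F'(rho)` is continuous in `rho`.
#'
#' The mixture viscosity follows the linear law
#' `mu(rho) = mu_v + (mu_l - mu_v) (rho - rho_v)/b`, clamped to
#' `[mu_v, mu_l]`. `rho_v` is a representative vapor density used in the
#' viscosity law and in initial/bubble conditions; it is *not* obtained by
#' inverting `F` at `p_sat` (that inverse is `rho_c` by construction).
#'
#' @param p_sat saturation pressure \[Pa\].
#' @param C equation-of-state stiffness \[Pa kg m^-3\].
#' @param b liquid-limit density (reciprocal covolume) \[kg m^-3\].
#' @param rho_c density of minimum sound speed \[kg m^-3\].
#' @param rho_v representative vapor density \[kg m^-3\].
#' @param mu_l,mu_v liquid and vapor dynamic viscosities \[Pa s\].
#' @return An object of class `fluid_eos`.
#' @seealso [eos_pressure()], [eos_viscosity()], [preset_table1()]
#' @examples
#' eos <- fluid_eos()
#' eos_pressure(eos, c(8.8, 500, 998))
#' @export
fluid_eos <- function(p_sat = 2339, C = 1450, b = 998.5, rho_c = 500,
                      rho_v = 8.8, mu_l = 1e-3, mu_v = 1.3e-5) {
  stopifnot(is.numeric(p_sat), is.numeric(C), is.numeric(b),
            is.numeric(rho_c), is.numeric(rho_v))
  if (!(rho_v > 0 && rho_v < rho_c && rho_c < b))
    stop("require 0 < rho_v < rho_c < b", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (p_sat <= 0) stop("p_sat must be positive", call. = FALSE)
  if (!(mu_v < mu_l)) stop("require mu_v < mu_l", call. = FALSE)
  structure(
    list(p_sat = p_sat, C = C, b = b, rho_c = rho_c, rho_v = rho_v,
         mu_l = mu_l, mu_v = mu_v),
    class = "fluid_eos"
  )
}

#' @export
print.fluid_eos <- function(x, ...) {
  cat("<fluid_eos> barotropic liquid-vapor law\n")
  cat(sprintf("  p_sat = %g Pa, C = %g Pa kg/m^3, b = %g, rho_c = %g, rho_v = %g kg/m^3\n",
              x$p_sat, x$C, x$b, x$rho_c, x$rho_v))
  cat(sprintf("  mu_l = %g, mu_v = %g Pa s\n", x$mu_l, x$mu_v))
  invisible(x)
}

check_rho_domain <- function(eos, rho) {
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho >= eos$b))
    stop("density outside the EOS domain (0, b): covolume singularity",
         call. = FALSE)
}

#' Pore pressure from density
#'
#' Evaluates the barotropic law `p = F(rho)`. `F` is strictly increasing on
#' `(0, b)`: its derivative `C/rho^2 + C (b-rho_c)^2 / (rho_c^2 (b-rho)^2)`
#' is positive. `F(rho_c) = p_sat` exactly (both correction terms vanish at
#' `rho = rho_c`).
#'
#' @param eos a [fluid_eos()] object.
#' @param rho density \[kg m^-3\], in `(0, b)`; vectorized.
#' @return pressure \[Pa\].
#' @export
eos_pressure <- function(eos, rho) {
  check_rho_domain(eos, rho)
  eos$p_sat + eos$C * (1 / eos$rho_c - 1 / rho) +
    eos$C * (eos$b - eos$rho_c) / eos$rho_c^2 * (rho - eos$rho_c) / (eos$b - rho)
}

#' Pressure derivative dF/drho
#'
#' Analytic derivative of the barotropic law,
#' `F'(rho) = C/rho^2 + C (b-rho_c)^2 / (rho_c^2 (b-rho)^2)`, always
#' positive on `(0, b)`. This is also the squared sound speed.
#'
#' @inheritParams eos_pressure
#' @return dp/drho \[Pa m^3 kg^-1\].
#' @export
eos_dpressure <- function(eos, rho) {
  check_rho_domain(eos, rho)
  eos$C / rho^2 +
    eos$C * (eos$b - eos$rho_c)^2 / (eos$rho_c^2 * (eos$b - rho)^2)
}

#' Storage function W(rho) = rho F'(rho)
#'
#' The compressibility-weighted density that appears in both the storage and
#' the mobility coefficients of the flow equation. At `rho = rho_c` it equals
#' `2C/rho_c`, the fluid bulk modulus at minimum sound speed.
#'
#' @inheritParams eos_pressure
#' @return W \[Pa\].
#' @export
eos_storage <- function(eos, rho) {
  rho * eos_dpressure(eos, rho)
}

# Antiderivative of F (up to a constant); used for conservative storage.
eos_int_pressure <- function(eos, rho) {
  check_rho_domain(eos, rho)
  eos$p_sat * rho + eos$C * (rho / eos$rho_c - log(rho)) +
    eos$C * (eos$b - eos$rho_c) / eos$rho_c^2 *
      (-rho - (eos$b - eos$rho_c) * log(eos$b - rho))
}

#' Antiderivative of the storage function
#'
#' Returns `Psi(rho)` with `Psi'(rho) = W(rho) = rho F'(rho)`, computed in
#' closed form as `rho F(rho) - int F`. Only differences of `Psi` are
#' meaningful; the additive constant is arbitrary. Used to write the discrete
#' storage term in conservation form so that per-step mass balance holds to
#' the nonlinear-solver tolerance.
#'
#' @inheritParams eos_pressure
#' @return Psi \[Pa kg m^-3\].
#' @export
eos_storage_integral <- function(eos, rho) {
  rho * eos_pressure(eos, rho) - eos_int_pressure(eos, rho)
}

#' Mixture dynamic viscosity
#'
#' Linear mixing law `mu(rho) = mu_v + (mu_l - mu_v)(rho - rho_v)/b`, clamped
#' to `[mu_v, mu_l]` to guard against transient overshoot of `rho` outside
#' `[rho_v, b]` during nonlinear iterations.
#'
#' @param eos a [fluid_eos()] object.
#' @param rho density \[kg m^-3\]; vectorized, any positive value.
#' @return dynamic viscosity \[Pa s\].
#' @export
eos_viscosity <- function(eos, rho) {
  mu <- eos$mu_v + (eos$mu_l - eos$mu_v) * (rho - eos$rho_v) / eos$b
  pmin(eos$mu_l, pmax(eos$mu_v, mu))
}

#' Squared sound speed
#'
#' `c^2 = dp/drho = F'(rho)`, continuous in `rho` (the minimum lies near
#' `rho_c`; the exact minimizer solves `(b-rho)/rho = ((b-rho_c)/rho_c)^{2/3}`).
#'
#' @inheritParams eos_pressure
#' @return squared sound speed \[m^2 s^-2\].
#' @export
eos_sound_speed_sq <- function(eos, rho) {
  eos_dpressure(eos, rho)
}

#' Invert the equation of state
#'
#' Finds the unique density with `F(rho) = p`, using monotonicity of `F` and
#' a bracketed root solve on `(0, b)`.
#'
#' @param eos a [fluid_eos()] object.
#' @param p pressure \[Pa\]; vectorized.
#' @param tol relative tolerance of the root solve.
#' @return density \[kg m^-3\].
#' @export
eos_density_from_pressure <- function(eos, p, tol = 1e-12) {
  lo <- eos$b * 1e-9
  hi <- eos$b * (1 - 1e-12)
  p_lo <- eos_pressure(eos, lo)
  p_hi <- eos_pressure(eos, hi)
  vapply(p, function(pi) {
    if (!is.finite(pi) || pi <= p_lo || pi >= p_hi)
      stop("pressure outside the range of F on (0, b)", call. = FALSE)
    uniroot(function(r) eos_pressure(eos, r) - pi,
            lower = lo, upper = hi, tol = tol * eos$b)$root
  }, numeric(1))
}
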
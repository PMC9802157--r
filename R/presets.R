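#' Reference parameter preset (water in a generic soft porous material)
#'
#' Returns the fixed model parameters used throughout: a water-like
#' liquid--vapor equation of state (`p_sat` = 2339 Pa, `C` = 1450 Pa kg/m^3,
#' `b` = 998.5 kg/m^3, `rho_c` = 500 kg/m^3, `mu_l` = 1e-3 Pa s,
#' `mu_v` = 1.3e-5 Pa s, `rho_v` = 8.8 kg/m^3) and the pore-structure
#' defaults of a generic soft tissue-like material (`alpha` = 1,
#' `k` = 1e-13 m^2, `phi0` = 0.01, incompressible grains `Ks_inv` = 0).
#' Elastic moduli are not part of the preset; supply `E` and `nu` through
#' [table1_medium()] or [poroelastic_medium()].
#'
#' @return list with elements `eos` (a [fluid_eos()]) and `medium_defaults`
#'   (named list `alpha`, `Ks_inv`, `phi0`, `k`).
#' @examples
#' p <- preset_table1()
#' eos_pressure(p$eos, 500)  # = p_sat
#' @export
preset_table1 <- function() {
  list(
    eos = fluid_eos(p_sat = 2339, C = 1450, b = 998.5, rho_c = 500,
                    rho_v = 8.8, mu_l = 1e-3, mu_v = 1.3e-5),
    medium_defaults = list(alpha = 1, Ks_inv = 0, phi0 = 0.01, k = 1e-13)
  )
}

#' Poroelastic medium with the reference pore-structure parameters
#'
#' Convenience wrapper around [poroelastic_medium()] using the
#' [preset_table1()] pore-structure defaults.
#'
#' @param E Young's modulus \[Pa\] (`Inf` for rigid).
#' @param nu Poisson ratio.
#' @return a [poroelastic_medium()].
#' @export
table1_medium <- function(E = Inf, nu = 0.45) {
  d <- preset_table1()$medium_defaults
  poroelastic_medium(E = E, nu = nu, alpha = d$alpha, Ks_inv = d$Ks_inv,
                     phi0 = d$phi0, k = d$k)
}
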
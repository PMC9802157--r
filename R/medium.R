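#' Poroelastic medium parameters
#'
#' Describes the fluid-saturated solid skeleton: elasticity (Young's modulus
#' `E`, Poisson ratio `nu`) and pore structure (Biot coefficient `alpha`,
#' grain compressibility `Ks_inv = 1/K_s`, reference porosity `phi0`,
#' absolute permeability `k`). Derived quantities follow linear isotropic
#' elasticity:
#' \deqn{\lambda = \frac{E\nu}{(1+\nu)(1-2\nu)}, \quad
#'       G = \frac{E}{2(1+\nu)}, \quad
#'       M = \lambda + 2G = \frac{E(1-\nu)}{(1+\nu)(1-2\nu)},}
#' where `M` is the P-wave (uniaxial-strain) modulus. The Biot storage
#' compressibilities are `1/N = (alpha - phi0) Ks_inv` and
#' `B = 1/N + alpha^2 / M`; the rigid limit `E = Inf` gives `B = 1/N`
#' (and `B = 0` for incompressible grains, `Ks_inv = 0`).
#'
#' @param E Young's modulus \[Pa\]; `Inf` for a rigid skeleton.
#' @param nu Poisson ratio; ignored in the rigid limit.
#' @param alpha Biot coefficient in `(phi0, 1]`.
#' @param Ks_inv grain compressibility `1/K_s` \[Pa^-1\] (0 for
#'   incompressible grains, the usual soft-tissue assumption).
#' @param phi0 reference porosity of the undeformed skeleton.
#' @param k absolute permeability \[m^2\].
#' @return An object of class `poroelastic_medium` with fields
#'   `lambda`, `G`, `M`, `Ninv`, `B` in addition to the inputs.
#' @examples
#' poroelastic_medium(E = 15e3, nu = 0.45)
#' poroelastic_medium(E = Inf)  # rigid skeleton
#' @export
poroelastic_medium <- function(E = Inf, nu = 0.45, alpha = 1, Ks_inv = 0,
                               phi0 = 0.01, k = 1e-13) {
  stopifnot(is.numeric(E), length(E) == 1, E > 0)
  if (!(phi0 > 0 && phi0 < alpha && alpha <= 1))
    stop("require 0 < phi0 < alpha <= 1", call. = FALSE)
  if (Ks_inv < 0) stop("Ks_inv must be non-negative", call. = FALSE)
  if (k <= 0) stop("permeability k must be positive", call. = FALSE)
  if (is.finite(E)) {
    if (!(nu > -1 && nu < 0.5))
      stop("Poisson ratio must lie in (-1, 0.5)", call. = FALSE)
    lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
    G <- E / (2 * (1 + nu))
    M <- lambda + 2 * G
  } else {
    lambda <- Inf; G <- Inf; M <- Inf
  }
  Ninv <- (alpha - phi0) * Ks_inv
  B <- Ninv + if (is.finite(M)) alpha^2 / M else 0
  structure(
    list(E = E, nu = nu, alpha = alpha, Ks_inv = Ks_inv, phi0 = phi0, k = k,
         lambda = lambda, G = G, M = M, Ninv = Ninv, B = B),
    class = "poroelastic_medium"
  )
}

#' Is the skeleton rigid?
#'
#' @param medium a [poroelastic_medium()].
#' @return `TRUE` when `E = Inf`.
#' @export
is_rigid <- function(medium) !is.finite(medium$E)

#' @export
print.poroelastic_medium <- function(x, ...) {
  cat("<poroelastic_medium>\n")
  if (is_rigid(x)) {
    cat("  rigid skeleton (E = Inf)\n")
  } else {
    cat(sprintf("  E = %g Pa, nu = %g  ->  lambda = %g, G = %g, M = %g Pa\n",
                x$E, x$nu, x$lambda, x$G, x$M))
  }
  cat(sprintf("  alpha = %g, Ks_inv = %g 1/Pa, phi0 = %g, k = %g m^2\n",
              x$alpha, x$Ks_inv, x$phi0, x$k))
  cat(sprintf("  1/N = %g, B = %g 1/Pa\n", x$Ninv, x$B))
  invisible(x)
}
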
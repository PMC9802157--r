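#' Spherical finite-volume grid
#'
#' Uniform cell-centered grid on the radial domain `(0, L)`. Face radii span
#' `[0, L]`; cell volumes carry the spherical metric `(r_e^3 - r_w^3)/3`
#' (the common factor `4*pi` is omitted consistently throughout the solver).
#' The `r = 0` face carries zero flux by symmetry.
#'
#' @param L domain radius \[m\].
#' @param n_cells number of cells.
#' @return An object of class `spherical_grid` with fields `faces`,
#'   `centers`, `dr`, `vol`, `L`, `n_cells`.
#' @export
spherical_grid <- function(L = 1e-3, n_cells = 1024) {
  stopifnot(L > 0, n_cells >= 4)
  faces <- seq(0, L, length.out = n_cells + 1)
  structure(
    list(L = L, n_cells = as.integer(n_cells), faces = faces,
         centers = 0.5 * (faces[-1] + faces[-(n_cells + 1)]),
         dr = L / n_cells,
         vol = diff(faces^3) / 3),
    class = "spherical_grid"
  )
}

#' Discrete 1D density field
#'
#' @param grid a [spherical_grid()].
#' @param rho density per cell \[kg m^-3\].
#' @param t time \[s\].
#' @return object of class `density_field_1d`.
#' @export
density_field <- function(grid, rho, t = 0) {
  stopifnot(length(rho) == grid$n_cells, all(rho > 0))
  structure(list(grid = grid, rho = rho, t = t), class = "density_field_1d")
}

#' Initial bubble density profile
#'
#' Smooth monotone profile transitioning from `rho_in` (inside the bubble,
#' `r < R0`) to `rho_out` (liquid, `r > R0`) over a transition length
#' `width`, via a tanh regularization of the sharp-interface (Heaviside)
#' profile. As `width -> 0` the profile tends to the step
#' `rho_in + (rho_out - rho_in) H(r - R0)`.
#'
#' @param grid a [spherical_grid()].
#' @param R0 initial bubble radius \[m\], in `(0, L)`.
#' @param rho_in in-bubble (vapor) density \[kg m^-3\].
#' @param rho_out outer (liquid) density \[kg m^-3\].
#' @param width interface transition length \[m\]; default 4 cells. A width
#'   below the grid resolution triggers a warning (under-resolved interface).
#' @return a [density_field()] at `t = 0`.
#' @export
initial_condition <- function(grid, R0, rho_in, rho_out,
                              width = 4 * grid$dr) {
  stopifnot(R0 > 0, R0 < grid$L, width > 0, rho_in > 0, rho_out > 0)
  if (width < grid$dr)
    warning("interface width below grid resolution; profile under-resolved",
            call. = FALSE)
  s <- 0.5 * (1 + tanh(2 * (grid$centers - R0) / width))
  density_field(grid, rho_in + (rho_out - rho_in) * s, t = 0)
}

#' Bubble radius of a density field
#'
#' Locates the liquid--vapor interface as the largest radius where the
#' density crosses the threshold `rho* = rho_c` (the midpoint of the EOS
#' mixture branch), by linear interpolation between cell centers. Returns 0
#' if the field is everywhere above the threshold (all liquid) and `L` if it
#' is everywhere below.
#'
#' @param state a [density_field()].
#' @param eos a [fluid_eos()]; supplies the threshold `rho_c`.
#' @return interface radius \[m\].
#' @export
bubble_radius <- function(state, eos) {
  g <- state$grid
  d <- state$rho - eos$rho_c
  if (all(d >= 0)) return(0)
  if (all(d < 0)) return(g$L)
  cross <- which(d[-1] * d[-g$n_cells] <= 0 & d[-1] != d[-g$n_cells])
  if (length(cross) == 0L) return(0)
  i <- max(cross)
  r1 <- g$centers[i]; r2 <- g$centers[i + 1]
  r1 + (r2 - r1) * (0 - d[i]) / (d[i + 1] - d[i])
}

#' Solid radial displacement from the density field
#'
#' In the spherically symmetric reduction the momentum balance integrates to
#' \deqn{u_r(r) = -\frac{\alpha p_L}{3M} r
#'   + \frac{\alpha}{M r^2}\int_0^r z^2 F(\rho(z))\,dz,}
#' evaluated here by cumulative quadrature exact for the piecewise-constant
#' cell densities. Displacements are returned at cell faces with
#' `u_r(0) = 0`. A rigid medium (`M = Inf`) returns an identically zero
#' field.
#'
#' @param state a [density_field()].
#' @param medium a [poroelastic_medium()].
#' @param eos a [fluid_eos()].
#' @param p_L boundary fluid pressure \[Pa\].
#' @return tibble with columns `r` (face radii) and `u_r` \[m\].
#' @export
displacement <- function(state, medium, eos, p_L) {
  g <- state$grid
  if (is_rigid(medium))
    return(tibble::tibble(r = g$faces, u_r = rep(0, g$n_cells + 1)))
  cum <- c(0, cumsum(eos_pressure(eos, state$rho) * g$vol))
  r <- g$faces
  u <- -medium$alpha * p_L / (3 * medium$M) * r
  pos <- r > 0
  u[pos] <- u[pos] + medium$alpha / (medium$M * r[pos]^2) * cum[pos]
  tibble::tibble(r = r, u_r = u)
}

#' Volumetric strain of the solid skeleton
#'
#' From the integrated momentum balance, `M eps_v = alpha (p - p_L)`, so
#' `eps_v(r) = alpha (F(rho(r)) - p_L)/M` at cell centers. Satisfies
#' `eps_v(L) = 0` whenever the boundary density obeys `F(rho_L) = p_L`.
#' Rigid media give a zero field.
#'
#' @inheritParams displacement
#' @return tibble with columns `r` (cell centers) and `eps_v` \[-\].
#' @export
volumetric_strain <- function(state, medium, eos, p_L) {
  g <- state$grid
  if (is_rigid(medium))
    return(tibble::tibble(r = g$centers, eps_v = rep(0, g$n_cells)))
  tibble::tibble(
    r = g$centers,
    eps_v = medium$alpha * (eos_pressure(eos, state$rho) - p_L) / medium$M
  )
}
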
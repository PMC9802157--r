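#' Structured axisymmetric cylindrical mesh
#'
#' Uniform structured quadrilateral mesh on the axisymmetric half-plane
#' `[0, r_max] x [0, z_max]`. The axis of symmetry is at radial coordinate
#' 0 and the solid wall at axial coordinate 0. Cell volumes carry the
#' cylindrical metric `0.5 (r_e^2 - r_w^2) dz` per radian (the factor
#' `2*pi` is omitted consistently; [vapor_volume()] restores it).
#'
#' @param r_max radial extent \[m\].
#' @param z_max axial extent \[m\].
#' @param nr,nz cell counts in the radial and axial directions.
#' @return object of class `cyl_mesh`. Cells are numbered radially fastest:
#'   cell `(i, j)` has index `(j-1)*nr + i`.
#' @export
cyl_mesh <- function(r_max = 5e-3, z_max = 6.5e-3, nr = 100, nz = 65) {
  stopifnot(r_max > 0, z_max > 0, nr >= 2, nz >= 2)
  dr <- r_max / nr
  dz <- z_max / nz
  r_faces <- seq(0, r_max, length.out = nr + 1)
  z_faces <- seq(0, z_max, length.out = nz + 1)
  rc <- 0.5 * (r_faces[-1] + r_faces[-(nr + 1)])
  zc <- 0.5 * (z_faces[-1] + z_faces[-(nz + 1)])
  ring <- 0.5 * diff(r_faces^2)          # per-radian annulus area
  ii <- rep(seq_len(nr), nz)
  jj <- rep(seq_len(nz), each = nr)
  structure(
    list(r_max = r_max, z_max = z_max, nr = as.integer(nr),
         nz = as.integer(nz), dr = dr, dz = dz,
         r_faces = r_faces, z_faces = z_faces, rc = rc, zc = zc,
         cell_r = rc[ii], cell_z = zc[jj], cell_i = ii, cell_j = jj,
         ring = ring, vol = ring[ii] * dz,
         n_cells = as.integer(nr * nz)),
    class = "cyl_mesh"
  )
}

#' Coupled 2D state (fluid density + solid displacement)
#'
#' @param mesh a [cyl_mesh()].
#' @param rho density per cell \[kg m^-3\].
#' @param u solid displacement per node dof \[m\] (`NULL` for a rigid run).
#' @param eps_v volumetric strain per cell \[-\] (`NULL` for rigid).
#' @param t time \[s\].
#' @param eps_t nonlocal strain remainder `eps_v - alpha p/M` per cell,
#'   maintained by the coupled stepper (`NULL` for rigid).
#' @return object of class `coupled_state_2d`.
#' @export
coupled_state <- function(mesh, rho, u = NULL, eps_v = NULL, t = 0,
                          eps_t = NULL) {
  stopifnot(length(rho) == mesh$n_cells, all(rho > 0))
  structure(list(mesh = mesh, rho = rho, u = u, eps_v = eps_v,
                 eps_t = eps_t, t = t),
            class = "coupled_state_2d")
}

#' Total vapor volume of a 2D state
#'
#' Volume (in m^3, factor `2*pi` included) of the region with density below
#' the interface threshold `rho_c`.
#'
#' @param state a [coupled_state()].
#' @param eos a [fluid_eos()].
#' @return vapor volume \[m^3\].
#' @export
vapor_volume <- function(state, eos) {
  2 * pi * sum(state$mesh$vol[state$rho < eos$rho_c])
}

#' Equivalent spherical radius of the vapor region
#'
#' @inheritParams vapor_volume
#' @return radius of the sphere with the same volume \[m\].
#' @export
equivalent_radius <- function(state, eos) {
  (3 * vapor_volume(state, eos) / (4 * pi))^(1 / 3)
}

#' Bubble interface contour
#'
#' Extracts the `rho = rho_c` level set of a 2D density field as polyline
#' segments in the `(r, z)` plane.
#'
#' @inheritParams vapor_volume
#' @return tibble with columns `piece`, `r`, `z`.
#' @export
interface_contour <- function(state, eos) {
  m <- state$mesh
  cl <- grDevices::contourLines(m$rc, m$zc,
                                matrix(state$rho, m$nr, m$nz),
                                levels = eos$rho_c)
  if (length(cl) == 0L)
    return(tibble::tibble(piece = integer(0), r = numeric(0), z = numeric(0)))
  do.call(rbind, lapply(seq_along(cl), function(k)
    tibble::tibble(piece = k, r = cl[[k]]$x, z = cl[[k]]$y)))
}
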
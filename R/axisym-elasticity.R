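# Axisymmetric linear elasticity on the structured mesh
#
# Weak form of  div(sigma_eff) = alpha grad(p)  with total-traction-free
# outer boundaries (sigma_eff . n = alpha p n there):
#
#   int sigma_eff(u) : eps(v) r dr dz  =  int alpha p div(v) r dr dz
#
# for all v vanishing on the Dirichlet part.  All boundary terms cancel
# against the traction condition, so the load is a volume integral of the
# cell-wise pressure against the divergence of the test functions.
# Bilinear (Q1) elements, 2x2 Gauss quadrature with the radial weight r;
# strain components (err, ezz, e_theta, g_rz) with e_theta = u_r / r.

# local node order: (-1,-1), (1,-1), (1,1), (-1,1)
q1_gauss <- function() {
  g <- 1 / sqrt(3)
  list(xi = c(-g, g, g, -g), eta = c(-g, -g, g, g),
       xin = c(-1, 1, 1, -1), etan = c(-1, -1, 1, 1))
}

# element stiffness, divergence-load vector and center strain operator for
# a column of cells with west face radius r_w (all cells in a radial column
# share the same geometry)
q1_column_ops <- function(r_w, dr, dz, lambda, G) {
  gp <- q1_gauss()
  D <- matrix(c(lambda + 2 * G, lambda, lambda, 0,
                lambda, lambda + 2 * G, lambda, 0,
                lambda, lambda, lambda + 2 * G, 0,
                0, 0, 0, G), 4, 4)
  detJ <- dr * dz / 4
  Ke <- matrix(0, 8, 8)
  ge <- numeric(8)
  for (q in 1:4) {
    xi <- gp$xi[q]; eta <- gp$eta[q]
    N <- 0.25 * (1 + gp$xin * xi) * (1 + gp$etan * eta)
    dNdr <- 0.25 * gp$xin * (1 + gp$etan * eta) * 2 / dr
    dNdz <- 0.25 * gp$etan * (1 + gp$xin * xi) * 2 / dz
    r <- r_w + dr * (1 + xi) / 2
    B <- matrix(0, 4, 8)
    ur <- seq(1, 8, by = 2); uz <- seq(2, 8, by = 2)
    B[1, ur] <- dNdr
    B[2, uz] <- dNdz
    B[3, ur] <- N / r
    B[4, ur] <- dNdz
    B[4, uz] <- dNdr
    Ke <- Ke + crossprod(B, D %*% B) * r * detJ
    ge[ur] <- ge[ur] + (dNdr + N / r) * r * detJ
    ge[uz] <- ge[uz] + dNdz * r * detJ
  }
  list(Ke = Ke, ge = ge)
}

#' Discrete axisymmetric elasticity operator
#'
#' Assembles the Q1 finite-element stiffness for the effective-stress
#' balance, the pressure-divergence load operator, and the cell-center
#' volumetric-strain operator, applies the Dirichlet boundary conditions,
#' and factors the reduced stiffness once (it is reused for every pressure
#' field). Boundary conditions are given per boundary:
#' `"fixed"` (both components zero), `"roller"` (normal component zero),
#' or `"free"` (total-traction-free); the axis is always treated as a
#' symmetry boundary (`u_r = 0`).
#'
#' @param mesh a [cyl_mesh()].
#' @param medium a [poroelastic_medium()] with finite `E`.
#' @param bcs list with entries `bottom`, `side`, `top` (defaults:
#'   bottom `"fixed"`, side and top `"free"` — the near-wall setup).
#' @return object of class `elasticity_operator`.
#' @export
elasticity_operator <- function(mesh, medium,
                                bcs = list(bottom = "fixed", side = "free",
                                           top = "free")) {
  if (is_rigid(medium))
    stop("elasticity operator requires finite E", call. = FALSE)
  nr <- mesh$nr; nz <- mesh$nz
  n_nodes <- (nr + 1) * (nz + 1)
  ndof <- 2 * n_nodes

  # cell -> node connectivity (local order ll, lr, ur, ul)
  ci <- mesh$cell_i; cj <- mesh$cell_j
  nid_ll <- (cj - 1) * (nr + 1) + ci
  nid_lr <- nid_ll + 1
  nid_ul <- cj * (nr + 1) + ci
  nid_ur <- nid_ul + 1
  nodes <- cbind(nid_ll, nid_lr, nid_ur, nid_ul)
  dofs <- matrix(0L, mesh$n_cells, 8)
  dofs[, seq(1, 8, 2)] <- 2L * nodes - 1L   # u_r
  dofs[, seq(2, 8, 2)] <- 2L * nodes        # u_z

  # element operators per radial column
  Kcols <- vector("list", nr); gcols <- vector("list", nr)
  for (i in seq_len(nr)) {
    ops <- q1_column_ops(mesh$r_faces[i], mesh$dr, mesh$dz,
                         medium$lambda, medium$G)
    Kcols[[i]] <- ops$Ke; gcols[[i]] <- ops$ge
  }
  Kvals <- t(vapply(ci, function(i) as.numeric(Kcols[[i]]), numeric(64)))
  gvals <- t(vapply(ci, function(i) gcols[[i]], numeric(8)))

  ii <- as.integer(dofs[, rep(1:8, times = 8)])
  jj <- as.integer(dofs[, rep(1:8, each = 8)])
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(Kvals),
                            dims = c(ndof, ndof))
  Gdiv <- Matrix::sparseMatrix(i = as.integer(dofs),
                               j = rep(seq_len(mesh$n_cells), 8),
                               x = as.numeric(gvals),
                               dims = c(ndof, mesh$n_cells))

  # cell-center volumetric strain operator
  xin <- c(-1, 1, 1, -1); etan <- c(-1, -1, 1, 1)
  evals <- matrix(0, mesh$n_cells, 8)
  for (a in 1:4) {
    evals[, 2 * a - 1] <- 0.5 * xin[a] / mesh$dr + 0.25 / mesh$cell_r
    evals[, 2 * a]     <- 0.5 * etan[a] / mesh$dz
  }
  Ecell <- Matrix::sparseMatrix(i = rep(seq_len(mesh$n_cells), 8),
                                j = as.integer(dofs),
                                x = as.numeric(evals),
                                dims = c(mesh$n_cells, ndof))

  # Dirichlet dofs
  node_p <- rep(0:nr, nz + 1)
  node_q <- rep(0:nz, each = nr + 1)
  fixed <- 2L * which(node_p == 0L) - 1L            # axis: u_r = 0
  pick <- function(sel, comp) {
    w <- which(sel)
    if (comp == "both") c(2L * w - 1L, 2L * w) else
      if (comp == "ur") 2L * w - 1L else 2L * w
  }
  add_bc <- function(kind, sel, normal) {
    if (kind == "fixed") pick(sel, "both")
    else if (kind == "roller") pick(sel, normal)
    else integer(0)
  }
  fixed <- c(fixed,
             add_bc(bcs$bottom %||% "fixed", node_q == 0L, "uz"),
             add_bc(bcs$side %||% "free", node_p == nr, "ur"),
             add_bc(bcs$top %||% "free", node_q == nz, "uz"))
  fixed <- sort(unique(fixed))
  free <- setdiff(seq_len(ndof), fixed)
  if (length(free) == ndof)
    stop("all-traction boundary conditions leave the system singular",
         call. = FALSE)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  structure(
    list(mesh = mesh, medium = medium, bcs = bcs, ndof = ndof,
         K = K, Gdiv = Gdiv, Ecell = Ecell,
         free = free, fixed = fixed,
         chol = Matrix::Cholesky(Kff, LDL = FALSE)),
    class = "elasticity_operator"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the axisymmetric elasticity problem for a pressure field
#'
#' Computes the solid displacement driven by the pore-pressure field,
#' `div(sigma_eff) = alpha grad(p)`, with the operator's boundary
#' conditions (optionally with prescribed nonzero Dirichlet values).
#'
#' @param op an [elasticity_operator()], or a [cyl_mesh()] (in which case
#'   `medium` and `bcs` must be given and the operator is built on the fly).
#' @param p cell-wise pore pressure \[Pa\].
#' @param medium,bcs used only when `op` is a mesh.
#' @param fixed_values prescribed values at the fixed dofs (default 0).
#' @return list with `u` (all dofs), `eps_v` (cell centers), and
#'   `residual` (relative residual of the free equations).
#' @export
solve_elasticity <- function(op, p, medium = NULL, bcs = NULL,
                             fixed_values = NULL) {
  if (inherits(op, "cyl_mesh")) {
    if (is.null(medium)) stop("medium required when passing a mesh",
                              call. = FALSE)
    op <- elasticity_operator(op, medium,
                              bcs %||% list(bottom = "fixed", side = "free",
                                            top = "free"))
  }
  stopifnot(length(p) == op$mesh$n_cells)
  rhs <- as.numeric(op$Gdiv %*% (op$medium$alpha * p))
  u <- numeric(op$ndof)
  if (!is.null(fixed_values)) {
    stopifnot(length(fixed_values) == length(op$fixed))
    u[op$fixed] <- fixed_values
  }
  b <- rhs[op$free] - as.numeric(op$K[op$free, op$fixed, drop = FALSE] %*%
                                   u[op$fixed])
  u[op$free] <- as.numeric(Matrix::solve(op$chol, b))
  res <- as.numeric(op$K[op$free, , drop = FALSE] %*% u) - rhs[op$free]
  scale <- max(sqrt(sum(rhs[op$free]^2)), sqrt(sum(u^2)) * max(abs(op$K)),
               .Machine$double.xmin)
  list(u = u, eps_v = as.numeric(op$Ecell %*% u),
       residual = sqrt(sum(res^2)) / scale)
}

#' Hydrostatic component of the solid stress
#'
#' For isotropic linear elasticity the trace of the effective stress is
#' `(3 lambda + 2 G) eps_v`, so the hydrostatic (mean) effective stress per
#' cell is `sigma_h = (lambda + 2G/3) eps_v`. Optionally reports the total
#' stress variant `sigma_h - alpha p`. Negative values indicate
#' compression; during collapse most of the domain is compressed with
#' tensile pockets near the periphery.
#'
#' @param state a [coupled_state()] with strain (deformable run).
#' @param medium a [poroelastic_medium()] with finite `E`.
#' @param eos a [fluid_eos()] (needed for the total-stress variant).
#' @param total if `TRUE`, return `tr(sigma)/3 = sigma_h - alpha p`.
#' @return per-cell hydrostatic stress \[Pa\].
#' @export
hydrostatic_stress <- function(state, medium, eos = NULL, total = FALSE) {
  if (is_rigid(medium))
    stop("hydrostatic stress requires a deformable medium", call. = FALSE)
  if (is.null(state$eps_v))
    stop("state carries no solid strain (rigid run?)", call. = FALSE)
  sh <- (medium$lambda + 2 * medium$G / 3) * state$eps_v
  if (total) {
    if (is.null(eos)) stop("eos required for total stress", call. = FALSE)
    sh <- sh - medium$alpha * eos_pressure(eos, state$rho)
  }
  sh
}
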
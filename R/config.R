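# Run configuration: structured, human-readable (YAML), all SI units.
# Display conversions (kPa, mm, us) happen at the I/O layer only.

#' Build a run configuration
#'
#' Assembles and validates the configuration for one of the four scenarios:
#' `"spherical_collapse"` (1D PDE collapse), `"prp"` (Rayleigh--Plesset,
#' static overpressure), `"prp_ultrasound"` (Rayleigh--Plesset under
#' sinusoidal forcing), and `"near_wall"` (2D axisymmetric coupled
#' collapse). All quantities are SI. The configuration round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param scenario scenario name.
#' @param eos `"table1"` or a named list of [fluid_eos()] arguments.
#' @param medium named list: `E` (number or `"inf"`), `nu`, and optionally
#'   `alpha`, `Ks_inv`, `phi0`, `k` (defaults from [preset_table1()]).
#' @param geometry named list. Spherical/RP: `L`, `R0`, (`n_cells`).
#'   Near-wall: `r_max`, `z_max`, `nr`, `nz`, `R0`, `center_z`.
#' @param forcing named list of [forcing_spec()] arguments.
#' @param rp named list: `rho_l`, `rho_R` (RP scenarios only).
#' @param controls named list passed to [collapse_control()] /
#'   [near_wall_control()] / [rp_integrate()] as appropriate.
#' @param output named list: `prefix` for output file names.
#' @return object of class `run_config`.
#' @export
run_config <- function(scenario = c("spherical_collapse", "prp",
                                    "prp_ultrasound", "near_wall"),
                       eos = "table1", medium = list(E = "inf"),
                       geometry = list(), forcing = list(mode = "static"),
                       rp = list(), controls = list(),
                       output = list(prefix = "porocav")) {
  cfg <- structure(
    list(units = "SI", scenario = match.arg(scenario), eos = eos,
         medium = medium, geometry = geometry, forcing = forcing,
         rp = rp, controls = controls, output = output),
    class = "run_config"
  )
  validate_run_config(cfg)
  cfg
}

resolve_eos <- function(eos) {
  if (identical(eos, "table1")) return(preset_table1()$eos)
  if (is.list(eos)) return(do.call(fluid_eos, eos))
  stop("unresolvable eos preset: ", format(eos), call. = FALSE)
}

resolve_medium <- function(medium) {
  d <- preset_table1()$medium_defaults
  E <- medium$E %||% "inf"
  if (identical(E, "inf") || identical(E, Inf)) E <- Inf
  if (!is.numeric(E)) stop("medium$E must be numeric or \"inf\"",
                           call. = FALSE)
  poroelastic_medium(E = E, nu = medium$nu %||% 0.45,
                     alpha = medium$alpha %||% d$alpha,
                     Ks_inv = medium$Ks_inv %||% d$Ks_inv,
                     phi0 = medium$phi0 %||% d$phi0,
                     k = medium$k %||% d$k)
}

resolve_forcing <- function(forcing) do.call(forcing_spec, forcing)

#' Validate a run configuration
#'
#' Checks that presets resolve, densities lie inside the EOS domain
#' `(0, b)`, and the bubble fits in the domain (`R0 < L`), before any
#' solve is attempted.
#'
#' @param cfg a [run_config()] (or a plain list with the same fields).
#' @return `cfg`, invisibly; errors describe the first violated constraint.
#' @export
validate_run_config <- function(cfg) {
  if (!identical(cfg$units %||% "SI", "SI"))
    stop("config must declare units: SI", call. = FALSE)
  eos <- resolve_eos(cfg$eos %||% "table1")
  medium <- resolve_medium(cfg$medium %||% list())
  forcing <- resolve_forcing(cfg$forcing %||% list(mode = "static"))
  if (!(forcing$rho_L > 0 && forcing$rho_L < eos$b))
    stop("forcing rho_L outside (0, b)", call. = FALSE)
  g <- cfg$geometry %||% list()
  if (cfg$scenario %in% c("spherical_collapse", "prp", "prp_ultrasound")) {
    L <- g$L %||% 1e-3; R0 <- g$R0 %||% (L / 2)
    if (!(R0 > 0 && R0 < L))
      stop("geometry requires 0 < R0 < L", call. = FALSE)
  }
  if (cfg$scenario == "near_wall") {
    R0 <- g$R0 %||% 1.2e-3
    if (!(R0 > 0 && R0 < (g$r_max %||% 5e-3)))
      stop("near-wall bubble does not fit the radial extent", call. = FALSE)
    if (!((g$center_z %||% 1.5e-3) > 0))
      stop("bubble center must sit above the wall", call. = FALSE)
  }
  if (!is.null(cfg$rp$rho_R) &&
      !(cfg$rp$rho_R > eos$rho_v && cfg$rp$rho_R < eos$b))
    stop("rp$rho_R outside (rho_v, b)", call. = FALSE)
  invisible(cfg)
}

#' Read / write run configurations (YAML)
#'
#' @param path file path.
#' @return `read_run_config` returns a validated [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$scenario <- raw$scenario %||% "spherical_collapse"
  cfg <- structure(raw, class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Execute a configured scenario and write its artifacts
#'
#' Runs the scenario named in the configuration and writes, under
#' `out_dir`: the bubble trace as CSV, field snapshots (CSV; plus a legacy
#' VTK structured grid for 2D runs), a machine-readable JSON summary
#' (collapse time, extrema, conservation residuals, the fully resolved
#' configuration and package version), and a plain-text log. The model has
#' no source of randomness: re-running an identical configuration
#' reproduces the outputs bit-identically.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly.
#' @export
run_experiment <- function(cfg, out_dir = ".") {
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(out_dir, cfg$output$prefix %||% "porocav")
  eos <- resolve_eos(cfg$eos %||% "table1")
  medium <- resolve_medium(cfg$medium %||% list())
  forcing <- resolve_forcing(cfg$forcing %||% list(mode = "static"))
  g <- cfg$geometry %||% list()
  ctl <- cfg$controls %||% list()
  log_lines <- c(sprintf("porocav %s scenario=%s",
                         as.character(utils::packageVersion("porocav")),
                         cfg$scenario))

  summary <- list(package_version =
                    as.character(utils::packageVersion("porocav")),
                  scenario = cfg$scenario, config = unclass(cfg))

  if (cfg$scenario == "spherical_collapse") {
    grid <- spherical_grid(L = g$L %||% 1e-3,
                           n_cells = g$n_cells %||% 1024)
    control <- do.call(collapse_control, ctl)
    run <- run_collapse(medium, eos, grid, forcing,
                        R0 = g$R0 %||% (grid$L / 2), control = control)
    utils::write.csv(run$trace, paste0(prefix, "_trace.csv"),
                     row.names = FALSE)
    st <- run$state
    p_L <- eos_pressure(eos, run$rho_L)
    fields <- tibble::tibble(
      r = grid$centers, rho = st$rho, p = eos_pressure(eos, st$rho),
      eps_v = volumetric_strain(st, medium, eos, p_L)$eps_v)
    utils::write.csv(fields, paste0(prefix, "_field.csv"), row.names = FALSE)
    summary$collapse_time <- run$collapse_time
    summary$collapsed <- run$collapsed
    summary$max_mass_residual <- max(run$trace$mass_residual, na.rm = TRUE)
    log_lines <- c(log_lines,
                   sprintf("steps=%d t_c=%s", nrow(run$trace) - 1L,
                           format(run$collapse_time)))
  } else if (cfg$scenario %in% c("prp", "prp_ultrasound")) {
    L <- g$L %||% 1e-3
    params <- prp_params(L, g$R0 %||% (L / 2), medium, eos,
                         rho_l = cfg$rp$rho_l %||% 998,
                         rho_R = cfg$rp$rho_R)
    t_max <- ctl$t_max %||%
      (if (forcing$mode == "ultrasound") 2 / forcing$freq else 1)
    trace <- rp_integrate(params, forcing, eos, t_max = t_max,
                          n_out = ctl$n_out %||% 2000,
                          rtol = ctl$rtol %||% 1e-9)
    utils::write.csv(trace, paste0(prefix, "_trace.csv"), row.names = FALSE)
    summary$collapse_time <- rp_collapse_time(trace)
    summary$collapsed <- isTRUE(attr(trace, "collapsed"))
    summary$R_max <- max(trace$R)
    summary$R_min <- min(trace$R)
  } else { # near_wall
    mesh <- cyl_mesh(r_max = g$r_max %||% 5e-3, z_max = g$z_max %||% 6.5e-3,
                     nr = g$nr %||% 100, nz = g$nz %||% 65)
    control <- do.call(near_wall_control, ctl)
    run <- run_near_wall(medium, eos, mesh,
                         rho_b = forcing$rho_L,
                         R0 = g$R0 %||% 1.2e-3,
                         center_z = g$center_z %||% 1.5e-3,
                         control = control)
    utils::write.csv(run$trace, paste0(prefix, "_trace.csv"),
                     row.names = FALSE)
    fields <- list(rho = run$state$rho)
    if (!is_rigid(medium)) {
      fields$eps_v <- run$state$eps_v
      fields$sigma_h_kPa <- hydrostatic_stress(run$state, medium) / 1e3
    }
    write_vtk_structured(paste0(prefix, "_field.vtk"), mesh, fields)
    utils::write.csv(cbind(tibble::tibble(r = mesh$cell_r, z = mesh$cell_z),
                           tibble::as_tibble(fields)),
                     paste0(prefix, "_field.csv"), row.names = FALSE)
    contour <- interface_contour(run$snapshots[[2]], eos)
    utils::write.csv(contour, paste0(prefix, "_interface.csv"),
                     row.names = FALSE)
    summary$collapse_time <- run$collapse_time
    summary$collapsed <- run$collapsed
    summary$collapse_point <- as.list(run$collapse_point)
    summary$max_mass_residual <- max(run$trace$mass_residual, na.rm = TRUE)
  }

  jsonlite::write_json(summary, paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, paste0(prefix, "_log.txt"))
  invisible(summary)
}
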
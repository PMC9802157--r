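# Memoized expensive runs shared across test files.  Everything is
# deterministic, so caching changes nothing but wall time.

run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = run_cache)) assign(key, force(expr), run_cache)
  get(key, envir = run_cache)
}

t1_eos <- function() preset_table1()$eos

static_998 <- function() forcing_spec("static", rho_L = 998)

# 1D PDE collapse at the reference resolution (L = 1 mm, R0 = L/2)
pde_run <- function(E, nu = 0.45, n_cells = 1024) {
  cached(sprintf("pde_%s_%g_%d", format(E), nu, n_cells), {
    run_collapse(table1_medium(E = E, nu = nu), t1_eos(),
                 spherical_grid(1e-3, n_cells), static_998())
  })
}

# interface density calibrated once against the E = 15 kPa PDE run
calibrated_rho_R <- function() {
  cached("rho_R", {
    eos <- t1_eos()
    cal <- pde_run(15e3)
    params <- prp_params(1e-3, 0.5e-3, table1_medium(E = 15e3, nu = 0.45),
                         eos, rho_l = 998)
    calibrate_rho_R(cal$collapse_time, params, static_998(), eos)
  })
}

# full-resolution near-wall runs (shared by the acceptance tests)
near_wall_full <- function(rigid) {
  cached(sprintf("nw_full_%d", rigid), {
    experiment_near_wall(rigid = rigid)
  })
}
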
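# Shared simulation scenarios for the acceptance tests, computed once per
# test session. Production discretization: 8 elements across the PVS, 40
# axial, 16 across the brain; dt = 1e-4 s (heartbeat, resolving the
# 2.5e-4 s pulse transit) and 0.01 s (hyperemia).

.scenario_cache <- new.env(parent = emptyenv())

scenario <- function(name) {
  if (!is.null(.scenario_cache[[name]])) return(.scenario_cache[[name]])
  p <- default_parameters()
  pn <- pvs_parameters(k_s = Inf)
  val <- switch(name,
    rigid_db = run_rigid(p, wall_motion("heartbeat", p),
                         duration = 0.1, dt = 1e-4, nr_pvs = 8, nz = 40),
    rigid_ns = run_rigid(pn, wall_motion("heartbeat", pn),
                         duration = 0.1, dt = 1e-4, nr_pvs = 8, nz = 40),
    fsi_hb = run_coupled(p, wall_motion("heartbeat", p),
                         duration = 0.1, dt = 1e-4,
                         nr_pvs = 8, nz = 40, nr_brain = 16),
    fsi_hy = run_coupled(p, wall_motion("hyperemia", p),
                         duration = 10, dt = 0.01,
                         nr_pvs = 8, nz = 40, nr_brain = 16),
    fsi_hy_ns = run_coupled(pn, wall_motion("hyperemia", pn),
                            duration = 10, dt = 0.01,
                            nr_pvs = 8, nz = 40, nr_brain = 16),
    fsi_hy_rsas = {
      p9 <- pvs_parameters(r_sas = 0.1)
      run_coupled(p9, wall_motion("hyperemia", p9),
                  duration = 10, dt = 0.01,
                  nr_pvs = 8, nz = 40, nr_brain = 16)
    },
    stop("unknown scenario: ", name))
  .scenario_cache[[name]] <- val
  val
}

# relative agreement helper used throughout the acceptance comparisons
expect_within <- function(value, target, tol) {
  testthat::expect_lt(abs(value / target - 1), tol,
                      label = sprintf("|%.4g / %.4g - 1|", value, target))
}
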
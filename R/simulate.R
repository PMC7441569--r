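#' Run a PVS flow simulation
#'
#' `run_rigid()` time-marches the Darcy-Brinkman (or Navier-Stokes) fluid in
#' the PVS with the outer wall held fixed (non-compliant brain);
#' `run_coupled()` solves the fully coupled fluid-structure interaction
#' problem with the compressible Saint Venant-Kirchhoff brain tissue.
#' Both are driven by a prescribed arteriolar [wall_motion()] and record
#' boundary fluxes, the PVS fluid-domain volume, interface pressure and
#' displacement profiles, and (optionally) full velocity field snapshots
#' for particle tracking.
#'
#' @param params A [pvs_parameters] object.
#' @param motion A [wall_motion()] object (or `NULL` for a motionless wall,
#'   useful with nonzero initial solid data).
#' @param duration Simulated time, s; defaults to the motion's natural
#'   duration (one period for periodic waveforms, 10 s for hyperemia).
#' @param dt Time step, s. Defaults: 1e-4 for heartbeat (resolving the
#'   2.5e-4 s wave transit), 0.01 for hyperemia, T/500 for sinusoids.
#' @param nr_pvs,nz,nr_brain Mesh resolution (elements across the PVS
#'   width, along the axis, and across the brain annulus).
#' @param resistances If `FALSE`, zero-traction outlets replace the Robin
#'   resistances (the "no flow resistances" variant).
#' @param convection Include the ALE convective term (Picard-lagged).
#' @param bdf Time integrator order (2 = BDF2 after a BDF1 start).
#' @param store_fields Store velocity/mesh snapshots every `store_stride`
#'   steps (needed by [advect_particles()]).
#' @param store_stride Snapshot stride, steps.
#' @param init_solid Optional initial solid displacement, a function
#'   `(r, z)` returning `list(ur, uz)` evaluated on solid nodes (coupled
#'   runs only); used for free-decay/energy studies.
#' @param track_energy Record kinetic + elastic energy per step.
#' @param couple_tol,couple_maxit Interface fixed-point tolerance (relative
#'   solution change) and iteration cap per step.
#' @param stab_alpha Pressure stabilization coefficient.
#' @param progress Print progress every ~10% of steps.
#' @return A `pvs_flow_record` object; see Details.
#' @details
#' The record holds `time` (s), per-step signed outflow fluxes `q_pial`,
#' `q_par` (m^3/s, positive out of the PVS), the interior cross-section flux
#' `q_50` at `z = La - 50 um` (positive toward the pial end), the fluid
#' domain volume `V` (m^3, with `V0` its initial value), the volume-averaged
#' downstream velocity `mean_vz_down` (m/s, positive toward the
#' parenchyma), peak velocity/pressure magnitudes, interface pressure and
#' (coupled) radial displacement profiles, and solver diagnostics.
#' @export
run_rigid <- function(params, motion, duration = NULL, dt = NULL,
                      nr_pvs = 8, nz = 40, resistances = TRUE,
                      convection = TRUE, bdf = 2,
                      store_fields = FALSE, store_stride = 10L,
                      stab_alpha = 0.1, progress = FALSE) {
  run_simulation(params, motion, mode = "rigid", duration = duration, dt = dt,
                 nr_pvs = nr_pvs, nz = nz, nr_brain = 2,
                 resistances = resistances, convection = convection, bdf = bdf,
                 store_fields = store_fields, store_stride = store_stride,
                 stab_alpha = stab_alpha, progress = progress)
}

#' @rdname run_rigid
#' @export
run_coupled <- function(params, motion, duration = NULL, dt = NULL,
                        nr_pvs = 8, nz = 40, nr_brain = 16,
                        resistances = TRUE, convection = TRUE, bdf = 2,
                        store_fields = FALSE, store_stride = 10L,
                        init_solid = NULL, track_energy = FALSE,
                        couple_tol = 1e-8, couple_maxit = 12,
                        stab_alpha = 0.1, progress = FALSE) {
  run_simulation(params, motion, mode = "fsi", duration = duration, dt = dt,
                 nr_pvs = nr_pvs, nz = nz, nr_brain = nr_brain,
                 resistances = resistances, convection = convection, bdf = bdf,
                 store_fields = store_fields, store_stride = store_stride,
                 init_solid = init_solid, track_energy = track_energy,
                 couple_tol = couple_tol, couple_maxit = couple_maxit,
                 stab_alpha = stab_alpha, progress = progress)
}

default_dt <- function(motion) {
  switch(motion$kind,
         heartbeat = 1e-4,
         hyperemia = 0.01,
         sinusoid = 1 / (motion$f * 500),
         none = 1e-3)
}

null_motion <- function() {
  structure(list(kind = "none", amplitude = 0, duration = 1,
                 displacement = function(z, t) 0 * z + 0 * t,
                 velocity = function(z, t) 0 * z + 0 * t),
            class = "wall_motion")
}

run_simulation <- function(params, motion, mode, duration, dt,
                           nr_pvs, nz, nr_brain, resistances, convection,
                           bdf, store_fields, store_stride,
                           init_solid = NULL, track_energy = FALSE,
                           couple_tol = 1e-8, couple_maxit = 12,
                           stab_alpha = 0.1, progress = FALSE) {
  if (is.null(motion)) motion <- null_motion()
  if (is.null(duration)) duration <- motion$duration
  if (is.null(dt)) dt <- default_dt(motion)
  nsteps <- max(1L, round(duration / dt))
  ctx <- fsi_context(params, motion, mode = mode, nr_pvs = nr_pvs, nz = nz,
                     nr_brain = nr_brain, resistances = resistances,
                     convection = convection, stab_alpha = stab_alpha,
                     bdf = bdf, couple_tol = couple_tol,
                     couple_maxit = couple_maxit)
  st <- fsi_initial_state(ctx)
  if (!is.null(init_solid) && mode == "fsi") {
    nd <- ctx$so$nodes
    ini <- init_solid(nd[, 1], nd[, 2])
    ur0 <- ini$ur; uz0 <- ini$uz
    ur0[ctx$so$outer] <- 0; uz0[ctx$so$outer] <- 0   # clamped outer face
    us0 <- c(ur0, uz0)
    st$us <- us0; st$us2 <- us0
  }
  nzn <- nz + 1L
  time <- numeric(nsteps)
  q_pial <- q_par <- q_50 <- V <- mvz <- max_v <- max_p <- iters <- numeric(nsteps)
  p_int <- matrix(0, nsteps, nzn)
  u_int <- if (mode == "fsi") matrix(0, nsteps, nzn) else NULL
  energy <- if (track_energy) numeric(nsteps) else NULL
  fields <- if (store_fields) vector("list", nsteps %/% store_stride + 1L) else NULL
  nfield <- 0L
  for (n in seq_len(nsteps)) {
    t_new <- n * dt
    adv <- fsi_advance(ctx, st, t_new, dt)
    dg <- step_diagnostics(ctx, adv)
    time[n] <- t_new
    q_pial[n] <- dg$q_pial; q_par[n] <- dg$q_par; q_50[n] <- dg$q_50
    V[n] <- dg$V; mvz[n] <- dg$mean_vz_down
    max_v[n] <- dg$max_v; max_p[n] <- dg$max_p
    p_int[n, ] <- dg$p_interface
    if (mode == "fsi") u_int[n, ] <- dg$u_interface
    iters[n] <- dg$iters
    if (track_energy) {
      ke_f <- pi * params$rho_f * kinetic_quad(adv$ops, adv$x, ctx)
      en <- ke_f
      if (mode == "fsi") {
        vs <- numeric(ctx$ndof)
        sel <- c(ctx$dof_vr_s, ctx$dof_vz_s)
        vs[sel] <- adv$x[sel]
        ke_s <- pi * params$rho_s * as.numeric(vs %*% (ctx$Ms %*% vs))
        el <- svk_energy(ctx$ops_s, ctx$so$tri, adv$us[seq_len(ctx$Ns)],
                         adv$us[ctx$Ns + seq_len(ctx$Ns)],
                         params$lambda_s, params$mu_s)
        en <- en + ke_s + el
      }
      energy[n] <- en
    }
    if (store_fields && (n %% store_stride == 0L || n == nsteps)) {
      nfield <- nfield + 1L
      fields[[nfield]] <- list(t = t_new, nodes = adv$nodes_cur,
                               vr = adv$x[ctx$dof_vr_f], vz = adv$x[ctx$dof_vz_f])
    }
    st <- list(x = adv$x, x2 = st$x, um = adv$um, um2 = st$um,
               us = if (mode == "fsi") adv$us else st$us, us2 = st$us,
               nstep = st$nstep + 1L)
    if (progress && n %% max(1L, nsteps %/% 10L) == 0L) {
      message(sprintf("  t = %.4g s (%d/%d), iters %d", t_new, n, nsteps, dg$iters))
    }
  }
  structure(list(
    time = time, dt = dt, q_pial = q_pial, q_par = q_par, q_50 = q_50,
    V = V, V0 = params$V_pvs, mean_vz_down = mvz, max_v = max_v, max_p = max_p,
    p_interface = p_int, u_interface = u_int, iters = iters,
    energy = energy,
    fields = if (store_fields) fields[seq_len(nfield)] else NULL,
    zv = ctx$fl$zv, params = params, mode = mode,
    motion = motion[c("kind", "amplitude", "duration", "f")],
    resolution = c(nr_pvs = nr_pvs, nz = nz, nr_brain = nr_brain),
    resistances = resistances
  ), class = "pvs_flow_record")
}

kinetic_quad <- function(ops, x, ctx) {
  vrq <- ops$nodal_at_q(x[ctx$dof_vr_f])
  vzq <- ops$nodal_at_q(x[ctx$dof_vz_f])
  sum((ops$area / 3) * ((vrq^2 + vzq^2) * ops$rq))
}

#' @export
print.pvs_flow_record <- function(x, ...) {
  cat(sprintf("PVS flow record: %s mode, '%s' wall motion, %d steps of dt = %.3g s\n",
              x$mode, x$motion$kind, length(x$time), x$dt))
  cat(sprintf("  mesh %s x %s (PVS), peak |v| = %.3g um/s, peak |p| = %.3g Pa\n",
              x$resolution["nr_pvs"], x$resolution["nz"],
              max(x$max_v) * 1e6, max(x$max_p)))
  cat(sprintf("  peak pial outflow %.3g um^3/s, volume swing %.3g%% of V0\n",
              max(abs(x$q_pial)) * 1e18, 100 * max(abs(x$V - x$V0)) / x$V0))
  invisible(x)
}

#' @export
summary.pvs_flow_record <- function(object, ...) {
  exchange_summary(object)
}

#' @export
plot.pvs_flow_record <- function(x, which = c("flux", "volume", "speed"), ...) {
  which <- match.arg(which)
  t <- x$time
  if (which == "flux") {
    graphics::plot(t, x$q_pial * 1e18, type = "l", xlab = "time (s)",
                   ylab = expression(q ~ (mu * m^3 / s)),
                   main = "Outflow fluxes (positive = leaving the PVS)", ...)
    graphics::lines(t, x$q_par * 1e18, lty = 2)
    graphics::legend("topright", c("pial (SAS) end", "parenchymal end"),
                     lty = 1:2, bty = "n")
  } else if (which == "volume") {
    graphics::plot(t, (x$V - x$V0) / x$V0 * 100, type = "l", xlab = "time (s)",
                   ylab = "PVS volume change (%)", ...)
  } else {
    graphics::plot(t, x$mean_vz_down * 1e6, type = "l", xlab = "time (s)",
                   ylab = expression(-bar(v)[z] ~ (mu * m / s)), ...)
  }
  invisible(x)
}
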
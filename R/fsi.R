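# Monolithic axisymmetric fluid-structure interaction engine.
#
# Unknowns per time step: fluid velocity and pressure on the (moving) PVS
# mesh and solid nodal velocities on the (fixed, total-Lagrangian) brain
# mesh. Interface velocity DOFs are shared between the two discretizations,
# so velocity continuity holds by construction and the traction balance is
# automatic in the Galerkin sum. Solid displacements are recovered from the
# BDF update u^{n+1} = (dt/beta0) v^{n+1} + u_hist. Geometric (ALE mesh)
# and material (SVK) nonlinearities are handled by outer fixed-point
# iterations with the reference-configuration elastic tangent.

# Sparse direct solve with symmetric diagonal equilibration: the monolithic
# matrix mixes fluid, solid and Robin entries spanning many orders of
# magnitude, so the raw condition estimate can trip the solver even though
# the scaled system is perfectly solvable.
solve_scaled <- function(A, b) {
  d <- sqrt(abs(Matrix::diag(A)))
  d[d <= 0 | !is.finite(d)] <- 1
  Dinv <- Matrix::Diagonal(x = 1 / d)
  As <- Dinv %*% A %*% Dinv
  y <- Matrix::solve(As, b / d)
  as.vector(y) / d
}

bdf_coefs <- function(order) {
  if (order == 1) list(beta0 = 1, h1 = 1, h2 = 0)      # (v - v^n)/dt
  else list(beta0 = 1.5, h1 = 2, h2 = -0.5)            # (1.5 v - 2 v^n + .5 v^(n-1))/dt
}

# Scalar Laplace factorizations for the harmonic mesh motion on the
# reference fluid block. The radial component is free to slide on the end
# faces; the axial component is pinned there.
mesh_motion_system <- function(blk) {
  ops <- tri_ops(blk$nodes, blk$tri)
  tri <- blk$tri
  n <- nrow(blk$nodes)
  I <- J <- V <- NULL
  for (i in 1:3) for (j in 1:3) {
    I <- c(I, tri[, i]); J <- c(J, tri[, j])
    V <- c(V, (ops$b[, i] * ops$b[, j] + ops$c[, i] * ops$c[, j]) * ops$area)
  }
  K <- assemble_from_cache(triplet_cache(I, J, n), V)
  dir_r <- sort(unique(c(blk$inner, blk$outer)))
  dir_z <- sort(unique(c(blk$inner, blk$outer, blk$z0, blk$zL)))
  free_r <- setdiff(seq_len(n), dir_r)
  free_z <- setdiff(seq_len(n), dir_z)
  list(K = K,
       dir_r = dir_r, free_r = free_r, fac_r = Matrix::Cholesky(K[free_r, free_r]),
       dir_z = dir_z, free_z = free_z, fac_z = Matrix::Cholesky(K[free_z, free_z]))
}

solve_harmonic <- function(mm, comp, bvals) {
  n <- nrow(mm$K)
  u <- numeric(n)
  if (comp == "r") { dir <- mm$dir_r; free <- mm$free_r; fac <- mm$fac_r }
  else { dir <- mm$dir_z; free <- mm$free_z; fac <- mm$fac_z }
  u[dir] <- bvals
  rhs <- -as.vector(mm$K[free, dir] %*% bvals)
  u[free] <- as.vector(Matrix::solve(fac, rhs))
  u
}

#' Harmonic mesh displacement of the PVS fluid domain
#'
#' Extends prescribed boundary displacements (arteriolar wall and PVS-brain
#' interface) into the PVS by solving a vector Laplace problem on the
#' reference mesh, the "harmonic model" of mesh motion. The two end faces
#' slide axially (zero axial displacement, free radial displacement).
#'
#' @param mesh A [build_mesh()] result (the fluid block is used).
#' @param wall_disp Radial displacement on the arteriolar wall: function of
#'   z or vector on the wall nodes (m).
#' @param interface_disp Displacement of the PVS-brain interface: list with
#'   `r` and `z` components (functions of z or nodal vectors), or a single
#'   function/vector for the radial component (axial taken zero).
#' @return A two-column matrix (`dr`, `dz`) of nodal mesh displacements on
#'   the fluid block.
#' @export
harmonic_mesh_motion <- function(mesh, wall_disp, interface_disp = 0) {
  blk <- mesh$fluid
  mm <- mesh_motion_system(blk)
  zw <- blk$nodes[blk$inner, 2]
  wd_v <- if (is.function(wall_disp)) wall_disp(zw) else rep_len(wall_disp, length(zw))
  if (!is.list(interface_disp)) interface_disp <- list(r = interface_disp, z = 0)
  zi <- blk$nodes[blk$outer, 2]
  ir <- if (is.function(interface_disp$r)) interface_disp$r(zi) else rep_len(interface_disp$r, length(zi))
  iz <- if (is.function(interface_disp$z)) interface_disp$z(zi) else rep_len(interface_disp$z, length(zi))
  n <- nrow(blk$nodes)
  br <- numeric(n); br[blk$inner] <- wd_v; br[blk$outer] <- ir
  bz <- numeric(n); bz[blk$outer] <- iz
  ur <- solve_harmonic(mm, "r", br[mm$dir_r])
  uz <- solve_harmonic(mm, "z", bz[mm$dir_z])
  cbind(dr = ur, dz = uz)
}

# Build the complete stepping context for a run.
fsi_context <- function(params, motion, mode = c("fsi", "rigid"),
                        nr_pvs = 8, nz = 40, nr_brain = 16,
                        resistances = TRUE, convection = TRUE,
                        stab_alpha = 0.1, bdf = 2, couple_tol = 1e-8,
                        couple_maxit = 12) {
  mode <- match.arg(mode)
  mesh <- build_mesh(params, nr_pvs = nr_pvs, nz = nz, nr_brain = nr_brain)
  fl <- mesh$fluid; so <- mesh$solid
  Nf <- nrow(fl$nodes); Ns <- nrow(so$nodes)
  if (mode == "fsi") {
    vmap_s <- integer(Ns)
    vmap_s[so$inner] <- fl$outer            # shared interface nodes (same j order)
    rest <- setdiff(seq_len(Ns), so$inner)
    vmap_s[rest] <- Nf + seq_along(rest)
    Nv <- Nf + length(rest)
  } else {
    vmap_s <- integer(0); Nv <- Nf
  }
  dof_vr_f <- seq_len(Nf); dof_vz_f <- Nv + dof_vr_f; dof_p <- 2L * Nv + seq_len(Nf)
  ndof <- 2L * Nv + Nf
  dir <- c(dof_vr_f[fl$inner], dof_vz_f[fl$inner])
  if (mode == "rigid") {
    dir <- c(dir, dof_vr_f[fl$outer], dof_vz_f[fl$outer])
    dof_vr_s <- dof_vz_s <- integer(0)
  } else {
    dof_vr_s <- vmap_s; dof_vz_s <- Nv + vmap_s
    dir <- c(dir, dof_vr_s[so$outer], dof_vz_s[so$outer], dof_vz_s[so$z0])
  }
  dir <- sort(unique(dir))
  free <- setdiff(seq_len(ndof), dir)

  ops_ref <- tri_ops_full(fl$nodes, fl$tri)
  em0 <- fluid_element_matrices(ops_ref, params, beta0_dt = 1, stab_alpha = stab_alpha)
  ftrip <- fluid_triplets(fl$tri, dof_vr_f, dof_vz_f, dof_p, em0)
  I <- ftrip$I; J <- ftrip$J

  Ks <- Ms <- NULL; Vk <- Vm <- numeric(0); svk_cache <- NULL; ops_s <- NULL
  if (mode == "fsi") {
    ops_s <- tri_ops_full(so$nodes, so$tri)
    kb <- solid_linear_blocks(ops_s, params$lambda_s, params$mu_s)
    mb <- mass_blocks(ops_s)
    tri_s <- so$tri
    Is <- Js <- NULL
    blocks <- list(list(kb$Krr, 1L, 1L), list(kb$Krz, 1L, 2L),
                   list(kb$Kzr, 2L, 1L), list(kb$Kzz, 2L, 2L))
    dofmaps <- list(dof_vr_s, dof_vz_s)
    for (bl in blocks) {
      rowmap <- dofmaps[[bl[[2]]]]; colmap <- dofmaps[[bl[[3]]]]
      diagb <- bl[[2]] == bl[[3]]
      for (i in 1:3) for (j in 1:3) {
        k <- (j - 1L) * 3L + i
        Is <- c(Is, rowmap[tri_s[, i]]); Js <- c(Js, colmap[tri_s[, j]])
        Vk <- c(Vk, bl[[1]][, k])
        Vm <- c(Vm, if (diagb) mb[, k] else numeric(nrow(tri_s)))
      }
    }
    scache <- triplet_cache(Is, Js, ndof)
    Ks <- assemble_from_cache(scache, Vk)
    Ms <- assemble_from_cache(scache, Vm)
    I <- c(I, Is); J <- c(J, Js)
    svk_idx <- c(dof_vr_s[tri_s[, 1]], dof_vr_s[tri_s[, 2]], dof_vr_s[tri_s[, 3]],
                 dof_vz_s[tri_s[, 1]], dof_vz_s[tri_s[, 2]], dof_vz_s[tri_s[, 3]])
    svk_cache <- vector_cache(svk_idx, ndof)
  }

  # Robin rank-one patterns on the two end rows (v_z dofs)
  rob_pial <- dof_vz_f[fl$zL]; rob_par <- dof_vz_f[fl$z0]
  nr1 <- length(rob_pial)
  I <- c(I, rep(rob_pial, each = nr1), rep(rob_par, each = nr1))
  J <- c(J, rep(rob_pial, times = nr1), rep(rob_par, times = nr1))

  cache <- triplet_cache(I, J, ndof)

  # fluid mass matrix cache (for RHS history terms), on fluid v dofs
  Im <- Jm <- NULL
  tri_f <- fl$tri
  for (i in 1:3) for (j in 1:3) {
    Im <- c(Im, dof_vr_f[tri_f[, i]], dof_vz_f[tri_f[, i]])
    Jm <- c(Jm, dof_vr_f[tri_f[, j]], dof_vz_f[tri_f[, j]])
  }
  mcache <- triplet_cache(Im, Jm, ndof)

  RR <- if (resistances) outlet_resistances(params) else list(sas = 0, par = 0)

  list(params = params, motion = motion, mode = mode, mesh = mesh,
       fl = fl, so = so, Nf = Nf, Ns = Ns, Nv = Nv, ndof = ndof,
       dof_vr_f = dof_vr_f, dof_vz_f = dof_vz_f, dof_p = dof_p,
       dof_vr_s = dof_vr_s, dof_vz_s = dof_vz_s, vmap_s = vmap_s,
       dir = dir, free = free, cache = cache, mcache = mcache,
       Ks = Ks, Ms = Ms, Vk = Vk, Vm = Vm,
       svk_cache = svk_cache, ops_s = ops_s,
       mm = mesh_motion_system(fl), RR = RR,
       resistances = resistances, convection = convection,
       stab_alpha = stab_alpha, bdf = bdf,
       couple_tol = couple_tol, couple_maxit = couple_maxit,
       j50 = which.min(abs(fl$zv - (params$La - 50e-6))))
}

fsi_initial_state <- function(ctx) {
  list(x = numeric(ctx$ndof), x2 = numeric(ctx$ndof),
       um = matrix(0, ctx$Nf, 2), um2 = matrix(0, ctx$Nf, 2),
       us = numeric(2L * max(ctx$Ns * (ctx$mode == "fsi"), 1L)),
       us2 = numeric(2L * max(ctx$Ns * (ctx$mode == "fsi"), 1L)),
       nstep = 0L)
}

solid_fint <- function(ctx, us_local) {
  as.vector(ctx$svk_cache %*% as.vector(
    svk_residual_elements(ctx$ops_s, ctx$so$tri,
                          us_local[seq_len(ctx$Ns)],
                          us_local[ctx$Ns + seq_len(ctx$Ns)],
                          ctx$params$lambda_s, ctx$params$mu_s)))
}

# scatter a solid-local (2 Ns) vector into a global ndof vector
put_solid <- function(ctx, us_local) {
  out <- numeric(ctx$ndof)
  out[ctx$dof_vr_s] <- us_local[seq_len(ctx$Ns)]
  out[ctx$dof_vz_s] <- us_local[ctx$Ns + seq_len(ctx$Ns)]
  out
}

# One implicit step. st holds the running state; returns the updated state
# pieces plus per-step diagnostics.
fsi_advance <- function(ctx, st, t_new, dt) {
  p <- ctx$params; fl <- ctx$fl
  order <- if (st$nstep == 0L) 1 else ctx$bdf
  bc <- bdf_coefs(order)
  beta0_dt <- bc$beta0 / dt
  n <- nrow(fl$nodes)
  zw <- fl$nodes[fl$inner, 2]
  wall_u <- ctx$motion$displacement(zw, t_new)
  wall_v <- ctx$motion$velocity(zw, t_new)

  x <- st$x                                    # warm start
  fsi <- ctx$mode == "fsi"
  u_hist_s <- if (fsi) (bc$h1 * st$us + bc$h2 * st$us2) / bc$beta0 else NULL
  v_hist <- bc$h1 * st$x + bc$h2 * st$x2

  iters <- 0L; relchg <- Inf
  um <- nodes_cur <- ops <- b_pial <- b_par <- us_new <- NULL
  repeat {
    iters <- iters + 1L
    if (fsi) {
      us_new <- (dt / bc$beta0) * c(x[ctx$dof_vr_s], x[ctx$dof_vz_s]) + u_hist_s
      ui_r <- us_new[ctx$so$inner]
      ui_z <- us_new[ctx$Ns + ctx$so$inner]
    } else {
      ui_r <- numeric(length(fl$outer)); ui_z <- ui_r
    }
    br <- numeric(n); br[fl$inner] <- wall_u; br[fl$outer] <- ui_r
    bz <- numeric(n); bz[fl$outer] <- ui_z
    um_r <- solve_harmonic(ctx$mm, "r", br[ctx$mm$dir_r])
    um_z <- solve_harmonic(ctx$mm, "z", bz[ctx$mm$dir_z])
    um <- cbind(um_r, um_z)
    nodes_cur <- fl$nodes + um
    w_r <- (bc$beta0 * um_r - (bc$h1 * st$um[, 1] + bc$h2 * st$um2[, 1])) / dt
    w_z <- (bc$beta0 * um_z - (bc$h1 * st$um[, 2] + bc$h2 * st$um2[, 2])) / dt

    ops <- tri_ops_full(nodes_cur, fl$tri)
    a_r <- a_z <- NULL
    if (ctx$convection) {
      a_r <- st$x[ctx$dof_vr_f] - w_r
      a_z <- st$x[ctx$dof_vz_f] - w_z
    }
    em <- fluid_element_matrices(ops, p, beta0_dt, a_r = a_r, a_z = a_z,
                                 stab_alpha = ctx$stab_alpha)
    Vf <- fluid_triplet_values(fl$tri, em)
    Vs <- if (fsi) (p$rho_s * beta0_dt) * ctx$Vm + (dt / bc$beta0) * ctx$Vk else numeric(0)
    b_pial <- row_flux_vector(nodes_cur[fl$zL, 1])
    b_par <- row_flux_vector(nodes_cur[fl$z0, 1])
    Vr <- c(2 * pi * ctx$RR$sas * as.vector(outer(b_pial, b_pial)),
            2 * pi * ctx$RR$par * as.vector(outer(b_par, b_par)))
    A <- assemble_from_cache(ctx$cache, c(Vf, Vs, Vr))

    mb <- mass_blocks(ops)
    Vmf <- NULL
    for (k in 1:9) Vmf <- c(Vmf, mb[, k], mb[, k])
    Mf <- assemble_from_cache(ctx$mcache, Vmf)
    rhs <- (p$rho_f / dt) * as.vector(Mf %*% v_hist)
    if (fsi) {
      rhs <- rhs + (p$rho_s / dt) * as.vector(ctx$Ms %*% v_hist)
      # modified-Newton correction: F_int(u*) replaced by
      # (dt/beta0) K v + [F_int(u*) - K (u* - u_hist)]
      fint <- solid_fint(ctx, us_new)
      corr <- fint - as.vector(ctx$Ks %*% put_solid(ctx, us_new - u_hist_s))
      rhs <- rhs - corr
    }

    g <- numeric(ctx$ndof)
    g[ctx$dof_vr_f[fl$inner]] <- wall_v
    rhs_red <- rhs[ctx$free] - as.vector(A[ctx$free, ctx$dir, drop = FALSE] %*% g[ctx$dir])
    x_new <- g
    x_new[ctx$free] <- solve_scaled(A[ctx$free, ctx$free], rhs_red)

    relchg <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x_new^2)), 1e-300)
    x <- x_new
    if (!fsi || relchg < ctx$couple_tol || iters >= ctx$couple_maxit) break
  }
  if (fsi) {
    us_new <- (dt / bc$beta0) * c(x[ctx$dof_vr_s], x[ctx$dof_vz_s]) + u_hist_s
  }
  list(x = x, um = um, nodes_cur = nodes_cur, us = us_new, iters = iters,
       relchg = relchg, ops = ops, order = order, wall_u = wall_u,
       b_pial = b_pial, b_par = b_par)
}

#' Advance a PVS flow simulation by one fluid time step
#'
#' Thin stepping interface over the engine used by [run_rigid()] and
#' [run_coupled()]: advances the current state by `dt` and returns the
#' updated stepper with instantaneous diagnostics (boundary fluxes, domain
#' volume, peak velocity/pressure).
#'
#' @param stepper A stepper created by [flow_stepper()].
#' @param dt Time step, s.
#' @return The updated stepper; element `last` holds the step diagnostics.
#' @export
fluid_step <- function(stepper, dt) {
  ctx <- stepper$ctx
  st <- stepper$st
  t_new <- stepper$t + dt
  adv <- fsi_advance(ctx, st, t_new, dt)
  stepper$st <- list(x = adv$x, x2 = st$x, um = adv$um, um2 = st$um,
                     us = if (ctx$mode == "fsi") adv$us else st$us,
                     us2 = st$us, nstep = st$nstep + 1L)
  stepper$t <- t_new
  stepper$last <- step_diagnostics(ctx, adv)
  stepper
}

#' @rdname fluid_step
#' @param params,motion,mode,... Passed to the internal context builder:
#'   mesh resolution (`nr_pvs`, `nz`, `nr_brain`), `resistances`,
#'   `convection`, `stab_alpha`, `bdf`, coupling tolerances.
#' @export
flow_stepper <- function(params, motion, mode = c("fsi", "rigid"), ...) {
  ctx <- fsi_context(params, motion, mode = mode, ...)
  list(ctx = ctx, st = fsi_initial_state(ctx), t = 0, last = NULL)
}

step_diagnostics <- function(ctx, adv) {
  fl <- ctx$fl
  x <- adv$x
  vz_pial <- x[ctx$dof_vz_f[fl$zL]]
  vz_par <- x[ctx$dof_vz_f[fl$z0]]
  q_pial <- 2 * pi * sum(adv$b_pial * vz_pial)       # positive out (+z)
  q_par <- -2 * pi * sum(adv$b_par * vz_par)         # positive out (-z)
  j50 <- ctx$j50
  sel50 <- ((j50 - 1L) * fl$nrn + 1L):(j50 * fl$nrn)
  q_50 <- row_flux(adv$nodes_cur[sel50, 1], x[ctx$dof_vz_f[sel50]])
  ops <- adv$ops
  V <- 2 * pi * sum(ops$area * ops$rc)
  vzq <- ops$nodal_at_q(x[ctx$dof_vz_f])
  int_vz <- sum((ops$area / 3) * (vzq[, 1] * ops$rq[, 1] + vzq[, 2] * ops$rq[, 2] +
                                  vzq[, 3] * ops$rq[, 3]))
  vmag <- sqrt(x[ctx$dof_vr_f]^2 + x[ctx$dof_vz_f]^2)
  # normalized by the reference volume (flow rate / reference cross-section,
  # the convention behind the reported "mean flow speed")
  list(q_pial = q_pial, q_par = q_par, q_50 = q_50, V = V,
       mean_vz_down = -2 * pi * int_vz / ctx$params$V_pvs,
       max_v = max(vmag), max_p = max(abs(x[ctx$dof_p])),
       p_interface = x[ctx$dof_p[fl$outer]],
       u_interface = if (ctx$mode == "fsi") adv$us[ctx$so$inner] else numeric(0),
       iters = adv$iters, relchg = adv$relchg)
}
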
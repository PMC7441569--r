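# Darcy-Brinkman / Navier-Stokes fluid discretization on the axisymmetric
# PVS annulus. P1/P1 triangles with direction-aware Brezzi-Pitkaranta
# pressure stabilization; all integrals carry the radial measure (the
# global 2*pi is attached only to fluxes and the Robin rank-one terms).
#
# Momentum:   rho (dv/dt + (v - w).grad v) + (mu zeta / k_s) v = div sigma
# sigma    = -p I + mu (grad v + grad v^T)
# Mass:       div v = 0

# Per-element block matrices for the fluid system. Returns M x 9 matrices,
# column k = (i, j) with i = test, j = trial, k = (j-1)*3 + i.
#
# The viscous term uses the gradient (vector-Laplacian) form, equivalent to
# the divergence of the full stress for divergence-free fields; its natural
# boundary condition is the pseudo-traction -p n + mu dv/dn, which
# reproduces fully developed profiles at open/Robin ends (the symmetric
# form's do-nothing condition would force eps_rz = 0 there).
fluid_element_matrices <- function(ops, params, beta0_dt,
                                   a_r = NULL, a_z = NULL,
                                   stab_alpha = 0.1) {
  mu <- params$mu_f; rho <- params$rho_f
  drag <- if (is.infinite(params$k_s)) 0 else mu * params$zeta / params$k_s
  A <- ops$area; b <- ops$b; cc <- ops$c; rq <- ops$rq; rc <- ops$rc; phi <- ops$phi
  M <- length(A)
  mass <- matrix(0, M, 9); hoop <- matrix(0, M, 9)
  Bp_r <- matrix(0, M, 9); Bp_z <- matrix(0, M, 9)
  conv <- if (is.null(a_r)) NULL else matrix(0, M, 9)
  Kbb <- matrix(0, M, 9); Kcc <- matrix(0, M, 9); Kbc <- matrix(0, M, 9); Kcb <- matrix(0, M, 9)
  phjr <- sapply(1:3, function(j) (A / 3) * (phi[j, 1] * rq[, 1] + phi[j, 2] * rq[, 2] + phi[j, 3] * rq[, 3]))
  for (i in 1:3) for (j in 1:3) {
    k <- (j - 1L) * 3L + i
    mass[, k] <- (A / 3) * (phi[i, 1] * phi[j, 1] * rq[, 1] +
                            phi[i, 2] * phi[j, 2] * rq[, 2] +
                            phi[i, 3] * phi[j, 3] * rq[, 3])
    hoop[, k] <- (A / 3) * (phi[i, 1] * phi[j, 1] / rq[, 1] +
                            phi[i, 2] * phi[j, 2] / rq[, 2] +
                            phi[i, 3] * phi[j, 3] / rq[, 3])
    phiphi <- (A / 3) * (phi[i, 1] * phi[j, 1] + phi[i, 2] * phi[j, 2] + phi[i, 3] * phi[j, 3])
    Kbb[, k] <- b[, i] * b[, j] * A * rc
    Kcc[, k] <- cc[, i] * cc[, j] * A * rc
    Kbc[, k] <- b[, i] * cc[, j] * A * rc
    Kcb[, k] <- cc[, i] * b[, j] * A * rc
    Bp_r[, k] <- b[, i] * phjr[, j] + phiphi     # int p (dphi_i/dr r + phi_i)
    Bp_z[, k] <- cc[, i] * phjr[, j]
  }
  if (!is.null(a_r)) {
    # advecting velocity (v_prev - w) interpolated to quadrature points
    aq_r <- ops$nodal_at_q(a_r); aq_z <- ops$nodal_at_q(a_z)
    for (i in 1:3) for (j in 1:3) {
      k <- (j - 1L) * 3L + i
      conv[, k] <- rho * (A / 3) * (
        phi[i, 1] * (aq_r[, 1] * b[, j] + aq_z[, 1] * cc[, j]) * rq[, 1] +
        phi[i, 2] * (aq_r[, 2] * b[, j] + aq_z[, 2] * cc[, j]) * rq[, 2] +
        phi[i, 3] * (aq_r[, 3] * b[, j] + aq_z[, 3] * cc[, j]) * rq[, 3])
    }
  }
  # Brezzi-Pitkaranta pressure stabilization acting in the radial direction
  # only: on these strongly anisotropic cells the unstable equal-order
  # pressure modes are radial, while an axial stabilization of the same
  # strength would smear the axial pressure drop into spurious mass
  # sources at the traction/Robin ends. The scaling covers the Stokes
  # (viscosity), Darcy (drag) and transient limits.
  tau <- stab_alpha / (4 * mu / ops$hr^2 + drag + rho * beta0_dt)
  stab <- matrix(0, M, 9)
  for (i in 1:3) for (j in 1:3) {
    k <- (j - 1L) * 3L + i
    stab[, k] <- tau * b[, i] * b[, j] * A * rc
  }
  coef_t <- rho * beta0_dt + drag
  lap <- Kbb + Kcc
  vrvr <- coef_t * mass + mu * lap + mu * hoop
  vzvz <- coef_t * mass + mu * lap
  vrvz <- 0 * Kcb
  vzvr <- 0 * Kbc
  if (!is.null(conv)) { vrvr <- vrvr + conv; vzvz <- vzvz + conv }
  list(vrvr = vrvr, vrvz = vrvz, vzvr = vzvr, vzvz = vzvz,
       Bp_r = -Bp_r, Bp_z = -Bp_z,       # momentum pressure blocks
       Dp_r = t_block(Bp_r), Dp_z = t_block(Bp_z),  # continuity rows
       Spp = stab, mass = mass)
}

# transpose an M x 9 block in (i, j) indexing
t_block <- function(v) {
  v[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
}

# Extend tri_ops with a nodal->quadrature interpolation closure.
tri_ops_full <- function(nodes, tri) {
  ops <- tri_ops(nodes, tri)
  phi <- ops$phi
  ops$nodal_at_q <- function(u) {
    u1 <- u[tri[, 1]]; u2 <- u[tri[, 2]]; u3 <- u[tri[, 3]]
    cbind(phi[1, 1] * u1 + phi[2, 1] * u2 + phi[3, 1] * u3,
          phi[1, 2] * u1 + phi[2, 2] * u2 + phi[3, 2] * u3,
          phi[1, 3] * u1 + phi[2, 3] * u2 + phi[3, 3] * u3)
  }
  ops$tri <- tri
  ops
}

# Edge-lumped functional b with b^T v_z = int_row r v_z dr along a
# horizontal node row (given current radial coordinates of that row).
row_flux_vector <- function(rrow) {
  n <- length(rrow)
  bvec <- numeric(n)
  for (e in seq_len(n - 1L)) {
    r1 <- rrow[e]; r2 <- rrow[e + 1L]; len <- r2 - r1
    bvec[e] <- bvec[e] + len * (2 * r1 + r2) / 6
    bvec[e + 1L] <- bvec[e + 1L] + len * (r1 + 2 * r2) / 6
  }
  bvec
}

# Cross-section flux through a node row, m^3/s (positive in +z).
row_flux <- function(rrow, vzrow) 2 * pi * sum(row_flux_vector(rrow) * vzrow)

#' Steady Darcy-Brinkman annulus flow
#'
#' Solves the steady, fully developed axisymmetric Brinkman (or Stokes)
#' problem in the rigid PVS annulus driven by a pressure drop `dp` between
#' the parenchymal (`z = 0`) and pial (`z = La`) ends, with no-slip walls.
#' Used for verification against the one-dimensional two-point
#' boundary-value reduction.
#'
#' @param params A [pvs_parameters] object.
#' @param dp Pressure drop `p(0) - p(La)`, Pa.
#' @param nr,nz Mesh resolution.
#' @return A list with the mesh, nodal velocity (`vr`, `vz`), pressure `p`,
#'   the mid-length radial profile (`r`, `vz_profile`) and the volumetric
#'   flow rate `q` (m^3/s).
#' @export
solve_fluid_steady <- function(params, dp, nr = 24, nz = 16) {
  mesh <- build_mesh(params, nr_pvs = nr, nz = nz, nr_brain = 2)
  blk <- mesh$fluid
  n_nodes <- nrow(blk$nodes)
  ndof <- 3L * n_nodes
  dof_vr <- seq_len(n_nodes); dof_vz <- n_nodes + dof_vr; dof_p <- 2L * n_nodes + dof_vr
  ops <- tri_ops_full(blk$nodes, blk$tri)
  em <- fluid_element_matrices(ops, params, beta0_dt = 0)
  tri <- blk$tri
  trip <- fluid_triplets(tri, dof_vr, dof_vz, dof_p, em)
  cache <- triplet_cache(trip$I, trip$J, ndof)
  A <- assemble_from_cache(cache, trip$V)
  rhs <- numeric(ndof)
  # pressure traction dp at z = 0 acting on v_z test functions
  b0 <- row_flux_vector(blk$nodes[blk$z0, 1])
  rhs[dof_vz[blk$z0]] <- rhs[dof_vz[blk$z0]] + dp * b0
  dir <- c(dof_vr[blk$inner], dof_vz[blk$inner], dof_vr[blk$outer], dof_vz[blk$outer])
  free <- setdiff(seq_len(ndof), dir)
  x <- numeric(ndof)
  x[free] <- as.vector(Matrix::solve(A[free, free], rhs[free]))
  vz <- x[dof_vz]
  mid <- blk$zv[which.min(abs(blk$zv - params$La / 2))]
  sel <- which(abs(blk$nodes[, 2] - mid) < 1e-12)
  q <- row_flux(blk$nodes[sel, 1], vz[sel])
  list(mesh = mesh, vr = x[dof_vr], vz = vz, p = x[dof_p],
       r = blk$nodes[sel, 1], vz_profile = vz[sel], q = q)
}

# Global triplets for the fluid blocks (shared by steady and transient
# solvers). Returns I, J, V vectors; the (I, J) pattern is reusable.
fluid_triplets <- function(tri, dof_vr, dof_vz, dof_p, em) {
  M <- nrow(tri)
  Ib <- Jb <- Vb <- vector("list", 9L)
  blocks <- list(
    list(em$vrvr, dof_vr, dof_vr), list(em$vrvz, dof_vr, dof_vz),
    list(em$vzvr, dof_vz, dof_vr), list(em$vzvz, dof_vz, dof_vz),
    list(em$Bp_r, dof_vr, dof_p),  list(em$Bp_z, dof_vz, dof_p),
    list(em$Dp_r, dof_p, dof_vr),  list(em$Dp_z, dof_p, dof_vz),
    list(em$Spp, dof_p, dof_p))
  for (bi in seq_along(blocks)) {
    vals <- blocks[[bi]][[1]]
    rowmap <- blocks[[bi]][[2]]; colmap <- blocks[[bi]][[3]]
    I <- J <- V <- numeric(9L * M)
    for (i in 1:3) for (j in 1:3) {
      k <- (j - 1L) * 3L + i
      idx <- ((k - 1L) * M + 1L):(k * M)
      I[idx] <- rowmap[tri[, i]]
      J[idx] <- colmap[tri[, j]]
      V[idx] <- vals[, k]
    }
    Ib[[bi]] <- I; Jb[[bi]] <- J; Vb[[bi]] <- V
  }
  list(I = unlist(Ib), J = unlist(Jb), V = unlist(Vb))
}

# Stack only the V values in the same order as fluid_triplets built them.
fluid_triplet_values <- function(tri, em) {
  M <- nrow(tri)
  out <- vector("list", 9L)
  mats <- list(em$vrvr, em$vrvz, em$vzvr, em$vzvz, em$Bp_r, em$Bp_z,
               em$Dp_r, em$Dp_z, em$Spp)
  for (bi in seq_along(mats)) out[[bi]] <- as.vector(mats[[bi]])
  unlist(out)
}
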
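# Compressible Saint Venant-Kirchhoff brain tissue on the axisymmetric
# annulus R1+wd <= r <= R3, total Lagrangian formulation on the reference
# mesh. The dynamic solver works in nodal velocities (the displacement is
# recovered through the BDF update), so that interface velocity DOFs can be
# shared with the fluid in the monolithic FSI system.

#' Cauchy stress of a Saint Venant-Kirchhoff solid
#'
#' Computes `sigma = (1/det F) F (lambda tr(E) I + 2 mu E) F^T` from a
#' deformation gradient `F`. By default `E` is the Green-Lagrange strain
#' `(F^T F - I)/2`; `strain = "left-cauchy-green"` instead evaluates the
#' variant built on `F F^T - I` (twice the Euler-Almansi-conjugate measure),
#' retained for comparison because some formulations print the strain
#' without the 1/2 factor.
#'
#' @param F Deformation gradient, a 3x3 (or 2x2) matrix with positive
#'   determinant.
#' @param params A [pvs_parameters] object (uses `mu_s`, `lambda_s`), or a
#'   list with elements `mu_s`, `lambda_s` in Pa.
#' @param strain `"green-lagrange"` (default) or `"left-cauchy-green"`.
#' @return The Cauchy stress matrix, Pa.
#' @export
#' @examples
#' svk_stress(diag(3), default_parameters())          # zero at reference
svk_stress <- function(F, params,
                       strain = c("green-lagrange", "left-cauchy-green")) {
  strain <- match.arg(strain)
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0) stop("det F <= 0: mesh or step failure (non-physical deformation)")
  I <- diag(nrow(F))
  E <- switch(strain,
              "green-lagrange" = (crossprod(F) - I) / 2,   # (F^T F - I)/2
              "left-cauchy-green" = tcrossprod(F) - I)     # F F^T - I
  S <- params$lambda_s * sum(diag(E)) * I + 2 * params$mu_s * E
  (F %*% S %*% t(F)) / J
}

# Linear (reference configuration) axisymmetric elasticity stiffness
# triplets; also the exact tangent of the SVK residual at zero displacement.
# Returns M x 9 blocks for (ur,ur), (ur,uz), (uz,ur), (uz,uz).
solid_linear_blocks <- function(ops, lambda, mu) {
  A <- ops$area; b <- ops$b; cc <- ops$c; rq <- ops$rq; rc <- ops$rc; phi <- ops$phi
  M <- length(A)
  Krr <- Krz <- Kzr <- Kzz <- matrix(0, M, 9)
  lam2mu <- lambda + 2 * mu
  for (i in 1:3) for (j in 1:3) {
    k <- (j - 1L) * 3L + i
    phij <- (A / 3) * (phi[j, 1] + phi[j, 2] + phi[j, 3])        # int phi_j dA
    phii <- (A / 3) * (phi[i, 1] + phi[i, 2] + phi[i, 3])
    hoop <- (A / 3) * (phi[i, 1] * phi[j, 1] / rq[, 1] +
                       phi[i, 2] * phi[j, 2] / rq[, 2] +
                       phi[i, 3] * phi[j, 3] / rq[, 3])
    Krr[, k] <- lam2mu * b[, i] * b[, j] * A * rc + mu * cc[, i] * cc[, j] * A * rc +
      lambda * (b[, i] * phij + phii * b[, j]) + lam2mu * hoop
    Krz[, k] <- lambda * b[, i] * cc[, j] * A * rc + mu * cc[, i] * b[, j] * A * rc +
      lambda * phii * cc[, j]
    Kzr[, k] <- lambda * cc[, i] * b[, j] * A * rc + mu * b[, i] * cc[, j] * A * rc +
      lambda * cc[, i] * phij
    Kzz[, k] <- lam2mu * cc[, i] * cc[, j] * A * rc + mu * b[, i] * b[, j] * A * rc
  }
  list(Krr = Krr, Krz = Krz, Kzr = Kzr, Kzz = Kzz)
}

# Mass blocks int phi_i phi_j r dA (for the solid inertia term).
mass_blocks <- function(ops) {
  A <- ops$area; rq <- ops$rq; phi <- ops$phi
  M <- length(A)
  out <- matrix(0, M, 9)
  for (i in 1:3) for (j in 1:3) {
    k <- (j - 1L) * 3L + i
    out[, k] <- (A / 3) * (phi[i, 1] * phi[j, 1] * rq[, 1] +
                           phi[i, 2] * phi[j, 2] * rq[, 2] +
                           phi[i, 3] * phi[j, 3] * rq[, 3])
  }
  out
}

# Internal-force residual of the axisymmetric SVK solid (total Lagrangian),
# vectorized over elements. u is the nodal displacement (ur then uz on the
# solid node numbering local to the block). Returns per-element M x 6
# contributions (ur at 3 nodes, then uz at 3 nodes).
svk_residual_elements <- function(ops, tri, ur, uz, lambda, mu) {
  A <- ops$area; b <- ops$b; cc <- ops$c; rq <- ops$rq; phi <- ops$phi
  u1 <- ur[tri[, 1]]; u2 <- ur[tri[, 2]]; u3 <- ur[tri[, 3]]
  w1 <- uz[tri[, 1]]; w2 <- uz[tri[, 2]]; w3 <- uz[tri[, 3]]
  # P1: meridional deformation gradient constant per element
  F11 <- 1 + b[, 1] * u1 + b[, 2] * u2 + b[, 3] * u3
  F12 <- cc[, 1] * u1 + cc[, 2] * u2 + cc[, 3] * u3
  F21 <- b[, 1] * w1 + b[, 2] * w2 + b[, 3] * w3
  F22 <- 1 + cc[, 1] * w1 + cc[, 2] * w2 + cc[, 3] * w3
  E11 <- (F11^2 + F21^2 - 1) / 2
  E22 <- (F12^2 + F22^2 - 1) / 2
  E12 <- (F11 * F12 + F21 * F22) / 2
  M <- length(A)
  res <- matrix(0, M, 6)
  for (q in 1:3) {
    urq <- phi[1, q] * u1 + phi[2, q] * u2 + phi[3, q] * u3
    lamth <- 1 + urq / rq[, q]
    Eth <- (lamth^2 - 1) / 2
    trE <- E11 + E22 + Eth
    S11 <- lambda * trE + 2 * mu * E11
    S22 <- lambda * trE + 2 * mu * E22
    S12 <- 2 * mu * E12
    Sth <- lambda * trE + 2 * mu * Eth
    P11 <- F11 * S11 + F12 * S12
    P12 <- F11 * S12 + F12 * S22
    P21 <- F21 * S11 + F22 * S12
    P22 <- F21 * S12 + F22 * S22
    Pth <- lamth * Sth
    wgt <- A / 3
    for (i in 1:3) {
      res[, i] <- res[, i] + wgt * ((P11 * b[, i] + P12 * cc[, i]) * rq[, q] +
                                    Pth * phi[i, q])
      res[, i + 3] <- res[, i + 3] + wgt * (P21 * b[, i] + P22 * cc[, i]) * rq[, q]
    }
  }
  res
}

# Elastic strain energy of the SVK solid (for energy-decay diagnostics).
svk_energy <- function(ops, tri, ur, uz, lambda, mu) {
  A <- ops$area; b <- ops$b; cc <- ops$c; rq <- ops$rq; phi <- ops$phi
  u1 <- ur[tri[, 1]]; u2 <- ur[tri[, 2]]; u3 <- ur[tri[, 3]]
  w1 <- uz[tri[, 1]]; w2 <- uz[tri[, 2]]; w3 <- uz[tri[, 3]]
  F11 <- 1 + b[, 1] * u1 + b[, 2] * u2 + b[, 3] * u3
  F12 <- cc[, 1] * u1 + cc[, 2] * u2 + cc[, 3] * u3
  F21 <- b[, 1] * w1 + b[, 2] * w2 + b[, 3] * w3
  F22 <- 1 + cc[, 1] * w1 + cc[, 2] * w2 + cc[, 3] * w3
  E11 <- (F11^2 + F21^2 - 1) / 2
  E22 <- (F12^2 + F22^2 - 1) / 2
  E12 <- (F11 * F12 + F21 * F22) / 2
  tot <- 0
  for (q in 1:3) {
    urq <- phi[1, q] * u1 + phi[2, q] * u2 + phi[3, q] * u3
    Eth <- ((1 + urq / rq[, q])^2 - 1) / 2
    trE <- E11 + E22 + Eth
    dens <- lambda / 2 * trE^2 + mu * (E11^2 + E22^2 + 2 * E12^2 + Eth^2)
    tot <- tot + sum((A / 3) * dens * rq[, q])
  }
  2 * pi * tot
}

# Build a standalone solid system (static or dynamic) on the brain block.
# bc_deep / bc_pial: "roller" (u_z = 0) or "free"; outer face clamped.
solid_system <- function(blk, params, bc_deep = "roller", bc_pial = "free") {
  n <- nrow(blk$nodes)
  ndof <- 2L * n
  dof_ur <- seq_len(n); dof_uz <- n + dof_ur
  ops <- tri_ops_full(blk$nodes, blk$tri)
  kb <- solid_linear_blocks(ops, params$lambda_s, params$mu_s)
  tri <- blk$tri
  blocks <- list(list(kb$Krr, dof_ur, dof_ur), list(kb$Krz, dof_ur, dof_uz),
                 list(kb$Kzr, dof_uz, dof_ur), list(kb$Kzz, dof_uz, dof_uz))
  I <- J <- V <- NULL
  for (bl in blocks) {
    for (i in 1:3) for (j in 1:3) {
      k <- (j - 1L) * 3L + i
      I <- c(I, bl[[2]][tri[, i]]); J <- c(J, bl[[3]][tri[, j]])
      V <- c(V, bl[[1]][, k])
    }
  }
  cache <- triplet_cache(I, J, ndof)
  K <- assemble_from_cache(cache, V)
  # residual accumulator
  idx <- c(dof_ur[tri[, 1]], dof_ur[tri[, 2]], dof_ur[tri[, 3]],
           dof_uz[tri[, 1]], dof_uz[tri[, 2]], dof_uz[tri[, 3]])
  vc <- vector_cache(idx, ndof)
  dir <- c(dof_ur[blk$outer], dof_uz[blk$outer])
  if (bc_deep == "roller") dir <- c(dir, dof_uz[blk$z0])
  if (bc_pial == "roller") dir <- c(dir, dof_uz[blk$zL])
  list(blk = blk, ops = ops, K = K, vcache = vc, ndof = ndof,
       dof_ur = dof_ur, dof_uz = dof_uz, dir = sort(unique(dir)),
       free = setdiff(seq_len(ndof), sort(unique(dir))), params = params)
}

solid_residual <- function(sys, ur, uz) {
  re <- svk_residual_elements(sys$ops, sys$blk$tri, ur, uz,
                              sys$params$lambda_s, sys$params$mu_s)
  as.vector(sys$vcache %*% as.vector(re))
}

#' Static brain-tissue displacement from an interface pressure profile
#'
#' Solves the static Saint Venant-Kirchhoff problem on the brain annulus
#' (inner radius `R1 + wd`, outer radius `R3` clamped, deep face on rollers,
#' pial face traction-free) loaded by a fluid pressure profile applied as a
#' normal traction on the inner face, and returns the peak outward radial
#' displacement. This is the "how much would the brain deform under the
#' rigid-model pressures" estimate.
#'
#' @param pressure Pressure profile along the interface: either a single
#'   number (uniform), a function of `z` (m), or a numeric vector sampled on
#'   the interface nodes from `z = 0` to `z = La`.
#' @param params A [pvs_parameters] object.
#' @param nr,nz Brain mesh resolution.
#' @param bc_deep `"roller"` (default) or `"free"` deep-face condition.
#' @param bc_pial `"free"` (default) or `"roller"` pial-face condition (the
#'   roller/roller pair reproduces plane-strain thick-cylinder conditions
#'   for uniform loads).
#' @param details If `TRUE` return the full solution as well.
#' @return Peak radial interface displacement (m), or a list if
#'   `details = TRUE`.
#' @export
static_tissue_estimate <- function(pressure, params, nr = 24, nz = 40,
                                   bc_deep = "roller", bc_pial = "free",
                                   details = FALSE) {
  mesh <- build_mesh(params, nr_pvs = 2, nz = nz, nr_brain = nr)
  blk <- mesh$solid
  sys <- solid_system(blk, params, bc_deep = bc_deep, bc_pial = bc_pial)
  zin <- blk$nodes[blk$inner, 2]
  pz <- if (is.function(pressure)) pressure(zin)
        else if (length(pressure) == 1L) rep(pressure, length(zin))
        else stats::approx(seq(0, params$La, length.out = length(pressure)),
                           pressure, xout = zin, rule = 2)$y
  # traction p * e_r on the inner face: consistent load int p phi_i r dz
  f <- numeric(sys$ndof)
  rin <- blk$nodes[blk$inner, 1]
  for (e in seq_len(length(zin) - 1L)) {
    len <- zin[e + 1L] - zin[e]
    n1 <- blk$inner[e]; n2 <- blk$inner[e + 1L]
    f[sys$dof_ur[n1]] <- f[sys$dof_ur[n1]] + len * rin[e] * (2 * pz[e] + pz[e + 1L]) / 6
    f[sys$dof_ur[n2]] <- f[sys$dof_ur[n2]] + len * rin[e + 1L] * (pz[e] + 2 * pz[e + 1L]) / 6
  }
  # modified Newton with the reference-configuration tangent
  u <- numeric(sys$ndof)
  Kff <- sys$K[sys$free, sys$free]
  fac <- Matrix::lu(Kff)
  for (it in 1:30) {
    res <- solid_residual(sys, u[sys$dof_ur], u[sys$dof_uz]) - f
    rn <- sqrt(sum(res[sys$free]^2))
    du <- as.vector(Matrix::solve(fac, res[sys$free]))
    u[sys$free] <- u[sys$free] - du
    if (max(abs(du)) < 1e-14 + 1e-10 * max(abs(u))) break
  }
  ur_int <- u[sys$dof_ur[blk$inner]]
  peak <- max(abs(ur_int))
  if (details) list(peak = peak, u = u, sys = sys, z = zin, ur_interface = ur_int)
  else peak
}

#' One implicit dynamic step of the brain-tissue solid
#'
#' Advances the Saint Venant-Kirchhoff solid by one implicit (BDF1) step
#' under a radial traction applied on the inner (PVS-interface) face.
#' Standalone entry point used for verification; the coupled simulations
#' drive the same residual/stiffness machinery through the monolithic FSI
#' solver.
#'
#' @param state List with `u` (2N displacement), `v` (2N velocity) or
#'   `NULL` for rest; use the `sys` returned in the result to continue.
#' @param traction Radial traction profile on the inner face (Pa): number,
#'   function of z, or nodal vector (as in [static_tissue_estimate()]).
#' @param dt Time step, s.
#' @param params A [pvs_parameters] object.
#' @param nr,nz Mesh resolution (first call).
#' @param sys Optional prebuilt system from a previous call.
#' @return List with updated `u`, `v`, the `sys`, and the interface radial
#'   displacement profile `ur_interface`.
#' @export
solid_step <- function(state, traction, dt, params, nr = 16, nz = 24,
                       sys = NULL) {
  if (is.null(sys)) {
    mesh <- build_mesh(params, nr_pvs = 2, nz = nz, nr_brain = nr)
    sys <- solid_system(mesh$solid, params)
    sys$Mmat <- {
      mb <- mass_blocks(sys$ops)
      tri <- sys$blk$tri
      I <- J <- V <- NULL
      for (i in 1:3) for (j in 1:3) {
        k <- (j - 1L) * 3L + i
        I <- c(I, sys$dof_ur[tri[, i]], sys$dof_uz[tri[, i]])
        J <- c(J, sys$dof_ur[tri[, j]], sys$dof_uz[tri[, j]])
        V <- c(V, mb[, k], mb[, k])
      }
      ca <- triplet_cache(I, J, sys$ndof)
      assemble_from_cache(ca, V)
    }
  }
  blk <- sys$blk
  n <- nrow(blk$nodes)
  if (is.null(state)) state <- list(u = numeric(2L * n), v = numeric(2L * n))
  zin <- blk$nodes[blk$inner, 2]
  tz <- if (is.function(traction)) traction(zin)
        else if (length(traction) == 1L) rep(traction, length(zin))
        else traction
  f <- numeric(sys$ndof)
  rin <- blk$nodes[blk$inner, 1]
  for (e in seq_len(length(zin) - 1L)) {
    len <- zin[e + 1L] - zin[e]
    n1 <- blk$inner[e]; n2 <- blk$inner[e + 1L]
    f[sys$dof_ur[n1]] <- f[sys$dof_ur[n1]] + len * rin[e] * (2 * tz[e] + tz[e + 1L]) / 6
    f[sys$dof_ur[n2]] <- f[sys$dof_ur[n2]] + len * rin[e + 1L] * (tz[e] + 2 * tz[e + 1L]) / 6
  }
  rho <- params$rho_s
  # BDF1 in v with u = u_n + dt v; modified Newton on the SVK residual
  Mf <- sys$Mmat
  Kt <- (rho / dt) * Mf + dt * sys$K
  free <- sys$free
  fac <- Matrix::lu(Kt[free, free])
  v <- state$v
  for (it in 1:30) {
    u <- state$u + dt * v
    res <- rho / dt * as.vector(Mf %*% (v - state$v)) +
      solid_residual(sys, u[sys$dof_ur], u[sys$dof_uz]) - f
    dv <- as.vector(Matrix::solve(fac, res[free]))
    v[free] <- v[free] - dv
    if (max(abs(dv)) < 1e-14 + 1e-9 * max(abs(v), 1e-30)) break
  }
  u <- state$u + dt * v
  u[sys$dir] <- 0; v[sys$dir] <- 0
  list(u = u, v = v, sys = sys,
       ur_interface = u[sys$dof_ur[blk$inner]])
}
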
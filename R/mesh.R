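#' Build the axisymmetric computational mesh
#'
#' Structured triangular mesh of the meridional (r, z) section: the PVS
#' annulus `R1 <= r <= R1 + wd` and (for coupled runs) the brain annulus
#' `R1 + wd <= r <= R3`, both over `0 <= z <= La`. Radial node spacing in
#' the PVS follows a cosine distribution clustering nodes at both walls
#' (to resolve the Brinkman boundary layers); the brain is graded
#' geometrically toward the PVS-brain interface. Axial spacing is uniform.
#' Fluid and solid blocks share their interface nodes.
#'
#' @param params A [pvs_parameters] object.
#' @param nr_pvs Number of radial elements across the PVS width (>= 8
#'   recommended).
#' @param nz Number of axial elements.
#' @param nr_brain Number of radial elements across the brain annulus.
#' @param grade_brain Geometric grading strength for the brain (0 =
#'   uniform).
#' @return A `pvs_mesh` object with components `fluid` and `solid`, each a
#'   structured block (`nodes`, `tri`, grid sizes, boundary node index
#'   vectors), plus the parameters used.
#' @export
build_mesh <- function(params, nr_pvs = 8, nz = 40, nr_brain = 16,
                       grade_brain = 2.5) {
  stopifnot(inherits(params, "pvs_parameters"), nr_pvs >= 2, nz >= 2, nr_brain >= 2)
  R1 <- params$R1; R2 <- params$R1 + params$wd; R3 <- params$R3; La <- params$La

  # cosine clustering at both walls of the PVS
  xf <- (1 - cos(pi * (0:nr_pvs) / nr_pvs)) / 2
  rv_f <- R1 + params$wd * xf
  # geometric grading in the brain, fine near the interface
  xs <- (0:nr_brain) / nr_brain
  if (grade_brain > 0) xs <- (exp(grade_brain * xs) - 1) / (exp(grade_brain) - 1)
  rv_s <- R2 + (R3 - R2) * xs
  zv <- seq(0, La, length.out = nz + 1)

  fluid <- structured_block(rv_f, zv)
  solid <- structured_block(rv_s, zv)
  structure(list(fluid = fluid, solid = solid, params = params,
                 nr_pvs = nr_pvs, nz = nz, nr_brain = nr_brain),
            class = "pvs_mesh")
}

# Structured block mesh on the tensor grid rv x zv, each quad split into two
# triangles. Node id = (j-1)*(length(rv)) + i for radial index i, axial j.
structured_block <- function(rv, zv) {
  nrn <- length(rv); nzn <- length(zv)
  nodes <- cbind(r = rep(rv, nzn), z = rep(zv, each = nrn))
  id <- function(i, j) (j - 1L) * nrn + i
  i <- rep(seq_len(nrn - 1L), nzn - 1L)
  j <- rep(seq_len(nzn - 1L), each = nrn - 1L)
  n00 <- id(i, j); n10 <- id(i + 1L, j); n01 <- id(i, j + 1L); n11 <- id(i + 1L, j + 1L)
  # counter-clockwise triangles (positive Jacobian)
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  if (any(tri_signed_area(nodes, tri) <= 0)) {
    stop("mesh construction produced inverted cells")
  }
  list(nodes = nodes, tri = tri, nrn = nrn, nzn = nzn, rv = rv, zv = zv,
       inner = id(1L, seq_len(nzn)),            # r = min(rv)
       outer = id(nrn, seq_len(nzn)),           # r = max(rv)
       z0 = id(seq_len(nrn), 1L),               # z = 0 (parenchymal/deep end)
       zL = id(seq_len(nrn), nzn))              # z = La (pial end)
}

tri_signed_area <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# Geometry and P1 shape-function data for a triangulation, vectorized over
# elements. b, c are the r- and z-derivatives of the three hat functions;
# rq the radii of the three edge midpoints (degree-2 quadrature points);
# phi[k, q] the value of hat k at midpoint q.
tri_ops <- function(nodes, tri) {
  x <- matrix(nodes[tri, 1], ncol = 3)
  y <- matrix(nodes[tri, 2], ncol = 3)
  area <- 0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
                 (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
  if (any(area <= 0)) stop("inverted cell(s): ", paste(utils::head(which(area <= 0), 5), collapse = ", "))
  inv2A <- 1 / (2 * area)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) * inv2A
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) * inv2A
  # midpoint q is opposite vertex q
  rq <- cbind((x[, 2] + x[, 3]) / 2, (x[, 1] + x[, 3]) / 2, (x[, 1] + x[, 2]) / 2)
  phi <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, 3)  # phi[k, q]
  hr <- pmax(x[, 1], x[, 2], x[, 3]) - pmin(x[, 1], x[, 2], x[, 3])
  hz <- pmax(y[, 1], y[, 2], y[, 3]) - pmin(y[, 1], y[, 2], y[, 3])
  list(area = area, b = b, c = cc, rq = rq, rc = rowMeans(x), phi = phi,
       hr = hr, hz = hz, x = x, y = y)
}

#' @export
print.pvs_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric PVS/brain mesh: PVS %d x %d, brain %d x %d elements\n",
              x$nr_pvs, x$nz, x$nr_brain, x$nz))
  cat(sprintf("  fluid nodes %d, solid nodes %d (interface shared: %d)\n",
              nrow(x$fluid$nodes), nrow(x$solid$nodes), x$nz + 1L))
  invisible(x)
}

# --- sparse assembly cache -------------------------------------------------
#
# All system matrices are rebuilt every time step (the fluid mesh moves), so
# the sparsity pattern and the triplet->slot aggregation map are computed
# once and each assembly reduces to one sparse mat-vec.

triplet_cache <- function(I, J, n) {
  stopifnot(length(I) == length(J))
  key <- (J - 1) * n + I                      # CSC (column-major) order
  uk <- sort(unique(key))
  pos <- match(key, uk)
  ntrip <- length(I)
  agg <- Matrix::sparseMatrix(i = pos, j = seq_len(ntrip), x = 1,
                              dims = c(length(uk), ntrip))
  Jc <- floor((uk - 1) / n) + 1
  Ic <- uk - (Jc - 1) * n
  tmpl <- Matrix::sparseMatrix(i = Ic, j = Jc, x = rep(1, length(uk)),
                               dims = c(n, n))
  # sparseMatrix with unique (i,j) keeps CSC order; x slots align with uk
  list(agg = agg, tmpl = tmpl, n = n)
}

assemble_from_cache <- function(cache, vals) {
  A <- cache$tmpl
  A@x <- as.vector(cache$agg %*% vals)
  A
}

# Aggregator for dense residual accumulation: maps per-element stacked
# contributions to a dense vector of length n.
vector_cache <- function(idx, n) {
  Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                       dims = c(n, length(idx)))
}
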
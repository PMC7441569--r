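p <- default_parameters()

test_that("structured mesh covers the annuli exactly with positive cells", {
  m <- build_mesh(p, nr_pvs = 8, nz = 20, nr_brain = 10)
  fo <- pvsflow:::tri_ops(m$fluid$nodes, m$fluid$tri)
  expect_equal(sum(fo$area), p$wd * p$La, tolerance = 1e-12)   # meridional area
  so <- pvsflow:::tri_ops(m$solid$nodes, m$solid$tri)
  expect_equal(sum(so$area), (p$R3 - p$R1 - p$wd) * p$La, tolerance = 1e-12)
  expect_true(all(fo$area > 0) && all(so$area > 0))
  # axisymmetric volume 2 pi int r dA matches mensuration
  expect_equal(2 * pi * sum(fo$area * fo$rc), p$V_pvs, tolerance = 1e-12)
  # interface rows coincide (conforming blocks)
  expect_equal(m$fluid$nodes[m$fluid$outer, ], m$solid$nodes[m$solid$inner, ])
})

test_that("the long-arteriole geometry meshes with positive Jacobians", {
  pl <- pvs_parameters(La = 1e5, validate = FALSE)   # 0.1 m
  m <- build_mesh(pl, nr_pvs = 4, nz = 60, nr_brain = 4)
  fo <- pvsflow:::tri_ops(m$fluid$nodes, m$fluid$tri)
  expect_true(all(fo$area > 0))
  expect_equal(sum(fo$area), pl$wd * pl$La, tolerance = 1e-12)
})

test_that("refinement preserves boundary tags and nests the boundary", {
  m1 <- build_mesh(p, nr_pvs = 4, nz = 10, nr_brain = 4)
  m2 <- build_mesh(p, nr_pvs = 8, nz = 20, nr_brain = 8)
  for (m in list(m1, m2)) {
    expect_true(all(abs(m$fluid$nodes[m$fluid$inner, 1] - p$R1) < 1e-18))
    expect_true(all(abs(m$fluid$nodes[m$fluid$outer, 1] - (p$R1 + p$wd)) < 1e-18))
    expect_true(all(abs(m$fluid$nodes[m$fluid$zL, 2] - p$La) < 1e-18))
    expect_true(all(m$fluid$nodes[m$fluid$z0, 2] == 0))
  }
  # coarse boundary nodes appear in the refined wall too
  expect_true(all(m1$fluid$nodes[m1$fluid$z0, 1] %in% m2$fluid$nodes[m2$fluid$z0, 1] |
                  vapply(m1$fluid$nodes[m1$fluid$z0, 1],
                         function(r) any(abs(m2$fluid$nodes[m2$fluid$z0, 1] - r) < 1e-15),
                         logical(1))))
})

test_that("harmonic mesh motion: zero data, bilinear interpolant, maximum principle", {
  m <- build_mesh(p, nr_pvs = 6, nz = 16, nr_brain = 4)
  u0 <- harmonic_mesh_motion(m, 0, 0)
  expect_equal(max(abs(u0)), 0)
  # radial data varying linearly in z on both walls: the interior harmonic
  # solution is the bilinear interpolant (exactly representable in P1)
  a <- 0.1e-6; b <- 0.3e-6
  wallf <- function(z) a * z / p$La
  intf <- function(z) b * z / p$La
  u <- harmonic_mesh_motion(m, wallf, list(r = intf, z = 0))
  nd <- m$fluid$nodes
  xi <- (nd[, 1] - p$R1) / p$wd
  exact <- (1 - xi) * wallf(nd[, 2]) + xi * intf(nd[, 2])
  expect_equal(u[, "dr"], exact, tolerance = 1e-6)
  # heartbeat-scale boundary data obeys the discrete maximum principle
  mo <- wall_motion("heartbeat", p)
  uh <- harmonic_mesh_motion(m, function(z) mo$displacement(z, 0.025), 0)
  expect_lte(max(abs(uh[, "dr"])), max(abs(mo$displacement(nd[m$fluid$inner, 2], 0.025))) * (1 + 1e-9))
  expect_equal(max(abs(uh[, "dr"])), 0.06e-6, tolerance = 0.03)
})
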
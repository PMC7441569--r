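# Independent numerical oracles used by the verification tests.

# 1-D finite-difference solution of steady, fully developed annular
# Darcy-Brinkman (or Stokes) flow: mu (v'' + v'/r) - drag v = dp/dz with
# no-slip walls. Fine-grid two-point boundary-value solve, independent of
# the finite-element path.
brinkman_profile_1d <- function(params, dpdz, n = 4000) {
  R1 <- params$R1; R2 <- params$R1 + params$wd
  r <- seq(R1, R2, length.out = n)
  h <- r[2] - r[1]
  mu <- params$mu_f
  drag <- if (is.infinite(params$k_s)) 0 else mu * params$zeta / params$k_s
  ri <- r[2:(n - 1)]
  n_i <- n - 2
  A <- Matrix::bandSparse(n_i, n_i, k = -1:1, diagonals = list(
    (mu / h^2 - mu / (2 * h * ri))[-1],
    rep(-2 * mu / h^2 - drag, n_i),
    (mu / h^2 + mu / (2 * h * ri))[-n_i]))
  v <- as.vector(Matrix::solve(A, rep(dpdz, n_i)))
  list(r = r, v = c(0, v, 0),
       q = 2 * pi * sum(diff(r) * (r[-1] * c(0, v, 0)[-1] +
                                   r[-n] * c(0, v, 0)[-n]) / 2))
}

# Closed-form thick-walled-cylinder (Lame) radial displacement under
# internal pressure with the outer radius fixed, plane strain.
lame_inner_displacement <- function(pressure, params) {
  R2 <- params$R1 + params$wd; R3 <- params$R3
  lam <- params$lambda_s; mu <- params$mu_s
  A <- -pressure / (2 * (lam + mu) + 2 * mu * (R3 / R2)^2)
  A * R2 * (1 - (R3 / R2)^2)
}

# cumulative trapezoid from rest (t = 0, q = 0)
cum_outflow <- function(time, q) {
  x <- c(0, time); y <- c(0, q)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
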
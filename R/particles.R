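# Lagrangian fluid-particle tracking in the deforming PVS: forward-Euler
# integration of laboratory-frame velocities interpolated from stored
# field snapshots (or from a user-supplied analytic velocity field, used
# for convergence verification).

#' Advect fluid particles through a recorded flow
#'
#' Forward-Euler particle tracking `x_{n+1} = x_n + v(x_n, t_n) dt` using
#' the velocity snapshots stored on a `pvs_flow_record` (run with
#' `store_fields = TRUE`), with a batch of fresh particles seeded near the
#' pial (SAS) end every `seed_every` seconds to visualize PVS-SAS fluid
#' exchange. Particles are colored by their seeding depth; a particle
#' leaving through an end is flagged `exited` (frozen, not an error).
#'
#' @param record A `pvs_flow_record` with stored fields, or `NULL` when
#'   `velocity` is given.
#' @param dt Integration step, s (default: snapshot spacing).
#' @param duration Tracking horizon, s (default: record length).
#' @param seed_every Interval between SAS-side seed batches, s (`Inf` for
#'   none).
#' @param seed_n Particles per seed batch.
#' @param n_r,n_z Initial particle grid resolution across the PVS.
#' @param velocity Optional analytic velocity: `function(t, xy)` taking an
#'   `n x 2` matrix of (r, z) positions and returning an `n x 2` matrix of
#'   (v_r, v_z).
#' @param domain With `velocity`: list with `r = c(min, max)`,
#'   `z = c(min, max)` bounds (default: the record's PVS geometry).
#' @return A `pvs_particles` object: `times`, a `[n_particles x 2 x
#'   n_times]` position array (NA before a particle's seeding time),
#'   `seed_depth` (initial z, m), `batch` (0 = initial fill), and `exited`
#'   flags.
#' @export
advect_particles <- function(record, dt = NULL, duration = NULL,
                             seed_every = 0.5, seed_n = 24,
                             n_r = 4, n_z = 30, velocity = NULL,
                             domain = NULL) {
  if (is.null(velocity)) {
    if (is.null(record$fields) || !length(record$fields)) {
      stop("record has no stored fields; rerun with store_fields = TRUE")
    }
    snap_t <- vapply(record$fields, function(f) f$t, numeric(1))
    if (is.null(dt)) dt <- if (length(snap_t) > 1) diff(snap_t)[1] else record$dt
    if (is.null(duration)) duration <- max(snap_t)
    pr <- record$params
    rlim <- c(pr$R1, pr$R1 + pr$wd); zlim <- c(0, pr$La)
    nrn <- record$resolution[["nr_pvs"]] + 1L
  } else {
    if (is.null(dt) || is.null(duration)) {
      stop("dt and duration are required with an analytic velocity")
    }
    if (is.null(domain)) stop("domain is required with an analytic velocity")
    rlim <- domain$r; zlim <- domain$z
  }
  times <- seq(0, duration, by = dt)
  nt <- length(times)

  rg <- seq(rlim[1], rlim[2], length.out = n_r + 2L)[-c(1, n_r + 2L)]
  zg <- seq(zlim[1], zlim[2], length.out = n_z + 2L)[-c(1, n_z + 2L)]
  init <- cbind(r = rep(rg, times = n_z), z = rep(zg, each = n_r))
  batch_times <- if (is.finite(seed_every)) seq(seed_every, duration, by = seed_every) else numeric(0)
  n_init <- nrow(init)
  n_tot <- n_init + seed_n * length(batch_times)
  pos <- array(NA_real_, c(n_tot, 2, nt))
  seed_depth <- c(init[, 2], rep(NA_real_, n_tot - n_init))
  batch <- c(rep(0L, n_init), rep(seq_along(batch_times), each = seed_n))
  exited <- logical(n_tot)
  active <- c(rep(TRUE, n_init), rep(FALSE, n_tot - n_init))
  cur <- matrix(NA_real_, n_tot, 2)
  cur[seq_len(n_init), ] <- init
  pos[, , 1] <- cur
  next_batch <- 1L

  interp_v <- function(t, xy) {
    if (!is.null(velocity)) return(velocity(t, xy))
    k <- findInterval(t, snap_t, all.inside = TRUE)
    f1 <- record$fields[[k]]
    f2 <- record$fields[[min(k + 1L, length(snap_t))]]
    wt <- if (f2$t > f1$t) (t - f1$t) / (f2$t - f1$t) else 0
    v1 <- snap_velocity(f1, xy, nrn, record$zv)
    if (wt <= 0) return(v1)
    v2 <- snap_velocity(f2, xy, nrn, record$zv)
    (1 - wt) * v1 + wt * v2
  }

  for (n in seq_len(nt - 1L)) {
    t <- times[n]
    # seed a fresh SAS-side batch when due
    while (next_batch <= length(batch_times) && batch_times[next_batch] <= t + 1e-12) {
      idx <- n_init + (next_batch - 1L) * seed_n + seq_len(seed_n)
      rr <- seq(rlim[1], rlim[2], length.out = seed_n + 2L)[-c(1, seed_n + 2L)]
      zz <- rep(zlim[2] - 0.01 * diff(zlim), seed_n)
      cur[idx, ] <- cbind(rr, zz)
      seed_depth[idx] <- zz
      active[idx] <- TRUE
      next_batch <- next_batch + 1L
    }
    mov <- which(active & !exited)
    if (length(mov)) {
      v <- interp_v(t, cur[mov, , drop = FALSE])
      cur[mov, ] <- cur[mov, , drop = FALSE] + v * dt
      out <- cur[mov, 2] < zlim[1] | cur[mov, 2] > zlim[2]
      exited[mov[out]] <- TRUE
      cur[mov, 2] <- pmin(pmax(cur[mov, 2], zlim[1]), zlim[2])
    }
    pos[, , n + 1L] <- cur
  }
  # batches scheduled exactly at the end of the record are still appended
  while (next_batch <= length(batch_times) &&
         batch_times[next_batch] <= times[nt] + 1e-12) {
    idx <- n_init + (next_batch - 1L) * seed_n + seq_len(seed_n)
    rr <- seq(rlim[1], rlim[2], length.out = seed_n + 2L)[-c(1, seed_n + 2L)]
    cur[idx, ] <- cbind(rr, rep(zlim[2] - 0.01 * diff(zlim), seed_n))
    seed_depth[idx] <- cur[idx, 2]
    active[idx] <- TRUE
    pos[idx, , nt] <- cur[idx, ]
    next_batch <- next_batch + 1L
  }
  structure(list(times = times, positions = pos, seed_depth = seed_depth,
                 batch = batch, batch_times = batch_times, exited = exited),
            class = "pvs_particles")
}

# Bilinear velocity interpolation on a structured snapshot.
snap_velocity <- function(field, xy, nrn, zv) {
  nzn <- length(zv)
  R <- matrix(field$nodes[, 1], nrn, nzn)
  VR <- matrix(field$vr, nrn, nzn)
  VZ <- matrix(field$vz, nrn, nzn)
  np <- nrow(xy)
  out <- matrix(0, np, 2)
  j <- findInterval(xy[, 2], zv, all.inside = TRUE)
  tz <- (xy[, 2] - zv[j]) / (zv[j + 1L] - zv[j])
  for (p in seq_len(np)) {
    rcol <- R[, j[p]] * (1 - tz[p]) + R[, j[p] + 1L] * tz[p]
    rr <- min(max(xy[p, 1], rcol[1]), rcol[nrn])
    i <- findInterval(rr, rcol, all.inside = TRUE)
    tr <- (rr - rcol[i]) / (rcol[i + 1L] - rcol[i])
    vr1 <- VR[i, j[p]] + tr * (VR[i + 1L, j[p]] - VR[i, j[p]])
    vr2 <- VR[i, j[p] + 1L] + tr * (VR[i + 1L, j[p] + 1L] - VR[i, j[p] + 1L])
    vz1 <- VZ[i, j[p]] + tr * (VZ[i + 1L, j[p]] - VZ[i, j[p]])
    vz2 <- VZ[i, j[p] + 1L] + tr * (VZ[i + 1L, j[p] + 1L] - VZ[i, j[p] + 1L])
    out[p, 1] <- vr1 * (1 - tz[p]) + vr2 * tz[p]
    out[p, 2] <- vz1 * (1 - tz[p]) + vz2 * tz[p]
  }
  out
}

#' @export
print.pvs_particles <- function(x, ...) {
  cat(sprintf("Particle ensemble: %d particles (%d seed batches), %d time points, %d exited\n",
              length(x$seed_depth), length(x$batch_times), length(x$times),
              sum(x$exited)))
  invisible(x)
}

#' @export
plot.pvs_particles <- function(x, at = max(x$times), ...) {
  n <- which.min(abs(x$times - at))
  p <- x$positions[, , n] * 1e6
  cols <- ifelse(x$batch > 0, "red",
                 grDevices::hcl.colors(100, "viridis")[
                   pmax(1, ceiling(99 * (x$seed_depth / max(x$seed_depth,
                                                            na.rm = TRUE))) )])
  graphics::plot(p[, 1], p[, 2], col = cols, pch = 16, cex = 0.5,
                 xlab = "r (um)", ylab = "z (um)",
                 main = sprintf("fluid particles at t = %.2f s", x$times[n]), ...)
  invisible(x)
}
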
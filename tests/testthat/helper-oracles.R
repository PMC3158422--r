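# Independent numeric oracles. These never call the closed-form overlap
# kernel under test: densities are evaluated on explicit grids and the
# hard-sphere union volume is estimated by Monte Carlo.

# Gaussian shape density evaluated on a regular grid (separable per axis),
# integrated as sum * h^3. power = 1 -> monopole volume, 2 -> self-overlap.
grid_density_integral <- function(g, power = 1, spacing = 0.1,
                                  padding = 5) {
  lo <- apply(g$centers, 2, min) - padding
  hi <- apply(g$centers, 2, max) + padding
  xs <- seq(lo[1], hi[1], by = spacing)
  ys <- seq(lo[2], hi[2], by = spacing)
  zs <- seq(lo[3], hi[3], by = spacing)
  rho <- array(0, c(length(xs), length(ys), length(zs)))
  for (i in seq_len(nrow(g$centers))) {
    ax <- exp(-g$alpha[i] * (xs - g$centers[i, 1])^2)
    ay <- exp(-g$alpha[i] * (ys - g$centers[i, 2])^2)
    az <- exp(-g$alpha[i] * (zs - g$centers[i, 3])^2)
    rho <- rho + g$p[i] * outer(outer(ax, ay), az)
  }
  sum(rho^power) * spacing^3
}

# Cross overlap of two densities on a shared grid.
grid_cross_overlap <- function(gA, gB, spacing = 0.1, padding = 5) {
  all_centers <- rbind(gA$centers, gB$centers)
  lo <- apply(all_centers, 2, min) - padding
  hi <- apply(all_centers, 2, max) + padding
  xs <- seq(lo[1], hi[1], by = spacing)
  ys <- seq(lo[2], hi[2], by = spacing)
  zs <- seq(lo[3], hi[3], by = spacing)
  dens <- function(g) {
    rho <- array(0, c(length(xs), length(ys), length(zs)))
    for (i in seq_len(nrow(g$centers))) {
      ax <- exp(-g$alpha[i] * (xs - g$centers[i, 1])^2)
      ay <- exp(-g$alpha[i] * (ys - g$centers[i, 2])^2)
      az <- exp(-g$alpha[i] * (zs - g$centers[i, 3])^2)
      rho <- rho + g$p[i] * outer(outer(ax, ay), az)
    }
    rho
  }
  sum(dens(gA) * dens(gB)) * spacing^3
}

# Monte-Carlo volume of a union of hard spheres.
mc_union_volume <- function(centers, radii, n_points = 1e7, seed = 1,
                            chunk = 1e6) {
  lo <- apply(sweep(centers, 1, radii, function(c, r) c), 2, min) -
    max(radii)
  hi <- apply(centers, 2, max) + max(radii)
  box <- prod(hi - lo)
  set.seed(seed)
  inside <- 0
  done <- 0
  while (done < n_points) {
    m <- min(chunk, n_points - done)
    pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                 runif(m, lo[3], hi[3]))
    hit <- rep(FALSE, m)
    for (i in seq_len(nrow(centers))) {
      hit <- hit | (pts[, 1] - centers[i, 1])^2 +
        (pts[, 2] - centers[i, 2])^2 +
        (pts[, 3] - centers[i, 3])^2 <= radii[i]^2
    }
    inside <- inside + sum(hit)
    done <- done + m
  }
  box * inside / n_points
}

# Best overlap volume over an exhaustive Euler-angle rotation grid with
# both centroids at the origin (no translation refinement).
rotation_grid_best <- function(gA, gB, step_deg = 15) {
  rotz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
  roty <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                               -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  qa <- quadrupoles(gA)
  qb <- quadrupoles(gB)
  Ac <- sweep(gA$centers, 2, qa$centroid)
  Bc <- sweep(gB$centers, 2, qb$centroid)
  step <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - step, by = step)
  betas <- seq(0, pi, by = step)
  rots <- do.call(rbind, lapply(alphas, function(a) {
    do.call(rbind, lapply(betas, function(b) {
      do.call(rbind, lapply(alphas, function(g) {
        rotz(a) %*% roty(b) %*% rotz(g)
      }))
    }))
  }))
  vals <- shapequad:::cpp_overlap_rotgrid(Ac, gA$alpha, gA$p, Bc,
                                          gB$alpha, gB$p, rots)
  max(vals)
}

# A compact bonded-geometry conformer used where tests need fixed small
# structures (chain of n atoms, 1.5 A spacing, slight zig-zag so the
# quadrupole spectrum is non-degenerate).
chain_conformer <- function(n, element = "C", id = "chain") {
  coords <- cbind(1.5 * (seq_len(n) - 1),
                  0.2 * (seq_len(n) %% 2),
                  0.1 * (seq_len(n) %% 3))
  conformer(rep(element, n), coords, id = id,
            bonds = if (n > 1) cbind(seq_len(n - 1), 2:n))
}

random_rigid_copy <- function(conf, seed, id = paste0(conf$id, "_copy")) {
  perturb_conformer(conf, sigma = 0, seed = seed, id = id)
}
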
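#' Atomic Gaussian shape model
#'
#' Each atom is represented by a single spherical Gaussian
#' \eqn{g_i(r) = p \exp(-\alpha_i |r - c_i|^2)} whose amplitude-weighted
#' integral is calibrated to the hard-sphere atomic volume:
#' \eqn{p (\pi/\alpha_i)^{3/2} = (4/3) \pi r_i^3}. Solving for the exponent
#' gives \eqn{\alpha_i = \pi (3p / 4\pi)^{2/3} / r_i^2}. The default
#' amplitude \eqn{p = 2\sqrt{2}} is the standard Gaussian-shape convention
#' under which a single atom's self-overlap volume equals its monopole
#' volume exactly.
#'
#' @param conf A [conformer()].
#' @param radii A [radius_table()].
#' @param amplitude Gaussian amplitude \eqn{p} (dimensionless, default
#'   \eqn{2\sqrt{2}}).
#' @return An object of class `gaussian_set` with per-atom `centers`
#'   (n x 3), `alpha` (1/A^2), `p`, and hard-sphere volumes `vol` (A^3).
#' @examples
#' g <- build_gaussians(conformer("C", matrix(0, 1, 3)), radius_table())
#' g$alpha  # ~0.8366 for r = 1.70
#' @export
build_gaussians <- function(conf, radii = radius_table(),
                            amplitude = 2 * sqrt(2)) {
  stopifnot(inherits(conf, "conformer"))
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  r <- atom_radius(radii, conf$elements)
  alpha <- pi * (3 * amplitude / (4 * pi))^(2 / 3) / r^2
  structure(
    list(id = conf$id, centers = conf$coords, alpha = alpha,
         p = rep(amplitude, length(alpha)), vol = (4 / 3) * pi * r^3,
         radius = r),
    class = "gaussian_set"
  )
}

#' @export
print.gaussian_set <- function(x, ...) {
  cat("<gaussian_set> ", nrow(x$centers), " atoms, p=",
      format(x$p[1], digits = 4), ", V_mp=",
      format(sum(x$vol), digits = 6), " A^3\n", sep = "")
  invisible(x)
}

#' Monopole volume
#'
#' The integral of the summed atomic Gaussian density: the monopole (zeroth
#' moment) of the shape multipole expansion. Under the hard-sphere
#' calibration it equals the sum of the atomic sphere volumes and is
#' independent of the conformation.
#'
#' @param g A `gaussian_set`.
#' @return Volume in A^3.
#' @export
monopole_volume <- function(g) {
  stopifnot(inherits(g, "gaussian_set"))
  sum(g$vol)
}

#' Self-overlap volume
#'
#' The integral of the squared Gaussian density,
#' \eqn{V_{so} = \int \rho(r)^2 dr =
#' \sum_{ij} p^2 (\pi/(\alpha_i+\alpha_j))^{3/2}
#' \exp(-\alpha_i \alpha_j d_{ij}^2/(\alpha_i+\alpha_j))}.
#' This is the \eqn{V_{AA}} term of the shape-Tanimoto score; it counts
#' overlapping atoms more than once and therefore overestimates the
#' hard-sphere volume for bonded systems.
#'
#' @param g A `gaussian_set`.
#' @return Volume in A^3.
#' @export
self_overlap_volume <- function(g) {
  stopifnot(inherits(g, "gaussian_set"))
  cpp_overlap(g$centers, g$alpha, g$p, g$centers, g$alpha, g$p)
}

#' Analytic volume
#'
#' Approximates the hard-sphere union volume by inclusion-exclusion over
#' Gaussian product integrals:
#' \eqn{V_{an} = \sum_k (-1)^{k+1} \sum_{i_1<...<i_k} \int g_{i_1} \cdots
#' g_{i_k}\, dr}, truncated at `max_order` (default 3, which captures
#' pairwise and three-body corrections). Intersections whose atoms are
#' farther apart than `prune_factor` times the radius sum contribute
#' negligibly and are pruned; a k-tuple is kept only when all its pairs
#' survive pruning.
#'
#' @param g A `gaussian_set`.
#' @param max_order Highest inclusion-exclusion order (>= 1).
#' @param prune_factor Distance cutoff multiplier on the radius sum.
#' @return Volume in A^3.
#' @export
analytic_volume <- function(g, max_order = 3, prune_factor = 1.2) {
  stopifnot(inherits(g, "gaussian_set"))
  if (max_order < 1) stop("`max_order` must be >= 1", call. = FALSE)
  n <- nrow(g$centers)
  v <- sum(g$vol)
  if (max_order == 1 || n == 1) return(v)

  d <- as.matrix(stats::dist(g$centers))
  cutoff <- outer(g$radius, g$radius, "+") * prune_factor
  adj <- d <= cutoff & upper.tri(d)
  pairs <- which(adj, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(v)

  v <- v - sum(vapply(seq_len(nrow(pairs)), function(k) {
    gaussian_product_integral(g, pairs[k, ])
  }, numeric(1)))

  if (max_order >= 3 && n >= 3) {
    adj_sym <- adj | t(adj)
    for (i in seq_len(n - 2)) {
      nb <- which(adj_sym[i, ] & seq_len(n) > i)
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) {
        for (b in seq(a + 1, length(nb))) {
          j <- nb[a]; k <- nb[b]
          if (adj_sym[j, k]) {
            v <- v + gaussian_product_integral(g, c(i, j, k))
          }
        }
      }
    }
  }
  if (max_order >= 4) {
    warning("inclusion-exclusion truncated at order 3", call. = FALSE)
  }
  v
}

# Closed-form integral of a product of spherical Gaussians over R^3:
# prod_m p exp(-alpha_m |r - c_m|^2) integrates to
# (prod p) exp(-K) (pi/A)^{3/2}, A = sum alpha, K = sum alpha_m |c_m|^2 -
# A |cbar|^2 with cbar the alpha-weighted mean center.
gaussian_product_integral <- function(g, idx) {
  a <- g$alpha[idx]
  cc <- g$centers[idx, , drop = FALSE]
  A <- sum(a)
  cbar <- colSums(cc * a) / A
  K <- sum(a * rowSums(cc^2)) - A * sum(cbar^2)
  prod(g$p[idx]) * exp(-K) * (pi / A)^1.5
}
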
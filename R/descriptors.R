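#' Steric shape quadrupole moments
#'
#' Second moments of the Gaussian shape density about its centroid, in the
#' principal-axes frame. The per-atom closed form for the second-moment
#' integral is \eqn{V_i (c_i c_i^T + I/(2\alpha_i))}; the tensor is
#' normalized by the monopole volume so the components have units of A^2 and
#' satisfy \eqn{Q_x + Q_y + Q_z = R_g^2} with \eqn{R_g} the radius of
#' gyration of the shape density. Components are sorted descending
#' (\eqn{Q_x \ge Q_y \ge Q_z}), so they act as proxies for squared length,
#' width and height. A volume-scaled variant (components multiplied by
#' \eqn{V_{mp}}, units A^5) is available via `scale = "volume"`.
#'
#' The principal-axes rotation is made deterministic even under near-ties:
#' eigenvalues are sorted descending, the first two axes are flipped so
#' their largest-magnitude component is non-negative, and the third axis is
#' their cross product, guaranteeing a proper rotation (det +1).
#'
#' @param g A `gaussian_set`.
#' @param scale `"normalized"` (default; monopole-normalized, A^2) or
#'   `"volume"` (multiplied by the monopole volume, A^5).
#' @return List with `centroid`, `principal_axes` (columns are axes,
#'   det +1), `q` (named Qx/Qy/Qz) and `rg`.
#' @export
quadrupoles <- function(g, scale = c("normalized", "volume")) {
  stopifnot(inherits(g, "gaussian_set"))
  scale <- match.arg(scale)
  vmp <- sum(g$vol)
  centroid <- colSums(g$centers * g$vol) / vmp
  centered <- sweep(g$centers, 2, centroid)
  # sum_i V_i (c_i c_i^T + I/(2 alpha_i)), centered
  M <- crossprod(centered * g$vol, centered) / vmp +
    diag(3) * sum(g$vol / (2 * g$alpha)) / vmp
  e <- eigen(M, symmetric = TRUE)  # eigenvalues already descending
  axes <- e$vectors
  for (k in 1:2) {
    if (axes[which.max(abs(axes[, k])), k] < 0) axes[, k] <- -axes[, k]
  }
  axes[, 3] <- c(
    axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
    axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
    axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2]
  )
  q <- e$values
  rg <- sqrt(sum(q))
  if (scale == "volume") q <- q * vmp
  list(centroid = centroid, principal_axes = axes,
       q = c(qx = q[1], qy = q[2], qz = q[3]), rg = rg)
}

#' Compute the full steric descriptor set for a conformer
#'
#' Bundles the three volume types (analytic, monopole, self-overlap), the
#' principal-frame quadrupole components and the radius of gyration into one
#' record. All quantities are invariant under proper rigid motion of the
#' conformer; centroid and principal axes transform covariantly.
#'
#' @param conf A [conformer()].
#' @param radii A [radius_table()].
#' @param amplitude Gaussian amplitude (default \eqn{2\sqrt{2}}).
#' @param max_order Inclusion-exclusion order for the analytic volume.
#' @param quad_scale Quadrupole scale, see [quadrupoles()].
#' @return An object of class `shape_descriptors`: fields `id`, `n_atoms`,
#'   `v_an`, `v_mp`, `v_so`, `qx`, `qy`, `qz`, `rg`, `centroid`,
#'   `principal_axes`, `quad_scale`.
#' @examples
#' d <- shape_descriptors(conformer("F", matrix(0, 1, 3), id = "f"),
#'                        radius_table())
#' c(d$v_mp, d$qx)  # single-sphere volume; isotropic second moment
#' @export
shape_descriptors <- function(conf, radii = radius_table(),
                              amplitude = 2 * sqrt(2), max_order = 3,
                              quad_scale = c("normalized", "volume")) {
  quad_scale <- match.arg(quad_scale)
  g <- build_gaussians(conf, radii, amplitude)
  qq <- quadrupoles(g, scale = quad_scale)
  structure(
    list(id = conf$id, n_atoms = nrow(g$centers),
         v_an = analytic_volume(g, max_order = max_order),
         v_mp = monopole_volume(g),
         v_so = self_overlap_volume(g),
         qx = unname(qq$q["qx"]), qy = unname(qq$q["qy"]),
         qz = unname(qq$q["qz"]), rg = qq$rg,
         centroid = qq$centroid, principal_axes = qq$principal_axes,
         quad_scale = quad_scale),
    class = "shape_descriptors"
  )
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf(
    "<shape_descriptors> id=%s n=%d  V_an=%.2f V_mp=%.2f V_so=%.2f  Q=(%.3f, %.3f, %.3f) Rg=%.3f\n",
    x$id, x$n_atoms, x$v_an, x$v_mp, x$v_so, x$qx, x$qy, x$qz, x$rg))
  invisible(x)
}

#' Descriptor tables
#'
#' Compute descriptors for a list of conformers, or read/write the standard
#' tab-separated descriptor table (`id n_atoms v_an v_mp v_so qx qy qz rg`,
#' floats written at 6 significant digits).
#'
#' @param conformers List of [conformer()] objects.
#' @param ... Passed to [shape_descriptors()].
#' @return A data frame with one row per conformer.
#' @export
descriptor_table <- function(conformers, ...) {
  rows <- lapply(conformers, function(cf) {
    d <- shape_descriptors(cf, ...)
    data.frame(id = d$id, n_atoms = d$n_atoms, v_an = d$v_an, v_mp = d$v_mp,
               v_so = d$v_so, qx = d$qx, qy = d$qy, qz = d$qz, rg = d$rg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname descriptor_table
#' @param desc Data frame as returned by [descriptor_table()].
#' @param path File path.
#' @export
write_descriptor_table <- function(desc, path) {
  out <- desc
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_atoms"
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 6,
                                                   format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname descriptor_table
#' @export
read_descriptor_table <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  required <- c("id", "n_atoms", "v_an", "v_mp", "v_so", "qx", "qy", "qz",
                "rg")
  if (!all(required %in% header)) {
    stop("descriptor table is missing column(s): ",
         paste(setdiff(required, header), collapse = ", "),
         call. = FALSE)
  }
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
}
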
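#' Rigid transforms
#'
#' A proper rigid-body motion: rotation (3 x 3, det +1) plus translation
#' (Angstrom). Used to pose conformer B relative to conformer A during
#' superposition.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("`rotation` must be a proper rotation (orthonormal, det +1)",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform A `rigid_transform`.
#' @param coords n x 3 coordinate matrix.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> t=(",
      paste(formatC(x$translation, digits = 4, format = "g"),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# unit quaternion (w,x,y,z) -> rotation matrix
rotmat_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
}

# rotation matrix -> unit quaternion (Shepperd's method)
quat_from_rotmat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Cross overlap volume
#'
#' The Gaussian overlap volume \eqn{V_{AB} = \int \rho_A \rho_{t(B)} dr}
#' between the density of A and the density of B posed by a rigid
#' transform, evaluated by the closed-form pairwise Gaussian sum.
#'
#' @param gA,gB `gaussian_set` objects.
#' @param transform `rigid_transform` applied to B (identity by default).
#' @return Volume in A^3.
#' @export
cross_overlap <- function(gA, gB, transform = rigid_transform()) {
  stopifnot(inherits(gA, "gaussian_set"), inherits(gB, "gaussian_set"))
  bc <- apply_transform(transform, gB$centers)
  cpp_overlap(gA$centers, gA$alpha, gA$p, bc, gB$alpha, gB$p)
}

#' Shape Tanimoto from overlap volumes
#'
#' \eqn{ST = V_{AB} / (V_{AA} + V_{BB} - V_{AB})}, the overlap-volume
#' similarity between two superposed shapes. Tiny floating-point excursions
#' outside `[0, 1]` (at most 1e-12) are clamped; anything larger indicates
#' inconsistent volumes and is an error.
#'
#' @param v_aa,v_bb Self-overlap volumes (> 0).
#' @param v_ab Cross overlap volume (>= 0).
#' @return ST in `[0, 1]`.
#' @export
st_from_volumes <- function(v_aa, v_bb, v_ab) {
  if (any(v_aa <= 0) || any(v_bb <= 0)) {
    stop("self-overlap volumes must be > 0", call. = FALSE)
  }
  denom <- v_aa + v_bb - v_ab
  if (any(denom <= 0)) {
    stop("ST denominator V_AA + V_BB - V_AB must be > 0", call. = FALSE)
  }
  st <- v_ab / denom
  if (any(st < -1e-12) || any(st > 1 + 1e-12)) {
    stop("ST outside [0,1] beyond floating tolerance; inconsistent volumes",
         call. = FALSE)
  }
  pmin(pmax(st, 0), 1)
}

#' Volume-only upper bound on the shape Tanimoto
#'
#' For the Gaussian shape model the cross overlap obeys the Cauchy-Schwarz
#' bound \eqn{V_{AB} \le \sqrt{V_{AA} V_{BB}}}, so no superposition of the
#' pair can exceed \eqn{s/(V_{AA}+V_{BB}-s)} with \eqn{s = \sqrt{V_{AA}
#' V_{BB}}}. Pairs whose bound falls below the search threshold can be
#' discarded before any superposition work.
#'
#' @param v_aa,v_bb Self-overlap volumes (> 0). Vectorized.
#' @return Upper bound on achievable ST.
#' @export
st_volume_bound <- function(v_aa, v_bb) {
  if (any(v_aa <= 0) || any(v_bb <= 0)) {
    stop("volumes must be > 0", call. = FALSE)
  }
  s <- sqrt(v_aa * v_bb)
  s / (v_aa + v_bb - s)
}

#' Maximize the overlap volume of two conformers
#'
#' Rigid-body superposition optimization: starting from the four proper
#' principal-axes alignments (both centroids at the origin, axes aligned;
#' identity plus pi rotations about each principal axis), the overlap
#' volume is maximized over rotation (quaternion) and translation by
#' quasi-Newton ascent with analytic gradients of the Gaussian sum. The
#' best pose over all starts is returned; the reported ST uses the
#' self-overlap volumes.
#'
#' @param gA,gB `gaussian_set` objects.
#' @param max_iter Iteration cap per start (default 200).
#' @param reltol Relative convergence tolerance on the overlap volume.
#' @param extra_starts Number of additional random-rotation starts.
#' @param seed Seed for the extra starts (required when `extra_starts > 0`).
#' @return An `overlap_result`: `v_ab`, `st`, `transform`, `n_starts`,
#'   `converged` (FALSE when an ascent hit the iteration cap; the
#'   best-so-far pose is still returned).
#' @examples
#' conf <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
#' g <- build_gaussians(conf, radius_table())
#' optimize_superposition(g, g)$st  # 1
#' @export
optimize_superposition <- function(gA, gB, max_iter = 200, reltol = 1e-12,
                                   extra_starts = 0, seed = NULL) {
  stopifnot(inherits(gA, "gaussian_set"), inherits(gB, "gaussian_set"))
  qa <- quadrupoles(gA)
  qb <- quadrupoles(gB)
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                diag(c(-1, -1, 1)))
  starts <- lapply(flips, function(D) {
    R0 <- qa$principal_axes %*% D %*% t(qb$principal_axes)
    list(R = R0, t = qa$centroid - as.numeric(R0 %*% qb$centroid))
  })
  if (extra_starts > 0) {
    if (is.null(seed)) {
      stop("`seed` is required when `extra_starts` > 0", call. = FALSE)
    }
    rng <- make_rng(seed)
    for (k in seq_len(extra_starts)) {
      R0 <- random_rotation(rng)
      starts <- c(starts, list(
        list(R = R0, t = qa$centroid - as.numeric(R0 %*% qb$centroid))))
    }
  }

  # optim() asks for the value and the gradient separately; one C++ call
  # produces both, so cache the last evaluation
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!identical(par, cache$par)) {
      cache$res <- cpp_overlap_qgrad(gA$centers, gA$alpha, gA$p,
                                     gB$centers, gB$alpha, gB$p, par)
      cache$par <- par
    }
    cache$res
  }
  fn <- function(par) eval_at(par)$value
  gr <- function(par) eval_at(par)$gradient

  best <- NULL
  converged <- TRUE
  for (s in starts) {
    par0 <- c(quat_from_rotmat(s$R), s$t)
    fit <- stats::optim(par0, fn, gr, method = "BFGS",
                        control = list(fnscale = -1, maxit = max_iter,
                                       reltol = reltol))
    if (fit$convergence == 1) converged <- FALSE
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  v_ab <- best$value
  v_aa <- self_overlap_volume(gA)
  v_bb <- self_overlap_volume(gB)
  # the optimum can exceed the analytic ST range only by floating error
  v_ab <- min(v_ab, v_aa + v_bb - 1e-9)
  structure(
    list(v_ab = v_ab, st = st_from_volumes(v_aa, v_bb, v_ab),
         transform = rigid_transform(rotmat_from_quat(best$par[1:4]),
                                     best$par[5:7]),
         n_starts = length(starts), converged = converged),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> ST=%.4f V_AB=%.2f A^3 (%d starts%s)\n",
              x$st, x$v_ab, x$n_starts,
              if (x$converged) "" else ", iteration cap hit"))
  invisible(x)
}

#' Shape Tanimoto between two conformers
#'
#' Convenience wrapper: builds the Gaussian sets and runs
#' [optimize_superposition()].
#'
#' @param confA,confB [conformer()] objects.
#' @param radii A [radius_table()].
#' @param ... Passed to [optimize_superposition()].
#' @return An `overlap_result`.
#' @export
shape_tanimoto <- function(confA, confB, radii = radius_table(), ...) {
  optimize_superposition(build_gaussians(confA, radii),
                         build_gaussians(confB, radii), ...)
}
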
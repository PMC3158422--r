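#' Conformer objects
#'
#' A conformer is one rigid 3-D arrangement of atoms: element symbols plus
#' Cartesian coordinates in Angstrom. The shape model is a heavy-atom model by
#' default, so hydrogens are dropped unless `include_hydrogens = TRUE`; the
#' hydrogen policy is applied at construction time.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param id Record identifier (coerced to character).
#' @param bonds Optional integer matrix (two columns, 1-based atom indices)
#'   kept only so the conformer can be written back to SDF; bonds play no role
#'   in the shape model.
#' @param include_hydrogens Keep hydrogen atoms (`FALSE` by default).
#' @return An object of class `conformer`.
#' @examples
#' conf <- conformer(c("C", "O"), rbind(c(0, 0, 0), c(1.4, 0, 0)), id = "co")
#' conf
#' @export
conformer <- function(elements, coords, id = "conf", bonds = NULL,
                      include_hydrogens = FALSE) {
  coords <- as.matrix(coords)
  if (is.vector(elements)) elements <- as.character(elements)
  if (ncol(coords) != 3L || nrow(coords) != length(elements)) {
    stop("`coords` must be an n x 3 matrix matching `elements`",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  if (!include_hydrogens) {
    keep <- elements != "H"
    if (!is.null(bonds) && !all(keep)) {
      idx <- which(keep)
      remap <- match(seq_along(elements), idx)
      b <- bonds[keep[bonds[, 1]] & keep[bonds[, 2]], , drop = FALSE]
      bonds <- cbind(remap[b[, 1]], remap[b[, 2]])
    }
    elements <- elements[keep]
    coords <- coords[keep, , drop = FALSE]
  }
  if (length(elements) < 1L) {
    stop("conformer has no atoms after applying the hydrogen policy",
         call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(id = as.character(id), elements = elements, coords = coords,
         bonds = bonds, include_hydrogens = include_hydrogens),
    class = "conformer"
  )
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> id=", x$id, ", ", length(x$elements), " atoms (",
      paste(names(sort(table(x$elements), decreasing = TRUE)),
            collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to a conformer
#'
#' @param conf A `conformer`.
#' @param transform A `rigid_transform` (see [rigid_transform()]).
#' @return A new conformer with transformed coordinates.
#' @export
transform_conformer <- function(conf, transform) {
  stopifnot(inherits(conf, "conformer"), inherits(transform, "rigid_transform"))
  out <- conf
  out$coords <- apply_transform(transform, conf$coords)
  out
}
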
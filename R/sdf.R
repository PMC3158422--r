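#' Read conformers from an SDF (V2000) file
#'
#' One conformer per record, 3-D coordinates. Parsing is delegated to
#' ChemmineR; elements, coordinates and bond indices are lifted out of its
#' atom/bond blocks. Record ids come from the title line by default or
#' from a named SDF data property.
#'
#' @param path SDF file path.
#' @param id_property `NULL` to use the title line, or the name of an SDF
#'   data field holding the record id.
#' @param include_hydrogens Keep hydrogens (default drops them, matching
#'   the heavy-atom shape model).
#' @param skip_2d Skip records whose z coordinates are all zero (flat,
#'   i.e. 2-D depictions) with a warning instead of keeping them.
#' @return List of [conformer()] objects; attribute `n_skipped` counts the
#'   records dropped by the 2-D check.
#' @export
read_sdf <- function(path, id_property = NULL, include_hydrogens = FALSE,
                     skip_2d = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdf)
  if (any(!ok)) {
    stop("unparseable SDF record(s) at index: ",
         paste(utils::head(which(!ok), 10), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  skipped <- 0L
  for (i in seq_along(ChemmineR::cid(sdf))) {
    rec <- sdf[[i]]
    ab <- ChemmineR::atomblock(rec)
    coords <- unname(ab[, 1:3, drop = FALSE])
    elements <- sub("_\\d+$", "", rownames(ab))
    if (skip_2d && all(coords[, 3] == 0)) {
      skipped <- skipped + 1L
      next
    }
    bb <- ChemmineR::bondblock(rec)
    bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
      unname(cbind(as.integer(bb[, 1]), as.integer(bb[, 2])))
    }
    id <- if (is.null(id_property)) {
      ChemmineR::sdfid(rec)
    } else {
      val <- ChemmineR::datablock(rec)[[id_property]]
      if (is.null(val) || is.na(val)) {
        stop("record ", i, " has no SDF property '", id_property, "'",
             call. = FALSE)
      }
      val
    }
    out[[length(out) + 1L]] <- conformer(
      elements, coords, id = id, bonds = bonds,
      include_hydrogens = include_hydrogens)
  }
  if (skipped > 0) {
    warning(skipped, " record(s) without 3-D coordinates skipped",
            call. = FALSE)
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write conformers to an SDF (V2000) file
#'
#' Minimal molfile records: title line carries the conformer id, atom
#' block holds the 3-D coordinates, and the recorded bond list (if any) is
#' written as single bonds.
#'
#' @param conformers A [conformer()] or list of them.
#' @param path Output path.
#' @export
write_sdf <- function(conformers, path) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformers) {
    n <- nrow(cf$coords)
    nb <- if (is.null(cf$bonds)) 0L else nrow(cf$bonds)
    writeLines(c(
      cf$id, "  shapequad", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              cf$coords[, 1], cf$coords[, 2], cf$coords[, 3],
              cf$elements),
      if (nb > 0) sprintf("%3d%3d  1  0", cf$bonds[, 1], cf$bonds[, 2]),
      "M  END", "$$$$"
    ), con)
  }
  invisible(path)
}
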
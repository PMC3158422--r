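#' Van der Waals radius tables
#'
#' A radius table maps element symbols to van der Waals radii in Angstrom and
#' carries a default radius applied to elements not listed. The built-in table
#' uses the Bondi radii for the elements common in drug-like molecules; any
#' element absent from the table falls back to the default (1.70 A, the carbon
#' radius) unless the default is disabled.
#'
#' @param radii Named numeric vector of radii in Angstrom (names are element
#'   symbols). Values supplied here override or extend the Bondi defaults.
#' @param default Fallback radius in Angstrom for elements not in the table,
#'   or `NA` to make unknown elements an error.
#' @return An object of class `radius_table`.
#' @examples
#' rt <- radius_table()
#' atom_radius(rt, c("C", "O", "S"))
#' @export
radius_table <- function(radii = NULL, default = 1.70) {
  base <- c(
    H = 1.20, He = 1.40, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
    As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98,
    Xe = 2.16
  )
  if (!is.null(radii)) {
    if (is.null(names(radii)) || any(names(radii) == "")) {
      stop("`radii` must be a fully named numeric vector", call. = FALSE)
    }
    if (any(!is.finite(radii)) || any(radii <= 0)) {
      stop("all radii must be finite and > 0", call. = FALSE)
    }
    base[names(radii)] <- radii
  }
  if (!is.na(default) && default <= 0) {
    stop("`default` radius must be > 0", call. = FALSE)
  }
  structure(list(radii = base, default = default), class = "radius_table")
}

#' @rdname radius_table
#' @param table A `radius_table`.
#' @param elements Character vector of element symbols.
#' @export
atom_radius <- function(table, elements) {
  stopifnot(inherits(table, "radius_table"))
  r <- unname(table$radii[elements])
  missing <- is.na(r)
  if (any(missing)) {
    if (is.na(table$default)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(elements[missing]), collapse = ", "),
           call. = FALSE)
    }
    r[missing] <- table$default
  }
  r
}

#' @export
print.radius_table <- function(x, ...) {
  cat("<radius_table> ", length(x$radii), " elements, default ",
      if (is.na(x$default)) "none (strict)" else paste0(x$default, " A"),
      "\n", sep = "")
  invisible(x)
}
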
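#' Read and write quadrupole filter files
#'
#' Filters are stored one component per file in a plain TSV format
#' (`qfilter-1`): `#`-prefixed metadata lines (`format`, `volume_type`,
#' `component`, `st_threshold`, `vol_binsize`, `q_binsize`, `rounding`),
#' a header row, then `v1bin v2bin dqmin dqmax` rows sorted by
#' `(v1bin, v2bin)`. Writing a filter read from a file reproduces the file
#' byte-for-byte.
#'
#' @param filter A `quad_filter`.
#' @param path File path.
#' @return `write_filter` returns the path invisibly; `read_filter`
#'   returns a `quad_filter`.
#' @export
write_filter <- function(filter, path) {
  stopifnot(inherits(filter, "quad_filter"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    "#format qfilter-1",
    paste("#volume_type", attr(filter, "volume_type")),
    paste("#component", attr(filter, "component")),
    paste("#st_threshold", as.character(attr(filter, "st_threshold"))),
    paste("#vol_binsize", as.character(attr(filter, "vol_binsize"))),
    paste("#q_binsize", as.character(attr(filter, "q_binsize"))),
    "#rounding floor",
    "v1bin\tv2bin\tdqmin\tdqmax"
  )
  writeLines(meta, con)
  writeLines(sprintf("%d\t%d\t%d\t%d", filter$v1, filter$v2,
                     filter$dqmin, filter$dqmax), con)
  invisible(path)
}

#' @rdname write_filter
#' @export
read_filter <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^#", "", ln), " ", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- paste(parts[-1], collapse = " ")
  }
  if (!identical(meta$format, "qfilter-1")) {
    stop("not a qfilter-1 file: ", path, call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  tbl <- utils::read.table(text = body, header = TRUE, sep = "\t")
  names(tbl) <- c("v1", "v2", "dqmin", "dqmax")
  cfg <- bin_config(
    vol_binsize = as.numeric(meta$vol_binsize),
    q_binsize = stats::setNames(rep(as.numeric(meta$q_binsize), 3),
                                c("x", "y", "z")),
    volume_type = meta$volume_type,
    st_threshold = as.numeric(meta$st_threshold)
  )
  f <- quad_filter(tbl, component = meta$component, cfg = cfg)
  f
}

#' Read and write a three-component filter set
#'
#' Writes `<prefix>_x.tsv`, `<prefix>_y.tsv` and `<prefix>_z.tsv`.
#'
#' @param fs A `filter_set`.
#' @param prefix Path prefix for the three component files.
#' @export
write_filter_set <- function(fs, prefix) {
  stopifnot(inherits(fs, "filter_set"))
  paths <- stats::setNames(paste0(prefix, "_", c("x", "y", "z"), ".tsv"),
                           c("x", "y", "z"))
  for (comp in c("x", "y", "z")) write_filter(fs[[comp]], paths[[comp]])
  invisible(paths)
}

#' @rdname write_filter_set
#' @export
read_filter_set <- function(prefix) {
  paths <- paste0(prefix, "_", c("x", "y", "z"), ".tsv")
  if (!all(file.exists(paths))) {
    stop("missing filter file(s): ",
         paste(paths[!file.exists(paths)], collapse = ", "), call. = FALSE)
  }
  members <- lapply(paths, read_filter)
  names(members) <- c("x", "y", "z")
  comps <- vapply(members, attr, "", "component")
  if (!identical(unname(comps), c("x", "y", "z"))) {
    stop("filter files have unexpected components: ",
         paste(comps, collapse = ", "), call. = FALSE)
  }
  vt <- unique(vapply(members, attr, "", "volume_type"))
  st <- unique(vapply(members, attr, 0, "st_threshold"))
  vb <- unique(vapply(members, attr, 0, "vol_binsize"))
  if (length(vt) != 1 || length(st) != 1 || length(vb) != 1) {
    stop("filter files disagree on volume type / threshold / bin size",
         call. = FALSE)
  }
  cfg <- bin_config(
    vol_binsize = vb,
    q_binsize = c(x = attr(members$x, "q_binsize"),
                  y = attr(members$y, "q_binsize"),
                  z = attr(members$z, "q_binsize")),
    volume_type = vt, st_threshold = st
  )
  # single-file reads only know their own component's bin size; the full
  # triple is reconstructed here so canonical ordering is exact
  for (comp in c("x", "y", "z")) attr(members[[comp]], "config") <- cfg
  structure(list(x = members$x, y = members$y, z = members$z,
                 config = cfg, n_training_pairs = NA_integer_),
            class = "filter_set")
}

#' Read and write labeled pair tables
#'
#' TSV with header `id1 id2 st` (the `st` column is optional on read).
#'
#' @param pairs Data frame with columns `id1`, `id2` and optionally `st`.
#' @param path File path.
#' @export
write_pair_table <- function(pairs, path) {
  out <- pairs
  if ("st" %in% names(out)) out$st <- formatC(out$st, digits = 6,
                                              format = "f")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(id1 = "character",
                                         id2 = "character"))
  if (!all(c("id1", "id2") %in% names(df))) {
    stop("pair table must have columns id1, id2", call. = FALSE)
  }
  df
}
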
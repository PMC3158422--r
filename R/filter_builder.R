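#' Bin configuration for quadrupole filters
#'
#' Volumes and quadrupole components are discretized by integer truncation,
#' `floor(value / binsize)`. Defaults follow the production filter setup:
#' 5.0 (volume, all three types) and 2.5 / 0.5 / 0.1 for the Qx / Qy / Qz
#' components; these ratios track the components' spreads (Qx varies the
#' most, Qz the least).
#'
#' @param vol_binsize Volume bin size (A^3).
#' @param q_binsize Named vector `c(x=, y=, z=)` of quadrupole bin sizes.
#' @param volume_type Which volume the filter keys on: `"mp"` (monopole,
#'   default), `"an"` (analytic) or `"so"` (self-overlap).
#' @param st_threshold Shape-Tanimoto threshold defining "neighbor" pairs,
#'   in (0, 1].
#' @return An object of class `bin_config`.
#' @export
bin_config <- function(vol_binsize = 5.0,
                       q_binsize = c(x = 2.5, y = 0.5, z = 0.1),
                       volume_type = c("mp", "an", "so"),
                       st_threshold = 0.80) {
  volume_type <- match.arg(volume_type)
  if (vol_binsize <= 0 || any(q_binsize <= 0)) {
    stop("all bin sizes must be > 0", call. = FALSE)
  }
  if (!all(c("x", "y", "z") %in% names(q_binsize))) {
    stop("`q_binsize` must have names x, y, z", call. = FALSE)
  }
  if (st_threshold <= 0 || st_threshold > 1) {
    stop("`st_threshold` must be in (0, 1]", call. = FALSE)
  }
  structure(list(vol_binsize = vol_binsize,
                 q_binsize = q_binsize[c("x", "y", "z")],
                 volume_type = volume_type, st_threshold = st_threshold),
            class = "bin_config")
}

#' Integer binning
#'
#' `to_bin(v, s)` = `floor(v / s)`: non-negative values map to non-negative
#' integer bin indices, with the bin boundary belonging to the upper bin
#' (`to_bin(2.5, 2.5) == 1`).
#'
#' @param value Non-negative numeric vector.
#' @param binsize Positive bin width.
#' @return Integer vector of bin indices.
#' @export
to_bin <- function(value, binsize) {
  if (binsize <= 0) stop("`binsize` must be > 0", call. = FALSE)
  if (any(value < 0)) stop("cannot bin negative values", call. = FALSE)
  as.integer(floor(value / binsize))
}

#' Bin a descriptor table
#'
#' Applies [to_bin()] to the configured volume type and the three
#' quadrupole components of a descriptor table.
#'
#' @param desc Descriptor data frame ([descriptor_table()]) or a single
#'   `shape_descriptors` object.
#' @param cfg A [bin_config()].
#' @return Data frame `id, v_bin, qx_bin, qy_bin, qz_bin`.
#' @export
bin_descriptors <- function(desc, cfg) {
  stopifnot(inherits(cfg, "bin_config"))
  if (inherits(desc, "shape_descriptors")) {
    desc <- data.frame(id = desc$id, v_an = desc$v_an, v_mp = desc$v_mp,
                       v_so = desc$v_so, qx = desc$qx, qy = desc$qy,
                       qz = desc$qz, stringsAsFactors = FALSE)
  }
  vol <- desc[[paste0("v_", cfg$volume_type)]]
  data.frame(
    id = desc$id,
    v_bin = to_bin(vol, cfg$vol_binsize),
    qx_bin = to_bin(desc$qx, cfg$q_binsize[["x"]]),
    qy_bin = to_bin(desc$qy, cfg$q_binsize[["y"]]),
    qz_bin = to_bin(desc$qz, cfg$q_binsize[["z"]]),
    stringsAsFactors = FALSE
  )
}

# Vectorized canonical-ordering test: TRUE where the (b) member should be
# molecule 1, i.e. b precedes a lexicographically on
# (v_bin, qx_bin, qy_bin, qz_bin); exact ties keep input order.
pair_needs_swap <- function(a, b) {
  lt <- function(x, y) x < y
  swap <- lt(b$v_bin, a$v_bin)
  tie <- b$v_bin == a$v_bin
  swap <- swap | (tie & lt(b$qx_bin, a$qx_bin))
  tie <- tie & b$qx_bin == a$qx_bin
  swap <- swap | (tie & lt(b$qy_bin, a$qy_bin))
  tie <- tie & b$qy_bin == a$qy_bin
  swap <- swap | (tie & lt(b$qz_bin, a$qz_bin))
  swap
}

#' Canonical ordering of a binned pair
#'
#' The member with the smaller binned volume becomes molecule 1; volume
#' ties fall through to the smaller binned Qx, then Qy, then Qz, and a full
#' tie preserves the input order. Filter construction and lookup both use
#' this ordering, so swapping the two inputs never changes a filter.
#'
#' @param a,b Single rows (lists or one-row data frames) with fields
#'   `v_bin`, `qx_bin`, `qy_bin`, `qz_bin`.
#' @return List with `mol1`, `mol2` and the logical `swapped`.
#' @export
order_pair <- function(a, b) {
  swap <- pair_needs_swap(as.data.frame(a), as.data.frame(b))
  if (swap) list(mol1 = b, mol2 = a, swapped = TRUE)
  else list(mol1 = a, mol2 = b, swapped = FALSE)
}

#' Accumulate a raw quadrupole-difference map
#'
#' Canonically orders each binned pair and tallies the signed quadrupole
#' bin difference `dq = Q_bin(mol2) - Q_bin(mol1)` of one component under
#' the key `(v1_bin, v2_bin)` (molecule 1 has the smaller volume bin, so
#' `v1 <= v2` for every key).
#'
#' @param pairs Either a list of two-element lists of binned descriptor
#'   rows, or a data frame with columns `v_bin1, qx_bin1, ..., v_bin2,
#'   qx_bin2, ...`.
#' @param component `"x"`, `"y"` or `"z"`.
#' @return A `raw_delta_map`: data frame `v1, v2, dq, n` with attribute
#'   `component`.
#' @export
accumulate <- function(pairs, component = c("x", "y", "z")) {
  component <- match.arg(component)
  if (is.data.frame(pairs)) {
    cols <- c("v_bin", "qx_bin", "qy_bin", "qz_bin")
    a <- stats::setNames(pairs[paste0(cols, "1")], cols)
    b <- stats::setNames(pairs[paste0(cols, "2")], cols)
  } else {
    grab <- function(k) do.call(rbind, lapply(pairs, function(p)
      as.data.frame(p[[k]])))
    a <- grab(1); b <- grab(2)
  }
  swap <- pair_needs_swap(a, b)
  m1 <- a; m2 <- b
  m1[swap, ] <- b[swap, ]
  m2[swap, ] <- a[swap, ]
  qcol <- paste0("q", component, "_bin")
  df <- data.frame(v1 = m1$v_bin, v2 = m2$v_bin,
                   dq = m2[[qcol]] - m1[[qcol]])
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))), df, sum)
  agg <- agg[order(agg$v1, agg$v2, agg$dq), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, component = component, class = c("raw_delta_map",
                                                  "data.frame"))
}

# Row/column closure of a sparse set of (v1, v2) keys, iterated to a fixed
# point: for each v1 all v2 between the populated min and max are added,
# then likewise for each v2 over v1, until nothing changes. Input and
# output are two-column integer matrices with v1 <= v2.
close_region <- function(keys) {
  repeat {
    n0 <- nrow(keys)
    filled <- lapply(split(keys[, 2], keys[, 1]), function(v2s)
      seq(min(v2s), max(v2s)))
    keys <- cbind(
      rep(as.integer(names(filled)), lengths(filled)),
      unlist(filled, use.names = FALSE))
    filled <- lapply(split(keys[, 1], keys[, 2]), function(v1s)
      seq(min(v1s), max(v1s)))
    keys <- cbind(
      unlist(filled, use.names = FALSE),
      rep(as.integer(names(filled)), lengths(filled)))
    keys <- unique(keys)
    if (nrow(keys) == n0) return(keys)
  }
}

# One fill branch. obs: data frame (v1, v2, dq) restricted to the branch;
# levels are processed from the extreme toward zero, the region is
# cumulative across levels, and each level's region is closed row- and
# column-wise. Returns data frame (v1, v2, level) with each key's extreme
# level for this branch.
fill_branch <- function(obs, negative = FALSE) {
  if (nrow(obs) == 0) {
    return(data.frame(v1 = integer(), v2 = integer(), level = integer()))
  }
  levels <- sort(unique(obs$dq), decreasing = !negative)
  region <- matrix(integer(), 0, 2)
  entry <- new.env(parent = emptyenv())
  for (L in levels) {
    new_keys <- obs[obs$dq == L, c("v1", "v2"), drop = FALSE]
    region <- unique(rbind(region, as.matrix(new_keys)))
    region <- close_region(region)
    ks <- paste(region[, 1], region[, 2])
    for (i in which(!vapply(ks, exists, logical(1), envir = entry))) {
      assign(ks[i], L, envir = entry)
    }
  }
  ks <- ls(entry)
  parts <- do.call(rbind, strsplit(ks, " ", fixed = TRUE))
  data.frame(v1 = as.integer(parts[, 1]), v2 = as.integer(parts[, 2]),
             level = vapply(ks, get, numeric(1), envir = entry),
             row.names = NULL)
}

#' Turn a raw difference map into a quadrupole filter (fringe fill)
#'
#' A raw map sampled from a finite corpus has ragged fringes: at a given
#' quadrupole difference, not every volume-bin key between the populated
#' extremes of a row or column has been observed, yet such keys could well
#' be occupied by future neighbor pairs. The fill therefore processes the
#' unique difference levels from the extreme toward zero, separately for
#' the positive and the negative branch; at each level the region populated
#' at this or any more extreme level of the branch is closed row-wise (for
#' each `v1`, every `v2` between the populated minimum and maximum) and
#' column-wise (likewise per `v2`), iterating the two passes to a fixed
#' point. Each key's allowed difference range `[dq_min, dq_max]` is the
#' span of levels at which it is present. The result is a superset of the
#' raw map and the operation is idempotent.
#'
#' @param raw A `raw_delta_map` from [accumulate()].
#' @param cfg Optional [bin_config()] whose metadata (volume type,
#'   threshold, bin sizes) is stamped onto the filter.
#' @return A `quad_filter`: data frame `v1, v2, dqmin, dqmax` plus
#'   metadata attributes.
#' @export
fill_map <- function(raw, cfg = NULL) {
  if (!inherits(raw, "raw_delta_map")) {
    stop("`raw` must be a raw_delta_map", call. = FALSE)
  }
  if (nrow(raw) == 0) stop("cannot fill an empty map", call. = FALSE)
  if (any(raw$v1 > raw$v2)) {
    stop("raw map violates canonical ordering (v1 <= v2)", call. = FALSE)
  }
  component <- attr(raw, "component")

  pos <- fill_branch(raw[raw$dq >= 0, , drop = FALSE], negative = FALSE)
  neg <- fill_branch(raw[raw$dq <= 0, , drop = FALSE], negative = TRUE)

  key <- function(df) paste(df$v1, df$v2)
  all_keys <- unique(rbind(pos[c("v1", "v2")], neg[c("v1", "v2")]))
  kp <- match(key(all_keys), key(pos))
  kn <- match(key(all_keys), key(neg))
  # keys seen in only one branch span that branch's levels closest to zero
  max_neg <- if (nrow(neg)) max(neg$level) else NA_integer_
  min_pos <- if (nrow(pos)) min(pos$level) else NA_integer_
  dqmax <- ifelse(is.na(kp), max_neg, pos$level[kp])
  dqmin <- ifelse(is.na(kn), min_pos, neg$level[kn])

  tbl <- data.frame(v1 = all_keys$v1, v2 = all_keys$v2,
                    dqmin = as.integer(dqmin), dqmax = as.integer(dqmax))
  tbl <- tbl[order(tbl$v1, tbl$v2), , drop = FALSE]
  rownames(tbl) <- NULL
  quad_filter(tbl, component = component, cfg = cfg)
}

#' @rdname fill_map
#' @param table Data frame `v1, v2, dqmin, dqmax`.
#' @param component Quadrupole component `"x"`, `"y"` or `"z"`.
#' @export
quad_filter <- function(table, component, cfg = NULL) {
  stopifnot(all(c("v1", "v2", "dqmin", "dqmax") %in% names(table)))
  if (any(table$dqmin > table$dqmax)) {
    stop("filter has dqmin > dqmax", call. = FALSE)
  }
  if (any(table$v1 > table$v2)) {
    stop("filter violates canonical ordering (v1 <= v2)", call. = FALSE)
  }
  meta <- if (is.null(cfg)) {
    list(volume_type = NA_character_, st_threshold = NA_real_,
         vol_binsize = NA_real_, q_binsize = NA_real_)
  } else {
    list(volume_type = cfg$volume_type, st_threshold = cfg$st_threshold,
         vol_binsize = cfg$vol_binsize,
         q_binsize = unname(cfg$q_binsize[[component]]))
  }
  structure(table[c("v1", "v2", "dqmin", "dqmax")],
            component = component, volume_type = meta$volume_type,
            st_threshold = meta$st_threshold,
            vol_binsize = meta$vol_binsize, q_binsize = meta$q_binsize,
            rounding = "floor", config = cfg,
            class = c("quad_filter", "data.frame"))
}

#' @export
as.data.frame.raw_delta_map <- function(x, ...) {
  data.frame(v1 = x$v1, v2 = x$v2, dq = x$dq, n = x$n)
}

#' @export
as.data.frame.quad_filter <- function(x, ...) {
  data.frame(v1 = x$v1, v2 = x$v2, dqmin = x$dqmin, dqmax = x$dqmax)
}

#' @export
print.quad_filter <- function(x, ...) {
  cat(sprintf(
    "<quad_filter> Q%s on V_%s, ST>=%s: %d volume-bin keys\n",
    attr(x, "component"), attr(x, "volume_type"),
    format(attr(x, "st_threshold")), nrow(x)))
  invisible(x)
}

#' Build the three-component filter set from a labeled pair corpus
#'
#' Restricts the corpus to neighbor pairs (`st >= cfg$st_threshold`), bins
#' the descriptors of both members, canonically orders each pair, and runs
#' [accumulate()] and [fill_map()] for each quadrupole component.
#'
#' @param pairs Data frame `id1, id2, st`.
#' @param desc Descriptor table covering every id in `pairs`.
#' @param cfg A [bin_config()].
#' @return A `filter_set`: list with members `x`, `y`, `z` sharing the
#'   volume type and threshold.
#' @export
build_filter_set <- function(pairs, desc, cfg = bin_config()) {
  stopifnot(is.data.frame(pairs), is.data.frame(desc),
            inherits(cfg, "bin_config"))
  if (!all(c("id1", "id2", "st") %in% names(pairs))) {
    stop("`pairs` must have columns id1, id2, st", call. = FALSE)
  }
  miss <- setdiff(unique(c(pairs$id1, pairs$id2)), desc$id)
  if (length(miss) > 0) {
    stop("descriptor table is missing id(s): ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }
  keep <- pairs$st >= cfg$st_threshold
  if (!any(keep)) {
    stop("no pairs at or above ST threshold ", cfg$st_threshold,
         call. = FALSE)
  }
  pairs <- pairs[keep, , drop = FALSE]
  binned <- bin_descriptors(desc, cfg)
  i1 <- match(pairs$id1, binned$id)
  i2 <- match(pairs$id2, binned$id)
  cols <- c("v_bin", "qx_bin", "qy_bin", "qz_bin")
  pb <- cbind(stats::setNames(binned[i1, cols], paste0(cols, "1")),
              stats::setNames(binned[i2, cols], paste0(cols, "2")))
  fs <- lapply(c(x = "x", y = "y", z = "z"), function(comp)
    fill_map(accumulate(pb, comp), cfg = cfg))
  structure(list(x = fs$x, y = fs$y, z = fs$z, config = cfg,
                 n_training_pairs = nrow(pairs)),
            class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf(
    "<filter_set> V_%s, ST>=%s (built from %d neighbor pairs)\n",
    x$config$volume_type, format(x$config$st_threshold),
    x$n_training_pairs))
  for (comp in c("x", "y", "z")) {
    cat("  "); print(x[[comp]])
  }
  invisible(x)
}
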
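#' Filter verdicts
#'
#' The outcome of applying a quadrupole filter (or the cascade) to one
#' conformer pair: whether it passed, which stage rejected it (`"none"`,
#' `"x"`, `"y"`, `"z"` or `"volume_bound"`), and whether the volume-bin key
#' was present in every filter consulted.
#'
#' @param passed Logical.
#' @param rejected_by Rejection stage.
#' @param key_found Logical.
#' @return An object of class `filter_verdict`.
#' @export
filter_verdict <- function(passed, rejected_by = "none", key_found = TRUE) {
  stopifnot(identical(passed, rejected_by == "none"))
  structure(list(passed = passed, rejected_by = rejected_by,
                 key_found = key_found), class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat("<filter_verdict> ", if (x$passed) "pass" else
    paste0("reject (", x$rejected_by, ")"),
    if (!x$key_found) " [unknown key]", "\n", sep = "")
  invisible(x)
}

filter_config <- function(f) {
  cfg <- attr(f, "config")
  if (is.null(cfg)) {
    stop("filter carries no bin configuration", call. = FALSE)
  }
  cfg
}

as_desc_row <- function(d) {
  if (inherits(d, "shape_descriptors")) {
    data.frame(id = d$id, v_an = d$v_an, v_mp = d$v_mp, v_so = d$v_so,
               qx = d$qx, qy = d$qy, qz = d$qz, stringsAsFactors = FALSE)
  } else {
    as.data.frame(d)
  }
}

#' Apply one quadrupole filter to a conformer pair
#'
#' Bins both descriptor sets, orders the pair canonically, and looks up the
#' `(v1_bin, v2_bin)` key. If the key is present the pair passes iff the
#' signed quadrupole bin difference lies within the filter's allowed range.
#' Keys never seen in training follow the unknown-key policy: `"pass"`
#' (default; the filter only rejects pairs it has evidence against) or
#' `"reject"` (strict mode for efficiency experiments).
#'
#' @param f A `quad_filter`.
#' @param a,b `shape_descriptors` (or descriptor-table rows).
#' @param unknown_key `"pass"` or `"reject"`.
#' @param cfg Optional [bin_config()] describing the caller's expectation;
#'   an inconsistency with the filter's own configuration is an error.
#' @return A [filter_verdict()].
#' @export
apply_single <- function(f, a, b, unknown_key = c("pass", "reject"),
                         cfg = NULL) {
  stopifnot(inherits(f, "quad_filter"))
  unknown_key <- match.arg(unknown_key)
  fcfg <- filter_config(f)
  if (!is.null(cfg) && !isTRUE(all.equal(unclass(cfg), unclass(fcfg)))) {
    stop("bin configuration mismatch between filter and request",
         call. = FALSE)
  }
  comp <- attr(f, "component")
  ba <- bin_descriptors(as_desc_row(a), fcfg)
  bb <- bin_descriptors(as_desc_row(b), fcfg)
  op <- order_pair(ba, bb)
  hit <- which(f$v1 == op$mol1$v_bin & f$v2 == op$mol2$v_bin)
  qcol <- paste0("q", comp, "_bin")
  if (length(hit) == 0) {
    if (unknown_key == "pass") {
      filter_verdict(TRUE, "none", key_found = FALSE)
    } else {
      filter_verdict(FALSE, comp, key_found = FALSE)
    }
  } else {
    dq <- op$mol2[[qcol]] - op$mol1[[qcol]]
    ok <- dq >= f$dqmin[hit] && dq <= f$dqmax[hit]
    filter_verdict(ok, if (ok) "none" else comp, key_found = TRUE)
  }
}

#' Apply the quadrupole filter cascade to a conformer pair
#'
#' Optionally checks the volume-only ST bound first, then applies the x, y
#' and z filters in order, short-circuiting at the first rejection. The
#' rejection set of the cascade equals the union of the member filters'
#' rejection sets (plus the volume bound when enabled).
#'
#' @param fs A `filter_set`.
#' @param a,b `shape_descriptors` (or descriptor-table rows).
#' @param use_volume_bound Apply [st_volume_bound()] on the self-overlap
#'   volumes before the quadrupole filters.
#' @param unknown_key Unknown-key policy, see [apply_single()].
#' @return A [filter_verdict()]; `key_found` is TRUE iff every filter
#'   consulted before the decision had the pair's volume-bin key.
#' @export
apply_cascade <- function(fs, a, b, use_volume_bound = FALSE,
                          unknown_key = c("pass", "reject")) {
  stopifnot(inherits(fs, "filter_set"))
  unknown_key <- match.arg(unknown_key)
  if (use_volume_bound) {
    ra <- as_desc_row(a); rb <- as_desc_row(b)
    if (st_volume_bound(ra$v_so, rb$v_so) < fs$config$st_threshold) {
      return(filter_verdict(FALSE, "volume_bound", key_found = TRUE))
    }
  }
  key_found <- TRUE
  for (comp in c("x", "y", "z")) {
    v <- apply_single(fs[[comp]], a, b, unknown_key = unknown_key)
    key_found <- key_found && v$key_found
    if (!v$passed) {
      return(filter_verdict(FALSE, comp, key_found = key_found))
    }
  }
  filter_verdict(TRUE, "none", key_found = key_found)
}

# Vectorized pass/fail of every member filter over a pair table.
# Returns a data frame with pass_x/y/z, found_x/y/z and (optionally)
# pass_bound, plus the cascade columns derived with x -> y -> z ordering.
screen_pairs <- function(fs, pairs, desc, use_volume_bound = FALSE,
                         unknown_key = "pass") {
  cfg <- fs$config
  miss <- setdiff(unique(c(pairs$id1, pairs$id2)), desc$id)
  if (length(miss) > 0) {
    stop("descriptor table is missing id(s): ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }
  binned <- bin_descriptors(desc, cfg)
  i1 <- match(pairs$id1, binned$id)
  i2 <- match(pairs$id2, binned$id)
  a <- binned[i1, , drop = FALSE]
  b <- binned[i2, , drop = FALSE]
  swap <- pair_needs_swap(a, b)
  m1 <- a; m2 <- b
  m1[swap, ] <- b[swap, ]
  m2[swap, ] <- a[swap, ]

  out <- data.frame(id1 = pairs$id1, id2 = pairs$id2,
                    stringsAsFactors = FALSE)
  for (comp in c("x", "y", "z")) {
    f <- fs[[comp]]
    hit <- match(paste(m1$v_bin, m2$v_bin), paste(f$v1, f$v2))
    qcol <- paste0("q", comp, "_bin")
    dq <- m2[[qcol]] - m1[[qcol]]
    found <- !is.na(hit)
    pass <- ifelse(found, dq >= f$dqmin[hit] & dq <= f$dqmax[hit],
                   unknown_key == "pass")
    out[[paste0("pass_", comp)]] <- pass
    out[[paste0("found_", comp)]] <- found
  }
  if (use_volume_bound) {
    vcol <- "v_so"
    j1 <- match(pairs$id1, desc$id)
    j2 <- match(pairs$id2, desc$id)
    out$pass_bound <- st_volume_bound(desc[[vcol]][j1], desc[[vcol]][j2]) >=
      cfg$st_threshold
  } else {
    out$pass_bound <- TRUE
  }
  out$passed <- out$pass_bound & out$pass_x & out$pass_y & out$pass_z
  out$rejected_by <- ifelse(!out$pass_bound, "volume_bound",
                     ifelse(!out$pass_x, "x",
                     ifelse(!out$pass_y, "y",
                     ifelse(!out$pass_z, "z", "none"))))
  out
}

#' Confusion matrix of a filter against ST ground truth
#'
#' Classifies each pair by the filter verdict crossed with the true
#' neighbor status (`st >= st_threshold`): TP = passed true neighbors,
#' FP = passed non-neighbors, FN = rejected true neighbors (the cost the
#' filters are designed to keep negligible), TN = rejected non-neighbors
#' (the saving).
#'
#' @param passed Logical vector of filter verdicts.
#' @param st Numeric vector of ground-truth ST values.
#' @param st_threshold Neighbor threshold.
#' @return An object of class `confusion_matrix` with counts, percentages
#'   and the threshold.
#' @export
confusion_matrix <- function(passed, st, st_threshold) {
  stopifnot(length(passed) == length(st))
  truth <- st >= st_threshold
  counts <- c(TP = sum(passed & truth), FP = sum(passed & !truth),
              FN = sum(!passed & truth), TN = sum(!passed & !truth))
  structure(list(counts = counts, total = length(passed),
                 percent = 100 * counts / length(passed),
                 st_threshold = st_threshold),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix at ST >= %s (n = %d)\n",
              format(x$st_threshold), x$total))
  for (k in c("TP", "FP", "FN", "TN")) {
    cat(sprintf("  %s  %8d  (%.1f%%)\n", k, x$counts[[k]],
                x$percent[[k]]))
  }
  invisible(x)
}

#' Evaluate a filter set against a labeled pair corpus
#'
#' Applies each member filter on its own and the x/y/z cascade to every
#' labeled pair and tabulates confusion matrices against the ST labels.
#'
#' @param fs A `filter_set`.
#' @param pairs Data frame `id1, id2, st` (labels mandatory).
#' @param desc Descriptor table covering all ids.
#' @param st_threshold Neighbor threshold (defaults to the filter set's
#'   training threshold).
#' @param use_volume_bound Include the volume-bound stage in the cascade.
#' @param unknown_key Unknown-key policy, see [apply_single()].
#' @return A `filter_evaluation`: confusion matrices `x`, `y`, `z`,
#'   `cascade`, plus the verdict table.
#' @export
evaluate_filters <- function(fs, pairs, desc,
                             st_threshold = fs$config$st_threshold,
                             use_volume_bound = FALSE,
                             unknown_key = c("pass", "reject")) {
  unknown_key <- match.arg(unknown_key)
  if (!"st" %in% names(pairs) || any(is.na(pairs$st))) {
    stop("every pair must carry an ST label", call. = FALSE)
  }
  v <- screen_pairs(fs, pairs, desc, use_volume_bound = use_volume_bound,
                    unknown_key = unknown_key)
  cms <- lapply(c(x = "x", y = "y", z = "z"), function(comp)
    confusion_matrix(v[[paste0("pass_", comp)]], pairs$st, st_threshold))
  structure(
    list(x = cms$x, y = cms$y, z = cms$z,
         cascade = confusion_matrix(v$passed, pairs$st, st_threshold),
         verdicts = v, st_threshold = st_threshold,
         unknown_key = unknown_key,
         use_volume_bound = use_volume_bound),
    class = "filter_evaluation"
  )
}

#' @export
print.filter_evaluation <- function(x, ...) {
  n <- x$cascade$total
  cat(sprintf(
    "filter evaluation: %d pairs, ST >= %s, unknown keys %s\n",
    n, format(x$st_threshold), x$unknown_key))
  cat(sprintf("%-8s %10s %10s %10s %10s\n", "filter", "TP", "FP", "FN",
              "TN"))
  for (nm in c("x", "y", "z", "cascade")) {
    cm <- x[[nm]]
    cat(sprintf("%-8s %10d %10d %10d %10d\n", paste0("Q", nm),
                cm$counts[["TP"]], cm$counts[["FP"]], cm$counts[["FN"]],
                cm$counts[["TN"]]))
    cat(sprintf("%-8s %9.1f%% %9.1f%% %9.1f%% %9.1f%%\n", "",
                cm$percent[["TP"]], cm$percent[["FP"]],
                cm$percent[["FN"]], cm$percent[["TN"]]))
  }
  invisible(x)
}

#' Sweep the ST threshold
#'
#' For each threshold, builds a filter set from the training pairs
#' restricted to that threshold and evaluates it on the test pairs at the
#' same threshold. Thresholds at which the training restriction is empty
#' are flagged rather than fatal.
#'
#' @param train_pairs,test_pairs Labeled pair data frames (`id1, id2,
#'   st`).
#' @param desc Descriptor table covering both corpora.
#' @param thresholds Numeric vector of thresholds in (0, 1].
#' @param cfg A [bin_config()] (its `st_threshold` is overridden per row).
#' @param unknown_key Unknown-key policy.
#' @return Data frame with one row per threshold and filter (`x`, `y`,
#'   `z`, `cascade`): rejected fraction `(TN + FN) / total`, FN count, and
#'   an `empty_training` flag.
#' @export
threshold_sweep <- function(train_pairs, test_pairs, desc, thresholds,
                            cfg = bin_config(),
                            unknown_key = c("pass", "reject")) {
  unknown_key <- match.arg(unknown_key)
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  rows <- list()
  for (t in thresholds) {
    cfg_t <- bin_config(cfg$vol_binsize, cfg$q_binsize, cfg$volume_type,
                        st_threshold = t)
    built <- tryCatch(build_filter_set(train_pairs, desc, cfg_t),
                      error = function(e) NULL)
    if (is.null(built)) {
      rows[[length(rows) + 1]] <- data.frame(
        st_threshold = t, filter = c("x", "y", "z", "cascade"),
        rejected_fraction = NA_real_, fn = NA_integer_,
        empty_training = TRUE)
      next
    }
    ev <- evaluate_filters(built, test_pairs, desc, st_threshold = t,
                           unknown_key = unknown_key)
    rows[[length(rows) + 1]] <- data.frame(
      st_threshold = t, filter = c("x", "y", "z", "cascade"),
      rejected_fraction = vapply(
        ev[c("x", "y", "z", "cascade")],
        function(cm) (cm$counts[["TN"]] + cm$counts[["FN"]]) / cm$total,
        numeric(1)),
      fn = vapply(ev[c("x", "y", "z", "cascade")],
                  function(cm) cm$counts[["FN"]], numeric(1)),
      empty_training = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
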
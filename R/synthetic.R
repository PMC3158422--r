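#' Default element palette for synthetic conformers
#'
#' Heavy-atom composition roughly matching drug-like organic molecules:
#' mostly carbon with nitrogen, oxygen and a sprinkling of sulfur and
#' halogens.
#'
#' @return Data frame `element, weight`.
#' @export
default_palette <- function() {
  data.frame(element = c("C", "N", "O", "S", "F", "Cl"),
             weight = c(10, 2, 2, 1, 0.5, 0.5),
             stringsAsFactors = FALSE)
}

#' Generate a random drug-like heavy-atom conformer
#'
#' Atoms are placed sequentially: each new atom sits at a bonded distance
#' (uniform in 1.3-1.6 A) from a randomly chosen existing atom, in a
#' uniformly random direction, and is rejected if it comes closer than 0.8
#' times the radius sum to any existing atom other than its bond partner
#' (hard-core clash check). The placement tree is recorded as the bond
#' list. Fully deterministic per seed.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param palette Element palette (data frame `element, weight`).
#' @param seed Integer seed (required).
#' @param radii A [radius_table()].
#' @param id Conformer id.
#' @param max_rejects Abort after this many rejected placements.
#' @return A [conformer()].
#' @export
random_conformer <- function(n_atoms, palette = default_palette(),
                             seed = NULL, radii = radius_table(),
                             id = "conf", max_rejects = 1e4) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  if (n_atoms < 1) stop("`n_atoms` must be >= 1", call. = FALSE)
  elements <- with_rng(rng, sample(palette$element, n_atoms, replace = TRUE,
                                   prob = palette$weight))
  r <- atom_radius(radii, elements)
  coords <- matrix(0, n_atoms, 3)
  bonds <- NULL
  rejects <- 0L
  k <- 2L
  while (k <= n_atoms) {
    parent <- with_rng(rng, sample.int(k - 1L, 1L))
    u <- with_rng(rng, stats::rnorm(3))
    u <- u / sqrt(sum(u^2))
    d <- with_rng(rng, stats::runif(1, 1.3, 1.6))
    cand <- coords[parent, ] + d * u
    others <- setdiff(seq_len(k - 1L), parent)
    clash <- length(others) > 0 &&
      any(sqrt(colSums((t(coords[others, , drop = FALSE]) - cand)^2)) <
            0.8 * (r[others] + r[k]))
    if (clash) {
      rejects <- rejects + 1L
      if (rejects > max_rejects) {
        stop("atom placement failed after ", max_rejects, " rejections",
             call. = FALSE)
      }
      next
    }
    coords[k, ] <- cand
    bonds <- rbind(bonds, c(parent, k))
    k <- k + 1L
  }
  conformer(elements, coords, id = id, bonds = bonds,
            include_hydrogens = TRUE)
}

#' Perturb a conformer
#'
#' Adds seeded isotropic Gaussian coordinate noise of scale `sigma` and
#' then applies a random proper rigid transform, producing a pair partner
#' with controlled shape similarity: `sigma = 0` yields an exact rigid
#' copy (ST = 1), small `sigma` a high-ST near-copy, large `sigma` an
#' effectively unrelated shape.
#'
#' @param conf A [conformer()].
#' @param sigma Noise scale in Angstrom (>= 0).
#' @param seed Integer seed (required).
#' @param id Id for the perturbed copy.
#' @return A [conformer()].
#' @export
perturb_conformer <- function(conf, sigma, seed = NULL,
                              id = paste0(conf$id, "_p")) {
  stopifnot(inherits(conf, "conformer"))
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  n <- nrow(conf$coords)
  noise <- if (sigma > 0) {
    with_rng(rng, matrix(stats::rnorm(3 * n, sd = sigma), n, 3))
  } else {
    matrix(0, n, 3)
  }
  R <- random_rotation(rng)
  t <- with_rng(rng, stats::rnorm(3, sd = 5))
  out <- conf
  out$id <- id
  out$coords <- apply_transform(rigid_transform(R, t), conf$coords + noise)
  out
}

#' Specification of a synthetic pair corpus
#'
#' Describes the study conditions for a generated conformer-pair corpus:
#' how many training and held-out test pairs, the atom-count range of the
#' conformers, the perturbation scale used to manufacture similar
#' ("neighbor") pairs, and the fraction of pairs that are perturbation
#' pairs rather than independent conformer pairs.
#'
#' @param n_train_pairs,n_test_pairs Pair counts (> 0).
#' @param atoms_min,atoms_max Atom-count range (defaults 6-24, wide enough
#'   that volume bins overlap across the corpus).
#' @param palette Element palette, see [default_palette()].
#' @param perturbation_sigma Coordinate noise for similar pairs (A).
#' @param fraction_similar Fraction of pairs built by perturbation.
#' @param seed Integer seed (required).
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_train_pairs, n_test_pairs, atoms_min = 6,
                        atoms_max = 24, palette = default_palette(),
                        perturbation_sigma = 0.05,
                        fraction_similar = 0.3, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required", call. = FALSE)
  }
  stopifnot(n_train_pairs > 0, n_test_pairs > 0,
            atoms_min >= 1, atoms_max >= atoms_min,
            perturbation_sigma >= 0,
            fraction_similar >= 0, fraction_similar <= 1)
  structure(list(n_train_pairs = n_train_pairs,
                 n_test_pairs = n_test_pairs, atoms_min = atoms_min,
                 atoms_max = atoms_max, palette = palette,
                 perturbation_sigma = perturbation_sigma,
                 fraction_similar = fraction_similar,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Build a labeled synthetic pair corpus
#'
#' Generates fresh conformers for every pair (so the training and test
#' corpora are disjoint by conformer id), labels each pair with the
#' optimized shape Tanimoto from [optimize_superposition()], and computes
#' the full descriptor table. Similar pairs are a conformer plus its
#' perturbed copy; dissimilar pairs are two independent conformers.
#'
#' @param spec A [corpus_spec()].
#' @param radii A [radius_table()].
#' @param progress Print a dot every 500 labeled pairs.
#' @return List with `train` and `test` pair data frames (`id1, id2, st,
#'   kind`), the `descriptors` table, the list of `conformers`, and the
#'   `spec`.
#' @export
build_corpus <- function(spec, radii = radius_table(), progress = FALSE) {
  stopifnot(inherits(spec, "corpus_spec"))
  rng <- make_rng(spec$seed)
  conformers <- list()
  make_set <- function(n_pairs, prefix) {
    n_similar <- round(spec$fraction_similar * n_pairs)
    rows <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      n1 <- with_rng(rng, sample(seq(spec$atoms_min, spec$atoms_max), 1))
      id1 <- sprintf("%s%05d_a", prefix, i)
      c1 <- random_conformer(n1, spec$palette, seed = rng, radii = radii,
                             id = id1)
      if (i <= n_similar) {
        id2 <- sprintf("%s%05d_b", prefix, i)
        c2 <- perturb_conformer(c1, spec$perturbation_sigma, seed = rng,
                                id = id2)
        kind <- "perturbed"
      } else {
        n2 <- with_rng(rng, sample(seq(spec$atoms_min, spec$atoms_max), 1))
        id2 <- sprintf("%s%05d_b", prefix, i)
        c2 <- random_conformer(n2, spec$palette, seed = rng, radii = radii,
                               id = id2)
        kind <- "independent"
      }
      conformers[[id1]] <<- c1
      conformers[[id2]] <<- c2
      st <- optimize_superposition(build_gaussians(c1, radii),
                                   build_gaussians(c2, radii))$st
      rows[[i]] <- data.frame(id1 = id1, id2 = id2, st = st, kind = kind,
                              stringsAsFactors = FALSE)
      if (progress && i %% 500 == 0) cat(".")
    }
    do.call(rbind, rows)
  }
  train <- make_set(spec$n_train_pairs, "tr")
  test <- make_set(spec$n_test_pairs, "te")
  if (progress) cat("\n")
  desc <- descriptor_table(conformers, radii = radii)
  list(train = train, test = test, descriptors = desc,
       conformers = conformers, spec = spec)
}
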
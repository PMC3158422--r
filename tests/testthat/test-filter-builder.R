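test_that("integer binning truncates and shifts by whole bins", {
  expect_identical(to_bin(511.2, 5.0), 102L)
  expect_identical(to_bin(0, 2.5), 0L)
  expect_identical(to_bin(2.4999, 2.5), 0L)
  expect_identical(to_bin(2.5, 2.5), 1L)
  expect_error(to_bin(-0.1, 2.5), "negative")
  expect_error(to_bin(1, 0), "binsize")
  set.seed(3)
  v <- runif(50, 0, 100)
  expect_identical(to_bin(v + 5.0, 5.0), to_bin(v, 5.0) + 1L)
})

test_that("canonical pair ordering follows the volume-then-Qx-Qy-Qz chain", {
  mk <- function(v, qx = 0L, qy = 0L, qz = 0L) {
    list(v_bin = v, qx_bin = qx, qy_bin = qy, qz_bin = qz)
  }
  expect_identical(order_pair(mk(110L), mk(100L))$mol1$v_bin, 100L)
  expect_identical(order_pair(mk(100L, qx = 5L), mk(100L, qx = 3L))$
                     mol1$qx_bin, 3L)
  expect_identical(order_pair(mk(100L, qy = 9L), mk(100L, qy = 2L))$
                     mol1$qy_bin, 2L)
  expect_identical(order_pair(mk(100L, qz = 4L), mk(100L, qz = 1L))$
                     mol1$qz_bin, 1L)
  # a full tie preserves input order
  op <- order_pair(mk(100L), mk(100L))
  expect_false(op$swapped)
})

test_that("accumulate canonicalizes, tallies and conserves counts", {
  p <- data.frame(v_bin1 = 10L, qx_bin1 = 4L, qy_bin1 = 0L, qz_bin1 = 0L,
                  v_bin2 = 12L, qx_bin2 = 7L, qy_bin2 = 0L, qz_bin2 = 0L)
  raw <- accumulate(p, "x")
  expect_equal(as.data.frame(raw),
               data.frame(v1 = 10L, v2 = 12L, dq = 3L, n = 1L))
  # presenting the same pair in both orders yields the identical map
  p_rev <- p[c(5:8, 1:4)]
  names(p_rev) <- names(p)
  expect_equal(as.data.frame(accumulate(p_rev, "x")), as.data.frame(raw))

  set.seed(1)
  n <- 100
  big <- data.frame(v_bin1 = sample(5:9, n, TRUE),
                    qx_bin1 = sample(0:6, n, TRUE),
                    qy_bin1 = sample(0:4, n, TRUE),
                    qz_bin1 = sample(0:3, n, TRUE),
                    v_bin2 = sample(5:9, n, TRUE),
                    qx_bin2 = sample(0:6, n, TRUE),
                    qy_bin2 = sample(0:4, n, TRUE),
                    qz_bin2 = sample(0:3, n, TRUE))
  expect_equal(sum(accumulate(big, "y")$n), n)
})

test_that("fringe fill closes gaps, is monotone and idempotent", {
  mk_raw <- function(df) {
    structure(df, component = "x",
              class = c("raw_delta_map", "data.frame"))
  }
  # row gap between (10,10) and (10,12) at the same level gets filled
  raw <- mk_raw(data.frame(v1 = c(10L, 10L), v2 = c(10L, 12L),
                           dq = c(2L, 2L), n = c(1L, 1L)))
  f <- fill_map(raw, cfg = bin_config())
  expect_true(any(f$v1 == 10 & f$v2 == 11 & f$dqmin <= 2 & f$dqmax >= 2))

  # single key: nothing to fill
  one <- mk_raw(data.frame(v1 = 8L, v2 = 9L, dq = -1L, n = 1L))
  f1 <- fill_map(one, cfg = bin_config())
  expect_equal(as.data.frame(f1),
               data.frame(v1 = 8L, v2 = 9L, dqmin = -1L, dqmax = -1L))

  # monotonicity: every raw observation is admitted
  set.seed(42)
  obs <- unique(data.frame(v1 = sample(5:10, 60, TRUE),
                           v2 = sample(5:10, 60, TRUE),
                           dq = sample(-3:3, 60, TRUE)))
  obs <- obs[obs$v1 <= obs$v2, ]
  obs$n <- 1L
  f2 <- fill_map(mk_raw(obs), cfg = bin_config())
  key <- paste(f2$v1, f2$v2)
  hit <- match(paste(obs$v1, obs$v2), key)
  expect_false(anyNA(hit))
  expect_true(all(obs$dq >= f2$dqmin[hit] & obs$dq <= f2$dqmax[hit]))

  # idempotence: re-filling a filter's own endpoint map changes nothing
  refill <- mk_raw(rbind(
    data.frame(v1 = f2$v1, v2 = f2$v2, dq = f2$dqmin, n = 1L),
    data.frame(v1 = f2$v1, v2 = f2$v2, dq = f2$dqmax, n = 1L)))
  f3 <- fill_map(refill, cfg = bin_config())
  expect_equal(as.data.frame(f3), as.data.frame(f2))

  expect_error(fill_map(mk_raw(data.frame(v1 = integer(), v2 = integer(),
                                          dq = integer(), n = integer()))),
               "empty")
  expect_error(fill_map(mk_raw(data.frame(v1 = 14L, v2 = 12L, dq = 3L,
                                          n = 1L))), "canonical")
})

test_that("a self-pair corpus yields all-zero difference ranges", {
  corp <- small_corpus()
  ids <- corp$train$id1[1:40]
  selfp <- data.frame(id1 = ids, id2 = ids, st = 1)
  fs <- build_filter_set(selfp, corp$descriptors, bin_config())
  for (comp in c("x", "y", "z")) {
    expect_true(all(fs[[comp]]$dqmin == 0L & fs[[comp]]$dqmax == 0L))
  }
})

test_that("filters built at a stricter threshold nest inside looser ones", {
  corp <- small_corpus()
  f80 <- build_filter_set(corp$train, corp$descriptors,
                          bin_config(st_threshold = 0.80))
  f95 <- build_filter_set(corp$train, corp$descriptors,
                          bin_config(st_threshold = 0.95))
  for (comp in c("x", "y", "z")) {
    a <- f95[[comp]]; b <- f80[[comp]]
    hit <- match(paste(a$v1, a$v2), paste(b$v1, b$v2))
    expect_false(anyNA(hit))
    expect_true(all(b$dqmin[hit] <= a$dqmin & b$dqmax[hit] >= a$dqmax))
  }
})

test_that("filter construction validates its inputs", {
  corp <- small_corpus()
  bad <- data.frame(id1 = "nope", id2 = corp$train$id2[1], st = 1)
  expect_error(build_filter_set(bad, corp$descriptors, bin_config()),
               "nope")
  expect_error(build_filter_set(corp$train, corp$descriptors,
                                bin_config(st_threshold = 0.99999)),
               "no pairs")
  expect_error(bin_config(vol_binsize = 0), "bin sizes")
  expect_error(bin_config(st_threshold = 1.2), "st_threshold")
})

test_that("swapping pair input order never changes the built filters", {
  corp <- small_corpus()
  rev_pairs <- data.frame(id1 = corp$train$id2, id2 = corp$train$id1,
                          st = corp$train$st)
  fs1 <- build_filter_set(corp$train, corp$descriptors, bin_config())
  fs2 <- build_filter_set(rev_pairs, corp$descriptors, bin_config())
  for (comp in c("x", "y", "z")) {
    expect_equal(as.data.frame(fs1[[comp]]), as.data.frame(fs2[[comp]]))
  }
})
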
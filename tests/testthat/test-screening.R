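# A hand-built filter set over a tiny descriptor universe, so the lookup
# logic can be pinned without a corpus.
toy_filter_set <- function() {
  cfg <- bin_config(vol_binsize = 5, q_binsize = c(x = 2.5, y = 0.5,
                                                   z = 0.1),
                    volume_type = "mp", st_threshold = 0.8)
  mk <- function(comp, tbl) quad_filter(tbl, component = comp, cfg = cfg)
  structure(list(
    x = mk("x", data.frame(v1 = 40L, v2 = 40L, dqmin = -3L, dqmax = 4L)),
    y = mk("y", data.frame(v1 = 40L, v2 = 40L, dqmin = 0L, dqmax = 0L)),
    z = mk("z", data.frame(v1 = 40L, v2 = 40L, dqmin = -1L, dqmax = 1L)),
    config = cfg, n_training_pairs = 1L), class = "filter_set")
}

toy_desc <- function(id, v_mp, qx, qy, qz, v_so = v_mp) {
  data.frame(id = id, n_atoms = 10L, v_an = v_mp, v_mp = v_mp,
             v_so = v_so, qx = qx, qy = qy, qz = qz,
             rg = sqrt(qx + qy + qz), stringsAsFactors = FALSE)
}

test_that("single-filter application bins, orders and looks up correctly", {
  fs <- toy_filter_set()
  a <- toy_desc("a", 201, 10.0, 1.0, 0.5)
  b <- toy_desc("b", 203, 12.6, 1.0, 0.5)   # dqx_bin = 5 - 4 = 1
  v <- apply_single(fs$x, a, b)
  expect_true(v$passed)
  expect_true(v$key_found)

  big <- toy_desc("c", 203, 135.0, 1.0, 0.5)  # dqx_bin = 54 - 4 = 50
  v2 <- apply_single(fs$x, a, big)
  expect_false(v2$passed)
  expect_identical(v2$rejected_by, "x")

  # identical descriptors always fall inside a self-pair-trained range
  v3 <- apply_single(fs$y, a, a)
  expect_true(v3$passed)
})

test_that("unknown volume-bin keys follow the configured policy", {
  fs <- toy_filter_set()
  a <- toy_desc("a", 300, 10, 1, 0.5)   # v_bin 60: never trained
  b <- toy_desc("b", 300, 10, 1, 0.5)
  v <- apply_single(fs$x, a, b)
  expect_true(v$passed)
  expect_false(v$key_found)
  v2 <- apply_single(fs$x, a, b, unknown_key = "reject")
  expect_false(v2$passed)
  expect_false(v2$key_found)
})

test_that("cascade short-circuits in x, y, z order and reports the stage", {
  fs <- toy_filter_set()
  a <- toy_desc("a", 201, 10.0, 1.0, 0.5)
  b_y <- toy_desc("b", 203, 10.0, 3.0, 0.5)  # passes x, fails y
  v <- apply_cascade(fs, a, b_y)
  expect_false(v$passed)
  expect_identical(v$rejected_by, "y")

  ok <- toy_desc("c", 202, 10.0, 1.0, 0.55)
  expect_true(apply_cascade(fs, a, ok)$passed)
})

test_that("volume-bound stage precedes the quadrupole filters", {
  fs <- toy_filter_set()
  a <- toy_desc("a", 201, 10, 1, 0.5, v_so = 100)
  b <- toy_desc("b", 203, 10, 1, 0.5, v_so = 5000)
  v <- apply_cascade(fs, a, b, use_volume_bound = TRUE)
  expect_false(v$passed)
  expect_identical(v$rejected_by, "volume_bound")
})

test_that("cascade rejection equals the union of member rejections", {
  corp <- small_corpus()
  fs <- build_filter_set(corp$train, corp$descriptors, bin_config())
  pairs <- rbind(corp$train[c("id1", "id2", "st")],
                 corp$test[c("id1", "id2", "st")])
  v <- shapequad:::screen_pairs(fs, pairs, corp$descriptors)
  expect_identical(v$passed, v$pass_x & v$pass_y & v$pass_z)
  # and the short-circuit bookkeeping is consistent with the verdicts
  expect_true(all(v$rejected_by[!v$passed] %in% c("x", "y", "z")))
  expect_true(all(v$rejected_by[v$passed] == "none"))
})

test_that("evaluation conserves totals and is sound on training data", {
  corp <- small_corpus()
  fs <- build_filter_set(corp$train, corp$descriptors, bin_config())
  ev <- evaluate_filters(fs, corp$train, corp$descriptors)
  for (nm in c("x", "y", "z", "cascade")) {
    expect_identical(sum(ev[[nm]]$counts), nrow(corp$train))
    expect_identical(ev[[nm]]$counts[["FN"]], 0L)
    expect_equal(sum(ev[[nm]]$percent), 100, tolerance = 0.1)
  }
  no_labels <- corp$train
  no_labels$st <- NULL
  expect_error(evaluate_filters(fs, no_labels, corp$descriptors), "label")
})

test_that("an all-self-pair corpus evaluates to pure true positives", {
  corp <- small_corpus()
  ids <- corp$train$id1[1:30]
  selfp <- data.frame(id1 = ids, id2 = ids, st = 1)
  fs <- build_filter_set(selfp, corp$descriptors, bin_config())
  ev <- evaluate_filters(fs, selfp, corp$descriptors)
  expect_identical(ev$cascade$counts[["TP"]], 30L)
  expect_identical(sum(ev$cascade$counts[c("FP", "FN", "TN")]), 0L)
})

test_that("threshold sweep handles degenerate corpora and duplicates", {
  corp <- small_corpus()
  ids <- corp$train$id1[1:25]
  selfp <- data.frame(id1 = ids, id2 = ids, st = 1)
  sw <- threshold_sweep(selfp, selfp, corp$descriptors,
                        thresholds = c(0.8, 0.9, 0.9))
  expect_true(all(sw$rejected_fraction == 0))
  r1 <- sw[sw$st_threshold == 0.9, ][1:4, -1]
  r2 <- sw[sw$st_threshold == 0.9, ][5:8, -1]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
  expect_error(threshold_sweep(selfp, selfp, corp$descriptors,
                               thresholds = c(0.5, 1.5)), "0, 1")

  # a threshold with an empty training restriction is flagged, not fatal
  low <- data.frame(id1 = corp$train$id1, id2 = corp$train$id2,
                    st = pmin(corp$train$st, 0.5))
  sw2 <- threshold_sweep(low, low, corp$descriptors, thresholds = 0.9)
  expect_true(all(sw2$empty_training))
  expect_true(all(is.na(sw2$rejected_fraction)))
})

test_that("confusion matrix classifies by verdict crossed with truth", {
  cm <- confusion_matrix(passed = c(TRUE, TRUE, FALSE, FALSE),
                         st = c(0.9, 0.5, 0.9, 0.5), st_threshold = 0.8)
  expect_identical(cm$counts,
                   c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_equal(unname(cm$percent), rep(25, 4))
})
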
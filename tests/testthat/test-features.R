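# features: time-domain operators vs brute-force oracles, extraction, splits.

test_that("feature operators match their definitions on fixed examples", {
  expect_equal(mav(c(1, -1, 1, -1)), 1)
  expect_equal(mav(rep(0, 10)), 0)
  expect_equal(waveform_length(c(0, 1, 0, 1)), 3)
  expect_equal(waveform_length(rep(3, 7)), 0)
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossings(1:10), 0)             # monotone positive ramp
  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0)), 3)
  expect_equal(slope_sign_changes(1:10), 0)          # strictly monotone
  # zero samples carry the previous nonzero sign: no double-counted crossing
  expect_equal(zero_crossings(c(1, 0, -1)), 1)
  expect_equal(zero_crossings(c(1, 0, 1)), 0)
  # errors on too-short or non-finite windows
  expect_error(mav(numeric(0)), "at least 1")
  expect_error(waveform_length(1), "at least 2")
  expect_error(slope_sign_changes(c(1, 2)), "at least 3")
  expect_error(mav(c(1, NA)), "non-finite")
})

test_that("feature operators equal brute-force oracles on random windows", {
  set.seed(11)
  for (i in 1:30) {
    x <- rnorm(sample(10:200, 1))
    eps <- sample(c(0, 0.1, 0.5, 2), 1)
    expect_equal(mav(x), oracle_mav(x), tolerance = 1e-12)
    expect_equal(waveform_length(x), oracle_wl(x), tolerance = 1e-12)
    expect_identical(as.integer(zero_crossings(x, eps)),
                     as.integer(oracle_zc(x, eps)))
    expect_identical(as.integer(slope_sign_changes(x, eps)),
                     as.integer(oracle_ssc(x, eps)))
  }
})

test_that("ZC and SSC are monotone non-increasing in the deadband", {
  set.seed(3)
  x <- rnorm(500)
  epss <- c(0, 0.1, 0.5, 1, 2, 5, Inf)
  zc <- vapply(epss, function(e) zero_crossings(x, e), numeric(1))
  ssc <- vapply(epss, function(e) slope_sign_changes(x, e), numeric(1))
  expect_true(all(diff(zc) <= 0))
  expect_true(all(diff(ssc) <= 0))
  expect_equal(zc[length(zc)], 0)
  expect_equal(ssc[length(ssc)], 0)
})

test_that("MAV/WL scale linearly; ZC/SSC with eps = 0 are scale-invariant", {
  set.seed(8)
  x <- rnorm(300)
  for (k in c(0.5, 3, 100)) {
    expect_equal(mav(k * x), k * mav(x), tolerance = 1e-12)
    expect_equal(waveform_length(k * x), k * waveform_length(x),
                 tolerance = 1e-10)
    expect_identical(zero_crossings(k * x), zero_crossings(x))
    expect_identical(slope_sign_changes(k * x), slope_sign_changes(x))
  }
})

test_that("extract_features assembles channel-major columns and matches scalar ops", {
  s <- small_session(seed = 10, n_channels = 3)
  ws <- windows_from_session(s)
  fm <- extract_features(ws)
  expect_equal(ncol(fm$x), 3 * 4)
  expect_equal(colnames(fm$x)[1:5],
               c("ch01_mav", "ch01_wl", "ch01_ssc", "ch01_zc", "ch02_mav"))
  # vectorized path equals the exported scalar operators, window by window
  w1 <- ws$windows[5, ]
  sig <- ws$signals[[w1$label]]
  win <- sig[(w1$start + 1):w1$end, , drop = FALSE]
  row <- which(ws$windows$label == w1$label)[5]
  for (ch in 1:3) {
    expect_equal(unname(fm$x[row, sprintf("ch%02d_mav", ch)]), mav(win[, ch]))
    expect_equal(unname(fm$x[row, sprintf("ch%02d_wl", ch)]),
                 waveform_length(win[, ch]))
    expect_equal(unname(fm$x[row, sprintf("ch%02d_ssc", ch)]),
                 slope_sign_changes(win[, ch]))
    expect_equal(unname(fm$x[row, sprintf("ch%02d_zc", ch)]),
                 zero_crossings(win[, ch]))
  }
  # empty window set -> empty matrix with correct column count
  ws0 <- ws; ws0$windows <- ws$windows[0, ]
  expect_equal(dim(extract_features(ws0)$x), c(0, 12))
})

test_that("feature matrices round-trip through CSV", {
  fm <- extract_features(windows_from_session(small_session(seed = 12)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_identical(back$labels, fm$labels)
})

test_that("split_sets stratifies with largest-remainder rounding", {
  fm <- gaussian_feature_matrix(n_classes = 1, n_per_class = 163)
  sp <- split_sets(fm, c(0.4, 0.2, 0.4), seed = 1)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 65, validation = 33, test = 65))
  # disjoint and exhaustive
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, seq_len(163))
  # proportions (1, 0, 0): everything in training
  sp1 <- split_sets(fm, c(1, 0, 0), seed = 1)
  expect_equal(length(sp1$train), 163)
  expect_equal(length(sp1$test), 0)
  # deterministic per seed, different across seeds, sizes equal
  spA <- split_sets(fm, seed = 7)
  spB <- split_sets(fm, seed = 7)
  spC <- split_sets(fm, seed = 8)
  expect_identical(spA$train, spB$train)
  expect_false(identical(spA$train, spC$train))
  expect_equal(length(spC$train), length(spA$train))
  # per-class stratification within one window of the target
  fm2 <- gaussian_feature_matrix(n_classes = 3, n_per_class = 50)
  sp2 <- split_sets(fm2, seed = 2)
  for (cl in unique(fm2$labels)) {
    n_train_cl <- sum(fm2$labels[sp2$train] == cl)
    expect_lte(abs(n_train_cl - 0.4 * 50), 1)
  }
  # errors
  expect_error(split_sets(fm, c(0.5, 0.2, 0.4)), "sum to 1")
  tiny <- gaussian_feature_matrix(n_classes = 1, n_per_class = 2)
  expect_error(split_sets(tiny, c(0.4, 0.2, 0.4)), "class")
})
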
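# lda_ovo: pairwise discriminants, voting, ties, oracles.

test_that("pair count is n(n-1)/2 and training uses only the pair's classes", {
  fm <- gaussian_feature_matrix(n_classes = 9, n_per_class = 20, dim = 5)
  clf <- fit_ovo(fm)
  expect_length(clf$pairs, 36)
  fm2 <- gaussian_feature_matrix(n_classes = 2, n_per_class = 20, dim = 5)
  expect_length(fit_ovo(fm2)$pairs, 1)
  # refitting after removing a third class leaves the (c01, c02) pair identical
  fm3 <- gaussian_feature_matrix(n_classes = 3, n_per_class = 20, dim = 5)
  keep <- fm3$labels != "c03"
  fm3b <- fm3; fm3b$x <- fm3$x[keep, ]; fm3b$labels <- fm3$labels[keep]
  p_all <- fit_ovo(fm3, lambda = 1e-8)$pairs[[1]]
  p_two <- fit_ovo(fm3b, lambda = 1e-8)$pairs[[1]]
  expect_equal(p_all$w, p_two$w)
  expect_equal(p_all$b0, p_two$b0)
})

test_that("w is parallel to the mean difference for identity covariance", {
  set.seed(2)
  n <- 4000; d <- 4
  mu_a <- c(10, 0, 0, 0); mu_b <- c(-10, 0, 0, 0)
  x <- rbind(matrix(rnorm(n * d), n, d) + matrix(mu_a, n, d, byrow = TRUE),
             matrix(rnorm(n * d), n, d) + matrix(mu_b, n, d, byrow = TRUE))
  colnames(x) <- paste0("f", 1:d)
  fm <- structure(list(x = x, labels = rep(c("a", "b"), each = n),
                       feature_names = colnames(x), n_channels = 1L),
                  class = "feature_matrix")
  clf <- fit_ovo(fm, lambda = 1e-12)
  w <- clf$pairs[[1]]$w
  mu_diff <- colMeans(x[1:n, ]) - colMeans(x[-(1:n), ])
  angle <- acos(sum(w * mu_diff) / sqrt(sum(w^2) * sum(mu_diff^2)))
  expect_lt(angle, 0.05) # near-parallel (sampling error only at n = 4000)
  # decision sign: midpoint bias sends each training mean to its own class
  expect_identical(predict(clf, mu_a), "a")
  expect_identical(predict(clf, mu_b), "b")
})

test_that("prediction returns the majority class with conserved votes", {
  fm <- gaussian_feature_matrix(n_classes = 5, n_per_class = 30, dim = 6,
                                sep = 10)
  clf <- fit_ovo(fm)
  # points at the class training means are classified to their class
  for (cl in clf$classes) {
    mu <- colMeans(fm$x[fm$labels == cl, ])
    expect_identical(predict(clf, mu), cl)
  }
  votes <- predict(clf, fm$x, type = "votes")
  expect_true(all(rowSums(votes) == choose(5, 2)))
  acc <- mean(predict(clf, fm$x) == fm$labels)
  expect_equal(acc, 1) # separable construction
  expect_error(predict(clf, fm$x[, 1:3]), "columns")
})

test_that("ties break deterministically by margin sum then class index", {
  # symmetric two-class problem: all-zero vector sits on the boundary
  x <- rbind(matrix(c(1, 1), 1), matrix(c(-1, -1), 1),
             matrix(c(1.1, 0.9), 1), matrix(c(-0.9, -1.1), 1))
  colnames(x) <- c("f1", "f2")
  fm <- structure(list(x = x, labels = c("a", "b", "a", "b"),
                       feature_names = colnames(x), n_channels = 1L),
                  class = "feature_matrix")
  clf <- fit_ovo(fm, lambda = 1e-6)
  # d(0) == 0 exactly -> documented rule: vote goes to the lower class
  expect_identical(predict(clf, c(0, 0)), "a")
  expect_identical(predict(clf, c(0, 0)), predict(clf, c(0, 0)))
})

test_that("OVO equals plain two-class LDA on 2-class problems", {
  set.seed(31)
  for (trial in 1:5) {
    fm <- gaussian_feature_matrix(n_classes = 2, n_per_class = 60, dim = 5,
                                  sep = sample(1:4, 1), seed = trial)
    clf <- fit_ovo(fm, lambda = 1e-9)
    # direct 2-class LDA from the definition (independent arithmetic)
    xa <- fm$x[fm$labels == "c01", ]; xb <- fm$x[fm$labels == "c02", ]
    sp <- ((nrow(xa) - 1) * cov(xa) + (nrow(xb) - 1) * cov(xb)) /
      (nrow(xa) + nrow(xb) - 2)
    w <- solve(sp + diag(1e-9, ncol(sp)), colMeans(xa) - colMeans(xb))
    b0 <- -sum(w * (colMeans(xa) + colMeans(xb))) / 2
    direct <- ifelse(fm$x %*% w + b0 >= 0, "c01", "c02")
    expect_identical(predict(clf, fm$x), as.vector(direct))
  }
})

test_that("relabeling classes permutes predictions consistently", {
  fm <- gaussian_feature_matrix(n_classes = 4, n_per_class = 25, dim = 4,
                                sep = 3, seed = 5)
  clf <- fit_ovo(fm)
  relabel <- c(c01 = "z_far", c02 = "a_near", c03 = "m_mid", c04 = "b_other")
  fm2 <- fm; fm2$labels <- unname(relabel[fm$labels])
  clf2 <- fit_ovo(fm2)
  p1 <- predict(clf, fm$x)
  p2 <- predict(clf2, fm$x)
  expect_identical(unname(relabel[p1]), p2)
})

test_that("agreement with the reference LDA implementation is >= 99%", {
  # MASS::lda as independent reference; equal priors, moderate separation
  set.seed(99)
  fm <- gaussian_feature_matrix(n_classes = 3, n_per_class = 100, dim = 6,
                                sep = 1.5, seed = 99)
  clf <- fit_ovo(fm, lambda = 0)
  ref <- MASS::lda(fm$x, grouping = fm$labels,
                   prior = rep(1 / 3, 3))
  test_x <- fm$x + matrix(rnorm(length(fm$x), sd = 0.3), nrow(fm$x))
  ours <- predict(clf, test_x)
  theirs <- as.character(predict(ref, test_x)$class)
  expect_gte(mean(ours == theirs), 0.99)
})

test_that("singular covariance with lambda = 0 errors, lambda > 0 succeeds", {
  x <- cbind(rep(c(0, 1), each = 10), rep(c(0, 1), each = 10)) # rank 1
  colnames(x) <- c("f1", "f2")
  fm <- structure(list(x = x, labels = rep(c("a", "b"), each = 10),
                       feature_names = colnames(x), n_channels = 1L),
                  class = "feature_matrix")
  expect_error(fit_ovo(fm, lambda = 0), "lambda > 0")
  expect_s3_class(fit_ovo(fm, lambda = 1e-6), "ovo_classifier")
  # class with < 2 rows
  fm_small <- gaussian_feature_matrix(n_classes = 2, n_per_class = 1)
  expect_error(fit_ovo(fm_small), "fewer than 2")
})

test_that("classifiers round-trip exactly through JSON", {
  fm <- gaussian_feature_matrix(n_classes = 3, n_per_class = 20, dim = 4)
  clf <- fit_ovo(fm)
  f <- withr::local_tempfile(fileext = ".json")
  write_ovo(clf, f)
  back <- read_ovo(f)
  expect_equal(back$classes, clf$classes)
  for (k in seq_along(clf$pairs)) {
    expect_identical(back$pairs[[k]]$w, unname(clf$pairs[[k]]$w))
    expect_identical(back$pairs[[k]]$b0, clf$pairs[[k]]$b0)
  }
  expect_identical(predict(back, fm$x), predict(clf, fm$x))
})

test_that("offline_accuracy scores the test partition", {
  fm <- gaussian_feature_matrix(n_classes = 3, n_per_class = 40, dim = 4,
                                sep = 10)
  sp <- split_sets(fm, seed = 1)
  clf <- fit_ovo(fm, sp)
  expect_equal(offline_accuracy(clf, fm, sp), 1)
  sp_empty <- sp; sp_empty$test <- integer(0)
  expect_error(offline_accuracy(clf, fm, sp_empty), "empty")
})
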
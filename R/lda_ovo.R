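#' Fit a one-vs-one LDA classifier
#'
#' Trains one linear discriminant per unordered class pair on the training
#' rows of those two classes only. Each pair `(a, b)` (classes ordered
#' alphabetically, `a < b`) stores `w = solve(S_pooled + lambda I, mu_a -
#' mu_b)` and the equal-priors midpoint bias `b0 = -w . (mu_a + mu_b) / 2`;
#' the decision value `d(x) = w . x + b0` votes for `a` when positive.
#'
#' @param fm a `feature_matrix`
#' @param split optional `data_split`; when supplied, only `split$train`
#'   rows are used
#' @param lambda ridge coefficient added to the pooled within-class
#'   covariance; default `1e-6 * trace(S_pooled) / dim` per pair, which keeps
#'   near-singular 64-dimensional problems solvable. `lambda = 0` requests
#'   the unridged solve and errors if the covariance is singular.
#' @return an `ovo_classifier`
#' @export
fit_ovo <- function(fm, split = NULL, lambda = NULL) {
  rows <- if (is.null(split)) seq_len(nrow(fm$x)) else split$train
  x <- fm$x[rows, , drop = FALSE]
  y <- fm$labels[rows]
  classes <- sort(unique(y))
  if (length(classes) < 2) stop_invalid("fm", "need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2))
    stop_invalid("fm", sprintf("class '%s' has fewer than 2 training rows",
                               names(counts)[which.min(counts)]))
  d <- ncol(x)
  pairs <- utils::combn(classes, 2)
  fits <- vector("list", ncol(pairs))
  stats_by_class <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(n = nrow(xi), mu = colMeans(xi), scatter = stats::cov(xi) * (nrow(xi) - 1))
  })
  names(stats_by_class) <- classes
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sa <- stats_by_class[[a]]; sb <- stats_by_class[[b]]
    pooled <- (sa$scatter + sb$scatter) / (sa$n + sb$n - 2)
    lam <- lambda %||% (1e-6 * sum(diag(pooled)) / d)
    reg <- pooled + diag(lam, d)
    w <- tryCatch(solve(reg, sa$mu - sb$mu),
                  error = function(e)
                    stop(sprintf("singular pooled covariance for pair (%s, %s) with lambda = %g; use lambda > 0",
                                 a, b, lam), call. = FALSE))
    fits[[k]] <- list(a = a, b = b, w = w,
                      b0 = -sum(w * (sa$mu + sb$mu)) / 2, lambda = lam)
  }
  structure(list(classes = classes, pairs = fits,
                 feature_names = colnames(fm$x), lambda = lambda,
                 tie_break = "margin_sum_then_index"),
            class = "ovo_classifier")
}

#' @export
print.ovo_classifier <- function(x, ...) {
  cat(sprintf("<ovo_classifier> %d classes, %d pairwise discriminants, %d features\n",
              length(x$classes), length(x$pairs), length(x$feature_names)))
  invisible(x)
}

#' Predict classes by one-vs-one majority vote
#'
#' Each pairwise discriminant votes for one of its two classes (`d(x) > 0`
#' votes the alphabetically lower class; an exact `d(x) = 0` also goes to the
#' lower class, a documented deterministic rule). The predicted class has the
#' most votes; ties are broken by the largest sum of absolute decision
#' margins over the tied class's pairs, then by lowest class index.
#'
#' @param object an `ovo_classifier`
#' @param newdata numeric vector (one feature vector) or matrix (rows =
#'   observations); column count must match training
#' @param type `"class"` (default) for the predicted labels, `"votes"` for
#'   the per-class vote-count matrix, or `"full"` for a list with `class`,
#'   `votes` and the raw pairwise `decisions`
#' @param ... unused
#' @return see `type`
#' @export
predict.ovo_classifier <- function(object, newdata,
                                   type = c("class", "votes", "full"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$feature_names))
    stop_invalid("newdata", sprintf("has %d columns; classifier expects %d",
                                    ncol(newdata), length(object$feature_names)))
  n <- nrow(newdata)
  n_cl <- length(object$classes)
  votes <- matrix(0L, n, n_cl, dimnames = list(NULL, object$classes))
  margin_sum <- matrix(0, n, n_cl, dimnames = list(NULL, object$classes))
  decisions <- matrix(0, n, length(object$pairs))
  for (k in seq_along(object$pairs)) {
    p <- object$pairs[[k]]
    dv <- as.numeric(newdata %*% p$w) + p$b0
    decisions[, k] <- dv
    to_a <- dv >= 0
    votes[, p$a] <- votes[, p$a] + to_a
    votes[, p$b] <- votes[, p$b] + !to_a
    margin_sum[, p$a] <- margin_sum[, p$a] + abs(dv)
    margin_sum[, p$b] <- margin_sum[, p$b] + abs(dv)
  }
  winner <- character(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      best <- top[margin_sum[i, top] == max(margin_sum[i, top])]
      top <- best[1] # lowest class index among remaining ties
    }
    winner[i] <- object$classes[top]
  }
  switch(type,
         class = winner,
         votes = votes,
         full = list(class = winner, votes = votes, decisions = decisions))
}

#' Offline classification accuracy on the test partition
#'
#' @param clf an `ovo_classifier`
#' @param fm the `feature_matrix` the split indexes into
#' @param split a `data_split`; accuracy is computed on `split$test`
#' @return fraction of test rows predicted correctly, in [0, 1]
#' @export
offline_accuracy <- function(clf, fm, split) {
  rows <- split$test
  if (length(rows) == 0) stop_invalid("split", "test partition is empty")
  mean(predict(clf, fm$x[rows, , drop = FALSE]) == fm$labels[rows])
}

#' Serialize / restore an OVO classifier as JSON
#'
#' Human-readable model file: class list, per-pair weights and biases, ridge
#' coefficients and feature-column names, written with 17 significant digits
#' so the round-trip is exact.
#'
#' @param clf an `ovo_classifier`
#' @param path JSON file path
#' @return `path` invisibly / an `ovo_classifier`
#' @export
write_ovo <- function(clf, path) {
  payload <- list(
    type = "ovo_classifier", version = "1.0",
    classes = clf$classes, feature_names = clf$feature_names,
    lambda = clf$lambda, tie_break = clf$tie_break,
    pairs = lapply(clf$pairs, function(p)
      list(a = p$a, b = p$b, w = p$w, b0 = p$b0, lambda = p$lambda)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ovo
#' @export
read_ovo <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(j$type, "ovo_classifier"))
    stop("not an ovo_classifier file: ", path, call. = FALSE)
  structure(list(classes = j$classes,
                 pairs = lapply(j$pairs, function(p)
                   list(a = p$a, b = p$b, w = as.numeric(p$w),
                        b0 = p$b0, lambda = p$lambda)),
                 feature_names = j$feature_names,
                 lambda = j$lambda, tie_break = j$tie_break),
            class = "ovo_classifier")
}
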
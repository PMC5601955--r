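# Classic time-domain sEMG features, per window and per channel:
# MAV (mean absolute value), WL (waveform length), SSC (slope sign changes),
# ZC (zero crossings). ZC/SSC take a deadband threshold eps (volts), default 0.

#' Mean absolute value of a window
#' @param x numeric vector (window samples of one channel), length >= 1
#' @return `mean(abs(x))`
#' @export
mav <- function(x) {
  check_window(x, 1)
  mean(abs(x))
}

#' Waveform length (total variation) of a window
#' @param x numeric vector, length >= 2
#' @return `sum(abs(diff(x)))`
#' @export
waveform_length <- function(x) {
  check_window(x, 2)
  sum(abs(diff(x)))
}

#' Zero crossings of a window
#'
#' Counts consecutive sample pairs of opposite sign whose difference exceeds
#' the deadband `eps`. Zero-valued samples carry the sign of the previous
#' nonzero sample, so a touch of exactly zero does not double-count.
#'
#' @param x numeric vector, length >= 2
#' @param eps deadband threshold in signal units, >= 0
#' @return integer count
#' @export
zero_crossings <- function(x, eps = 0) {
  check_window(x, 2)
  check_scalar_num(eps, "eps", lower = 0, allow_inf = TRUE)
  s <- carry_sign(sign(x))
  n <- length(x)
  sum(s[-n] * s[-1] < 0 & abs(diff(x)) > eps)
}

#' Slope sign changes of a window
#'
#' Counts interior samples that are a local extremum — where
#' `(x[i] - x[i-1]) * (x[i] - x[i+1]) > 0` — and at least one of the two
#' adjacent differences exceeds the deadband `eps`.
#'
#' @inheritParams zero_crossings
#' @param x numeric vector, length >= 3
#' @return integer count
#' @export
slope_sign_changes <- function(x, eps = 0) {
  check_window(x, 3)
  check_scalar_num(eps, "eps", lower = 0, allow_inf = TRUE)
  n <- length(x)
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  sum(d1 * d2 > 0 & (abs(d1) > eps | abs(d2) > eps))
}

check_window <- function(x, min_n) {
  if (!is.numeric(x) || length(x) < min_n)
    stop_invalid("x", sprintf("window must be numeric with at least %d samples", min_n))
  if (any(!is.finite(x))) stop_invalid("x", "window contains non-finite values")
  invisible(x)
}

# LOCF on a sign vector: zeros inherit the previous nonzero sign.
carry_sign <- function(s) {
  z <- s == 0
  if (!any(z)) return(s)
  idx <- cummax(seq_along(s) * !z)
  out <- s
  out[idx > 0] <- s[idx][idx > 0]
  out[idx == 0] <- 0
  out
}

#' Feature-extraction specification
#'
#' @param features ordered subset of `"mav"`, `"wl"`, `"ssc"`, `"zc"`
#' @param eps deadband threshold (volts) applied to ZC and SSC; default 0
#' @return object of class `feature_spec`
#' @export
feature_spec <- function(features = c("mav", "wl", "ssc", "zc"), eps = 0) {
  features <- match.arg(features, c("mav", "wl", "ssc", "zc"),
                        several.ok = TRUE)
  if (length(features) == 0) stop_invalid("features", "must be non-empty")
  check_scalar_num(eps, "eps", lower = 0)
  structure(list(features = features, eps = eps), class = "feature_spec")
}

# Vectorized per-feature computation over a window matrix W (samples x windows).
feature_columns <- function(W, features, eps) {
  n <- nrow(W)
  out <- matrix(0, ncol(W), length(features))
  for (j in seq_along(features)) {
    out[, j] <- switch(
      features[j],
      mav = colMeans(abs(W)),
      wl = colSums(abs(W[-1, , drop = FALSE] - W[-n, , drop = FALSE])),
      zc = {
        s <- sign(W)
        for (i in 2:n) {
          z <- s[i, ] == 0
          if (any(z)) s[i, z] <- s[i - 1, z]
        }
        d <- abs(W[-1, , drop = FALSE] - W[-n, , drop = FALSE])
        colSums((s[-n, , drop = FALSE] * s[-1, , drop = FALSE] < 0) & d > eps)
      },
      ssc = {
        d1 <- W[2:(n - 1), , drop = FALSE] - W[1:(n - 2), , drop = FALSE]
        d2 <- W[2:(n - 1), , drop = FALSE] - W[3:n, , drop = FALSE]
        colSums(d1 * d2 > 0 & (abs(d1) > eps | abs(d2) > eps))
      })
  }
  out
}

#' Extract per-window, per-channel features from a window set
#'
#' Assembles the feature matrix: one row per window, columns ordered
#' channel-major then feature (`ch01_mav, ch01_wl, ch01_ssc, ch01_zc,
#' ch02_mav, ...`), with one class label per row. 16 channels with the four
#' default features give 64 columns.
#'
#' @param window_set a `window_set` from [windows_from_session()] or
#'   [segment_windows()]
#' @param spec a [feature_spec()]
#' @return a `feature_matrix`: list with `x` (numeric matrix), `labels`
#'   (character), `feature_names`, `n_channels`
#' @export
extract_features <- function(window_set, spec = feature_spec()) {
  wins <- window_set$windows
  labs <- unique(wins$label)
  n_ch <- ncol(window_set$signals[[1]])
  n_feat <- length(spec$features)
  wlen <- window_set$window_samples
  cols <- as.vector(t(outer(seq_len(n_ch), spec$features,
                            function(c, f) sprintf("ch%02d_%s", c, f))))
  if (nrow(wins) == 0) {
    return(structure(list(x = matrix(0, 0, n_ch * n_feat,
                                     dimnames = list(NULL, cols)),
                          labels = character(0),
                          feature_names = cols, n_channels = n_ch),
                     class = "feature_matrix"))
  }
  blocks <- vector("list", length(labs))
  labels <- vector("list", length(labs))
  for (li in seq_along(labs)) {
    sig <- window_set$signals[[labs[li]]]
    if (any(!is.finite(sig))) stop_invalid("signal", "contains non-finite values")
    starts <- wins$start[wins$label == labs[li]]
    nw <- length(starts)
    idx <- outer(seq_len(wlen), starts, `+`) # 0-based starts -> 1-based rows
    feat <- matrix(0, nw, n_ch * n_feat)
    for (ch in seq_len(n_ch)) {
      W <- matrix(sig[idx, ch], nrow = wlen)
      feat[, (ch - 1) * n_feat + seq_len(n_feat)] <-
        feature_columns(W, spec$features, spec$eps)
    }
    blocks[[li]] <- feat
    labels[[li]] <- rep(labs[li], nw)
  }
  x <- do.call(rbind, blocks)
  colnames(x) <- cols
  structure(list(x = x, labels = unlist(labels), feature_names = cols,
                 n_channels = n_ch),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%d ch), %d class(es)\n",
              nrow(x$x), ncol(x$x), x$n_channels,
              length(unique(x$labels))))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' One row per window: a `class` column followed by the named feature
#' columns, 17 significant digits.
#'
#' @param fm a `feature_matrix`
#' @param path CSV file path
#' @return `path` invisibly / a `feature_matrix`
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(class = fm$labels,
                   formatC(fm$x, digits = 17, format = "g"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  n_ch <- length(unique(sub("_.*$", "", colnames(x))))
  structure(list(x = x, labels = as.character(df$class),
                 feature_names = colnames(x), n_channels = n_ch),
            class = "feature_matrix")
}

#' Stratified train/validation/test split
#'
#' Randomly partitions the rows of a feature matrix, stratified by class,
#' into training/validation/test sets in the given proportions (default
#' 40/20/40). Within each class the set sizes follow largest-remainder
#' rounding (ties broken in set order), so 163 windows split 40/20/40 gives
#' 65/33/65. Deterministic for a fixed seed.
#'
#' @param fm a `feature_matrix`
#' @param proportions length-3 numeric, summing to 1 (tolerance 1e-9)
#' @param seed RNG seed
#' @return a `data_split`: list of integer row-index vectors `train`,
#'   `validation`, `test`
#' @export
split_sets <- function(fm, proportions = c(0.4, 0.2, 0.4), seed = 1) {
  if (length(proportions) != 3 || any(proportions < 0))
    stop_invalid("proportions", "must be three non-negative numbers")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_invalid("proportions", "must sum to 1")
  n_sets <- sum(proportions > 0)
  classes <- unique(fm$labels)
  sets <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in classes) {
      rows <- which(fm$labels == cl)
      if (length(rows) < n_sets)
        stop_invalid("fm", sprintf("class '%s' has %d windows; need >= %d for %d nonempty sets",
                                   cl, length(rows), n_sets, n_sets))
      sizes <- largest_remainder(length(rows), proportions)
      rows <- sample(rows)
      cuts <- cumsum(sizes)
      sets$train <- c(sets$train, rows[seq_len(sizes[1])])
      if (sizes[2] > 0)
        sets$validation <- c(sets$validation, rows[(cuts[1] + 1):cuts[2]])
      if (sizes[3] > 0)
        sets$test <- c(sets$test, rows[(cuts[2] + 1):cuts[3]])
    }
  })
  structure(c(lapply(sets, sort), list(proportions = proportions, seed = seed)),
            class = "data_split")
}

# Integer apportionment of n by the largest-remainder (Hamilton) method.
largest_remainder <- function(n, proportions) {
  quota <- n * proportions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    frac <- quota - base
    give <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train %d / validation %d / test %d (seed %s)\n",
              length(x$train), length(x$validation), length(x$test),
              format(x$seed)))
  invisible(x)
}
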
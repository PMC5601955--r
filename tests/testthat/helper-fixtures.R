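# Shared fixtures (built in code) and independent brute-force oracles.
# The oracles deliberately re-derive every quantity from first principles,
# independently of the R/ implementations they check.

# A small, fast protocol: 4 movements, 2 reps of 1.5 s + 0.5 s rest, 4 ch.
small_protocol <- function(n_channels = 4, movements = paste0("m", 1:4)) {
  protocol_spec(n_channels = n_channels, movements = movements,
                n_repetitions = 2, contraction_s = 1.5, rest_s = 0.5)
}

small_session <- function(seed = 1, overlap = 0, n_channels = 4,
                          movements = paste0("m", 1:4)) {
  p <- small_protocol(n_channels, movements)
  m <- make_activation_matrix(length(movements), n_channels,
                              overlap = overlap, seed = seed)
  generate_session(p, m, seed = seed + 100)
}

# ---- brute-force feature oracles (loops, no vectorization tricks) ----

oracle_mav <- function(x) {
  s <- 0
  for (xi in x) s <- s + abs(xi)
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}

oracle_zc <- function(x, eps = 0) {
  n <- length(x)
  sgn <- numeric(n)
  last <- 0
  for (i in 1:n) {
    if (x[i] > 0) last <- 1 else if (x[i] < 0) last <- -1
    sgn[i] <- last
  }
  cnt <- 0
  for (i in 1:(n - 1)) {
    if (sgn[i] * sgn[i + 1] < 0 && abs(x[i] - x[i + 1]) > eps) cnt <- cnt + 1
  }
  cnt
}

oracle_ssc <- function(x, eps = 0) {
  cnt <- 0
  for (i in 2:(length(x) - 1)) {
    d1 <- x[i] - x[i - 1]
    d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && (abs(d1) > eps || abs(d2) > eps)) cnt <- cnt + 1
  }
  cnt
}

# ---- exact Wilcoxon oracles by full enumeration (n <= ~10) ----

oracle_signed_rank_p <- function(a, b) {
  d <- (a - b)[a - b != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    vs[mask + 1] <- sum(r[signs])
  }
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

oracle_rank_sum_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(r), na)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Gaussian feature clouds for classifier tests: k well-separated classes.
gaussian_feature_matrix <- function(n_classes = 3, n_per_class = 40, dim = 6,
                                    sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  mus <- matrix(rnorm(n_classes * dim), n_classes, dim) * sep
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k)
    matrix(rnorm(n_per_class * dim, sd = sd), n_per_class, dim) +
      matrix(mus[k, ], n_per_class, dim, byrow = TRUE)))
  colnames(x) <- sprintf("ch01_f%02d", seq_len(dim))
  structure(list(x = x,
                 labels = rep(sprintf("c%02d", seq_len(n_classes)),
                              each = n_per_class),
                 feature_names = colnames(x), n_channels = 1L),
            class = "feature_matrix")
}
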
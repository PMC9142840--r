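# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Linear-interpolation percentile on a sorted copy (the textbook formula).
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- (n - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
}

# Tie-corrected Kruskal-Wallis H from first principles.
oracle_kruskal_h <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  n <- lengths(groups)
  N <- length(pooled)
  idx <- rep(seq_along(groups), n)
  rsum <- tapply(r, idx, sum)
  h <- 12 / (N * (N + 1)) * sum(rsum^2 / n) - 3 * (N + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Brute-force angular wedge spectrum: loop over every FFT bin, bin by
# atan2 with nearest-wedge assignment after the 90-degree fiber mapping.
oracle_wedge_spectrum <- function(shg, pixel_size_um, step = 1,
                                  dc_radius = 3, fmin = 1 / 20,
                                  fmax = NULL) {
  n <- nrow(shg)
  stopifnot(n == ncol(shg))
  if (is.null(fmax)) fmax <- 1 / (2 * pixel_size_um)
  x <- shg - mean(shg)
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  x <- x * (h %o% h)
  pw <- Mod(stats::fft(x))^2
  k <- 0:(n - 1)
  fr <- ifelse(k <= n %/% 2, k, k - n) / n
  nb <- as.integer(180 / step)
  e <- numeric(nb)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      fx <- fr[j] / pixel_size_um
      fy <- -fr[i] / pixel_size_um
      fm <- sqrt(fx^2 + fy^2)
      rad <- fm * pixel_size_um * n
      if (rad > dc_radius && fm >= fmin && fm <= fmax) {
        fib <- ((atan2(fy, fx) * 180 / pi) %% 180 + 90) %% 180
        b <- (floor(fib / step + 0.5) %% nb) + 1
        e[b] <- e[b] + pw[i, j]
      }
    }
  }
  e / sum(e)
}

# Best-overlap intersection-over-union of each ground-truth region.
region_ious <- function(truth, labels, n_true) {
  vapply(seq_len(n_true), function(i) {
    g <- truth == i
    best <- 0
    for (l in setdiff(unique(labels[labels > 0]), 0)) {
      s <- labels == l
      best <- max(best, sum(g & s) / sum(g | s))
    }
    best
  }, numeric(1))
}

# Circular mean of undirected angles in degrees.
axial_mean_deg <- function(a) {
  (atan2(mean(sin(2 * a * pi / 180)), mean(cos(2 * a * pi / 180))) *
     90 / pi) %% 180
}
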
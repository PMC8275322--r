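# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive loops so they share no code path with the implementation.

# a tiny hand-built run: n1 MS1 scans, K windows x n2 MS2 scans
tiny_run <- function(run_id = "tiny", n1 = 3, K = 2, n2 = 3) {
  ms1 <- lapply(seq_len(n1), function(i) {
    new_scan(1, rt = 10 * i, mz = c(450 + i, 700, 1100),
             intensity = c(5, 10 * i, 2))
  })
  edges <- seq(400, 1249, length.out = K + 1)
  scheme <- window_scheme(edges[-length(edges)], edges[-1])
  ms2 <- lapply(seq_len(K), function(w) {
    lapply(seq_len(n2), function(i) {
      new_scan(2, rt = 10 * i, mz = c(150.5, 900 + w, 1700),
               intensity = c(1, 2 * i, 0.5 * w),
               precursor_window = c(scheme$lower[w], scheme$upper[w]))
    })
  })
  new_run(run_id, ms1, ms2, scheme)
}

# brute-force rasterization oracle: per-point triple loop with direct
# floor-formula binning and running mean
brute_force_raster <- function(scans, G, mz_lo = 0, mz_hi = 2000) {
  rts <- sapply(scans, function(s) s$rt)
  rt_min <- min(rts); rt_max <- max(rts)
  sums <- matrix(0, G, G)
  cnts <- matrix(0, G, G)
  for (s in scans) {
    if (rt_max > rt_min) {
      row <- floor((s$rt - rt_min) / (rt_max - rt_min) * G)
      if (row >= G) row <- G - 1
    } else {
      row <- 0
    }
    for (j in seq_along(s$mz)) {
      col <- floor((s$mz[j] - mz_lo) / (mz_hi - mz_lo) * G)
      if (col >= G) col <- G - 1
      sums[row + 1, col + 1] <- sums[row + 1, col + 1] + s$intensity[j]
      cnts[row + 1, col + 1] <- cnts[row + 1, col + 1] + 1
    }
  }
  out <- matrix(0, G, G)
  nz <- cnts > 0
  out[nz] <- sums[nz] / cnts[nz]
  out
}

# random toy scan series for the oracle-equivalence property
random_series <- function(seed, max_points = 1000, ms_level = 1) {
  set.seed(seed)
  n_scans <- sample(2:8, 1)
  rts <- sort(runif(n_scans, 0, 300))
  lapply(seq_len(n_scans), function(i) {
    npts <- sample(0:floor(max_points / n_scans), 1)
    mz <- sort(runif(npts, 0, 2000))
    mz <- unique(mz)
    new_scan(ms_level, rts[i], mz, runif(length(mz), 0, 1e5),
             precursor_window = if (ms_level == 2) c(400, 500) else NULL)
  })
}

# naive per-pixel bilinear interpolation oracle (half-pixel centers)
brute_force_bilinear <- function(m, out_rows, out_cols) {
  out <- matrix(0, out_rows, out_cols)
  for (i in seq_len(out_rows)) {
    for (j in seq_len(out_cols)) {
      y <- (i - 0.5) * nrow(m) / out_rows - 0.5
      x <- (j - 0.5) * ncol(m) / out_cols - 0.5
      y <- min(max(y, 0), nrow(m) - 1)
      x <- min(max(x, 0), ncol(m) - 1)
      y0 <- floor(y); x0 <- floor(x)
      y1 <- min(y0 + 1, nrow(m) - 1); x1 <- min(x0 + 1, ncol(m) - 1)
      fy <- y - y0; fx <- x - x0
      out[i, j] <- (1 - fy) * ((1 - fx) * m[y0 + 1, x0 + 1] + fx * m[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * m[y1 + 1, x0 + 1] + fx * m[y1 + 1, x1 + 1])
    }
  }
  out
}

# independent AUC oracle: explicit pair counting with half-credit ties
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# a small feature matrix with known class separation; the first `informative`
# columns are shifted by `gap` in class 1 (default: all of them)
separable_fm <- function(n_per_class = 12, d = 5, gap = 4, seed = 42,
                         informative = d) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * d), ncol = d)
  x[labels == 1L, seq_len(informative)] <-
    x[labels == 1L, seq_len(informative)] + gap
  feature_matrix(x, sprintf("s%02d", seq_along(labels)), labels)
}

# tiny fast cohort for pipeline-level tests
tiny_cohort_config <- function(seed = 1, ...) {
  synthetic_cohort_config(n_per_class = 10, n_windows = 4, n_scans = 16,
                          n_background = 10, seed = seed, ...)
}
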
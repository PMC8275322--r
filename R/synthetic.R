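#' Describe one synthetic peptide-like peak
#'
#' A peak is a precursor with a Gaussian elution profile in retention time
#' and a set of fragment ions. Its MS1 signal is a point at the precursor
#' m/z; its MS2 signal is one point per fragment, emitted only into the
#' isolation window containing the precursor. A discriminative peak is
#' amplified by `fold_change` in class-1 samples — in both MS levels for
#' `signal_location = "ms1_and_ms2"`, or in the fragments only for
#' `"ms2_only"` (its MS1 trace is then identical across classes, which is
#' what makes the MS2-information-gain experiments possible).
#'
#' @param precursor_mz precursor m/z in `[400, 1249]` Th.
#' @param rt_center,rt_sigma Gaussian elution center and width, seconds.
#' @param base_intensity peak apex intensity (arbitrary units).
#' @param fragments data.frame with columns `mz` (in `[0, 2000]`) and
#'   `rel_intensity` (in `(0, 1]`).
#' @param discriminative does the peak carry class signal?
#' @param fold_change class-1 amplification factor (>= 1).
#' @param signal_location `"ms1_and_ms2"` or `"ms2_only"`.
#' @return An object of class `rawms_peak_spec`.
#' @export
peak_spec <- function(precursor_mz, rt_center, rt_sigma, base_intensity,
                      fragments, discriminative = FALSE, fold_change = 1,
                      signal_location = c("ms1_and_ms2", "ms2_only")) {
  signal_location <- match.arg(signal_location)
  stopifnot(precursor_mz >= 400, precursor_mz <= 1249, rt_sigma > 0,
            base_intensity > 0, fold_change >= 1,
            all(fragments$mz >= 0), all(fragments$mz <= 2000),
            all(fragments$rel_intensity > 0), all(fragments$rel_intensity <= 1))
  structure(
    list(precursor_mz = precursor_mz, rt_center = rt_center,
         rt_sigma = rt_sigma, base_intensity = base_intensity,
         fragments = fragments, discriminative = discriminative,
         fold_change = fold_change, signal_location = signal_location),
    class = "rawms_peak_spec"
  )
}

#' Draw a default peak inventory
#'
#' A reproducible inventory of `n_peaks` peaks with precursors uniform over
#' the MS1 acquisition range (400-1249 Th), elution centers spread over the
#' middle 80% of the gradient, widths of 5-15 s, log-normal apex
#' intensities around 1e4, and 5 fragments per peak uniform over the MS2
#' axis with relative intensities in 0.2-1. The first `n_discriminative`
#' peaks carry the class signal.
#'
#' @param n_peaks,n_discriminative inventory size and how many peaks are
#'   class-discriminative.
#' @param fold_change class-1 amplification of discriminative peaks.
#' @param signal_location where the class signal lives, see [peak_spec()].
#' @param rt_span gradient length in seconds.
#' @param seed seed for the inventory draw.
#' @return List of `rawms_peak_spec`s.
#' @export
default_peak_inventory <- function(n_peaks = 20L, n_discriminative = 5L,
                                   fold_change = 4,
                                   signal_location = "ms1_and_ms2",
                                   rt_span = 600, seed = 0L) {
  stopifnot(n_discriminative <= n_peaks)
  with_seed(derive_seed(seed, "peak_inventory"), {
    lapply(seq_len(n_peaks), function(i) {
      peak_spec(
        precursor_mz = stats::runif(1, 400, 1249),
        rt_center = stats::runif(1, 0.1, 0.9) * rt_span,
        rt_sigma = stats::runif(1, 5, 15),
        base_intensity = stats::rlnorm(1, log(1e4), 0.5),
        fragments = data.frame(mz = stats::runif(5, 0, 2000),
                               rel_intensity = stats::runif(5, 0.2, 1)),
        discriminative = i <= n_discriminative,
        fold_change = if (i <= n_discriminative) fold_change else 1,
        signal_location = signal_location
      )
    })
  })
}

#' Configuration for a synthetic SWATH cohort
#'
#' Defines the acquisition geometry and the class structure of a simulated
#' two-class cohort. The isolation windows tile the precursor range
#' 400-1249 Th contiguously (the MS2 m/z axis itself spans 0-2000 Th), so
#' every precursor is routed to exactly one fragment series.
#'
#' @param n_per_class samples per class (default 30).
#' @param n_windows number of isolation windows K (default 10; 100 mimics a
#'   full-scale SWATH scheme at 10x the cost).
#' @param n_scans scans per series across the gradient (default 32).
#' @param rt_span gradient length, seconds (default 600).
#' @param peaks peak inventory; defaults to [default_peak_inventory()]
#'   drawn from `seed` with the given `fold_change`/`signal_location`.
#' @param fold_change,signal_location forwarded to the default inventory.
#' @param n_background background (chemical noise) points per scan
#'   (default 20), uniform in m/z with exponential intensities.
#' @param background_mean mean background intensity (default 200).
#' @param noise_sigma sdlog of the multiplicative log-normal intensity
#'   noise on peak points (default 0.3).
#' @param seed master seed for the cohort.
#' @return An object of class `rawms_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_per_class = 30L, n_windows = 10L,
                                    n_scans = 32L, rt_span = 600,
                                    peaks = NULL, fold_change = 4,
                                    signal_location = "ms1_and_ms2",
                                    n_background = 20L,
                                    background_mean = 200,
                                    noise_sigma = 0.3, seed = 1L) {
  stopifnot(n_per_class >= 2, n_windows >= 1, n_scans >= 2, rt_span > 0)
  if (is.null(peaks)) {
    peaks <- default_peak_inventory(fold_change = fold_change,
                                    signal_location = signal_location,
                                    rt_span = rt_span, seed = seed)
  }
  edges <- seq(400, 1249, length.out = n_windows + 1)
  scheme <- window_scheme(edges[-length(edges)], edges[-1])
  for (p in peaks) {
    if (p$precursor_mz < min(scheme$lower) || p$precursor_mz > max(scheme$upper)) {
      rawms_stop("rawms_config_error",
                 "precursor %.2f Th falls outside every isolation window",
                 p$precursor_mz)
    }
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_windows = as.integer(n_windows), n_scans = as.integer(n_scans),
         rt_span = rt_span, peaks = peaks, scheme = scheme,
         n_background = as.integer(n_background),
         background_mean = background_mean, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "rawms_cohort_config"
  )
}

# route a precursor m/z to its (single) isolation window index
route_window <- function(mz, scheme) {
  w <- findInterval(mz, c(scheme$lower, max(scheme$upper)),
                    rightmost.closed = TRUE)
  if (w < 1 || w > nrow(scheme)) {
    rawms_stop("rawms_config_error", "precursor %.2f Th outside the scheme", mz)
  }
  w
}

# sort points by m/z and merge exact duplicates (scan invariant: strictly
# increasing m/z)
as_scan_points <- function(mz, intensity) {
  if (length(mz) == 0) return(list(mz = numeric(0), intensity = numeric(0)))
  s <- rowsum(intensity, mz)  # sums by sorted unique mz
  list(mz = as.double(rownames(s)), intensity = as.double(s))
}

#' Generate one synthetic run
#'
#' Simulates one sample's acquisition under the cohort configuration: at
#' each of `n_scans` retention times, every peak contributes a point at its
#' precursor m/z to the MS1 scan and one point per fragment to the MS2
#' series of the window containing the precursor, with intensity
#' `base * rel * exp(-(rt - center)^2 / (2 sigma^2))` times multiplicative
#' log-normal noise, amplified by `fold_change` in class-1 samples where
#' the peak is discriminative (in MS1 only when `signal_location` covers
#' MS1). Uniform-m/z background points with exponential intensities are
#' added to every scan. All randomness derives from `sample_seed`.
#'
#' @param class_label 0 or 1.
#' @param config a [synthetic_cohort_config()].
#' @param sample_seed integer seed for this sample.
#' @param run_id identifier (default derived from seed and class).
#' @return A `rawms_run`.
#' @export
generate_run <- function(class_label, config, sample_seed,
                         run_id = sprintf("run_s%d_c%d", sample_seed, class_label)) {
  stopifnot(inherits(config, "rawms_cohort_config"), class_label %in% c(0, 1))
  scheme <- config$scheme
  K <- nrow(scheme)
  rts <- seq(0, config$rt_span, length.out = config$n_scans)
  peaks <- config$peaks
  win_of_peak <- vapply(peaks, function(p) route_window(p$precursor_mz, scheme), 0L)

  with_seed(sample_seed, {
    ms1_scans <- vector("list", config$n_scans)
    ms2_scans <- lapply(seq_len(K), function(w) vector("list", config$n_scans))
    for (si in seq_along(rts)) {
      rt <- rts[si]
      # MS1: one point per peak + background over the MS1 range
      mz1 <- numeric(0); i1 <- numeric(0)
      for (pi in seq_along(peaks)) {
        p <- peaks[[pi]]
        g <- exp(-(rt - p$rt_center)^2 / (2 * p$rt_sigma^2))
        amp_ms1 <- if (p$discriminative && class_label == 1 &&
                       p$signal_location == "ms1_and_ms2") p$fold_change else 1
        amp_ms2 <- if (p$discriminative && class_label == 1) p$fold_change else 1
        noise1 <- stats::rlnorm(1, 0, config$noise_sigma)
        mz1 <- c(mz1, p$precursor_mz)
        i1 <- c(i1, p$base_intensity * g * amp_ms1 * noise1)
        # fragments into the routed window
        nf <- nrow(p$fragments)
        noise2 <- stats::rlnorm(nf, 0, config$noise_sigma)
        w <- win_of_peak[pi]
        prev <- ms2_scans[[w]][[si]]
        ms2_scans[[w]][[si]] <- list(
          mz = c(prev$mz, p$fragments$mz),
          intensity = c(prev$intensity,
                        p$base_intensity * p$fragments$rel_intensity * g *
                          amp_ms2 * noise2)
        )
      }
      if (config$n_background > 0) {
        mz1 <- c(mz1, stats::runif(config$n_background, 400, 1249))
        i1 <- c(i1, stats::rexp(config$n_background, 1 / config$background_mean))
      }
      pts <- as_scan_points(mz1, i1)
      ms1_scans[[si]] <- new_scan(1L, rt, pts$mz, pts$intensity)
      for (w in seq_len(K)) {
        acc <- ms2_scans[[w]][[si]]
        mzw <- acc$mz; iw <- acc$intensity
        if (config$n_background > 0) {
          mzw <- c(mzw, stats::runif(config$n_background, 0, 2000))
          iw <- c(iw, stats::rexp(config$n_background, 1 / config$background_mean))
        }
        pts <- as_scan_points(mzw, iw)
        ms2_scans[[w]][[si]] <- new_scan(2L, rt, pts$mz, pts$intensity,
                                         precursor_window = c(scheme$lower[w],
                                                              scheme$upper[w]))
      }
    }
    new_run(run_id, ms1_scans, ms2_scans, scheme)
  })
}

#' Generate a labelled synthetic cohort
#'
#' `2 * n_per_class` runs with balanced labels (all class 0 first, then all
#' class 1); each sample's seed derives from the cohort master seed and the
#' sample index.
#'
#' @param config a [synthetic_cohort_config()].
#' @return List: `runs` (list of `rawms_run`), `labels` (data.frame
#'   `sample_id`, `label`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "rawms_cohort_config"))
  n <- 2L * config$n_per_class
  labels <- rep(c(0L, 1L), each = config$n_per_class)
  ids <- sprintf("sample_%03d_c%d", seq_len(n), labels)
  runs <- lapply(seq_len(n), function(i) {
    generate_run(labels[i], config,
                 sample_seed = derive_seed(config$seed, sprintf("sample_%d", i)),
                 run_id = ids[i])
  })
  list(runs = runs, labels = data.frame(sample_id = ids, label = labels,
                                        stringsAsFactors = FALSE))
}

#' End-to-end pipeline on a synthetic cohort
#'
#' Convenience wrapper for the full chain: generate the cohort, rasterize
#' and encode every run, assemble the requested input mode, and run the
#' evaluation protocol.
#'
#' @param config a [synthetic_cohort_config()].
#' @param encoder a `rawms_encoder` (default: [reference_encoder()] seeded
#'   from the cohort seed).
#' @param grid_size raster resolution (default 512).
#' @param mode `"ms1_only"` or `"ms1_and_ms2"`.
#' @param classifier classifier name (default `"logreg"`).
#' @param seed master seed for the evaluation protocol (default: cohort
#'   seed).
#' @param ... passed to [train_and_evaluate()].
#' @return A `rawms_evaluation`.
#' @export
evaluate_synthetic_cohort <- function(config, encoder = NULL, grid_size = 512L,
                                      mode = "ms1_and_ms2",
                                      classifier = "logreg", seed = NULL,
                                      ...) {
  if (is.null(encoder)) encoder <- reference_encoder(seed = config$seed)
  if (is.null(seed)) seed <- config$seed
  cohort <- generate_cohort(config)
  cfg <- raster_config(grid_size = grid_size)
  per_run <- lapply(cohort$runs, encode_run_features, config = cfg,
                    encoder = encoder)
  fm <- build_feature_matrix(per_run, cohort$labels$sample_id,
                             cohort$labels$label, mode = mode)
  train_and_evaluate(fm, classifier, seed = seed,
                     config = list(resolution = grid_size,
                                   encoder = encoder$spec$name, mode = mode),
                     ...)
}
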
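#' Sweep pipeline configurations over a cohort
#'
#' Runs the full evaluation once per combination of raster resolution,
#' encoder, input mode and classifier. Per (resolution, encoder) pair the
#' runs are rasterized and encoded once and both input modes are assembled
#' from the same per-window encodings. Every configuration receives a seed
#' derived from the master seed and its configuration key, so the sweep is
#' reproducible row by row. Failures in individual configurations are
#' recorded (NA metrics plus the error message) and the sweep continues.
#'
#' @param runs list of `rawms_run`s.
#' @param labels binary labels, one per run.
#' @param encoders named list of `rawms_encoder`s.
#' @param resolutions integer vector of grid sizes (default `c(512)`).
#' @param modes subset of `c("ms1_only", "ms1_and_ms2")`.
#' @param classifiers subset of the [hyper_grid()] names.
#' @param seed master seed.
#' @param transform intensity transform for encoding.
#' @param ... passed through to [train_and_evaluate()].
#' @return A `rawms_sweep_table` data.frame with one row per configuration
#'   (resolution, encoder, mode, classifier, auc, cv_auc, secondary metrics,
#'   best_params, error), sorted by descending per-encoder median AUC.
#' @export
run_sweep <- function(runs, labels, encoders,
                      resolutions = c(512L),
                      modes = c("ms1_only", "ms1_and_ms2"),
                      classifiers = c("logreg", "svc", "random_forest",
                                      "gradient_boosted_trees"),
                      seed = 1L, transform = "linear_max", ...) {
  stopifnot(length(runs) == length(labels), length(runs) >= 4,
            !is.null(names(encoders)))
  sample_ids <- vapply(runs, function(r) r$run_id, "")
  rows <- list()
  for (res in resolutions) {
    cfg <- raster_config(grid_size = res)
    for (enc_name in names(encoders)) {
      per_run <- tryCatch(
        lapply(runs, encode_run_features, config = cfg,
               encoder = encoders[[enc_name]], transform = transform),
        error = function(e) e
      )
      for (mode in modes) {
        fm <- if (inherits(per_run, "error")) {
          per_run
        } else {
          tryCatch(build_feature_matrix(per_run, sample_ids, labels, mode = mode),
                   error = function(e) e)
        }
        for (clf in classifiers) {
          key <- sprintf("res%d_%s_%s_%s", res, enc_name, mode, clf)
          row <- data.frame(resolution = as.integer(res), encoder = enc_name,
                            mode = mode, classifier = clf,
                            auc = NA_real_, cv_auc = NA_real_,
                            brier = NA_real_, log_loss = NA_real_,
                            accuracy = NA_real_, f1 = NA_real_,
                            youden = NA_real_, recall = NA_real_,
                            precision = NA_real_, specificity = NA_real_,
                            best_params = NA_character_,
                            error = NA_character_,
                            stringsAsFactors = FALSE)
          res_or_err <- if (inherits(fm, "error")) {
            fm
          } else {
            tryCatch(
              train_and_evaluate(fm, clf, seed = derive_seed(seed, key),
                                 config = list(resolution = res,
                                               encoder = enc_name, mode = mode),
                                 ...),
              error = function(e) e
            )
          }
          if (inherits(res_or_err, "error")) {
            row$error <- conditionMessage(res_or_err)
          } else {
            m <- res_or_err$metrics
            row$auc <- m$auc; row$cv_auc <- res_or_err$cv_auc
            row$brier <- m$brier; row$log_loss <- m$log_loss
            row$accuracy <- m$accuracy; row$f1 <- m$f1
            row$youden <- m$youden; row$recall <- m$recall
            row$precision <- m$precision; row$specificity <- m$specificity
            row$best_params <- paste(
              sprintf("%s=%s", names(res_or_err$best_params),
                      unlist(res_or_err$best_params)), collapse = ";")
          }
          rows[[key]] <- row
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  med <- tapply(tab$auc, tab$encoder, stats::median, na.rm = TRUE)
  tab <- tab[order(-med[tab$encoder], tab$encoder, -tab$auc), ]
  rownames(tab) <- NULL
  class(tab) <- c("rawms_sweep_table", "data.frame")
  tab
}

#' Per-encoder AUC summary
#'
#' Median, mean and sample standard deviation of AUC over all rows sharing
#' an encoder (pooling classifiers, resolutions and, unless filtered
#' beforehand, input modes). A single-row group reports sd = 0 and is
#' flagged by its `n`.
#'
#' @param table a `rawms_sweep_table` (or any data.frame with `encoder` and
#'   `auc` columns).
#' @return A data.frame (`encoder`, `n`, `median_auc`, `mean_auc`,
#'   `sd_auc`) sorted by descending median.
#' @export
summarize_by_encoder <- function(table) {
  stopifnot(nrow(table) >= 1, all(c("encoder", "auc") %in% names(table)))
  out <- do.call(rbind, lapply(split(table$auc, table$encoder), function(a) {
    a <- a[!is.na(a)]
    data.frame(n = length(a), median_auc = stats::median(a), mean_auc = mean(a),
               sd_auc = if (length(a) > 1) stats::sd(a) else 0)
  }))
  out <- data.frame(encoder = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$median_auc), ]
}

#' One-sided paired t-test on matched AUC sequences
#'
#' Classical paired t-test of the alternative `mean(a) > mean(b)`, used to
#' compare two pipeline variants (e.g. ms1_and_ms2 vs ms1_only) over
#' configurations matched on everything else.
#'
#' @param a,b equal-length numeric vectors (>= 3), matched pairwise.
#' @return List: `t`, `p_value`, `mean_diff`, `df`.
#' @export
paired_onesided_ttest <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) {
    rawms_stop("rawms_validation_error", "need at least 3 matched pairs")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    rawms_stop("rawms_degenerate_test",
               "paired differences have zero variance; t statistic undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d), df = unname(tt$parameter))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the rank-transformed sequences, with average
#' ranks for ties.
#'
#' @param a,b equal-length numeric vectors (>= 3).
#' @return The correlation coefficient rho.
#' @export
spearman_rank_corr <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) {
    rawms_stop("rawms_validation_error", "need at least 3 observations")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rawms_stop("rawms_degenerate_test",
               "correlation undefined for a constant sequence")
  }
  stats::cor(a, b, method = "spearman")
}
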
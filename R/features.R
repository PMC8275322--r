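#' Assemble one sample's feature vector from per-grid encodings
#'
#' Concatenates the MS1 encoding and, in `ms1_and_ms2` mode, every MS2
#' window encoding in canonical order (MS1 first, then windows ascending).
#' The layout table records where each source landed so the concatenation
#' is lossless and slice-recoverable.
#'
#' @param vectors named list of `rawms_feature_vector`s; names `"MS1"`,
#'   `"MS2_w0"`, `"MS2_w1"`, ....
#' @param mode `"ms1_only"` or `"ms1_and_ms2"`.
#' @param n_windows number of isolation windows K (required for
#'   `ms1_and_ms2`; defaults to the number of `MS2_w*` entries present).
#' @return A `rawms_sample_features`: list with `vector`, `mode` and
#'   `layout` (data.frame `source`, `offset` (0-based), `length`).
#' @export
assemble_sample <- function(vectors, mode = c("ms1_only", "ms1_and_ms2"),
                            n_windows = NULL) {
  mode <- match.arg(mode)
  if (!"MS1" %in% names(vectors)) {
    rawms_stop("rawms_assembly_error", "missing MS1 feature vector")
  }
  sources <- "MS1"
  if (mode == "ms1_and_ms2") {
    if (is.null(n_windows)) {
      n_windows <- sum(grepl("^MS2_w\\d+$", names(vectors)))
    }
    if (n_windows < 1) {
      rawms_stop("rawms_assembly_error",
                 "ms1_and_ms2 mode requires at least one MS2 window vector")
    }
    sources <- c(sources, sprintf("MS2_w%d", seq_len(n_windows) - 1L))
  }
  missing <- setdiff(sources, names(vectors))
  if (length(missing)) {
    rawms_stop("rawms_assembly_error",
               "missing feature vector(s) for: %s", paste(missing, collapse = ", "))
  }
  parts <- lapply(sources, function(s) vectors[[s]]$values)
  lens <- vapply(parts, length, 0L)
  layout <- data.frame(
    source = sources,
    offset = cumsum(c(0L, lens[-length(lens)])),
    length = lens,
    stringsAsFactors = FALSE
  )
  structure(
    list(vector = unlist(parts, use.names = FALSE), mode = mode, layout = layout),
    class = "rawms_sample_features"
  )
}

#' Construct a cohort feature matrix
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of row identifiers.
#' @param labels binary labels (tumor = 1, normal = 0), one per sample.
#' @param feature_names optional column names.
#' @param retained_mask logical mask over the ORIGINAL feature set recording
#'   which columns survive filtering; defaults to all TRUE.
#' @return An object of class `rawms_feature_matrix`.
#' @export
feature_matrix <- function(values, sample_ids, labels, feature_names = NULL,
                           retained_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (length(sample_ids) != n || length(labels) != n) {
    rawms_stop("rawms_validation_error",
               "sample_ids/labels length must equal nrow(values)")
  }
  if (anyDuplicated(sample_ids)) {
    rawms_stop("rawms_validation_error", "duplicate sample_ids")
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    rawms_stop("rawms_validation_error", "labels must be binary 0/1 with no missing values")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- sprintf("f%d", seq_len(ncol(values)) - 1L)
  }
  colnames(values) <- feature_names
  rownames(values) <- sample_ids
  if (is.null(retained_mask)) retained_mask <- rep(TRUE, ncol(values))
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         labels = labels, retained_mask = retained_mask),
    class = "rawms_feature_matrix"
  )
}

#' @export
print.rawms_feature_matrix <- function(x, ...) {
  cat(sprintf("<rawms_feature_matrix> %d samples x %d features (%d/%d original retained)\n",
              nrow(x$values), ncol(x$values), sum(x$retained_mask),
              length(x$retained_mask)))
  cat(sprintf("  labels: %d positive / %d negative\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Remove constant features
#'
#' Drops every column whose standard deviation is zero over the chosen rows
#' — tested as exact equality of all entries, since encoder outputs are
#' deterministic floats and "constant" is meant absolutely. The default
#' scope is the whole cohort, matching the usual practice of dataset-level
#' constant elimination; `train_only` restricts the test to training rows
#' for a strictly leakage-free variant.
#'
#' @param fm a [feature_matrix()].
#' @param scope `"all_samples"` or `"train_only"`.
#' @param train_ids sample ids of the training rows (required for
#'   `"train_only"`).
#' @return The filtered `rawms_feature_matrix`; its `retained_mask` is
#'   composed with any previous mask, and attribute `"retention"` carries
#'   the retained/original fraction for this call.
#' @export
drop_constant_features <- function(fm, scope = c("all_samples", "train_only"),
                                   train_ids = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(fm, "rawms_feature_matrix"))
  if (nrow(fm$values) < 2) {
    rawms_stop("rawms_validation_error", "need at least 2 samples")
  }
  rows <- if (scope == "train_only") {
    if (is.null(train_ids)) {
      rawms_stop("rawms_validation_error", "train_only scope requires train_ids")
    }
    match(train_ids, fm$sample_ids)
  } else {
    seq_len(nrow(fm$values))
  }
  v <- fm$values[rows, , drop = FALSE]
  keep <- colSums(v != rep(v[1, ], each = nrow(v))) > 0
  if (!any(keep)) {
    rawms_stop("rawms_empty_matrix", "all features are constant")
  }
  mask <- fm$retained_mask
  mask[which(mask)[!keep]] <- FALSE
  out <- feature_matrix(fm$values[, keep, drop = FALSE], fm$sample_ids,
                        fm$labels, retained_mask = mask)
  attr(out, "retention") <- mean(keep)
  out
}

#' Read a tabular feature matrix from CSV
#'
#' Entry point for externally derived comparator matrices (e.g. curated
#' protein or peptide quantification tables). Expected columns:
#' `sample_id`, `label`, then numeric feature columns.
#'
#' @param path CSV file path.
#' @return A `rawms_feature_matrix`.
#' @export
load_tabular_features <- function(path) {
  if (!file.exists(path)) rawms_stop("rawms_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "label")
  if (!all(need %in% names(df))) {
    rawms_stop("rawms_validation_error", "CSV must have 'sample_id' and 'label' columns")
  }
  if (anyNA(df$label)) {
    rawms_stop("rawms_validation_error", "missing labels in %s", path)
  }
  feat <- df[, setdiff(names(df), need), drop = FALSE]
  bad <- names(feat)[!vapply(feat, is.numeric, TRUE)]
  if (length(bad)) {
    rawms_stop("rawms_validation_error",
               "non-numeric feature column(s): %s", paste(bad, collapse = ", "))
  }
  feature_matrix(as.matrix(feat), df$sample_id, df$label,
                 feature_names = names(feat))
}

#' Write a feature matrix to CSV
#'
#' Inverse of [load_tabular_features()].
#'
#' @param fm a `rawms_feature_matrix`.
#' @param path output CSV path.
#' @export
write_tabular_features <- function(fm, path) {
  stopifnot(inherits(fm, "rawms_feature_matrix"))
  df <- data.frame(sample_id = fm$sample_ids, label = fm$labels,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}

#' Encode every grid of a run
#'
#' Convenience wrapper: rasterize the run and encode each grid, returning
#' the named per-source list [assemble_sample()] consumes.
#'
#' @param run a `rawms_run`.
#' @param config a [raster_config()].
#' @param encoder a `rawms_encoder`.
#' @param transform intensity transform for [prepare_image()].
#' @return Named list of `rawms_feature_vector`s.
#' @export
encode_run_features <- function(run, config, encoder,
                                transform = c("linear_max", "log1p_then_linear")) {
  transform <- match.arg(transform)
  grids <- rasterize_run(run, config)
  lapply(grids, encode_grid, encoder = encoder, transform = transform)
}

#' Build a cohort feature matrix from per-run encodings
#'
#' @param per_run list (one element per sample) of named feature-vector
#'   lists, as produced by [encode_run_features()].
#' @param sample_ids,labels cohort identifiers and binary labels.
#' @param mode `"ms1_only"` or `"ms1_and_ms2"`.
#' @return A `rawms_feature_matrix`; attribute `"layout"` holds the shared
#'   concatenation layout.
#' @export
build_feature_matrix <- function(per_run, sample_ids, labels,
                                 mode = c("ms1_only", "ms1_and_ms2")) {
  mode <- match.arg(mode)
  assembled <- lapply(per_run, assemble_sample, mode = mode)
  lens <- vapply(assembled, function(a) length(a$vector), 0L)
  if (length(unique(lens)) != 1L) {
    rawms_stop("rawms_assembly_error",
               "samples produced feature vectors of differing lengths")
  }
  values <- do.call(rbind, lapply(assembled, function(a) a$vector))
  layout <- assembled[[1]]$layout
  fnames <- unlist(lapply(seq_len(nrow(layout)), function(i) {
    sprintf("%s_f%d", layout$source[i], seq_len(layout$length[i]) - 1L)
  }), use.names = FALSE)
  fm <- feature_matrix(values, sample_ids, labels, feature_names = fnames)
  attr(fm, "layout") <- layout
  fm
}
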
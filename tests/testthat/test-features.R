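fake_fv <- function(values, source) {
  structure(list(values = values, encoder_name = "toy", source = source),
            class = "rawms_feature_vector")
}

test_that("assembly concatenates in canonical order with a lossless layout", {
  vecs <- list(
    MS1 = fake_fv(1:4, "MS1"),
    MS2_w0 = fake_fv(5:8, "MS2_w0"),
    MS2_w1 = fake_fv(9:12, "MS2_w1")
  )
  sf <- assemble_sample(vecs, mode = "ms1_and_ms2")
  expect_length(sf$vector, 12)
  expect_equal(sf$layout$source, c("MS1", "MS2_w0", "MS2_w1"))
  expect_equal(sf$layout$offset, c(0, 4, 8))
  expect_equal(sf$layout$length, c(4, 4, 4))
  # slicing by layout recovers every input exactly
  for (i in seq_len(nrow(sf$layout))) {
    src <- sf$layout$source[i]
    slice <- sf$vector[(sf$layout$offset[i] + 1):(sf$layout$offset[i] + sf$layout$length[i])]
    expect_identical(slice, as.integer(vecs[[src]]$values))
  }

  # ms1_only ignores the MS2 vectors
  sf1 <- assemble_sample(vecs, mode = "ms1_only")
  expect_length(sf1$vector, 4)
  expect_equal(sf1$layout$source, "MS1")

  # missing window is an error naming the window, never a silent zero-fill
  err <- tryCatch(assemble_sample(vecs[c("MS1", "MS2_w1")],
                                  mode = "ms1_and_ms2", n_windows = 2),
                  error = identity)
  expect_s3_class(err, "rawms_assembly_error")
  expect_match(conditionMessage(err), "MS2_w0")
  expect_error(assemble_sample(vecs[-1], mode = "ms1_only"),
               class = "rawms_assembly_error")
})

test_that("full-scale concatenation width is D * (1 + K)", {
  D <- 2048; K <- 100
  vecs <- c(list(MS1 = fake_fv(numeric(D), "MS1")),
            setNames(lapply(seq_len(K) - 1L,
                            function(w) fake_fv(numeric(D), sprintf("MS2_w%d", w))),
                     sprintf("MS2_w%d", seq_len(K) - 1L)))
  sf <- assemble_sample(vecs, mode = "ms1_and_ms2")
  expect_length(sf$vector, 206848)  # 2048 * 101
})

test_that("constant features are dropped exactly and idempotently", {
  # planted example: column 1 constant
  fm <- feature_matrix(matrix(c(1, 2, 1, 3), 2, byrow = TRUE),
                       c("a", "b"), c(0, 1))
  out <- drop_constant_features(fm)
  expect_equal(ncol(out$values), 1)
  expect_equal(attr(out, "retention"), 0.5)
  expect_equal(out$retained_mask, c(FALSE, TRUE))

  # 20 x 50 with 7 planted constant columns: exactly those dropped
  set.seed(8)
  vals <- matrix(rnorm(20 * 50), 20, 50)
  const_cols <- sample(50, 7)
  vals[, const_cols] <- rep(rnorm(7), each = 20)
  fm2 <- feature_matrix(vals, sprintf("s%d", 1:20), rep(0:1, 10))
  out2 <- drop_constant_features(fm2)
  # oracle: per-column sd by direct loop
  oracle_sd <- sapply(seq_len(50), function(j) sd(vals[, j]))
  expect_equal(which(!out2$retained_mask), sort(const_cols))
  expect_equal(sum(out2$retained_mask), sum(oracle_sd > 0))
  expect_equal(attr(out2, "retention"), 43 / 50)
  # no surviving column has zero variance
  expect_true(all(apply(out2$values, 2, sd) > 0))
  # idempotence
  out3 <- drop_constant_features(out2)
  expect_identical(out3$values, out2$values)
  expect_identical(out3$retained_mask, out2$retained_mask)
  expect_equal(attr(out3, "retention"), 1)

  # nothing dropped on a generic matrix
  fm3 <- feature_matrix(matrix(rnorm(40), 4), sprintf("s%d", 1:4), c(0, 0, 1, 1))
  expect_equal(ncol(drop_constant_features(fm3)$values), 10)

  # all-constant matrix is an error
  fm4 <- feature_matrix(matrix(1, 3, 2), c("a", "b", "c"), c(0, 1, 1))
  expect_error(drop_constant_features(fm4), class = "rawms_empty_matrix")
})

test_that("train_only scope ignores test rows when deciding constancy", {
  vals <- matrix(rnorm(12), 4, 3)
  vals[1:2, 1] <- 5      # constant on the first two rows only
  fm <- feature_matrix(vals, c("a", "b", "c", "d"), c(0, 1, 0, 1))
  out <- drop_constant_features(fm, scope = "train_only", train_ids = c("a", "b"))
  expect_equal(out$retained_mask, c(FALSE, TRUE, TRUE))
  expect_equal(ncol(drop_constant_features(fm)$values), 3)  # all vary cohort-wide
})

test_that("tabular feature matrices round-trip through CSV", {
  fm <- feature_matrix(matrix(round(rnorm(12), 6), 4, 3), sprintf("s%d", 1:4),
                       c(0, 0, 1, 1), feature_names = c("fA", "fB", "fC"))
  path <- file.path(tempdir(), "features.csv")
  write_tabular_features(fm, path)
  back <- load_tabular_features(path)
  expect_equal(back$values, fm$values)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$sample_ids, fm$sample_ids)

  # missing label -> error
  df <- utils::read.csv(path)
  df$label[2] <- NA
  bad <- file.path(tempdir(), "bad.csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(load_tabular_features(bad), class = "rawms_validation_error")

  # non-numeric feature -> error
  df2 <- utils::read.csv(path)
  df2$fA <- as.character(df2$fA)
  df2$fA[1] <- "oops"
  utils::write.csv(df2, bad, row.names = FALSE)
  expect_error(load_tabular_features(bad), class = "rawms_validation_error")

  # duplicate sample ids -> error
  df3 <- utils::read.csv(path)
  df3$sample_id[2] <- df3$sample_id[1]
  utils::write.csv(df3, bad, row.names = FALSE)
  expect_error(load_tabular_features(bad), class = "rawms_validation_error")
})
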
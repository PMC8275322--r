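#' Describe an image encoder
#'
#' An encoder ingests a prepared S x S x 3 image and emits a fixed-length
#' feature vector of dimension D. Pretrained convolutional networks used as
#' off-the-shelf feature extractors fit this contract (input sizes such as
#' 224, 299 or 331 and output dimensions such as 512-2048); so does the
#' built-in deterministic [reference_encoder()].
#'
#' @param name encoder name.
#' @param input_size square input side S (>= 8).
#' @param output_dim feature dimension D (>= 1).
#' @param pixel_scaling `"unit_interval"` (pixels in `[0, 1]`) or
#'   `"symmetric_unit"` (rescaled to `[-1, 1]`); pretrained families differ
#'   in which they expect.
#' @return An object of class `rawms_encoder_spec`.
#' @export
encoder_spec <- function(name, input_size, output_dim,
                         pixel_scaling = c("unit_interval", "symmetric_unit")) {
  pixel_scaling <- match.arg(pixel_scaling)
  input_size <- as.integer(input_size)
  output_dim <- as.integer(output_dim)
  stopifnot(input_size >= 8L, output_dim >= 1L)
  structure(
    list(name = name, input_size = input_size, output_dim = output_dim,
         pixel_scaling = pixel_scaling),
    class = "rawms_encoder_spec"
  )
}

# interpolation weights for one axis of a bilinear resize, half-pixel-center
# (align-corners-false) convention: out pixel i samples source coordinate
# (i + 0.5) * n_in/n_out - 0.5, clamped to the valid range
bilinear_weights <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  hi <- pmin(lo + 1, n_in - 1)
  frac <- pos - lo
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
  idx <- cbind(seq_len(n_out), hi + 1)
  W[idx] <- W[idx] + frac
  W
}

#' Bilinearly resize a matrix
#'
#' Separable bilinear interpolation under the half-pixel-center
#' (align-corners-false) convention. Constant inputs resize to the same
#' constant; values stay within the input's range (convex combinations).
#'
#' @param m numeric matrix.
#' @param out_rows,out_cols output dimensions.
#' @return An `out_rows` x `out_cols` matrix.
#' @export
bilinear_resize <- function(m, out_rows, out_cols) {
  Wr <- bilinear_weights(nrow(m), out_rows)
  Wc <- bilinear_weights(ncol(m), out_cols)
  Wr %*% m %*% t(Wc)
}

#' Prepare a raster grid as encoder input
#'
#' The image-preparation chain applied before any encoder: optional
#' intensity transform, per-image max normalization to `[0, 1]` (an all-zero
#' grid stays zero), bilinear resize from G x G to the encoder's S x S, and
#' triplication of the single gray channel into three identical RGB channels.
#' For `symmetric_unit` encoders the pixels are then mapped to `[-1, 1]`.
#'
#' @param grid a `rawms_raster_grid` (or plain matrix).
#' @param spec an [encoder_spec()].
#' @param transform `"linear_max"` or `"log1p_then_linear"`.
#' @return An S x S x 3 array of class `rawms_encoder_input`.
#' @export
prepare_image <- function(grid, spec,
                          transform = c("linear_max", "log1p_then_linear")) {
  transform <- match.arg(transform)
  stopifnot(inherits(spec, "rawms_encoder_spec"))
  v <- unclass(grid)
  attributes(v) <- list(dim = dim(grid))
  if (transform == "log1p_then_linear") v <- log1p(v)
  m <- max(v)
  if (m > 0) v <- v / m
  S <- spec$input_size
  ch <- bilinear_resize(v, S, S)
  if (spec$pixel_scaling == "symmetric_unit") ch <- 2 * ch - 1
  structure(array(ch, dim = c(S, S, 3L)), class = "rawms_encoder_input")
}

#' Built-in deterministic reference encoder
#'
#' A fully reproducible encoder used wherever a pretrained network is not:
#' it mean-pools the prepared image's first channel into P x P blocks,
#' flattens the pooled map, and applies a fixed random linear projection to
#' D dimensions. The projection is drawn once from `seed`, so the same seed
#' yields the same encoder forever; the encoding is a linear map of the
#' pooled image.
#'
#' @param seed integer; determines the projection.
#' @param output_dim feature dimension D.
#' @param pool pooling grid side P; must divide `input_size`.
#' @param input_size working image side S (default 64).
#' @param pixel_scaling passed to [encoder_spec()].
#' @return An object of class `rawms_encoder`: a list with elements `spec`
#'   and `encode` (a function from `rawms_encoder_input` to a numeric
#'   vector of length D).
#' @export
#' @examples
#' enc <- reference_encoder(seed = 0, output_dim = 32)
#' img <- prepare_image(matrix(1:16, 4), enc$spec)
#' length(enc$encode(img))
reference_encoder <- function(seed, output_dim = 256L, pool = 16L,
                              input_size = 64L,
                              pixel_scaling = "unit_interval") {
  output_dim <- as.integer(output_dim)
  pool <- as.integer(pool)
  input_size <- as.integer(input_size)
  stopifnot(output_dim >= 1L)
  if (input_size %% pool != 0L) {
    rawms_stop("rawms_validation_error",
               "pool (%d) must divide input_size (%d)", pool, input_size)
  }
  proj <- with_seed(seed, matrix(stats::rnorm(pool * pool * output_dim),
                                 nrow = pool * pool, ncol = output_dim) /
                      sqrt(pool * pool))
  spec <- encoder_spec(sprintf("reference_p%d_d%d_s%d", pool, output_dim, seed),
                       input_size = input_size, output_dim = output_dim,
                       pixel_scaling = pixel_scaling)
  f <- input_size %/% pool
  encode <- function(input) {
    ch <- input[, , 1]
    pooled <- t(rowsum(t(rowsum(ch, rep(seq_len(pool), each = f))),
                       rep(seq_len(pool), each = f))) / (f * f)
    as.numeric(as.vector(pooled) %*% proj)
  }
  structure(list(spec = spec, encode = encode), class = "rawms_encoder")
}

#' Encode a raster grid into a feature vector
#'
#' Runs the preparation chain for the encoder's spec and applies the
#' encoder. Deterministic whenever the encoder is.
#'
#' @param grid a `rawms_raster_grid`.
#' @param encoder a `rawms_encoder`.
#' @param transform intensity transform for [prepare_image()].
#' @return A `rawms_feature_vector`: list with `values` (length D),
#'   `encoder_name` and `source`.
#' @export
encode_grid <- function(grid, encoder,
                        transform = c("linear_max", "log1p_then_linear")) {
  transform <- match.arg(transform)
  stopifnot(inherits(encoder, "rawms_encoder"))
  src <- attr(grid, "source")
  if (is.null(src)) src <- "unknown"
  input <- prepare_image(grid, encoder$spec, transform)
  values <- tryCatch(
    encoder$encode(input),
    error = function(e) {
      rawms_stop("rawms_encoder_error", "encoder '%s' failed on grid '%s': %s",
                 encoder$spec$name, src, conditionMessage(e))
    }
  )
  if (length(values) != encoder$spec$output_dim || !all(is.finite(values))) {
    rawms_stop("rawms_encoder_error",
               "encoder '%s' returned an invalid vector for grid '%s'",
               encoder$spec$name, src)
  }
  structure(list(values = as.numeric(values),
                 encoder_name = encoder$spec$name, source = src),
            class = "rawms_feature_vector")
}

# registry for external encoder backends (e.g. a plugin bridging to an
# on-disk pretrained model); keyed by URI scheme
encoder_backends <- new.env(parent = emptyenv())

#' Register an external encoder backend
#'
#' A backend is a loader function `function(uri, spec)` returning an
#' encoding function (prepared image -> numeric vector). Registering a
#' backend makes `load_external_encoder("scheme://...")` work for that
#' scheme.
#'
#' @param scheme URI scheme, e.g. `"tfhub"`.
#' @param loader loader function.
#' @export
register_encoder_backend <- function(scheme, loader) {
  stopifnot(is.character(scheme), is.function(loader))
  assign(scheme, loader, envir = encoder_backends)
  invisible(NULL)
}

#' Load an external (pretrained) encoder through a registered backend
#'
#' Pretrained networks are optional plugins: no weights ship with the
#' package, and the pipeline is fully usable with [reference_encoder()].
#' The loaded model's output dimension is validated against the declared
#' spec on first use.
#'
#' @param uri backend URI, `"scheme://..."`.
#' @param spec the declared [encoder_spec()] for the model.
#' @return A `rawms_encoder`.
#' @export
load_external_encoder <- function(uri, spec) {
  stopifnot(inherits(spec, "rawms_encoder_spec"))
  scheme <- sub("://.*$", "", uri)
  if (!nzchar(scheme) || identical(scheme, uri) ||
      !exists(scheme, envir = encoder_backends)) {
    rawms_stop("rawms_optional_dependency_error",
               paste0("no encoder backend registered for '%s'; external ",
                      "encoders are an optional plugin - use ",
                      "reference_encoder() or register_encoder_backend()"),
               uri)
  }
  loader <- get(scheme, envir = encoder_backends)
  raw_fn <- loader(uri, spec)
  encode <- function(input) {
    v <- raw_fn(input)
    if (length(v) != spec$output_dim) {
      rawms_stop("rawms_spec_error",
                 "encoder '%s' produced %d values but its spec declares output_dim %d",
                 spec$name, length(v), spec$output_dim)
    }
    as.numeric(v)
  }
  structure(list(spec = spec, encode = encode), class = "rawms_encoder")
}
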
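#' Rasterization configuration
#'
#' Parameters controlling how a scan series is binned into a fixed grid:
#' grid side length G (512 and 2048 are the two standard choices), the fixed
#' m/z axis (0-2000 Th, so MS1 content at 400-1249 Th sits in the interior
#' with implicit black padding on both sides) and the retention-time
#' normalization policy.
#'
#' @param grid_size integer G >= 2; the grid is G x G.
#' @param mz_range m/z axis bounds in Th; fixed at `c(0, 2000)` by default so
#'   one pipeline covers both MS1 and MS2 spectra.
#' @param rt_policy `"per_run_minmax"` (map each series' observed RT span
#'   onto the grid) or `"fixed_duration"` (map `[rt_start, rt_start +
#'   rt_duration]`).
#' @param rt_duration duration in seconds, required for `"fixed_duration"`.
#' @param rt_start start of the fixed RT axis in seconds (default 0).
#' @return An object of class `rawms_raster_config`.
#' @export
raster_config <- function(grid_size = 512L, mz_range = c(0, 2000),
                          rt_policy = c("per_run_minmax", "fixed_duration"),
                          rt_duration = NULL, rt_start = 0) {
  rt_policy <- match.arg(rt_policy)
  grid_size <- as.integer(grid_size)
  stopifnot(grid_size >= 2L, length(mz_range) == 2L, mz_range[1] < mz_range[2])
  if (rt_policy == "fixed_duration" && (is.null(rt_duration) || rt_duration <= 0)) {
    rawms_stop("rawms_validation_error",
               "rt_policy 'fixed_duration' requires a positive rt_duration")
  }
  structure(
    list(grid_size = grid_size, mz_range = as.double(mz_range),
         rt_policy = rt_policy, rt_duration = rt_duration,
         rt_start = as.double(rt_start)),
    class = "rawms_raster_config"
  )
}

#' Map m/z values to 0-based grid columns
#'
#' Bins are half-open `[lo, hi)` tiles of the m/z axis; the top edge is
#' closed so the full range is covered without overlap:
#' `floor((mz - min) / span * G)`, with `mz == max` clamped to `G - 1`.
#'
#' @param mz numeric vector of m/z values (Th) within the configured range.
#' @param config a [raster_config()].
#' @return Integer vector of 0-based column indices.
#' @export
#' @examples
#' cfg <- raster_config(512)
#' mz_to_bin(c(0, 400, 2000), cfg)  # 0, 102, 511
mz_to_bin <- function(mz, config) {
  lo <- config$mz_range[1]; hi <- config$mz_range[2]
  if (any(mz < lo | mz > hi)) {
    rawms_stop("rawms_range_error", "m/z outside [%g, %g]", lo, hi)
  }
  G <- config$grid_size
  pmin(as.integer(floor((mz - lo) / (hi - lo) * G)), G - 1L)
}

#' Map retention times to 0-based grid rows
#'
#' Linear mapping of `[rt_min, rt_max]` onto the G rows (half-open bins, top
#' edge clamped into the last row), which scales every series to a uniform
#' duration regardless of its own length.
#'
#' @param rt numeric vector of retention times, seconds.
#' @param rt_min,rt_max the RT axis bounds, `rt_min < rt_max`.
#' @param config a [raster_config()].
#' @return Integer vector of 0-based row indices.
#' @export
rt_to_bin <- function(rt, rt_min, rt_max, config) {
  if (rt_min >= rt_max) {
    rawms_stop("rawms_degenerate_run", "degenerate RT axis: rt_min >= rt_max")
  }
  if (any(rt < rt_min | rt > rt_max)) {
    rawms_stop("rawms_range_error", "RT outside [%g, %g]", rt_min, rt_max)
  }
  G <- config$grid_size
  pmin(as.integer(floor((rt - rt_min) / (rt_max - rt_min) * G)), G - 1L)
}

rt_axis_for_series <- function(scans, config) {
  if (config$rt_policy == "fixed_duration") {
    c(config$rt_start, config$rt_start + config$rt_duration)
  } else {
    rts <- vapply(scans, function(s) s$rt, 0)
    c(min(rts), max(rts))
  }
}

#' Rasterize one scan series into a G x G intensity grid
#'
#' Every recorded (RT, m/z, intensity) point is assigned to one cell (rows =
#' RT bins ascending, columns = m/z bins ascending); a cell's value is the
#' arithmetic mean of the intensities of the points assigned to it, and
#' cells receiving no points are zero. Empty cells are not included in any
#' average, which keeps regions without recorded signal exactly black.
#'
#' A series whose scans all share one retention time collapses onto row 0
#' (there is no time axis to spread over).
#'
#' @param scans nonempty list of `rawms_scan`s.
#' @param config a [raster_config()].
#' @param source label for provenance, e.g. `"MS1"` or `"MS2_w3"`.
#' @return A `rawms_raster_grid`: a G x G numeric matrix with attributes
#'   `source` and `config`.
#' @export
rasterize_series <- function(scans, config, source = "MS1") {
  if (length(scans) == 0) {
    rawms_stop("rawms_validation_error", "cannot rasterize an empty scan series")
  }
  G <- config$grid_size
  npts <- vapply(scans, function(s) length(s$mz), 0L)
  mz <- unlist(lapply(scans, function(s) s$mz), use.names = FALSE)
  intensity <- unlist(lapply(scans, function(s) s$intensity), use.names = FALSE)
  rt <- rep(vapply(scans, function(s) s$rt, 0), npts)

  vals <- matrix(0, nrow = G, ncol = G)
  if (length(mz) > 0) {
    axis <- rt_axis_for_series(scans, config)
    col <- mz_to_bin(mz, config)
    row <- if (axis[1] < axis[2]) rt_to_bin(rt, axis[1], axis[2], config) else 0L
    cell <- row + as.double(col) * G   # 0-based linear index, column-major
    sums <- rowsum(intensity, cell)
    cnts <- rowsum(rep(1, length(cell)), cell)
    idx <- as.double(rownames(sums)) + 1
    vals[idx] <- sums / cnts
  }
  structure(vals, source = source, config = config,
            class = c("rawms_raster_grid", class(vals)))
}

#' Rasterize a whole run
#'
#' Produces `1 + K` grids in canonical order: the MS1 grid first, then one
#' grid per MS2 isolation window ascending by lower bound. All grids share
#' the full 0-2000 Th m/z axis; the RT axis is normalized per scan series
#' under the configured policy.
#'
#' @param run a `rawms_run`.
#' @param config a [raster_config()].
#' @return Named list of `rawms_raster_grid`s (`"MS1"`, `"MS2_w0"`, ...).
#' @export
rasterize_run <- function(run, config = raster_config()) {
  stopifnot(inherits(run, "rawms_run"))
  K <- length(run$ms2_series)
  grids <- vector("list", 1L + K)
  names(grids) <- c("MS1", if (K) sprintf("MS2_w%d", seq_len(K) - 1L))
  grids[[1]] <- rasterize_series(run$ms1_scans, config, source = "MS1")
  for (w in seq_len(K)) {
    grids[[1L + w]] <- rasterize_series(run$ms2_series[[w]], config,
                                        source = sprintf("MS2_w%d", w - 1L))
  }
  grids
}

#' Export a grid to disk
#'
#' `"array"` writes the raw doubles (lossless; see [import_grid()]). The PNG
#' modes rescale by the per-image maximum after the chosen intensity
#' transform, so the brightest cell maps to full white; an all-zero grid
#' exports as an all-black image.
#'
#' @param grid a `rawms_raster_grid`.
#' @param path output file path.
#' @param mode `"array"`, `"png8"` or `"png16"`.
#' @param transform `"linear_max"` (identity) or `"log1p_then_linear"`
#'   (log1p dynamic-range compression before scaling).
#' @export
export_grid <- function(grid, path, mode = c("array", "png8", "png16"),
                        transform = c("linear_max", "log1p_then_linear")) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (!dir.exists(dirname(path))) {
    rawms_stop("rawms_io_error", "directory does not exist: %s", dirname(path))
  }
  G <- nrow(grid)
  if (mode == "array") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(c(G, ncol(grid))), con, size = 4L, endian = "little")
    writeBin(as.double(grid), con, size = 8L, endian = "little")
    return(invisible(NULL))
  }
  v <- unclass(grid)
  attributes(v) <- list(dim = dim(grid))
  if (transform == "log1p_then_linear") v <- log1p(v)
  m <- max(v)
  if (m > 0) v <- v / m
  if (mode == "png8") {
    png::writePNG(v, target = path)
  } else {
    write_png16_gray(v, path)
  }
  invisible(NULL)
}

# CRC32 lookup table (IEEE 802.3 polynomial), built once at load time
crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320 as signed int
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes, crc = -1L) {
  b <- as.integer(bytes)
  for (x in b) {
    crc <- bitwXor(bitwAnd(bitwShiftR(crc, 8L), 16777215L),
                   crc32_table[bitwAnd(bitwXor(crc, x), 255L) + 1L])
  }
  crc
}

uint32_be <- function(x) {
  # x may arrive as a signed 32-bit int; emit its 4 bytes big-endian
  x <- as.double(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- bitwXor(crc32(body), -1L)
  c(uint32_be(length(data)), body, uint32_be(crc))
}

# Minimal 16-bit grayscale PNG writer: values in [0,1], row-major matrix.
# Needed because the installed PNG bindings only emit 8-bit grayscale.
write_png16_gray <- function(v, path) {
  h <- nrow(v); w <- ncol(v)
  q <- round(pmin(pmax(v, 0), 1) * 65535)
  # scanlines: filter byte 0 then big-endian uint16 pixels, rows top to bottom
  hi <- as.raw(t(q) %/% 256)
  lo <- as.raw(t(q) %% 256)
  px <- as.raw(rbind(hi, lo))            # interleave high/low byte per pixel
  dim(px) <- NULL
  rows <- matrix(px, nrow = 2L * w)      # one column per scanline
  raw_data <- as.raw(rbind(matrix(as.raw(0), 1L, h), rows))
  dim(raw_data) <- NULL
  idat <- memCompress(raw_data, type = "gzip")  # zlib (RFC1950) stream
  ihdr <- c(uint32_be(w), uint32_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))    # 16-bit, grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(NULL)
}

#' Read back a grid written by `export_grid(mode = "array")`
#'
#' @param path file written by [export_grid()].
#' @return A numeric matrix with the exact stored values.
#' @export
import_grid <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  vals <- readBin(con, "double", n = dims[1] * dims[2], size = 8L,
                  endian = "little")
  matrix(vals, nrow = dims[1], ncol = dims[2])
}
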
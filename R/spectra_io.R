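#' Construct a single mass-spectrometry scan
#'
#' A scan is one spectrum acquired at a fixed retention time: a set of
#' (m/z, intensity) points, at MS level 1 (precursor survey) or 2 (fragments
#' of one precursor isolation window).
#'
#' @param ms_level 1 or 2.
#' @param rt retention time in seconds.
#' @param mz numeric vector of m/z values (Thomson), strictly increasing.
#' @param intensity numeric vector of nonnegative intensities, same length
#'   as `mz`.
#' @param precursor_window for MS2 scans, the isolation window as
#'   `c(lower, upper)` m/z bounds; must be `NULL` for MS1.
#' @return An object of class `rawms_scan`.
#' @export
#' @examples
#' new_scan(1, rt = 10, mz = c(450, 500), intensity = c(3, 8))
new_scan <- function(ms_level, rt, mz, intensity, precursor_window = NULL) {
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% c(1L, 2L)) {
    rawms_stop("rawms_validation_error", "ms_level must be 1 or 2, got %d", ms_level)
  }
  mz <- as.double(mz)
  intensity <- as.double(intensity)
  if (length(mz) != length(intensity)) {
    rawms_stop("rawms_validation_error",
               "mz and intensity lengths differ (%d vs %d)",
               length(mz), length(intensity))
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    rawms_stop("rawms_validation_error", "mz must be strictly increasing")
  }
  if (any(intensity < 0)) {
    rawms_stop("rawms_validation_error", "intensities must be nonnegative")
  }
  if (ms_level == 2L) {
    if (is.null(precursor_window) || length(precursor_window) != 2L ||
        precursor_window[1] >= precursor_window[2]) {
      rawms_stop("rawms_validation_error",
                 "MS2 scan requires precursor_window = c(lower, upper) with lower < upper")
    }
    precursor_window <- as.double(precursor_window)
  } else if (!is.null(precursor_window)) {
    rawms_stop("rawms_validation_error", "MS1 scan must not carry a precursor window")
  }
  structure(
    list(ms_level = ms_level, rt = as.double(rt), mz = mz,
         intensity = intensity, precursor_window = precursor_window),
    class = "rawms_scan"
  )
}

#' Construct a window scheme
#'
#' The ordered list of precursor isolation windows of a SWATH acquisition.
#'
#' @param lower,upper numeric vectors of window bounds (Th); `lower < upper`
#'   elementwise. Windows are stored sorted by ascending lower bound.
#' @return A data.frame of class `rawms_window_scheme` with columns
#'   `lower`, `upper`.
#' @export
window_scheme <- function(lower, upper) {
  lower <- as.double(lower); upper <- as.double(upper)
  if (length(lower) != length(upper)) {
    rawms_stop("rawms_validation_error", "lower/upper length mismatch")
  }
  if (any(lower >= upper)) {
    rawms_stop("rawms_validation_error", "every window needs lower < upper")
  }
  ord <- order(lower, upper)
  structure(data.frame(lower = lower[ord], upper = upper[ord]),
            class = c("rawms_window_scheme", "data.frame"))
}

#' Construct an in-memory SWATH run
#'
#' One sample's acquisition: an MS1 scan series plus one MS2 scan series per
#' isolation window. MS2 series are indexed in ascending order of window
#' lower bound; that order is the canonical concatenation order used by the
#' feature-assembly stage.
#'
#' @param run_id character sample identifier.
#' @param ms1_scans list of MS1 `rawms_scan`s, RT-nondecreasing.
#' @param ms2_series list (one element per window, ascending lower bound) of
#'   lists of MS2 `rawms_scan`s, RT-nondecreasing within each series.
#' @param scheme a `rawms_window_scheme`; each MS2 scan's precursor window
#'   must match its scheme entry to within 1e-6 Th.
#' @return An object of class `rawms_run`.
#' @export
new_run <- function(run_id, ms1_scans, ms2_series, scheme) {
  stopifnot(inherits(scheme, "rawms_window_scheme"))
  if (length(ms1_scans) == 0) {
    rawms_stop("rawms_validation_error", "run '%s': empty MS1 series", run_id)
  }
  if (length(ms2_series) != nrow(scheme)) {
    rawms_stop("rawms_validation_error",
               "run '%s': %d MS2 series but %d windows in scheme",
               run_id, length(ms2_series), nrow(scheme))
  }
  check_series <- function(scans, what) {
    if (length(scans) == 0) {
      rawms_stop("rawms_validation_error", "run '%s': empty %s series", run_id, what)
    }
    rts <- vapply(scans, function(s) s$rt, 0)
    if (is.unsorted(rts)) {
      rawms_stop("rawms_validation_error",
                 "run '%s': %s series not RT-nondecreasing", run_id, what)
    }
  }
  check_series(ms1_scans, "MS1")
  for (w in seq_along(ms2_series)) {
    check_series(ms2_series[[w]], sprintf("MS2 window %d", w - 1L))
    for (s in ms2_series[[w]]) {
      if (max(abs(s$precursor_window - c(scheme$lower[w], scheme$upper[w]))) > 1e-6) {
        rawms_stop("rawms_validation_error",
                   "run '%s': MS2 scan window (%.4f, %.4f) does not match scheme window %d (%.4f, %.4f)",
                   run_id, s$precursor_window[1], s$precursor_window[2],
                   w - 1L, scheme$lower[w], scheme$upper[w])
      }
    }
  }
  structure(
    list(run_id = run_id, ms1_scans = ms1_scans, ms2_series = ms2_series,
         window_scheme = scheme),
    class = "rawms_run"
  )
}

#' @export
print.rawms_run <- function(x, ...) {
  rts <- vapply(x$ms1_scans, function(s) s$rt, 0)
  cat(sprintf("<rawms_run> '%s'\n", x$run_id))
  cat(sprintf("  MS1: %d scans, RT %.1f-%.1f s\n",
              length(x$ms1_scans), min(rts), max(rts)))
  cat(sprintf("  MS2: %d isolation windows (%.1f-%.1f Th)\n",
              nrow(x$window_scheme), min(x$window_scheme$lower),
              max(x$window_scheme$upper)))
  invisible(x)
}

#' Read a raw run from mzML or mzXML
#'
#' Parses the file with the `mzR` backend, partitions scans by MS level,
#' groups MS2 scans by precursor isolation window (windows indexed ascending
#' by lower bound) and returns the uniform in-memory run model. Retention
#' times are in seconds regardless of the file's unit.
#'
#' @param path path to an mzML or mzXML file.
#' @param format `"auto"` (default, from the parser), `"mzML"` or `"mzXML"`;
#'   the named formats are accepted for interface symmetry with
#'   [write_run()] — the backend sniffs the actual content either way.
#' @param run_id run identifier; defaults to the file name without extension.
#' @return A `rawms_run`.
#' @seealso [write_run()], [validate_window_scheme()]
#' @export
read_run <- function(path, format = c("auto", "mzML", "mzXML"), run_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rawms_stop("rawms_io_error", "file not found: %s", path)
  }
  ms <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) {
      rawms_stop("rawms_format_error", "cannot parse '%s' as mzML/mzXML: %s",
                 path, conditionMessage(e))
    }
  )
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0) {
    rawms_stop("rawms_validation_error", "empty run: '%s' contains no spectra", path)
  }
  pks <- mzR::peaks(ms)
  if (nrow(hdr) == 1L) pks <- list(pks)

  make_scan <- function(i, win = NULL) {
    p <- pks[[i]]
    mzv <- p[, 1]; iv <- p[, 2]
    if (length(mzv) > 1 && is.unsorted(mzv, strictly = TRUE)) {
      ord <- order(mzv)
      mzv <- mzv[ord]; iv <- iv[ord]
    }
    new_scan(hdr$msLevel[i], hdr$retentionTime[i], mzv, iv, precursor_window = win)
  }

  ms1_idx <- which(hdr$msLevel == 1L)
  ms2_idx <- which(hdr$msLevel == 2L)
  ms1_idx <- ms1_idx[order(hdr$retentionTime[ms1_idx])]
  ms1_scans <- lapply(ms1_idx, make_scan)

  if (length(ms2_idx) > 0) {
    tgt <- hdr$isolationWindowTargetMZ[ms2_idx]
    # mzXML carries the window as precursorMz +/- windowWideness/2; the parser
    # surfaces the offsets but leaves the target column empty
    tgt[is.na(tgt)] <- hdr$precursorMZ[ms2_idx][is.na(tgt)]
    lo_off <- hdr$isolationWindowLowerOffset[ms2_idx]
    hi_off <- hdr$isolationWindowUpperOffset[ms2_idx]
    if (anyNA(tgt) || anyNA(lo_off) || anyNA(hi_off)) {
      bad <- ms2_idx[which(is.na(tgt) | is.na(lo_off) | is.na(hi_off))[1]]
      rawms_stop("rawms_validation_error",
                 "MS2 scan %d in '%s' lacks precursor isolation window metadata",
                 bad, path)
    }
    wlo <- tgt - lo_off
    whi <- tgt + hi_off
    # group identical windows (exact match after the parser's float decode)
    key <- paste(signif(wlo, 10), signif(whi, 10))
    ukey <- unique(key)
    ulo <- wlo[match(ukey, key)]
    uhi <- whi[match(ukey, key)]
    ord <- order(ulo, uhi)
    scheme <- window_scheme(ulo[ord], uhi[ord])
    widx <- match(key, ukey[ord])
    ms2_series <- vector("list", nrow(scheme))
    for (w in seq_len(nrow(scheme))) {
      sel <- which(widx == w)
      sel <- sel[order(hdr$retentionTime[ms2_idx][sel])]
      ms2_series[[w]] <- lapply(sel, function(j) {
        make_scan(ms2_idx[j], win = c(scheme$lower[w], scheme$upper[w]))
      })
    }
  } else {
    scheme <- window_scheme(numeric(0), numeric(0))
    ms2_series <- list()
  }

  if (is.null(run_id)) {
    run_id <- sub("\\.(mzML|mzXML|mzml|mzxml)$", "", basename(path))
  }
  if (length(ms2_series) == 0) {
    # MS1-only runs are legal: an empty scheme with no MS2 series
    structure(
      list(run_id = run_id, ms1_scans = ms1_scans, ms2_series = list(),
           window_scheme = scheme),
      class = "rawms_run"
    )
  } else {
    new_run(run_id, ms1_scans, ms2_series, scheme)
  }
}

#' Check that several runs share one isolation-window scheme
#'
#' Cross-run feature concatenation is only meaningful when every run was
#' acquired with the same window scheme; this verifies that (within an m/z
#' tolerance, since files may store bounds at different precisions) and
#' returns the shared scheme.
#'
#' @param runs list of `rawms_run`s.
#' @param tol m/z tolerance in Th for bound comparison (default 0.01).
#' @return The shared `rawms_window_scheme` (taken from the first run).
#' @export
validate_window_scheme <- function(runs, tol = 0.01) {
  stopifnot(length(runs) >= 1)
  ref <- runs[[1]]$window_scheme
  for (r in runs[-1]) {
    sc <- r$window_scheme
    if (nrow(sc) != nrow(ref)) {
      rawms_stop("rawms_scheme_mismatch",
                 "run '%s' has %d windows; expected %d (as in run '%s')",
                 r$run_id, nrow(sc), nrow(ref), runs[[1]]$run_id)
    }
    if (nrow(ref) > 0 &&
        max(abs(sc$lower - ref$lower), abs(sc$upper - ref$upper)) > tol) {
      rawms_stop("rawms_scheme_mismatch",
                 "run '%s' window bounds deviate from run '%s' by more than %g Th",
                 r$run_id, runs[[1]]$run_id, tol)
    }
  }
  ref
}

#' Write a run to mzML or mzXML
#'
#' Emits a standard-conformant file (centroided spectra, 64-bit float arrays)
#' that [read_run()] parses back to an equivalent run. Scans are written as
#' the MS1 series followed by each MS2 window series in canonical order;
#' grouping on re-read is by MS level and isolation window, so file order is
#' immaterial.
#'
#' @param run a `rawms_run`.
#' @param path output file path.
#' @param format `"mzML"` (default) or `"mzXML"`.
#' @export
write_run <- function(run, path, format = c("mzML", "mzXML")) {
  format <- match.arg(format)
  stopifnot(inherits(run, "rawms_run"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    rawms_stop("rawms_io_error", "directory does not exist: %s", dir)
  }

  scans <- run$ms1_scans
  wins <- rep(list(NULL), length(scans))
  for (w in seq_along(run$ms2_series)) {
    scans <- c(scans, run$ms2_series[[w]])
    wins <- c(wins, lapply(run$ms2_series[[w]], function(s) s$precursor_window))
  }
  n <- length(scans)
  tgt <- vapply(wins, function(w) if (is.null(w)) NA_real_ else mean(w), 0)
  lo_off <- vapply(wins, function(w) if (is.null(w)) NA_real_ else mean(w) - w[1], 0)
  hi_off <- vapply(wins, function(w) if (is.null(w)) NA_real_ else w[2] - mean(w), 0)

  npts <- vapply(scans, function(s) length(s$mz), 0L)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(scans, function(s) s$ms_level, 0L),
    polarity = rep(1L, n), peaksCount = npts,
    totIonCurrent = vapply(scans, function(s) sum(s$intensity), 0),
    retentionTime = vapply(scans, function(s) s$rt, 0),
    basePeakMZ = vapply(scans, function(s) {
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0
    }, 0),
    basePeakIntensity = vapply(scans, function(s) {
      if (length(s$intensity)) max(s$intensity) else 0
    }, 0),
    collisionEnergy = ifelse(is.na(tgt), 0, 25),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(scans, function(s) if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(scans, function(s) if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = rep(0L, n),
    precursorMZ = ifelse(is.na(tgt), 0, tgt),
    precursorCharge = ifelse(is.na(tgt), 0L, 2L),
    precursorIntensity = ifelse(is.na(tgt), 0, 100),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = tgt,
    isolationWindowLowerOffset = lo_off,
    isolationWindowUpperOffset = hi_off,
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n)
  )
  pks <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, file = path, header = hdr,
                   outformat = tolower(format), rtime_seconds = TRUE)
  invisible(NULL)
}
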
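# Centroided LC-MS data model: spectra, runs, mzML I/O (through mzR) and
# extracted ion chromatograms with ppm tolerance.
#
# Retention times are minutes throughout. Scan functions follow the
# three-scan acquisition the workflow relies on: full MS ("full"),
# all-ion fragmentation ("aif", MS2 with no selected precursor / full-range
# isolation) and targeted MS/MS ("targeted_msms").

.SCAN_FUNCTIONS <- c("full", "aif", "targeted_msms")

#' Construct a single centroided spectrum
#'
#' @param scan_id Scan identifier (string).
#' @param time Retention time in minutes.
#' @param ms_level 1 or 2.
#' @param scan_function One of `"full"`, `"aif"`, `"targeted_msms"`.
#' @param mz,intensity Parallel numeric vectors of centroided peaks;
#'   stored sorted ascending by m/z.
#' @param precursor_mz Selected precursor m/z for targeted MS/MS, else `NA`.
#' @return Object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(scan_id, time, ms_level, scan_function,
                        mz = numeric(), intensity = numeric(),
                        precursor_mz = NA_real_) {
  scan_function <- match.arg(scan_function, .SCAN_FUNCTIONS)
  stopifnot(length(mz) == length(intensity), time >= 0,
            all(intensity >= 0), ms_level %in% c(1L, 2L))
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  structure(
    list(scan_id = as.character(scan_id), time = as.numeric(time),
         ms_level = as.integer(ms_level), scan_function = scan_function,
         precursor_mz = as.numeric(precursor_mz),
         mz = as.numeric(mz), intensity = as.numeric(intensity)),
    class = "ms_spectrum"
  )
}

#' Construct an LC-MS run
#'
#' @param spectra List of [ms_spectrum()] objects; stored ordered by
#'   retention time (stable for ties).
#' @param source Source description (e.g. file path).
#' @param polarity `"positive"` or `"negative"`.
#' @return Object of class `ms_run`.
#' @export
ms_run <- function(spectra, source = NA_character_, polarity = "positive") {
  stopifnot(all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
  times <- vapply(spectra, `[[`, numeric(1), "time")
  spectra <- spectra[order(times)]
  structure(list(spectra = spectra, source = source, polarity = polarity),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  sf <- vapply(x$spectra, `[[`, character(1), "scan_function")
  cat(sprintf("LC-MS run: %d spectra", length(x$spectra)))
  if (length(sf)) {
    tab <- table(factor(sf, levels = .SCAN_FUNCTIONS))
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
    rng <- range(vapply(x$spectra, `[[`, numeric(1), "time"))
    cat(sprintf("\n  RT %.2f - %.2f min", rng[1], rng[2]))
  }
  if (!is.na(x$source)) cat("\n  source:", x$source)
  cat("\n")
  invisible(x)
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("%s scan %s @ %.3f min: %d peaks", x$scan_function, x$scan_id,
              x$time, length(x$mz)))
  if (!is.na(x$precursor_mz)) cat(sprintf(" (precursor m/z %.4f)", x$precursor_mz))
  cat("\n")
  invisible(x)
}

.run_times <- function(run) vapply(run$spectra, `[[`, numeric(1), "time")
.run_functions <- function(run) {
  vapply(run$spectra, `[[`, character(1), "scan_function")
}

# naive local-maxima centroiding for profile spectra
.centroid_peaks <- function(mzv, intv) {
  n <- length(mzv)
  if (n < 3L) return(list(mz = mzv[intv > 0], intensity = intv[intv > 0]))
  keep <- which(intv[2:(n - 1L)] > intv[1:(n - 2L)] &
                  intv[2:(n - 1L)] >= intv[3:n]) + 1L
  list(mz = mzv[keep], intensity = intv[keep])
}

# isolation width >= this many m/z units (or missing precursor) => AIF
.AIF_ISOLATION_WIDTH <- 100

#' Read a centroided LC-MS run from mzML
#'
#' Scan functions are inferred from the mzML metadata: MS1 scans are
#' `"full"`; MS2 scans with a full-range isolation window (width >= 100 m/z)
#' or no selected precursor are `"aif"`; remaining MS2 scans are
#' `"targeted_msms"`. Profile-mode spectra trigger a warning and are reduced
#' by naive local-maxima centroiding.
#'
#' @param path An mzML file.
#' @return An [ms_run()].
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("malformed mzML file: ", path, " (",
                                          conditionMessage(e), ")"))
  on.exit(mzR::close(fh), add = TRUE)
  h <- tryCatch(mzR::header(fh),
                error = function(e) stop("malformed mzML file: ", path, " (",
                                         conditionMessage(e), ")"))
  if (nrow(h) == 0L) return(ms_run(list(), source = path))
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  profile <- !is.na(h$centroided) & !h$centroided
  if (any(profile)) {
    warning("profile-mode spectra detected; applying naive local-maxima centroiding")
  }
  iso_w <- h$isolationWindowLowerOffset + h$isolationWindowUpperOffset
  spectra <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    prec <- h$precursorMZ[i]
    if (!is.na(prec) && prec <= 0) prec <- NA_real_
    sf <- if (h$msLevel[i] == 1L) {
      "full"
    } else if (is.na(prec) || (!is.na(iso_w[i]) && iso_w[i] >= .AIF_ISOLATION_WIDTH)) {
      "aif"
    } else {
      "targeted_msms"
    }
    mzv <- pk[[i]][, 1L]; intv <- pk[[i]][, 2L]
    if (profile[i]) {
      cp <- .centroid_peaks(mzv, intv)
      mzv <- cp$mz; intv <- cp$intensity
    }
    spectra[[i]] <- ms_spectrum(
      scan_id = if (!is.null(h$spectrumId)) h$spectrumId[i] else as.character(h$acquisitionNum[i]),
      time = h$retentionTime[i] / 60, ms_level = h$msLevel[i],
      scan_function = sf, mz = mzv, intensity = intv,
      precursor_mz = if (sf == "targeted_msms") prec else NA_real_)
  }
  ms_run(spectra, source = path,
         polarity = if (all(h$polarity == 0, na.rm = TRUE)) "negative" else "positive")
}

#' Write a run to mzML
#'
#' Scan-function metadata is encoded so that [read_run()] recovers it: AIF
#' scans are written as MS2 with a full-range isolation window, targeted
#' scans with their selected precursor and a narrow window.
#'
#' @param run An [ms_run()].
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  n <- length(run$spectra)
  if (n == 0L) stop("cannot write an empty run to mzML")
  pk <- lapply(run$spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  sf <- .run_functions(run)
  lvl <- vapply(run$spectra, `[[`, integer(1), "ms_level")
  prec <- vapply(run$spectra, `[[`, numeric(1), "precursor_mz")
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  npk <- vapply(run$spectra, function(s) length(s$mz), integer(1))
  bp <- function(s, what) if (length(s$mz)) what(s) else 0
  iso_target <- ifelse(sf == "aif", 800, ifelse(sf == "targeted_msms", prec, NA))
  iso_off <- ifelse(sf == "aif", 700, ifelse(sf == "targeted_msms", 0.5, NA))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = if (run$polarity == "positive") 1L else 0L,
    peaksCount = npk, totIonCurrent = tic,
    retentionTime = .run_times(run) * 60,
    basePeakMZ = vapply(run$spectra, bp, numeric(1),
                        what = function(s) s$mz[which.max(s$intensity)]),
    basePeakIntensity = vapply(run$spectra, bp, numeric(1),
                               what = function(s) max(s$intensity)),
    collisionEnergy = ifelse(lvl == 2L, 30, 0),
    ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, bp, numeric(1), what = function(s) min(s$mz)),
    highMZ = vapply(run$spectra, bp, numeric(1), what = function(s) max(s$mz)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(sf == "targeted_msms", prec,
                         ifelse(sf == "aif", 800, 0)),
    precursorCharge = ifelse(sf == "targeted_msms", 1L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = vapply(run$spectra, `[[`, character(1), "scan_id"),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = iso_target,
    isolationWindowLowerOffset = iso_off,
    isolationWindowUpperOffset = iso_off,
    scanWindowLowerLimit = 100, scanWindowUpperLimit = 2000,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Extract an ion chromatogram at ppm tolerance
#'
#' Per matching scan the intensity is the sum of all peaks within the
#' symmetric ppm window around `target_mz` (computed on the target); scans
#' with no matching peak contribute zero, so the trace has one point per
#' contributing scan.
#'
#' @param run An [ms_run()].
#' @param target_mz Target m/z.
#' @param ppm_tol Window half-width in ppm (> 0).
#' @param scan_function Optional filter (`"full"`, `"aif"`,
#'   `"targeted_msms"`); `NULL` uses all scans.
#' @return Data frame of class `xic` with columns `time`, `intensity` and
#'   attributes `target_mz`, `ppm_tol`.
#' @export
extract_xic <- function(run, target_mz, ppm_tol = 5, scan_function = NULL) {
  stopifnot(inherits(run, "ms_run"), ppm_tol > 0, target_mz > 0)
  spectra <- run$spectra
  if (!is.null(scan_function)) {
    scan_function <- match.arg(scan_function, .SCAN_FUNCTIONS)
    spectra <- spectra[.run_functions(run) == scan_function]
  }
  lo <- target_mz * (1 - ppm_tol * 1e-6)
  hi <- target_mz * (1 + ppm_tol * 1e-6)
  out <- data.frame(
    time = vapply(spectra, `[[`, numeric(1), "time"),
    intensity = vapply(spectra, function(s) {
      i <- findInterval(c(lo, hi), s$mz)
      if (i[2] > i[1]) sum(s$intensity[(i[1] + 1L):i[2]]) else 0
    }, numeric(1)))
  attr(out, "target_mz") <- target_mz
  attr(out, "ppm_tol") <- ppm_tol
  class(out) <- c("xic", "data.frame")
  out
}

#' @export
plot.xic <- function(x, ...) {
  graphics::plot(x$time, x$intensity, type = "l",
                 xlab = "retention time (min)", ylab = "intensity",
                 main = sprintf("XIC m/z %.4f ± %g ppm",
                                attr(x, "target_mz"), attr(x, "ppm_tol")),
                 ...)
  invisible(x)
}

#' Detect chromatographic peaks in an XIC
#'
#' A peak is a maximal contiguous stretch of points with intensity >=
#' `min_intensity` spanning at least `min_points` points; its apex is the
#' most intense point (earliest wins on ties).
#'
#' @param xic Output of [extract_xic()].
#' @param min_intensity Intensity threshold (> 0).
#' @param min_points Minimum number of consecutive above-threshold points.
#' @return Data frame with columns `apex_time`, `apex_intensity`,
#'   `start_time`, `end_time`, `n_points`.
#' @export
find_peaks <- function(xic, min_intensity = 1, min_points = 3L) {
  stopifnot(min_intensity > 0, min_points >= 1L)
  above <- xic$intensity >= min_intensity
  empty <- data.frame(apex_time = numeric(), apex_intensity = numeric(),
                      start_time = numeric(), end_time = numeric(),
                      n_points = integer())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_points
  if (!any(keep)) return(empty)
  rows <- lapply(which(keep), function(j) {
    idx <- starts[j]:ends[j]
    apex <- idx[which.max(xic$intensity[idx])]
    data.frame(apex_time = xic$time[apex],
               apex_intensity = xic$intensity[apex],
               start_time = xic$time[starts[j]],
               end_time = xic$time[ends[j]],
               n_points = length(idx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
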
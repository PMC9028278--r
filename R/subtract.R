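# Dynamic control-scan background subtraction for AIF (or MS1) data.
#
# For every analyte scan, a range of control scans is defined by a time
# window around the analyte scan's retention time; each analyte ion is
# matched against control ions within a ppm window, and the highest matched
# control intensity, multiplied by a scaling factor, is subtracted. The
# control-window selection loops over every analyte scan, so slow drifts in
# the matrix background are tracked.

#' Background-subtraction configuration
#'
#' Defaults are the workflow's standard settings: a ±0.2 min control window,
#' ±10 ppm mass matching and a scaling factor of 2.
#'
#' @param time_window Control-scan half-window around each analyte scan, in
#'   minutes (> 0).
#' @param ppm_tol Mass-matching half-window in ppm (> 0).
#' @param scaling_factor Multiplier applied to the matched control intensity
#'   before subtraction (>= 0).
#' @param drop_nonpositive If `TRUE` (default), peaks whose subtracted
#'   intensity is <= 0 are removed; if `FALSE` they are kept clamped at 0.
#' @return A list of class `subtraction_config`.
#' @export
subtraction_config <- function(time_window = 0.2, ppm_tol = 10,
                               scaling_factor = 2, drop_nonpositive = TRUE) {
  stopifnot(time_window > 0, ppm_tol > 0, scaling_factor >= 0)
  structure(list(time_window = time_window, ppm_tol = ppm_tol,
                 scaling_factor = scaling_factor,
                 drop_nonpositive = isTRUE(drop_nonpositive)),
            class = "subtraction_config")
}

# max matched control intensity per analyte peak; cmz must be sorted
.matched_max <- function(amz, cmz, cint, ppm) {
  lo <- findInterval(amz * (1 - ppm * 1e-6), cmz)
  hi <- findInterval(amz * (1 + ppm * 1e-6), cmz)
  vapply(seq_along(amz), function(i) {
    if (hi[i] > lo[i]) max(cint[(lo[i] + 1L):hi[i]]) else 0
  }, numeric(1))
}

#' Subtract a matrix-only control run from an analyte run
#'
#' For each analyte scan at time t, control scans of the same scan function
#' within `[t - w, t + w]` are pooled; for each analyte peak, the maximum
#' control intensity within `ppm_tol` of its m/z across those scans is
#' multiplied by `scaling_factor` and subtracted. Scan times and ids are
#' preserved; no new m/z values can appear.
#'
#' @param analyte,control [ms_run()] objects acquired with the same LC
#'   method (no retention-time warping is applied).
#' @param config A [subtraction_config()].
#' @param scan_function Restrict subtraction to scans of this function
#'   (typically `"aif"`); other scans pass through unchanged. `NULL`
#'   (default) processes every scan, matching each against control scans of
#'   its own scan function.
#' @return The background-subtracted [ms_run()].
#' @export
subtract_background <- function(analyte, control,
                                config = subtraction_config(),
                                scan_function = NULL) {
  stopifnot(inherits(analyte, "ms_run"), inherits(control, "ms_run"),
            inherits(config, "subtraction_config"))
  if (!is.null(scan_function)) {
    scan_function <- match.arg(scan_function, .SCAN_FUNCTIONS)
  }
  if (length(control$spectra) == 0L) {
    warning("empty control run; analyte returned unchanged")
    return(analyte)
  }
  ctimes <- .run_times(control)
  cfuns <- .run_functions(control)
  out <- analyte
  for (i in seq_along(analyte$spectra)) {
    s <- analyte$spectra[[i]]
    if (!is.null(scan_function) && s$scan_function != scan_function) next
    if (!length(s$mz)) next
    sel <- which(cfuns == s$scan_function &
                   abs(ctimes - s$time) <= config$time_window)
    if (!length(sel)) next
    cmz <- unlist(lapply(control$spectra[sel], `[[`, "mz"))
    cint <- unlist(lapply(control$spectra[sel], `[[`, "intensity"))
    o <- order(cmz)
    bg <- .matched_max(s$mz, cmz[o], cint[o], config$ppm_tol)
    newint <- s$intensity - config$scaling_factor * bg
    if (config$drop_nonpositive) {
      keep <- newint > 0
      s$mz <- s$mz[keep]
      s$intensity <- newint[keep]
    } else {
      s$intensity <- pmax(newint, 0)
    }
    out$spectra[[i]] <- s
  }
  out
}

#' Build a control run from the other analytes' runs
#'
#' When no matrix-only control was acquired, runs of samples incubated with
#' other cyclic peptides cover the same matrix components and serve as
#' control scans. The designated control for run `index_of_analyte` is the
#' concatenation of all remaining runs, ordered by retention time.
#'
#' @param runs List of >= 2 [ms_run()] objects.
#' @param index_of_analyte Which run is the analyte.
#' @return An [ms_run()] merging the other runs.
#' @export
cross_peptide_controls <- function(runs, index_of_analyte) {
  stopifnot(is.list(runs), all(vapply(runs, inherits, logical(1), "ms_run")))
  if (length(runs) < 2L) stop("need at least two runs to build cross-peptide controls")
  stopifnot(index_of_analyte >= 1L, index_of_analyte <= length(runs))
  others <- runs[-index_of_analyte]
  ms_run(do.call(c, lapply(others, `[[`, "spectra")),
         source = "cross-peptide control",
         polarity = others[[1]]$polarity)
}
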
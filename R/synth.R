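# Synthetic LC-MS/MS run generator with known ground truth.
#
# Emulates the data shape of a soft-spot incubation experiment: a
# matrix-only control run and an analyte run sharing the exact same matrix
# background (same LC method, no retention-time drift modelled), with the
# analyte run additionally carrying hydrolyzed + 2PCA-derivatized species
# as Gaussian chromatographic peaks, AIF scans emitting the marker ion, and
# targeted MS/MS spectra containing the diagnostic doublet, b/y ladders,
# internal fragments and uniform random noise.

#' Synthetic-run configuration
#'
#' Defaults reflect a typical dilute-matrix incubation measured on a
#' high-resolution instrument: 50 matrix components of which 20% carry a
#' 2PCA-reactive N-terminus (and hence emit the marker ion), 3 ppm mass
#' jitter, 0.05 min chromatographic sigma.
#'
#' @param parent A [cyclic_peptide()].
#' @param true_opening_sites Data frame with columns `site` (opening site,
#'   see [enumerate_openings()]) and `abundance` (relative, > 0); one row
#'   per planted metabolite species.
#' @param matrix_ion_count Number of matrix background species.
#' @param matrix_pca_fraction Fraction of matrix species carrying 2PCA
#'   (these emit the marker ion in AIF too).
#' @param rt_range Retention-time span of the run (minutes).
#' @param peak_width_sigma Gaussian chromatographic sigma (minutes).
#' @param cycle_time Time between acquisition cycles (minutes); each cycle
#'   holds one full scan, one AIF scan and one targeted MS/MS scan per
#'   derivatized-target charge state.
#' @param split_peak_isomers If `TRUE`, each analyte species elutes as two
#'   peaks offset by `split_rt_offset` (the two imidazolidinone isomers,
#'   whose MS/MS spectra are indistinguishable), the later at 60% abundance.
#' @param split_rt_offset RT offset of the isomer peak (minutes).
#' @param noise_peak_count Uniform random noise peaks per MS2 spectrum.
#' @param analyte_intensity Apex MS1 intensity scale of the analyte species.
#' @param matrix_intensity_range MS1 intensity range (log-uniform) of matrix
#'   species.
#' @param marker_fraction Marker-ion intensity as a fraction of the species'
#'   apex intensity (the marker is a minor product ion, < 5-10% of base
#'   peak).
#' @param y_completeness,b_completeness Fraction of the y/b ladder planted
#'   in MS/MS spectra.
#' @param doublet_h_offset Hydrogen-transfer offset of the planted doublet.
#' @param mz_jitter_ppm Bound (ppm) on the Gaussian m/z jitter applied to
#'   every emitted peak, as a ~3-sigma envelope of the scan-to-scan mass
#'   error.
#' @param max_charge Charge states planted for the analyte precursor.
#' @param seed Integer seed; a fixed seed gives identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(parent,
                         true_opening_sites = data.frame(site = 1L,
                                                         abundance = 1),
                         matrix_ion_count = 50L,
                         matrix_pca_fraction = 0.2,
                         rt_range = c(1, 8),
                         peak_width_sigma = 0.05,
                         cycle_time = 0.05,
                         split_peak_isomers = FALSE,
                         split_rt_offset = 0.15,
                         noise_peak_count = 20L,
                         analyte_intensity = 1e6,
                         matrix_intensity_range = c(1e3, 1e5),
                         marker_fraction = 0.1,
                         y_completeness = 0.9,
                         b_completeness = 0.5,
                         doublet_h_offset = 0L,
                         mz_jitter_ppm = 3,
                         max_charge = 2L,
                         seed = 1L) {
  stopifnot(inherits(parent, "cyclic_peptide"),
            is.data.frame(true_opening_sites),
            all(c("site", "abundance") %in% names(true_opening_sites)),
            all(true_opening_sites$abundance > 0),
            matrix_pca_fraction >= 0, matrix_pca_fraction <= 1,
            rt_range[2] > rt_range[1], peak_width_sigma > 0, cycle_time > 0)
  sites <- enumerate_openings(parent)$opening_site
  bad <- setdiff(true_opening_sites$site, sites)
  if (length(bad)) {
    stop("opening site(s) out of range for this parent: ",
         paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "synth_config")
}

.gauss <- function(t, apex, sigma) exp(-((t - apex)^2) / (2 * sigma^2))

#' Generate matched analyte and control runs with ground truth
#'
#' The control run holds only the matrix species; the analyte run holds the
#' exact same matrix peaks (identical m/z and intensity, emulating perfectly
#' reproducible chromatography) plus the planted analyte species. Each
#' analyte species contributes MS1 precursor peaks, AIF marker + high-mass
#' fragment peaks, and targeted MS/MS spectra with the configured doublet,
#' partial b/y ladders, all internal fragments and noise.
#'
#' @param config A [synth_config()].
#' @return List with elements `analyte` ([ms_run()]), `control`
#'   ([ms_run()]) and `truth` (list: `species` data frame with planted site,
#'   RT apex(es) and precursor m/z; `matrix` data frame; `scan_functions`).
#' @export
simulate_runs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  k <- .CONSTANTS
  parent <- cf$parent
  candidates <- enumerate_openings(parent)
  targets <- build_target_list(parent, max_charge = cf$max_charge)
  deriv <- targets[targets$species == "derivatized", , drop = FALSE]

  # mz_jitter_ppm bounds the scan-to-scan mass error (~3 sigma envelope)
  jit <- function(m) {
    m * (1 + stats::rnorm(length(m), 0, cf$mz_jitter_ppm / 3 * 1e-6))
  }
  times <- seq(cf$rt_range[1], cf$rt_range[2], by = cf$cycle_time)

  # --- matrix species (shared between runs) -------------------------------
  nm <- cf$matrix_ion_count
  matrix_df <- data.frame(
    mz = stats::runif(nm, 400, 1200),
    rt = stats::runif(nm, cf$rt_range[1] + 0.3, cf$rt_range[2] - 0.3),
    intensity = exp(stats::runif(nm, log(cf$matrix_intensity_range[1]),
                                 log(cf$matrix_intensity_range[2]))),
    pca = seq_len(nm) <= round(nm * cf$matrix_pca_fraction))
  # each matrix species sheds a few AIF fragments (random tryptic-like m/z)
  matrix_frags <- lapply(seq_len(nm), function(i) {
    nf <- sample(2:4, 1)
    data.frame(mz = stats::runif(nf, 150, matrix_df$mz[i]),
               rel = stats::runif(nf, 0.1, 0.3))
  })

  # --- analyte species ----------------------------------------------------
  nsp <- nrow(cf$true_opening_sites)
  apexes <- sort(stats::runif(nsp, cf$rt_range[1] + 0.8,
                              cf$rt_range[2] - 0.8))
  # enforce separation so planted species give distinct marker peaks
  if (nsp > 1L) {
    min_gap <- 8 * cf$peak_width_sigma
    for (i in 2:nsp) {
      if (apexes[i] - apexes[i - 1] < min_gap) {
        apexes[i] <- apexes[i - 1] + min_gap
      }
    }
  }
  species <- data.frame(site = cf$true_opening_sites$site,
                        abundance = cf$true_opening_sites$abundance,
                        rt = apexes)
  species$sequence <- candidates$sequence[match(species$site,
                                                candidates$opening_site)]

  # pre-computed fragment sets per species (shared by split-peak isomers)
  frag_sets <- lapply(seq_len(nsp), function(i) {
    cand <- candidates[candidates$opening_site == species$site[i], ,
                       drop = FALSE]
    fr <- generate_fragments(cand, fragment_config(
      max_charge = 1L, h_transfer_offsets = cf$doublet_h_offset))
    n_res <- nchar(cand$sequence)
    keep_y <- sort(sample(seq_len(n_res - 1L),
                          max(1L, round(cf$y_completeness * (n_res - 1L)))))
    keep_b <- sort(sample(seq_len(n_res - 1L),
                          max(1L, round(cf$b_completeness * (n_res - 1L)))))
    ions <- rbind(
      fr[fr$kind == "doublet" & fr$h_offset == cf$doublet_h_offset, ],
      fr[fr$kind == "marker", ],
      fr[fr$kind == "y" & (nchar(species$sequence[i]) - fr$start + 1L) %in% keep_y, ],
      fr[fr$kind == "b" & fr$end %in% keep_b, ],
      fr[fr$kind == "internal_b", ])
    # log-uniform intensities; y-ions boosted when an internal Lys
    # sequesters charge at its epsilon-amine
    rel <- exp(stats::runif(nrow(ions), log(0.05), log(0.6)))
    has_k <- grepl("K", substr(species$sequence[i], 2,
                               nchar(species$sequence[i]) - 1L))
    rel[ions$kind == "y"] <- rel[ions$kind == "y"] * (if (has_k) 3 else 1)
    rel[ions$kind == "doublet"] <- pmax(rel[ions$kind == "doublet"], 0.4)
    rel[ions$kind == "marker"] <- cf$marker_fraction
    rel[ions$kind == "internal_b"] <-
      rel[ions$kind == "internal_b"] * 0.15
    ions$rel <- rel
    ions
  })

  elution <- function(i, t) {
    g <- .gauss(t, species$rt[i], cf$peak_width_sigma)
    if (cf$split_peak_isomers) {
      g <- g + 0.6 * .gauss(t, species$rt[i] + cf$split_rt_offset,
                            cf$peak_width_sigma)
    }
    g * species$abundance[i]
  }

  floor_int <- 10   # peaks below this are not recorded (detector floor)

  build_spectrum <- function(mzv, intv, scan_id, t, lvl, sf, prec = NA_real_) {
    keep <- intv >= floor_int
    ms_spectrum(scan_id, t, lvl, sf, mz = jit(mzv[keep]),
                intensity = intv[keep], precursor_mz = prec)
  }

  control_spectra <- list()
  analyte_extra <- list()   # per scan index: analyte-only peaks to append
  scan_meta <- list()

  sid <- 0L
  for (t in times) {
    # ---- full MS ----
    sid <- sid + 1L
    g_m <- .gauss(t, matrix_df$rt, cf$peak_width_sigma)
    m_mz <- matrix_df$mz
    m_int <- matrix_df$intensity * g_m
    keep <- m_int >= floor_int
    ctrl_full <- ms_spectrum(sprintf("scan=%d", sid), t, 1L, "full",
                             mz = jit(m_mz[keep]), intensity = m_int[keep])
    # analyte precursors
    a_mz <- numeric(); a_int <- numeric()
    for (i in seq_len(nsp)) {
      e <- elution(i, t) * cf$analyte_intensity
      if (e < floor_int) next
      a_mz <- c(a_mz, deriv$mz)
      a_int <- c(a_int, e * c(1, 0.6)[seq_len(nrow(deriv))])
    }
    control_spectra[[sid]] <- ctrl_full
    analyte_extra[[sid]] <- list(mz = jit(a_mz), intensity = a_int)
    scan_meta[[sid]] <- data.frame(scan_id = sprintf("scan=%d", sid),
                                   time = t, scan_function = "full")

    # ---- AIF ----
    sid <- sid + 1L
    f_mz <- numeric(); f_int <- numeric()
    for (i in seq_len(nm)) {
      if (g_m[i] * matrix_df$intensity[i] < floor_int) next
      f_mz <- c(f_mz, matrix_frags[[i]]$mz)
      f_int <- c(f_int, matrix_frags[[i]]$rel * matrix_df$intensity[i] * g_m[i])
      if (matrix_df$pca[i]) {
        # the marker is a minor product ion, below 5-10% of the base peak
        f_mz <- c(f_mz, k$DIAG_ION_MZ)
        f_int <- c(f_int, 0.08 * matrix_df$intensity[i] * g_m[i])
      }
    }
    ctrl_aif <- build_spectrum(f_mz, f_int, sprintf("scan=%d", sid), t, 2L,
                               "aif")
    a_mz <- numeric(); a_int <- numeric()
    for (i in seq_len(nsp)) {
      e <- elution(i, t) * cf$analyte_intensity
      if (e < floor_int) next
      fs <- frag_sets[[i]]
      hi <- fs$kind %in% c("marker", "y")   # AIF: marker + high-mass y ions
      a_mz <- c(a_mz, fs$mz[hi])
      a_int <- c(a_int, fs$rel[hi] * e)
    }
    control_spectra[[sid]] <- ctrl_aif
    analyte_extra[[sid]] <- list(mz = jit(a_mz), intensity = a_int)
    scan_meta[[sid]] <- data.frame(scan_id = sprintf("scan=%d", sid),
                                   time = t, scan_function = "aif")

    # ---- targeted MS/MS (unscheduled PRM on the derivatized targets) ----
    for (zi in seq_len(nrow(deriv))) {
      sid <- sid + 1L
      n_noise <- cf$noise_peak_count
      noise_mz <- stats::runif(n_noise, 100, 1500)
      noise_int <- stats::runif(n_noise, 20, 400)
      ctrl_ms2 <- ms_spectrum(sprintf("scan=%d", sid), t, 2L,
                              "targeted_msms",
                              mz = stats::runif(n_noise, 100, 1500),
                              intensity = stats::runif(n_noise, 20, 400),
                              precursor_mz = deriv$mz[zi])
      a_mz <- noise_mz; a_int <- noise_int
      for (i in seq_len(nsp)) {
        e <- elution(i, t) * cf$analyte_intensity
        if (e < floor_int) next
        fs <- frag_sets[[i]]
        a_mz <- c(a_mz, jit(fs$mz))
        a_int <- c(a_int, fs$rel * e * 0.5)
      }
      control_spectra[[sid]] <- ctrl_ms2
      analyte_extra[[sid]] <- list(mz = a_mz, intensity = a_int,
                                   replace = TRUE)
      scan_meta[[sid]] <- data.frame(scan_id = sprintf("scan=%d", sid),
                                     time = t,
                                     scan_function = "targeted_msms")
    }
  }

  # analyte spectra = control spectra (identical matrix peaks) + extras;
  # targeted MS/MS spectra are independent between runs (replace = TRUE)
  analyte_spectra <- lapply(seq_len(sid), function(i) {
    s <- control_spectra[[i]]
    ex <- analyte_extra[[i]]
    if (isTRUE(ex$replace)) {
      ms_spectrum(s$scan_id, s$time, s$ms_level, s$scan_function,
                  mz = ex$mz, intensity = ex$intensity,
                  precursor_mz = s$precursor_mz)
    } else if (length(ex$mz)) {
      ms_spectrum(s$scan_id, s$time, s$ms_level, s$scan_function,
                  mz = c(s$mz, ex$mz), intensity = c(s$intensity, ex$intensity),
                  precursor_mz = s$precursor_mz)
    } else {
      s
    }
  })

  species$precursor_mz_z1 <- deriv$mz[deriv$charge == 1L]
  if (any(deriv$charge == 2L)) {
    species$precursor_mz_z2 <- deriv$mz[deriv$charge == 2L]
  }
  truth <- list(
    species = species,
    planted_fragments = frag_sets,
    matrix = matrix_df,
    scan_functions = do.call(rbind, scan_meta))

  list(analyte = ms_run(analyte_spectra, source = "synthetic analyte"),
       control = ms_run(control_spectra, source = "synthetic control"),
       truth = truth)
}
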
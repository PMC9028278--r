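# Soft-spot identification: inclusion lists, marker-ion screening on
# background-subtracted AIF data, candidate scoring against targeted MS/MS
# spectra, and ranking with duplicate-residue disambiguation.
#
# The scoring function encodes the manual interpretation logic as an
# explicit, overridable combination of the workflow's evidence channels:
# the residue-specific a1/b1 doublet and the derivatization-invariant y-ion
# ladder carry most of the weight.

.DEFAULT_WEIGHTS <- c(doublet = 0.4, y = 0.4, b = 0.1, marker = 0.05,
                      intensity = 0.05)

#' Build the targeted inclusion list for a cyclic peptide
#'
#' Targets the intact parent, the hydrolyzed (ring-opened) parent at
#' parent + H2O, and the 2PCA-derivatized hydrolyzed parent at
#' parent + H2O + C6H3N, at charge states 1..`max_charge`.
#'
#' @param parent A [cyclic_peptide()].
#' @param max_charge Highest charge state to include.
#' @return Data frame of class `target_list` with columns `species`,
#'   `neutral_mass`, `charge`, `mz`.
#' @export
build_target_list <- function(parent, max_charge = 2L) {
  stopifnot(inherits(parent, "cyclic_peptide"), max_charge >= 1L)
  k <- .CONSTANTS
  pm <- parent_mass(parent)
  masses <- c(parent = pm,
              hydrolyzed = pm + k$WATER,
              derivatized = pm + k$WATER + k$PCA_RESIDUAL)
  out <- expand.grid(species = names(masses),
                     charge = seq_len(as.integer(max_charge)),
                     stringsAsFactors = FALSE)
  out$neutral_mass <- masses[out$species]
  out$mz <- mz(out$neutral_mass, out$charge)
  out <- out[order(out$charge, match(out$species, names(masses))),
             c("species", "neutral_mass", "charge", "mz")]
  rownames(out) <- NULL
  attr(out, "parent") <- parent
  class(out) <- c("target_list", "data.frame")
  out
}

#' Export an inclusion list as TSV
#'
#' Columns `mass`, `mz`, `z`, `species`, compatible with targeted-method
#' editors.
#'
#' @param targets Output of [build_target_list()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_target_list <- function(targets, path) {
  out <- data.frame(mass = targets$neutral_mass, mz = targets$mz,
                    z = targets$charge, species = targets$species)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen the marker-ion chromatogram
#'
#' Extracts the XIC of the imidazolidinone marker ion (m/z 107.0609) over
#' the AIF scans and detects chromatographic peaks. On background-subtracted
#' data the apexes locate 2PCA conjugates of the analyte: the soft-spot
#' species plus any secondary metabolites retaining the derivatized
#' terminus.
#'
#' @param run An [ms_run()] with AIF scans, normally after
#'   [subtract_background()].
#' @param ppm_tol XIC tolerance in ppm (default 5).
#' @param min_intensity,min_points Peak-detection thresholds, see
#'   [find_peaks()].
#' @return Data frame of marker peaks (see [find_peaks()]).
#' @export
screen_marker <- function(run, ppm_tol = 5, min_intensity = 1000,
                          min_points = 3L) {
  xic <- extract_xic(run, .CONSTANTS$DIAG_ION_MZ, ppm_tol,
                     scan_function = "aif")
  find_peaks(xic, min_intensity = min_intensity, min_points = min_points)
}

#' Score one ring-opening candidate against an MS/MS spectrum
#'
#' Theoretical fragments are generated for the candidate and matched to
#' spectrum peaks within `match_ppm`. The score combines the evidence
#' channels linearly:
#' `w_doublet * doublet + w_y * y_coverage + w_b * b_coverage +
#'  w_marker * marker + w_intensity * matched_intensity_fraction`.
#' The doublet is credited only when BOTH members match at one consistent
#' hydrogen-transfer offset — its diagnostic power is the 27.9949 Da
#' spacing, not either mass alone.
#'
#' @param spectrum An [ms_spectrum()] (typically targeted MS/MS of the
#'   derivatized hydrolyzed parent).
#' @param candidate One row of [enumerate_openings()].
#' @param frag_config A [fragment_config()].
#' @param match_ppm Peak-matching tolerance in ppm.
#' @param weights Named numeric with entries `doublet`, `y`, `b`, `marker`,
#'   `intensity`.
#' @return A list of class `candidate_score`: `opening_site`,
#'   `n_term_residue`, `doublet_matched`, `doublet_h_offset`,
#'   `doublet_mz`, `marker_matched`, `y_coverage`, `b_coverage`,
#'   `n_matched_peaks`, `matched_intensity_fraction`,
#'   `internal_ambiguity`, `score`.
#' @export
score_candidate <- function(spectrum, candidate,
                            frag_config = fragment_config(),
                            match_ppm = 15,
                            weights = .DEFAULT_WEIGHTS) {
  frags <- generate_fragments(candidate, frag_config)
  .score_fragments(spectrum, frags, isobaric_internal_groups(frags),
                   .as_candidate(candidate), match_ppm, weights)
}

# scoring core against precomputed fragments (cached across spectra)
.score_fragments <- function(spectrum, frags, groups, cand, match_ppm,
                             weights) {
  stopifnot(inherits(spectrum, "ms_spectrum"))
  weights <- weights[c("doublet", "y", "b", "marker", "intensity")]
  stopifnot(!anyNA(weights))

  matched <- logical(nrow(frags))
  if (length(spectrum$mz) && nrow(frags)) {
    lo <- findInterval(frags$mz * (1 - match_ppm * 1e-6), spectrum$mz)
    hi <- findInterval(frags$mz * (1 + match_ppm * 1e-6), spectrum$mz)
    matched <- hi > lo
  }

  cover <- function(kind) {
    sp <- frags$kind == kind
    if (!any(sp)) return(0)
    spans <- unique(frags$end[sp])          # per ladder rung, any charge
    hit <- unique(frags$end[sp & matched])
    length(hit) / length(spans)
  }
  y_cov <- {
    sp <- frags$kind == "y"
    if (!any(sp)) 0 else length(unique(frags$start[sp & matched])) /
      length(unique(frags$start[sp]))
  }
  b_cov <- cover("b")

  dbl <- frags$kind == "doublet"
  doublet_matched <- FALSE
  doublet_h <- NA_integer_
  doublet_mz <- NA_real_
  if (any(dbl)) {
    for (h in sort(unique(frags$h_offset[dbl]), decreasing = FALSE)) {
      idx <- which(dbl & frags$h_offset == h)
      if (length(idx) == 2L && all(matched[idx])) {
        doublet_matched <- TRUE
        doublet_h <- h
        doublet_mz <- max(frags$mz[idx])    # the b1-type member
        break
      }
    }
  }
  marker_matched <- any(matched[frags$kind == "marker"])

  # matched spectrum peaks (union over all matched fragments)
  peak_hit <- logical(length(spectrum$mz))
  if (any(matched)) {
    for (i in which(matched)) {
      lo_i <- findInterval(frags$mz[i] * (1 - match_ppm * 1e-6), spectrum$mz)
      hi_i <- findInterval(frags$mz[i] * (1 + match_ppm * 1e-6), spectrum$mz)
      if (hi_i > lo_i) peak_hit[(lo_i + 1L):hi_i] <- TRUE
    }
  }
  tot <- sum(spectrum$intensity)
  mif <- if (tot > 0) sum(spectrum$intensity[peak_hit]) / tot else 0

  # isobaric internal groups with at least one matched member overlap the
  # evidence and are flagged as ambiguous
  amb <- Filter(function(g) {
    any(vapply(g$mz, function(m) {
      i <- findInterval(c(m * (1 - match_ppm * 1e-6),
                          m * (1 + match_ppm * 1e-6)), spectrum$mz)
      i[2] > i[1]
    }, logical(1)))
  }, groups)

  score <- unname(weights["doublet"] * doublet_matched +
                    weights["y"] * y_cov + weights["b"] * b_cov +
                    weights["marker"] * marker_matched +
                    weights["intensity"] * mif)
  structure(list(
    opening_site = cand$opening_site,
    n_term_residue = substr(cand$sequence, 1, 1),
    doublet_matched = doublet_matched, doublet_h_offset = doublet_h,
    doublet_mz = doublet_mz, marker_matched = marker_matched,
    y_coverage = y_cov, b_coverage = b_cov,
    n_matched_peaks = sum(peak_hit),
    matched_intensity_fraction = mif,
    internal_ambiguity = amb,
    score = score), class = "candidate_score")
}

# rank a per-candidate score table: score desc, then doublet, y-coverage,
# opening site ascending
.rank_scores <- function(df) {
  df[order(-df$score, -df$doublet_matched, -df$y_coverage, df$opening_site), ,
     drop = FALSE]
}

.verdict <- function(ranked, margin) {
  if (nrow(ranked) == 0L) return("no evidence")
  if (nrow(ranked) == 1L ||
      ranked$score[1] - ranked$score[2] >= margin) {
    sprintf("opening at %s%d", ranked$n_term_residue[1],
            ranked$opening_site[1])
  } else {
    "ambiguous"
  }
}

.score_table <- function(scores) {
  if (!length(scores)) {
    return(data.frame(opening_site = integer(), n_term_residue = character(),
                      score = numeric(), doublet_matched = logical(),
                      doublet_h_offset = integer(), marker_matched = logical(),
                      y_coverage = numeric(), b_coverage = numeric(),
                      n_matched_peaks = integer(),
                      matched_intensity_fraction = numeric(),
                      n_internal_ambiguities = integer()))
  }
  do.call(rbind, lapply(scores, function(s) {
    data.frame(opening_site = s$opening_site,
               n_term_residue = s$n_term_residue,
               score = s$score, doublet_matched = s$doublet_matched,
               doublet_h_offset = s$doublet_h_offset,
               marker_matched = s$marker_matched,
               y_coverage = s$y_coverage, b_coverage = s$b_coverage,
               n_matched_peaks = s$n_matched_peaks,
               matched_intensity_fraction = s$matched_intensity_fraction,
               n_internal_ambiguities = length(s$internal_ambiguity))
  }))
}

#' Identify the soft spot(s) of a cyclic peptide
#'
#' Runs the full three-scan workflow: background-subtract the AIF scans
#' against the control run, screen the marker-ion XIC for 2PCA conjugates,
#' select targeted MS/MS spectra whose precursor matches the derivatized
#' hydrolyzed parent, score every ring-opening candidate against each
#' spectrum, and rank candidates by their best score across spectra.
#'
#' Marker peaks with no matching MS/MS spectrum in their retention window
#' are reported as unassigned 2PCA species (e.g. secondary metabolites that
#' underwent a further hydrolysis) with the strongest co-eluting
#' background-subtracted MS1 peak as observed precursor; they are flagged,
#' not sequenced.
#'
#' @param analyte,control [ms_run()] objects for the analyte incubation and
#'   the matrix-only control (or [cross_peptide_controls()]).
#' @param parent A [cyclic_peptide()].
#' @param subtraction A [subtraction_config()].
#' @param frag_config A [fragment_config()].
#' @param match_ppm Fragment-matching tolerance (ppm).
#' @param marker_ppm Marker XIC tolerance (ppm, default 5).
#' @param precursor_ppm Precursor-matching tolerance (ppm).
#' @param max_charge Highest precursor charge considered.
#' @param weights Scoring weights, see [score_candidate()].
#' @param margin Minimum lead of the top candidate over the runner-up for a
#'   non-ambiguous verdict (score units).
#' @param min_evidence Minimum best score required to report any verdict;
#'   below it the result carries a `"no evidence"` status (chance matches in
#'   noise-only spectra give small nonzero scores).
#' @param rt_gating If `TRUE`, only MS/MS spectra eluting within a marker
#'   peak are scored and a per-peak verdict is produced; default `FALSE`
#'   because targeted scans may fire outside AIF marker peaks.
#' @param min_marker_intensity,min_marker_points Marker peak-detection
#'   thresholds, see [screen_marker()].
#' @return Object of class `softspot_result`: fields `parent`, `targets`,
#'   `marker_peaks`, `scores` (ranked per-candidate table), `verdict`,
#'   `by_peak` (per-marker-peak rankings when `rt_gating`), `unassigned`,
#'   `n_spectra`, `status`.
#' @export
identify_soft_spots <- function(analyte, control, parent,
                                subtraction = subtraction_config(),
                                frag_config = fragment_config(),
                                match_ppm = 15, marker_ppm = 5,
                                precursor_ppm = 10, max_charge = 2L,
                                weights = .DEFAULT_WEIGHTS,
                                margin = 0.1, min_evidence = 0.1,
                                rt_gating = FALSE,
                                min_marker_intensity = 1000,
                                min_marker_points = 3L) {
  stopifnot(inherits(parent, "cyclic_peptide"))
  sub_aif <- subtract_background(analyte, control, subtraction,
                                 scan_function = "aif")
  marker_peaks <- screen_marker(sub_aif, ppm_tol = marker_ppm,
                                min_intensity = min_marker_intensity,
                                min_points = min_marker_points)
  targets <- build_target_list(parent, max_charge = max_charge)
  deriv <- targets[targets$species == "derivatized", , drop = FALSE]
  candidates <- enumerate_openings(parent)

  funs <- .run_functions(analyte)
  msms <- analyte$spectra[funs == "targeted_msms"]
  prec_ok <- vapply(msms, function(s) {
    !is.na(s$precursor_mz) &&
      any(.within_ppm(s$precursor_mz, deriv$mz, precursor_ppm))
  }, logical(1))
  msms <- msms[prec_ok]

  in_peak <- function(t) {
    nrow(marker_peaks) > 0L &&
      any(t >= marker_peaks$start_time & t <= marker_peaks$end_time)
  }
  if (rt_gating) {
    msms <- msms[vapply(msms, function(s) in_peak(s$time), logical(1))]
  }

  # fragments depend only on the candidate: compute once, score per spectrum
  cand_frags <- lapply(seq_len(nrow(candidates)), function(i) {
    fr <- generate_fragments(candidates[i, , drop = FALSE], frag_config)
    list(frags = fr, groups = isobaric_internal_groups(fr),
         cand = .as_candidate(candidates[i, , drop = FALSE]))
  })
  score_block <- function(spectra) {
    if (!length(spectra)) return(NULL)
    per_cand <- lapply(cand_frags, function(cf) {
      best <- NULL
      for (s in spectra) {
        sc <- .score_fragments(s, cf$frags, cf$groups, cf$cand,
                               match_ppm, weights)
        if (is.null(best) || sc$score > best$score) best <- sc
      }
      best
    })
    .rank_scores(.score_table(per_cand))
  }

  ranked <- score_block(msms)
  # "no evidence": no target-matching MS/MS at all, or none whose best
  # score clears the evidence floor (chance matches in noise score > 0)
  status <- if (is.null(ranked) || max(ranked$score) < min_evidence) {
    "no evidence"
  } else "ok"
  if (is.null(ranked)) {
    ranked <- .score_table(list())
  }
  verdict <- if (status == "no evidence") "no evidence"
             else .verdict(ranked, margin)

  by_peak <- NULL
  if (rt_gating && nrow(marker_peaks) > 0L) {
    by_peak <- lapply(seq_len(nrow(marker_peaks)), function(j) {
      sel <- vapply(msms, function(s) {
        s$time >= marker_peaks$start_time[j] &&
          s$time <= marker_peaks$end_time[j]
      }, logical(1))
      r <- score_block(msms[sel])
      list(apex_time = marker_peaks$apex_time[j], ranking = r,
           verdict = if (is.null(r) || max(r$score) < min_evidence) {
             "no evidence"
           } else .verdict(r, margin))
    })
  }

  # marker peaks without any scored MS/MS in their window: unassigned
  # 2PCA species; report the strongest co-eluting subtracted MS1 peak
  unassigned <- NULL
  if (nrow(marker_peaks) > 0L) {
    covered <- vapply(seq_len(nrow(marker_peaks)), function(j) {
      any(vapply(msms, function(s) {
        s$time >= marker_peaks$start_time[j] &&
          s$time <= marker_peaks$end_time[j]
      }, logical(1)))
    }, logical(1))
    if (any(!covered)) {
      sub_full <- subtract_background(analyte, control, subtraction,
                                      scan_function = "full")
      ffuns <- .run_functions(sub_full)
      ftimes <- .run_times(sub_full)
      rows <- lapply(which(!covered), function(j) {
        near <- which(ffuns == "full")
        if (!length(near)) {
          return(data.frame(apex_time = marker_peaks$apex_time[j],
                            observed_mz = NA_real_, intensity = NA_real_))
        }
        i <- near[which.min(abs(ftimes[near] - marker_peaks$apex_time[j]))]
        s <- sub_full$spectra[[i]]
        if (!length(s$mz)) {
          data.frame(apex_time = marker_peaks$apex_time[j],
                     observed_mz = NA_real_, intensity = NA_real_)
        } else {
          k <- which.max(s$intensity)
          data.frame(apex_time = marker_peaks$apex_time[j],
                     observed_mz = s$mz[k], intensity = s$intensity[k])
        }
      })
      unassigned <- do.call(rbind, rows)
    }
  }

  structure(list(parent = parent, targets = targets,
                 marker_peaks = marker_peaks, scores = ranked,
                 verdict = verdict, by_peak = by_peak,
                 unassigned = unassigned, n_spectra = length(msms),
                 status = status,
                 subtracted_aif = sub_aif, margin = margin),
            class = "softspot_result")
}

#' @export
print.softspot_result <- function(x, ...) {
  cat(sprintf("Soft-spot identification for '%s' (%s)\n", x$parent$name,
              x$parent$sequence))
  cat(sprintf("  marker-ion peaks after subtraction: %d\n",
              nrow(x$marker_peaks)))
  cat(sprintf("  targeted MS/MS spectra scored: %d\n", x$n_spectra))
  cat(sprintf("  verdict: %s\n", x$verdict))
  if (nrow(x$scores) > 0L) {
    top <- utils::head(x$scores, 3L)
    cat("  top candidates:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s%-3d score %.3f (doublet %s, y-coverage %.2f)\n",
                  top$n_term_residue[i], top$opening_site[i], top$score[i],
                  ifelse(top$doublet_matched[i], "yes", "no"),
                  top$y_coverage[i]))
    }
  }
  if (!is.null(x$unassigned) && nrow(x$unassigned) > 0L) {
    cat(sprintf("  unassigned 2PCA species: %d (secondary metabolites?)\n",
                nrow(x$unassigned)))
  }
  invisible(x)
}

#' @export
summary.softspot_result <- function(object, ...) {
  print(object)
  if (nrow(object$scores) > 0L) {
    cat("\nFull ranking:\n")
    print(object$scores, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$unassigned) && nrow(object$unassigned) > 0L) {
    cat("\nUnassigned 2PCA species:\n")
    print(object$unassigned, row.names = FALSE, digits = 5)
  }
  invisible(object)
}

#' @export
plot.softspot_result <- function(x, ...) {
  xic <- extract_xic(x$subtracted_aif, .CONSTANTS$DIAG_ION_MZ, 5,
                     scan_function = "aif")
  plot(xic, ...)
  if (nrow(x$marker_peaks) > 0L) {
    graphics::points(x$marker_peaks$apex_time, x$marker_peaks$apex_intensity,
                     pch = 17, col = 2)
  }
  invisible(x)
}

#' Serialize a result to JSON
#'
#' Machine-readable report: ranked candidates with scores, marker peaks and
#' any unassigned 2PCA species.
#'
#' @param result A `softspot_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "softspot_result"))
  payload <- list(
    peptide = result$parent$name,
    sequence = result$parent$sequence,
    topology = result$parent$topology,
    verdict = result$verdict,
    status = result$status,
    n_spectra = result$n_spectra,
    marker_peaks = result$marker_peaks,
    ranking = result$scores,
    unassigned = result$unassigned)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
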
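# Theoretical fragment ions for 2PCA-derivatized ring-opening candidates.
#
# N-terminal (b/a-type) fragments carry the imidazolidinone residual C6H3N;
# y-type fragments never do, which is what makes the y-ladder invariant to
# derivatization and usable for duplicate-residue disambiguation. Collisional
# activation across the imidazolidinone gives a residue-specific a1/b1-type
# doublet spaced by CO plus a conjugation-specific marker ion at m/z
# 107.0609, independent of the first residue.

#' Fragment generation configuration
#'
#' @param ion_types Subset of `c("b", "y", "a", "internal_b", "doublet",
#'   "marker")`.
#' @param max_charge Maximum fragment charge state (>= 1).
#' @param h_transfer_offsets Integer offsets, in hydrogen-atom masses,
#'   applied to the doublet ions. Gas-phase fragmentation of the
#'   imidazolidinone shows poorly understood +/- 1 H transfers, so the
#'   doublet is also generated at these offsets. Default `c(0, -1)`.
#' @param include_parent_ions Also emit the intact candidate `[M + zH]z+`.
#' @return A list of class `fragment_config`.
#' @export
fragment_config <- function(ion_types = c("b", "y", "a", "internal_b",
                                          "doublet", "marker"),
                            max_charge = 1L,
                            h_transfer_offsets = c(0L, -1L),
                            include_parent_ions = FALSE) {
  ion_types <- match.arg(ion_types, several.ok = TRUE)
  stopifnot(max_charge >= 1L, all(h_transfer_offsets == round(h_transfer_offsets)))
  structure(list(ion_types = ion_types,
                 max_charge = as.integer(max_charge),
                 h_transfer_offsets = as.integer(h_transfer_offsets),
                 include_parent_ions = isTRUE(include_parent_ions)),
            class = "fragment_config")
}

#' Diagnostic a1/b1-type doublet for an N-terminal residue
#'
#' Cleavage on either side of the first carbonyl of a 2PCA-conjugated
#' peptide yields two singly charged fragments that both contain the first
#' residue's side chain and the imidazolidinone residual, separated by
#' exactly the mass of CO (27.9949 Da).
#'
#' @param residue_code One-letter code of the N-terminal residue.
#' @return Named numeric `c(b1 = ..., a1 = ...)` in m/z;
#'   `b1 = residue + C6H3N + proton`, `a1 = b1 - CO`.
#' @examples
#' doublet_for_residue("T")  # 191.0815 / 163.0866, the Thr doublet
#' @export
doublet_for_residue <- function(residue_code) {
  r <- .residue_mass(residue_code)
  k <- .CONSTANTS
  b1 <- r + k$PCA_RESIDUAL + k$PROTON
  c(b1 = b1, a1 = b1 - k$CO)
}

#' Hydrogen-transfer variants of the diagnostic doublet
#'
#' Each doublet member is shifted by `k * H_ATOM` for every offset `k`.
#' Two bookkeeping conventions are supported for the base value: the
#' canonical protonated ion (`residue + C6H3N + proton`, the default) and
#' the neutral-plus-H form (`residue + C6H3N + H_ATOM`) sometimes used when
#' quoting calculated masses for these H-transfer species.
#'
#' @param residue_code One-letter code.
#' @param offsets Integer hydrogen-atom offsets.
#' @param convention `"protonated"` or `"neutral_h"`.
#' @return Data frame with columns `member` ("b1"/"a1"), `h_offset`, `mz`.
#' @examples
#' doublet_variants("S", 0)                        # canonical 177.0658
#' doublet_variants("S", 1, convention = "neutral_h")  # 178.0742
#' @export
doublet_variants <- function(residue_code, offsets = c(0L, -1L),
                             convention = c("protonated", "neutral_h")) {
  convention <- match.arg(convention)
  r <- .residue_mass(residue_code)
  k <- .CONSTANTS
  carrier <- if (convention == "protonated") k$PROTON else k$H_ATOM
  b1 <- r + k$PCA_RESIDUAL + carrier
  out <- expand.grid(member = c("b1", "a1"), h_offset = as.integer(offsets),
                     stringsAsFactors = FALSE)
  out$mz <- ifelse(out$member == "b1", b1, b1 - k$CO) +
    out$h_offset * k$H_ATOM
  out[order(out$h_offset, out$member), , drop = FALSE]
}

# sum of residue masses over a candidate span, plus the disulfide-chain
# appendage when the span covers the anchor Cys
.span_mass <- function(resmass, from, to, cterm_mod, cterm_mod_pos) {
  m <- sum(resmass[from:to])
  if (!is.na(cterm_mod_pos) && cterm_mod_pos >= from && cterm_mod_pos <= to) {
    m <- m + cterm_mod
  }
  m
}

.as_candidate <- function(candidate) {
  if (inherits(candidate, "data.frame")) {
    stopifnot(nrow(candidate) == 1L)
    candidate <- as.list(candidate)
  }
  if (is.character(candidate)) {
    candidate <- list(sequence = candidate)
  }
  candidate$cterm_mod <- candidate$cterm_mod %||% 0
  candidate$cterm_mod_pos <- candidate$cterm_mod_pos %||% NA_integer_
  candidate$opening_site <- candidate$opening_site %||% NA_integer_
  candidate
}

#' Generate theoretical fragments for a linearized candidate
#'
#' The candidate is assumed to carry the 2PCA imidazolidinone on its
#' N-terminus. b-type ions (and the derived a-type) therefore include the
#' C6H3N residual; y-type ions never do. Internal fragments are generated
#' as internal b-type (acylium) over every contiguous span touching neither
#' terminus. Doublet ions are emitted at each configured hydrogen-transfer
#' offset; the marker ion C6H7N2 is emitted once.
#'
#' @param candidate One row of [enumerate_openings()], or a plain residue
#'   string for an underivatized-independent calculation.
#' @param config A [fragment_config()].
#' @return Data frame of class `theoretical_fragments` with columns `label`,
#'   `kind`, `start`, `end` (1-based residue span, inclusive), `charge`,
#'   `mz`, `pca_modified`, `h_offset`; deterministically ordered by kind,
#'   span start, span length, charge.
#' @export
generate_fragments <- function(candidate, config = fragment_config()) {
  stopifnot(inherits(config, "fragment_config"))
  cand <- .as_candidate(candidate)
  res <- .split_residues(cand$sequence)
  n <- length(res)
  rm <- .residue_mass(res, seq_along(res))
  k <- .CONSTANTS
  types <- config$ion_types

  # neutral fragment series as parallel vectors, multiply charged later
  lab <- character(); kind <- character()
  st <- integer(); en <- integer(); neutral <- numeric(); pca <- logical()

  # disulfide-chain appendage: add cterm_mod to spans covering its anchor
  mod_pos <- cand$cterm_mod_pos
  covers <- function(i, j) {
    !is.na(mod_pos) & mod_pos >= i & mod_pos <= j
  }
  cum0 <- c(0, cumsum(rm))
  spanm <- function(i, j) {
    cum0[j + 1L] - cum0[i] + ifelse(covers(i, j), cand$cterm_mod, 0)
  }

  if (n >= 2L) {
    i <- seq_len(n - 1L)
    if ("b" %in% types) {
      lab <- c(lab, sprintf("b%d+2PCA", i)); kind <- c(kind, rep("b", n - 1L))
      st <- c(st, rep(1L, n - 1L)); en <- c(en, i)
      neutral <- c(neutral, spanm(rep(1L, n - 1L), i) + k$PCA_RESIDUAL)
      pca <- c(pca, rep(TRUE, n - 1L))
    }
    if ("a" %in% types) {
      lab <- c(lab, sprintf("a%d+2PCA", i)); kind <- c(kind, rep("a", n - 1L))
      st <- c(st, rep(1L, n - 1L)); en <- c(en, i)
      neutral <- c(neutral, spanm(rep(1L, n - 1L), i) + k$PCA_RESIDUAL - k$CO)
      pca <- c(pca, rep(TRUE, n - 1L))
    }
    if ("y" %in% types) {
      lab <- c(lab, sprintf("y%d", i)); kind <- c(kind, rep("y", n - 1L))
      st <- c(st, n - i + 1L); en <- c(en, rep(n, n - 1L))
      neutral <- c(neutral, spanm(n - i + 1L, rep(n, n - 1L)) + k$WATER)
      pca <- c(pca, rep(FALSE, n - 1L))
    }
    if ("internal_b" %in% types && n >= 4L) {
      ij <- expand.grid(i = 2:(n - 1L), j = 2:(n - 1L))
      ij <- ij[ij$j >= ij$i, , drop = FALSE]
      seqs <- vapply(seq_len(nrow(ij)), function(r) {
        paste(res[ij$i[r]:ij$j[r]], collapse = "")
      }, character(1))
      lab <- c(lab, sprintf("internal %s", seqs))
      kind <- c(kind, rep("internal_b", nrow(ij)))
      st <- c(st, ij$i); en <- c(en, ij$j)
      neutral <- c(neutral, spanm(ij$i, ij$j))
      pca <- c(pca, rep(FALSE, nrow(ij)))
    }
  }

  # expand over charge states
  z <- rep(seq_len(config$max_charge), each = length(neutral))
  out <- data.frame(
    label = ifelse(z == 1L, rep(lab, config$max_charge),
                   sprintf("%s^%d+", rep(lab, config$max_charge), z)),
    kind = rep(kind, config$max_charge),
    start = rep(st, config$max_charge), end = rep(en, config$max_charge),
    charge = z, mz = (rep(neutral, config$max_charge) + z * k$PROTON) / z,
    pca_modified = rep(pca, config$max_charge),
    h_offset = 0L, stringsAsFactors = FALSE)

  if ("doublet" %in% types) {
    base <- rm[1L] + k$PCA_RESIDUAL + k$PROTON
    h <- rep(config$h_transfer_offsets, each = 2L)
    suff <- ifelse(h == 0L, "", sprintf(" (%+dH)", h))
    member <- rep(c("b1", "a1"), length(config$h_transfer_offsets))
    out <- rbind(out, data.frame(
      label = paste0(member, "+2PCA doublet", suff), kind = "doublet",
      start = 1L, end = 1L, charge = 1L,
      mz = base - ifelse(member == "a1", k$CO, 0) + h * k$H_ATOM,
      pca_modified = TRUE, h_offset = h, stringsAsFactors = FALSE))
  }
  if ("marker" %in% types) {
    out <- rbind(out, data.frame(
      label = "marker C6H7N2", kind = "marker", start = 0L, end = 0L,
      charge = 1L, mz = k$DIAG_ION_MZ, pca_modified = TRUE, h_offset = 0L,
      stringsAsFactors = FALSE))
  }
  if (config$include_parent_ions) {
    zp <- seq_len(config$max_charge)
    pm <- spanm(1L, n) + k$WATER + k$PCA_RESIDUAL
    out <- rbind(out, data.frame(
      label = sprintf("[M+2PCA]^%d+", zp), kind = "parent", start = 1L,
      end = n, charge = zp, mz = (pm + zp * k$PROTON) / zp,
      pca_modified = TRUE, h_offset = 0L, stringsAsFactors = FALSE))
  }
  ord <- order(match(out$kind, c("doublet", "marker", "b", "a", "y",
                                 "internal_b", "parent")),
               out$start, out$end - out$start, out$charge, out$h_offset)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("theoretical_fragments", "data.frame")
  out
}

#' Group isobaric internal fragments
#'
#' Internal fragments with (near-)identical m/z cannot be told apart and can
#' masquerade as terminal sequence ions, suggesting a false start site. Any
#' set of two or more internal fragments whose m/z fall within `ppm_tol` of
#' one another is flagged as one ambiguity group (e.g. the JB1 internals PLK
#' and LKP at m/z 339.2391).
#'
#' @param fragments Output of [generate_fragments()] for one candidate.
#' @param ppm_tol Grouping tolerance in ppm.
#' @return List of data frames, each a group of >= 2 isobaric internal
#'   fragments (singly charged representatives).
#' @export
isobaric_internal_groups <- function(fragments, ppm_tol = 10) {
  int <- fragments[fragments$kind == "internal_b" & fragments$charge == 1L, ,
                   drop = FALSE]
  if (nrow(int) < 2L) return(list())
  int <- int[order(int$mz), , drop = FALSE]
  # chain neighbours within tolerance into groups
  gap <- diff(int$mz) <= int$mz[-nrow(int)] * ppm_tol * 1e-6
  grp <- cumsum(c(TRUE, !gap))
  out <- split(int, grp)
  out <- out[vapply(out, nrow, integer(1)) >= 2L]
  out <- lapply(out, function(g) { rownames(g) <- NULL; g })
  unname(out)
}

#' Export a fragment table as TSV
#'
#' @param fragments Output of [generate_fragments()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  out <- fragments[, c("label", "kind", "start", "end", "charge", "mz",
                       "h_offset")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
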
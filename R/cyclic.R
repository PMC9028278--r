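# Cyclic peptide representation and ring-opening enumeration.
#
# A single amide hydrolysis linearizes a macrocycle with an M + 18.0106 Da
# shift irrespective of the site, so every possible opening is isomeric with
# every other. The candidate space the downstream evidence must discriminate
# is enumerated here.

#' Define a cyclic peptide
#'
#' @param name Identifier used in reports.
#' @param sequence One-letter residue string in written order
#'   (e.g. `"CYAAPLKPAKSC"`).
#' @param topology `"head_to_tail"` (backbone amide macrocycle) or
#'   `"disulfide"` (linear backbone closed by a Cys-Cys bridge). Topology is
#'   never inferred from the sequence; it is a required modelling choice.
#' @param disulfide_pair Integer pair of 1-based residue indices of the
#'   bridged cysteines (required when `topology = "disulfide"`).
#' @return An object of class `cyclic_peptide`.
#' @examples
#' cyclic_peptide("JB1", "CYAAPLKPAKSC", "head_to_tail")
#' cyclic_peptide("somatostatin", "AGCKNFFWKTFTSC", "disulfide",
#'                disulfide_pair = c(3, 14))
#' @export
cyclic_peptide <- function(name, sequence,
                           topology = c("head_to_tail", "disulfide"),
                           disulfide_pair = NULL) {
  topology <- match.arg(topology)
  res <- .split_residues(sequence)
  if (!length(res)) stop("empty sequence")
  .residue_mass(res, seq_along(res))  # validates
  if (topology == "disulfide") {
    if (is.null(disulfide_pair) || length(disulfide_pair) != 2L) {
      stop("disulfide topology requires 'disulfide_pair' (two residue indices)")
    }
    disulfide_pair <- sort(as.integer(disulfide_pair))
    if (any(disulfide_pair < 1L) || any(disulfide_pair > length(res)) ||
        disulfide_pair[1] == disulfide_pair[2]) {
      stop("disulfide_pair indices out of range")
    }
    if (any(res[disulfide_pair] != "C")) {
      stop("disulfide_pair must point at Cys residues")
    }
  } else {
    disulfide_pair <- NULL
  }
  structure(
    list(name = name, sequence = sequence, residues = res,
         topology = topology, disulfide_pair = disulfide_pair),
    class = "cyclic_peptide"
  )
}

#' Neutral monoisotopic mass of the intact cyclic parent
#'
#' Head-to-tail: bare residue sum (one water fewer than the linear peptide).
#' Disulfide: linear backbone (residues + water) minus two hydrogen atoms
#' lost on S-S bond formation.
#'
#' @param parent A [cyclic_peptide()].
#' @return Mass in Da.
#' @export
parent_mass <- function(parent) {
  stopifnot(inherits(parent, "cyclic_peptide"))
  total <- sum(.residue_mass(parent$residues))
  k <- .CONSTANTS
  switch(parent$topology,
    head_to_tail = total,
    disulfide    = total + k$WATER - 2 * k$H_ATOM
  )
}

#' @export
print.cyclic_peptide <- function(x, ...) {
  cat(sprintf("Cyclic peptide '%s': %s (%d residues, %s)\n",
              x$name, x$sequence, length(x$residues),
              gsub("_", "-", x$topology)))
  if (!is.null(x$disulfide_pair)) {
    cat(sprintf("  disulfide bridge: Cys%d-Cys%d\n",
                x$disulfide_pair[1], x$disulfide_pair[2]))
  }
  cat(sprintf("  parent neutral mass: %.4f Da\n", parent_mass(x)))
  invisible(x)
}

#' Enumerate ring-opening hydrolysis candidates
#'
#' Every backbone amide inside the ring is a possible initial hydrolysis
#' site; each opening yields a linearized isomer at parent mass + H2O. For a
#' head-to-tail n-mer there are exactly n candidates (one per inter-residue
#' amide), each a rotation of the written sequence. For a disulfide-bridged
#' peptide, only amides strictly between the bridged cysteines open the
#' ring; the opened species is branched (two chains joined by S-S) but is
#' represented pseudo-linearly: the sequence runs from the new N-terminus to
#' the written C-terminus, and the mass of the other chain (minus 2 H for
#' the intact bridge) is carried as a fixed appendage on the C-terminal-side
#' bridged Cys (`cterm_mod` at residue `cterm_mod_pos` of the candidate).
#'
#' @param parent A [cyclic_peptide()].
#' @return A data frame of class `linear_candidates` with columns
#'   `opening_site` (1-based index of the residue that becomes the new
#'   N-terminus, on the written sequence), `sequence`, `n_term_residue`,
#'   `neutral_mass` (whole species, Da), `cterm_mod`, `cterm_mod_pos`
#'   (position within the candidate sequence; `NA` when no appendage).
#'   Ordered by opening site. The parent is attached as attribute
#'   `"parent"`.
#' @export
enumerate_openings <- function(parent) {
  stopifnot(inherits(parent, "cyclic_peptide"))
  res <- parent$residues
  n <- length(res)
  k <- .CONSTANTS
  ring_mass <- parent_mass(parent)

  if (parent$topology == "head_to_tail") {
    sites <- seq_len(n)
    seqs <- vapply(sites, function(i) {
      paste(res[c(seq(i, n), if (i > 1) seq_len(i - 1))], collapse = "")
    }, character(1))
    out <- data.frame(
      opening_site = sites,
      sequence = seqs,
      n_term_residue = res[sites],
      neutral_mass = ring_mass + k$WATER,
      cterm_mod = 0,
      cterm_mod_pos = NA_integer_,
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(parent$disulfide_pair)) {
      stop("disulfide topology without disulfide_pair")
    }
    c1 <- parent$disulfide_pair[1]
    c2 <- parent$disulfide_pair[2]
    # amides strictly inside the loop: between residues i and i+1,
    # i = c1 .. c2-1; the new N-terminus is residue i+1
    sites <- seq(c1 + 1L, c2)
    seqs <- vapply(sites, function(i) paste(res[i:n], collapse = ""),
                   character(1))
    # other chain: residues 1..(i-1), a peptide in its own right, joined
    # through the still-intact disulfide (2 H lost on bridge formation)
    mods <- vapply(sites, function(i) {
      sum(.residue_mass(res[seq_len(i - 1L)])) + k$WATER - 2 * k$H_ATOM
    }, numeric(1))
    out <- data.frame(
      opening_site = sites,
      sequence = seqs,
      n_term_residue = res[sites],
      neutral_mass = vapply(seqs, peptide_mass, numeric(1)) + mods,
      cterm_mod = mods,
      cterm_mod_pos = c2 - sites + 1L,
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  attr(out, "parent") <- parent
  class(out) <- c("linear_candidates", "data.frame")
  out
}

#' Candidates whose new N-terminus is a given residue
#'
#' Duplicate residues make the diagnostic doublet alone ambiguous; this
#' lookup returns every opening that would place `residue_code` at the new
#' N-terminus, for disambiguation via the y-ion series.
#'
#' @param parent A [cyclic_peptide()].
#' @param residue_code One-letter code.
#' @return Subset of [enumerate_openings()] (possibly zero rows).
#' @export
candidate_for_nterm <- function(parent, residue_code) {
  cands <- enumerate_openings(parent)
  out <- cands[cands$n_term_residue == residue_code, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parent") <- attr(cands, "parent")
  out
}

#' Read cyclic peptide definitions from a YAML or JSON config
#'
#' The file holds one peptide or a list of peptides, each with fields
#' `name`, `sequence`, `topology` (`head_to_tail` or `disulfide`) and
#' optionally `disulfide_pair`.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return List of [cyclic_peptide()] objects, named by peptide name.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  defs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(defs$sequence)) defs <- list(defs)
  peps <- lapply(defs, function(d) {
    cyclic_peptide(
      name = d$name %||% d$sequence,
      sequence = d$sequence,
      topology = d$topology %||% "head_to_tail",
      disulfide_pair = unlist(d$disulfide_pair)
    )
  })
  names(peps) <- vapply(peps, `[[`, character(1), "name")
  peps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
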
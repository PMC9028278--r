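# Theoretical fragment generation: diagnostic doublet, ladders, internals.

test_that("the diagnostic doublet reproduces the printed threonine values", {
  d <- doublet_for_residue("T")
  expect_equal(round(unname(d["b1"]), 4), 191.0815)
  expect_equal(round(unname(d["a1"]), 4), 163.0866)
  # two-decimal printed precision
  expect_lt(abs(d[["b1"]] - 191.08), 0.01)
  expect_lt(abs(d[["a1"]] - 163.08), 0.01)
  expect_error(doublet_for_residue("Z"), "unknown residue")
})

test_that("doublet spacing is exactly CO for every residue and offset", {
  k <- pca_constants()
  for (r in names(residue_masses())) {
    d <- doublet_for_residue(r)
    expect_equal(unname(d["b1"] - d["a1"]), k$CO, tolerance = 1e-12)
    v <- doublet_variants(r, c(-1, 0, 1))
    for (h in unique(v$h_offset)) {
      pair <- v[v$h_offset == h, ]
      expect_equal(pair$mz[pair$member == "b1"] - pair$mz[pair$member == "a1"],
                   k$CO, tolerance = 1e-12)
    }
  }
})

test_that("doublet composed from mass-table constants (glycine oracle)", {
  k <- pca_constants()
  b1 <- residue_masses()[["G"]] + k$PCA_RESIDUAL + k$PROTON
  d <- doublet_for_residue("G")
  expect_equal(unname(d), c(b1, b1 - k$CO), tolerance = 1e-12)
  expect_equal(round(unname(d), 4), c(147.0553, 119.0604))
})

test_that("hydrogen-transfer variants cover both printed serine conventions", {
  # canonical protonated ion (the observed 177.0671 is within 10 ppm)
  v0s <- doublet_variants("S", 0)
  b1s <- v0s$mz[v0s$member == "b1"]
  expect_lt(abs(b1s - 177.0658), 2e-4)
  expect_lt(abs(b1s - 177.0671) / 177.0671 * 1e6, 10)
  # the neutral-plus-H bookkeeping with one transferred hydrogen
  v <- doublet_variants("S", 1, convention = "neutral_h")
  expect_equal(round(v$mz[v$member == "b1"], 4), 178.0742)
  # offset 0 is the identity on doublet_for_residue
  v0 <- doublet_variants("T", 0)
  expect_equal(sort(v0$mz), sort(unname(doublet_for_residue("T"))))
})

test_that("a dipeptide candidate has exactly one rung per ladder", {
  fr <- generate_fragments("GG", fragment_config())
  expect_equal(sum(fr$kind == "b"), 1)
  expect_equal(sum(fr$kind == "a"), 1)
  expect_equal(sum(fr$kind == "y"), 1)
  expect_equal(sum(fr$kind == "internal_b"), 0)
  expect_true(all(fr$mz > 0))
  # y ions are never 2PCA-modified; N-terminal ions always are
  expect_false(any(fr$pca_modified[fr$kind == "y"]))
  expect_true(all(fr$pca_modified[fr$kind %in% c("a", "b")]))
})

test_that("b/y complementarity holds for every ring-opening candidate", {
  k <- pca_constants()
  cands <- enumerate_openings(jb1())
  for (i in seq_len(nrow(cands))) {
    fr <- generate_fragments(cands[i, ], fragment_config())
    n <- nchar(cands$sequence[i])
    b_last <- fr$mz[fr$kind == "b" & fr$end == n - 1]
    y1 <- fr$mz[fr$kind == "y" & fr$start == n]
    expect_equal(b_last + y1 - k$PROTON,
                 cands$neutral_mass[i] + k$PCA_RESIDUAL + k$PROTON,
                 tolerance = 1e-9)
  }
})

test_that("fragment m/z agree with an elemental-composition oracle", {
  # compose each span's formula by concatenating residue formulas (the
  # parser sums repeated elements), then add the terminal groups
  res_formula <- c(S = "C3H5NO2", C = "C3H5NOS", Y = "C9H9NO2",
                   A = "C3H5NO", P = "C5H7NO", L = "C6H11NO",
                   K = "C6H12N2O")
  seqv <- strsplit("SCCYAAPLKPAK", "")[[1]]
  fr <- generate_fragments("SCCYAAPLKPAK", fragment_config(max_charge = 2L))
  k <- pca_constants()
  # y4 = last four residues + water, protonated
  y4 <- formula_mass(paste0(paste(res_formula[seqv[9:12]], collapse = ""),
                            "H2O"))
  expect_equal(fr$mz[fr$kind == "y" & fr$start == 9 & fr$charge == 1],
               mz(y4, 1), tolerance = 1e-9)
  expect_equal(fr$mz[fr$kind == "y" & fr$start == 9 & fr$charge == 2],
               mz(y4, 2), tolerance = 1e-9)
  # b3 carries the imidazolidinone residual C6H3N
  b3 <- formula_mass(paste0(paste(res_formula[seqv[1:3]], collapse = ""),
                            "C6H3N"))
  expect_equal(fr$mz[fr$kind == "b" & fr$end == 3 & fr$charge == 1],
               mz(b3, 1), tolerance = 1e-9)
  # internal PLK at the printed 339.24
  plk <- fr$mz[fr$label == "internal PLK" & fr$charge == 1]
  expect_equal(round(plk, 4), 339.2391)
  expect_lt(abs(plk - 339.24), 0.01)
})

test_that("y-ladders are invariant to N-terminal derivatization", {
  # same sequence, with and without 2PCA on the b-series: identical y m/z
  fr <- generate_fragments("CYAAPLKPAKSC", fragment_config())
  yv <- fr$mz[fr$kind == "y"]
  k <- pca_constants()
  seqv <- strsplit("CYAAPLKPAKSC", "")[[1]]
  plain_y <- vapply(1:11, function(i) {
    mz(peptide_mass(paste(seqv[(12 - i + 1):12], collapse = ""), "linear"), 1)
  }, numeric(1))
  expect_equal(sort(yv), sort(plain_y), tolerance = 1e-9)
})

test_that("isobaric internal fragments group (PLK/LKP) and distinct ones do not", {
  fr <- generate_fragments("SCCYAAPLKPAK", fragment_config())
  groups <- isobaric_internal_groups(fr, ppm_tol = 10)
  labs <- lapply(groups, function(g) sort(unique(g$label)))
  expect_true(any(vapply(labs, function(l) {
    all(c("internal PLK", "internal LKP") %in% l)
  }, logical(1))))
  # a candidate with all-distinct residues and distinct span sums
  fr2 <- generate_fragments("GASVT", fragment_config())
  expect_length(isobaric_internal_groups(fr2, ppm_tol = 10), 0)
})

test_that("permuted spans with equal residue multisets always group", {
  set.seed(3)
  aa <- names(residue_masses())
  for (trial in 1:10) {
    s <- paste(sample(aa, 8, TRUE), collapse = "")
    fr <- generate_fragments(s, fragment_config())
    int <- fr[fr$kind == "internal_b", ]
    groups <- isobaric_internal_groups(fr, ppm_tol = 1)
    grouped <- unlist(lapply(groups, function(g) {
      paste(g$start, g$end)
    }))
    # brute force: every pair of internal spans with equal multisets
    seqv <- strsplit(s, "")[[1]]
    for (i in seq_len(nrow(int))) for (j in seq_len(nrow(int))) {
      if (i >= j) next
      mi <- sort(seqv[int$start[i]:int$end[i]])
      mj <- sort(seqv[int$start[j]:int$end[j]])
      if (identical(mi, mj)) {
        expect_true(paste(int$start[i], int$end[i]) %in% grouped)
        expect_true(paste(int$start[j], int$end[j]) %in% grouped)
      }
    }
  }
})

test_that("fragment tables export as TSV", {
  fr <- generate_fragments("GAST", fragment_config())
  path <- tempfile(fileext = ".tsv")
  write_fragment_table(fr, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(fr))
  expect_equal(back$mz, fr$mz, tolerance = 1e-9)
})
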
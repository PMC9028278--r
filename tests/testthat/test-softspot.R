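# Target lists, marker screening, candidate scoring and the full pipeline.

test_that("inclusion-list deltas reproduce the hydrolysis and 2PCA shifts", {
  tl <- build_target_list(jb1(), max_charge = 2L)
  z1 <- tl[tl$charge == 1, ]
  expect_equal(round(z1$mz[z1$species == "derivatized"] -
                       z1$mz[z1$species == "hydrolyzed"], 4), 89.0265)
  expect_equal(round(z1$mz[z1$species == "hydrolyzed"] -
                       z1$mz[z1$species == "parent"], 4), 18.0106)
  z2 <- tl[tl$charge == 2, ]
  expect_equal(z2$mz[z2$species == "derivatized"] -
                 z2$mz[z2$species == "hydrolyzed"],
               (z1$mz[z1$species == "derivatized"] -
                  z1$mz[z1$species == "hydrolyzed"]) / 2, tolerance = 1e-9)
  path <- tempfile(fileext = ".tsv")
  write_target_list(tl, path)
  expect_equal(read.delim(path)$mz, tl$mz, tolerance = 1e-9)
})

test_that("marker screening recovers planted conjugates and only those", {
  sim <- small_sim(seed = 13L,
                   sites = data.frame(site = c(5L, 11L), abundance = c(1, 1)))
  sub <- subtract_background(sim$analyte, sim$control, scan_function = "aif")
  pk <- screen_marker(sub)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(abs(pk$apex_time - sim$truth$species$rt)) < 0.051,
               c(TRUE, TRUE))
  # self-subtracted control has no marker signal at all
  ctrl_sub <- subtract_background(sim$control, sim$control,
                                  scan_function = "aif")
  expect_equal(nrow(screen_marker(ctrl_sub)), 0)
})

test_that("unsubtracted data shows extra marker peaks from the matrix", {
  # make the matrix 2PCA conjugates abundant enough to cross the threshold
  sim <- small_sim(seed = 14L, matrix_intensity_range = c(1e4, 1e6))
  raw <- screen_marker(sim$analyte)
  sub <- subtract_background(sim$analyte, sim$control, scan_function = "aif")
  cleaned <- screen_marker(sub)
  expect_gt(nrow(raw), nrow(cleaned))
  expect_equal(nrow(cleaned), 1)
})

test_that("scoring separates duplicate threonines via the y-ion series", {
  som <- somatostatin()
  cands <- enumerate_openings(som)
  thr <- candidate_for_nterm(som, "T")
  true_cand <- thr[1, ]   # opening at T10, followed by Phe
  decoy <- thr[2, ]       # opening at T12, followed by Ser
  fr <- generate_fragments(true_cand, fragment_config())
  planted <- sort(c(fr$mz[fr$kind %in% c("doublet", "y")],
                    pca_constants()$DIAG_ION_MZ))
  spec <- spec_from_peaks(planted, rep(1000, length(planted)))
  s_true <- score_candidate(spec, true_cand)
  s_decoy <- score_candidate(spec, decoy)
  expect_true(s_true$doublet_matched)
  expect_true(s_decoy$doublet_matched)   # doublet alone cannot separate them
  expect_gt(s_true$y_coverage, s_decoy$y_coverage)
  expect_gt(s_true$score, s_decoy$score)
})

test_that("an empty spectrum scores zero for every candidate", {
  cands <- enumerate_openings(jb1())
  spec <- spec_from_peaks(numeric(), numeric())
  scores <- vapply(seq_len(nrow(cands)), function(i) {
    score_candidate(spec, cands[i, ])$score
  }, numeric(1))
  expect_true(all(scores == 0))
})

test_that("a lone isobaric internal peak flags ambiguity, not a doublet", {
  cands <- enumerate_openings(jb1())
  ser <- cands[cands$n_term_residue == "S", ]
  spec <- spec_from_peaks(339.2391, 1000)
  sc <- score_candidate(spec, ser)
  expect_false(sc$doublet_matched)
  expect_gt(length(sc$internal_ambiguity), 0)
  labs <- unlist(lapply(sc$internal_ambiguity, `[[`, "label"))
  expect_true(all(c("internal PLK", "internal LKP") %in% labs))
})

test_that("adding a matched theoretical peak never lowers the score", {
  cands <- enumerate_openings(jb1())
  ser <- cands[cands$n_term_residue == "S", ]
  fr <- generate_fragments(ser, fragment_config())
  set.seed(21)
  base_peaks <- sort(sample(fr$mz, 6))
  spec0 <- spec_from_peaks(base_peaks, rep(100, 6))
  s0 <- score_candidate(spec0, ser)$score
  extra <- setdiff(fr$mz, base_peaks)
  for (add in extra[1:10]) {
    spec1 <- spec_from_peaks(c(base_peaks, add), rep(100, 7))
    expect_gte(score_candidate(spec1, ser)$score, s0 - 1e-12)
  }
})

test_that("the generating candidate outranks every rotation", {
  set.seed(31)
  aa <- names(residue_masses())
  for (trial in 1:20) {
    s <- paste(sample(aa, sample(6:12, 1), TRUE), collapse = "")
    pep <- cyclic_peptide("random", s, "head_to_tail")
    cands <- enumerate_openings(pep)
    k <- sample(nrow(cands), 1)
    fr <- generate_fragments(cands[k, ], fragment_config())
    keep <- fr$kind %in% c("doublet", "y", "b", "marker")
    spec <- spec_from_peaks(fr$mz[keep], rep(500, sum(keep)))
    scores <- vapply(seq_len(nrow(cands)), function(i) {
      score_candidate(spec, cands[i, ])$score
    }, numeric(1))
    expect_gte(scores[k], max(scores) - 1e-12)
  }
})

test_that("the full pipeline recovers a planted opening site", {
  sim <- small_sim(seed = 41L)
  res <- identify_soft_spots(sim$analyte, sim$control, jb1())
  expect_s3_class(res, "softspot_result")
  expect_equal(res$status, "ok")
  expect_equal(res$scores$opening_site[1], 11)
  expect_equal(res$verdict, "opening at S11")
  expect_equal(nrow(res$marker_peaks), 1)
  expect_output(print(res), "opening at S11")
})

test_that("two planted openings yield per-peak verdicts under RT gating", {
  sim <- small_sim(seed = 42L,
                   sites = data.frame(site = c(5L, 11L), abundance = c(1, 1)))
  res <- identify_soft_spots(sim$analyte, sim$control, jb1(),
                             rt_gating = TRUE)
  expect_equal(nrow(res$marker_peaks), 2)
  expect_length(res$by_peak, 2)
  verdicts <- vapply(res$by_peak, `[[`, character(1), "verdict")
  expect_setequal(verdicts, c("opening at P5", "opening at S11"))
})

test_that("an analyte identical to the control gives no evidence", {
  sim <- small_sim(seed = 43L)
  res <- identify_soft_spots(sim$control, sim$control, jb1())
  expect_equal(res$status, "no evidence")
  expect_equal(res$verdict, "no evidence")
  expect_equal(nrow(res$marker_peaks), 0)
})

test_that("identification reports are deterministic byte for byte", {
  sim <- small_sim(seed = 44L)
  r1 <- identify_soft_spots(sim$analyte, sim$control, jb1())
  r2 <- identify_soft_spots(sim$analyte, sim$control, jb1())
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_report(r1, p1); write_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
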
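make_hits <- function(target_scores, decoy_scores,
                      target_class = "reference",
                      decoy_class = "reference") {
  nt <- length(target_scores)
  nd <- length(decoy_scores)
  data.frame(
    spectrum_id = sprintf("s%04d", seq_len(nt + nd)),
    peptide = sprintf("PEP%04d", seq_len(nt + nd)),
    score = c(target_scores, decoy_scores),
    label = rep(c("target", "decoy"), c(nt, nd)),
    pep_class = c(rep_len(target_class, nt), rep_len(decoy_class, nd)),
    stringsAsFactors = FALSE)
}

test_that("the best PSM per peptide is the score maximum with lexicographic ties", {
  psms <- data.frame(
    spectrum_id = c("s3", "s1", "s2", "s9", "s5"),
    peptide = c("AAK", "AAK", "AAK", "CCK", "CCK"),
    score = c(10, 30, 20, 7, 7),
    label = "target", stringsAsFactors = FALSE)
  hits <- best_psm_per_peptide(psms)
  expect_identical(hits$score[hits$peptide == "AAK"], 30)
  # equal scores: smallest spectrum_id wins
  expect_identical(hits$spectrum_id[hits$peptide == "CCK"], "s5")
  expect_identical(sort(hits$n_psms), c(2L, 3L))
})

test_that("best-PSM reduction matches a brute-force group-by oracle", {
  set.seed(21)
  psms <- data.frame(
    spectrum_id = sprintf("sp%04d", sample(1000)),
    peptide = sprintf("P%03d", sample(100, 1000, replace = TRUE)),
    score = round(rnorm(1000, 10, 3), 1),  # rounding forces some ties
    label = sample(c("target", "decoy"), 1000, replace = TRUE),
    stringsAsFactors = FALSE)
  got <- best_psm_per_peptide(psms)
  got <- got[order(got$peptide, got$label), ]
  want <- bf_best_psm(psms)
  expect_equal(got$spectrum_id, want$spectrum_id)
  expect_equal(got$score, want$score)
})

test_that("peptides are classified by reference-set membership of the plain sequence", {
  ref <- c("PEPMK", "AAAK")
  expect_identical(assign_pep_class(c("PEPMK", "CCCK"), ref),
                   c("reference", "variant"))
  # modification characters are stripped before mapping
  expect_identical(assign_pep_class("PEP1K", ref), "reference")
})

test_that("global estimator arithmetic and separation cases are exact", {
  # 500 targets above every decoy except 5 high decoys -> D/T = 5/500
  hits <- make_hits(target_scores = seq(100, 599),
                    decoy_scores = c(rep(600, 5), rep(10, 95)))
  rep <- global_fdr(hits)
  worst <- rep$hits[rep$hits$label == "target", ]
  expect_equal(min(worst$q_value), 5 / 500)
  # full separation -> all target q-values are zero
  hits2 <- make_hits(target_scores = 101:200, decoy_scores = 1:50)
  rep2 <- global_fdr(hits2)
  expect_true(all(rep2$hits$q_value[rep2$hits$label == "target"] == 0))
  expect_identical(nrow(rep2$hits_passing), 100L)
  # no targets -> empty report
  rep3 <- global_fdr(make_hits(numeric(0), 1:3))
  expect_identical(nrow(rep3$hits_passing), 0L)
})

test_that("global q-values equal the brute-force per-cutoff oracle", {
  set.seed(22)
  hits <- make_hits(target_scores = round(rnorm(300, 12, 3), 1),
                    decoy_scores = round(rnorm(80, 9, 3), 1))
  rep <- global_fdr(hits)
  t <- rep$hits[rep$hits$label == "target", ]
  expect_equal(t$q_value,
               bf_global_q(t$score, hits$score[hits$label == "decoy"]),
               tolerance = 1e-12)
  # q-values are monotone non-increasing in score
  ord <- order(t$score, decreasing = TRUE)
  expect_true(all(diff(t$q_value[ord]) >= 0))
})

test_that("variant-class q-values equal the brute-force class-specific oracle", {
  set.seed(23)
  n <- 400
  hits <- data.frame(
    spectrum_id = sprintf("s%04d", 1:n),
    peptide = sprintf("P%04d", 1:n),
    score = round(c(rnorm(200, 13, 2), rnorm(60, 11, 2),
                    rnorm(100, 9, 2), rnorm(40, 9, 2)), 2),
    label = rep(c("target", "target", "decoy", "decoy"),
                c(200, 60, 100, 40)),
    pep_class = rep(c("reference", "variant", "reference", "variant"),
                    c(200, 60, 100, 40)),
    stringsAsFactors = FALSE)
  res <- separate_fdr(hits)
  vt <- res$variant$hits[res$variant$hits$label == "target", ]
  expect_equal(vt$q_value,
               bf_separate_variant_q(vt$score,
                                     hits$score[hits$label == "decoy"],
                                     d_n = 40, d_total = 140),
               tolerance = 1e-12)
  # the reference class is scored by the plain estimator on its own hits
  rt <- res$reference$hits[res$reference$hits$label == "target", ]
  ref_decoys <- hits$score[hits$label == "decoy" &
                             hits$pep_class == "reference"]
  expect_equal(rt$q_value, bf_global_q(rt$score, ref_decoys),
               tolerance = 1e-12)
})

test_that("when all decoys are variant-class the class estimator reduces to D+/Tn+", {
  set.seed(24)
  hits <- data.frame(
    spectrum_id = sprintf("s%03d", 1:120),
    peptide = sprintf("P%03d", 1:120),
    score = round(c(rnorm(80, 12, 2), rnorm(40, 9, 2)), 2),
    label = rep(c("target", "decoy"), c(80, 40)),
    pep_class = c(rep("variant", 80), rep("variant", 40)),
    stringsAsFactors = FALSE)
  res <- separate_fdr(hits)
  vt <- res$variant$hits[res$variant$hits$label == "target", ]
  # D_n = D, so the correction factor is 1 and plain D/T arithmetic applies
  expect_equal(vt$q_value,
               bf_global_q(vt$score, hits$score[hits$label == "decoy"]),
               tolerance = 1e-12)
})

test_that("two-stage filtering removes the spectra identified in stage 1", {
  stage1 <- data.frame(
    spectrum_id = c("a", "b", "c"),
    peptide = c("REFA", "REFB", "REFC"),
    score = c(100, 100, 1),
    label = "target", stringsAsFactors = FALSE)
  stage2 <- data.frame(
    spectrum_id = c("a", "b", "d", "e"),
    peptide = c("VARA", "VARB", "VARD", "VARE"),
    score = c(50, 50, 50, 50),
    label = "target", stringsAsFactors = FALSE)
  rep <- two_stage_fdr(stage1, stage2)
  # spectra a and b pass stage 1 (no decoys -> q = 0) and are removed
  expect_identical(sort(rep$hits_passing$peptide), c("VARD", "VARE"))
  expect_identical(rep$counts$n_spectra_removed, 2L)
  # disjoint spectrum sets leave stage 2 untouched
  stage2b <- transform(stage2, spectrum_id = c("w", "x", "y", "z"))
  rep2 <- two_stage_fdr(stage1, stage2b)
  g2 <- global_fdr(best_psm_per_peptide(stage2b))
  expect_identical(nrow(rep2$hits_passing), nrow(g2$hits_passing))
})

test_that("a 30-spectrum two-stage fixture matches hand enumeration", {
  # stage 1: 10 confident reference spectra (r01..r10), 5 weak ones,
  # 3 decoys below everything
  stage1 <- data.frame(
    spectrum_id = sprintf("r%02d", 1:18),
    peptide = sprintf("REF%02d", 1:18),
    score = c(rep(90, 10), rep(20, 5), rep(20, 3)),
    label = rep(c("target", "decoy"), c(15, 3)),
    stringsAsFactors = FALSE)
  # cutoff 90: 0/10 -> q = 0 for r01..r10; cutoff 20 ties with the three
  # decoys: 3/15 = 0.2 -> r11..r15 fail, so only r01..r10 are removed
  # stage 2: 12 variant spectra, 4 of them on removed spectra (r01..r04),
  # plus 2 decoys below the targets
  stage2 <- data.frame(
    spectrum_id = c(sprintf("r%02d", 1:4), sprintf("v%02d", 1:8),
                    "vd1", "vd2"),
    peptide = c(sprintf("VARX%02d", 1:4), sprintf("VAR%02d", 1:8),
                "VDEC1", "VDEC2"),
    score = c(rep(60, 4), rep(70, 8), 5, 5),
    label = rep(c("target", "decoy"), c(12, 2)),
    stringsAsFactors = FALSE)
  rep <- two_stage_fdr(stage1, stage2)
  # hand enumeration: r01..r04 rows are dropped; remaining 8 targets all
  # outscore both decoys -> q = 0 -> exactly the 8 VARnn peptides pass
  expect_identical(rep$counts$n_spectra_removed, 4L)
  expect_identical(sort(rep$hits_passing$peptide), sprintf("VAR%02d", 1:8))
})

test_that("FDR reports round-trip through the TSV contract", {
  set.seed(25)
  hits <- make_hits(round(rnorm(50, 12, 2), 1), round(rnorm(20, 9, 2), 1))
  rep <- global_fdr(hits)
  f <- tempfile(fileext = ".tsv")
  write_fdr_report(rep, f)
  back <- read.delim(f)
  expect_identical(nrow(back), 70L)
  expect_identical(sum(back$passing), nrow(rep$hits_passing))
})
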
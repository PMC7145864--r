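test_that("simulated peptides are reproducible, in range, and uniform", {
  ab <- rt_alphabet()
  p1 <- simulate_peptides(50, c(7, 45), ab, seed = 3)
  p2 <- simulate_peptides(50, c(7, 45), ab, seed = 3)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_peptides(50, c(7, 45), ab, seed = 4)))
  lens <- nchar(p1)
  expect_true(all(lens >= 7 & lens <= 45))
  expect_identical(anyDuplicated(p1), 0L)
  # residue frequencies uniform over the alphabet
  res <- unlist(strsplit(simulate_peptides(1500, c(7, 45), ab, seed = 9),
                         ""))
  k <- length(ab$tokens)
  freq <- table(factor(res, levels = ab$tokens)) / length(res)
  sigma <- sqrt((1 / k) * (1 - 1 / k) / length(res))
  expect_true(all(abs(freq - 1 / k) < 4.5 * sigma))
})

test_that("noiseless RTs equal the additive closed form", {
  ab <- rt_alphabet()
  law <- retention_law(ab, noise_sd = 0)
  peps <- simulate_peptides(40, c(7, 20), ab, seed = 6)
  rec <- simulate_rt(peps, law, seed = 7)
  # closed-form recomputation in the test, independent of true_rt()
  manual <- vapply(peps, function(p) {
    ch <- strsplit(p, "")[[1]]
    5 + sum(law$residue_coefficients[ch]) + 1.2 * length(ch)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(rec$observed_rt, pmax(manual, 0), tolerance = 1e-12)
  expect_equal(rec$true_rt, manual, tolerance = 1e-12)
})

test_that("observation noise has the configured standard deviation", {
  ab <- rt_alphabet()
  law <- retention_law(ab, noise_sd = 0.5)
  peps <- simulate_peptides(10000, c(7, 20), ab, seed = 8)
  rec <- simulate_rt(peps, law, seed = 9)
  expect_equal(sd(rec$observed_rt - rec$true_rt), 0.5, tolerance = 0.05)
})

test_that("run distortions are monotone and relate two runs of one peptide set", {
  d <- run_distortion(max_offset = 8, seed = 4)
  x <- sort(runif(200, -10, 110))
  y <- peprt:::apply_distortion(d, x)
  expect_true(all(diff(y) > 0))
  ab <- rt_alphabet()
  lawA <- retention_law(ab, noise_sd = 0)
  lawB <- retention_law(ab, noise_sd = 0, distortion = d)
  peps <- simulate_peptides(30, c(7, 20), ab, seed = 10)
  rtA <- true_rt(peps, lawA)
  rtB <- true_rt(peps, lawB)
  expect_equal(rtB, peprt:::apply_distortion(d, rtA), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(rtA, rtB)))
  expect_error(run_distortion(max_offset = 15, n_knots = 4),
               "monotonicity")
})

test_that("the PSM simulator is reproducible and hides truth from the estimators", {
  s1 <- simulate_psms(seed = 2)
  s2 <- simulate_psms(seed = 2)
  expect_identical(s1, s2)
  expect_false("correct" %in% names(s1$psms))
  expect_false("correct" %in% names(s1$stage1))
  expect_false("correct" %in% names(s1$stage2))
  expect_true(all(c("spectrum_id", "peptide", "correct") %in%
                    names(s1$truth)))
  spec <- psm_sim_spec()
  expect_identical(nrow(s1$psms),
                   spec$n_true_reference + spec$n_false_reference +
                     spec$n_true_variant + spec$n_false_variant +
                     spec$n_decoy_reference + spec$n_decoy_variant)
})

test_that("with no incorrect matches and no decoys every q-value is zero", {
  spec <- psm_sim_spec(n_false_reference = 0L, n_false_variant = 0L,
                       n_decoy_reference = 0L, n_decoy_variant = 0L,
                       p_cross_reference = 0, p_variant_lost = 0,
                       p_noise_stage2 = 0)
  sim <- simulate_psms(spec, seed = 3)
  rep <- global_fdr(best_psm_per_peptide(sim$psms))
  expect_true(all(rep$hits$q_value[rep$hits$label == "target"] == 0))
})

test_that("decoy scores model the incorrect-match score distribution", {
  # with matched counts, decoys above any cutoff track incorrect targets
  sim <- simulate_psms(psm_sim_spec(), seed = 11)
  truth <- sim$truth[match(sim$psms$spectrum_id, sim$truth$spectrum_id), ]
  incorrect_targets <- sim$psms$score[sim$psms$label == "target" &
                                        !truth$correct]
  decoys <- sim$psms$score[sim$psms$label == "decoy"]
  for (cutoff in c(8, 10, 12, 14)) {
    d_above <- sum(decoys >= cutoff)
    t_above <- sum(incorrect_targets >= cutoff)
    expect_lt(abs(d_above - t_above), 0.35 * max(10, t_above))
  }
})
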
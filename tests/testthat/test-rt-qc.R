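test_that("RT error is the absolute observed-predicted difference", {
  ds <- make_dataset(n = 150, seed = 101)
  fit <- rtnet(tiny_genome(), ds, max_epochs = 2, seed = 1)
  hits <- data.frame(peptide = ds$records$peptide[1:30],
                     spectrum_rt = ds$records$observed_rt[1:30],
                     run_id = "run1", stringsAsFactors = FALSE)
  rec <- rt_error(hits, fit)
  # element-wise recomputation oracle
  pred <- predict(fit, hits$peptide)
  expect_equal(rec$abs_error, abs(hits$spectrum_rt - pred))
  expect_true(all(rec$abs_error >= 0))
  expect_identical(nrow(rt_error(hits[0, ], fit)), 0L)
})

test_that("the MAE metric is the interpolated median of absolute errors", {
  expect_equal(rt_mae(c(1, 0, 1)), 1)
  expect_equal(rt_mae(c(0, 2)), 1)
  set.seed(31)
  err <- runif(1001, 0, 10)
  expect_equal(rt_mae(err), sort(err)[501])  # sort-and-pick-middle oracle
  expect_equal(rt_mae(sample(err)), rt_mae(err))
  signed <- rnorm(100)
  expect_equal(rt_mae(abs(signed)), rt_mae(abs(-signed)))
  expect_error(rt_mae(numeric(0)), "no records")
})

test_that("the RT-error filter flags strictly beyond the threshold", {
  rec <- data.frame(peptide = sprintf("P%03d", 1:100),
                    abs_error = c(rep(1, 93), rep(6, 7)))
  out <- filter_by_rt_error(rec)
  expect_identical(nrow(out$flagged), 7L)
  expect_identical(nrow(out$kept) + nrow(out$flagged), 100L)
  expect_identical(intersect(out$kept$peptide, out$flagged$peptide),
                   character(0))
  # the 5-minute boundary itself is kept
  edge <- data.frame(peptide = c("a", "b"), abs_error = c(5.0, 5.1))
  out2 <- filter_by_rt_error(edge)
  expect_identical(out2$kept$peptide, "a")
  expect_identical(out2$flagged$peptide, "b")
})

test_that("group summaries report per-group medians deterministically", {
  rec <- data.frame(peptide = sprintf("P%02d", 1:40),
                    abs_error = c(rnorm(20, 1, 0.1), rnorm(20, 3, 0.1)))
  grp <- rep(c("b_shifted", "a_baseline"), c(20, 20))
  tab <- rt_group_summary(rec, grp)
  expect_identical(tab$group, c("a_baseline", "b_shifted"))
  expect_equal(tab$median_abs_error[2] - tab$median_abs_error[1], -2,
               tolerance = 0.2)
  # one group covering everything reproduces the MAE metric
  tab1 <- rt_group_summary(rec, rep("all", 40))
  expect_equal(tab1$median_abs_error, rt_mae(rec))
})

test_that("false identifications separate from true ones in RT error", {
  # correct identifications carry law-consistent RTs; incorrect ones have
  # sequence-independent RTs, so their RT errors are larger
  ab <- rt_alphabet()
  law <- retention_law(ab, noise_sd = 0.3)
  sim <- simulate_psms(psm_sim_spec(), law, ab, seed = 5)
  truth <- sim$truth[match(sim$psms$spectrum_id, sim$truth$spectrum_id), ]
  targets <- sim$psms$label == "target" & sim$psms$pep_class == "reference"
  pred <- true_rt(sim$psms$peptide[targets], law)  # oracle predictor
  err <- abs(sim$psms$spectrum_rt[targets] - pred)
  correct <- truth$correct[targets]
  expect_gt(median(err[!correct]), median(err[correct]) + 5)
})

test_that("QC reports include the flag column on disk", {
  rec <- data.frame(peptide = c("a", "b"), run_id = "r",
                    observed_rt = c(10, 20), predicted_rt = c(10.2, 28),
                    abs_error = c(0.2, 8))
  f <- tempfile(fileext = ".tsv")
  write_qc_report(rec, f)
  back <- read.delim(f)
  expect_identical(back$flagged, c(FALSE, TRUE))
})
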
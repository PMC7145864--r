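test_that("observed RT is the mean over a peptide's spectra", {
  obs <- data.frame(peptide = c("PEPTIDEK", "PEPTIDEK", "ACDEFGH"),
                    rt_minutes = c(10, 12, 7.5))
  rec <- aggregate_observed_rt(obs)
  rec <- rec[order(rec$peptide), ]
  expect_equal(rec$observed_rt, c(7.5, 11))
  expect_equal(rec$rt_span, c(0, 2))
  expect_equal(rec$n_spectra, c(1L, 2L))
})

test_that("aggregation matches a brute-force mean on many spectra", {
  set.seed(3)
  rts <- runif(100, 10, 90)
  obs <- data.frame(peptide = "AAAAAAK", rt_minutes = rts,
                    n_engines = sample(1:3, 100, replace = TRUE))
  rec <- aggregate_observed_rt(obs)
  expect_equal(rec$observed_rt, sum(rts) / length(rts), tolerance = 1e-9)
  expect_equal(rec$rt_span, max(rts) - min(rts))
  expect_identical(rec$n_engines, max(obs$n_engines))
  expect_identical(nrow(aggregate_observed_rt(obs[0, ])), 0L)
  mixed <- data.frame(peptide = c("A", "A"), rt_minutes = c(1, 2),
                      run_id = c("r1", "r2"))
  expect_error(aggregate_observed_rt(mixed), "multiple runs")
})

test_that("training filters keep >=2 engine peptides with span <= 3 min", {
  rec <- data.frame(peptide = letters[1:4],
                    observed_rt = 1:4,
                    rt_span = c(0, 3.0, 3.5, 1),
                    n_spectra = 1L,
                    n_engines = c(1L, 2L, 3L, 3L))
  kept <- filter_training_records(rec)
  expect_identical(kept$peptide, c("b", "d"))
  # the 3-minute boundary itself survives; strictly greater is removed
  expect_true("b" %in% kept$peptide)
  expect_false("c" %in% kept$peptide)
  # idempotent
  expect_identical(filter_training_records(kept), kept)
})

test_that("dataset split has 90/10 proportions with validation inside train", {
  ab <- rt_alphabet()
  peps <- simulate_peptides(1000, c(7, 20), ab, seed = 5)
  rec <- data.frame(peptide = peps, observed_rt = runif(1000, 10, 80))
  ds <- split_rt_dataset(rec, seed = 7)
  tab <- table(ds$records$partition)
  expect_identical(unname(tab[["test"]]), 100L)
  expect_identical(unname(tab[["validation"]]), 90L)
  expect_identical(unname(tab[["train"]]), 810L)
  # same seed reproduces, different seed differs
  ds2 <- split_rt_dataset(rec, seed = 7)
  expect_identical(ds$records$partition, ds2$records$partition)
  ds3 <- split_rt_dataset(rec, seed = 8)
  expect_false(identical(ds$records$partition, ds3$records$partition))
  expect_error(split_rt_dataset(rec[1:5, ], seed = 1), "at least 10")
})

test_that("RT scaler maps the training range onto [0,1] and inverts", {
  sc <- fit_rt_scaler(c(10, 25, 60))
  expect_equal(unname(sc), c(10, 60))
  expect_equal(scale_rt(35, sc), 0.5)
  expect_equal(scale_rt(70, sc), 1.2)  # out-of-range extrapolation allowed
  x <- runif(1000, -20, 120)
  expect_equal(unscale_rt(scale_rt(x, sc), sc), x, tolerance = 1e-9)
  expect_error(fit_rt_scaler(rep(42, 5)), "degenerate")
})

test_that("scaler is fit on the training partition only", {
  ds <- make_dataset(n = 200, noise_sd = 0, seed = 31)
  tr <- ds$records[ds$records$partition == "train", ]
  expect_equal(unname(ds$scaler),
               unname(range(tr$observed_rt)))
})

test_that("run TSV round-trips through the on-disk contract", {
  f <- tempfile(fileext = ".tsv")
  obs <- data.frame(spectrum_id = c("s1", "s2"), peptide = c("AK", "AK"),
                    rt_minutes = c(10, 11), n_engines = c(2L, 3L))
  write.table(obs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_run_tsv(f)
  expect_equal(back$rt_minutes, obs$rt_minutes)
  bad <- tempfile(fileext = ".tsv")
  write.table(obs[, 1:3], bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_run_tsv(bad), "n_engines")
})
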
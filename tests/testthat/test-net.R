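# The analytic gradients of the network core are validated against central
# finite differences; everything downstream (training, transfer learning,
# the architecture search) rests on them.
test_that("backpropagated gradients match finite differences", {
  ab <- rt_alphabet()
  g <- structure(list(
    n_conv = 2L, n_dense = 2L,
    conv = list(list(filters = 4L, activation = "tanh", dropout = 0.1,
                     batch_norm = TRUE, max_pool = TRUE),
                list(filters = 3L, activation = "leaky_relu", dropout = 0,
                     batch_norm = FALSE, max_pool = FALSE)),
    dense = list(list(units = 5L, activation = "relu", dropout = 0.25,
                      batch_norm = TRUE),
                 list(units = 4L, activation = "tanh", dropout = 0,
                      batch_norm = FALSE)),
    optimizer = "adam", gru_units = 3L), class = "rt_genome")
  spec <- peprt:::genome_to_spec(g, length(ab$tokens), 9L)
  init <- peprt:::cpp_rtnet_init(spec, 7L)
  peps <- simulate_peptides(6, c(5, 9), ab, seed = 3)
  x <- peprt:::pep_encode_index(peps, ab, 9L)
  set.seed(8)
  y <- runif(6)
  lg <- peprt:::cpp_rtnet_loss_grad(spec, init$weights, init$bn_state, x, y)
  eps <- 1e-5
  set.seed(42)
  idx <- sort(sample(length(init$weights), 100))
  num <- vapply(idx, function(i) {
    wp <- init$weights; wp[i] <- wp[i] + eps
    wm <- init$weights; wm[i] <- wm[i] - eps
    (peprt:::cpp_rtnet_loss_grad(spec, wp, init$bn_state, x, y)$loss -
       peprt:::cpp_rtnet_loss_grad(spec, wm, init$bn_state, x, y)$loss) /
      (2 * eps)
  }, numeric(1))
  ana <- lg$grad[idx]
  rel <- abs(num - ana) / pmax(1e-8, abs(num) + abs(ana))
  # a handful of parameters sit near relu/max-pool kinks where finite
  # differences are one-sided; the bulk must agree tightly
  expect_lt(median(rel), 1e-7)
  expect_lt(sort(rel, decreasing = TRUE)[3], 1e-5)
})

test_that("a small network learns an additive retention law", {
  ds <- make_dataset(n = 220, noise_sd = 0, seed = 17)
  fit <- rtnet(tiny_genome(), ds, max_epochs = 40, batch_size = 32,
               patience = 40, seed = 2)
  # beats the mean predictor on the validation partition by a wide margin
  va <- ds$records[ds$records$partition == "validation", ]
  tr <- ds$records[ds$records$partition == "train", ]
  baseline <- mean((scale_rt(va$observed_rt, ds$scaler) -
                      mean(scale_rt(tr$observed_rt, ds$scaler)))^2)
  expect_lt(fit$provenance$best_val_mse, baseline / 2)
})

test_that("training is reproducible under a fixed seed", {
  ds <- make_dataset(n = 120, noise_sd = 0.2, seed = 23)
  f1 <- rtnet(tiny_genome(), ds, max_epochs = 3, seed = 9)
  f2 <- rtnet(tiny_genome(), ds, max_epochs = 3, seed = 9)
  expect_identical(f1$weights, f2$weights)
  f3 <- rtnet(tiny_genome(), ds, max_epochs = 3, seed = 10)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("training refuses a zero-epoch budget", {
  ds <- make_dataset(n = 120, seed = 29)
  expect_error(rtnet(tiny_genome(), ds, max_epochs = 0), "max_epochs")
})

test_that("the saved provenance MSE is reproducible from the weights", {
  ds <- make_dataset(n = 150, noise_sd = 0.2, seed = 37)
  fit <- rtnet(tiny_genome(), ds, max_epochs = 5, seed = 4)
  va <- ds$records[ds$records$partition == "validation", ]
  pred_scaled <- scale_rt(predict(fit, va$peptide), fit$scaler)
  mse <- mean((pred_scaled - scale_rt(va$observed_rt, ds$scaler))^2)
  expect_equal(mse, fit$provenance$best_val_mse, tolerance = 1e-6)
})

test_that("zero-epoch fine-tuning only swaps the scaler", {
  ds <- make_dataset(n = 150, seed = 41)
  base <- rtnet(tiny_genome(), ds, max_epochs = 3, seed = 6)
  run <- make_dataset(n = 120, seed = 43,
                      distortion = run_distortion(seed = 5))
  swapped <- fine_tune(base, run, max_epochs = 0)
  expect_identical(swapped$weights, base$weights)
  expect_identical(unname(swapped$scaler), unname(run$scaler))
  expect_true(swapped$provenance$fine_tuned)
})

test_that("fine-tuning keeps the genome and changes only weights and scaler", {
  ds <- make_dataset(n = 150, seed = 47)
  base <- rtnet(tiny_genome(), ds, max_epochs = 3, seed = 6)
  run <- make_dataset(n = 120, seed = 53,
                      distortion = run_distortion(seed = 9))
  expect_warning(tuned <- fine_tune(base, make_dataset(n = 40, seed = 59),
                                    max_epochs = 1),
                 "only .* peptides")
  tuned <- fine_tune(base, run, max_epochs = 5, seed = 3)
  expect_identical(tuned$genome, base$genome)
  expect_false(identical(tuned$weights, base$weights))
})

test_that("model bundles round-trip through plain-text files", {
  ds <- make_dataset(n = 150, seed = 61)
  fit <- rtnet(tiny_genome(), ds, max_epochs = 2, seed = 1)
  dir <- tempfile("bundle")
  save_rt_model(fit, dir)
  expect_setequal(list.files(dir),
                  c("genome.json", "weights.txt", "bn_state.txt",
                    "scaler.json", "manifest.json"))
  back <- load_rt_model(dir)
  peps <- ds$records$peptide[1:20]
  expect_equal(predict(back, peps), predict(fit, peps), tolerance = 1e-12)
})

test_that("print, summary, residuals and coef behave", {
  ds <- make_dataset(n = 120, seed = 67)
  fit <- rtnet(tiny_genome(), ds, max_epochs = 2, seed = 1)
  expect_output(print(fit), "Retention time model")
  expect_output(print(summary(fit)), "parameters")
  r <- residuals(fit, ds, "test")
  expect_length(r, sum(ds$records$partition == "test"))
  expect_identical(coef(fit), fit$weights)
})
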
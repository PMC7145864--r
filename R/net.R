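#' Fit a retention time regression network
#'
#' Trains the package's sequence regression network — one-hot encoded
#' peptide -> convolutional blocks -> fixed bidirectional GRU -> dense
#' blocks -> linear output — on the training partition of an
#' [split_rt_dataset()] dataset.  Retention times are min-max scaled to
#' \[0, 1\] using the dataset's train-partition scaler before fitting and
#' mapped back to minutes at prediction time.  Training minimizes mean
#' squared error by minibatch gradient descent with the genome's optimizer;
#' after every epoch the validation MSE is evaluated and the weights of the
#' best validation epoch are kept (early stopping with patience).
#'
#' @param genome an `rt_genome` describing the architecture (see
#'   [random_genome()], [default_genome()]).
#' @param dataset an `rt_dataset` from [split_rt_dataset()].
#' @param alphabet the [rt_alphabet()] the peptides are tokenized over.
#' @param fixed_length encoding length; defaults to the longest peptide in
#'   the dataset.
#' @param max_epochs maximum training epochs (default 100).
#' @param batch_size minibatch size (default 64).
#' @param patience epochs without validation improvement before stopping
#'   (default 10).
#' @param seed integer seed for weight initialization, shuffling and
#'   dropout; fixing it makes training reproducible.
#' @param learning_rate optional learning rate; `NULL` uses the optimizer's
#'   default (0.001 for adam and rmsprop, 0.01 for sgd with momentum).
#' @return an object of class `rtnet`: the genome, flat weight vector,
#'   batch-norm state, scaler, alphabet, `fixed_length`, and a `provenance`
#'   list (run id, epochs run, best epoch, best validation MSE in scaled
#'   units, seed, per-epoch history).
#' @seealso [fine_tune()], [predict.rtnet()], [rt_nas()]
#' @export
rtnet <- function(genome, dataset, alphabet = rt_alphabet(),
                  fixed_length = NULL, max_epochs = 100L, batch_size = 64L,
                  patience = 10L, seed = 1L, learning_rate = NULL) {
  stopifnot(inherits(genome, "rt_genome"), inherits(dataset, "rt_dataset"))
  if (max_epochs < 1L)
    stop("max_epochs must be >= 1: no checkpoint can be produced otherwise",
         call. = FALSE)
  tr <- dataset_part(dataset, "train")
  va <- dataset_part(dataset, "validation")
  if (!nrow(va))
    stop("dataset has no validation partition", call. = FALSE)
  if (is.null(fixed_length))
    fixed_length <- max(nchar(c(tr$peptide, va$peptide,
                                dataset_part(dataset, "test")$peptide)))
  spec <- genome_to_spec(genome, length(alphabet$tokens), fixed_length)
  xtr <- pep_encode_index(tr$peptide, alphabet, fixed_length)
  xva <- pep_encode_index(va$peptide, alphabet, fixed_length)
  ytr <- scale_rt(tr$observed_rt, dataset$scaler)
  yva <- scale_rt(va$observed_rt, dataset$scaler)
  fit <- cpp_rtnet_train(spec, xtr, ytr, xva, yva,
                         as.integer(max_epochs), as.integer(batch_size),
                         as.integer(patience),
                         numeric(0), numeric(0), as.integer(seed),
                         if (is.null(learning_rate)) -1 else learning_rate)
  if (fit$diverged)
    stop("training diverged (non-finite loss) at epoch ", fit$epochs_run,
         call. = FALSE)
  structure(list(
    genome = genome,
    weights = fit$weights,
    bn_state = fit$bn_state,
    scaler = dataset$scaler,
    alphabet = alphabet,
    fixed_length = fixed_length,
    provenance = list(run_id = dataset$run_id,
                      n_train = nrow(tr), n_validation = nrow(va),
                      epochs_run = fit$epochs_run,
                      best_epoch = fit$best_epoch,
                      best_val_mse = fit$best_val_mse,
                      seed = seed,
                      history = data.frame(epoch = seq_along(fit$history_train),
                                           train_mse = fit$history_train,
                                           val_mse = fit$history_val),
                      fine_tuned = FALSE)),
    class = "rtnet")
}

#' Fine-tune a trained model on a run-specific dataset
#'
#' Transfer learning for LC-MS/MS runs: starting from the weights of a
#' base model, all layers are further trained (none frozen) on the run's
#' own training partition, and the checkpoint with the best run-validation
#' MSE is returned.  The returned model carries the run's own RT scaler.
#' With `max_epochs = 0` the base weights are returned unchanged except for
#' the scaler swap.
#'
#' @param base a fitted [rtnet()] model.
#' @param run_dataset an `rt_dataset` for the run, with the scaler fit on
#'   the run's own training partition.
#' @param max_epochs maximum fine-tuning epochs (default 40).
#' @param batch_size minibatch size (default 64, as in base training).
#' @param patience early-stop patience (default 5).
#' @param seed integer seed.
#' @param learning_rate optional learning rate override.
#' @return an `rtnet` with updated weights, the run's scaler, and
#'   provenance noting the fine-tuning.
#' @export
fine_tune <- function(base, run_dataset, max_epochs = 40L, batch_size = 64L,
                      patience = 5L, seed = 1L, learning_rate = NULL) {
  stopifnot(inherits(base, "rtnet"), inherits(run_dataset, "rt_dataset"))
  tr <- dataset_part(run_dataset, "train")
  va <- dataset_part(run_dataset, "validation")
  if (nrow(tr) < 50L)
    warning("run training set has only ", nrow(tr),
            " peptides; fine-tuning proceeds but may be unstable")
  out <- base
  out$scaler <- run_dataset$scaler
  if (max_epochs == 0L) {
    out$provenance$fine_tuned <- TRUE
    out$provenance$run_id <- run_dataset$run_id
    return(out)
  }
  spec <- genome_to_spec(base$genome, length(base$alphabet$tokens),
                         base$fixed_length)
  xtr <- pep_encode_index(tr$peptide, base$alphabet, base$fixed_length)
  xva <- pep_encode_index(va$peptide, base$alphabet, base$fixed_length)
  ytr <- scale_rt(tr$observed_rt, run_dataset$scaler)
  yva <- scale_rt(va$observed_rt, run_dataset$scaler)
  fit <- cpp_rtnet_train(spec, xtr, ytr, xva, yva,
                         as.integer(max_epochs), as.integer(batch_size),
                         as.integer(patience),
                         base$weights, base$bn_state, as.integer(seed),
                         if (is.null(learning_rate)) -1 else learning_rate)
  if (fit$diverged)
    stop("fine-tuning diverged (non-finite loss)", call. = FALSE)
  out$weights <- fit$weights
  out$bn_state <- fit$bn_state
  out$provenance <- list(run_id = run_dataset$run_id,
                         n_train = nrow(tr), n_validation = nrow(va),
                         epochs_run = fit$epochs_run,
                         best_epoch = fit$best_epoch,
                         best_val_mse = fit$best_val_mse,
                         seed = seed,
                         history = data.frame(
                           epoch = seq_along(fit$history_train),
                           train_mse = fit$history_train,
                           val_mse = fit$history_val),
                         fine_tuned = TRUE,
                         base_val_mse = base$provenance$best_val_mse)
  out
}

#' Predict retention times for peptides
#'
#' @param object a fitted [rtnet()] model.
#' @param newdata character vector of peptide token strings, or a data
#'   frame with a `peptide` column.
#' @param ... unused.
#' @return numeric vector of predicted retention times in minutes.
#' @export
predict.rtnet <- function(object, newdata, ...) {
  peptides <- if (is.data.frame(newdata)) newdata$peptide else newdata
  x <- pep_encode_index(peptides, object$alphabet, object$fixed_length)
  spec <- genome_to_spec(object$genome, length(object$alphabet$tokens),
                         object$fixed_length)
  scaled <- cpp_rtnet_predict(spec, object$weights, object$bn_state, x)
  unscale_rt(scaled, object$scaler)
}

#' @export
print.rtnet <- function(x, ...) {
  p <- x$provenance
  cat("Retention time model (",
      if (isTRUE(p$fine_tuned)) "fine-tuned" else "base",
      ")\n", sep = "")
  cat("  architecture: ", x$genome$n_conv, " conv + BiGRU(",
      x$genome$gru_units, ") + ", x$genome$n_dense, " dense, ",
      x$genome$optimizer, "\n", sep = "")
  cat("  parameters:", length(x$weights), "\n")
  cat("  trained:", p$epochs_run, "epochs (best epoch", p$best_epoch,
      "), validation MSE", signif(p$best_val_mse, 4), "(scaled RT)\n")
  cat("  RT range: [", format(x$scaler[1]), ",", format(x$scaler[2]),
      "] min\n")
  invisible(x)
}

#' @export
summary.rtnet <- function(object, ...) {
  out <- list(genome = object$genome,
              n_parameters = length(object$weights),
              provenance = object$provenance,
              scaler = object$scaler)
  class(out) <- "summary.rtnet"
  out
}

#' @export
print.summary.rtnet <- function(x, ...) {
  print(x$genome)
  cat("parameters:", x$n_parameters, "\n")
  h <- x$provenance$history
  if (!is.null(h) && nrow(h)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(h, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.rtnet <- function(object, ...) object$weights

#' Residuals of a retention time model
#'
#' Observed minus predicted RT (minutes) on a chosen partition of a
#' dataset.
#'
#' @param object a fitted `rtnet`.
#' @param dataset an `rt_dataset`; defaults to requiring one explicitly.
#' @param partition which partition to evaluate (default `"test"`).
#' @param ... unused.
#' @return numeric vector of residuals in minutes.
#' @export
residuals.rtnet <- function(object, dataset, partition = "test", ...) {
  part <- dataset_part(dataset, partition)
  part$observed_rt - predict(object, part$peptide)
}

#' Observed-versus-predicted plot for a retention time model
#'
#' @param x a fitted `rtnet`.
#' @param dataset an `rt_dataset`.
#' @param partition partition to plot (default `"test"`).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of observed and predicted RTs.
#' @export
plot.rtnet <- function(x, dataset, partition = "test", ...) {
  part <- dataset_part(dataset, partition)
  pred <- predict(x, part$peptide)
  graphics::plot(part$observed_rt, pred,
                 xlab = "observed RT (min)", ylab = "predicted RT (min)",
                 main = paste("rtnet:", partition, "partition"), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(peptide = part$peptide,
                       observed_rt = part$observed_rt,
                       predicted_rt = pred))
}

#' Evaluate a model's median absolute error on a dataset partition
#'
#' @param model a fitted `rtnet`.
#' @param dataset an `rt_dataset`.
#' @param partition partition to evaluate (default `"test"`).
#' @return median absolute RT error in minutes.
#' @export
evaluate_mae <- function(model, dataset, partition = "test") {
  median(abs(residuals(model, dataset, partition)))
}
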
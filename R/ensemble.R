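#' IQR-filtered average
#'
#' Averages a vector of predictions after removing outliers by the
#' interquartile-range rule: values outside the inclusive bounds
#' `[Q1 - whisker * IQR, Q3 + whisker * IQR]` are excluded and the mean of
#' the remainder is returned.  Quartiles use linear interpolation between
#' order statistics (the common type-7 convention; the choice is frozen in
#' the package's tests).  Because the bounds are inclusive and contain the
#' central half of the data, at least one value always survives.
#'
#' @param values numeric vector of predictions (at least one).
#' @param whisker multiplier of the IQR beyond the quartiles (default 1.5).
#' @return a list with `final` (mean of retained values), `retained`
#'   (the surviving values, input order), `q1`, `q3`, `iqr`, `lower`,
#'   `upper`.
#' @examples
#' iqr_average(c(rep(10, 9), 100))$final  # 10
#' @export
iqr_average <- function(values, whisker = 1.5) {
  if (!length(values)) stop("no values to average", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numerics", call. = FALSE)
  qs <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  lower <- qs[1] - whisker * iqr
  upper <- qs[2] + whisker * iqr
  keep <- values >= lower & values <= upper
  if (!any(keep)) keep <- rep(TRUE, length(values))  # defensive; unreachable
  list(final = mean(values[keep]), retained = values[keep],
       q1 = qs[1], q3 = qs[2], iqr = iqr, lower = lower, upper = upper)
}

#' Ensemble retention time prediction
#'
#' Predicts RT for each peptide with every member model (each predicting
#' in its own scaled space and inverting its own scaler back to minutes)
#' and combines the member predictions by [iqr_average()].  All member
#' models must share the residue alphabet and encoding length.
#'
#' @param models list of fitted [rtnet()] models (typically the top
#'   architectures from [rt_nas()], fine-tuned per run).
#' @param peptides character vector of peptide token strings.
#' @param whisker IQR whisker multiplier (default 1.5).
#' @return a data frame of class `rt_ensemble_prediction` with columns
#'   `peptide`, `final_rt`, `n_members`, `n_retained`, and a list column
#'   `member_rts`.
#' @export
predict_rt_ensemble <- function(models, peptides, whisker = 1.5) {
  if (!length(models)) stop("need at least one model", call. = FALSE)
  tok0 <- paste(models[[1]]$alphabet$tokens, collapse = "")
  for (m in models) {
    if (!inherits(m, "rtnet"))
      stop("all models must be rtnet objects", call. = FALSE)
    if (!identical(paste(m$alphabet$tokens, collapse = ""), tok0))
      stop("models disagree on the residue alphabet", call. = FALSE)
    if (m$fixed_length != models[[1]]$fixed_length)
      stop("models disagree on the encoding length", call. = FALSE)
  }
  preds <- vapply(models, predict, numeric(length(peptides)),
                  newdata = peptides)
  if (length(peptides) == 1L) preds <- matrix(preds, nrow = 1)
  rows <- lapply(seq_along(peptides), function(i) {
    r <- iqr_average(preds[i, ], whisker)
    list(final_rt = r$final, n_retained = length(r$retained))
  })
  out <- data.frame(peptide = peptides,
                    final_rt = vapply(rows, `[[`, numeric(1), "final_rt"),
                    n_members = length(models),
                    n_retained = vapply(rows, `[[`, numeric(1),
                                        "n_retained"),
                    stringsAsFactors = FALSE)
  out$member_rts <- lapply(seq_along(peptides), function(i) unname(preds[i, ]))
  class(out) <- c("rt_ensemble_prediction", class(out))
  out
}

#' @export
print.rt_ensemble_prediction <- function(x, ...) {
  cat("Ensemble RT predictions:", nrow(x), "peptides,",
      x$n_members[1], "member models\n")
  print.data.frame(head(x[, c("peptide", "final_rt", "n_retained")], 10),
                   row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write ensemble predictions to TSV
#'
#' Columns: `peptide`, `final_rt`, `n_members`, `n_retained`,
#' `member_rts` (JSON array).
#'
#' @param predictions an `rt_ensemble_prediction`.
#' @param path output file path.
#' @export
write_rt_predictions <- function(predictions, path) {
  out <- predictions[, c("peptide", "final_rt", "n_members", "n_retained")]
  out$member_rts <- vapply(predictions$member_rts, function(v)
    as.character(jsonlite::toJSON(v, digits = NA)), character(1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
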
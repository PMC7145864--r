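#' RT error of peptide identifications
#'
#' For identification quality control the observed RT of a peptide is the
#' spectrum RT of its best PSM (unlike model training, which averages over
#' all spectra of the peptide); the predicted RT comes from the run's
#' ensemble model.  The absolute difference between the two is the quality
#' metric.
#'
#' @param hits peptide-level hits (e.g. `hits_passing` of an
#'   [global_fdr()] report) with columns `peptide`, `spectrum_rt` and
#'   optionally `run_id`.
#' @param models list of fitted [rtnet()] models for the run (the
#'   ensemble), or a single `rtnet`.
#' @param whisker IQR whisker for the ensemble combination (default 1.5).
#' @return data frame with columns `peptide`, `run_id`, `observed_rt`,
#'   `predicted_rt`, `abs_error` (all RTs in minutes).
#' @export
rt_error <- function(hits, models, whisker = 1.5) {
  stopifnot(all(c("peptide", "spectrum_rt") %in% names(hits)))
  if (inherits(models, "rtnet")) models <- list(models)
  if (!nrow(hits))
    return(data.frame(peptide = character(0), run_id = character(0),
                      observed_rt = numeric(0), predicted_rt = numeric(0),
                      abs_error = numeric(0)))
  ens <- predict_rt_ensemble(models, hits$peptide, whisker)
  data.frame(peptide = hits$peptide,
             run_id = if ("run_id" %in% names(hits)) hits$run_id
                      else NA_character_,
             observed_rt = hits$spectrum_rt,
             predicted_rt = ens$final_rt,
             abs_error = abs(hits$spectrum_rt - ens$final_rt),
             stringsAsFactors = FALSE)
}

#' Median absolute RT error
#'
#' The package's headline accuracy metric: the median of the absolute
#' observed-minus-predicted RT errors, in minutes (interpolated median for
#' even counts).
#'
#' @param x numeric vector of absolute errors, or a data frame with an
#'   `abs_error` column (as from [rt_error()]).
#' @return median absolute error in minutes.
#' @export
rt_mae <- function(x) {
  err <- if (is.data.frame(x)) x$abs_error else x
  if (!length(err)) stop("no records", call. = FALSE)
  median(err)
}

#' Flag identifications with large RT errors
#'
#' Splits RT-error records at a threshold: records with
#' `abs_error > max_error_minutes` are flagged for more critical
#' evaluation, the rest are kept.  The boundary is strict, so an error of
#' exactly the threshold is kept.  The 5-minute default is a soft
#' screening value, not a hard rule.
#'
#' @param records data frame from [rt_error()].
#' @param max_error_minutes flagging threshold in minutes (default 5).
#' @return list with data frames `kept` and `flagged`.
#' @export
filter_by_rt_error <- function(records, max_error_minutes = 5.0) {
  flag <- records$abs_error > max_error_minutes
  list(kept = records[!flag, , drop = FALSE],
       flagged = records[flag, , drop = FALSE])
}

#' Per-group RT error summary
#'
#' Summarizes RT-error records by caller-supplied group labels (e.g. FDR
#' method crossed with validation status): group size and median absolute
#' error, ordered by group name.  Empty groups are omitted.
#'
#' @param records data frame from [rt_error()].
#' @param group character or factor vector of group labels, one per
#'   record.
#' @return data frame with columns `group`, `n`, `median_abs_error`.
#' @export
rt_group_summary <- function(records, group) {
  stopifnot(length(group) == nrow(records))
  sp <- split(records$abs_error, as.character(group))
  out <- data.frame(group = names(sp),
                    n = vapply(sp, length, integer(1)),
                    median_abs_error = vapply(sp, median, numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare RT error between two groups
#'
#' Convenience Wilcoxon rank-sum comparison of absolute RT errors between
#' two groups of identifications; reporting, not method.
#'
#' @param errors_a,errors_b numeric vectors of absolute errors.
#' @param alternative passed to [stats::wilcox.test()].
#' @return the `htest` object.
#' @export
compare_rt_error <- function(errors_a, errors_b,
                             alternative = "two.sided") {
  wilcox.test(errors_a, errors_b, alternative = alternative)
}

#' Write an RT quality-control report
#'
#' Columns: `peptide`, `run_id`, `observed_rt`, `predicted_rt`,
#' `abs_error`, `flagged`.
#'
#' @param records data frame from [rt_error()].
#' @param path output file path.
#' @param max_error_minutes flagging threshold (default 5).
#' @export
write_qc_report <- function(records, path, max_error_minutes = 5.0) {
  records$flagged <- records$abs_error > max_error_minutes
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
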
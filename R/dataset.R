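#' Aggregate spectrum-level retention times per peptide
#'
#' For model training the observed RT of a peptide is the arithmetic mean of
#' the RTs of all spectra identified for it in the same LC-MS/MS run; the
#' spread (max - min) across those spectra is kept as `rt_span` so unstable
#' peptides can be filtered out.
#'
#' @param observations data frame with columns `peptide` (token string),
#'   `rt_minutes` (non-negative, minutes) and optionally `n_engines` (1-3,
#'   number of search engines agreeing on the identification; propagated as
#'   the maximum over spectra) and `run_id` (must be constant).
#' @return data frame with one row per distinct peptide and columns
#'   `peptide`, `observed_rt`, `rt_span`, `n_spectra`, `n_engines`.
#' @examples
#' obs <- data.frame(peptide = c("PEPTIDEK", "PEPTIDEK"),
#'                   rt_minutes = c(10, 12))
#' aggregate_observed_rt(obs)
#' @export
aggregate_observed_rt <- function(observations) {
  empty <- data.frame(peptide = character(0), observed_rt = numeric(0),
                      rt_span = numeric(0), n_spectra = integer(0),
                      n_engines = integer(0), stringsAsFactors = FALSE)
  if (!nrow(observations)) return(empty)
  stopifnot(all(c("peptide", "rt_minutes") %in% names(observations)))
  if ("run_id" %in% names(observations) &&
      length(unique(observations$run_id)) > 1L)
    stop("observations span multiple runs; aggregate one run at a time",
         call. = FALSE)
  if (any(observations$rt_minutes < 0))
    stop("negative rt_minutes", call. = FALSE)
  ne <- if ("n_engines" %in% names(observations)) observations$n_engines
        else rep(1L, nrow(observations))
  sp <- split(seq_len(nrow(observations)), observations$peptide)
  out <- lapply(sp, function(ix) {
    rts <- observations$rt_minutes[ix]
    data.frame(peptide = observations$peptide[ix[1]],
               observed_rt = mean(rts),
               rt_span = max(rts) - min(rts),
               n_spectra = length(ix),
               n_engines = as.integer(max(ne[ix])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter peptide records for training quality
#'
#' Keeps only peptides identified by at least `min_engines` search engines
#' and whose spectrum-to-spectrum RT span does not exceed
#' `max_span_minutes`.  The span boundary is strict: a record is removed
#' only when its span is greater than the threshold, so a span of exactly
#' 3 minutes survives the default filter.
#'
#' @param records data frame as produced by [aggregate_observed_rt()].
#' @param min_engines minimum number of agreeing search engines (default 2
#'   of the usual 3).
#' @param max_span_minutes maximum tolerated RT span in minutes (default 3).
#' @return the retained rows, input order preserved.
#' @export
filter_training_records <- function(records, min_engines = 2,
                                    max_span_minutes = 3.0) {
  stopifnot(all(c("n_engines", "rt_span") %in% names(records)))
  keep <- records$n_engines >= min_engines &
    records$rt_span <= max_span_minutes
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split peptide records into train / validation / test partitions
#'
#' Partitions at the peptide level (never the spectrum level, which would
#' leak information): by default 90% of peptides form the training part and
#' 10% are held out for testing; 10% of the training part is set aside as
#' validation data for early stopping and model selection.  The RT scaler is
#' fit on the training partition only.
#'
#' @param records data frame with at least `peptide` and `observed_rt`.
#' @param train_frac fraction of peptides in the training part (default 0.9).
#' @param valid_frac_of_train fraction of the training part used for
#'   validation (default 0.1).
#' @param seed integer seed making the split reproducible.
#' @param run_id optional run label stored with the dataset.
#' @return an object of class `rt_dataset`: list with `records` (the input
#'   plus a `partition` column with values `"train"`, `"validation"`,
#'   `"test"`), `scaler` (from [fit_rt_scaler()] on the train partition) and
#'   `run_id`.
#' @export
split_rt_dataset <- function(records, train_frac = 0.9,
                             valid_frac_of_train = 0.1, seed = 1L,
                             run_id = NA_character_) {
  stopifnot(all(c("peptide", "observed_rt") %in% names(records)))
  n <- nrow(records)
  if (n < 10L)
    stop("need at least 10 peptide records to split, got ", n, call. = FALSE)
  if (anyDuplicated(records$peptide))
    stop("duplicate peptides in records; aggregate first", call. = FALSE)
  part <- with_seed_(seed, {
    p <- rep("train", n)
    n_test <- round((1 - train_frac) * n)
    test_ix <- sample.int(n, n_test)
    p[test_ix] <- "test"
    train_ix <- setdiff(seq_len(n), test_ix)
    n_val <- round(valid_frac_of_train * length(train_ix))
    val_ix <- sample(train_ix, n_val)
    p[val_ix] <- "validation"
    p
  })
  records$partition <- part
  scaler <- fit_rt_scaler(records$observed_rt[part == "train"])
  structure(list(records = records, scaler = scaler, run_id = run_id,
                 seed = seed),
            class = "rt_dataset")
}

#' @export
print.rt_dataset <- function(x, ...) {
  tab <- table(x$records$partition)
  cat("RT dataset", if (!is.na(x$run_id)) paste0("(run ", x$run_id, ")"),
      "\n  peptides:", nrow(x$records),
      sprintf("(train %d / validation %d / test %d)",
              tab[["train"]], tab[["validation"]], tab[["test"]]),
      "\n  RT scaler: [", format(x$scaler[1]), ",", format(x$scaler[2]),
      "] min\n")
  invisible(x)
}

#' Min-max retention time scaler
#'
#' Fits the linear map that sends the training RT range onto \[0, 1\].  The
#' scaler must be fit on the training partition only; applying it to test
#' RTs outside the training range extrapolates beyond \[0, 1\], which is
#' legitimate.
#'
#' @param rt numeric vector of training RTs in minutes.
#' @return numeric vector `c(rt_min, rt_max)` of class `rt_scaler`.
#' @export
fit_rt_scaler <- function(rt) {
  if (!length(rt) || !all(is.finite(rt)))
    stop("non-finite or empty RT vector", call. = FALSE)
  r <- range(rt)
  if (r[1] >= r[2])
    stop("degenerate RT scaler: all training RTs equal (", r[1], ")",
         call. = FALSE)
  structure(c(rt_min = r[1], rt_max = r[2]), class = "rt_scaler")
}

#' @rdname fit_rt_scaler
#' @param scaler an `rt_scaler`.
#' @export
scale_rt <- function(rt, scaler) {
  (rt - scaler[[1]]) / (scaler[[2]] - scaler[[1]])
}

#' @rdname fit_rt_scaler
#' @param scaled scaled RT values.
#' @export
unscale_rt <- function(scaled, scaler) {
  scaled * (scaler[[2]] - scaler[[1]]) + scaler[[1]]
}

dataset_part <- function(dataset, which) {
  dataset$records[dataset$records$partition == which, , drop = FALSE]
}

#' Read and write per-run peptide tables
#'
#' The on-disk contract for one LC-MS/MS run is a UTF-8 tab-separated file
#' with a header and columns `spectrum_id`, `peptide`, `rt_minutes`,
#' `n_engines` ('.' decimal separator, RT in minutes).  `write_rt_dataset()`
#' emits the aggregated per-peptide table with its partition labels.
#'
#' @param path file path.
#' @return `read_run_tsv()`: data frame of spectrum observations.
#' @export
read_run_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("spectrum_id", "peptide", "rt_minutes", "n_engines")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("run TSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$rt_minutes))
    stop("run TSV ", path, ": rt_minutes is not numeric", call. = FALSE)
  df
}

#' @rdname read_run_tsv
#' @param dataset an `rt_dataset`.
#' @export
write_rt_dataset <- function(dataset, path) {
  out <- dataset$records[, c("peptide", "observed_rt", "rt_span",
                             "n_spectra", "partition")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
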
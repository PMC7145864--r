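#' Reduce peptide-spectrum matches to peptide-level hits
#'
#' Peptide-level FDR estimation uses only the best-scoring PSM for each
#' peptide.  Hits are formed per distinct (peptide, label) pair so a
#' target and a decoy sequence that happen to share tokens stay separate.
#' Score ties are broken deterministically by the lexicographically
#' smallest `spectrum_id`.
#'
#' @param psms data frame with columns `spectrum_id`, `peptide`, `score`,
#'   `label` (`"target"`/`"decoy"`) and optionally `run_id`, `pep_class`
#'   (`"reference"`/`"variant"`), `spectrum_rt`.
#' @return data frame with one row per (peptide, label): all PSM columns
#'   of the best PSM plus `n_psms`.
#' @export
best_psm_per_peptide <- function(psms) {
  stopifnot(all(c("spectrum_id", "peptide", "score", "label") %in%
                  names(psms)))
  if (!nrow(psms)) {
    psms$n_psms <- integer(0)
    return(psms)
  }
  key <- paste(psms$peptide, psms$label, sep = "\r")
  ord <- order(key, -psms$score, psms$spectrum_id, method = "radix")
  sorted <- psms[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  out <- sorted[first, , drop = FALSE]
  out$n_psms <- as.integer(table(key)[key[ord][first]])
  rownames(out) <- NULL
  out
}

#' Classify peptides as reference or variant
#'
#' A peptide that can be mapped to the reference protein database is a
#' reference peptide; everything else is a variant peptide.  Mapping uses
#' the unmodified sequence (modifications are ignored), so a modified form
#' of a reference peptide is still a reference peptide.
#'
#' @param peptides character vector of peptide token strings.
#' @param reference_peptides character vector or set of plain reference
#'   sequences (e.g. from tryptic digestion of the reference proteome).
#' @param alphabet alphabet used to strip modification characters.
#' @return character vector `"reference"`/`"variant"`.
#' @export
assign_pep_class <- function(peptides, reference_peptides,
                             alphabet = rt_alphabet()) {
  plain <- pep_plain(peptides, alphabet)
  ifelse(plain %in% reference_peptides, "reference", "variant")
}

# Shared machinery: walk candidate cutoffs down the observed target
# scores, computing FDR at each, then convert to q-values by a running
# minimum from the most permissive cutoff upward. At an exactly tied
# score, decoys are counted before targets (conservative).
#
# hits: data frame with score and label; fdr_at: function(D_above, T_above)
# -> FDR where D_above counts decoys with score >= cutoff among
# `decoy_pool` and T_above counts targets with score >= cutoff among
# `target_pool`.
qvalues_from_counts <- function(target_scores, decoy_scores, fdr_fun) {
  nt <- length(target_scores)
  if (!nt) return(numeric(0))
  ord <- order(target_scores, decreasing = TRUE)
  sorted_t <- target_scores[ord]
  # decoys with score >= each target score (ties: decoy counted)
  sorted_d <- sort(decoy_scores, decreasing = TRUE)
  d_above <- findInterval(-sorted_t, -sorted_d)
  t_above <- seq_len(nt)
  # at tied target scores every tied target shares the most permissive
  # count (all ties are above a cutoff placed at that score)
  last_of_tie <- c(sorted_t[-nt] != sorted_t[-1], TRUE)
  ends <- which(last_of_tie)
  tie_group <- rep(ends, times = diff(c(0L, ends)))
  d_above <- d_above[tie_group]
  t_above <- tie_group
  fdr <- vapply(seq_len(nt), function(i) fdr_fun(d_above[i], t_above[i]),
                numeric(1))
  q <- rev(cummin(rev(pmin(fdr, 1))))
  q[order(ord)]  # back to input order
}

fdr_report <- function(method, hits, q, threshold, counts) {
  hits$q_value <- q
  passing <- hits[hits$label == "target" & hits$q_value <= threshold, ,
                  drop = FALSE]
  rownames(passing) <- NULL
  structure(list(method = method, hits = hits, hits_passing = passing,
                 threshold = threshold, counts = counts),
            class = "fdr_report")
}

#' Global target-decoy FDR at peptide level
#'
#' Scores reference and variant peptides together: at a score cutoff the
#' FDR estimate is `D / T`, the number of decoy peptide hits at or above
#' the cutoff divided by the number of target peptide hits at or above it.
#' Estimates are converted to q-values by a running minimum so that
#' filtering at a threshold is well defined, and target hits with
#' `q <= threshold` pass.
#'
#' @param hits peptide-level hits from [best_psm_per_peptide()] with
#'   columns `peptide`, `score`, `label`.
#' @param threshold q-value threshold (default 0.01).
#' @return an object of class `fdr_report`: `hits` (targets and decoys
#'   with `q_value` on targets), `hits_passing`, `threshold`, `counts`.
#' @export
global_fdr <- function(hits, threshold = 0.01) {
  stopifnot(all(c("peptide", "score", "label") %in% names(hits)))
  targets <- hits[hits$label == "target", , drop = FALSE]
  decoys <- hits[hits$label == "decoy", , drop = FALSE]
  if (!nrow(targets))
    return(fdr_report("global", transform(hits[0, ], q_value = numeric(0)),
                      numeric(0), threshold,
                      list(n_targets = 0L, n_decoys = nrow(decoys))))
  q <- qvalues_from_counts(targets$score, decoys$score,
                           function(D, T) D / T)
  targets$q_value <- q
  decoys$q_value <- rep(NA_real_, nrow(decoys))
  all_hits <- rbind(targets, decoys)
  fdr_report("global", all_hits, all_hits$q_value, threshold,
             list(n_targets = nrow(targets), n_decoys = nrow(decoys)))
}

#' Separate (class-specific) FDR for reference and variant peptides
#'
#' Reference-class hits are scored by the global estimator restricted to
#' the reference class.  Variant-class hits are scored by
#' `FDR_n = (D+ * D_n / D) / T_n+`, where at each cutoff `D+` counts all
#' decoy hits (both classes) at or above the cutoff and `T_n+` counts
#' variant target hits at or above it, while `D_n` (total decoy variant
#' hits) and `D` (total decoy hits) are cutoff-independent totals whose
#' ratio approximates the fraction of variant sequences in the search
#' space.
#'
#' @param hits peptide-level hits with columns `peptide`, `score`,
#'   `label`, `pep_class`.
#' @param threshold q-value threshold (default 0.01).
#' @return list with elements `reference` and `variant`, each an
#'   `fdr_report`.
#' @export
separate_fdr <- function(hits, threshold = 0.01) {
  stopifnot(all(c("peptide", "score", "label", "pep_class") %in%
                  names(hits)))
  ref <- hits[hits$pep_class == "reference", , drop = FALSE]
  ref_report <- global_fdr(ref, threshold)
  ref_report$method <- "separate"

  var_targets <- hits[hits$label == "target" & hits$pep_class == "variant", ,
                      drop = FALSE]
  all_decoys <- hits[hits$label == "decoy", , drop = FALSE]
  D_n <- sum(all_decoys$pep_class == "variant")
  D <- nrow(all_decoys)
  if (D == 0L && nrow(all_decoys) == 0L) {
    # no decoys at all: D+ is identically zero, so FDR_n = 0
    frac <- 0
  } else if (D_n == 0L) {
    frac <- 0  # no variant decoys observed; variant search-space fraction ~ 0
  } else {
    frac <- D_n / D
  }
  q <- if (nrow(var_targets))
    qvalues_from_counts(var_targets$score, all_decoys$score,
                        function(Dp, Tn) Dp * frac / Tn)
  else numeric(0)
  var_targets$q_value <- q
  var_decoys <- hits[hits$label == "decoy" & hits$pep_class == "variant", ,
                     drop = FALSE]
  var_decoys$q_value <- rep(NA_real_, nrow(var_decoys))
  var_hits <- rbind(var_targets, var_decoys)
  var_report <- fdr_report("separate", var_hits, var_hits$q_value,
                           threshold,
                           list(D_n = D_n, D = D,
                                n_variant_targets = nrow(var_targets)))
  list(reference = ref_report, variant = var_report)
}

#' Two-stage FDR for variant peptides
#'
#' Emulates the sequential search strategy: the first-stage matches
#' against the reference database are filtered at the peptide-level
#' q-value threshold, the spectra so identified are removed from the
#' second-stage (variant database) matches, and the global estimator is
#' applied to the remaining second-stage hits.
#'
#' @param stage1_psms PSM data frame from the reference-database search.
#' @param stage2_psms PSM data frame from the variant-database search
#'   (shares the spectrum id space with stage 1).
#' @param threshold q-value threshold used at both stages (default 0.01).
#' @return an `fdr_report` for the second stage, with `counts` recording
#'   the number of spectra removed after stage 1.
#' @export
two_stage_fdr <- function(stage1_psms, stage2_psms, threshold = 0.01) {
  stage1_hits <- best_psm_per_peptide(stage1_psms)
  stage1 <- global_fdr(stage1_hits, threshold)
  passing_peptides <- stage1$hits_passing$peptide
  # spectra whose (best) identification passed: every stage-1 PSM whose
  # target peptide is in the passing set counts as a confidently
  # identified spectrum
  t1 <- stage1_psms[stage1_psms$label == "target", , drop = FALSE]
  confident_spectra <- unique(t1$spectrum_id[t1$peptide %in%
                                               passing_peptides])
  keep <- !(stage2_psms$spectrum_id %in% confident_spectra)
  stage2 <- stage2_psms[keep, , drop = FALSE]
  hits2 <- best_psm_per_peptide(stage2)
  report <- global_fdr(hits2, threshold)
  report$method <- "two_stage"
  report$counts$n_spectra_removed <- sum(!keep)
  report$counts$n_stage1_passing <- length(passing_peptides)
  report
}

#' @export
print.fdr_report <- function(x, ...) {
  cat("FDR report (", x$method, "), threshold ", x$threshold, "\n",
      sep = "")
  cat("  hits:", nrow(x$hits), " passing targets:",
      nrow(x$hits_passing), "\n")
  invisible(x)
}

#' Read and write PSM tables
#'
#' The PSM TSV contract: tab-separated with header, columns `spectrum_id`,
#' `run_id`, `peptide`, `score`, `label` (`target`/`decoy`), `pep_class`
#' (`reference`/`variant`), `spectrum_rt` (minutes).  Scores must be
#' oriented higher-is-better; engines reporting e-values should be
#' negated or log-transformed during ingestion.
#'
#' @param path file path.
#' @return `read_psm_tsv()`: data frame of PSMs.
#' @export
read_psm_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("spectrum_id", "run_id", "peptide", "score", "label",
            "pep_class", "spectrum_rt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("PSM TSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !df$label %in% c("target", "decoy")
  if (any(bad))
    stop("PSM TSV ", path, ": bad label at line ", which(bad)[1] + 1L,
         call. = FALSE)
  df
}

#' @rdname read_psm_tsv
#' @param report an `fdr_report`.
#' @export
write_fdr_report <- function(report, path) {
  h <- report$hits
  out <- data.frame(peptide = h$peptide, score = h$score, label = h$label,
                    pep_class = if ("pep_class" %in% names(h)) h$pep_class
                                else NA_character_,
                    q_value = h$q_value,
                    passing = !is.na(h$q_value) &
                      h$q_value <= report$threshold &
                      h$label == "target",
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
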
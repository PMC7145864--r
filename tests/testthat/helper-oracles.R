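# Independent brute-force oracles used to check the package's estimators.
# These are deliberately naive O(n^2) implementations written from the
# definitions, sharing no code with the package internals.

# q-values for the plain decoy/target estimator: for each target score s,
# the minimum over all candidate cutoffs c <= s (c running over observed
# target scores) of (#decoys >= c) / (#targets >= c), capped at 1.
bf_global_q <- function(target_scores, decoy_scores) {
  cutoffs <- sort(unique(target_scores))
  fdr <- vapply(cutoffs, function(cc) {
    min(sum(decoy_scores >= cc) / sum(target_scores >= cc), 1)
  }, numeric(1))
  vapply(target_scores, function(s) min(fdr[cutoffs <= s]), numeric(1))
}

# q-values for the class-specific variant estimator:
# FDR_n(c) = (D_plus(c) * D_n / D) / T_n_plus(c) with D_plus over all
# decoys (both classes) and T_n_plus over variant targets only.
bf_separate_variant_q <- function(variant_target_scores, all_decoy_scores,
                                  d_n, d_total) {
  frac <- if (d_total > 0) d_n / d_total else 0
  cutoffs <- sort(unique(variant_target_scores))
  fdr <- vapply(cutoffs, function(cc) {
    min(sum(all_decoy_scores >= cc) * frac /
          sum(variant_target_scores >= cc), 1)
  }, numeric(1))
  vapply(variant_target_scores, function(s) min(fdr[cutoffs <= s]),
         numeric(1))
}

# brute-force sequential-search pipeline built from the oracles above:
# stage-1 q-values, removal of confidently identified spectra, stage-2
# q-values on the remainder; returns q named by peptide
bf_two_stage_q <- function(stage1, stage2, threshold = 0.01) {
  h1 <- bf_best_psm(stage1)
  t1 <- h1[h1$label == "target", , drop = FALSE]
  q1 <- bf_global_q(t1$score, h1$score[h1$label == "decoy"])
  passing <- t1$peptide[q1 <= threshold]
  conf <- unique(stage1$spectrum_id[stage1$label == "target" &
                                      stage1$peptide %in% passing])
  s2 <- stage2[!stage2$spectrum_id %in% conf, , drop = FALSE]
  h2 <- bf_best_psm(s2)
  t2 <- h2[h2$label == "target", , drop = FALSE]
  setNames(bf_global_q(t2$score, h2$score[h2$label == "decoy"]),
           t2$peptide)
}

# brute-force best PSM per (peptide, label): explicit group-by with
# max score and lexicographic spectrum_id tie-break
bf_best_psm <- function(psms) {
  key <- paste(psms$peptide, psms$label, sep = "|")
  rows <- lapply(split(seq_len(nrow(psms)), key), function(ix) {
    grp <- psms[ix, , drop = FALSE]
    grp <- grp[grp$score == max(grp$score), , drop = FALSE]
    grp[order(grp$spectrum_id)[1], , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out[order(out$peptide, out$label), , drop = FALSE]
}

# brute-force IQR filter and mean with a hand-coded type-7 quantile
bf_iqr_average <- function(values, whisker = 1.5) {
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  q1 <- q7(values, 0.25)
  q3 <- q7(values, 0.75)
  iqr <- q3 - q1
  keep <- values >= q1 - whisker * iqr & values <= q3 + whisker * iqr
  mean(values[keep])
}

# a tiny, quick-to-train genome for tests that only need *a* network
tiny_genome <- function(space = rt_search_space()) {
  g <- default_genome(space)
  g$conv[[1]]$filters <- 8L
  g$dense[[1]]$units <- 16L
  g
}

# small synthetic dataset builder (identity distortion unless given)
make_dataset <- function(n = 120, noise_sd = 0, seed = 1,
                         distortion = NULL, length_range = c(7, 20)) {
  ab <- rt_alphabet()
  law <- retention_law(ab, noise_sd = noise_sd, distortion = distortion)
  peps <- simulate_peptides(n, length_range, ab, seed = seed)
  split_rt_dataset(simulate_rt(peps, law, seed = seed + 1),
                   seed = seed + 2)
}
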
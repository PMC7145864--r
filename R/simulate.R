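#' Synthetic retention law
#'
#' A ground-truthed model of peptide retention used by the package's
#' simulators: the noiseless RT of a peptide is an additive function of
#' its residues plus a length term, passed through an optional monotone
#' nonlinear run distortion, with Gaussian noise added on observation:
#' `RT = distortion(intercept + sum(coef[residue]) + length_coef * |p|) +
#' N(0, noise_sd)`.
#'
#' The default residue coefficients follow the familiar hydrophobicity
#' ordering (W, F, L, I most retained; K, R, H least), in minutes, and a
#' modification character contributes its base residue's coefficient
#' reduced by 1.5 min (oxidation makes peptides elute earlier).  With the
#' default intercept (5 min) and length coefficient (1.2 min/residue),
#' tryptic-length peptides (7-45 residues) span roughly a 10-80 min
#' gradient.
#'
#' @param alphabet an [rt_alphabet()].
#' @param intercept baseline RT in minutes.
#' @param length_coefficient minutes per residue.
#' @param residue_coefficients optional named vector (minutes) overriding
#'   the defaults; must cover every alphabet token.
#' @param distortion optional [run_distortion()]; `NULL` is the identity.
#' @param noise_sd Gaussian observation noise, minutes.
#' @return an object of class `rt_retention_law`.
#' @export
retention_law <- function(alphabet = rt_alphabet(), intercept = 5,
                          length_coefficient = 1.2,
                          residue_coefficients = NULL,
                          distortion = NULL, noise_sd = 0.3) {
  if (is.null(residue_coefficients)) {
    base <- c(A = 0.5, C = 0.2, D = -1.5, E = -1.2, F = 2.8, G = -0.5,
              H = -2.0, I = 2.6, K = -2.5, L = 2.7, M = 1.8, N = -1.3,
              P = 0.3, Q = -1.0, R = -2.2, S = -0.8, T = -0.4, V = 1.9,
              W = 3.0, Y = 1.3)
    mods <- alphabet$base  # modification char -> base residue
    modc <- setNames(base[mods] - 1.5, names(mods))
    residue_coefficients <- c(base, modc)
  }
  missing_tok <- setdiff(alphabet$tokens, names(residue_coefficients))
  if (length(missing_tok))
    stop("no retention coefficient for token(s): ",
         paste(missing_tok, collapse = ", "), call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(alphabet = alphabet, intercept = intercept,
                 length_coefficient = length_coefficient,
                 residue_coefficients = residue_coefficients,
                 distortion = distortion, noise_sd = noise_sd),
            class = "rt_retention_law")
}

#' Monotone nonlinear between-run RT distortion
#'
#' Emulates the run-to-run nonlinear RT shifts seen even on a single LC
#' system: a piecewise-linear map through `n_knots + 2` evenly spaced
#' knots over `range`, each knot displaced vertically by a draw from
#' `Unif(-max_offset, +max_offset)`.  With the default geometry (knots
#' ~20 min apart, offsets up to +/-8 min) consecutive offsets can never
#' reverse the ordering, so the map is strictly increasing by
#' construction; outside the knot range it extrapolates with the end
#' segment slopes.
#'
#' @param max_offset maximum vertical knot displacement, minutes
#'   (default 8).
#' @param n_knots number of interior knots (default 4).
#' @param range RT interval covered by the knots, minutes.
#' @param seed integer seed.
#' @return an object of class `rt_run_distortion` (knot coordinates).
#' @export
run_distortion <- function(max_offset = 8, n_knots = 4,
                           range = c(0, 100), seed = 1L) {
  stopifnot(max_offset >= 0, n_knots >= 0, range[2] > range[1])
  x <- seq(range[1], range[2], length.out = n_knots + 2)
  spacing <- diff(x)[1]
  if (2 * max_offset >= spacing)
    stop("max_offset too large for the knot spacing: monotonicity not ",
         "guaranteed (need 2*max_offset < ", signif(spacing, 3), ")",
         call. = FALSE)
  y <- with_seed_(seed, x + runif(length(x), -max_offset, max_offset))
  structure(list(x = x, y = y), class = "rt_run_distortion")
}

apply_distortion <- function(distortion, rt) {
  if (is.null(distortion)) return(rt)
  x <- distortion$x
  y <- distortion$y
  k <- length(x)
  slope_lo <- (y[2] - y[1]) / (x[2] - x[1])
  slope_hi <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
  out <- approx(x, y, xout = pmin(pmax(rt, x[1]), x[k]))$y
  lo <- rt < x[1]
  hi <- rt > x[k]
  out[lo] <- y[1] + slope_lo * (rt[lo] - x[1])
  out[hi] <- y[k] + slope_hi * (rt[hi] - x[k])
  out
}

#' Noiseless RT of peptides under a retention law
#'
#' @param peptides character vector of token strings.
#' @param law an [retention_law()].
#' @return numeric vector of noiseless (but distorted) RTs in minutes.
#' @export
true_rt <- function(peptides, law) {
  co <- law$residue_coefficients
  base <- vapply(peptides, function(p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    law$intercept + sum(co[chars]) +
      law$length_coefficient * length(chars)
  }, numeric(1), USE.NAMES = FALSE)
  apply_distortion(law$distortion, base)
}

#' Simulate random peptides
#'
#' Draws i.i.d. peptides with uniform lengths in `length_range` and
#' residues uniform over the alphabet tokens; duplicates are redrawn so
#' the returned peptides are distinct.
#'
#' @param n number of peptides.
#' @param length_range inclusive length range (default the 7-45 window
#'   used for identification).
#' @param alphabet an [rt_alphabet()].
#' @param seed integer seed.
#' @return character vector of `n` distinct token strings.
#' @export
simulate_peptides <- function(n, length_range = c(7L, 45L),
                              alphabet = rt_alphabet(), seed = 1L) {
  stopifnot(n >= 1, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  with_seed_(seed, {
    draw <- function(k) {
      lens <- sample(seq(length_range[1], length_range[2]), k,
                     replace = TRUE)
      vapply(lens, function(L)
        paste(sample(alphabet$tokens, L, replace = TRUE), collapse = ""),
        character(1))
    }
    out <- unique(draw(n))
    while (length(out) < n)
      out <- unique(c(out, draw(n - length(out))))
    out[seq_len(n)]
  })
}

#' Simulate observed RTs for peptides
#'
#' Applies a retention law to peptides and emits training-ready records:
#' `observed_rt` is the distorted noiseless RT plus Gaussian noise,
#' truncated at zero (an instrument never reports a negative elution
#' time), and the raw noiseless value is carried in `true_rt` for oracle
#' tests.  Records are marked as identified by all 3 search engines with
#' zero span so the training filters pass them through.
#'
#' @param peptides character vector of token strings.
#' @param law an [retention_law()].
#' @param seed integer seed (drives the observation noise).
#' @return data frame with columns `peptide`, `observed_rt`, `true_rt`,
#'   `rt_span`, `n_spectra`, `n_engines`.
#' @export
simulate_rt <- function(peptides, law, seed = 1L) {
  truth <- true_rt(peptides, law)
  obs <- with_seed_(seed,
                    truth + rnorm(length(peptides), 0, law$noise_sd))
  obs <- pmax(obs, 0)
  data.frame(peptide = peptides, observed_rt = obs, true_rt = truth,
             rt_span = 0, n_spectra = 1L, n_engines = 3L,
             stringsAsFactors = FALSE)
}

#' Specification of a simulated target/decoy PSM population
#'
#' Defines the group sizes and score distributions of a simulated
#' peptide-level search result.  Correct identifications score higher on
#' average than incorrect ones; decoy matches are drawn from the
#' incorrect-match score distribution — the core modelling assumption of
#' target-decoy estimation, and the fidelity limit of this simulation.
#' The default sizes emulate a proteogenomic search in which variant
#' sequences are a small fraction of the search space: the decoy counts
#' mirror the incorrect-target counts class by class, so the decoy
#' variant fraction (`D_n/D` = 30/300 = 0.1) matches the variant share of
#' incorrect matches.  Cross-stage effects are modelled explicitly: a
#' fraction of true-reference spectra acquire an additional incorrect
#' variant-database match (removed by the two-stage filter when the
#' spectrum is confidently identified in stage 1), and a fraction of
#' true-variant spectra are confidently but wrongly matched to the
#' reference database in stage 1 and are thereby lost to the second
#' stage — the false-negative mode of two-stage estimation.
#'
#' @param n_true_reference,n_false_reference correct / incorrect
#'   reference-class target PSMs.
#' @param n_true_variant,n_false_variant correct / incorrect
#'   variant-class target PSMs.
#' @param n_decoy_reference,n_decoy_variant decoy PSMs per class.
#' @param score_correct_mean,score_incorrect_mean,score_sd score
#'   distribution parameters (arbitrary search-score units).
#' @param p_cross_reference probability that a true-reference spectrum
#'   also yields an incorrect variant match in the stage-2 search.
#' @param p_variant_lost probability that a true-variant spectrum is
#'   confidently matched to a reference peptide in stage 1.
#' @param p_noise_stage2 probability that a noise spectrum (one whose
#'   combined-search match is incorrect or decoy) yields a scoreable
#'   incorrect match in the other stage's database.
#' @param rt_noise_sd spectrum RT noise for correct identifications,
#'   minutes.
#' @return an object of class `psm_sim_spec`.
#' @export
psm_sim_spec <- function(n_true_reference = 1800L,
                         n_false_reference = 270L,
                         n_true_variant = 100L,
                         n_false_variant = 30L,
                         n_decoy_reference = 270L,
                         n_decoy_variant = 30L,
                         score_correct_mean = 16,
                         score_incorrect_mean = 10,
                         score_sd = 2,
                         p_cross_reference = 0.10,
                         p_variant_lost = 0.08,
                         p_noise_stage2 = 0.5,
                         rt_noise_sd = 0.5) {
  stopifnot(score_correct_mean > score_incorrect_mean, score_sd > 0,
            p_cross_reference >= 0, p_cross_reference <= 1,
            p_variant_lost >= 0, p_variant_lost <= 1)
  counts <- c(n_true_reference, n_false_reference, n_true_variant,
              n_false_variant, n_decoy_reference, n_decoy_variant)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(n_true_reference = n_true_reference,
                 n_false_reference = n_false_reference,
                 n_true_variant = n_true_variant,
                 n_false_variant = n_false_variant,
                 n_decoy_reference = n_decoy_reference,
                 n_decoy_variant = n_decoy_variant,
                 score_correct_mean = score_correct_mean,
                 score_incorrect_mean = score_incorrect_mean,
                 score_sd = score_sd,
                 p_cross_reference = p_cross_reference,
                 p_variant_lost = p_variant_lost,
                 p_noise_stage2 = p_noise_stage2,
                 rt_noise_sd = rt_noise_sd),
            class = "psm_sim_spec")
}

#' Simulate a scored target/decoy PSM population with known truth
#'
#' Generates one run's worth of peptide-spectrum matches under a
#' [psm_sim_spec()]: correct identifications draw scores from the
#' correct-match distribution and spectrum RTs from the retention law
#' (plus noise); incorrect identifications and decoys draw scores from
#' the incorrect-match distribution and spectrum RTs independent of the
#' peptide sequence.  Three views are returned: the combined-search table
#' (`psms`, consumed by the global and separate estimators), the
#' stage-1/stage-2 tables of the sequential search (`stage1`, `stage2`),
#' and a truth side channel (`truth`) that the estimators never see.
#'
#' @param spec a [psm_sim_spec()].
#' @param law an [retention_law()] for correct-identification RTs.
#' @param alphabet an [rt_alphabet()].
#' @param seed integer seed; the simulation is reproducible given it.
#' @param run_id run label.
#' @return list with data frames `psms`, `stage1`, `stage2` (PSM
#'   contract columns) and `truth` (`spectrum_id`, `peptide`, `correct`).
#' @export
simulate_psms <- function(spec = psm_sim_spec(), law = retention_law(),
                          alphabet = rt_alphabet(), seed = 1L,
                          run_id = "run1") {
  n_total <- spec$n_true_reference + spec$n_false_reference +
    spec$n_true_variant + spec$n_false_variant +
    spec$n_decoy_reference + spec$n_decoy_variant
  peptides <- simulate_peptides(n_total, c(7L, 45L), alphabet,
                                seed = seed + 104729L)
  with_seed_(seed, {
    rt_lo <- 10
    rt_hi <- 80
    idx <- 0L
    spec_no <- 0L
    take_peps <- function(k) {
      p <- peptides[idx + seq_len(k)]
      idx <<- idx + k
      p
    }
    make_group <- function(k, correct, label, pep_class) {
      if (!k) return(NULL)
      peps <- take_peps(k)
      ids <- sprintf("S%06d", spec_no + seq_len(k))
      spec_no <<- spec_no + k
      score_mean <- if (correct) spec$score_correct_mean
                    else spec$score_incorrect_mean
      rt <- if (correct)
        true_rt(peps, law) + rnorm(k, 0, spec$rt_noise_sd)
      else
        runif(k, rt_lo, rt_hi)
      data.frame(spectrum_id = ids, run_id = run_id, peptide = peps,
                 score = rnorm(k, score_mean, spec$score_sd),
                 label = label, pep_class = pep_class, spectrum_rt = rt,
                 correct = correct, stringsAsFactors = FALSE)
    }
    tr <- make_group(spec$n_true_reference, TRUE, "target", "reference")
    fr <- make_group(spec$n_false_reference, FALSE, "target", "reference")
    tv <- make_group(spec$n_true_variant, TRUE, "target", "variant")
    fv <- make_group(spec$n_false_variant, FALSE, "target", "variant")
    dr <- make_group(spec$n_decoy_reference, FALSE, "decoy", "reference")
    dv <- make_group(spec$n_decoy_variant, FALSE, "decoy", "variant")
    combined <- rbind(tr, fr, tv, fv, dr, dv)
    truth <- combined[, c("spectrum_id", "peptide", "correct")]
    psms <- combined[, setdiff(names(combined), "correct")]

    # sequential search views -----------------------------------------
    # stage 1 (reference database): reference targets and decoys, plus
    # true-variant spectra wrongly but confidently matched to reference
    lost <- if (!is.null(tv) && nrow(tv))
      tv[runif(nrow(tv)) < spec$p_variant_lost, , drop = FALSE]
    else tv[0, ]
    stage1_extra <- NULL
    if (nrow(lost)) {
      wrong_ref <- simulate_peptides(nrow(lost), c(7L, 45L), alphabet,
                                     seed = seed + 224737L)
      stage1_extra <- data.frame(
        spectrum_id = lost$spectrum_id, run_id = run_id,
        peptide = wrong_ref,
        score = rnorm(nrow(lost), spec$score_correct_mean, spec$score_sd),
        label = "target", pep_class = "reference",
        spectrum_rt = lost$spectrum_rt, correct = FALSE,
        stringsAsFactors = FALSE)
    }
    # noise spectra of the variant class also yield incorrect stage-1
    # reference-database matches (target or decoy with equal probability)
    noise1 <- rbind(fv, dv)
    stage1_noise <- NULL
    if (!is.null(noise1) && nrow(noise1)) {
      noise1 <- noise1[runif(nrow(noise1)) < spec$p_noise_stage2, ,
                       drop = FALSE]
      if (nrow(noise1)) {
        wrong1 <- simulate_peptides(nrow(noise1), c(7L, 45L), alphabet,
                                    seed = seed + 611953L)
        stage1_noise <- data.frame(
          spectrum_id = noise1$spectrum_id, run_id = run_id,
          peptide = wrong1,
          score = rnorm(nrow(noise1), spec$score_incorrect_mean,
                        spec$score_sd),
          label = ifelse(runif(nrow(noise1)) < 0.5, "decoy", "target"),
          pep_class = "reference",
          spectrum_rt = noise1$spectrum_rt, correct = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    stage1 <- rbind(tr, fr, dr, stage1_extra, stage1_noise)
    stage1 <- stage1[, setdiff(names(stage1), "correct")]
    # stage 2 (variant database): variant targets and decoys, plus
    # incorrect variant matches for a fraction of true-reference spectra
    cross <- if (!is.null(tr) && nrow(tr))
      tr[runif(nrow(tr)) < spec$p_cross_reference, , drop = FALSE]
    else tr[0, ]
    stage2_extra <- NULL
    if (nrow(cross)) {
      wrong_var <- simulate_peptides(nrow(cross), c(7L, 45L), alphabet,
                                     seed = seed + 350377L)
      # an incorrect match falls on the target or the decoy variant
      # database with equal probability (databases of equal size), so the
      # stage-2 decoys keep tracking the incorrect matches that survive
      # the stage-1 spectrum removal
      is_decoy <- runif(nrow(cross)) < 0.5
      stage2_extra <- data.frame(
        spectrum_id = cross$spectrum_id, run_id = run_id,
        peptide = wrong_var,
        score = rnorm(nrow(cross), spec$score_incorrect_mean,
                      spec$score_sd),
        label = ifelse(is_decoy, "decoy", "target"),
        pep_class = "variant",
        spectrum_rt = cross$spectrum_rt, correct = FALSE,
        stringsAsFactors = FALSE)
    }
    # noise spectra of the reference class (incorrect and decoy matches
    # in the combined search) are not removed after stage 1 and are
    # searched against the variant database in stage 2
    noise2 <- rbind(fr, dr)
    stage2_noise <- NULL
    if (!is.null(noise2) && nrow(noise2)) {
      noise2 <- noise2[runif(nrow(noise2)) < spec$p_noise_stage2, ,
                       drop = FALSE]
      if (nrow(noise2)) {
        wrong2 <- simulate_peptides(nrow(noise2), c(7L, 45L), alphabet,
                                    seed = seed + 784727L)
        stage2_noise <- data.frame(
          spectrum_id = noise2$spectrum_id, run_id = run_id,
          peptide = wrong2,
          score = rnorm(nrow(noise2), spec$score_incorrect_mean,
                        spec$score_sd),
          label = ifelse(runif(nrow(noise2)) < 0.5, "decoy", "target"),
          pep_class = "variant",
          spectrum_rt = noise2$spectrum_rt, correct = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    stage2 <- rbind(tv, fv, dv, stage2_extra, stage2_noise)
    stage2 <- stage2[, setdiff(names(stage2), "correct")]
    extra_truth <- rbind(
      if (!is.null(stage1_extra))
        stage1_extra[, c("spectrum_id", "peptide", "correct")],
      if (!is.null(stage2_extra))
        stage2_extra[, c("spectrum_id", "peptide", "correct")],
      if (!is.null(stage1_noise))
        stage1_noise[, c("spectrum_id", "peptide", "correct")],
      if (!is.null(stage2_noise))
        stage2_noise[, c("spectrum_id", "peptide", "correct")])
    truth <- rbind(truth, extra_truth)
    rownames(psms) <- rownames(stage1) <- rownames(stage2) <-
      rownames(truth) <- NULL
    list(psms = psms, stage1 = stage1, stage2 = stage2, truth = truth)
  })
}
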
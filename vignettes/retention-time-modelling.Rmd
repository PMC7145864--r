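---
title: "Retention time modelling and variant peptide quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention time modelling and variant peptide quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In proteogenomics, MS/MS spectra are searched against customized protein
databases that contain both the reference proteome and sample-specific
variant sequences (from somatic and germline SNVs and INDELs).  Because a
variant peptide is far less likely to be observed than a reference
peptide, the standard target-decoy false discovery rate (FDR) computed
over all peptides together systematically understates the error among
variant peptides, and the alternatives — class-separate estimation and
sequential two-stage searching — trade that bias for higher variance or
lost sensitivity.  Choosing among them requires a quality metric that is
independent of the search scores.  Chromatographic retention time (RT) is
such a metric: it is an intrinsic, sequence-determined property of a
peptide that plays no role in spectrum matching, so the difference
between a peptide's observed RT and an accurate sequence-based prediction
measures identification quality without circularity.

`peprt` implements both halves of this program: an RT predictor accurate
enough for per-run quality control, and the three FDR estimators it is
used to arbitrate, together with ground-truthed simulators that make the
whole pipeline testable at desk scale.

## The retention time model

`rtnet()` fits a sequence regression network.  A peptide is tokenized
over an alphabet of the 20 amino acids plus one extra character per
*variable* modification (oxidized methionine is `"1"` by default), then
one-hot encoded into a `fixed_length x |alphabet|` binary matrix, zero
rows padding the tail (post-padding; the fixed length defaults to the
longest training peptide).  Fixed, experiment-wide modifications such as
carbamidomethyl-C or TMT labels apply to every occurrence of a residue
and therefore carry no sequence information, so they get no character.
Residues outside the alphabet (B, J, O, U, X, Z) are rejected rather
than imputed, since silent imputation would corrupt the very feature the
model learns.

The network is a stack of 1-D convolutional blocks (kernel width 3,
"same" padding) over the sequence axis, feeding a fixed bidirectional
GRU of 50 units per direction, whose concatenated final states pass
through a stack of dense blocks into a single linear output.
Convolutional blocks may include batch normalization, any of
relu/tanh/leaky-relu activations, max pooling (width 2 along the
sequence), and dropout; dense blocks have the same options minus
pooling.  The loss is mean squared error on RT min-max scaled to
`[0, 1]` by the *training partition's* range; predictions are mapped
back to minutes by the inverse transform.  Scaling stabilizes training
across runs with different gradient lengths; the scaler never sees
validation or test RTs.

Training is plain minibatch gradient descent (adam, rmsprop, or SGD with
momentum 0.9, at the conventional default learning rates 0.001/0.001/
0.01), with validation MSE evaluated after every epoch; the weights of
the best validation epoch are kept, and training stops early when no
improvement is seen for `patience` epochs (default 10 for base training,
5 for fine-tuning — the monitored quantity is always validation MSE).
The entire computational core, including backpropagation through the
convolution, batch-norm, pooling and GRU layers, is implemented in the
package's C++ code and is verified against central finite differences in
the test suite.

Numerical conventions worth knowing: batch-norm uses the biased batch
variance with epsilon 1e-3 and running statistics with momentum 0.9 for
inference; dropout is inverted (scaled at train time); max pooling drops
a trailing odd position; GRU states update as
`h_t = z_t * h_(t-1) + (1 - z_t) * htilde_t`; weights initialize
Glorot-uniform with zero biases.  Training is bit-reproducible given the
`seed` argument because all randomness (initialization, shuffling,
dropout) flows from one generator.

## Architecture search

The best architecture is not known a priori, so `rt_nas()` searches a
constrained space with a genetic algorithm.  A genome is fixed-width: it
always carries the maximum number of convolutional and dense layer
slots, of which the first `n_conv` / `n_dense` are active, plus an
optimizer choice; the BiGRU(50) is never searched.  The default space
allows 1–4 convolutional layers with feature maps in {16, 32, 64, 128},
activations {relu, tanh, leaky-relu}, dropout {0, 0.1, 0.25, 0.5}, and
free batch-norm/pooling flags; 1–3 dense layers with widths {32, 64,
128, 256}; and optimizers {adam, rmsprop, sgd-momentum}.  These values
span the option families of the search design; the space is fully
configurable.

Fitness is the validation MSE of a short from-scratch training (at most
20 epochs with early stopping); the trained weights are discarded.  The
genetic operators are deliberately standard, each a config knob:
tournament selection of size 3 (without replacement), uniform crossover
over the aligned genome slots, per-field mutation at rate 0.1, and
elitism of 1.  Fitness values are cached by genome so elites are not
retrained; with elitism the per-generation best is therefore
non-increasing by construction, which the tests assert.  A non-finite
training loss maps to infinite fitness, so a pathological architecture
survives as the worst individual instead of aborting the search.  The
reference configuration is 20 generations of 50 individuals with the
top 10 architectures retained; the test suite exercises a reduced run
(population 8, 5 generations, 2000 peptides, a small space) chosen to
keep the full suite in the minutes range on one CPU.

## Transfer learning

A single LC-MS/MS run typically yields too few confidently identified
peptides (hundreds to a few thousand) to train a deep model from
scratch, and nonlinear RT shifts between runs mean one global model
cannot serve all runs.  `fine_tune()` therefore continues training a
base model on the run's own training partition with **no layers
frozen**, at most 40 epochs, early stopping on the run's validation
partition, and returns the best-validation checkpoint carrying the run's
own RT scaler.  Training data for a run are prepared by the package's
quality filters: the observed RT of a peptide is the mean spectrum RT
over all its spectra in the run, peptides identified by fewer than 2 of
the 3 search engines are dropped, as are peptides whose spectrum RT span
exceeds 3 minutes (strictly greater; the boundary survives); the
remainder splits 90/10 into train/test with 10% of the training part
held out for validation, always at the peptide level to prevent leakage.
The engine-agreement and span filters commute, so their order is
immaterial.

## Ensemble averaging

Predictions from the top architectures are combined per peptide by IQR
outlier removal: with member predictions' first and third quartiles Q1
and Q3 and IQR = Q3 − Q1, members outside the inclusive interval
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` are discarded and the rest averaged.
Quartiles use linear interpolation between order statistics (the type-7
convention); nothing in the rule's description fixes a convention, so
one is declared and frozen in the tests.  Because the bounds are
inclusive and bracket the central half of the data, at least one member
always survives.  Each member predicts in its own scaled space and
inverts its own scaler, so members with different training histories
combine in minutes.

## FDR estimation for variant peptides

All estimation is at the peptide level: only the best-scoring PSM per
(peptide, label) enters, with exact score ties broken by the smallest
spectrum id.  Scores are oriented higher-is-better at ingestion.

* **Global**: reference and variant hits are pooled; at a score cutoff
  the estimate is `D/T`, decoy hits over target hits at or above the
  cutoff.
* **Separate**: the reference class is scored by `D/T` over reference
  hits only.  The variant class uses
  `FDR_n = (D+ · D_n/D) / T_n+`, where `D+` counts all decoy hits (both
  classes) above the cutoff, `T_n+` the variant target hits above it,
  and `D_n/D` — variant decoys over all decoys, both totals independent
  of the cutoff — approximates the fraction of variant sequences in the
  search space.  `D+` is interpreted as class-unrestricted, following
  the definition literally; restricting it to variant decoys would
  double-count the `D_n/D` correction.
* **Two-stage**: the first search is against the reference database
  only; spectra whose best identification passes the peptide-level 1%
  threshold are removed, and the `D/T` estimator is applied to the
  remaining second-stage (variant database) hits.

Raw per-cutoff estimates are converted to q-values by a running minimum
from the most permissive cutoff upward, which makes threshold filtering
well defined when the raw curve is non-monotone; at an exactly tied
cutoff decoys are counted before targets (the conservative direction).
No target-decoy competition is imposed — counting follows the plain
`D/T` definitions.  All three estimators are checked against
independently coded brute-force per-cutoff oracles to 1e-12 in the
tests.

## Quality evaluation by RT error

For identification QC the observed RT of a peptide is the spectrum RT of
its **best PSM** — unlike training, which uses the per-peptide spectrum
average; both rules are implemented side by side because they serve
different purposes.  The error metric is the median absolute error (MAE)
between observed and ensemble-predicted RT, in minutes; `rt_mae()` uses
the interpolated median.  `filter_by_rt_error()` flags identifications
whose absolute error exceeds 5 minutes (strictly; the boundary is kept)
for more critical evaluation — a soft screening default, not a hard
rule, since a large RT error can also reflect prediction failure or a
wide elution profile.  `rt_group_summary()` and `compare_rt_error()`
(a Wilcoxon rank-sum convenience) support group comparisons; they are
reporting, not method.

## What the simulators emulate — and what they do not

The synthetic retention law is additive: each residue contributes a
fixed coefficient (in minutes, following the familiar hydrophobicity
ordering, with modified residues eluting 1.5 min earlier than their base
residue), plus 1.2 min per residue of length and a 5 min intercept, so
7–45-residue tryptic peptides span roughly a 10–80 min gradient.
Between-run behaviour is a monotone piecewise-linear distortion through
six knots about 20 min apart with vertical offsets up to ±8 min — large
enough that an un-adapted base model fails visibly, making transfer
learning measurably necessary; with this geometry consecutive offsets
cannot reverse order, so monotonicity holds by construction.
Observation noise is Gaussian (0.3–0.5 min in the test conditions).
Real retention is not additive — position effects, neighbouring-residue
interactions and column aging all violate the law — so passing the
recovery tests shows the estimator machinery works, not that any
particular accuracy will transfer to real chromatograms.

The PSM simulator draws correct-match scores from N(16, 2) and
incorrect-match scores from N(10, 2) in arbitrary search-score units,
with decoys drawn from the incorrect distribution — the core assumption
of target-decoy estimation and the simulation's declared fidelity limit.
The default population (1800 correct + 270 incorrect reference targets,
100 correct + 30 incorrect variant targets, 270 + 30 decoys) mirrors the
incorrect-target counts with the decoy counts class by class, so
`D_n/D = 0.1` matches the variant share of incorrect matches.  Spectrum
RTs of correct identifications follow the retention law; incorrect ones
are drawn independently of sequence, which is what makes RT error
informative about correctness.  Cross-stage structure is modelled
explicitly: 10% of correctly-identified reference spectra also produce
an incorrect variant-database match (removed by the two-stage filter
when the spectrum is confidently identified first), 8% of true variant
spectra are confidently mis-assigned to the reference database in stage
1 and thereby lost — the false-negative mode of two-stage estimation —
and noise spectra of either class reach the other stage's database with
probability 0.5, splitting evenly between target and decoy sequences
(equal-size databases).  Truth labels live in a side-channel table the
estimators never receive.

## Problem sizes and test conditions

The package's tests train on synthetic corpora of 5000 peptides (runs of
700), evaluate FDR calibration over 20 simulation replicates of ~2500
peptide hits each, and run the reduced architecture search described
above; these sizes were chosen so the entire suite completes in minutes
on a single CPU while leaving each phenomenon clearly measurable.  The
acceptance script (`scripts/acceptance.R`) re-runs the same pipeline at
a slightly smaller scale (3000-peptide corpus, 3 runs, 10 FDR
replicates) from a caller-supplied seed.

## Known limitations

* The RT model has no attention or positional encoding; very long
  peptides are represented only through the GRU's summary states.
* Modification handling is categorical — localization ambiguity and
  mass-based encodings are out of scope.
* The simulators are score-level abstractions: no spectra, no m/z, no
  search engine.  Conclusions about estimator calibration rest on the
  decoy-models-incorrect assumption stated above.
* Deterministic training relies on single-threaded BLAS; with a
  multi-threaded BLAS bitwise reproducibility across machines is not
  guaranteed (same-machine reproducibility is).
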
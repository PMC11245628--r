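---
title: "Estimating language timescale selectivity with voxelwise encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating language timescale selectivity with voxelwise encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langscales)
```

## The model

Narrative language unfolds over many temporal granularities at once: word
identity changes every word, sentence-level syntax over tens of words,
discourse topics over hundreds. `langscales` operationalizes these levels
as *language timescales*: the spectral components of a word-level stimulus
representation whose period, measured in words, falls in a given range.
The package estimates, for every fMRI voxel, which timescales of the
stimulus drive its BOLD response, and summarizes each voxel by a single
number -- its timescale selectivity, in words -- that can be compared
across stimulus conditions (for example reading versus listening to the
same narratives).

The analysis proceeds in five stages.

**1. Stimulus embedding.** Each stimulus word is mapped to a column of a
`p x w` embedding matrix `M`. With real data this comes from a contextual
language model through a pluggable adapter (`extract_embeddings()`); an
input-embedding layer plus 12 transformer layers of width 768 gives
`p = 9984`. The package ships a deterministic mock adapter for testing
and a synthetic generator (below) whose spectral content is known exactly.

**2. Timescale decomposition.** A bank of eight FIR band-pass filters
separates `M` into timescale-specific embeddings. The period ranges are
octaves: 2-4, 4-8, 8-16, 16-32, 32-64, 64-128, 128-256 and 256+ words,
the last closed at 512 words by octave continuation so that every band
has a nominal timescale `t_i = (p_low + p_high) / 2` (3, 6, 12, 24, 48,
96, 192, 384 words). Each filter is a cosine at `1 / t_i` cycles/word
multiplied by a Blackman window (the window method), applied centered
after mirror padding, so filtering is zero-phase. Gains are normalized to
unit peak so that per-band prediction scores are not confounded by filter
gain.

**3. Temporal alignment.** Word-rate signals are interpolated to a dense
uniform grid (25 samples per TR) with a *normalized* Gaussian RBF kernel
anchored at word midpoints -- interpolating before downsampling prevents
the irregular word rate from masquerading as slow stimulus structure --
then resampled to the middle of each fMRI volume with a 3-lobe Lanczos
anti-aliasing filter cut off at the 0.25 Hz Nyquist rate of a 2-second
TR. Each run then loses 10 TRs at each edge, channels are z-scored with
training-run statistics only, and four FIR-delayed copies (1-4 TRs,
roughly 2-8 s) absorb the hemodynamic lag. Responses are optionally
detrended by subtracting a third-order Savitzky-Golay smooth with a
120-second window, z-scored per run and voxel, and repeated test
presentations averaged.

**4. Banded ridge regression.** The delayed feature spaces are
concatenated into a design `X` and a separate ridge penalty is fit per
feature space (and optionally per delay), minimizing
`||Y - XB||^2 + sum_g lambda_g ||B_g||^2` per voxel. Hyperparameters are
selected by leave-one-run-out cross-validation in two stages: a random
search draws normalized penalty candidates from a Dirichlet distribution
and scales each by 10 log-spaced values spanning `1e-5` to `1e5`, keeping
the per-voxel combination with the smallest summed validation squared
error; the best 20% of voxels are then refined by backtracking gradient
descent on the log-penalties, which by construction never increases the
validation loss. The held-out test run plays no role in either stage.

**5. Evaluation and selectivity.** The joint prediction performance `r`
is the Pearson correlation between predicted and recorded test responses.
It is decomposed into per-band *split* performances
`r~_i = sum_t(Yhat_i Y) / sqrt(sum(Yhat^2) sum(Y^2))` -- note the joint
prediction in the denominator -- which sum exactly to `r` and may be
negative. Language-selective voxels are those whose summed split
performance over the eight bands beats a blockwise permutation null
(blocks of 10 TRs, preserving BOLD autocorrelation; one-sided p with
add-one smoothing) after Benjamini-Hochberg FDR correction at 0.05. For
selective voxels the clipped, normalized split vector forms the
selectivity profile, and its weighted geometric mean over the nominal
timescales gives the scalar timescale selectivity
`T = 2^(sum_i profile_i log2 t_i)`, bounded between 3 and 384 words. A
weighted mean is used instead of the argmax so that small accuracy
changes cannot cause large selectivity jumps. Conditions are compared by
correlating `T` (or per-band profile entries) across jointly selective
voxels, with a permutation null built by re-estimating selectivity from
block-shuffled test responses in each condition independently.

## The synthetic generator, and what it does and does not show

`simulate_timescale_dataset()` emulates one participant x condition of a
narrative session: by default 6 training runs of 300 TRs (TR 2.0045 s,
about 10 minutes each), one test run presented twice, inter-word
intervals drawn log-normal with mean 0.4 s (about 150 words per minute)
and coefficient of variation 0.3, and 200 voxels. Each embedding
dimension is a sinusoid in word index with period drawn uniformly inside
its assigned band (two dimensions per band by default) plus white noise.
Voxel responses are linear in the *filtered, TR-rate* band features --
the generative assumption the analysis inverts -- lagged by 2 TRs to
emulate the hemodynamic delay, scaled to unit signal variance, plus slow
cosine drift (periods 240-600 s, unit s.d.) and Gaussian noise at SNR 1.
Ground truth is one-hot over bands, cycling through all eight.

Passing parameter recovery on this generator shows that every stage of
the estimation chain -- filtering, resampling, regularized regression,
split-performance decomposition, permutation inference and the
selectivity summary -- inverts the generative model correctly at
realistic noise levels. It does *not* show that real BOLD data satisfy
the linear encoding assumption, that contextual-embedding geometry
resembles band-limited sinusoids, or that voxels are spatially
independent (no spatial correlation or hemodynamic nonlinearity is
simulated).

Two physical effects are faithfully reproduced and worth knowing about.
At 2.5 words/s the 2-4-word band lives around 0.8 Hz, above the scanner
Nyquist rate, so the anti-aliasing filter attenuates it; and the 256+
band varies with periods near 150 s, partially inside the drift band
removed by Savitzky-Golay detrending. Both edges of the timescale axis
are therefore recovered with reduced sensitivity -- voxels there tend to
fall out of the selective set rather than being mislabeled, mirroring the
known limitation that drift removal discards information about very long
timescales in real recordings.

## Numerical and design choices

* **Filter length.** The default is 2049 taps. The slowest band's center
  (`1/384` cycles/word) must clear the Blackman mainlobe around DC, or
  the band-pass would leak DC; at 2049 taps every filter's DC gain is
  below 0.2% of peak, and anything at least two bands away is below 1%.
  Shorter banks (down to 1025 taps, twice the longest period) are
  accepted but will leak near DC in the slowest band.
* **Cosine center.** Arithmetic band centers `1/t_i` match the printed
  nominal timescales; geometric centers are available by configuration.
* **Mirror padding** uses symmetric extension with edge repetition and
  repeats the reflection when the pad exceeds the signal, so short runs
  never fail.
* **Normalized RBF interpolation** makes the interpolant a partition of
  unity: during silent gaps the signal decays to the local word average
  rather than to zero, and a constant word stream stays exactly constant
  through interpolation plus Lanczos downsampling (both steps have unit
  DC gain).
* **Word anchor time** is the midpoint of onset and offset; the RBF
  width defaults to the run's mean inter-word interval.
* **Delays in integer TRs.** 2/4/6/8 s are only approximately integer
  multiples of the 2.0045-s TR; shifting by 1-4 whole TRs keeps run
  boundaries exact (shifts never cross runs; run starts are zero-filled).
* **Trim before z-scoring**, for features and responses alike; feature
  statistics come from training runs only and are reused on the test run.
* **Penalty grouping.** The solver supports one penalty per feature
  space or per space x delay (32 groups). The pipeline defaults to
  per-space grouping: with reduced candidate budgets a 32-dimensional
  Dirichlet is sampled too sparsely to be useful, while 8 dimensions
  behave well even at 100 candidates.
* **Search bookkeeping.** Stage-one losses are summed (not averaged)
  over folds -- equivalent for fixed folds; the Dirichlet concentration
  is 1 (uniform on the simplex); `lambda_g = scale * weight_g`.
* **Degenerate cases** are flagged, not propagated: zero-variance
  channels are zeroed, zero-variance predictions score `r = 0`, voxels
  with all-non-positive split vectors have undefined profiles and are
  excluded from selectivity analyses.
* **Permutation estimator.** One-sided with add-one smoothing, so
  `p >= 1/(n_perm + 1) > 0`; the final short block is kept intact and
  shuffled as a unit; blocks are reordered (not circularly shifted).
* **Group aggregation** averages raw selectivities over the subjects in
  whom a vertex is selective and masks vertices selective in fewer than
  `ceiling(n_subjects / 3)` subjects; a log-domain mean is a trivial
  caller-side variant (`2^group_aggregate(log2(T), ...)`).

## Problem sizes used in validation

The shipped tests exercise the full pipeline at 6 training runs x 300
TRs, 200 voxels, SNR 1, with a 100-candidate x 10-scale search and 10
refinement iterations (the package default search is 1000 candidates and
1000 refinement iterations). At that size, well over half the voxels are
language-selective, over 95% of selective voxels' profile argmaxes land
on the true band, the Spearman correlation between true and estimated
log timescale exceeds 0.9, and two conditions sharing ground truth
correlate above 0.9 in selectivity while shuffled truth correlates near
zero. Permutation calibration is checked on a null model with 200
voxels, 300 test TRs and 500 permutations.

## A worked example

```{r example, eval = FALSE}
library(langscales)

ds <- simulate_timescale_dataset(n_train_runs = 4, run_length_trs = 200,
                                 n_voxels = 60, seed = 7)
cfg <- ts_config(n_candidates = 50, refine_iter = 5, n_perm = 500, seed = 8)
fit <- fit_timescale_model(ds, cfg)
fit
head(fit$scores[fit$selective,
                c("voxel", "r", "r_all", "q", "tbar")])
table(true = ds$truth$true_band[fit$selective],
      estimated = apply(fit$profile[fit$selective, ], 1, which.max))
```

## Known limitations

* The mock adapter stands in for a real contextual language model; an
  adapter wrapping an actual transformer must supply per-layer token
  activations and a token-to-word map with the documented interface.
* Surface projection to a shared vertex space is assumed to happen
  upstream of `group_aggregate()`; no NIfTI-space spatial operations or
  flatmap visualization are provided.
* Sensory-level (nuisance) feature spaces are accepted as additional
  already-TR-rate matrices in the solver's grouping, but the package does
  not construct Gabor-pyramid or cochleogram features.
* With fewer than three jointly selective voxels the cross-condition
  comparison is undefined and skipped with a warning.
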
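---
title: "Methods: feature selection and evaluation in the locustsel pipeline"
author: "locustsel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature selection and evaluation in the locustsel pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustsel)
```

## The problem

Locust swarms are a recurring threat to crops, and camera-equipped field
robots offer a way to detect infestations early. The computational task is
binary image classification — *with locust* versus *without locust* — built
from four stages: image quality filtering, convolutional feature
extraction, feature selection, and classifier evaluation, plus a small
simulator for the robot's sensor-decision and movement-command logic.
`locustsel` implements that whole pipeline as an offline-runnable R
package with synthetic ground-truth generators, so every stage is testable
without the original field imagery.

## Image quality filtering

The pipeline screens images by mean squared error (MSE) and peak
signal-to-noise ratio, PSNR $= 10\log_{10}(255^2/\mathrm{MSE})$ dB for
8-bit images. No clean reference image exists in a field setting, so
`qualityFilter()` uses a *self-referential* proxy: the PSNR is computed
between each image and a smoothed copy of itself (3×3 median by default, a
3×3 binomial kernel as the alternative). Heavy pixel noise is removed by
the smoother, producing a large MSE against the original and hence a low
PSNR; clean natural texture survives smoothing largely intact. Images
below the keep-threshold (default 20 dB, configurable) are dropped. This
is one reading of an underspecified design space — comparing against a
denoised copy rather than a reference or duplicate — and is flagged as
such here; the threshold is a tunable in dB, and both smoothers are exact
on constant images so that the identical-image case returns the documented
`Inf` sentinel rather than an overflow artifact. The two 3×3 kernels are
implemented directly (replicate-padded, exact integer arithmetic) for
precisely that reason; all image IO and resizing goes through `EBImage`.

Resizing uses bilinear interpolation without aspect-ratio preservation,
matching common pretrained-backbone preprocessing.

## Backbone feature extraction

Backbones are pluggable: a `BackboneSpec` declares the input resolution,
the emitted width and the pixel normalization, and `registerBackbone()`
verifies the width contract on a probe image at registration. The three
named built-ins honour the canonical input/output contracts of their
namesake architectures — `vgg19` maps 224×224×3 to a 4096-wide
fully-connected tap, `resnet50` maps 224×224×3 to a 2048-wide pooled
embedding, `inceptionv3` maps 299×299×3 to 2048 — but are *compact
random-weight* convolutional networks: fixed-seed He-initialized filters,
reduced channel widths, pure-R im2col convolutions. Random untrained
convolutional features are a well-studied baseline that preserves class
structure, and everything this package contributes (ranking, subset
search, evaluation) lies downstream of the backbone, so the bundled
extractors keep the package fully offline and deterministic while
exercising the genuine interface. A 64×64→32 `tinycnn` is bundled for
fast tests. Extraction is a pure function of (fixed weights, image);
repeated calls agree exactly.

What this does **not** show: accuracy numbers obtained with these
extractors on real imagery are not comparable to numbers from pretrained
ImageNet weights. Users with network access can register a pretrained
forward function under a new name and the rest of the pipeline is
unchanged.

## SVC feature ranking (filter stage)

`fitMarginWeights()` standardizes each column (constant columns pass
through as all-zero and get weight exactly 0), fits a linear soft-margin
SVC (cost 1, hinge loss via libsvm) and returns the hyperplane
coefficients $w$. Features are ranked by $|w_j|$, ties broken by ascending
index; the ranking is invariant to positive rescaling of $w$. Two cutoffs
are offered: top-$k$, and the mean-score threshold (keep features with
$|w_j| \ge \overline{|w|}$), which adapts the kept count to the score
distribution and is the default in the combined `abc+svc` pipeline.

## Artificial Bee Colony subset search (wrapper stage)

Candidate subsets are binary masks over features. Fitness of a mask is the
stratified $k$-fold cross-validated accuracy (default 3 folds) of a linear
SVC on the masked columns, minus a parsimony penalty
$\lambda \cdot \mathrm{popcount}/d$ (default $\lambda = 0.01$). Three
design points matter:

* **Fixed folds per run.** The fold assignment is drawn once from the
  configuration seed, so every mask is scored on identical folds. Fitness
  is then a deterministic function of the mask, comparisons between masks
  are paired rather than noisy, and memoization (masks are revisited
  constantly; cross-validation is the cost center) is sound.
* **Phases.** *Employed*: every food source proposes a neighbour — each
  bit flips independently with probability $1/d$, at least one flip
  forced, all-zero proposals repaired by turning one random bit on — and
  the neighbour replaces the source only if strictly fitter, else the
  source's trial counter increments. *Onlooker*: `colonySize` further
  proposals are allocated with probability proportional to shifted
  fitness ($f - \min f + \varepsilon$; uniform when all are equal).
  *Scout*: sources whose trial counter exceeds `limit` are replaced by
  fresh uniform-random masks.
* **Elitism.** The best mask is tracked outside the colony, so
  abandonment can never lose the reported optimum and the per-cycle
  best-so-far history is non-decreasing by construction. Under strict
  greedy acceptance a rejected neighbour can never beat its own source,
  so the colony-tracked best equals the best mask ever evaluated.

Defaults (colony 10, limit 5, 50 cycles) are desk-scale choices: on
$d \le 12$ problems they let the search evaluate a large fraction of the
$2^d - 1$ masks, which is what makes the exhaustive-search comparison in
the test suite a meaningful check of the search rather than of luck. The
`abc+svc` composition applies the mean-threshold SVC cut first and
searches the reduced set — a standard filter→wrapper design that keeps the
wrapper's search space small.

## Evaluation protocol

The protocol is an 80/20 stratified hold-out split plus stratified 5-fold
cross-validation, both seeded. Train/test proportions use
largest-remainder allocation so the overall training count equals
`round(splitFraction * n)` exactly while classes stay balanced. Seven
classifiers are wrapped behind one interface (`svm` RBF, `rf` 200 trees,
`dt`, `nb`, `xgb` 50 rounds / depth 3, `knn` $k=5$, `lr`), each with fixed
documented defaults and seeded where stochastic. Metrics are the
positive-class ("with locust") percentages
$A = \frac{TP+TN}{TP+FP+FN+TN}\cdot 100$, $P = \frac{TP}{TP+FP}\cdot 100$,
$R = \frac{TP}{TP+FN}\cdot 100$, and F1 the harmonic mean of $P$ and $R$.
A 0/0 in $P$ or $R$ yields 0 with a warning rather than an error, and
F1 is defined as 0 when $P + R = 0$. Because both hold-out and
cross-validated accuracies are legitimate headline numbers, pipeline
reports carry both, labelled.

## Synthetic ground truth

The **image generator** emulates the binary field-imagery task: a
vegetation-textured background (sinusoidal "grass stripes" or smooth
speckle), additive Gaussian pixel noise, and for the positive class a dark
elongated ellipse at random position and orientation — an insect *proxy*,
not a rendered locust. With/without images are paired on the same
background so the noise-free difference is provably confined to the blob's
bounding box. Default 64×64 for fast tests; 224×224 supported for
backbone-contract checks. The claims such data can support are
computational (shapes, determinism, separability); nothing entomological.

The **table generator** emulates extracted-feature matrices: balanced
classes, standard-normal noise columns (optionally sharing a latent factor
for exchangeable correlation), and $k$ informative columns whose class-1
mean is shifted by a standardized effect size. The informative mask is
returned, enabling recovery testing of both selectors. Study scales used
by the acceptance checks, chosen once as desk-scale conditions: the
easy-separation pipeline check uses $n=500, d=50, k=5$, effect 3; the
exhaustive-oracle check uses $n=80, d=10, k=3$, effect 1.5 over 20 seeds
(moderate effect, so the optimum subset is not trivially the full
informative set); recovery uses $n=300, d=50, k=5$, effect 2 over 20
seeds.

## Telemetry simulator

Soil moisture (raw analog 0–1023) maps monotonically to
dry / almost dry / almost wet / wet through three ascending cut points.
The reference sensor log this rule is drawn from is internally
inconsistent at the wet boundary (650 labelled wet while 800 is almost
wet), which no monotone map can reproduce; the defaults
$t_1=500, t_2=640, t_3=790$ reproduce the consistent rows (450 dry; 522,
590, 600 almost dry) — note $t_1$ must lie in $(450, 522]$ for that, and
500 is the round choice. Movement commands are fail-safe and total: bytes
are compared directly (no locale-dependent case folding), `F/B/L/R` in
either case drive at the requested speed clamped to the threshold, and
every other byte — including invalid encodings and the empty string —
degrades to `STOP` at speed 0 with a warning.

## Reproducibility and numerical choices

All randomness flows through explicit integer seeds; seeded entry points
restore the caller's RNG state. The linear-SVC fits are deterministic
given data, so ranking and ABC runs are bit-reproducible from their
configuration. Feature tables round-trip through delimited text at 9
significant digits; PSNR's infinite sentinel is `Inf`, never an overflow;
ranking ties break by ascending index; `selectTop()` always keeps at
least one feature. Known limitations: random-weight backbones (above),
binary classes only, no ROC/AUC, and the wet-boundary inconsistency in
the reference sensor rules is documented rather than resolved.

## A worked example

```{r example, eval = FALSE}
cfg <- validateConfig(c(selector = "abc+svc", classifiers = "lr",
                        seed = "42", synth_n = "500", synth_d = "50",
                        synth_k = "5", synth_effect = "3",
                        out = tempfile()))
res <- runPipeline(cfg)
res$results
```

The run writes `features.csv`, `ranking.csv`, `abc_result.json`,
`comparison.csv`, `metrics.json` and a `manifest.json` of MD5 digests to
the output directory; re-running the identical configuration reproduces
identical digests.
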
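---
title: "Multi-level gene set dysfunction analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level gene set dysfunction analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dgsa)
```

## The problem

Tumor tissue differs from normal tissue at several molecular levels at
once: promoter methylation, microRNA expression, and mRNA expression.
These levels are usually profiled in different studies on different
platforms, so sample-wise integration (fitting one model across matched
samples) is often impossible.  This package implements a set-level
alternative: compare levels through *functional gene sets*, asking for each
annotation term which level's measurements best separate tumor from normal
samples, and ranking terms by how dysfunctional they are overall.

Each term `t` is represented by three parallel member sets:

* the **methylation set** — genes annotated to `t` whose methylation was
  measured;
* the **microRNA set** — measured microRNAs with at least one consensus
  target gene annotated to `t`;
* the **mRNA set** — genes annotated to `t` and measured on the mRNA
  platform.

MicroRNA–target links come from several prediction tools; a pair is
accepted when at least `min_tools` distinct tools (default 3, of typically
6) predict it.  Predictions are noisy and tool-specific, so requiring a
multi-tool consensus trades recall for precision.

## Scoring a set's discriminating ability

The discriminating ability of a feature set is measured by a deliberately
simple, assumption-light classifier: 1-nearest-neighbor under the cosine
distance

$$ d(\mathbf{x}, \mathbf{y}) \;=\; 1 -
   \frac{\mathbf{x}\cdot\mathbf{y}}{\lVert\mathbf{x}\rVert\,
   \lVert\mathbf{y}\rVert}, $$

where $\mathbf{x}$, $\mathbf{y}$ are two samples restricted to the set's
features, as measured (no standardization).  Performance is evaluated by
leave-one-out cross-validation — every sample is predicted once from all
others — and summarized by the Matthews correlation coefficient

$$ \mathrm{MCC} \;=\; \frac{TP \cdot TN - FP \cdot FN}
   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} $$

with tumor as the positive class.  The MCC is preferred over accuracy
because the cohorts need not be balanced and the MCC weighs both error
kinds symmetrically.

Numerical conventions (the field's standard ones, stated explicitly because
they matter in edge cases):

* **MCC zero denominator.** If any factor under the square root is zero the
  MCC is defined as 0.
* **Distance ties.** The nearest neighbor is the smallest-index training
  sample among the minimizers.  This makes every result deterministic and
  permutation-testable; on continuous data exact ties essentially never
  occur.
* **Zero-norm vectors.** A constant-zero sample slice has no direction; its
  cosine distance to anything is defined as 1 (with a warning) rather than
  failing, so one degenerate slice cannot abort a scan over thousands of
  sets.

## Ranks, the six groups, and the dysfunction ordering

Raw MCCs are *not* compared across levels: the three platforms come from
different cohorts with different sample sizes and noise, so their MCC
scales differ.  Instead MCCs are ranked within each level across all terms
(rank 1 = highest MCC; tied values get mean ranks, so ranks always sum to
$T(T+1)/2$).  Each term is then classified by the ordering of its three
ranks — one of the $3! = 6$ possible orderings — and the level with the
best rank is the term's leading dysfunctional level.  Terms are prioritized
by **summed rank** (the sum of the three level ranks; smaller = more
dysfunctional overall).

Two conventions were genuinely open and are fixed as follows:

* **Rank direction.** Rank 1 is the *highest* MCC: a dysfunctional level is
  one whose signal separates tumor from normal well relative to other
  terms.
* **Within-term rank ties.** Every term is forced into one of the six
  groups; exact ties between two of a term's level ranks are resolved by
  the fixed priority methylation → microRNA → mRNA and flagged
  (`tie_flag`), rather than introducing a seventh "tied" category.  The
  flag keeps forced assignments identifiable downstream.
* **Summed-rank ties** break lexicographically by term id, for
  reproducibility, and are flagged.

Level-wise MCC distributions are compared with one-sided Welch
(unequal-variance) *t*-tests; the variance of set-level MCCs differs
between platforms, so the pooled-variance form would be hard to justify.

## Downstream: frequent members, enrichment, validation

From the top `k` (canonically 300) dysfunctional terms, the frequency of
every gene (separately for mRNA-level and methylation-level membership)
and every microRNA is counted; members appearing in strictly more than the
threshold (canonically 50) of the top sets are the *high-frequency*
members.  Overlap of the high-frequency genes with a reference pathway is
tested with the upper-tail hypergeometric probability
$P(X \ge k_{\text{obs}})$; the default universe is the set of genes
measured on the mRNA platform, since that is the space the high-frequency
genes were selected from.  Finally, the high-frequency genes are validated
by running the same LOOCV nearest-neighbor machinery *within* an
independent labeled cohort; validation within the cohort (rather than
cross-cohort training) keeps the evaluation machinery identical at every
stage.

## The synthetic-study generator

`simulate_study()` produces a complete study — three matrices, annotation,
multi-tool target predictions, an independent cohort, and a ground-truth
record — so the entire pipeline can be exercised and its recovery behavior
measured without any external data.  Default sizes are desk-scale: 300
genes, 60 microRNAs, 40 terms of 8–15 genes, 30 + 30 samples per platform,
a 0.6 methylation coverage fraction, 2–5 true targets per microRNA, and a
6-tool prediction mechanism in which a true pair is predicted per tool with
probability 0.7 (background 0.02), so true pairs usually survive the
3-of-6 consensus and background pairs rarely do.  Term sizes and the
target map are kept sparse deliberately: on a 300-gene universe, larger
terms or denser target maps make member sharing between terms so high that
a planted effect leaks into most terms, and no per-term signal
concentration — the structure the analysis is meant to detect — remains.

The generative law for a platform's values is

$$ x_{fs} \;=\; b_f \;+\; s_f\,\Delta_f\,\sigma\,[s \in \text{tumor}]
   \;+\; \varepsilon_{fs},\qquad \varepsilon_{fs}\sim N(0,\sigma^2), $$

where $b_f \sim N(6, 1)$ is a fixed per-feature baseline (shared by both
classes; gene baselines are shared between the main and independent mRNA
cohorts), $\Delta_f$ is the planted standardized effect magnitude of
feature `f` (the largest delta among the planted (term, level) pairs the
feature belongs to; shifts do not stack), and $s_f = \pm 1$ is a fixed
per-feature direction drawn with equal probability.

Two aspects of this law are deliberate and worth explaining, because the
"obvious" simpler model fails with a cosine-distance classifier:

* **Nonzero baselines.** If features had mean 0 in the normal class, normal
  samples would be isotropic noise with no preferred direction, and the
  probability that a normal sample's nearest neighbor is a tumor sample
  turns out to be asymptotically independent of both the effect size and
  the panel size (both the attraction toward the tumor direction and the
  spread of normal–normal similarities scale as $1/\sqrt{d}$).  Perfect
  separation would then hold only for lucky seeds.  Measured array
  intensities are positive with feature-specific levels; the shared
  baseline profile gives every class a coherent direction, as in real
  data.
* **Signed shifts.** A purely upward shift on all planted features is
  almost parallel to the baseline profile, and the cosine distance is
  scale-invariant, so such a shift is nearly invisible.  Real dysregulation
  goes both ways (hyper- and hypomethylation, over- and under-expression);
  drawing the direction per feature makes the class-difference direction
  essentially orthogonal to the baseline, and separability becomes
  tunable by $\Delta$.  The realized directions are recorded in the truth
  (`truth$signs`), and the per-feature standardized mean difference
  converges to $\pm\Delta$.

MicroRNA-level membership at generation time uses the *true* target
assignment; the analysis side has to recover it through the tool-consensus
filter.  MicroRNA differential signal is planted on microRNA rows directly,
because microRNA sets are scored on the microRNA matrix itself.

What the generator does **not** emulate: realistic methylation beta-value
distributions (all platforms share one Gaussian scale), batch and
cohort-composition effects, copy-number confounding, correlated noise
between features, and annotation bias.  Passing recovery tests therefore
show that the machinery detects the kind of concentrated, level-specific
mean-shift signal it was designed for — not that any particular real
cohort contains such signal.

## Problem sizes used by the test suite

The recovery experiments are sized to be informative yet quick, and are the
package's canonical desk-scale conditions: the single-level recovery study
uses the default 40 terms with 30 + 30 samples and ten terms planted at
$\Delta = 2.5$ (one level each); the level-ordering study uses 100 terms
with effects 2.0 / 1.2 / 0.6 at the mRNA / microRNA / methylation levels;
oracle equivalence checks use 200 random instances of up to 20 samples and
10 features, all $7^4$ confusion matrices with counts 0–6, and exhaustive
hypergeometric enumeration up to universe size 12.  Since planting requires
term membership and membership is drawn before effects are applied, a
configuration can be planted on exactly the terms that can carry it by
first generating an unplanted study at the same seed and reading its
membership — the second pass reproduces the identical universe.

## Known limitations

* Rank-based cross-level comparison removes scale, not cohort bias: if one
  platform's cohorts are easier to separate for technical reasons, its
  ranks are still globally favored.  The method inherits this from its
  design; only matched-sample studies would remove it.
* Annotation is used exactly as supplied (no ontology propagation), and
  identifiers are matched as exact strings; mapping between probe, gene and
  microRNA id spaces is the caller's responsibility.
* The 1-NN/LOOCV score is a point estimate without an uncertainty measure;
  no permutation significance of individual MCCs is computed.
* `filter_terms()` requires data at all three levels, so terms unmeasured
  at any level are silently out of scope (as in any three-way design).
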
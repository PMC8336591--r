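---
title: "Methods: detecting differentially responsive gene sets between very small cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting differentially responsive gene sets between very small cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(internof1)
```

## The problem

Transcript-level differential expression between two human cohorts becomes
unreliable well before cohort sizes drop to the handful of subjects typical of
rare-disease or micro-stratified studies: between-subject heterogeneity swamps
the within-group signal. When each subject contributes a *paired* pair of
samples under two conditions (tumour versus matched normal, treated versus
pre-treatment), a different route is available. Each subject can first be
analysed as a self-contained single-subject study, producing a per-subject
*effect size* for every gene set; those effect sizes, which come with known
approximate sampling variances, can then be contrasted across cohorts. This
package implements that two-stage design, a moderated-GLM comparator, a
cohort simulator with ground-truth labels, and the benchmarking harness that
evaluates all of them.

## Stage 1: single-subject gene-set effect sizes

For one subject, with pseudocounted counts $x^{T}_g$ and $x^{N}_g$ in the two
conditions, the per-gene signal is the absolute log fold change
$|\mathrm{log_2}(x^T_g / x^N_g)|$. A two-component Gaussian mixture is fitted
to these values by EM: a low-mean component for unresponsive genes and a
high-mean component for differentially expressed (DE) ones. A gene is called
a subject-level DEG when its posterior probability of belonging to the
high-mean component exceeds 0.99 (strict), optionally gated on
$|\mathrm{log_2 FC}| > \log_2 1.2$ for real cohorts, where the extra gate was
found useful; simulated data use the posterior gate alone.

With DEG status in hand, every gene set $gs$ yields a 2x2 table over the
analysis universe: $g$ DEGs in the set, $g'$ non-DEGs in the set, $h$ DEGs
outside, $h'$ neither. Two statistics are computed from it:

* a two-sided Fisher exact test p-value (on the raw integer counts), with
  Benjamini–Hochberg adjustment across all sets scored for that subject —
  this flags the subject's own enriched sets; and
* the continuity-corrected log odds ratio and its Woolf-type variance,

$$Q = \ln\frac{(g+\tfrac12)(h'+\tfrac12)}{(h+\tfrac12)(g'+\tfrac12)},\qquad
\mathrm{var}(Q) = \frac{1}{g+\tfrac12}+\frac{1}{g'+\tfrac12}+
\frac{1}{h+\tfrac12}+\frac{1}{h'+\tfrac12},$$

which is the effect size carried into stage 2. Adding 0.5 to each cell keeps
both quantities finite for any table (the all-zero table gives $Q = 0$,
$\mathrm{var}(Q) = 8$); the correction applies only here, never to the Fisher
test.

## Stage 2: the cross-cohort W statistic

Within each cohort $K \in \{A, B\}$ of $S_K$ subjects, the per-subject log
odds ratios for a set are averaged,
$\bar Q_K = S_K^{-1} \sum_j Q_{kj}$ with variance
$\sum_j \mathrm{var}(Q_{kj}) / S_K^2$, and the cohorts are contrasted with

$$W = \frac{\bar Q_A - \bar Q_B}
          {\sqrt{\mathrm{var}(\bar Q_A) + \mathrm{var}(\bar Q_B)}},$$

approximately standard normal under the null hypothesis that both cohorts
share the same expected log odds ratio. Two-sided p-values $2P(Z > |W|)$ are
BH-adjusted across all $N$ sets tested — all sets passed in, never a
hard-coded count. Finally the *negative-means rule* overwrites the adjusted
value with 1.0 wherever **both** cohort means are strictly negative, so that
discoveries are confined to sets enriched in at least one cohort; impoverished
sets (fewer DEGs than expected) are deliberately not reported because they
lack a clean biological reading. Suppression happens *after* BH, on the
adjusted values, and the remaining q-values are not recomputed; the property
suite verifies that a suppressed set can never be significant and that BH
still sees all $N$ sets.

Two modelling caveats are intrinsic and worth stating. The per-set test treats
transcripts as independent when filling the 2x2 table, which gene correlation
structure violates; and the cohort mean is annotated with a single expectation
per cohort without a per-subject random effect. Both are accepted as part of
the method's design.

## The GLM+EGS comparator

The comparator represents the conventional route: find cohort-interaction
DEGs with a generalized linear model, then test gene sets for
overrepresentation. It is deliberately a *documented simplification* of the
usual voom-with-quality-weights pipeline: counts are TMM-normalized (edgeR's
trimmed mean of M-values, 30%/5% trims) and log2-CPM transformed with a 0.5
offset, each subject is reduced to its within-pair log-ratio — which realizes
subject blocking in a paired design exactly — and the two cohorts' subject
log-ratios are compared per gene with limma's empirical-Bayes moderated
t-statistic (variances shrunk toward a common prior, the classic moderated-t
construction), followed by BH across genes. DEGs (strict $q < 0.05$;
real-data mode adds $|\mathrm{log_2 FC}| > \log_2 1.2$) feed a Fisher exact
test per set with BH across sets. Sample-level quality weights have no
analogue in this reduction; conclusions that could be sensitive to them (the
comparator's exact behaviour at the smallest cohort sizes) should be read as
qualitative, and the benchmark treats them accordingly. A simple
tumour-only contrast (no pairing) is also provided for completeness.

## The simulator

`sim_config()` bundles the six parameters of the benchmark's data generator;
its defaults are the study conditions themselves, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 17414 | simulated gene universe |
| `cohort_size` | 2, 3, 7, 10, 30 in the grid | subjects per (balanced) cohort |
| `prop_coordinated` | 0.25, 0.48, 0.75 in the grid | probability a cohort-A subject uses the shared DEG selection |
| `gamma_shape`, `gamma_scale` | 0.55, 6.06 | distribution of positive DEG log2 fold changes |
| `enriched_sets` | sizes 200 and 40, DEG proportion 0.10 | sets seeded in cohort A |
| `control_sets` | sizes 196 and 41 | never seeded |

A dataset is built as follows. Gene-level means are drawn log-normal
(`meanlog = log(300)`, `sdlog = 1.6` — a realistic bulk RNA-seq abundance
spread) and per-sample normal-tissue counts negative-binomial with
mean-dependent dispersion $\phi(\mu) = 0.02 + 2/\mu$, chosen so that
replicate-pair log2 fold changes have a spread of roughly 0.3–0.5 at moderate
expression, growing at low counts, as replicate RNA-seq data show. The same
generator emits same-condition replicate pairs (7 by default, mirroring a
replicate cell-line experiment) from which an *empirical null fold-change
pool* is built: gene-wise log2 fold changes between replicates, binned by
deciles of baseline expression, with any decile whose expression range
includes zero merged into one category. We read that merge rule as applying
to the baseline-expression axis (bins containing zero-expression genes);
reading it as zero *fold changes* instead would merge nearly all bins and
erase the mean–variance dependence the binning exists to preserve. A
tumour count for an unaltered gene is
$\mathrm{round}(\text{normal} \times 2^{\lambda})$ with $\lambda$ drawn from
the gene's own expression bin; a DEG instead draws
$\lambda \sim \Gamma(0.55, 6.06)$, always positive. Counts are exact
integers but stored as doubles, since the long gamma tail occasionally
produces values beyond the 32-bit range.

Ground truth: the four gene sets occupy disjoint random gene selections (the
real GO terms they stand in for are distinct; overlap handling would
otherwise be unspecified). Each enriched set receives
$\mathrm{round}(\pi \cdot m)$ DEGs (half-up rounding; the rule is not
specified beyond "the proportions of genes specified", and half-up keeps the
count positive whenever the product is at least one half). One shared
selection is drawn per set; each cohort-A subject is flagged coordinated by a
Bernoulli draw and then either reuses the shared selection or draws its own
of the same size. Cohort B and the control sets receive nothing, setting up
the responsive-versus-unresponsive interaction the W statistic targets.
Users with real normal-tissue profiles can pass a count matrix and replicate
pairs through `sim_config(normals=, replicates=)`; subject baselines are then
sampled from its columns without replacement.

What the simulator does *not* emulate: library-size variation between
samples (tumours are derived from their own normals), correlated expression
within gene sets, negative (down-regulated) DEG fold changes — positive-only
fold changes are used deliberately so the GLM comparator is not handicapped
by sign cancellation — and overlap between gene sets. Passing benchmarks here
therefore demonstrates the machinery under favourable, well-specified
conditions, not performance on any particular clinical dataset.

## Preprocessing rules

Two filters reproduce the intended analysis conditions and are deliberately
asymmetric:

* **single-subject route**: within each pair, drop genes with within-pair
  mean at or below 5 counts (real data; the simulation uses a strict
  below-30 rule), keep the union across pairs of everything retained
  anywhere, then add 1 to all counts. The union rule matters: a gene silenced
  in one subject but responsive in another must stay in the universe.
* **GLM route**: drop genes with overall mean below the threshold, add 1;
  for real cohorts, additionally remove any transcript with a zero count in
  any sample and keep the top 70% by coefficient of variation (ceiling, so a
  nonzero fraction always keeps at least one gene). We read the zero-count
  rule as "zero in any sample of the analysis" — the most conservative
  reading, and the one that guarantees CV and log computations are defined.

Both the 5-count boundary (inclusive) and the 30-count boundary (exclusive)
are kept exactly as stated in their respective contexts and exposed as
parameters.

## Numerical choices

* **EM**: deterministic initialization (split at the 90th percentile,
  moments from the two groups), tolerance $10^{-8}$ on the log-likelihood,
  at most 500 iterations, component standard deviations floored at
  $10^{-3}$, mixing weights floored at $10^{-12}$ to prevent component
  death. Components are ordinary Gaussians on the $|\mathrm{log_2 FC}|$
  scale — no folded-normal correction — matching the established practice of
  the single-subject method this stage reproduces. Identical data therefore
  always give identical fits.
* A consequence worth knowing: on *null-only* data the high-mean component
  simply models the upper part of the null distribution, and a substantial
  fraction of genes can exceed posterior 0.99 (a reference mixture
  implementation, mclust, behaves identically). The method tolerates this
  because background DEGs spread evenly across sets — per-subject gene-set
  discoveries stay below the 5% FDR on global-null data, and the cross-cohort
  W statistic stays calibrated; both are verified in the test suite. The
  per-gene posterior should *not* be read as a calibrated per-gene error
  rate.
* **Fisher test**: two-sided by summing hypergeometric probabilities at most
  that of the observed table, with a $1 + 10^{-7}$ relative guard against
  floating-point ties (the standard convention). Verified exhaustively
  against direct enumeration for every table with total at most 60.
* **BH**: stable sort on (p, set id) so ties cannot reorder results.
* **Boundaries**: all significance gates are strict (`<` for FDR levels,
  `>` for posterior and fold-change gates); a cohort mean of exactly zero is
  *not* negative for the suppression rule.

## Problem sizes used by the checks

The packaged test suite and the acceptance script rerun the full design at a
4000-gene universe (3000 in the quickest tests) rather than the full 17,414,
with 30 replicate datasets per configuration thinned to 10 for the 30vs30
configurations (the test suite thins further). These sizes were chosen once
as the smallest at which the headline contrasts are stable; the claims being
checked — precision and recall of the cross-cohort method at 3vs3, the
precision floor across the grid, the comparator's collapse at 2vs2 — concern
proportions and orderings that do not depend on universe size in this design.

## Known limitations

* The single-subject stage needs both conditions from the same subject; there
  is no unpaired fallback.
* The per-gene mixture posterior is a ranking device, not a calibrated error
  rate (see above).
* The comparator is a simplified stand-in for a full voom pipeline and
  should not be cited as "limma's performance".
* Gene-set semantic similarity is accepted as a user-supplied matrix
  (`similarity_matched_pr()`); the package does not compute
  information-theoretic similarity over an ontology, nor does it parse
  ontology graphs or perform term subsumption.
* FDR control across correlated gene sets inherits the usual BH caveats
  under dependence.
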
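---
title: "Models and methods in hydrolnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hydrolnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrolnc)
```

hydrolnc couples two analysis tracks that meet in drought-germination
studies: a physiological track (hydrotime modelling of germination time
courses under osmotic stress) and a transcriptomic track (lncRNA
identification, differential expression, target prediction and network
assembly). This vignette documents the models, the conventions and
defaults chosen where the underlying methodology leaves room, and what
the synthetic-data generators do and do not emulate.

## The hydrotime model

The hydrotime model treats germination as threshold accumulation: seed
$i$ germinates at time $t$ satisfying
$\theta_H = (\Psi - \Psi_{b,i})\,t$, where $\Psi$ is the ambient water
potential (MPa), $\theta_H$ (MPa h) is a lot-level constant, and the
per-seed base water potential $\Psi_{b,i}$ is
$N(\Psi_b(50), \sigma_{\Psi b}^2)$. Seeds with $\Psi_{b,i} \ge \Psi$
never germinate; non-germination is therefore part of the threshold
distribution, not a separate state. The implied cumulative germination
fraction — relative to seeds *sown* — is

$$g(t) = \Phi\!\left(\frac{\Psi - \theta_H/t - \Psi_b(50)}{\sigma_{\Psi b}}\right),$$

which `predict_fraction()` evaluates and which is linear in
$x = \Psi - \theta_H/t$ on the probit scale.

### Parameter estimation

`fit_hydrotime()` implements the repeated-probit estimator:

* **Usable points.** Cumulative fractions with $0 < g < 1$ at each
  observation time and water potential. Boundary fractions carry
  infinite probits and are excluded; this is standard hydrotime
  practice. Replicates are pooled by summing counts before fractions
  are formed, so pooling is count-weighted and one parameter set is
  produced per seed lot.
* **Search.** For each candidate $\theta_H$, `probit(g)` is regressed
  on $x$ by ordinary least squares pooled across water potentials; the
  $R^2(\theta_H)$ profile is maximised by Brent's method
  (`stats::optimize`, golden-section plus parabolic interpolation) on
  $[0.1, 500]$ MPa h with absolute tolerance $10^{-3}$. The profile is
  smooth and unimodal on data generated by the model; the test suite
  verifies the selected optimum against a 500-point grid.
* **Back-transformation.** At the optimum,
  $\sigma_{\Psi b} = 1/\text{slope}$ and
  $\Psi_b(50) = -\text{intercept}\cdot\sigma_{\Psi b}$. A non-positive
  slope means the data carry no dose–response signal and is an error,
  as are designs with fewer than three usable points or a single water
  potential (which cannot separate $\theta_H$ from $\Psi_b(50)$).

OLS on probits is heteroscedastic — extreme fractions are noisier on
the probit scale than mid-range ones — but with several hundred seeds
per treatment the induced bias is small: in the packaged
simulation-and-refit experiments (500 seeds per level, daily scoring,
168-h censor) the mean recovered $\Psi_b(50)$ sits within a few
thousandths of an MPa and $\theta_H$ within about 1 % of the generating
values. An interval-censored maximum-likelihood refinement would remove
the residual bias but the probit-$R^2$ route is the reference
procedure.

## Germination-curve metrics

`build_curve()` divides pooled cumulative counts by pooled seeds sown.
The summary metrics in `germination_metrics()` use *max-relative*
thresholds — t50 is the time to half of the curve's own plateau — so
they remain defined for treatments that plateau below 100 %:

* Crossing times are linearly interpolated on the fraction scale
  between the bracketing observations. A threshold equal to an observed
  value returns the observed time; a threshold already met at the first
  observation degenerates to that observation time (daily scoring is
  coarse, and no interpolant before the first inspection is credible).
* AUC uses the trapezoid rule on the percentage (0–100) scale over
  $[0, 72]$ h, holding the curve at 0 before the first observation and
  at its plateau if scoring stopped early. U7525 is
  $t(0.75\,g_{max}) - t(0.25\,g_{max})$ and is non-negative for any
  monotone curve.
* A treatment with zero germination reports `NA` crossing times and
  zero area rather than an error.

The percentage denominators are seeds sown, not viable seeds; scoring
records rarely distinguish dead from dormant seeds, and the hydrotime
track absorbs non-germination into the threshold distribution.

## lncRNA identification

`identify_lncrnas()` applies five rules in a fixed order — reference
overlap, length < 200 bp, < 2 exons, < 3 supporting reads, coding
potential — and reports each rejected transcript with the *first* rule
it fails. Rule order affects only the reported reason, never the
retained set (rules are conjunctive).

Overlap semantics had to be pinned down: a candidate is excluded when
its span intersects (by at least 1 bp; no reciprocal-fraction
requirement) an exon of a reference mRNA on the *same strand*, or the
span of a structural RNA (rRNA, tRNA, snoRNA, snRNA) on *either*
strand. Strand-aware mRNA exclusion is the only reading consistent
with antisense and intronic lncRNAs existing downstream of the filter;
structural-RNA exclusion is strand-agnostic because those loci are
annotation magnets for assembly artifacts. Candidate *span* (not exon
chain) is used, which makes the filter consistent with
`classify_position()`, where intronic means "span inside a same-strand
gene without touching its exons". Coordinates are 1-based inclusive
throughout, matching GTF; interval arithmetic is delegated to
IRanges/GenomicRanges.

The three coding-potential verdicts (CPC, CPAT, Pfam domain scan) are
consumed as booleans supplied by the caller; a transcript is kept only
on unanimous non-coding agreement. Verdicts are required only for
candidates that survive the structural rules.

## Expression quantification and differential expression

`fpkm()` is the literal definition
$10^9 c_{ij} / (L_i \sum_k c_{kj})$ and therefore obeys the
conservation identity $\sum_i \text{FPKM}_{ij} L_i = 10^9$ per sample,
which the tests exploit. `bh_adjust()` is a validating front end over
`stats::p.adjust(method = "BH")`; each differential-expression contrast
forms its own BH family, mirroring per-comparison reporting of
differentially expressed lncRNAs.

`de_stats()` is deliberately a simple, fully specified stand-in for a
dispersion-modelling RNA-seq test: median-of-ratios size factors, fold
change $\log_2\frac{\bar a + 0.5}{\bar b + 0.5}$ on normalised means,
and Welch's t on $\log_2(\text{norm}+1)$, with $p = 1$ for features
constant in both groups. It exists so the pipeline runs end to end and
deterministically on synthetic data; it makes no claim to match any
particular RNA-seq package's inference, and nothing downstream depends
on such a match. Calling thresholds are strict: FDR < 0.05 and
$|\log_2 FC| > 2$.

## Target prediction and network assembly

`predict_targets()` correlates $\log_2(x+1)$ expression (FPKM
recommended; the log stabilises variance and the offset handles
zeroes), converts $r$ to a two-sided p-value via
$t = r\sqrt{(n-2)/(1-r^2)}$, and adjusts by BH over the *full*
tested-pair family in one run — applying the adjustment once, rather
than per lncRNA, is the stricter and simpler reading. Pairs pass at
$|r| > 0.9$ and $Q < 0.05$. Zero-variance features are skipped with a
warning rather than tested, and an optional externally computed
RNA–RNA interaction score table (e.g. duplex-formation FDRs) further
restricts passing pairs to `score < 0.05`; no interaction algorithm is
implemented here. When FPKM is computed for correlation work it should
be computed on the combined lncRNA + mRNA matrix, as "per million
mapped fragments" is a library-wide denominator; per-submatrix
denominators add spurious normalisation noise at desk scale.

`build_network()` keeps passing pairs, deduplicates edges and returns
node sets, per-side degrees and a bipartite igraph object; degree sums
on both sides equal the edge count by construction.

## qPCR quantification

`relative_expression()` implements plain $2^{-\Delta\Delta C_T}$
(no amplification-efficiency correction): technical replicates are
averaged on the CT scale before the $\Delta\Delta C_T$ step, while the
reported spread is the standard deviation of replicate-wise fold
changes against the calibrator's mean $\Delta C_T$ — the point estimate
uses the most stable averaging, the spread retains replicate scatter.
The calibrator condition's self-ratio is exactly 1, and results are
invariant to per-sample CT shifts (the reference gene cancels them).

## Synthetic data and what it shows

The generators produce every input the analysis functions consume, each
with a serialisable ground-truth ledger (`write_truth_ledger()`) and
full determinism under a seed (regeneration is byte-identical).

**Germination** (`simulate_germination`): per-seed $\Psi_b$ draws,
latent times by threshold inversion, scoring at the first inspection
after the latent time (events bin to the END of their interval, as in
daily scoring) and right censoring at 168 h. Defaults — 500 seeds per
level, $\Psi \in \{0, -0.5, -1.0\}$ MPa, daily scoring over 7 days —
mirror a realistic germination-box trial. Not emulated: seed lot
ageing, dormancy loss over time, temperature effects, or scoring error.

**Expression** (`simulate_expression`): the 42-sample design (two
cultivars; controls at 0/12/24/36 h, drought arms at 12/24/36 h; three
replicates). Background condition response is drawn once per design
cell and shared by its replicates (0.25 log2 units by default), so
replicate scatter is counting noise only, as in a well-behaved
experiment. Planted correlated pairs share a per-sample latent factor —
co-regulated partners tracking a continuous physiological state — whose
loading is tuned analytically so the *expected* observed correlation
equals `target_r` after negative-binomial noise attenuation
($v = (1/\mu + \phi)/\ln^2 2$ at the typical mean;
$c = \sqrt{v\,r/(1-r)}$, about 2.0 log2 units at $r = 0.95$ and
$\phi = 0.1$). Planted differentially expressed lncRNAs are shifted by
`true_lfc` in all drought cells and kept disjoint from planted-pair
lncRNAs. Dispersion defaults to 0.1, typical bulk RNA-seq
overdispersion. Not emulated: length-dependent counting efficiency, GC
bias, batch effects, or the correlation structure of real co-expression
modules — so passing recovery tests shows the *selection machinery*
works at the stated signal strengths, not that real transcriptomes are
this clean.

**Annotation** (`simulate_annotation`): a single-chromosome layout in
disjoint 10-kb slots — reference mRNA genes with exon structure, one
structural RNA of each type, `n_clean` candidates passing every rule
and exactly `violations_per_rule` single-rule violators per rule.
Because violations cannot compound by construction, per-rule rejection
counts must match the planted design exactly, which is the package's
sharpest filter test.

## Problem sizes and numerical choices

The shipped experiments are sized to be decisive yet quick: 20
replicate simulation-and-refit experiments of 1,500 seeds each per
cultivar for hydrotime recovery; 10 seeded 50 × 50-feature datasets
(2,500 tested pairs, 50 planted) for target recovery; 1,000 random
vectors of length up to 500 for the BH oracle comparison. The
$\theta_H$ search tolerance ($10^{-3}$ MPa h) is far below any
biological signal; probit inverse-consistency holds to $10^{-10}$;
FPKM conservation is checked to $10^{-6}$ relative. Ties in crossing
times resolve to observed times; `Inf` is the non-germination marker,
comparing correctly against any censoring horizon.

## Known limitations

* The probit-OLS hydrotime estimator carries a small finite-sample
  bias (see above); likelihood-based refinement is out of scope.
* `de_stats()` has no dispersion shrinkage, independent filtering or
  multi-factor designs and should not be used for real inference.
* Overlap filtering uses candidate spans; a candidate whose span
  straddles an exon it does not itself touch exonically is still
  excluded.
* The hydrotime module is water-potential-only — no hydrothermal
  (temperature) axis.
* Network assembly is structural; it attaches no directionality or
  mechanism to edges.
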
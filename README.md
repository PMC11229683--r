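# hydrolnc

Tools for studying how drought stress shapes seed germination and the
long non-coding RNA (lncRNA) layer of the germinating transcriptome.
The package grew out of work on leaf mustard (*Brassica juncea*)
cultivars of contrasting drought tolerance, where germination under
polyethylene-glycol-imposed water deficits is summarised by a hydrotime
threshold model and RNA-seq time courses are mined for
drought-responsive lncRNAs and their targets. Everything here runs on
tabular inputs (scoring CSVs, count TSVs, GTF annotation, CT tables) and
ships seeded synthetic-data generators with ground-truth ledgers, so
every stage can be exercised and validated without any sequencing data.

## The models

**Hydrotime germination model.** Each seed in a lot germinates once its
accumulated hydrotime reaches a fixed constant:

    theta_H = [psi - psi_b(g)] * t_g

where `psi` is the ambient water potential (MPa), `t_g` the germination
time of the fraction `g`, and the per-seed base water potential
`psi_b(g)` is normally distributed across the lot with median
`psi_b(50)` and standard deviation `sigma_psi(b)`. Probit-linearising
the cumulative germination fraction gives

    probit(g) = [psi - theta_H / t_g - psi_b(50)] / sigma_psi(b)

so for a candidate `theta_H` the probits fall on a line in
`x = psi - theta_H / t`; `fit_hydrotime()` searches `theta_H` to
maximise the pooled regression R², then reads `sigma = 1/slope` and
`psi_b(50) = -intercept * sigma`. Germination curves are additionally
summarised by t50 (time to 50 % of maximum germination), U7525 (time
from 25 % to 75 % of maximum, a uniformity measure) and AUC (area under
the germination-percentage curve within 72 h).

**lncRNA pipeline.** `identify_lncrnas()` applies the standard filter
cascade (reference overlap, < 200 bp, < 2 exons, < 3 reads, and a
three-predictor non-coding consensus from CPC/CPAT/Pfam verdicts),
`classify_position()` assigns lincRNA / antisense / intronic /
sense-overlapping classes, `fpkm()` and `differential_expression()`
quantify and call drought-responsive features (BH FDR < 0.05,
|log2FC| > 2), `predict_targets()` screens lncRNA–mRNA pairs by Pearson
correlation (|r| > 0.9, BH Q < 0.05) with an optional external RNA–RNA
interaction filter, `build_network()` assembles the bipartite
regulatory network, and `relative_expression()` handles 2^-ddCT qPCR
validation tables.

## Worked example

Simulate a seven-day, daily-scored germination trial for a
drought-tolerant cultivar (generating parameters
`psi_b50 = -1.073` MPa, `sigma = 0.339` MPa, `theta_H = 43.054` MPa h)
at three water potentials, refit the model, and summarise the curves:

```r
library(hydrolnc)

wl <- hydrotime_params(psi_b50 = -1.073, sigma = 0.339, theta_h = 43.054)
sim <- simulate_germination(wl, psi_levels = c(0, -0.5, -1.0),
                            n_seeds = 500, seed = 42)
fit_hydrotime(sim)
#> Hydrotime model fit (repeated probit regression)
#> Hydrotime model parameters
#>   psi_b50 :  -1.0754 MPa
#>   sigma   :   0.3367 MPa
#>   theta_H :  42.4434 MPa h
#>   R^2     : 0.998425 on 19 observations

germination_metrics_table(sim$observations)
#> # A tibble: 3 × 5
#>     psi t50_h u7525_h   auc max_fraction
#>   <dbl> <dbl>   <dbl> <dbl>        <dbl>
#> 1  -1   102.     52.2  103.        0.296
#> 2  -0.5  67.3    43.5 1027.        0.822
#> 3   0    40.4    19.0 2882.        0.992
```

The refit recovers the generating parameters from 1,500 interval-
censored seeds, and the curve metrics show the expected drought
response: at −1.0 MPa only 30 % of seeds germinate, half of maximum
germination takes 102 h instead of 40 h, spread (U7525) widens, and the
72-h area collapses from 2,882 to 103 %·h.

On the transcriptomic side:

```r
sim <- simulate_expression(n_lnc = 50, n_mrna = 50, n_planted_pairs = 50,
                           target_r = 0.95, n_planted_de = 0, seed = 1)
f <- fpkm(rbind(sim$lnc_counts, sim$mrna_counts), sim$lengths)
pairs <- predict_targets(f[rownames(sim$lnc_counts), ],
                         f[rownames(sim$mrna_counts), ])
build_network(pairs)
```

recovers the planted correlated pairs (the ground truth is in
`sim$truth$planted_pairs`) as the network's edges.

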
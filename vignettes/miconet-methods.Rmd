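---
title: "Methods: co-occurrence networks, keystone roles and community stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, keystone roles and community stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and design decisions behind
`miconet`. It states no empirical result that the package's tests do not
themselves compute.

## 1. From counts to a signed network

The input is an OTU-by-sample table of nonnegative integer counts,
typically rarefied to a common depth (the package default, 14,666 reads
per sample, matches the depth used in the gut-microbiota surveys this
pipeline is modelled on; `rarefy()` subsamples without replacement, i.e.
multivariate-hypergeometrically). Network construction then follows the
molecular-ecological-network convention:

1. keep OTUs detected in at least 20% of the replicate samples
   (`prevalence_filter`, inclusive boundary: "detected in 20%" is read as
   prevalence ≥ 0.20);
2. convert to relative abundances and take natural logs after adding a
   pseudocount. The upstream protocol does not state its zero policy; the
   default here is half the smallest nonzero abundance in the table,
   recorded on the result so a run is reproducible from its outputs.
   Because the association measure is a rank correlation, the pseudocount
   only matters through the ranking of zeros (all tied);
3. compute pairwise Spearman correlations across samples (average ranks
   for ties; OTUs with zero variance — possible after rarefaction — are
   flagged and given similarity 0, since a rank correlation is undefined
   for them);
4. link every pair with |r| ≥ *St* (inclusive, "similarity threshold"
   semantics); the link weight is the signed correlation, and OTUs with
   no link are excluded from the network.

### The RMT threshold scan

When *St* is not fixed, `rmt_threshold_scan()` chooses it by the
random-matrix-theory transition: for each candidate threshold the matrix
is hard-thresholded, rows/columns with no remaining off-diagonal entry
are dropped, eigenvalues are computed and *unfolded* by a smoothing
spline fitted to the empirical cumulative spectral function, and the
nearest-neighbour spacing distribution (NNSD) of the unfolded eigenvalues
is tested by chi-squared goodness of fit against the Poisson law
$e^{-s}$ (uncorrelated eigenvalues: the signature of a noise-free,
modular matrix) and the GOE Wigner surmise
$\frac{\pi s}{2} e^{-\pi s^2/4}$ (noise-dominated). The chosen *St* is
the smallest grid value at which Poisson is accepted (p > 0.05) and GOE
rejected (p < 0.05). The protocol this mirrors does not publish its
unfolding or binning constants, so they are explicit arguments here:
grid 0.30–0.95 by 0.01, NNSD histogram on [0, 3] with bin width 0.1 plus
an overflow bin, sparse expected cells pooled, eigenvalues deduplicated
at 8 decimals. A fixed `st = 0.802` bypasses the scan entirely and
reproduces the fixed-threshold path bit for bit.

## 2. Topology, modules, null models

All distance-based indices (connectedness, geodesic efficiency and its
reciprocal the harmonic geodesic distance, stress and betweenness
centrality, vulnerability) are computed on the **unweighted, unsigned
skeleton**: correlation weights measure association strength, not path
length. Stress centrality is reported as raw geodesic counts; its
centralization is $\sum_v (s_{max} - s_v) / ((n-1) s_{max})$, defined as
0 when every node has zero stress. Betweenness is normalized by
$(n-1)(n-2)/2$. Eigenvector centrality is computed on the largest
connected component (the principal eigenvector is only well defined
there); other nodes get 0.

Modules come from fast-greedy (CNM-style) agglomerative modularity
maximization, deterministic for a given graph. One engineering note: the
underlying library's default dendrogram cut can return a sub-optimal
partition on degenerate graphs (e.g. a complete graph), so
`detect_modules()` re-cuts the merge sequence at the recorded modularity
maximum and keeps whichever membership scores higher. "Large" modules
are those with ≥ 5 nodes, labelled M1, M2, … by decreasing size.

Significance of any topology statistic is assessed against
degree-preserving Maslov–Sneppen rewirings (default 100, with 10·L swap
attempts each). The node set and degree sequence are conserved exactly;
link weights (hence signs) are reassigned by permuting the original
weight multiset, because a rewired graph has no natural correlation
values — the sign *multiset* is therefore conserved too, while
sign–topology coupling is destroyed, which is the intended null. Metrics
that are functions of the degree sequence alone (average degree) have a
degenerate null (sd = 0) and are flagged rather than given a z-score;
p-values are two-sided normal.

## 3. Zi/Pi roles and keystone screening

For node *i* in module *b*,
$Z_i = (k_{ib} - \bar{k}_b)/\sigma_{k_b}$ and
$P_i = 1 - \sum_c (k_{ic}/k_i)^2$, where $k_{ib}$ counts links of *i*
into its own module and $k_{ic}$ into module *c*. Thresholds follow the
printed convention exactly and strictly: network hubs
($Z_i > 2.5, P_i > 0.62$), module hubs ($Z_i > 2.5, P_i \le 0.62$),
connectors ($Z_i \le 2.5, P_i > 0.62$), peripherals otherwise — the
boundary point (2.5, 0.62) is peripheral. A module in which every member
has the same within-module degree has $\sigma_{k_b} = 0$; such nodes get
$Z_i = 0$ (flagged), since nodes of a degree-homogeneous module are
non-hubs under any reading. Keystones (hubs + connectors) are joined
with abundance classes evaluated over the regional community (all
samples of a stage): abundant if mean > 0.1% or ≥ 0.01% everywhere and
≥ 1% somewhere; rare if < 0.01% somewhere and never ≥ 1%; the remainder
intermediate. Abundant is checked first, so the classes partition the
taxa.

The keystone–diversity screen correlates each keystone's relative
abundance with per-sample richness and Shannon diversity (natural log).
Spearman is the default (abundances are heavily skewed); Pearson is a
flag. Whether the association table of the motivating analyses used
Pearson or Spearman is not stated there, hence the flag. An OTU passes
only if every configured index is significant at α = 0.05; phylogenetic
diversity is excluded by default because the package handles no tree,
but the index set is an argument.

## 4. Stability layer

**Cohesion.** Observed pairwise Pearson correlations on relative
abundances (the cited cohesion protocol works on abundances, not on the
log-Spearman matrix used for networks) are corrected by a taxa-shuffle
null: each taxon's abundances are permuted independently across samples,
correlations recomputed, and the per-pair null mean over `null_reps`
(default 200; the protocol's count is unstated) subtracted. Per-taxon
connectedness is the sum of positive (resp. negative) corrected
correlations divided by the number of partner taxa, and per-sample
cohesion is the abundance-weighted sum of connectedness values. Two
conventions circulate for connectedness — mean over partners of one sign
only, versus the sign-restricted sum divided by all partners. This
package uses the divide-by-all-partners form: under the
mean-over-positives form, pure-noise data at *n* = 100 samples have a
positive-cohesion floor of $E[r \mid r>0] \approx 0.08$ (sampling noise
of a correlation is $\approx 1/\sqrt{n}$), which would make the
package's own null-calibration test unattainable; the divide-by-total
form halves that floor and matches the calibration the acceptance
criteria encode. Taxa present in fewer than 20% of samples are excluded
from the correlation step (reusing the network prevalence rule; the
protocol states no cutoff). N:P = |negative cohesion| / positive
cohesion is computed per sample and then averaged per group — matching
per-panel error bars — rather than as a ratio of group means.

**Vulnerability.** Global efficiency *E* is the mean inverse geodesic
distance over unordered node pairs (disconnected pairs contribute 0).
Node *i*'s vulnerability is $(E - E_i)/E$ with $E_i$ the efficiency of
the network with *i* removed, computed over the remaining $n-1$ nodes
(the denominator shrinks: "relative contribution to global efficiency").
The network's vulnerability is the maximum over nodes; lower reads as
more stable.

**Negative-link ratio.** The fraction of network links with negative
sign; higher is conventionally read as a more competition-buffered, more
stable community.

## 5. The synthetic world

The generator exists so that every pipeline stage has a testable ground
truth without any sequencing download. Each sample draws correlated
standard-normal module factors (pairwise correlation `factor_rho`); each
taxon's latent log-abundance is a loading on its module factor(s) plus
independent Gaussian noise, standardized and scaled by a global log-sd
(`sigma_log`); counts are multinomial at fixed depth on the softmax of
latent log-abundances. Negative associations are negative loadings.
Planted hubs are low-noise members; planted connectors load evenly on
several module factors.

Three structural facts shaped the defaults, all consequences of the role
definitions rather than tuning targets:

* **Connectors need ≥ 3, prefer 4 modules.** With links split over two
  modules $P_i \le 0.5 < 0.62$: a "connector" loading on two modules can
  never classify as one. Over three modules the even-split ceiling is
  0.667 — within noise of the 0.62 threshold — so the default world has
  four modules and connectors loading on all four (ceiling 0.75).
  Loading on multiple *orthogonal* factors caps the connector–member
  correlation at $1/\sqrt{k}$, which is why the module factors are
  correlated (`factor_rho = 0.3`): the common component lifts the
  connector's reach without creating inter-module links.
* **Hubs need degree heterogeneity.** $Z_i$ standardizes within-module
  degree including the hub itself, so in a clique-like module
  $\sigma_{k_b} \to 0$ and every node has $Z_i = 0$: a homogeneous
  strong-coupling world cannot contain detectable hubs, and the
  self-inclusion caps $Z_i$ near
  $d(1-1/m)/\sqrt{s_0^2 + d^2 m^{-1}}$ for module size *m*. The default
  world is therefore a *hub-star*: weak member–member correlations
  (noise variances evenly spaced over `member_noise_range` = (2.1, 2.7),
  giving latent pairwise r ≈ 0.26–0.30) under a strong hub–member
  correlation (hub noise 0.02, r ≈ 0.5), analysed at the recommended
  threshold `st_recommended = 0.36`. Member noise is evenly spaced, not
  drawn, so module density does not swing from seed to seed. The
  homogeneous strong world (within-module r ≈ 0.9, three 15-taxon
  modules falling into separate components) is kept as
  `strong_module_spec()` and is the benchmark for module recovery.
* **N:P is PSD-bounded for planted signals.** Correlation matrices are
  positive semidefinite, so no loading scheme can make planted negative
  association outweigh planted positive association in the cohesion sums;
  on top of that sits a noise floor common to both signs. The
  developmental series therefore produces its increasing N:P the way
  rarefied data actually do: later stages get stronger dominance swings
  (`sigma_log` 0.35 → 0.70 → 1.05), and under a fixed sequencing depth a
  blooming taxon necessarily displaces the rest — compositional closure
  as the expression of competitive exclusion — alongside an increasing
  fraction (0.10 → 0.30 → 0.50) and strength (0.4 → 0.75 → 1.0) of
  negative couplings, more coupled taxa (30 → 45 → 60 of ~74), a larger
  replicate count (80 → 100 → 120, inside the reference design's range),
  and a falling abundance share of coupled taxa (0.55 → 0.45 → 0.35).
  Under this schedule links, the negative-link ratio and N:P rise with
  stage while positive cohesion falls.

Planted rare taxa get baseline expected relative abundance 3 × 10⁻⁵,
safely under the 0.01% rarity line at depth 14,666. Stage metadata uses
the developmental windows 12–26, 27–42 and 56–98 days post-hatching with
network-bearing sampling points as the dph pool.

The generator's defaults were designed from the arithmetic above and
verified by design-stage simulation, then frozen *before* the acceptance
tests were written. What a green recovery test establishes is that the
pipeline recovers planted structure of this kind at these strengths; the
generator does not emulate sequencing error, chimeras, true ecological
dynamics (no Lotka–Volterra mechanism), or the taxonomic composition of
any real gut community.

## 6. Orchestration and reporting conventions

`run_pipeline()` groups samples by stage or by dph; groups under the
minimum replication (default 27, the usual floor for a reliable
correlation network) are excluded from network construction but stay in
the diversity report. Regression of a metric against dph is ordinary
least squares with the slope's p-value and adjusted R²; restricting the
fit to a subset of time points is always an explicit argument, never
automatic, because silent point-dropping is irreproducible. An exactly
constant metric returns slope 0 with p = 1 (no evidence of a trend)
rather than a 0/0. Group comparisons use one-way ANOVA followed by
unadjusted pairwise LSD t-tests (pooled variance, residual df) and a
compact letter display built by insert-and-absorb, so two groups share a
letter exactly when their pairwise test is non-significant at α = 0.05;
a Holm adjustment is available but off by default to match the classical
LSD protocol. Every seed, threshold and policy of a run is written to a
single manifest, which fully determines the outputs.

## 7. Known limitations

* No phylogeny: Faith's PD and related indices are out of scope.
* Spearman is the only association measure (no SparCC/proportionality);
  compositional artefacts are mitigated only by the cohesion null model.
* Modularity is computed on the unsigned skeleton; signed-modularity
  variants are deliberately excluded.
* The RMT scan needs a reasonably large matrix (≥ 20 OTUs after
  thresholding) for the spacing statistics to mean anything.
* Ordination, PERMANOVA/MRPP, SEM/path modelling and source-tracking are
  outside this package: the stability outputs are exported so external
  tools can consume them.
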
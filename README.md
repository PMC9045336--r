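# miconet

Co-occurrence networks, keystone taxa and stability statistics for
microbial communities.

`miconet` takes an OTU-by-sample count table (e.g. rarefied 16S rRNA
counts) and runs the network layer of a molecular-ecological-network
analysis:

* **Network construction** — Spearman correlations between
  log-transformed relative abundances of prevalence-filtered OTUs
  (detected in ≥ 20% of replicate samples), thresholded at a similarity
  threshold *St*. *St* can be fixed (0.802 is the conventional
  RMT-derived value for deeply replicated gut-microbiota data) or chosen
  by a random-matrix-theory scan: the smallest threshold at which the
  nearest-neighbour spacing distribution of the unfolded eigenvalues of
  the thresholded matrix follows Poisson statistics (noise removed)
  rather than the GOE/Wigner law (noise dominated). Every link keeps its
  signed correlation.
* **Topology and modules** — nodes, links, average degree (avgK = 2L/n),
  Krackhardt connectedness, geodesic efficiency and harmonic geodesic
  distance, stress-centrality centralization, power-law fit of the
  degree distribution, and fast-greedy modularity (Newman–Girvan Q),
  each testable against 100 degree-preserving Maslov–Sneppen
  randomizations (`null_ensemble`).
* **Node roles** — within-module connectivity
  `Zi = (k_ib − mean(k_b)) / sd(k_b)` and among-module connectivity
  `Pi = 1 − Σ_c (k_ic / k_i)²`; nodes with `Zi > 2.5` are module hubs
  (network hubs if additionally `Pi > 0.62`), nodes with `Pi > 0.62`
  alone are connectors, and hubs plus connectors form the potential
  keystone set, cross-tabulated with rare/abundant classes
  (mean > 0.1% abundant; < 0.01% somewhere and never ≥ 1% rare) and
  screened for associations with alpha diversity.
* **Stability** — community cohesion (per-sample abundance-weighted sums
  of null-corrected positive and negative correlations, with the
  taxa-shuffle null), the N:P ratio |negative cohesion| / positive
  cohesion, node-removal vulnerability (relative loss of global
  efficiency; the network value is the maximum over nodes), and the
  negative-link ratio.
* **Synthetic data** — a latent-factor generator of rarefied-style
  multinomial count tables with planted modules, hubs, connectors,
  negative couplings, rare taxa and a three-stage developmental schedule
  whose ground truth makes every stage of the pipeline testable offline.

## Worked example

```r
library(miconet)

stage <- generate_stage(synthetic_spec(seed = 42))
stage$table
#> count_table: 120 OTUs x 100 samples
#>   total reads: 1,466,600; median depth: 14,666
#>   metadata columns: sample_id, dph, stage, tank

rel <- to_relative(prevalence_filter(stage$table, 0.2))
net <- build_network(spearman_matrix(log_transform(rel)),
                     st = attr(stage$truth, "st_recommended"))
net
#> eco_network (st = 0.360): 61 nodes, 163 links (41.7% negative)

part <- detect_modules(net)
part
#> module_partition: 4 modules over 61 nodes, Q = 0.520

roles <- node_roles(net, part,
                    classes = classify_abundance(to_relative(stage$table)))
table(roles$role)
#>  connector module_hub peripheral
#>          2          4         55
```

The four planted module hubs and both planted connectors are recovered:
hubs sit at `Zi` 2.6–3.4 with small `Pi`, connectors at `Pi` ≈ 0.66 with
small `Zi`. Against 100 degree-preserving rewirings the empirical
modularity is far outside the null (`z ≈ 17.7`), while the average degree
is conserved exactly (`null_sd = 0`):

```r
null_ensemble(net, reps = 100, seed = 1)
#>                  metric empirical null_mean null_sd      z
#>              modularity     0.520     0.314  0.0116  17.69
#>              avg_degree     5.344     5.344  0.0000     NA
#>           connectedness     1.000     0.996  0.0154   0.25
#>     geodesic_efficiency     0.419     0.452  0.0067  -4.91
#>   centralization_stress     0.923     0.885  0.0112   3.37

co <- cohesion(to_relative(stage$table), null_reps = 200, seed = 1)
co
#> cohesion_result: 120 taxa, 100 samples (pearson, 200 null reps)
#>   mean cohesion_pos 0.0425, mean cohesion_neg -0.0507

vulnerability(net)$network_vulnerability
#> [1] 0.117
```

`generate_series()` produces a three-stage developmental schedule in
which links, the negative-link ratio and N:P increase stage by stage
while positive cohesion decreases, and `run_pipeline()` orchestrates the
whole per-group analysis (filtering, networks, nulls, roles, cohesion,
ANOVA + LSD letters, overlap counts) from a count table plus metadata,
writing TSV/GraphML outputs and a seed-complete manifest.

## Command line

```sh
Rscript inst/cli/miconet.R simulate --seed 1 --out synthetic
Rscript inst/cli/miconet.R pipeline \
    --counts synthetic/stage1_12to26dph_counts.tsv \
    --metadata synthetic/stage1_12to26dph_metadata.tsv \
    --st fixed:0.36 --seed 1 --out results
```

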
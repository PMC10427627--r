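# ampliclone

Joint inference of SNV and copy-number clone trees from targeted
single-cell DNA sequencing read counts.

## What it does, and for whom

Targeted single-cell DNA panels (e.g. MissionBio Tapestri) report, for
each of thousands of cells, the read depth of every panel region (a gene,
i.e. the amplicons targeting it) and the REF/ALT read counts at every
variable locus.  `ampliclone` is for cancer-genomics analysts who want,
from those two matrices alone, the clonal architecture of the sample: a
rooted tree of somatic events — SNVs plus allele-specific copy-number
alterations (gain, loss, copy-neutral LOH) — the fraction of cells in
each clone, per-variant allelic dropout rates, and posterior cell
assignments.

The model: each node `n` implies a genotype (region copy numbers
`c_k(n)`, per-variant allele copies `(c_r, c_a)`) by applying its
root-path events to the diploid genome.  Region depths are negative
binomial,

    D_kj | D_j ~ NB( mean = D_j * c_k * rho_k / sum_l c_l rho_l ,  theta )

with per-region amplification weights `rho` and inverse dispersion
`theta`.  ALT counts are a beta-binomial mixture over allele-specific
dropout configurations `(k, l)` (each chromosomal copy amplifies
independently with probability `1 - mu_i`, expected ALT fraction
error-adjusted by `eps`, concentration `omega_hom`/`omega_het`).
Cell attachments — including doublets, mixed in with rate `delta` — are
marginalised analytically:

    P(D, A | T) = prod_j [ (1-delta) sum_n pi_n P(D_j, A_j | n)
                           + delta sum_{n,n'} pi_n pi_n' P(D_j, A_j | n, n') ]

A penalising tree prior controls node count, copy-number events (after
merging events on genomically contiguous regions; LOH events cost twice
as much, scaled by `1500 + n_cells`) and off-root placement of
population-frequent variants.  Node weights `pi` and dropout rates `mu`
are fitted by an EM algorithm nested inside every step of a two-phase
simulated-annealing search: phase 1 fits the SNV tree, the cells at its
normal nodes calibrate `rho` and nominate candidate CNA regions by
normalised-depth deviation, and phase 2 searches full event trees with
gains/losses restricted to those candidates.

A synthetic-data generator (non-uniform amplicon efficiencies,
overdispersed depths, allele-specific dropout, sequencing error,
doublets, Dirichlet clone sizes, optional cross-amplicon coverage
correlation) and genotype-based evaluation metrics make the whole system
testable without any external download.

## Worked example

```r
library(ampliclone)

cfg <- sim_config(n_cells = 1000, n_snvs = 7, n_cnas = 3)   # Tapestri-like
sim <- simulate_dataset(cfg, seed = 1)
fit <- fit_clone_tree(sim$data,
                      infer_config(n_chains = 1, iterations = c(500, 800),
                                   seed = 1))
summary(fit)
#> clone_tree_fit: 1000 cells, 8 nodes, 11 SNVs, 4 CNA events
#> log posterior -158852.96 (log-likelihood -158705.88)
#> node weights: 0.429 0.005 0.011 0.034 0.247 0.173 0.078 0.024
#> dropout rates: median 0.043 (range 0.015-0.096)
#> CNA calls:
#>  node region  kind
#>     5 GENE16  GAIN
#>     6 GENE16  GAIN
#>     7  GENE7  GAIN
#>     7  GENE6 CNLOH
#> candidate regions: GENE7, GENE16

unlist(evaluate_fit(fit, sim$truth, sim$data)[1:3])
#> cell_assignment_accuracy                  cna_fpr                  cna_fnr
#>                0.9673684                0.0000000                0.0000000
```

96.7% of cells land in the right clone and all three simulated CNAs are
recovered with no false calls (`GAIN GENE16` appears once per lineage in
two sibling clones; calls are identified by region and kind).  `plot(fit)`
draws the tree; `predict(fit)` returns MAP attachments;
`coef(fit)` the fitted `pi`, `mu`, `rho`; `residuals(fit)` standardised
depth residuals; `simulate(fit)` parametric-bootstrap replicates.

Real data enter through four CSVs (region counts, variant REF/ALT counts,
variant metadata, region metadata) via `load_panel_data()`, or from the
shell:

```sh
Rscript inst/cli/ampliclone-simulate.R --out sim/ --cells 3000 --seed 1
Rscript inst/cli/ampliclone-infer.R \
    --region-counts sim/panel_region_counts.csv \
    --variant-counts sim/panel_variant_counts.csv \
    --variant-meta sim/panel_variant_meta.csv \
    --region-meta sim/panel_region_meta.csv \
    --out fit/ --seed 1
Rscript inst/cli/ampliclone-evaluate.R --inferred fit/ --truth sim/ \
    --out report.json
```

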
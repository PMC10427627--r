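---
title: "Joint SNV and copy-number clone trees from single-cell amplicon panels"
author: "ampliclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint SNV and copy-number clone trees from single-cell amplicon panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclone)
```

## The problem

Targeted single-cell DNA sequencing (e.g. the MissionBio Tapestri
platform) measures, for thousands of cells, the read depth of a few dozen
PCR amplicons and the REF/ALT read counts at a panel of variable loci.
Amplicons targeting the same gene are grouped into *regions*.  From these
two count layers `ampliclone` reconstructs a rooted tree of somatic
events — single-nucleotide variants (SNVs) and allele-specific
copy-number alterations (gains, losses and copy-neutral loss of
heterozygosity, CNLOH) — together with the fraction of cells in each
clone and per-variant allelic dropout rates.

Each node of the tree implies a genotype: the cumulative effect, on the
diploid genome, of the events on its root path.  SNVs are acquired
exactly once; a region may be hit by several CNAs but at most once per
root-to-leaf lineage; an event can only affect an allele present in the
node's pre-event genotype; and region copy numbers are restricted to
0–3, since targeted counts cannot distinguish higher states reliably.
Within a node, SNVs apply before CNAs (ties broken by target index), so
"SNV + CNLOH in one node" means the mutation is acquired and then made
homozygous.  Losing the ALT allele of a variant re-creates the wild-type
genotype in that lineage — mutation losses follow the Dollo model.

## The observation model

**Region depths.** Each region `k` has an amplification propensity
`rho_k` (a simplex over regions): the probability that a read falls in
region `k` for a CNA-free diploid cell.  For a cell with total depth
`D_j` attached to a node with region copy numbers `c_k`, the expected
depth is `D_j * c_k * rho_k / sum_l c_l rho_l`, and the observed depth is
negative binomial around that mean with inverse dispersion `theta`
(variance `m + m^2/theta`).  `theta = 6` by default, matching the strong
cell-to-cell amplification variability of panel data.

**Allelic counts.** A variant with `c_r` REF and `c_a` ALT copies in the
attached genotype is observed through allele-specific dropout: each
chromosomal copy amplifies independently with probability `1 - mu_i`
(`mu_i` is the variant-specific dropout rate).  Conditional on `(k, l)`
copies amplifying, the expected ALT read fraction is
`l/(k+l) * (1-eps) + k/(k+l) * eps` with sequencing error `eps`, and the
ALT count is beta-binomial with concentration `omega_hom = 50` when the
amplified material is single-allele and `omega_het = 15` otherwise
(heterozygous loci are more overdispersed).  The mixture excludes total
dropout `(0, 0)`; by default it is renormalised by `1 - mu^(c_r+c_a)`
(conditioning on the locus amplifying at all), because the unnormalised
form penalises high-copy genotypes by exactly the probability of an event
that is never observed.  `dropout_renormalize = FALSE` restores the
unnormalised form for comparison.

Two boundary conventions matter in practice.  A zero-depth locus
contributes nothing (the model conditions on the locus depth).  A locus
fully deleted in the attached genotype (`c_r + c_a = 0`) can still show
reads in real cells — stray amplification or doublet residue — so those
reads are scored as pure sequencing error (`f = eps`) rather than given
probability zero, which would veto the attachment outright.

**Doublets.** With probability `delta` a barcode holds two cells.  A
doublet's genotype sums the allele copies and averages the region copies
of its two nodes.  The per-cell likelihood mixes singlet attachments
(weight `(1-delta) pi_n`) and unordered node pairs (weight
`2 delta pi_n pi_n'`, `delta pi_n^2` for self-pairs), which reproduces the
ordered double sum exactly at half the cost.

**Marginalisation.** Cells are never assigned during search: the
likelihood of a tree sums the attachment mixture analytically per cell.
This is what makes thousands of cells cheap — the per-tree cost is linear
in cells times attachments.

## Tree prior

Three penalty groups, with empirically chosen weights:
`-p1 * n_SNVs * n_nodes` discourages gratuitous nodes (`p1 = 0.1` is low
because learned node weights already absorb most of the benefit of extra
nodes); `-(1500 + n_cells) * p2 * (n_LOH + n_noLOH/2)` charges
copy-number events after merging same-kind events on regions adjacent in
genomic order within a chromosome (real CNAs typically span large
stretches), with LOH-producing events charged twice as much because they
also reshape the allelic likelihood (`p2 = 0.01` is the main knob to
adjust if CNA calls look too liberal or too conservative); and every
variant placed off the root pays `p3 + p4 * popfreq` (`p3 = 3`,
`p4 = 20`), so population-frequent variants resist being called somatic.
Kinds never merge across types, and merges never span chromosomes.  The
prior's additive constant is dropped; every use is comparative.

## Fitting: EM inside simulated annealing

Given a tree, the node weights `pi` and dropout rates `mu` are fitted by
EM: the E-step computes posterior attachments (Bayes rule over the
attachment mixture) and, per variant and attachment, the posterior over
amplified-copy configurations; the M-step sets `pi` to mean
responsibility (flat Dirichlet prior; doublet attachments credit half a
cell to each member) and updates each `mu_i` to the maximiser of the
expected complete-data log posterior under a Beta prior with mean 0.05
and strength 40 (`alpha = 2, beta = 38`).  With the renormalised dropout
model that maximiser has no closed form, so it is found by a bracketed
golden-section search per variant, which preserves the EM monotonicity
guarantee to machine precision; with the unnormalised model the
closed-form ratio of expected dropped to total copies is exact.  Rates
are clamped to `[1e-4, 0.5]` — dropout beyond one half is implausible for
these panels.  The monotonicity of the log-posterior trace is asserted on
every fit; a decrease beyond `1e-7` raises an error.

The tree search is simulated annealing over event trees: propose a
neighbour, refit `pi`/`mu` with a short warm-started EM (at most 10
iterations, tolerance 0.1 log-units; `mu` warm-starts from the current
state and `pi` is carried through the move where the node set allows),
and accept with probability
`min(1, exp((logpost' - logpost)/T + log Hastings ratio))` under a
geometric temperature decay from 8 to 1.  Moves: prune-and-reattach a
subtree, swap the event sets of two nodes, move one SNV, split or merge a
node, add/delete a CNA, toggle a CNA's allele, with weights
(0.25, 0.1, 0.25, 0.2, 0.15, 0.05) in the CNA-free phase.  In the CNA
phase the CNA move share is raised to 0.38 (others rescaled): the SNV
structure is largely settled by then, and the add-CNA space
(kind x region x node x alleles) is large enough that a correct addition
would otherwise be proposed less than once per several hundred
iterations.  Invalid draws are resampled up to a bound before the move
type is redrawn, so every evaluated tree satisfies the constraints.
Because a short inner EM estimates posteriors with a noise of a log-unit
or so, a candidate for "best tree so far" is first re-evaluated with a
longer EM; event-free nodes (whose genotype equals their parent's, so
removal provably never lowers the posterior) are pruned at that point.

**Two phases.** Phase 1 searches CNA-free trees; with every genotype
diploid, the depth factor cancels and only SNVs drive the fit.  The cells
attached to "normal" nodes — nodes whose root path carries only
germline-candidate variants (a tolerant reading of "root cells" that
survives a germline SNP stranded one node below the root) — then estimate
`rho`, and regions whose responsibility-weighted normalised depth
`D_kj/(D_j rho_k)` at some node with at least 1% of cells departs from
the normal profile by more than 20% become CNA candidates.  Phase 2
anneals with gains and losses restricted to the candidates; CNLOH is
copy-neutral, leaves no depth footprint, and is therefore allowed on any
usable variant-bearing region — its evidence is allelic imbalance, which
the depth screen cannot see.  Poorly amplified regions (estimated weight
below `min_region_depth_fraction`) are excluded from CNA inference
entirely, and CNAs are never placed at the root, where they would be
unidentifiable from a rescaled `rho`.  A final long EM refit of the
winning tree produces the reported weights, dropout rates and attachment
posteriors.  Near-equal posteriors are resolved towards fewer nodes, then
fewer CNAs, then lexicographically, so a fit is a deterministic function
of `(data, seed)`.

Default budgets (1500 iterations per phase, 2 chains, best-of selection)
are sized for targeted panels — up to roughly ten SNVs and eight clones —
where the SNV tree space is small; the recovery studies in the test suite
use 500–800 iterations and one chain at 1000 cells, which the same
experiments show is already past the point of diminishing returns at that
problem size.

## The synthetic-data generator

`simulate_tree()` + `simulate_cells()` generate Tapestri-like panels with
full ground truth.  Clone weights are Dirichlet with concentration 0.3 —
the value typical of real clone-size imbalance, which regularly produces
near-empty clones.  Region efficiencies are uniform per amplicon or
log-normal (`sigma = 1`), reproducing the order-of-magnitude amplicon
spread of real panels; `depth_mean = 40` reads per amplicon per cell
matches the 30–80x per-amplicon coverage of the platform.  Cell totals
are log-normal; region depths are negative binomial around the
copy-number- and efficiency-scaled expectation; locus depths are the
multinomial share of one amplicon; ALT counts follow the dropout +
error + beta-binomial mechanism conditioned on at least one copy
amplifying; doublets draw two nodes; germline SNPs sit at the root with
population frequencies; and an optional per-cell binary latent factor
tilts a fixed random half of the regions by `1 + gamma`, reproducing the
block-correlated depth fractions seen across amplicons in real data
(a phenomenon that does not, in our experiments, perturb the inference).
Somatic CNAs are placed on non-root nodes only, respecting all tree
constraints, with a configurable fraction required to be supported by an
SNV or LOH at or below their node.

What passing recovery tests on these simulations does **not** show: the
generator draws from the fitted model family itself (plus the correlation
stressor), so it cannot reveal model misspecification present in real
panels — index hopping, cell-cycle coverage waves, segmental amplicon
dropout, or copy numbers above three.

## Known limitations

* **No normal-cell anchor.** When a sample contains essentially no
  wild-type cells, a clonal loss is unidentifiable from a rescaled
  amplification profile: the mirror-image solution (complementary gains
  in the minority clone) can have higher posterior than the truth.  This
  is a property of the model, not of the search; such draws appear in the
  recovery studies as rare low-accuracy replicates.
* **Dropout rates of variants private to tiny clones** shrink to the
  prior mode (about 0.026): with a handful of heterozygous cells there is
  simply no information, and at low locus depth dropout and clone
  membership partially explain each other.
* **Copy numbers are capped at three** and one CNA per region per
  lineage; whole-genome duplication is out of scope.
* Exact Hastings ratios are implemented per move pair, but the sampler is
  used for optimisation only; no posterior sample over trees is produced.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_cells = 1000, n_snvs = 7, n_cnas = 3)
sim <- simulate_dataset(cfg, seed = 1)
fit <- fit_clone_tree(sim$data,
                      infer_config(n_chains = 1, iterations = c(500, 800),
                                   seed = 1))
summary(fit)
evaluate_fit(fit, sim$truth, sim$data)[1:3]
plot(fit)
```
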
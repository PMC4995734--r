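---
title: "Models and methods in panselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in panselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`panselect` reimplements, as one tested toolchain, the comparative-genomics
workflow used to study how closely related bacterial strains diverge: which
gene families they share, how their gene content and core genomes branch,
which core genes evolve under positive selection — in the whole species and
on one focal clade — and how competitive the strains are when propagated
together in serial fermentations. This vignette explains the models, the
parameters that matter, and the design choices made where the standard
tools leave details open.

## Pan-genome construction

Proteins longer than 50 residues (strictly greater; shorter sequences are
mostly fragments and spurious ORFs) are compared all-against-all with exact
global Needleman–Wunsch alignment under BLOSUM62 with affine gaps (opening
10, extension 0.5). A pair becomes an edge of the similarity graph when
both the percent identity (identical aligned pairs over aligned columns)
and the coverage reach 70%. Coverage is defined here as the *minimum* of
the two per-sequence aligned fractions, the stricter of the conventions a
local-alignment search leaves ambiguous; requiring both sequences to be
covered prevents domain-level hits from gluing unrelated multi-domain
proteins into one family. Within-genome pairs are retained so paralogs
co-cluster.

Exact all-against-all alignment is quadratic, so candidate pairs are
prescreened by shared 5-mers: at 70% identity over 70% of a protein's
length, dozens of identical 5-mers are guaranteed, so demanding a single
shared 5-mer cannot lose a qualifying pair, while it removes almost all of
the quadratic bulk. A precomputed similarity table (TSV) can be ingested
instead for large inputs.

Families are read out of the graph by the Markov Cluster algorithm with
inflation 2.0: the column-normalized weighted adjacency (self-loops at the
maximum incident weight) is alternately squared (expansion) and raised
entry-wise to the inflation power with renormalization, until the matrix
changes by less than 1e-6 or 200 iterations pass; clusters are the
connected components of the limit matrix. Self-loop weight, tolerance and
iteration cap follow common MCL practice; they are configurable in
`clustering_config()`. Disconnected graph components are clustered
independently, which is mathematically identical and much faster. A
pan-genome over *n* genomes is partitioned into core (present in all *n*),
unique (exactly 1) and distributed (2 to *n* − 1) families.

## Gene-content tree

Gene content is summarized as a binary genomes × families matrix; the
distance between two genomes is one minus the Jaccard coefficient of their
family sets. The tree is built by UPGMA (average linkage, node height =
half the merge distance, hence ultrametric output). Agglomerative
tie-breaking is not standardized across implementations, so ties are broken
deterministically by the lexicographically smallest pair of cluster
representatives; two genomes with identical content get distance exactly 0
and merge first.

## Core-genome phylogeny

Single-copy core families are aligned at the protein level (deterministic
progressive alignment: 3-mer guide distances, UPGMA guide tree,
profile–profile Needleman–Wunsch merges), back-translated onto their coding
sequences (each residue becomes its source codon, each gap `---`; terminal
stops are stripped, internal stops are an error naming gene and position),
concatenated, and filtered: every column containing a gap is dropped, as is
every column whose majority residue is carried by fewer than half the rows.
The 0.5 majority rule is the package's reading of "too divergent to be
reliable"; it is exposed in `filter_policy()`.

The tree is inferred in two stages: a neighbor-joining topology on TN93
distances, then maximum-likelihood branch lengths and model parameters
under GTR+Γ4 on that fixed topology (L-BFGS-B on log/softmax transforms;
base frequencies empirical by default). A full topology search is
deliberately out of scope — on closely related strains the NJ topology is
nearly always the ML topology, and the likelihood machinery is fully
exercised through branch-length and parameter estimation. The likelihood
uses Felsenstein pruning with site-pattern compression; rate heterogeneity
uses the standard discretization into four equal-probability gamma
categories represented by their means. Gaps and ambiguity codes are
missing data (partial likelihood 1 in every state). Bootstrap support
resamples alignment columns with replacement, rebuilds each replicate by
the same distance+NJ route, and reports the percentage of replicates
containing each bipartition (1000 replicates by default; the pipeline
default is 100, which is ample for the strong signal of concatenated core
genomes at this scale).

## Positive-selection models

The unit of selection analysis is the dN/dS ratio ω under a Goldman–Yang
codon model: substitutions are single-nucleotide changes with rate
π_target × κ for synonymous transitions, π_target for synonymous
transversions, and ω times those for nonsynonymous changes; the generator
over the 61 sense codons is scaled so branch lengths are expected
substitutions per codon. Codon frequencies default to F3x4 (products of
position-specific nucleotide frequencies), with uniform and
observed-frequency options.

Two nested comparisons are implemented:

* **Site models.** M1a ("nearly neutral") mixes two site classes,
  ω₀ ∈ (0, 1) with proportion p₀ and ω₁ = 1; M2a adds a third class with
  ω₂ ≥ 1. Twice the log-likelihood difference is referred to χ² with 2
  degrees of freedom.
* **Branch-site model A.** Four site classes: ω₀ everywhere; neutral
  everywhere; and two classes that are ω₀ (or neutral) on background
  branches but ω₂ ≥ 1 on the designated foreground branches, with the
  constrained proportions of model A. The null fixes ω₂ = 1; the LRT has
  1 degree of freedom. The foreground defaults to the whole focal clade
  (stem plus internal branches), with a stem-only option; when the marked
  tips are not monophyletic on the working tree the MRCA clade is used,
  with a warning. Because the models are time-reversible the tree may
  arrive unrooted; it is then re-rooted at a background tip so the
  foreground forms a proper clade.

Both tests sit at a boundary of the parameter space (p₂ = 0, ω₂ = 1), so
the χ² reference is conservative; the null-calibration checks in the test
suite accordingly expect rejection rates at or below the nominal level.

Numerical strategy: all constrained parameters are optimized on
unconstrained transforms (softmax proportions, logit ω₀, ω₂ = 1 + e^u), so
constraints hold by construction; multi-start optimization (3 seeded starts
by default) guards against local optima; transition matrices come from the
eigendecomposition of the π^{1/2}-symmetrized generator, and
eigendecompositions of the unscaled generator are memoized per (κ, ω)
within a fit, since the mixture rescaling touches only the eigenvalues.
Because the alternative model contains its null, an optimum that lands
below the null log-likelihood is an optimizer artifact; fits restart from
the null optimum and, failing that, report the boundary point itself.
Residual statistics in (−1e−4, 0) are clamped to zero.

Branch lengths are estimated once under the single-ratio M0 model and then
held fixed across M1a/M2a/branch-site fits — common practice that bounds
runtime and removes a nuisance dimension; joint estimation remains
available. The genome-scale scan (`scan_core_genes()`) additionally holds
κ at each gene's M0 estimate and uses a slightly looser optimizer
tolerance; κ̂ is nearly identical across these nested models, and the scan
is read through ranks and counts rather than third-decimal likelihoods.
Per-gene failures are recorded in the output row, never fatal to the scan.
Raw LRT p-values at α = 0.05 are reported by default, with an optional
Benjamini–Hochberg flag.

## COG enrichment

Genes are mapped to COG functional categories from a two-column table
(multi-category genes count once per listed category; unmapped genes form
an "uncategorized" bucket). For each category, the proportion among
positively selected genes is tested against the core-genome background
proportion with an exact one-sided binomial upper tail — enrichment
direction only, no normal approximation, no correction by default,
matching how such scans are conventionally reported.

## Competition fitness

Strain abundances come from plate counts or from qPCR: a standard curve
(OLS of Ct on log₁₀ copies, with amplification efficiency 10^(−1/slope)−1)
converts threshold cycles to copy numbers, a calibration line fitted on
single-strain fermentations converts copies to CFU, and measurements below
the detection limit (10² copies/g by default, boundary inclusive) are
censored — flagged and excluded, never imputed or zeroed. The relative
fitness of strain x against strain y over one back-slopped fermentation
cycle is

w = ln(x_F / x_0) / ln(y_F / y_0),

the ratio of realized Malthusian growth. Serial-transfer assays report
this quantity under several algebraically equivalent presentations; the
package adopts the ratio-of-log-growth form of the classic competition
literature, the one convention under which w = 1 means exactly equal
competitiveness — this definitional choice is an assumption of the
module and is stated as such wherever w is reported. Per-cycle w values are pooled
across cycles and replicates into mean ± sample SD with the count of
finite values; the inverse of each cycle's dilution gives the default
start abundance when starts are unmeasured.

## Synthetic data: what it emulates and what it does not

Every input the pipeline consumes can be generated with known ground
truth, so each stage is testable against its planted answer:

* **Gene content** evolves per accessory family as a two-state
  (present/absent) continuous-time chain along the genome tree, simulated
  event-by-event so the truth includes realized event counts.
* **Codon alignments** evolve along the tree under the exact generators of
  the inference models (M1a, M2a, branch-site A), per-site classes drawn
  from the class proportions; stop codons cannot arise because the state
  space is the 61 sense codons.
* **Proteomes** assemble core families (aligned codon sequences split into
  per-genome CDS, translated to proteins) plus accessory families that
  follow the simulated presence/absence history.
* **Competition series** grow the reference strain by a fixed factor per
  cycle and the focal strain by that factor raised to w_true, dilute by
  the inoculum fraction between cycles, apply multiplicative lognormal
  measurement noise, and censor below the detection limit.

The default fixture (`mini_study_config()`) is a desk-scale analogue of a
16-genome within-species study: 6 genomes on a fixed tree of roughly 0.1
expected substitutions per codon root-to-tip (within-species divergence),
with an explicit 3-tip foreground clade (G4, G5, G6); 200 core and 300
accessory families of 150 codons; 3 core genes planted under branch-site
selection (ω₂ = 10 on 15% of sites, the foreground clade as foreground);
gene gain/loss at 2 events per unit branch length (accessory turnover is
much faster than per-site substitution, which is what makes gene content
informative); and a two-replicate, ten-cycle competition at w_true = 1.4
with 5% lognormal noise and a 5% inoculum. The defaults adopt the
conventional values of such study designs (70% clustering thresholds,
MCL inflation 2, a detection limit of 10² copies/g, ten back-slopped
cycles, duplicate experiments); the remaining values are one-time
choices of realistic magnitudes. Two fixture values
deserve a note: the planted selection is deliberately strong (ω₂ = 10 on
15% of sites) because on a shallow within-species clade most selected
sites see at most one substitution, which a branch-site null absorbs into
its neutral class — weak planted selection would be statistically
unidentifiable and the fixture exists to be recovered; and the foreground
clade is given a relatively deep subtree, mirroring the deep divergence
of a host-adapted focal lineage.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: indels inside codon alignments (real
alignments need the aligner; simulated ones are gap-free), genome
architecture (synteny, operons, mobile elements), recombination and
horizontal transfer *within* core genes, sequencing and annotation error,
and among-gene rate variation beyond the planted regimes.

## Pipeline and reproducibility

`run_pipeline()` chains the stages (simulate → cluster → partition →
gene-content tree → core tree → selection scan → enrichment → fitness),
writing one plain-text artifact per stage (TSV and Newick only) so
everything is diffable; a stage whose output file exists is skipped, which
makes interrupted runs resumable; rerunning with the same seed into a
fresh directory reproduces every artifact byte for byte. All randomness
derives from the single config seed through fixed per-stage offsets, so
component streams stay decoupled. The per-gene scan inside the pipeline
uses one optimizer start (the multi-start default matters for borderline
single-gene inference, not for rank-based scan summaries) and reuses the
core-genome tree with a per-gene M0 rescaling.

The validation studies run at fixed sizes chosen to exercise the
asymptotics that matter while staying desk-scale: null calibration on 100
alignments of 100 codons over 5 taxa; power and ω recovery on 20
alignments of 300 codons over 8 taxa; UPGMA against a naive oracle on 100
random 6×6 matrices; gene-content recovery over 50 replicates of 400
families on a fixed 8-leaf tree; and one full mini-study pipeline run.

## Known limitations

* No Bayes-Empirical-Bayes identification of the selected *sites*; the
  unit of inference is the gene.
* Codon models share one κ and one frequency vector across site classes,
  and the scan fixes κ at the M0 estimate (configurable).
* The core-genome topology comes from NJ, not from a likelihood search;
  for deeply divergent or heavily recombining data that shortcut can
  matter.
* Pruning does not rescale partial likelihoods per node, which is safe for
  tens of taxa at within-species divergence but would underflow on very
  large or very divergent trees.
* The progressive aligner is intentionally simple (no iterative
  refinement); badly misaligned regions are expected to be caught by the
  gap/divergence column filter.
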
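---
title: "Models and methods for bacterial tRNA repertoire dynamics"
author: "trnadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for bacterial tRNA repertoire dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnadyn)
```

This vignette documents the models behind `trnadyn`, the choices made
where the design was genuinely open, and what the synthetic-data
generator does and does not emulate.

## The decoding model: mandatory and auxiliary tRNAs

Each tRNA species is identified by its anticodon (positions 34–36,
written 5′→3′; position 34 pairs the third codon position). The wobble
rules used throughout are: G34 reads C (Watson–Crick) and U (G:U
wobble); U34 reads A (Watson–Crick), G (modification-dependent wobble)
and, by superwobbling, U and C — but only inside 4-fold family boxes,
where all four codons are synonymous and the broad specificity is
harmless; C34 reads only G; A34, deaminated to inosine, reads U, C and
A. The A34→U edge keeps its Watson–Crick label (the genomically encoded
base pairs U); codons that a rule would reach but that code for a
different amino acid are excluded, which removes the Met codon from the
range of the unmodified Ile U34A35U36 (its lysidine-modified form is
outside the package's scope).

Given the near-universal avoidance of A34 species in bacteria, the
species required to cover all sense codons are: every U34 species (A-
and G-ending codons), G34 species in 2- and 3-fold boxes (pyrimidine-
ending codons that no family-box U34 can cover), and the sole decoders
of Met (C34A35U36) and Trp (C34C35A36). The remaining C34 species and
family-box G34 species are auxiliary, U34A35U36 is special, and A34
species are avoided. Two decisions deserve note:

* **A34C35G36 (Arg) is classified mandatory.** It is the one inosine
  species in regular use; as I34 it reads CGU/CGC/CGA and most bacteria
  rely on it. The literal auxiliary/avoided rule lists would leave it
  unclassified, and calling it avoided would contradict its observed
  ubiquity.
* **The Arg box species G/U/C34C35G36 are flagged** (`argBox`): their
  status is context-dependent — I34 cannot read CGG, so U34C35G36 and
  C34C35G36 are mandatory as a pair but auxiliary individually.

The classification is a partition of all 61 species (23 mandatory, 22
auxiliary, 15 avoided, 1 special).

## Codon-bias statistics

`enc()` is Wright's index, ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, with
per-family homozygosity F = (nΣp̂ᵢ² − 1)/(n − 1). Families with fewer
than two codon observations are dropped from their class mean; a class
left empty is estimated as the average of the observed class means.
Genes with fewer than 100 usable codons trigger a warning; the value is
clamped at 61.

`encPrime()` replaces F with the χ²-based homozygosity
F = (X² + n − m)/(m(n − 1)), X² = nΣ(p̂ᵢ − eᵢ)²/eᵢ, where the expected
within-family frequencies eᵢ come from the gene's own background
nucleotide composition at the third codon position. The 6-fold families
(Leu, Ser, Arg) are split into their 2-fold + 4-fold subfamilies so that
every family varies only at position 3; the layout then has 12 two-fold,
one three-fold and 8 four-fold families and
ENC′ = 2 + 12/F̄₂ + 1/F̄₃ + 8/F̄₄, preserving the maximum of 61. ENC′ is
*not* clamped: sampling noise can push it slightly above 61 (about
+0.2 at 10⁴ codons), and clamping would hide exactly the calibration
the statistic is designed to show. The background is measured over all
gene positions; using gene-level (not genome-level) composition
throughout is a documented choice.

`encDiff()` is (mean ENC′ of all genes − mean ENC′ of ribosomal
genes) / mean ENC′ of all genes: stronger translational selection means
more biased ribosomal genes, hence larger positive values.

Percentiles use the nearest-rank convention (the ⌈pn⌉-th order
statistic); the usage shift of a species is the mean of the absent
group's 75th and the present group's 25th GC percentile, reported only
when a two-sided Mann–Whitney test (exact when the smaller group has
≤ 8 organisms, tie-corrected normal approximation otherwise) is
significant. Hamming clustering of presence profiles uses average
linkage, the least shape-biased default for binary profiles; the
distance itself fixes no particular linkage.

## Phylogenetic regression with Pagel's λ

Each species' binary presence profile is regressed on z-normalized
traits (sample mean 0, n−1 standard deviation 1) under
y ~ N(Xβ, σ²V(λ)), where V is the shared-path-length matrix of the
species tree and V(λ) multiplies its off-diagonal entries by λ ∈ [0, 1].
The binary response is treated as Gaussian — the same simplification
the established comparative-methods tools make for binary dependent
traits — so coefficients are interpretable as effect sizes but the
residual distribution is approximate. β and σ² have GLS closed forms at
fixed λ; λ is profiled by bounded scalar search with multi-start at
{0, 0.5, 1} (the profile can be bimodal near the boundary). R² is the
squared Pearson correlation between GLS-fitted and observed responses.
Nested models are compared with 2ΔlnL against χ²₁, and all p-values of
a screen are pooled into one Benjamini–Hochberg correction; a trait is
called significant and independent for a species only when adding it to
the regression on *each* other single trait survives the correction.
Species with three or fewer discordant organisms are skipped. Standard
errors use the n−p residual normalizer, which gives close-to-nominal
95% interval coverage in the 300-tip recovery simulations.

`traitCorrelation()` fits a bivariate Brownian model with one shared λ,
profiling the 2×2 scale matrix in closed form; R is the GLS correlation
and the p-value is an LRT against the diagonal-scale model.

## Gain/loss model and event calling

Each species evolves as a two-state (absent/present) continuous-time
Markov chain with gain rate g and loss rate l per unit branch length:
P₀₁(t) = g/(g+l)(1 − e^{−(g+l)t}). Likelihoods use Felsenstein pruning;
the root prior defaults to the stationary distribution of the species'
rates. Rates are fitted per species by bounded 2-D ML on log rates
(L-BFGS-B in [10⁻⁶, 10³]); constant columns are unidentifiable and
skipped. Optional rate variation uses K = 4 discrete-gamma multipliers
applied per branch, independently across branches — this integrates out
exactly to branch-averaged transition probabilities, and a shared shape
can be estimated jointly across species (`gammaShape = "joint"`), kept
only when it improves the pooled likelihood.

Ancestral posteriors come from the standard inside–outside pass.
Stochastic mapping samples joint node states from their conditional
distribution and then, per branch, the number and order of state
changes by uniformization at rate Λ = g + l; with this Λ the
virtual-jump chain is rank-one (each jump lands in state 1 with
probability g/(g+l) independently), so conditioning on the endpoints
only truncates the jump count, and sampling is exact. Per-branch gain
and loss probabilities are the fractions of maps containing ≥ 1 event
of the type (the expectation variant is a documented alternative, not
implemented as the default semantics). Events are called at probability
≥ 0.8 — inclusive, so 0.80 is called and 0.79 is not — and attributed
to the branch's child node.

## Co-gain/co-loss nulls

The permutation null reassigns each species' called gain (loss) events
to branches uniformly at random without replacement, preserving
per-species counts; gains and losses are permuted independently, and a
branch-length-weighted variant is available (the scheme used is
recorded in every result). The pair statistic is the number of branches
carrying called events of both species; p = (1 + #{null ≥ obs})/(1 + N),
so "never reached in 10⁴ permutations" reports p < 10⁻⁴. Because the
statistic is discrete, this conservative estimator cannot be exactly
uniform under the null; calibration tests therefore check the
randomized p-value built from the returned tail counts
(`nGreater`, `nEqual`), which is exactly U(0, 1) when the null is
correct, while the reported p-value stays conservative.

## Origins of gained tRNA genes

A most recent gain event (MRGE) is a called gain with no further gain
of the same species below it. Genes descending from an MRGE are aligned
(Smith–Waterman, both strands) against the complete gene database under
match +1, mismatch −3, gap open −5, gap extend −2 — chosen so that at
typical tRNA length (~76 nt) the 80%-of-self-score cutoff tolerates 3
mismatches (score 64 ≥ 60.8) but not 4 (60 < 60.8), or one short gap.
The threshold applies to raw scores and is inclusive. Hits are vertical
when query and subject share the anticodon and the same MRGE descent
(genes with no called gain above them descend from the per-species root
stock); otherwise the best non-vertical hit is classified:
same anticodon → HGT of the species; different anticodon in the same
organism → duplication + anticodon mutation; different anticodon in a
distant organism → HGT + mutation; otherwise → ortholog mutation.
"Distant" means patristic distance at or above the 90th percentile of
all pairwise tip distances — inclusive, because on balanced ultrametric
trees half of all pairs sit exactly at the maximal (root-spanning)
distance and a strict inequality would classify nothing as distant.

## The synthetic-data generator

The generator writes every input the pipeline reads, under one master
seed that fans out to fixed per-component offsets (tree +1, GC +2,
sizes +3, ENC′_diff +4, presence +10+i, genes +500, operons +600), so
identical configurations reproduce byte-identical fixtures.

The reference conditions (defaults of `simulationConfig()`):

* **Tree**: Yule, 300 tips, branch lengths scaled to unit root-to-tip
  depth.
* **GC**: an Ornstein–Uhlenbeck trait with optimum 0.5, stationary
  standard deviation 0.12 and reversion θ = 1.5. GC is a bounded trait
  (real bacterial genomes stay within roughly 25–75% GC at any
  divergence), and an unbounded Brownian walk lets entire trees drift
  to one side, collapsing presence variation; the OU keeps the
  cross-sectional spread stationary while leaving strong clade-level
  signal. A Brownian generator with the λ transform
  (`simulateContinuousTrait()`) is also provided.
* **Presence**: two-state chains simulated by exponential waiting
  times. Uncoupled species use gain 0.06 / loss 0.12 per unit depth
  (loss-dominant, as observed for auxiliary tRNAs); the four coupled
  species multiply baseline rates 0.01/0.02 by exp(±60 (GC − 0.5)),
  with opposite signs for gain and loss, using the branch's own GC
  (mean of the endpoint values). Both rates are coupled because
  selection that recruits a species at high GC also removes it at low
  GC; this produces the sharp GC usage shifts seen in real repertoires.
  A saturating logistic link with a quiet band around the threshold is
  available (`link = "logistic"`). All species start present at the
  root, matching the reconstructed GC-rich bacterial ancestor. Every
  realized event is recorded with its branch.
* **tRNA genes**: one 76-nt reference per species with the anticodon at
  positions 35–37; inheritance with Poisson substitutions at 0.15 per
  site per unit depth outside the anticodon, so distant lineages
  diverge to roughly 70–85% identity, the conservation range reported
  for bacterial tRNA genes. Organic gains draw a diverged copy from an
  unsampled donor pool. Twelve origin events are injected at tip level
  (4 same-anticodon HGT, 3 HGT + mutation, 2 ortholog mutations,
  3 duplications) by copying the template tip sequence with a fixed
  2-substitution load plus at most one anticodon position; injection
  sites are accepted only when every nearest neighbour of the new gene
  still supports the intended scenario, so the ground-truth labels are
  self-consistent.
* **Coding genes**: codons drawn from the product distribution of a
  base composition matching the GC target; ribosomal genes concentrate
  usage on the preferred codon of each family by a factor of 5, giving
  positive ENC′_diff.
* **Operons**: designated pairs co-placed in one operon per organism
  carrying both; other genes in singleton operons; 20% of genes left
  unannotated.

What the generator does **not** emulate: realistic sequence evolution
(no indels, no rate heterogeneity among sites, anticodon positions
frozen), gene copy-number variation (one gene per species per genome),
operon order/strand structure, and any feedback from codon usage to
tRNA content. Passing the recovery tests therefore shows that the
statistical machinery is correct under its stated assumptions, not that
those assumptions hold for any particular real dataset.

## Known limitations and an honest tension

The end-to-end recovery targets pull in opposite directions through the
GC process. Detecting a GC association after controlling for a strong
phylogenetic signal needs the presence state to track GC nearly
instantaneously (the test's power lives in shallow sister contrasts);
but an instantaneous response synchronizes the coupled species'
gain/loss events at the boundaries of GC zones, and parallel events on
sibling branches are not identifiable from presence data — an
all-absent clade is explained equally well by one stem loss, so no
calling threshold can recover them. Across the configurations explored,
regimes in which all four coupled species are reliably detected give
branch-exact event recall around 0.4–0.65 for the fixture as a whole
(higher for uncoupled species, lower for coupled ones), while regimes
with recall at or above 0.7 lose most of the association detections.
The defaults favour the association side; the event-calling recall on
the default fixture should be read with this in mind. Reconstruction
quality itself is verified independently against exhaustive-enumeration
oracles and homogeneous-rate recovery simulations, where it meets its
targets.

Problem sizes used by the test suite (300-tip screens and
reconstructions, 500-tip rate recovery, 10⁴-codon genes, 10⁴
permutations where exactness is asserted, 10³ stochastic maps) were
chosen so the full suite and the acceptance script complete comfortably
on a single CPU.
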
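# trnadyn

Bacteria decode all 61 sense codons with a subset of the possible tRNA
species. Because of wobble pairing at the anticodon's 34 position — G34
reads C- and U-ending codons, U34 reads A- and (with modification)
G-ending codons, inosine-modified A34 reads U/C/A — some species are
**mandatory** (without them a codon would be unreadable, given that A34
species are almost universally avoided) while the rest are **auxiliary**:
variably present, frequently gained and lost across lineages, and
correlated with genomic traits such as GC content.

`trnadyn` implements a comparative pipeline for analysing this
repertoire variation:

* **Repertoire** — parse tRNA gene tables (tRNAscan-SE tabular output or
  a simple TSV), classify the 61 anticodon species as
  mandatory / auxiliary / avoided / special under the wobble rules,
  check decoding completeness, and build the binary organisms × species
  `PresenceMatrix`.
* **Codon metrics** — GC content, Wright's effective number of codons
  ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, and the background-corrected
  ENC′ whose family homozygosity F = (X² + n − m)/(m(n − 1)) measures the
  χ² deviation of codon usage from the gene's own nucleotide
  composition (ENC′ = 61 when usage matches composition); the
  organism-level translational-selection proxy
  ENC′_diff = (mean ENC′ of all genes − mean ENC′ of ribosomal genes) /
  mean ENC′; usage-shift and variability statistics; Hamming clustering
  of presence profiles.
* **Phylogenetic regression** — ML regression of each species' binary
  presence profile on z-normalized genomic traits under a
  multivariate-normal model with Pagel's λ scaling the off-diagonal
  phylogenetic covariances, nested likelihood-ratio tests
  (2ΔlnL ~ χ²₁), a pooled Benjamini–Hochberg correction, and
  phylogenetic trait–trait correlations.
* **Gain/loss reconstruction** — per-species two-state
  continuous-time Markov models (optionally with discrete-gamma
  branch-rate multipliers), Felsenstein-pruning likelihoods, marginal
  ancestral posteriors, stochastic mapping by uniformization, calling of
  branch events at P ≥ 0.8, and genome-wide gain/loss rate sums.
* **Co-dynamics** — permutation tests for co-gain/co-loss of species
  pairs against a null that reassigns each species' events to random
  branches, multi-event node histograms, and sequential gain-order
  counts.
* **Origins** — most recent gain events (MRGEs), local alignment of
  descendant genes against the full gene database (match +1, mismatch
  −3, gap open −5, extend −2), the 80%-of-self-score rule, and
  classification of best hits into vertical inheritance, HGT of the same
  species, HGT + anticodon mutation, ortholog mutation, or
  duplication + mutation.
* **Operons** — co-gain/co-loss operon co-occurrence counts and operon
  coverage statistics.
* **Synthetic data** — a fully seeded generator for every input: Yule
  trees, OU-distributed GC, GC-coupled presence columns with true event
  lists, tRNA gene sequences with injected origin scenarios (ground
  truth written), coding genes with a codon-bias-enriched ribosomal
  subset, and operon maps.

## Worked example

```r
library(trnadyn)

## a complete synthetic study: 300 genomes, 12 tRNA species, 4 of them
## GC-coupled
fx  <- simulateFixture(simulationConfig(masterSeed = 1))
fx$presence
#> PresenceMatrix: 300 organisms x 12 tRNA species
#>   species: ACG CAC CCC CCG CGA CGG CGU CUC ...
#>   occupancy: 0.891

## which species track GC after phylogenetic control?
scr <- associationScreen(fx$presence, fx$traits, fx$tree, q = 0.05)
subset(scr$calls, called & trait == "gc.z")[, c("species", "beta",
                                                "lambda", "r.squared")]
#>    species       beta    lambda r.squared
#> 8      CCC 0.15489780 0.8742801 0.3503960
#> 23     CUC 0.12771874 0.8939446 0.3540996
#> 26     CUG 0.09784696 1.0000000 0.3311175
#> 29     GCC 0.11081791 0.9490492 0.3652275
```

The four called species are exactly the four the generator coupled to
GC: their presence rises with GC (positive `beta`, in standard-deviation
units of the z-normalized trait), the phylogenetic signal is strong
(λ ≈ 0.9–1), and GC explains 33–37% of the usage variability (R²).

```r
## reconstruct gain/loss histories and call events
rec <- reconstructAll(fx$tree, fx$presence, nMaps = 1000, seed = 7)
head(totalRates(rec), 3)
#>   species gainSum lossSum
#> 1     ACG   2.896   3.943
#> 2     CAC  13.075  13.607
#> 3     CCC  12.689  16.909
ev <- callEvents(rec, threshold = 0.8)

## are the GC-coupled Glu- and Gln-reading species lost together?
p <- pairCoeventTest(ev, fx$tree, c("CUC", "CUG"), "loss",
                     nPerm = 10000, seed = 17)
c(observed = p$observed, nullMean = p$nullMean, p = p$p)
#>  observed  nullMean         p
#> 4.000e+00 5.500e-02 9.999e-05
```

Loss sums exceeding gain sums reproduce the loss-dominant dynamics of
auxiliary tRNAs. The two GC-coupled species share called loss events on
4 branches, an overlap the randomized null (which preserves each
species' event count) never reached in 10⁴ permutations; the add-one
estimator (1 + #{null ≥ observed}) / (1 + N) therefore reports
p < 10⁻⁴.

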
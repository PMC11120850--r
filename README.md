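# DGGEtools

Analysis of denaturing gradient gel electrophoresis (DGGE) community
fingerprints in R, from the gel photograph to community-ecology
statistics, with a synthetic gel simulator that makes every stage
testable end to end.

DGGE separates same-length 16S rRNA amplicons by their melting behaviour
along a chemical denaturant gradient, yielding one band per dominant
sequence variant. It remains a workhorse for tracking microbial community
shifts in engineered ecosystems such as anaerobic digesters, where
replicate reactors are fingerprinted at successive incubation times and
the question is *how fast* and *in which direction* the community moves.
This package is aimed at microbial ecologists who have gel images (or
densitometric profiles) plus a lane layout, and want the standard
fingerprint statistics computed reproducibly rather than inside opaque
gel software.

## What it computes

* **Lane profiles** — lane detection from the column-intensity
  projection, densitometric curve extraction, 1-D morphological-opening
  background subtraction, and resampling to a common grid.
* **Band calling** — prominence-based peak detection, cross-lane band
  classes via single-linkage clustering of positions, binary and
  intensity (band-area) fingerprints.
* **Similarity** — Jaccard coefficient on band presence/absence,
  `S_J = 100·|A∩B|/|A∪B|`, and Pearson product-moment correlation of
  densitometric curves, `S_P = 100·max(0, r)`.
* **Clustering** — UPGMA dendrograms on the dissimilarity
  `d = 100 − S`, with Newick export and cophenetic similarities.
* **Ecology statistics** —
  range-weighted richness `Rr` = total band count per lane;
  community organization `Co = 100·G`, the Gini coefficient
  `G = Σᵢ (2i − n − 1) xᵢ / (n² μ)` of the sorted band intensities
  (with its Pareto–Lorenz curve);
  moving-window dynamics `% change = 100 − % similarity` between
  consecutive sampling days, and the rate of change `Δt` = mean of the
  per-interval mean percent changes.
* **Simulation** — ground-truth community trajectories over a species
  pool (each species a melting position plus a PCR amplification bias),
  rendered as Gaussian bands into 8/16-bit gel images with background
  gradient and noise. The default design emulates a 4-temperature
  (28/36/44/52 °C) × 3-reactor anaerobic-digestion experiment sampled at
  days 0, 7, 14, 30 and 60.

## Worked example

Simulate the default experiment, analyze its day-60 gel, and cluster the
lanes:

```r
library(DGGEtools)

pool   <- buildSpeciesPool(nSpecies = 40, seed = 1)
design <- experimentDesign()                 # 4 temps x 3 reactors x 5 days
traj   <- simulateTrajectories(design, shiftModel(), pool, seed = 1)

li  <- laneInfo(traj); ab <- abundanceMatrix(traj)
sel <- which(li$day == 60)
gel <- renderGel(ab[, sel], pool, gelRenderConfig(), seed = 1,
                 laneIds = li$lane[sel])
gel$image
#> GelImage: 400 x 440 px, 16 bit
#>   known lanes: 12

profiles <- processGel(gel$image, li[sel, ])
fp <- fingerprintGel(profiles)
fp
#> FingerprintSet: 12 lanes x 18 band classes; 88 called bands

richness(fp)
#> T28_R1_D60 T28_R2_D60 T28_R3_D60 T36_R1_D60 T36_R2_D60 T36_R3_D60 T44_R1_D60
#>          6          6          6          7          7          7          8
#> T44_R2_D60 T44_R3_D60 T52_R1_D60 T52_R2_D60 T52_R3_D60
#>          8          9          8          8          8

tree <- upgma(similarityMatrix(profiles, "pearson"))
round(copheneticSimilarity(tree, "T52_R1_D60", "T52_R2_D60"), 1)
#> [1] 97.3     # replicate reactors cluster tightly ...
round(copheneticSimilarity(tree, "T52_R1_D60", "T28_R1_D60"), 1)
#> [1] 12.4     # ... while thermophilic and mesophilic lanes diverge
```

Richness climbs toward nine called bands per lane by day 60, replicates
of one temperature join the dendrogram above 97% similarity, and lanes of
different temperature regimes share little — the qualitative behaviour
expected of diverging mesophilic vs thermophilic communities.

The whole chain (fixture + profiles + band tables + similarity matrices
+ Newick trees + indices + moving-window series, with a checksum
manifest) runs as one call:

```r
runPipeline(validateConfig(list(seed = 1)), "out/")
```

or from a shell via `inst/scripts/dgge-pipeline.R`
(`simulate` / `analyze` / `full` verbs).

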
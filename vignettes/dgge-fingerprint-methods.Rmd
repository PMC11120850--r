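---
title: "Methods: DGGE fingerprint analysis and the synthetic gel model"
author: "DGGEtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DGGE fingerprint analysis and the synthetic gel model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DGGEtools)
```

# Scope

DGGEtools turns denaturing gradient gel electrophoresis (DGGE) images of
microbial community fingerprints into the statistics this field reports:
densitometric lane profiles, called bands matched into cross-lane band
classes, Jaccard and Pearson similarity matrices, UPGMA dendrograms,
band-count richness, Gini-based community organization, and
moving-window percent-change dynamics. Because published DGGE studies
rarely deposit raw gel images, the package also ships a synthetic gel
generator whose ground truth makes every downstream stage testable; its
defaults emulate a 4-temperature (28/36/44/52&nbsp;°C) × 3-reactor
anaerobic-digestion design sampled at days 0, 7, 14, 30 and 60.

# The image-analysis chain

## Geometry conventions

The migration axis is the image row axis, row 1 at the well. The
normalized position of row $r$ in an image of height $H$ is
$p = (r-1)/(H-1) \in [0,1]$, so positions are comparable across images
of different resolution. A species' position on this axis encodes its
melting behaviour, not fragment size: DGGE separates same-length
fragments along a chemical denaturant gradient (here 40–60&nbsp;%
denaturant is metadata only; positions are already fractions).

## Lane detection and profile extraction

Lanes are the strongest peaks of the smoothed column-sum projection,
subject to a minimum spacing of half a nominal lane pitch (this spacing
guard matters on noiseless images, whose projections have flat-topped
plateaus that would otherwise double-count a lane). Span edges are
midpoints between adjacent centers. When fewer peaks than expected lanes
exist — a blank or heavily degraded image — the width is partitioned
uniformly and a warning is raised rather than failing the run. The
profile value at each row is the *mean* intensity across the span's
columns, which makes the curve invariant to lane width.

## Background subtraction

Per lane, the baseline is estimated by 1-D grayscale morphological
opening — a running minimum followed by a running maximum with a flat
structuring element of width $w = \mathrm{round}(f \cdot n)$, default
$f = 0.1$ of the profile length. An opening passes any feature wider
than $w$ and removes anything narrower, so with $w$ several times the
band width the baseline keeps staining/illumination trends while the
bands are preserved in the residual (floored at zero). A 2-D rolling
ball would model lateral background coupling too, but lane-wise analysis
never consumes inter-lane background, so the 1-D operator is simpler and
exactly testable against a brute-force oracle. The window must round to
at least 3 samples; narrower requests are errors, not silent clamps.

## Resampling and normalization

Profiles are linearly interpolated onto a uniform grid of 500 points
(configurable, minimum 32) and normalized by total area by default, so
that exposure differences between lanes do not dominate Pearson
similarities; max-normalization is available where peak-relative scaling
is wanted. All-zero profiles pass through with a warning since empty
lanes are legitimate (failed amplification) and downstream code decides
how to treat them.

## Band calling

Bands are local maxima with topographic prominence at least
`minProminence` (default 0.05) times the profile maximum — mirroring the
practice of profiling only bands of appreciable intensity — and pairwise
separation of at least `minSeparation` (default 0.01 of gel length);
within a conflict the taller peak wins. Each band's area is the
trapezoid integral between the minima separating it from its neighbours.
Area, not height, feeds the Gini statistic, because area is robust to
band-width variation between lanes. All three thresholds are plain
config values: gel software keeps its detection defaults proprietary, so
they must be visible and logged rather than hard-coded.

## Band classes

Positions of all called bands are pooled and clustered by single-linkage
chaining: sorted positions join one class while consecutive gaps stay
within `tolerance` (default 0.01 of gel length). Single linkage mirrors
how gel software aligns "the same band" across lanes, and is
deterministic and exactly checkable against an `hclust(..., "single")`
oracle. A consequence of chaining is that a class can span more than one
tolerance; membership tests therefore use the class *extent*, not its
center, and a band farther than one tolerance from every class extent is
an error (it signals classes built from a different band set). Within a
lane, two bands falling into one class have their areas summed.

# Similarity, clustering and dynamics

**Jaccard** operates on the binary band-class vectors,
$S_J = 100\,|A \cap B| / |A \cup B|$. Two empty fingerprints are defined
as 100&nbsp;% similar (identical, if empty) with a warning. **Pearson**
operates on the resampled densitometric curves with negative
correlations clipped to zero before conversion to percent, so that the
derived $\%\,\text{change} = 100 - \%\,\text{similarity}$ always lies in
$[0, 100]$; a constant profile has no defined correlation and raises an
error instead of propagating `NaN`.

**UPGMA** clusters in dissimilarity space $d = 100 - S$ with the classic
size-weighted update
$d_{(ij)k} = (n_i d_{ik} + n_j d_{jk})/(n_i + n_j)$, which keeps every
cluster-to-cluster distance equal to the mean pairwise leaf
dissimilarity — the property the test suite verifies against a naive
$O(n^3)$ re-averaging oracle. Exact ties break toward the smallest
(row, column) index pair, so trees are reproducible (and documented as
input-order dependent when exact ties exist). Newick export places each
node at depth height/2, the standard dendrogram convention, so tree-path
distance between leaves equals their merge dissimilarity.

**Moving-window analysis** compares consecutive sampling days of the
same reactor by Pearson similarity of the curves
($\%\,\text{change} = 100 - S_P$), then averages the three replicate
reactors per temperature and interval. Only consecutive pairs are used
(one value per timepoint); the first interval (day 0 to the first
sampled day) is computed but flagged, since presentations often start at
the second timepoint. The **rate of change** is the arithmetic mean of
the per-interval means — with equal replicate counts this equals the
pooled mean, which the tests assert.

**Richness** is the literal band count of a lane. The richness
literature also weights counts by the denaturant range covered; since
the analyzed gels share one gradient, the weighting would be a constant
factor, and the package implements the count definition.
**Community organization** is $100 \times$ the Gini coefficient of the
band areas, computed by the sorted-index formula
$G = \sum_i (2i - n - 1)x_i / (n^2\mu)$ and cross-checked against
trapezoidal integration of the Pareto–Lorenz curve. Zero intensities are
absences, not bands, and are rejected rather than treated as ties.

# The synthetic gel model

## What it emulates

The generator produces, per temperature, a shared community trajectory
over a pool of species (each species = a melting position unique at
profile resolution, drawn uniformly on [0.05, 0.95], plus a lognormal
PCR amplification factor, log-sd 0.25). The qualitative targets are the
patterns reported for anaerobic digestion fingerprints: a shared day-0
feedstock community with few bands near the top of the gel and one
clearly dominant member; band coverage growing with time; turnover
increasing with temperature; turnover peaking early under thermophilic
and later under mesophilic conditions; replicate reactors similar but
not identical.

## Turnover model

Between consecutive sampling days a fraction

$$f_k = 1 - (1 - \text{rate})^{w_k K}$$

of abundance mass moves to newly recruited species ($K$ = number of
intervals, $w_k \ge 0$, $\sum_k w_k = 1$). With uniform weights
$f_k = \text{rate}$ exactly, so the rate reads as "fraction of the
community replaced per sampling interval"; concentrated weights shift
turnover early or late while keeping $f_k < 1$. A plain product
$\text{rate} \times w_k$ was rejected because normalized weights would
cap per-interval replacement at $\text{rate} \times \max_k w_k$, making
realistically large between-day shifts unreachable.

The moved mass is taken half proportionally from all present species and
half from the most dominant ones by water-filling (the largest
abundances are lowered to a common cap). This blend was chosen after
examining the two extremes on rendered gels: pure proportional removal
never dethrones the initial dominant band, so all temperatures stay
highly correlated; pure dominant-first removal collapses the Pearson
similarity almost discontinuously in $f$, destroying the timing signal.
Recruits are drawn uniformly from currently absent species, with count
$\max(\text{richness shortfall}, \mathrm{round}(f \cdot R_{next}), 1)$,
and receive random (half-uniform, half-exponential) shares of $f$; if
afterwards more species than the target richness are detectable, the
weakest are zeroed. With turnover 0 a community is exactly constant.

Replicates share the temperature's trajectory and differ by one fixed
lognormal jitter factor per reactor (sd 0.15), so day-0 communities
agree across reactors up to jitter and replicate lanes stay more similar
to each other than to other temperatures.

## Defaults as study conditions

Turnover rates default to 0.25/0.40/0.55/0.70 for 28/36/44/52&nbsp;°C:
strictly increasing with temperature, spaced widely enough that the
nonlinear Pearson response preserves the ordering across simulation
seeds, and small enough at the top that thermophilic percent change does
not saturate at 100 (which would erase the peak-timing signal). Interval
weights are (0.15, 0.25, 0.40, 0.20) for mesophilic temperatures — peak
turnover on the day 14→30 interval — and (0.20, 0.45, 0.20, 0.15) for
thermophilic — peak on day 7→14. The richness trajectory defaults to
4/6/5/5/9 detectable species over days 0/7/14/30/60, anchored to
reported dominant-band counts for such experiments; day 0 uses the four
lowest melting positions of the pool so initial bands cluster near the
well. The detection limit defaults to 0.01 relative abundance, a classic
DGGE sensitivity bound, and is configurable because it is a convention,
not a measurement.

## Rendering

A species at or above the detection limit contributes a 2-D Gaussian
band (σ = 3 px along migration, 7 px lateral) at
(melting position × height, lane center), with peak amplitude
abundance × amplification × 30000 on the 16-bit scale. Background is a
vertical ramp (1000 + 500·p) plus i.i.d. Gaussian noise (sd 15);
intensities clip to the bit depth with a warning, never wrap. The
renderer writes a ground-truth band table, and fixtures regenerate
byte-identically from one seed: every stochastic stage draws from a seed
derived from (global seed, stage name), so stages can be re-run
independently.

## What the simulator does not model

No PCR chimeras or heteroduplexes, no co-migration of distinct sequences
beyond what random positions produce, no gel "smile" or lane warping, no
cross-gel normalization ladders, and no denaturant chemistry (gradient
bounds are metadata). Passing tests therefore demonstrate correctness of
the *analysis machinery* under controlled imaging physics — recovery of
known bands, similarity/cluster/dynamics arithmetic, determinism — not
robustness to distorted real-world gels, which would need marker-based
warping out of scope here.

# Numerical and testing choices

Profile resolution 500 and image height 400 px keep band positions
quantized well below the 1&nbsp;% matching tolerance. Tests assert exact
identities where the math is exact (Jaccard set arithmetic, Gini vs
Lorenz integration, opening vs brute force, UPGMA vs re-averaging oracle
to 1e-9) and use the generator's ground truth elsewhere: band recovery
demands 100&nbsp;% recall/precision with position error below 0.5&nbsp;%
of gel length on gels whose bands are separated by ≥ 3σ at
signal-to-noise ≥ 10 (20 seeds); turnover-ordering recovery requires a
perfect Spearman rank correlation between temperature and rate of change
in at least 18 of 20 simulated experiments, with the seed-averaged
thermophilic percent-change curve peaking at day 14; replicate lanes
must be copheneticly closer to each other than to other-temperature
lanes in at least 90&nbsp;% of day-14 dendrogram triples. End-to-end
determinism is asserted as byte-identical output checksums for repeated
runs of one (config, seed). Full-design simulations in the suite use the
default 60-lane experiment; per-operation tests use small constructed
profiles where the expected values are computable by hand.

# Known limitations

Band calling under default thresholds reports *dominant* bands; faint
bands below 5&nbsp;% relative prominence or co-migrating within the
matching tolerance merge or vanish, so called richness can undershoot
the simulator's detectable-species count — visible in the default run as
day-60 richness slightly below the ground-truth nine. The Pearson
percent change saturates once communities share essentially nothing,
which compresses contrasts between very high turnover regimes. Cophenetic
tie-breaking, and therefore exact tree shape, depends on lane order when
similarities tie exactly. Real-gel lane curvature and cross-gel
comparability are declared out of scope rather than half-modelled.
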
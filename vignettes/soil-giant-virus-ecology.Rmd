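---
title: "Methods: marker-gene ecology of soil giant-virus communities"
author: "soilgv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-gene ecology of soil giant-virus communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilgv)
```

## The problem

Nucleocytoplasmic large DNA viruses (NCLDVs, "giant viruses") infect a
wide range of soil eukaryotes, but their soil ecology is hard to study
directly: they leave no universal ribosomal marker, so surveys recruit
the family B DNA polymerase gene (*polB*) from shotgun metagenomes,
dereplicate the recovered sequences into phylotypes, and treat the
phylotype-by-sample coverage table as a community matrix. `soilgv`
implements the downstream computational workflow for such a survey over
five terrestrial habitat types (farmland, forest, grassland, Gobi
desert, mine wasteland): placement-based identification and taxonomy,
coverage normalization, occupancy and niche-breadth analysis,
permutation-based community statistics, virus–eukaryote co-occurrence
networks, and screening of assembled contigs for putative giant-virus
origin. Upstream steps (read QC, assembly, gene prediction, HMM search,
alignment, tree inference, read mapping, amplicon denoising) are out of
scope; the package consumes their standard outputs (TSV tables, jplace
files, newick trees).

## Dereplication into phylotypes

Marker sequences are clustered greedily in decreasing length order
(CD-HIT style): a sequence joins the first representative it matches
with identity above 0.95 **and** coverage of the shorter sequence above
0.90, else it founds a new cluster. Identity is computed from an
ends-free pairwise alignment (match +1, mismatch −1, gap −2) as matches
over aligned overlap columns, excluding terminal overhangs — the same
short-sequence semantics CD-HIT applies. Ties between equal-length
sequences are broken lexicographically by id so that clustering is
deterministic; permuting equal-length inputs never changes the number
of clusters.

## Identification and taxonomy from placements

Queries are placed on a fixed reference tree (502 NCLDV PolB references
plus eukaryote/bacteria/archaea/phage outgroups in the original survey
design); `soilgv` consumes the jplace output and a clade map assigning
every reference leaf to exactly one top-level clade. Only the best
placement (highest likelihood weight ratio) is used — the simplest
faithful reading of "placed within a clade"; multi-placement averaging
is deliberately not attempted. The decision rules:

* edge whose subtree lies inside a family clade with cultivated
  representatives → that family;
* edge inside one order but spanning several of its families, or inside
  a family without cultivated representatives → that order, family
  *unassigned*. "Basal" is operationalised as the stem/ancestral edges
  whose subtree spans more than one family clade; the convention is
  ours, since no operational definition accompanies the original rule;
* edge inside an outgroup clade, or above the NCLDV/outgroup split →
  *non-NCLDV*;
* order Pandoravirales → excluded (reason `pandoravirales-removed`);
  the group's long branches and weak support make placements there
  unreliable;
* best weight below `support_min` (default 0.5) → excluded
  (`low-support`). Placement weights, not bootstrap values, accompany
  jplace output, so the original tree-level bootstrap filter is
  mirrored by this weight threshold plus the option of masking
  low-confidence clades in the clade map.

Soundness is checked the way the original pipeline was benchmarked:
decoy queries whose placements all fall in outgroup clades must yield a
false-positive rate of exactly zero.

## Normalization and presence

Raw coverage is divided by the sample's read count and multiplied by
the mean read count over samples; a proportional (percent) table
divides each sample by its total. A phylotype is "detected" in a sample
iff its normalized coverage is strictly positive. No abundance floor is
stated for the original workflow, so > 0 is the minimal-assumption
default and the threshold is a configuration knob (`presence_min`).

## Environmental range (niche breadth)

Each of the 14 environmental variables (LON, LAT, ALT, MAP, pH, EC,
EX-Ca, CaCO3, CEC, clay, TP, TK, TN, TC) is min–max standardized to
[0, 1] across samples; the per-sample mean of the standardized
variables is the SEV. A phylotype's raw range is max SEV − min SEV over
its occupied samples, then min–max standardized across phylotypes.
Choices worth noting:

* constant variables are dropped (their standardization is 0/0; any
  imputed constant would shift every SEV arbitrarily);
* missing values are excluded from a variable's min/max and from the
  SEV average, avoiding imputation;
* the final standardization is min–max **across phylotypes**; the
  original description ("standardized from zero to one") is ambiguous
  between this and division by the global SEV span, and the choice is
  recorded here rather than asserted;
* "average abundance" is total normalized coverage divided by the
  number of *occupied* samples. Dividing by all samples would build the
  negative abundance–occupancy correlation in by construction;
* correlations involving `log(std_range)` offset exact zeros by one
  tenth of the smallest positive range, recorded in the output.

The tradeoff estimator `occupancy_tradeoff_slope()` regresses the mean
of log abundances (log geometric mean) on log occupancy: under the
log-normal abundance law the geometric mean estimates the location
parameter without an occupancy-dependent offset, whereas the log of an
arithmetic mean is shifted by up to sigma^2/2 as occupancy grows, which
would bias the slope toward zero.

## Community statistics

Alpha diversity is richness (detections per sample) and Shannon H on
relative abundances; habitat differences use the tie-corrected
Kruskal–Wallis test. Beta diversity uses Bray–Curtis dissimilarity;
PERMANOVA (999 permutations by default) uses Anderson's pseudo-F via
the Gower-centred matrix, with the exact permutation convention
p = (1 + #{F\* ≥ F}) / (1 + n_perm) — the observed statistic is always
included, so p ≥ 1/(n_perm + 1). Mantel and partial Mantel tests use
the same convention; the partial test permutes the first matrix only (a
simple Mantel permutation of the residual association — permutation
schemes for partial Mantel differ subtly between implementations, and
this one is documented rather than claimed universal). Geographic
distances are haversine on WGS84 decimal degrees with Earth radius
6371.0088 km; distance–decay fits community dissimilarity against
log10(km + 1) by least squares but takes its significance from a
Mantel permutation, because sample pairs are not independent
observations.

Variation partitioning decomposes the adjusted redundancy-analysis
R-squared of the (by default Hellinger-transformed) community matrix
over four predictor blocks — climatic (MAP), geographical (LON, LAT,
ALT), physicochemical (the ten edaphic variables) and eukaryotic
community composition — over all 15 block subsets. The Hellinger
transform is the standard abundance-data choice for RDA and is recorded
in the output; the physicochemical and eukaryotic blocks are first
reduced by PCA to the components retaining at least 80% of their
variance (the reduction is configurable; only "PCA was used" is given
in the original description). Adjusted fractions may be slightly
negative for noise blocks; raw values are stored, any truncation is
display-only.

## Co-occurrence networks

Within each habitat, phylotypes and eukaryotic ASVs present in at least
`ceiling(0.10 × n_samples)` samples are retained; every virus × ASV
pair gets a Spearman correlation (average ranks for ties), a two-sided
p from the t approximation (a permutation p is available for very small
n), and a Benjamini–Hochberg adjustment across all tested pairs within
the habitat — the habitat is the natural adjustment unit because
networks are built per habitat. An edge is kept when ρ ≥ 0.60 **and**
adjusted p < 0.05. Edges are positive-only by design (the threshold is
written ρ ≥ 0.60, and edges are read as putative virus–host pairings);
an absolute-value mode is a one-line change at the call site. Retention
is monotone: raising either threshold never adds edges.

## Contig screening

Contigs longer than 5 kb (strictly; the boundary is configurable) are
accepted as putative NCLDV contigs when flagged by the automatic
classifier, carrying at least 2 of the 20 ancestral NCVOG markers, or
carrying the NCLDV *polB* gene (NCVOG0038). The audit records which
criteria fired; criteria may co-fire, so per-criterion tallies sum to
at least the accepted count.

## The synthetic-data generator

The deposited metagenomes are not needed to test any of the above: the
generator produces every input with recorded ground truth.

* **Survey design.** Sites follow the original sampling layout — 29
  farmland, 27 forest, 9 grassland, 4 Gobi desert and 42 mine
  wasteland sites, 3 samples each (333 samples) — with coordinates
  drawn over the surveyed longitude/latitude window. Defaults are the
  study conditions; smaller designs are used in tests only to keep
  them fast, and the sizes are stated in the test code.
* **Abundance law.** Occupancy is decided first (specialists occupy
  their home habitat with probability `p_in` = 0.35 and foreign samples
  with `p_out` = 0.01; generalists occupy any sample with
  `p_generalist` = 0.15); abundances in occupied samples are log-normal
  (sdlog 1). Coverage data are strictly positive and right-skewed, and
  zeros arise from occupancy, not from the abundance law. The mean log
  abundance is `mu0 + tau * log(occupied samples)`, so `tau < 0` plants
  the abundance–occupancy tradeoff; `tau` is a free knob, not an
  estimate of the surveyed communities' value, which the original
  analysis reports only as a sign.
* **Specialist fraction** defaults to 0.7, matching the predominance of
  single-habitat phylotypes the survey reports; specialists are
  assigned home habitats proportionally to habitat size, which
  concentrates unique phylotypes in the largest habitat (mine
  wasteland) as observed.
* **Environment.** The 14 variables are habitat-shifted Gaussians with
  field-plausible centres (e.g. acidic mine wasteland, alkaline Gobi);
  TN tracks TC and CEC tracks clay so that two collinear pairs
  (Spearman ρ² > 0.7) always exercise the redundancy filter — both
  pairs are strongly coupled in real soils. Read counts are log-uniform
  between 2×10⁷ and 2×10⁸.
* **Virus–host couplings.** Planted host ASVs are Gaussian-copula
  transforms of their virus's abundance ranks, with the copula
  correlation set to `2 sin(πρ_s/6)` so the *population* Spearman
  correlation equals the requested `rho_target`; other ASVs are
  independent log-normal counts.
* **Placements and contigs** are drawn from labeled edge pools of a
  synthetic reference topology (orders/families/outgroups as above) and
  from Bernoulli/binomial marker-emission models, so classifier
  recall, decoy soundness and screening can be scored against truth.
* One global RNG stream per simulation; identical (parameters, seed)
  give identical outputs.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: compositional coupling between phylotypes
(rows are independent given occupancy), sequencing/mapping noise in
coverage values, spatial autocorrelation of communities beyond the
habitat structure, phylogenetic correlation of niches, and the
assembly artefacts that real contig tables inherit. Tests against the
generator validate the *computations*; they cannot validate the
biological assumptions of the survey design.

## Numerical conventions and degenerate inputs

* Empty samples: richness 0, Shannon undefined (NA, flagged); a pair of
  empty samples has Bray–Curtis 0 with an `empty_pairs` flag.
* Constant vectors in correlations are reported as undefined (NA with a
  note), never as 0.
* All permutation tests take explicit seeds and record them, and their
  p-values can never drop below 1/(n_perm + 1).
* Exhaustive modes (PERMANOVA enumeration, exact rarefaction) are
  limited to small n and are cross-checked against full enumeration in
  the test suite; the random rarefaction method converges to the exact
  mean.
* Problem sizes used by the test and acceptance suites: oracle
  equivalence on ≥ 50 random fixtures per statistic (n ≤ 6 samples for
  exhaustive checks), calibration over 1000 null simulations at n =
  12–15 samples, recovery over 10–20 seeds at 100–300 phylotypes and
  60–150 samples. These sizes were chosen to make sampling error small
  relative to the tested tolerances while keeping the suites quick to
  run.

## Known limitations

* The greedy clustering identity is computed by ends-free alignment
  with a fixed scoring scheme; CD-HIT's banded heuristics can differ on
  borderline pairs close to the thresholds.
* The partial Mantel permutation scheme and the PCA retention rule in
  variation partitioning are documented choices among several in use;
  results near significance boundaries can differ across conventions.
* The "basal" convention (any edge spanning multiple family clades of
  one order) may assign order-level calls where a different reading of
  basal (stem edges only) would not; both readings agree on every edge
  of the synthetic reference topology used in testing.
* Percentages are reported at two significant digits, the precision
  used in the survey's summaries.
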
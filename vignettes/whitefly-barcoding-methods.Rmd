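---
title: "Methods: mtCO1 barcode screening, species delimitation and host-association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtCO1 barcode screening, species delimitation and host-association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiteflyCOI)
```

## The problem

*Bemisia tabaci* is not one species but a complex of morphologically
indistinguishable putative species delimited genetically, conventionally
by divergence in a 651-bp 3' fragment of the mitochondrial cytochrome
oxidase I gene (*mtCO1*). Field surveys sequence this barcode from a few
adult whiteflies per host-plant sample and ask two questions: *which
species is each fly* (including whether it belongs to any described
species at all), and *which whitefly species associate with which host
plants*. Both questions are corrupted by a well-known artefact: PCR can
amplify nuclear copies of mitochondrial DNA (NUMTs) or produce chimeric
products, which masquerade as deeply divergent "novel species" unless
screened out. This package implements the screening cascade, the
distance-based delimitation, and the downstream host-association analyses
as one tested pipeline.

## The QC cascade

A candidate barcode is screened against a `reference_panel`: species-
labelled, gap-free reference sequences (in practice derived from
high-throughput-sequenced mitogenomes, which are immune to the Sanger
NUMT artefact) with a fixed 651-nt barcode window anchored on one
reference. The cascade applies, in order:

1. **Alignment.** The query is aligned to its nearest reference (most
   shared 8-mers; ties to the lexicographically smallest id) by ends-free
   Needleman–Wunsch: match +1, mismatch −1, gap open −5, gap extend −1.
   Ends-free is the right model for an amplicon: primer-flank sequence
   overhangs the reference at no cost, so flank artefacts cannot push
   gaps into the window. Queries under 400 nt, those whose alignment does
   not cover the full window, and those under 70% window identity fail as
   `fail_length` — they cannot be judged by the later filters.
2. **Indels.** Any gap column (either row) strictly inside the 651-nt
   window fails the sequence (`fail_indel`): a true mitochondrial barcode
   of this fragment is indel-free, so an in-window gap is a frameshifted
   pseudogene or sequencing error. Gaps in the flanks are ignored — the
   barcode is trimmed before translation, so flanks cannot matter.
3. **Trimming.** The surviving query is cut to exactly 651 nt at the
   window columns. The window starts on a codon boundary by construction,
   so the reading frame offset is always 0.
4. **Translation screens.** The barcode is translated under the
   invertebrate mitochondrial code (NCBI table 5: ATA=Met, TGA=Trp,
   AGA/AGG=Ser, stops TAA/TAG). Any stop among the 217 codons fails the
   sequence (`fail_premature_stop`). Otherwise the peptide is compared to
   the panel profile at *conserved columns* — columns where every panel
   member carries the same residue — and any deviation fails it
   (`fail_conserved_violation`).

Two conventions deserve comment. First, codons containing any non-ACGT
symbol translate to `X` and never to a stop: a Sanger base-calling
ambiguity must not trigger the stop filter, and an `X` is likewise exempt
from the conserved-column comparison. Second, "highly conserved region"
is operationalised as *strict invariance across the panel*. This is the
strictest reading consistent with a small curated panel; with very few
references it marks many columns conserved by chance, which is
conservative in the right direction (it can only reject more, and clean
within-species variation is overwhelmingly synonymous, so real barcodes
are not penalised).

All sequence coordinates in reports are 0-based with half-open windows;
stop positions index the peptide.

## Distances

Three pairwise measures are computed over positionally aligned 651-nt
barcodes, always under **pairwise deletion**: a site enters a pair's
comparison only if both sequences carry a plain A/C/G/T there. This
matches the common default in barcoding practice and maximises usable
sites per pair for Sanger data.

* `p_distance`: mismatches / usable sites.
* `percent_identity`: `100(1 − p)`, the scale used for reporting
  between-species identity matrices.
* `tajima_nei`: the 1984 model-corrected distance
  `d = −b·ln(1 − p/b)` with `b = (1 − Σqᵢ² + p²/h)/2` and
  `h = Σᵢ<ⱼ xᵢⱼ²/(2qᵢqⱼ)`, where the base frequencies `q` are averaged
  over the pooled pair and `xᵢⱼ` are the six unordered mismatch-type
  frequencies. With uniform composition and balanced mismatch types this
  reduces analytically to Jukes–Cantor, `−(3/4)ln(1 − 4p/3)`; the test
  suite verifies agreement to below 1e−12 across p = 0.05…0.50.
  Saturation (`p ≥ b`) raises an explicit error rather than returning a
  clamped or infinite value, so pathological pairs surface to the user.

The species threshold (next section) is applied on p-distance — the
barcoding convention when a bare "percent divergence" is quoted — but the
metric is switchable to Tajima–Nei, and matrices of all three measures
can be exported so either convention can be audited.

## Species delimitation

The rule is a strict dichotomy at a threshold `t = 0.04`:

* minimum divergence to the nearest reference `< t` → the query is called
  as that reference's species;
* `≥ t` to every reference → the query is a novel putative species.

A barcode at exactly the threshold is therefore novel. Distance ties are
broken lexicographically by reference id and flagged. Novel sequences are
grouped by **single linkage at the same threshold**, implemented as exact
union–find over `p < t` pairs (not a dendrogram cut, so the strict `<` is
preserved at the boundary). Groups are ordered by their lexicographically
smallest member id — making labels independent of input order — and named
by continuing the panel's numbering: groups whose nearest reference sits
inside the *B. tabaci* complex (any high-level genetic group except the
Uganda clade) extend the SSA series; others extend the B. Uganda series.
Single linkage is the least-commitment choice for grouping a handful of
mutually close novels; with the generator's separation (inter-species
≥ 2t, intra ≤ t/2) every linkage rule gives the same answer.

Subgroups (e.g. SSA1-SG1/SG2/SG3, ~1–1.5% apart) are called by nearest
subgroup reference, with the margin to the runner-up reported, since at
subgroup distances the margin, not just the winner, is what a cautious
reader wants to see.

## Host-association analyses

Counts of assigned flies are tallied into a host × species matrix; hosts
declared in the survey but carrying no assigned fly appear as explicit
zero rows (absence is data, not missingness). On this matrix the package
computes composition percentages (summing to 100 exactly before
rounding), the minimum-support association table (cells with ≥ 3 flies,
the conventional support floor for claiming a host association), and the
mixed-sample fraction — the share of samples with ≥ 2 assigned flies
whose flies carry more than one species call; subgroups of one species do
not make a sample mixed.

**Clustering.** Host-range profiles (rows or columns) are clustered
hierarchically; the defaults are Euclidean distance on raw counts with
average linkage (UPGMA), with correlation distance available for
shape-based questions. Neither choice is forced by the underlying survey
design, so both are plain arguments. Constant profiles under correlation
distance raise an error naming the offending rows.

**Optimal k** is chosen by a majority vote of five cluster validity
indices computed on dendrogram cuts: Calinski–Harabasz, mean silhouette
width, Dunn, Davies–Bouldin and C-index — variance-ratio, cohesion and
separation families. Ties go to the smallest k and are flagged. The
searched k is capped at half the item count: beyond that, partitions are
dominated by singleton clusters, which degenerate several indices
(Davies–Bouldin in particular rewards zero-scatter singletons and would
otherwise vote for near-trivial partitions).

**Cluster uncertainty** uses the multiscale bootstrap. For each scale
`r ∈ {0.5, …, 1.4}` the features (the other axis) are resampled with
replacement to size `round(r·n)`, `B` times; each observed node's
`BP_r` is the fraction of replicate dendrograms containing its exact leaf
set. The two-parameter model

```
qnorm(1 − BP_r) = v·σ + c/σ,   σ = sqrt(1/r)
```

is fitted by weighted least squares (weights from the binomial variance
of BP via the delta method; BP clamped to [1/(2B), 1 − 1/(2B)]), and the
approximately unbiased p-value is `AU = 1 − Φ(v − c)`, with `v` the
signed distance to the cluster boundary and `c` its curvature. The naive
bootstrap probability is reported at scale 1. Nodes with AU > 0.83 are
flagged strongly supported. Two degenerate profiles bypass the fit: a
node present in *every* replicate at *every* scale gets AU = 1, one
present in none gets AU = 0, both flagged. The fit cannot be used there —
on a constant clamped z the design (σ, 1/σ) is nearly collinear and the
least-squares solution splits the constant between `v` and `c`, driving
`v − c` toward 0 and AU toward 0.5, the opposite of what a node observed
10,000 times out of 10,000 warrants. The fit is exercised in the tests
against its closed-form cases (constant BP = 1/2 gives v = c = 0 and
AU = 1/2; noiseless model-generated profiles are recovered exactly).

## The synthetic-data generator

The generator is first-class, tested code that emulates the survey's
design, with ground truth returned for every stage:

* **Panels**: each of `n` species is derived from a fixed synthetic
  651-nt stop-free ORF (shipped as a plain-text fixture; not a real
  accession) by placing `round(inter·651/2)` substitutions at sites
  disjoint *across* species, so every species pair differs at
  ~`round(inter·651)` sites and the realised pairwise p-distance hits the
  target (default 0.08, twice the species threshold — the scale of
  separation typical between described species). Substitutions never create a
  stop and are 50% biased toward synonymous changes; a per-species count
  of half the target at disjoint sites is the only placement under which
  the *pairwise* divergence equals the stated target.
* **Queries**: 1…`floor(intra·651)` substitutions (default intra 0.01)
  from the species reference, strictly synonymous and placed outside the
  panel's diagnostic sites. Silent variation is the realistic model for
  within-species barcode polymorphism and guarantees clean queries pass
  QC — so QC failures in simulations measure detection, not collateral
  damage. `floor` (not `round`) keeps "intra ≤ 1%" literally true at
  651 sites.
* **NUMTs**: a 1-nt in-window deletion (frameshift) and/or a planted TAA
  at an interior codon, each defect recorded with its position. Chimeric
  products are not modelled as a separate class: the screening cascade
  detects them through the same stop/conserved filters, so they are
  represented by those defect classes.
* **Surveys**: 3 flies per host-site sample; with probability
  `mixing_p` (default 0.4, the mixed-sample rate scale observed in the
  field data) a sample draws from two species with at least one fly
  each; the sample's host is drawn from the primary species'
  host-preference profile (default: one preferred host per species at
  weight 0.7). The realised host × species truth matrix is returned.
* **Planted-block matrices**: k diagonal blocks of Poisson(50) cells in a
  Poisson(1) background, for clustering-recovery experiments with known
  membership.

Everything is deterministic under a fixed seed. What the generator does
*not* emulate: sequencing quality gradients, codon-model evolution,
recombinant chimeras, unbalanced species abundances, or hosts shared
between specialists — so passing recovery tests demonstrate correctness
of the algorithms under the stated separations, not robustness to every
property of real survey data.

## Problem sizes and runtime choices

The test suite and acceptance script use: 500 sequences for the QC
soundness check (252 clean, 248 NUMTs, 6 species); 6 known + 3 held-out
species with 50 and 10 queries each for delimitation recovery; 20 seeded
4-block matrices (16 hosts × 16 species) for optimal-k recovery; one
2-block matrix (10 hosts × 20 species) with B = 1000 bootstrap replicates
per scale across 10 scales for AU support; and a 300-sample survey for
the mixed-fraction estimator. These sizes keep a full run in the tens of
seconds on one CPU while leaving each check statistically meaningful
(e.g. the binomial 95% interval at 300 samples is ±5.5 percentage
points).

## Known limitations

* Phylogenetic placement is approximated by the nearest reference's
  high-level genetic group; no tree is inferred, so "clusters within the
  *B. tabaci* complex" is a distance proxy, not a topology statement.
* The conserved-column screen depends on panel size: tiny panels mark
  many columns invariant by chance, making the filter stricter. This is
  deliberate but worth knowing when assembling small panels.
* The 651-nt window is fixed by one anchor reference; primer systems
  targeting other fragments need a different `window_start`.
* The shipped Uganda matrix reflects the survey's own 870 typed flies;
  analyses that folded in external datasets (larger merged host sets) are
  out of scope, so clustering results on the fixture need not reproduce
  figures computed on merged data.
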
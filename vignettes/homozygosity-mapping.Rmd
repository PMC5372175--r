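---
title: "Homozygosity mapping with rohmap: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping with rohmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(rohmap))
```

# The mapping strategy

In populations with frequent consanguineous marriage, a recessive disease
allele inherited from a common ancestor sits inside a long stretch of
genome that is identical by descent on both chromosomes. In genotype data
this appears as a **run of homozygosity (ROH)**: a contiguous block of
markers without heterozygous calls. Homozygosity mapping exploits this in
three steps, each a module of this package:

1. **Call ROH** per individual from biallelic genotype calls
   (`callRohCohort()`).
2. **Filter under the recessive model**: within each nuclear family, keep
   only ROH of affected children that are *not* shared with unaffected
   relatives (`uniqueRoh()`). Under autosomal-recessive inheritance with
   high penetrance, a causal homozygous region cannot be present in an
   unaffected parent or sibling.
3. **Find recurrence across families**: genomic intervals where the unique
   ROH of at least *k* affected individuals from different families
   overlap (`recurrentRegions()`) are candidate disease loci; their gene
   content (`genesInRegion()`) yields candidate genes.

A fourth, independent piece is single-variant case-control association
(`genotypeTable()`, `pearsonChi2()`), used when a specific candidate
variant — here a 5 bp intronic insertion in *CNTNAP2* — is genotyped in
cases, relatives and population controls.

# The ROH caller

No algorithmic description is available for the commercial array software
that produced the study's ROH calls, so the caller here is the transparent
sliding-window heuristic popularised by genome-wide association toolkits,
with all parameters explicit in `RohParams()`:

| parameter | default | meaning |
|---|---|---|
| `windowMarkers` | 50 | markers per sliding window |
| `maxHetPerWindow` | 1 | heterozygous calls tolerated per window |
| `maxMissingPerWindow` | 5 | missing calls tolerated per window |
| `hitFraction` | 0.05 | fraction of containing windows that must pass to flag a marker |
| `minRunMarkers` | 25 | minimum markers per reported run |
| `minRunLengthBp` | 500 kb | minimum physical length per run |
| `maxInternalGapBp` | 1 Mb | marker gap that splits a run |

A window *passes* when it holds at most `maxHetPerWindow` HET and
`maxMissingPerWindow` MISSING calls; a marker is *flagged* when at least
`hitFraction` of the windows containing it pass. Maximal flagged stretches
become runs, split at physical gaps above `maxInternalGapBp` and filtered
by marker count and length. Run boundaries are the outermost flagged
markers and are never extended into unflagged territory; the reported
interval is half-open, ending one base past the last flagged marker.
Chromosomes shorter than one window are judged as a single window with
allowances scaled down proportionally (floored), the conservative choice.

Two consequences of this design are worth knowing. Missing calls inside a
run count toward `nMissing` but never break a run, because array dropouts
are positionally random. And because a marker is flagged when only a small
fraction of its windows pass, flagged territory extends up to one window
beyond a truly homozygous tract: called boundaries overshoot by a few tens
of kilobases at ~5 kb marker spacing. This "edge bleed" is shared by all
callers of this family and is why recovery of simulated segments is scored
by Jaccard overlap rather than exact coordinates.

The 500 kb minimum run length is set well below the 517–873 kb scale of
the candidate loci the pipeline is meant to resolve; with 25+ markers
required per run, chance runs at array density are rare.

# The recessive family filter

`FilterPolicy()` exposes two decisions the analysis text leaves open:

* **Comparator set** — "unique to the affected patient(s)" can be read
  against parents only, or against all unaffected relatives. The default
  is the stricter reading (`all_unaffected_relatives`); `parents_only`
  reproduces the laxer one. The strict output is always a subset of the
  lax output.
* **Overlap rule** — by default any shared base pair masks
  (`any_overlap`), the natural reading of "unique". A
  `reciprocal_fraction` mode is provided for sensitivity analysis when
  fragmentary calls make single-basepair masking too aggressive.

Affected siblings never mask each other, and families never interact:
deleting every other family from the input leaves a family's output
unchanged (a tested invariant).

# Recurrent regions

`recurrentRegions()` is a sweep-line over segment endpoints. Per-sample
segments are merged first, so each individual contributes at most once per
locus. Between consecutive endpoints the set of covering individuals is
constant; atomic intervals with support ≥ *k* are kept and adjacent atomic
intervals with *identical* support sets are merged. Regions are therefore
**maximal constant-support intervals**: a single coordinate pair with an
explicit patient list is only meaningful over an interval where that list
does not change, which is how the study tables print their loci. The
union-of-coverage alternative (any position with ≥ *k* coverage) would
glue together intervals supported by different patient subsets.

Support is counted in individuals by default, with family counts always
reported alongside: an affected sibling pair counts as two individuals but
one family, and published narratives sometimes use one unit and sometimes
the other (one locus in the packaged tables is "6 children" by family
count but 7 listed individuals).

Printed locus lengths are reproduced by *truncating* to kilobases:
`lengthKb()` is `floor((end - start)/1000)`, which matches all three
internally consistent fixture rows (517, 873, 591 kb); rounding would give
874 and 592. The fourth row's printed length (820 kb) is inconsistent with
its own coordinates (133,384 bp); the coordinates are treated as
authoritative and the printed value is preserved in the fixture for
transparency only.

# Coordinates

All intervals are 1-based half-open `[start, end)`; physical length is
`end − start`, which is exactly how the fixture coordinate pairs relate to
their printed kb lengths. The exclusive end is stored verbatim in the
`end` slot of every `GRanges`, so `width()` overstates length by one base
— `lengthBp()`/`lengthKb()` are the accessors to use. Overlap queries
shrink ends by one base internally so that touching intervals do not
overlap. BED export writes `start − 1` and leaves the end unchanged, and
import reverses this, making write/read an exact round trip; every writer
emits a `#` header naming the convention. GFF3 gene ends (1-based
inclusive) gain one base on import to enter the half-open convention.

# The cohort simulator

No raw genotypes are distributed with the package, so every stage is
validated against `simulateCohort()`, a seeded generator of
consanguineous-cohort-like data. What it emulates:

* an array-like grid of biallelic markers with exponentially jittered
  spacing (mean `markerSpacingBp`) and per-marker B-allele frequencies;
* nuclear families of two parents and `childrenPerFamily` children, the
  first `affectedPerFamily` affected;
* background genotypes drawn marker-wise from Hardy-Weinberg proportions
  p², 2pq, q² at the marker's own B-allele frequency;
* **planted autozygosity**: per affected child,
  `plantedSegmentsPerAffected` non-overlapping segments with lengths from
  `plantedLengthSampler` are forced fully homozygous (one allele coin flip
  per segment). Every other family member is forced heterozygous at up to
  three markers inside each segment, making the segment unique to the
  affected child *by construction* — this is the exact truth set against
  which caller and filter are scored;
* **incidental ROH** in unaffected members (Poisson count,
  `backgroundRohRate` expected per sample) from the same length sampler,
  drawn away from the family's planted intervals so they cannot contradict
  the constructed truth; on a crowded toy genome an unplaceable incidental
  segment is skipped rather than forced;
* **noise**: truly homozygous calls become HET with `hetErrorRate`, and
  any call becomes MISSING with `missingRate`, in that order.

Autozygosity is planted directly rather than simulated through
inbreeding-loop meioses: the downstream analysis consumes ROH coordinates,
not recombination histories, and direct planting gives an exact truth set.
The simulator therefore does **not** reproduce linkage disequilibrium
between markers, realistic human allele-frequency spectra, spatially
varying marker density, or the gradual length distribution of genuine
autozygosity — so passing recovery tests demonstrate correctness of the
calling/filtering machinery under the stated noise model, not performance
on real arrays.

Default scale: 36 families (the cohort size of the packaged study), two
children each with one affected, four autosomes of 3,000 markers at ~5 kb
mean spacing (a ~60 Mb toy genome), two planted segments of 1–3 Mb per
affected child, heterozygous-error rate 0.001, missing rate 0.01, one
incidental ROH expected per unaffected sample. The genome is deliberately
scaled down from a real 2.7M-probe array so that a full
simulate–call–filter–recur cycle stays in the tens of seconds; tests use
smaller cohorts still (2–6 families, 1,500–2,000 markers per chromosome),
sizes chosen so the whole suite completes in about a minute while keeping
≥ 150 planted segments in the pooled recovery checks. Everything is a pure
function of the seed: identical configurations reproduce bit-identical
cohorts.

Under the recovery conditions used by the tests (heterozygous-error rate
≤ 0.002, ≤ 5 kb spacing, planted lengths ≥ 1 Mb) the caller at defaults
recovers ≈ 97–99% of planted segments at Jaccard ≥ 0.9, pooled over 20
seeds. The residual losses are edge-bleed collisions: a called run
overshooting its planted boundary into an adjacent incidental ROH of a
relative is masked by the `any_overlap` filter.

# Association statistics

`pearsonChi2()` implements the classical Pearson test without continuity
correction — the choice that reproduces the study's genotype statistic
(χ² = 4.5335 on the 3×2 table of the 106-member family cohort against 100
controls) exactly. P-values come from the upper tail of the χ²
distribution (the regularised upper incomplete gamma function, `pchisq`),
which for df = 2 reduces to `exp(−x/2)`; the tail function is exposed as
`pearsonChi2FromStat()` and tested against closed forms. Frequencies are
kept at full precision and only rounded for display.

One documented discrepancy: the study prints an *allele-level* statistic
of 0.014 (p = 0.904) "between cases and controls". No combination of the
printed counts reproduces it: the family-cohort-vs-controls allele table
gives 2.697 (p = 0.101), while patients-vs-controls gives 0.0177
(p = 0.894) — numerically close to the printed pair, suggesting the
original comparison was patients against controls. The package computes
the standard statistic for whichever pair is requested and does not
imitate the printed value. Note also that family members are relatives of
the patients, so the combined-cohort comparison violates the independence
assumption of the test; it is reproduced because the genotype-level
statistic is anchored to it, not because it is recommended practice.

`hweTest()` (χ² goodness of fit against Hardy-Weinberg proportions within
a group) is an auxiliary diagnostic not present in the original analysis.

# Fixtures

The packaged fixtures under `inst/extdata/` carry the study's summary
tables as plain text: the four recurrent loci with hg19 coordinates, gene
lists and supporting patients; the per-group NN/NV/VV counts at the
*CNTNAP2* insertion; and an hg19 gene BED. Two files are explicitly
synthetic reconstructions (`_synthetic` in the file name): the
individual-level genotype table (the study published only group totals;
individual assignments are arbitrary but reproduce every group count
exactly) and the cohort pedigree (the published family identifiers with
placeholder parent/sibling records matching the published family
composition: 37 affected in 36 families, 36 genotyped parents, 33
unaffected siblings). The gene BED is likewise synthetic: gene intervals
are placed inside their printed loci rather than copied from RefSeq, so
gene *membership* is faithful while exact gene coordinates are not. One
patient-list normalisation: the locus table prints two sibling IDs without
zero-padding ("F19-88/89"); the fixture uses the padded form used
everywhere else.

```{r}
recomputeStudyTables()$tests
```

# Known limitations

* The caller is a window heuristic, not an HMM: boundary resolution is
  limited to roughly one window, and no genotyping-error model informs the
  calls beyond the per-window HET/MISSING allowances.
* Per-patient genome-wide ROH totals from the original arrays are not
  reproducible here — they depend on the raw array data and the unreported
  settings of the original software — and are not claimed.
* The recessive filter compares segment coordinates, not genotype states;
  whether the original analysis did likewise is unstated.
* X-chromosome handling, CNV calling, LD-aware pruning and any statistical
  significance model for recurrence (a permutation null, for example) are
  out of scope.
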
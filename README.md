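# rohmap

Homozygosity mapping in consanguineous pedigrees: from biallelic genotype
calls to candidate recessive-disease loci.

## What problem this solves

In populations with a high rate of consanguineous marriage, a recessive
disease allele inherited from a shared ancestor lies inside a long run of
homozygosity (ROH) — a stretch where both chromosome copies are identical
by descent. Mapping such loci from SNP-array-like genotypes takes four
steps, and `rohmap` implements each as a tested, reusable stage:

1. **ROH calling** — a sliding-window scan over genotype calls. A window
   of *w* consecutive markers (default 50) passes when it holds at most 1
   heterozygous and 5 missing calls; a marker is flagged homozygous when
   ≥ 5% of the windows containing it pass; maximal flagged stretches with
   ≥ 25 markers spanning ≥ 500 kb become ROH segments, split at marker
   gaps over 1 Mb.
2. **Recessive-model family filter** — for each affected individual, drop
   every ROH that overlaps an ROH of an unaffected relative in the same
   family. Under autosomal-recessive inheritance with high penetrance the
   causal homozygous region must be unique to the affected child(ren).
3. **Recurrence across families** — a sweep-line over segment endpoints
   reports every maximal interval covered by the unique ROH of ≥ *k*
   affected individuals, with its exact support set, family count, gene
   content and length in truncated kilobases, `⌊(end − start)/1000⌋`.
4. **Single-variant association** — NN/NV/VV genotype tables per group
   (N = reference, V = variant allele), allele frequencies
   `freq_V = (n_NV + 2 n_VV) / 2n`, carrier counts, and Pearson χ² tests
   `Σ (O − E)²/E` without continuity correction on genotype (3×2) and
   allele (2×2) tables.

Because raw genotypes for the motivating study are not redistributable,
the package ships (a) a seeded simulator of consanguineous nuclear-family
cohorts with *planted* autozygous segments — an exact truth set for
validating caller and filter — and (b) the study's summary tables as
plain-text fixtures, so its headline numbers are recomputed from scratch
at test time.

It is aimed at statistical geneticists and method developers who want a
transparent, fully scriptable alternative to black-box array software for
ROH-based mapping, in ordinary Bioconductor idiom (`GRanges`,
`SummarizedExperiment`).

## Worked example

Simulate a small cohort, run the three mapping stages, then reproduce the
packaged study's association test:

```r
library(rohmap)

sim <- simulateCohort(SimConfig(nFamilies = 4L, nMarkers = 2000L,
                                nChroms = 2L, seed = 11L))
sim$cohort
#> GenotypeCohort: 4000 markers x 16 samples
#>   chromosomes: chr1 chr2
#>   families: 4 | affected: 4 | unaffected: 12
#>   missing call rate: 0.0097

roh  <- callRohCohort(sim$cohort)          # 21 segments cohort-wide
uniq <- uniqueRoh(roh, pedigree(sim$cohort))   # 8 unique to affecteds
reg  <- recurrentRegions(uniq, k = 2, ped = pedigree(sim$cohort))
head(as.data.frame(reg)[, c("seqnames", "start", "end",
                            "supportIndividuals", "lengthKb")], 3)
#>   seqnames   start     end supportIndividuals lengthKb
#> 1     chr1 2431295 2912998                  2      481
#> 2     chr1 3133476 4394273                  2     1260
#> 3     chr2 3778789 5662595                  2     1883
```

The 21 called segments comprise the 8 planted autozygous segments (two per
affected child, recovered and kept by the filter) plus incidental
background ROH in unaffected relatives, which the filter removes. Regions
with `supportIndividuals ≥ k` are the candidate loci; with real data their
`supportSamples` column lists the patients behind each locus.

Association on the packaged genotype counts — a 106-member family cohort
versus 100 population controls at a 5 bp *CNTNAP2* insertion:

```r
tabs <- studyGenotypeCounts()
tabs$patients
#> GenotypeTable 'patients' (n = 37)
#>   NN: 14  NV: 15  VV: 8
#>   freq N: 0.58  freq V: 0.42  carriers: 23

pearsonChi2(genotypeCountMatrix(tabs$family_cohort, tabs$controls))
#> Pearson chi-square: X^2 = 4.5335, df = 2, p = 0.1036
```

So 23 of 37 patients carry the insertion, the V-allele frequency is 0.42
in patients (0.49 cohort-wide, 0.41 in controls), and the genotype
distributions of cohort and controls do not differ significantly.

`recomputeStudyTables()` rebuilds every locus length, support count, gene
list, frequency and test from the fixtures in one call, and
`runPipeline(pipelineConfig(...), outDir)` chains all stages with a JSON
manifest for byte-reproducible runs. A thin command-line wrapper with
`simulate` / `call-roh` / `filter` / `recur` / `annotate` / `assoc` /
`demo` subcommands lives at `inst/scripts/rohmap.R`.

## Layout

```
R/                    S4 classes, callers, filter, sweep-line, association
inst/extdata/         study fixtures (TSV/PED/BED; *_synthetic.* files are
                      reconstructions, see the vignette)
inst/scripts/rohmap.R command-line wrapper
vignettes/            methods vignette: models, parameters, design choices
tests/testthat/       unit, property and end-to-end tests with independent
                      brute-force oracles
scripts/acceptance.R  headline-number reproduction
```
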
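# EmbryoPGT

Haplotype-based preimplantation genetic testing for monogenic disease
(PGT-M) **using an embryo as the proband**, with read-depth CNV screening
of every embryo.

## The problem

PGT-M normally phases the parental haplotypes around a pathogenic variant
by genotyping an affected relative. When the variant is de novo, or the
informative relatives are unavailable, family-based phasing is impossible.
The alternative implemented here uses a sibling **embryo whose direct
mutation test (Sanger sequencing or Gap-PCR) shows it carries the
variant** as the proband: the parental haplotype it inherited must be the
mutant-linked one, and every other embryo can then be diagnosed from the
haplotype it inherited — a safeguard against allele dropout (ADO), the
main failure mode of whole-genome-amplified single-cell genotyping.

## The model

* **Markers.** Heterozygous SNPs within 5 Mb up- and downstream of the
  variant (`selectInformativeSnps()`).
* **Anchoring.** At markers where the carrier parent is heterozygous and
  the other parent homozygous, the proband's genotype identifies the
  transmitted allele, which is labelled **M** (mutant-linked); the other
  is **N** (`anchorParentalPhase()`). For a recessive deletion (e.g. the
  19,304-bp --SEA alpha-globin deletion, two carrier parents), the
  parental origin of the proband's deletion is resolved first from
  markers *inside* the deleted interval, where a carrier is hemizygous.
* **Decoding.** Each embryo's inheritance vector is the Viterbi path of a
  4-state HMM — hidden state = (paternal, maternal) haplotype ∈ {M, N}² —
  with transition probabilities from the recombination fraction
  *r* = (1 − e^(−2d))/2 (Haldane) over genetic-map distance *d*, and an
  emission model with ADO rate *a* and genotype-error rate *e*:
  P(het | het) = 1 − a − e, P(hom | het) = (a + e)/2 each
  (`decodePaths()`, `viterbiPath()`).
* **Diagnosis.** The decoded haplotype at the variant (consensus of the
  two flanking anchorable markers; disagreement flags possible
  recombination) is reconciled with the direct mutation test; on conflict
  the more severe status wins and a flag (`ado_suspect`,
  `recombination_in_window`) is raised (`diagnoseEmbryos()`).
* **Ploidy gate.** Triploid or monosomic embryos cannot be haplotyped;
  they are caught from genome-wide SNPs (Mendelian-inconsistency and
  heterozygosity-excess tests) and from the CNV module
  (`detectPloidyFailure()`).
* **CNV module.** 400-kb windows at a 200-kb stride, LOESS GC
  normalization, log2 ratios and Z-scores against a reference panel (with
  a 46,XY sex adjustment), circular binary segmentation with a seeded
  permutation test, and the clinical reporting rules: |log2| > 0.25;
  whole-chromosome, whole-arm, or segmental ≥ 4 Mb (≥ 20 bins); mosaic
  segments ≥ 10 Mb with estimated aberrant-cell level > 30%
  (`callCnv()`).

A seeded simulator (`simScenario()`, `simulateFamily()`,
`simulateDepth()`) generates families with map-distributed crossovers,
ADO/error-corrupted genotypes and GC-biased negative-binomial depth, so
the whole pipeline is testable without patient data.

## Worked example

```r
library(EmbryoPGT)

## deterministic three-family demonstration set (recessive --SEA deletion
## family with a triploid embryo, maternal-dominant EXT1 family,
## paternal-dominant CUL3 family), written through the package's own
## VCF / genetic-map / TSV writers
fx <- makeTable4Fixture(dir = "demo")

res <- runEndToEnd("demo/family1", outDir = "demo/out1")
res$diagnoses
```

```
  embryo_id cnv_flag direct_call proband_id haplotype_call final_status          flags
1      E1-1 abnormal   wild_type       E1-2      wild_type    wild_type
2      E1-2 abnormal     carrier       E1-2        carrier      carrier
3      E1-3   normal   wild_type       E1-2      wild_type    wild_type
4      E1-4 abnormal   wild_type       E1-2        failure    wild_type ploidy_failure
```

Embryo E1-2 (the proband) carries one parental deletion; E1-1 and E1-3
inherited both normal haplotypes and agree with their Gap-PCR result;
E1-4 is triploid — its haplotype cannot be constructed (`failure`,
`ploidy_failure`), so its reported status falls back on the direct test
and its CNV flag is abnormal. A thin command-line front end with the same
behaviour ships in `inst/cli/pgt.R`
(`Rscript pgt.R run --family demo/family1 --out demo/out1`).

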
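---
title: "Embryo-as-proband haplotyping and CNV screening for PGT-M: methods"
author: "EmbryoPGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embryo-as-proband haplotyping and CNV screening for PGT-M: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical method it
implements: the model, the parameters that matter, what the simulator
does and does not emulate, the numerical choices, and the design
decisions taken where the design was genuinely open.

## 1. Why an embryo as proband

Haplotype-based PGT-M guards the direct mutation assay against allele
dropout (ADO): during whole-genome amplification of a 5–10-cell
trophectoderm biopsy, one allele of a heterozygous site frequently fails
to amplify, so a carrier embryo can read as wild-type at the variant
itself. Phasing which parental haplotype carries the variant normally
requires an affected relative. For de novo variants, or when the
informative relatives are unavailable, this package uses a sibling
embryo whose **direct test** (Sanger sequencing for point variants,
Gap-PCR for the --SEA deletion) demonstrates it carries the variant.
That embryo is the proband: under the no-recombination assumption inside
a small window, the carrier parent's allele it inherited at each nearby
marker tags the mutant-linked haplotype **M**; the other allele tags
**N**.

## 2. The phasing model

**Markers.** Biallelic SNPs within `windowBp` (default 5,000,000 bp) of
the variant where at least one parent is heterozygous. Sites where both
parents are heterozygous (`double_het`) cannot anchor unambiguously;
they are kept for likelihood only, with their parental phase
marginalized until the refinement step resolves it. For deletion
variants, markers inside the deleted interval are special: a carrier
embryo is hemizygous there. The window default follows the method's
stated practice; a 2-Mb window is a supported configuration
(`runConfig(windowBp = 2e6)`) for laboratories that prefer the tighter
convention.

**Emission model.** Genotypes are coded hom-ref/het/hom-alt. With ADO
rate $a$ and genotyping error $e$ ($a + e < 1$; defaults $a = 0.05$,
$e = 0.01$, typical of WGA material, overridable everywhere):

* true het: observed het w.p. $1 - a - e$; either hom w.p. $(a+e)/2$;
* true hom: observed correctly w.p. $1 - e$; het or opposite hom w.p.
  $e/2$ each;
* missing observations have probability 1 (the locus is skipped, never
  imputed).

The simulator draws observations from exactly these conditionals
(`sampleObservedGt()` shares the model with `emissionProb()`), so the
decoding likelihood is well specified on simulated data. Parents are
genotyped from blood, so they receive error $e$ but no ADO.

**Hidden chain.** Per embryo, the hidden state at marker $k$ is the pair
(paternal, maternal) of inherited-haplotype indicators, four states.
Transitions factor per parent: switch with the recombination fraction
$r_k$, stay with $1-r_k$, where $r = \tfrac12(1 - e^{-2d})$ (Haldane, no
interference) and $d$ is the genetic-map distance in Morgans between
consecutive markers, linearly interpolated from a 3-column map
(position, cM/Mb, cumulative cM) with constant extrapolation outside the
table. Haldane is consistent with the simulator's Poisson crossover
process, making simulation-based validation exact.

**Decoding.** `viterbiPath()` computes the exact max-log-probability
path. Ties (common at markers where a parent is homozygous, so emissions
do not depend on that parent's state) are broken deterministically:
fewest indicator switches first, then lexicographically with M before N.
The implementation runs the dynamic program backward over the pair
objective (score, then switches) and reconstructs forward, which yields
the lexicographically smallest optimum; a float tolerance of $10^{-9}$
guards tie detection. The posterior margin (gap to the second-best path)
comes from a top-2 forward pass. The test suite proves equality with
exhaustive path enumeration on hundreds of instances up to 8 markers.

**Phase refinement and anchor auditing.** Markers the proband could not
anchor (double-het sites, proband-missing sites) are assigned after a
first decoding round by maximizing the joint likelihood of all embryos'
observations at that marker, then everything is decoded again (two fixed
rounds of coordinate ascent). The same joint likelihood audits the
*anchored* markers: if flipping an anchor improves the all-embryo log
likelihood by more than 2, the anchor was probably corrupted — a proband
ADO at anchoring time, or a proband crossover between that marker and
the variant — and the marker is flagged `conflicted` and excluded from
diagnosis. The threshold 2 (about a 7:1 likelihood ratio) is
deliberately conservative; the audit cannot catch a proband crossover
adjacent to the variant, which is the method's irreducible failure mode
and the reason the direct test is always run in parallel.

**Calling the variant.** The call at the variant position (deletions use
their interval midpoint) reads the decoded indicator at the two nearest
anchorable flanking markers, per carrier parent. Disagreeing flanks mean
a possible crossover inside the bracketing interval: the embryo gets
`failure` with `recombination_in_window` rather than a guess. Dominant
cases map carrier-parent M to carrier; recessive-biallelic cases count M
haplotypes from both parents (2 affected / 1 carrier / 0 wild-type).

**Recessive deletions and parental origin.** With two carrier parents
and a carrier proband, anchoring first needs to know *whose* deletion
the proband carries. Inside the deleted interval a carrier is
hemizygous: at father-het/mother-hom markers a paternal deletion forces
the observed call to equal the mother's allele, while under a maternal
deletion it is the father's transmitted allele (either, with probability
one half). The two origin hypotheses are compared by log likelihood with
a 5% mismatch rate absorbing genotyping error. With three or more
father-het/mother-hom inside markers a paternal deletion is always
recovered in noise-free data; the symmetric statement holds for maternal
deletions. When the evidence is absent or tied the function aborts with
the additional evidence it needs (inside-deletion coverage or an
affected embryo), rather than guessing.

## 3. The ploidy gate

Haplotyping presumes a biparental diploid embryo. Two genotype-level
screens run on genome-wide markers (the phasing window plus QC markers
on other chromosomes), each per chromosome with at least 10 complete
trio genotypes:

* **Mendelian consistency**: the fraction of markers where the embryo's
  diploid call cannot be one allele from each parent; above 10% the
  embryo fails (this catches monosomy, where the embryo lacks one
  parent's obligate allele).
* **Heterozygosity excess**: at markers where exactly one parent is
  heterozygous, a disomic embryo is het about half the time, but an
  embryo carrying *both* of that parent's haplotypes (heterodisomy, the
  signature of a meiosis-I-derived triploid) is het essentially always;
  a het fraction of 0.9 or more triggers failure. A plain 10%
  Mendelian rule cannot see uniform triploidy at all — a child whose
  alleles are a subset of its parents' never violates it — which is why
  this second screen exists, and why the triploid embryo in the
  regression fixture is detected "by SNP analysis" while its read-depth
  profile is ratio-neutral (a uniform 3n genome rescales away in any
  per-sample normalization).

A whole-chromosome or whole-arm CNV call overlapping the variant
chromosome also fails the gate. Failed embryos receive no haplotype
diagnosis; their final status falls back on the direct test, flagged
`ploidy_failure`.

## 4. The CNV module

* **Binning.** 400-kb windows at a 200-kb stride (half-overlapping). A
  final partial bin is kept only when it is at least one stride wide
  *and* extends past the last full bin's end. A bin is excluded when
  more than 50% of its width intersects the blacklist. A fragment start
  counts in every overlapping bin. The 4-Mb minimum segmental length
  divided by the stride is exactly the 20-bin support requirement, and
  the suite asserts this consistency against the grid arithmetic.
* **GC normalization.** LOESS of count on GC fraction over retained
  autosomal bins: span 0.3, *local quadratic*, symmetric (robust) family
  with three robustness iterations. A local-linear fit measurably
  underfits the curvature at the mode of a smooth unimodal bias and
  leaves a residual correlation with GC of 0.05–0.08; the quadratic
  brings it under 0.02. Bins whose fitted depth falls below 10% of the
  typical level (extreme GC) cannot be rescaled reliably and are
  excluded.
* **Ratios.** Sample and panel are scaled to equal autosomal *medians*
  (a mean would let a large aneuploidy drag its own baseline), then
  `log2Ratio = log2(sample/median)` and `z = (sample − median)/sd` per
  bin. For a 46,XY sample against a female or mixed panel, the expected
  X and Y depth is halved before the ratio.
* **Segmentation.** Recursive circular binary segmentation: each
  segment is scanned (compiled code) for the arc maximizing the circular
  two-sample statistic $|\bar x_{arc} - \bar x_{rest}| /
  \sqrt{1/n_1 + 1/n_2}$; the split is accepted if its permutation
  p-value is below 0.01 (1,000 permutations, seeded, with early
  rejection once the exceedance count guarantees p ≥ α — a pure
  speed-up that cannot change the decision). Adjacent segments closer
  than 0.1 in mean are re-merged; segments under 4 bins are not split.
* **Classification.** |mean log2| > 0.25 → gain/loss, reported if
  whole-chromosome or whole-arm (≥ 90% of that unit's retained bins) or
  segmental ≥ 4 Mb with ≥ 20 bins. Intermediate states (0.1 < |log2| ≤
  0.25) of ≥ 10 Mb are mosaic if the estimated aberrant-cell level
  $v = 2(2^L - 1)$ for gains, $2(1 - 2^L)$ for losses exceeds 30%. The
  level formula is the exact inverse of the expected mixture ratio
  $(2 \pm v)/2$ and is reported for every non-neutral segment (a full
  single-copy event has level 1). Arm boundaries come from a
  user-supplied centromere table; without one, whole-arm scope is simply
  not assessed.

## 5. The simulator

`simulateFamily()` draws parental haplotypes at uniform(0.2, 0.8) allele
frequencies, rides the variant on haplotype M of the carrier parent(s),
and generates each meiosis as a Poisson crossover process on the cM
scale of the same map the decoder uses (1 cM/Mb by default). Embryo
genotypes come from the allele complement — hemizygous inside deletions,
altered by ploidy events (monosomy; heterodisomic triploidy; and a
locus-isodisomic triploid variant whose meiotic-I error resolved to a
single maternal haplotype at the variant window, the configuration the
regression fixture's failed embryo uses). Depth profiles are negative
binomial with mean $\mu = 1000 \cdot b(\mathrm{GC}) \cdot \mathrm{cn}/2$
reads per bin and variance $\mu(1 + 0.1)$ — about 9 million reads over
400-kb windows, matching low-pass WGA sequencing practice — with a
Gaussian-shaped GC bias and copy-number multipliers $(2 + v\,\Delta)/2$
for injected events.

What the simulator does **not** emulate: linkage disequilibrium between
markers, locus-specific ADO (GC-rich amplicons drop out more), array
genotyping artifacts, segmental WGA amplification bias (which produces
wavy depth profiles real pipelines must additionally smooth), and
crossover interference. Passing tests therefore demonstrate correctness
of the inference machinery under its own model assumptions, not clinical
performance on real biopsies.

The packaged regression dataset (`makeTable4Fixture()`) is a fixed-seed
three-family scenario — a recessive --SEA deletion family of four
embryos including a carrier proband and a triploid haplotyping failure,
a maternal-dominant *EXT1* family of four, and a paternal-dominant
*CUL3* family of two — written out through the package's public writers
so the pipeline consumes it through its file interfaces only. Each
embryo's meiosis is redrawn until its truth status matches the target
pattern; with the packaged seed the full pipeline reproduces all ten
direct-test/haplotype pairs deterministically.

## 6. Problem sizes and determinism

The test suite and the acceptance script use 200 markers per clinical
fixture family, 30 markers and 4 embryos for the 200-family recovery
study, up to 8 markers for the enumeration oracle (where $4^n$ paths are
enumerated), and genomes of a few hundred megabases (hundreds to
thousands of bins) for the CNV studies — sizes at which every oracle is
exact or statistically well-powered while a full run stays in the
minutes range. All randomness flows from explicit seeds: simulation
scenarios carry a seed, CBS permutations are seeded, and report TSVs are
written with fixed column order and 4-decimal floats, so identical
inputs give byte-identical reports.

## 7. Known limitations

* A proband crossover immediately adjacent to the variant silently
  relabels the anchors on one side; the joint-likelihood audit catches
  it only when sibling data are decisive. This is intrinsic to the
  embryo-as-proband design and is why clinical use keeps the direct
  assay in the loop (conflicts surface as flags, with the more severe
  status reported).
* With hard genotype calls, a locus-isodisomic triploid region is
  indistinguishable from disomy in the window; detection relies on
  genome-wide markers. B-allele-frequency data would strengthen this but
  microarray intensities are out of scope.
* The recessive origin-resolution step needs informative markers inside
  the deletion (or an affected embryo); for deletions much smaller than
  the --SEA 19.3 kb this may simply not exist on an array, and the
  method then refuses rather than guesses.
* CBS p-values use unrestricted permutation, which assumes exchangeable
  noise within a segment; long-range autocorrelated depth (WGA waviness)
  would inflate splits on real data.
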
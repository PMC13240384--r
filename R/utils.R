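## Internal helpers shared across modules.

## genotype code from a pair of allele strings, given site ref/alt
.gtFromAlleles <- function(a1, a2, ref, alt) {
  ifelse(is.na(a1) | is.na(a2), NA_integer_,
         (a1 == alt) + (a2 == alt))
}

## genotype code from an allele multiset (character vector), collapsing a
## possibly non-disomic allele complement to the diploid call a genotyping
## platform would report: both alleles present -> het, otherwise hom.
.gtFromAlleleSet <- function(alleles, ref, alt) {
  hasRef <- ref %in% alleles
  hasAlt <- alt %in% alleles
  if (hasRef && hasAlt) 1L else if (hasAlt) 2L else if (hasRef) 0L else NA_integer_
}

## 1-based inclusive interval -> 0-based half-open (BED) and back.
## Property-tested on boundaries in the test suite.
toBed0 <- function(start1, end1) data.frame(start = start1 - 1, end = end1)
fromBed0 <- function(start0, end0) data.frame(start = start0 + 1, end = end0)

## fixed 4-decimal float formatting for deterministic report TSVs
.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 4))
}

## align a per-sample call data.frame (chrom, pos, ref, alt, gt) to a marker
## table; returns an integer gt vector (NA where the sample has no call or
## the alleles disagree with the marker definition)
.alignCalls <- function(calls, markers) {
  key <- paste(markers$chrom, markers$pos)
  ckey <- paste(calls$chrom, calls$pos)
  idx <- match(key, ckey)
  gt <- calls$gt[idx]
  bad <- !is.na(idx) &
    (calls$ref[idx] != markers$ref | calls$alt[idx] != markers$alt)
  gt[bad] <- NA_integer_
  as.integer(gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
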
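## Central S4 classes. Genotype codes throughout the package:
## 0 = hom ref, 1 = het, 2 = hom alt, NA = missing.

## ---- generics ----

#' Interpolate cumulative genetic distance at a physical position
#'
#' Linear interpolation of cumulative centimorgans between the tabulated
#' points of a [GeneticMap]; beyond the tabulated range the cumulative cM is
#' extrapolated as a constant, so physical distance outside the map
#' contributes zero genetic distance.
#'
#' @param map A [GeneticMap].
#' @param pos Numeric vector of 1-based physical positions (bp).
#' @return Numeric vector of cumulative cM, one per position.
#' @export
setGeneric("interpolateCM", function(map, pos) standardGeneric("interpolateCM"))

#' Genotype observation probability under the ADO + error model
#'
#' Probability of observing a diploid genotype class given the true class,
#' under a symmetric allele-dropout (ADO) and genotyping-error model with
#' rates `a` and `e`: a true heterozygote is observed het with probability
#' `1 - a - e` and as either homozygote with probability `(a + e)/2` each; a
#' true homozygote is observed correctly with probability `1 - e`, and as het
#' or the opposite homozygote with probability `e/2` each. A missing
#' observation has probability 1 (the locus is skipped).
#'
#' @param model An [EmissionModel].
#' @param trueGt Integer vector of true genotype codes (0 = hom ref,
#'   1 = het, 2 = hom alt).
#' @param obsGt Integer vector of observed codes (0/1/2 or `NA` for missing).
#' @return Numeric vector of probabilities.
#' @export
setGeneric("emissionProb", function(model, trueGt, obsGt) standardGeneric("emissionProb"))

#' @rdname VariantLocus-class
#' @param x A `VariantLocus`.
#' @export
setGeneric("variantLength", function(x) standardGeneric("variantLength"))

#' @rdname VariantLocus-class
#' @export
setGeneric("variantPosition", function(x) standardGeneric("variantPosition"))

#' @rdname PhasedParents-class
#' @param x A `PhasedParents` (or `InheritancePath`) object.
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname InheritancePath-class
#' @param x An `InheritancePath`.
#' @export
setGeneric("pathStates", function(x) standardGeneric("pathStates"))

#' @rdname BinProfile-class
#' @param x A `BinProfile` or `ReferencePanel`.
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))

## ---- classes ----

#' VariantLocus: a pathogenic variant under test
#'
#' Describes the familial pathogenic variant a PGT-M cycle targets: either a
#' point variant (chrom/pos/ref/alt) or a deletion given as a 1-based
#' inclusive interval, together with its inheritance mode. The inheritance
#' mode states which parent carries the variant (`dominant_paternal`,
#' `dominant_maternal`) or that both do (`recessive_biallelic`, e.g. two
#' carrier parents of the same deletion).
#'
#' @slot chrom Chromosome name.
#' @slot kind `"point"` or `"deletion"`.
#' @slot pos 1-based position (point variants; `NA` for deletions).
#' @slot delStart,delEnd 1-based inclusive deletion interval (deletions).
#' @slot ref,alt Allele strings (point variants).
#' @slot gene Gene label.
#' @slot inheritance One of `"dominant_paternal"`, `"dominant_maternal"`,
#'   `"recessive_biallelic"`.
#'
#' @examples
#' sea <- seaDeletionLocus()
#' variantLength(sea)  # 19304
#' @name VariantLocus-class
#' @aliases VariantLocus
#' @export
setClass("VariantLocus",
  representation(
    chrom = "character", kind = "character",
    pos = "numeric", delStart = "numeric", delEnd = "numeric",
    ref = "character", alt = "character",
    gene = "character", inheritance = "character"
  ),
  prototype(
    pos = NA_real_, delStart = NA_real_, delEnd = NA_real_,
    ref = NA_character_, alt = NA_character_, gene = NA_character_
  )
)

setValidity("VariantLocus", function(object) {
  msg <- character()
  if (!object@kind %in% c("point", "deletion"))
    msg <- c(msg, "kind must be 'point' or 'deletion'")
  if (!object@inheritance %in%
      c("dominant_paternal", "dominant_maternal", "recessive_biallelic"))
    msg <- c(msg, "unknown inheritance mode")
  if (identical(object@kind, "point")) {
    if (is.na(object@pos)) msg <- c(msg, "point variant needs pos")
    if (is.na(object@ref) || is.na(object@alt) ||
        !nzchar(object@ref) || !nzchar(object@alt))
      msg <- c(msg, "point variant needs non-empty ref and alt")
  } else if (identical(object@kind, "deletion")) {
    if (is.na(object@delStart) || is.na(object@delEnd))
      msg <- c(msg, "deletion needs delStart and delEnd")
    else if (object@delEnd < object@delStart)
      msg <- c(msg, "deletion must have delEnd >= delStart")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantLocus
#'
#' @param chrom Chromosome name.
#' @param kind `"point"` or `"deletion"`.
#' @param pos 1-based position (point variants).
#' @param delStart,delEnd 1-based inclusive deletion interval.
#' @param ref,alt Allele strings (point variants).
#' @param gene Gene label.
#' @param inheritance Inheritance mode (see [VariantLocus-class]).
#' @return A [VariantLocus-class] object.
#' @export
VariantLocus <- function(chrom, kind = c("point", "deletion"),
                         pos = NA_real_, delStart = NA_real_, delEnd = NA_real_,
                         ref = NA_character_, alt = NA_character_,
                         gene = NA_character_,
                         inheritance = c("dominant_paternal",
                                         "dominant_maternal",
                                         "recessive_biallelic")) {
  kind <- match.arg(kind)
  inheritance <- match.arg(inheritance)
  new("VariantLocus", chrom = as.character(chrom), kind = kind,
      pos = as.numeric(pos), delStart = as.numeric(delStart),
      delEnd = as.numeric(delEnd), ref = ref, alt = alt,
      gene = gene, inheritance = inheritance)
}

#' The Southeast-Asian (--SEA) alpha-globin cluster deletion
#'
#' The packaged locus for the --SEA deletion of the alpha-globin gene
#' cluster on chromosome 16 (GRCh38 coordinates 165,397-184,700; inclusive
#' length 19,304 bp), removing HBA1/HBA2 and neighbouring genes. Two carrier
#' parents make the case recessive-biallelic.
#'
#' @return A [VariantLocus-class].
#' @export
seaDeletionLocus <- function() {
  VariantLocus("chr16", "deletion", delStart = 165397, delEnd = 184700,
               gene = "HBA", inheritance = "recessive_biallelic")
}

setMethod("variantLength", "VariantLocus", function(x) {
  if (x@kind == "deletion") x@delEnd - x@delStart + 1 else 1
})

setMethod("variantPosition", "VariantLocus", function(x) {
  ## deletions are located at their interval midpoint for windowing/bracketing
  if (x@kind == "deletion") (x@delStart + x@delEnd) / 2 else x@pos
})

setMethod("show", "VariantLocus", function(object) {
  loc <- if (object@kind == "deletion")
    sprintf("%s:%s-%s del (%d bp)", object@chrom,
            format(object@delStart, big.mark = ","),
            format(object@delEnd, big.mark = ","),
            as.integer(variantLength(object)))
  else
    sprintf("%s:%s %s>%s", object@chrom,
            format(object@pos, big.mark = ","), object@ref, object@alt)
  cat("VariantLocus", if (!is.na(object@gene)) sprintf("[%s]", object@gene),
      loc, "-", object@inheritance, "\n")
})

#' GeneticMap: tabulated recombination map for one chromosome
#'
#' A genetic distance map in the 3-column layout distributed with phase-3
#' reference maps: physical position (bp), local rate (cM/Mb) and cumulative
#' genetic distance (cM). Positions must be strictly increasing and the
#' cumulative cM nondecreasing.
#'
#' @slot chrom Chromosome name.
#' @slot positions Strictly increasing 1-based positions (bp).
#' @slot cumCM Nondecreasing cumulative cM.
#' @slot rateCMperMb Nonnegative local rates (cM/Mb).
#' @name GeneticMap-class
#' @aliases GeneticMap
#' @export
setClass("GeneticMap",
  representation(chrom = "character", positions = "numeric",
                 cumCM = "numeric", rateCMperMb = "numeric"))

setValidity("GeneticMap", function(object) {
  msg <- character()
  n <- length(object@positions)
  if (n < 1) msg <- c(msg, "empty map")
  if (length(object@cumCM) != n || length(object@rateCMperMb) != n)
    msg <- c(msg, "column lengths differ")
  if (n > 1) {
    if (any(diff(object@positions) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
    if (any(diff(object@cumCM) < -1e-12))
      msg <- c(msg, "cumulative cM must be nondecreasing")
  }
  if (any(object@rateCMperMb < 0)) msg <- c(msg, "negative rate")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneticMap
#'
#' @param chrom Chromosome name.
#' @param positions Strictly increasing 1-based bp positions.
#' @param cumCM Nondecreasing cumulative cM at those positions.
#' @param rateCMperMb Local rates in cM/Mb (recomputed from `cumCM` gaps if
#'   omitted).
#' @return A [GeneticMap-class].
#' @export
GeneticMap <- function(chrom, positions, cumCM, rateCMperMb = NULL) {
  o <- order(positions)
  positions <- as.numeric(positions)[o]
  cumCM <- as.numeric(cumCM)[o]
  if (is.null(rateCMperMb)) {
    rateCMperMb <- if (length(positions) > 1)
      c(diff(cumCM) / (diff(positions) / 1e6), 0) else 0
  }
  new("GeneticMap", chrom = as.character(chrom), positions = positions,
      cumCM = cumCM, rateCMperMb = as.numeric(rateCMperMb)[o])
}

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap %s: %d points, %s-%s bp, %.3f cM total\n",
              object@chrom, length(object@positions),
              format(min(object@positions), big.mark = ","),
              format(max(object@positions), big.mark = ","),
              max(object@cumCM) - min(object@cumCM)))
})

setMethod("interpolateCM", "GeneticMap", function(map, pos) {
  stats::approx(map@positions, map@cumCM, xout = pos, rule = 2,
                ties = "ordered")$y
})

#' EmissionModel: allele dropout and genotyping error rates
#'
#' Observation model for single-cell/WGA genotype calls. `adoRate` is the
#' per-site probability that one allele of a true heterozygote drops out
#' (the call collapses to a homozygote); `genotypeError` is the residual
#' symmetric call-error rate. The two must satisfy `adoRate +
#' genotypeError < 1`.
#'
#' @slot adoRate ADO rate `a` in `[0, 1)`.
#' @slot genotypeError Error rate `e` in `[0, 1)`.
#' @name EmissionModel-class
#' @aliases EmissionModel
#' @export
setClass("EmissionModel",
  representation(adoRate = "numeric", genotypeError = "numeric"),
  prototype(adoRate = 0.05, genotypeError = 0.01))

setValidity("EmissionModel", function(object) {
  a <- object@adoRate; e <- object@genotypeError
  if (length(a) != 1 || length(e) != 1 || is.na(a) || is.na(e))
    return("adoRate and genotypeError must be single numbers")
  if (a < 0 || e < 0 || a + e >= 1)
    return("need 0 <= adoRate, 0 <= genotypeError and adoRate + genotypeError < 1")
  TRUE
})

#' Construct an EmissionModel
#' @param adoRate Allele dropout rate `a` (default 0.05).
#' @param genotypeError Genotyping error rate `e` (default 0.01).
#' @return An [EmissionModel-class].
#' @export
EmissionModel <- function(adoRate = 0.05, genotypeError = 0.01) {
  new("EmissionModel", adoRate = as.numeric(adoRate),
      genotypeError = as.numeric(genotypeError))
}

setMethod("show", "EmissionModel", function(object) {
  cat(sprintf("EmissionModel: ADO a = %g, genotype error e = %g\n",
              object@adoRate, object@genotypeError))
})

setMethod("emissionProb", "EmissionModel", function(model, trueGt, obsGt) {
  a <- model@adoRate; e <- model@genotypeError
  n <- max(length(trueGt), length(obsGt))
  trueGt <- rep_len(as.integer(trueGt), n)
  obsGt <- rep_len(as.integer(obsGt), n)
  p <- numeric(n)
  miss <- is.na(obsGt)
  p[miss] <- 1
  het <- !miss & trueGt == 1L
  p[het & obsGt == 1L] <- 1 - a - e
  p[het & obsGt != 1L] <- (a + e) / 2
  hom <- !miss & trueGt != 1L
  p[hom & obsGt == trueGt] <- 1 - e
  p[hom & obsGt != trueGt] <- e / 2
  p
})

#' PhasedParents: per-marker parental haplotype assignment
#'
#' The phased parental haplotypes over the informative-marker window. For a
#' carrier parent the two haplotypes are labelled M (mutant-linked) and N
#' (normal); for a non-carrier parent they are labelled H1/H2 with H1 the
#' haplotype transmitted to the proband. Per marker and parent a provenance
#' records how the assignment was obtained: `"anchored"` (proband genotype
#' determined the transmitted allele), `"inferred"` (joint-likelihood HMM
#' refinement), `"unresolved"`, `"conflicted"` (anchor contradicted by the
#' proband's own decoded path, i.e. a possible proband crossover), or
#' `"hom"` (parent homozygous: both haplotypes carry the same allele).
#'
#' @slot markers data.frame of the informative markers (chrom, pos, ref,
#'   alt, class, insideDeletion).
#' @slot fatherHap,motherHap 2 x n allele matrices; row 1 is M (or H1),
#'   row 2 is N (or H2). `NA` where unresolved.
#' @slot fatherProv,motherProv Per-marker provenance strings.
#' @slot fatherCarrier,motherCarrier Whether that parent carries the variant.
#' @slot variant The [VariantLocus-class].
#' @slot probandId Embryo id of the proband used for anchoring.
#' @name PhasedParents-class
#' @aliases PhasedParents
#' @export
setClass("PhasedParents",
  representation(
    markers = "data.frame",
    fatherHap = "matrix", motherHap = "matrix",
    fatherProv = "character", motherProv = "character",
    fatherCarrier = "logical", motherCarrier = "logical",
    variant = "VariantLocus", probandId = "character"
  ))

setValidity("PhasedParents", function(object) {
  n <- nrow(object@markers)
  if (ncol(object@fatherHap) != n || ncol(object@motherHap) != n)
    return("haplotype matrices must have one column per marker")
  if (length(object@fatherProv) != n || length(object@motherProv) != n)
    return("provenance vectors must have one entry per marker")
  ## where a parent is het and resolved, the two haplotype alleles differ
  for (p in c("father", "mother")) {
    hap <- slot(object, paste0(p, "Hap"))
    ok <- is.na(hap[1, ]) | is.na(hap[2, ]) |
      slot(object, paste0(p, "Prov")) == "hom" | hap[1, ] != hap[2, ]
    if (!all(ok)) return(sprintf("%s: resolved het marker with equal M/N alleles", p))
  }
  TRUE
})

setMethod("markerTable", "PhasedParents", function(x) x@markers)

setMethod("show", "PhasedParents", function(object) {
  n <- nrow(object@markers)
  lab <- function(carrier) if (carrier) "carrier (M/N)" else "non-carrier (H1/H2)"
  cat(sprintf("PhasedParents: %d markers on %s, proband %s\n", n,
              object@variant@chrom, object@probandId))
  cat(sprintf("  father %s: %s\n", lab(object@fatherCarrier),
              paste(names(tb <- table(object@fatherProv)), tb,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  mother %s: %s\n", lab(object@motherCarrier),
              paste(names(tb <- table(object@motherProv)), tb,
                    sep = "=", collapse = ", ")))
})

#' InheritancePath: an embryo's decoded inheritance vector
#'
#' Viterbi decoding of which parental haplotype an embryo inherited at each
#' informative marker: per marker a paternal and a maternal indicator in
#' {M, N} (carrier parent) or {H1, H2} (non-carrier parent), crossover
#' breakpoints (indicator switches), the log-probability of the decoded
#' path and the posterior margin (log-probability gap to the second-best
#' path). Markers where the embryo's genotype is missing are flagged
#' skipped. An embryo whose decoding was impossible (all markers missing,
#' or a ploidy failure) is marked failed with a reason.
#'
#' @slot embryoId Embryo id.
#' @slot paternal,maternal Integer indicators per marker (1 = M/H1,
#'   2 = N/H2; `NA` if failed).
#' @slot skipped Logical per marker: embryo genotype missing there.
#' @slot logProb Log-probability of the Viterbi path.
#' @slot margin Log-prob gap to the second-best path (>= 0).
#' @slot breakpoints data.frame (parent, afterMarker, leftPos, rightPos).
#' @slot failed,failureReason Failure flag and reason.
#' @name InheritancePath-class
#' @aliases InheritancePath
#' @export
setClass("InheritancePath",
  representation(
    embryoId = "character",
    paternal = "integer", maternal = "integer", skipped = "logical",
    logProb = "numeric", margin = "numeric",
    breakpoints = "data.frame",
    failed = "logical", failureReason = "character"
  ),
  prototype(failed = FALSE, failureReason = NA_character_,
            margin = NA_real_))

setMethod("pathStates", "InheritancePath", function(x)
  data.frame(paternal = x@paternal, maternal = x@maternal, skipped = x@skipped))

setMethod("show", "InheritancePath", function(object) {
  if (object@failed) {
    cat(sprintf("InheritancePath %s: FAILED (%s)\n", object@embryoId,
                object@failureReason))
  } else {
    cat(sprintf(
      "InheritancePath %s: %d markers, logP = %.3f, margin = %.3f, %d breakpoint(s)\n",
      object@embryoId, length(object@paternal), object@logProb,
      object@margin, nrow(object@breakpoints)))
  }
})

#' BinProfile: sliding-window read-depth profile of one sample
#'
#' Genome-wide 400-kb windows at a 200-kb stride (half-overlapping), each
#' carrying GC fraction, blacklist-exclusion flag, raw fragment count and -
#' as the normalization stages fill them in - GC-normalized depth, log2
#' copy-number ratio against a reference panel, and Z-score.
#'
#' @slot bins A [GenomicRanges::GRanges] with metadata columns `gc`,
#'   `excluded`, `count`, `gcNorm`, `log2Ratio`, `z`.
#' @slot window,step Window width and stride (bp).
#' @slot sampleSex `"XX"`, `"XY"` or `NA`.
#' @name BinProfile-class
#' @aliases BinProfile
#' @export
setClass("BinProfile",
  representation(bins = "GRanges", window = "numeric", step = "numeric",
                 sampleSex = "character"),
  prototype(sampleSex = NA_character_))

setValidity("BinProfile", function(object) {
  if (object@step > object@window) return("step must be <= window")
  mc <- S4Vectors::mcols(object@bins)
  need <- c("gc", "excluded", "count")
  if (!all(need %in% colnames(mc)))
    return(paste("bins need mcols:", paste(need, collapse = ", ")))
  cnt <- mc$count
  if (any(!is.na(cnt) & cnt < 0)) return("negative counts")
  TRUE
})

setMethod("binGrid", "BinProfile", function(x) x@bins)

setMethod("show", "BinProfile", function(object) {
  cat(sprintf("BinProfile: %d bins (%g kb / %g kb), %d excluded, sex %s\n",
              length(object@bins), object@window / 1e3, object@step / 1e3,
              sum(S4Vectors::mcols(object@bins)$excluded), object@sampleSex))
})

#' ReferencePanel: per-bin depth statistics of control samples
#'
#' Median and standard deviation of GC-normalized depth across a panel of
#' euploid control samples, on the same bin grid as the sample profiles.
#'
#' @slot bins The bin grid (GRanges, same as the profiles it is compared to).
#' @slot med,sd Per-bin median and sd of normalized control depth.
#' @slot n Number of control samples.
#' @slot sexComposition e.g. `"XX"`, `"XY"` or `"mixed"`.
#' @name ReferencePanel-class
#' @aliases ReferencePanel
#' @export
setClass("ReferencePanel",
  representation(bins = "GRanges", med = "numeric", sd = "numeric",
                 n = "integer", sexComposition = "character"))

setValidity("ReferencePanel", function(object) {
  if (length(object@med) != length(object@bins) ||
      length(object@sd) != length(object@bins))
    return("med/sd must match bin grid length")
  if (any(!is.na(object@sd) & object@sd <= 0))
    return("sd must be > 0 on retained bins")
  TRUE
})

setMethod("binGrid", "ReferencePanel", function(x) x@bins)

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel: %d bins, %d samples (%s)\n",
              length(object@bins), object@n, object@sexComposition))
})
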
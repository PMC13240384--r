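## Phasing core: informative-marker selection around the variant, proband
## anchoring of the carrier parent's M (mutant-linked) vs N (normal)
## haplotype, recombination fractions from the genetic map, and the embryo
## ploidy gate.

#' Select informative heterozygous SNPs around the variant
#'
#' Keeps biallelic SNPs within `windowBp` up- and downstream of the variant
#' where at least one parent is heterozygous. Sites are classed
#' `paternal_only` (father het, mother hom), `maternal_only` (mother het,
#' father hom) or `double_het` (both het; retained for likelihood but unable
#' to anchor unambiguously). Sites where both parents are missing or both
#' homozygous are excluded. For deletion variants, markers inside the
#' deleted interval are flagged: a carrier embryo is hemizygous there, which
#' is what resolves the parental origin of the deletion.
#'
#' @param father,mother Parent call data.frames (chrom, pos, ref, alt, gt).
#' @param variant A [VariantLocus-class].
#' @param windowBp Window half-width in bp (default 5 Mb).
#' @return data.frame sorted by position with columns chrom, pos, ref, alt,
#'   fatherGt, motherGt, class, insideDeletion.
#' @export
selectInformativeSnps <- function(father, mother, variant, windowBp = 5e6) {
  stopifnot(nrow(father) == nrow(mother),
            all(father$pos == mother$pos))
  ctr <- variantPosition(variant)
  keep <- father$chrom == variant@chrom &
    abs(father$pos - ctr) <= windowBp
  f <- father[keep, , drop = FALSE]
  m <- mother[keep, , drop = FALSE]
  fHet <- !is.na(f$gt) & f$gt == 1L
  mHet <- !is.na(m$gt) & m$gt == 1L
  inf <- fHet | mHet
  f <- f[inf, , drop = FALSE]; m <- m[inf, , drop = FALSE]
  fHet <- fHet[inf]; mHet <- mHet[inf]
  if (!nrow(f)) stop("no informative markers in window")
  cls <- ifelse(fHet & mHet, "double_het",
                ifelse(fHet, "paternal_only", "maternal_only"))
  inside <- if (variant@kind == "deletion")
    f$pos >= variant@delStart & f$pos <= variant@delEnd
  else rep(FALSE, nrow(f))
  out <- data.frame(chrom = f$chrom, pos = f$pos, ref = f$ref, alt = f$alt,
                    fatherGt = f$gt, motherGt = m$gt, class = cls,
                    insideDeletion = inside, stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

#' Recombination fraction between two positions
#'
#' Converts the genetic-map distance between two physical positions into a
#' recombination fraction with the Haldane map function (no interference):
#' \eqn{r = (1 - e^{-2d})/2} with \eqn{d} the distance in Morgans; r is 0
#' at zero map distance and always below 0.5.
#'
#' @param map A [GeneticMap-class].
#' @param posI,posJ Physical positions with `posI < posJ`, on the map's
#'   chromosome.
#' @param chrom Optional chromosome check: error if it differs from the
#'   map's chromosome (phasing is single-region by construction).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
recombinationFraction <- function(map, posI, posJ, chrom = NULL) {
  if (!is.null(chrom) && !identical(as.character(chrom), map@chrom))
    stop("positions on chromosome ", chrom,
         " but map is for ", map@chrom)
  if (any(posJ <= posI)) stop("need posI < posJ")
  d <- abs(interpolateCM(map, posJ) - interpolateCM(map, posI)) / 100
  (1 - exp(-2 * d)) / 2
}

## ---- anchoring ------------------------------------------------------------

## transmitted parental allele deducible from a single-parent-het marker:
## het parent with alleles {ref,alt}, other parent hom. Returns the het
## parent's transmitted allele code (0=ref,1=alt) or NA if the embryo call
## is missing/Mendelian-inconsistent/ambiguous.
.transmittedAllele <- function(hetParentGt, homParentGt, embryoGt) {
  if (is.na(embryoGt) || is.na(homParentGt)) return(NA_integer_)
  homAllele <- if (homParentGt == 0L) 0L else 1L   # hom parent's allele code
  if (embryoGt == 1L) return(1L - homAllele)       # het embryo: other allele
  obs <- if (embryoGt == 0L) 0L else 1L
  if (obs != homAllele) return(NA_integer_)        # inconsistent (ADO/error)
  obs                                              # hom embryo: same allele
}

#' Anchor the parental M/N haplotypes using a proband embryo
#'
#' The proband is an embryo whose direct mutation test (Sanger or Gap-PCR)
#' shows it carries the variant. At every marker where the carrier parent is
#' heterozygous and the other parent homozygous, the proband's genotype
#' identifies which parental allele was transmitted; under the
#' no-recombination-in-window assumption that transmitted allele is labelled
#' M (mutant-linked) and the other N. The non-carrier parent's transmitted
#' haplotype is labelled H1. For recessive deletion cases the parental
#' origin of the proband's deletion is first resolved from markers inside
#' the deleted interval, where a carrier proband is hemizygous (see
#' Details).
#'
#' @details For a `recessive_biallelic` deletion with a carrier proband, at
#' an inside-deletion marker the proband shows only the allele of the
#' parent whose chromosome is *not* deleted. Under the paternal-deletion
#' hypothesis the observed call must match the maternal contribution, and
#' vice versa; the hypothesis consistent with the most inside-deletion
#' informative markers wins. An affected proband (both deletions) anchors
#' both parents directly at outside markers. If origin cannot be resolved
#' (no inside-deletion markers, no affected embryo), an error lists the
#' evidence that would be needed.
#'
#' @param snps Marker table from [selectInformativeSnps()].
#' @param probandCalls Proband call data.frame (chrom, pos, ref, alt, gt).
#' @param probandTest A direct-test row (list/data.frame with `embryo_id`,
#'   `call`); the call must be `carrier` or `affected`.
#' @param variant A [VariantLocus-class].
#' @return A [PhasedParents-class] with provenance `anchored` at anchorable
#'   markers and `unresolved` elsewhere.
#' @export
anchorParentalPhase <- function(snps, probandCalls, probandTest, variant) {
  call <- probandTest$call
  if (!call %in% c("carrier", "affected"))
    stop("proband does not carry the variant (direct test: ", call, ")")
  n <- nrow(snps)
  egt <- .alignCalls(probandCalls, snps)
  inh <- variant@inheritance
  fatherCarrier <- inh %in% c("dominant_paternal", "recessive_biallelic")
  motherCarrier <- inh %in% c("dominant_maternal", "recessive_biallelic")

  ## which parent's variant copy does the proband carry?
  ## dominant: the single carrier parent. recessive affected: both.
  ## recessive carrier: resolve origin from inside-deletion hemizygosity (D5).
  probandHasPat <- fatherCarrier
  probandHasMat <- motherCarrier
  if (inh == "recessive_biallelic" && call == "carrier") {
    ori <- .resolveDeletionOrigin(snps, egt)
    probandHasPat <- ori == "paternal"
    probandHasMat <- ori == "maternal"
  }

  codeAllele <- function(code, ref, alt) ifelse(code == 1L, alt, ref)
  fatherHap <- matrix(NA_character_, 2, n)
  motherHap <- matrix(NA_character_, 2, n)
  fatherProv <- rep("unresolved", n)
  motherProv <- rep("unresolved", n)

  for (k in seq_len(n)) {
    fgt <- snps$fatherGt[k]; mgt <- snps$motherGt[k]
    ref <- snps$ref[k]; alt <- snps$alt[k]
    fHet <- !is.na(fgt) && fgt == 1L
    mHet <- !is.na(mgt) && mgt == 1L
    if (!fHet && !is.na(fgt)) {
      fatherHap[, k] <- codeAllele(if (fgt == 0L) 0L else 1L, ref, alt)
      fatherProv[k] <- "hom"
    }
    if (!mHet && !is.na(mgt)) {
      motherHap[, k] <- codeAllele(if (mgt == 0L) 0L else 1L, ref, alt)
      motherProv[k] <- "hom"
    }
    if (snps$insideDeletion[k]) next   # hemizygous in proband: no anchor here
    if (snps$class[k] == "paternal_only" && fHet) {
      t <- .transmittedAllele(fgt, mgt, egt[k])
      if (!is.na(t)) {
        trans <- codeAllele(t, ref, alt); other <- codeAllele(1L - t, ref, alt)
        ## transmitted allele is M if the proband carries father's variant copy
        if (fatherCarrier) {
          fatherHap[, k] <- if (probandHasPat) c(trans, other) else c(other, trans)
        } else {
          fatherHap[, k] <- c(trans, other)   # H1 = transmitted-to-proband
        }
        fatherProv[k] <- "anchored"
      }
    } else if (snps$class[k] == "maternal_only" && mHet) {
      t <- .transmittedAllele(mgt, fgt, egt[k])
      if (!is.na(t)) {
        trans <- codeAllele(t, ref, alt); other <- codeAllele(1L - t, ref, alt)
        if (motherCarrier) {
          motherHap[, k] <- if (probandHasMat) c(trans, other) else c(other, trans)
        } else {
          motherHap[, k] <- c(trans, other)
        }
        motherProv[k] <- "anchored"
      }
    }
    ## double_het: no unambiguous anchor (D3); left unresolved here
  }

  new("PhasedParents", markers = snps,
      fatherHap = fatherHap, motherHap = motherHap,
      fatherProv = fatherProv, motherProv = motherProv,
      fatherCarrier = fatherCarrier, motherCarrier = motherCarrier,
      variant = variant,
      probandId = as.character(probandTest$embryo_id %||% "proband"))
}

## Decide which parent's deletion a recessive carrier proband carries, from
## inside-deletion markers where the proband is hemizygous: under a
## paternal-origin deletion the proband shows only the maternal allele, so
## at father-het/mother-hom markers the observation must equal the mother's
## allele (and at mother-het/father-hom markers it is the mother's
## transmitted allele, either with probability 1/2); symmetrically for a
## maternal-origin deletion. The two hypotheses are compared by log
## likelihood with a small mismatch rate absorbing genotyping error.
## Returns "paternal" or "maternal"; errors when the evidence is absent.
.resolveDeletionOrigin <- function(snps, probandGt, mismatch = 0.05) {
  idx <- which(snps$insideDeletion & !is.na(probandGt) &
               snps$class %in% c("paternal_only", "maternal_only"))
  idx <- idx[probandGt[idx] != 1L]  # het calls are not hemizygous-consistent
  if (!length(idx))
    stop("cannot resolve parental origin of the deletion: no informative ",
         "inside-deletion markers with hemizygous proband calls; an ",
         "affected embryo (carrying both deletions) or inside-deletion ",
         "coverage is needed")
  lpPat <- 0; lpMat <- 0
  for (k in idx) {
    obs <- if (probandGt[k] == 0L) 0L else 1L
    fgt <- snps$fatherGt[k]; mgt <- snps$motherGt[k]
    if (snps$class[k] == "paternal_only") {
      momAllele <- if (mgt == 0L) 0L else 1L
      lpPat <- lpPat + log(if (obs == momAllele) 1 - mismatch else mismatch)
      lpMat <- lpMat + log(0.5)  # father het: either allele transmitted
    } else {
      dadAllele <- if (fgt == 0L) 0L else 1L
      lpMat <- lpMat + log(if (obs == dadAllele) 1 - mismatch else mismatch)
      lpPat <- lpPat + log(0.5)
    }
  }
  if (abs(lpPat - lpMat) < 1e-9)
    stop("cannot resolve parental origin of the deletion: inside-deletion ",
         "evidence is tied; more inside-deletion coverage or an affected ",
         "embryo is needed")
  if (lpPat > lpMat) "paternal" else "maternal"
}

## ---- ploidy gate ----------------------------------------------------------

#' Build a trio marker table from two parents' calls (no window filter)
#'
#' Same bookkeeping as [selectInformativeSnps()] but genome-wide and
#' without a variant: used to feed QC markers on other chromosomes into
#' [detectPloidyFailure()].
#'
#' @param father,mother Parent call data.frames over identical sites.
#' @return data.frame (chrom, pos, ref, alt, fatherGt, motherGt, class,
#'   insideDeletion = FALSE), sites with at least one non-missing parent.
#' @export
trioMarkerTable <- function(father, mother) {
  stopifnot(nrow(father) == nrow(mother), all(father$pos == mother$pos))
  keep <- !is.na(father$gt) & !is.na(mother$gt)
  f <- father[keep, , drop = FALSE]; m <- mother[keep, , drop = FALSE]
  cls <- ifelse(f$gt == 1L & m$gt == 1L, "double_het",
                ifelse(f$gt == 1L, "paternal_only",
                       ifelse(m$gt == 1L, "maternal_only", "both_hom")))
  data.frame(chrom = f$chrom, pos = f$pos, ref = f$ref, alt = f$alt,
             fatherGt = f$gt, motherGt = m$gt, class = cls,
             insideDeletion = FALSE, stringsAsFactors = FALSE)
}

#' Detect embryo ploidy failure in the phasing window
#'
#' Haplotyping assumes a biparental diploid embryo. Failure is declared
#' when (a) the CNV module reports a non-disomic call overlapping the
#' window, (b) more than 10% of markers with complete trio genotypes
#' violate biparental diploid Mendelian consistency (catches monosomy:
#' the embryo lacks one parent's obligate allele), or (c) the embryo shows
#' a heterozygosity excess consistent with inheriting both haplotypes of
#' one parent (triploidy/heterodisomy): at markers where exactly one parent
#' is het, a disomic embryo is het about half the time, while an embryo
#' with both of that parent's haplotypes is het essentially always.
#'
#' @param snps Marker table from [selectInformativeSnps()].
#' @param embryoCalls Embryo call data.frame.
#' @param cnvSegments Optional classified segment data.frame (from
#'   [classifySegments()]) for this embryo.
#' @param variant Optional [VariantLocus-class]; used with `cnvSegments` to
#'   test overlap with the variant chromosome.
#' @param mendelianThreshold Failure threshold on the violating fraction
#'   (default 0.10).
#' @param hetExcessThreshold Het fraction at one-parent-het markers above
#'   which heterodisomy is called (default 0.9, needs >= 10 such markers).
#' @return list(ok = logical, reason = character or NA, stats = list).
#' @export
detectPloidyFailure <- function(snps, embryoCalls, cnvSegments = NULL,
                                variant = NULL, mendelianThreshold = 0.10,
                                hetExcessThreshold = 0.9) {
  fail <- function(reason, stats = list())
    list(ok = FALSE, reason = reason, stats = stats)

  if (!is.null(cnvSegments) && nrow(cnvSegments)) {
    seg <- cnvSegments[cnvSegments$class %in% c("gain", "loss"), , drop = FALSE]
    if (!is.null(variant) && nrow(seg)) {
      hit <- seg$chrom == variant@chrom &
        seg$scope %in% c("whole_chromosome", "whole_arm")
      if (any(hit))
        return(fail(paste0("non-disomic CNV call on ", variant@chrom)))
    }
  }

  egt <- .alignCalls(embryoCalls, snps)
  full <- !is.na(egt) & !is.na(snps$fatherGt) & !is.na(snps$motherGt)
  if (!any(full)) return(fail("no complete trio genotypes in window"))

  ## Mendelian consistency under biparental diploidy: the embryo must be
  ## explainable as one allele from each parent. Evaluated per chromosome
  ## (a variant-chromosome monosomy should not be diluted by QC markers
  ## elsewhere) with a minimum of 10 complete markers per group.
  possible <- function(pgt) if (pgt == 1L) c(0L, 1L) else if (pgt == 0L) 0L else 1L
  viol <- vapply(seq_len(nrow(snps)), function(k) {
    if (!full[k]) return(NA)
    fa <- possible(snps$fatherGt[k]); mo <- possible(snps$motherGt[k])
    !(egt[k] %in% unique(as.vector(outer(fa, mo, "+"))))
  }, logical(1))
  stats <- list()
  for (ch in unique(snps$chrom)) {
    idx <- which(full & snps$chrom == ch)
    if (length(idx) < 10) next
    mendFrac <- mean(viol[idx])
    stats[[paste0("mendelianFraction.", ch)]] <- mendFrac
    if (mendFrac > mendelianThreshold)
      return(fail(sprintf(
        "Mendelian inconsistency %.1f%% on %s (monosomy-consistent)",
        100 * mendFrac, ch), stats))
  }

  ## heterodisomy signature: at markers where exactly one parent is het,
  ## an embryo carrying both of that parent's haplotypes is het nearly
  ## always instead of half the time; tested per chromosome and parent
  for (p in c("paternal", "maternal")) {
    cls <- if (p == "paternal") "paternal_only" else "maternal_only"
    for (ch in unique(snps$chrom)) {
      idx <- which(full & snps$class == cls & snps$chrom == ch)
      if (length(idx) < 10) next
      hetFrac <- mean(egt[idx] == 1L)
      stats[[paste0(p, "HetFraction.", ch)]] <- hetFrac
      if (hetFrac >= hetExcessThreshold)
        return(fail(sprintf(
          "heterozygosity excess on %s markers of %s (%.0f%%; triploid-consistent)",
          p, ch, 100 * hetFrac), stats))
    }
  }
  list(ok = TRUE, reason = NA_character_, stats = stats)
}
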
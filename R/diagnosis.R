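## Reconciliation of haplotype-based calls with direct mutation detection
## into a final per-embryo status.

.SEVERITY <- c(wild_type = 1, carrier = 2, affected = 3)

#' Haplotype-based genotype call at the variant
#'
#' Reads the decoded inheritance indicator in the marker interval
#' containing the variant: for each carrier parent, the two nearest
#' anchorable flanking markers (provenance `anchored` or `inferred`,
#' outside any deletion interval) must agree on M vs N; disagreement means
#' a possible crossover between them and the variant, which sets the
#' `recombination_in_window` flag and yields `failure`. Dominant cases map
#' carrier-parent M to `carrier` and N to `wild_type`; recessive-biallelic
#' cases count M haplotypes from both parents (2 = `affected`, 1 =
#' `carrier`, 0 = `wild_type`).
#'
#' @param path An [InheritancePath-class].
#' @param variant A [VariantLocus-class].
#' @param phased The refined [PhasedParents-class].
#' @return list(call, flags) with call in wild_type/carrier/affected/failure
#'   and flags a character vector.
#' @export
haplotypeCallFromPath <- function(path, variant, phased) {
  if (path@failed)
    return(list(call = "failure", flags = "haplotype_failure"))
  mk <- phased@markers
  vpos <- variantPosition(variant)

  consensus <- function(ind, prov) {
    usable <- which(prov %in% c("anchored", "inferred") & !mk$insideDeletion &
                    !path@skipped)
    if (!length(usable)) return(list(ind = NA_integer_, flag = "no_usable_markers"))
    lo <- usable[mk$pos[usable] < vpos]
    hi <- usable[mk$pos[usable] > vpos]
    if (!length(lo) || !length(hi))
      stop("variant not bracketed by informative markers")
    l <- lo[which.max(mk$pos[lo])]
    h <- hi[which.min(mk$pos[hi])]
    if (ind[l] != ind[h])
      return(list(ind = NA_integer_, flag = "recombination_in_window"))
    list(ind = ind[l], flag = NULL)
  }

  flags <- character()
  nM <- 0L
  carriers <- c(if (phased@fatherCarrier) "father",
                if (phased@motherCarrier) "mother")
  for (p in carriers) {
    ind <- if (p == "father") path@paternal else path@maternal
    prov <- slot(phased, paste0(p, "Prov"))
    cs <- consensus(ind, prov)
    if (!is.null(cs$flag)) flags <- c(flags, cs$flag)
    if (is.na(cs$ind))
      return(list(call = "failure", flags = unique(flags)))
    if (cs$ind == 1L) nM <- nM + 1L
  }
  call <- if (variant@inheritance == "recessive_biallelic") {
    c("wild_type", "carrier", "affected")[nM + 1L]
  } else {
    if (nM >= 1L) "carrier" else "wild_type"
  }
  list(call = call, flags = unique(flags))
}

#' Reconcile haplotype and direct-test calls for one embryo
#'
#' Agreement yields the shared call. A failed direct test falls back on the
#' haplotype call with `ado_suspect` set; a failed haplotype call (including
#' ploidy failures) falls back on the direct call annotated with the failure
#' flag. When both succeed but disagree, the more severe call (affected >
#' carrier > wild_type) is reported, never silently the milder one, and
#' `ado_suspect` (direct test milder) or `recombination_in_window`
#' (haplotype milder) is set.
#'
#' @param haplotypeCall One of wild_type/carrier/affected/failure.
#' @param direct A direct-test row (list with `call`, optionally `method`).
#' @param ploidyOk Logical: did the embryo pass the ploidy gate?
#' @param cnvFlag `"normal"` or `"abnormal"`.
#' @param flags Character vector of flags carried in from decoding.
#' @return list(final, flags).
#' @export
reconcileDiagnosis <- function(haplotypeCall, direct, ploidyOk = TRUE,
                               cnvFlag = "normal", flags = character()) {
  dcall <- direct$call
  hFail <- haplotypeCall == "failure"
  dFail <- dcall == "failed"
  if (!ploidyOk) flags <- c(flags, "ploidy_failure")
  final <-
    if (hFail && dFail) {
      flags <- c(flags, "haplotype_failure")
      "failure"
    } else if (hFail) {
      ## ploidy_failure / recombination_in_window already explain the
      ## failure when set; otherwise record a generic haplotype failure
      if (ploidyOk && !"recombination_in_window" %in% flags)
        flags <- c(flags, "haplotype_failure")
      dcall
    } else if (dFail) {
      flags <- c(flags, "ado_suspect")
      haplotypeCall
    } else if (haplotypeCall == dcall) {
      dcall
    } else {
      ## disagreement: report the more severe call, flag the cause
      flags <- c(flags,
                 if (.SEVERITY[dcall] < .SEVERITY[haplotypeCall])
                   "ado_suspect" else "recombination_in_window")
      names(.SEVERITY)[max(.SEVERITY[c(dcall, haplotypeCall)])]
    }
  list(final = final, flags = unique(flags[!is.na(flags)]))
}

#' Diagnose a set of embryos
#'
#' End-of-pipeline assembly: for each embryo, the haplotype call at the
#' variant (after the ploidy gate), the direct mutation test and the CNV
#' flag are reconciled into a final status row.
#'
#' @param paths Named list of [InheritancePath-class] (from [decodePaths()]).
#' @param phased Refined [PhasedParents-class].
#' @param variant A [VariantLocus-class].
#' @param directTests data.frame from [readDirectTests()].
#' @param ploidy Named list of ploidy-gate results per embryo (from
#'   [detectPloidyFailure()]); missing entries are treated as ok.
#' @param cnvFlags Named character vector `"normal"`/`"abnormal"` per embryo.
#' @return data.frame with columns embryo_id, cnv_flag, direct_call,
#'   proband_id, haplotype_call, final_status, flags.
#' @export
diagnoseEmbryos <- function(paths, phased, variant, directTests,
                            ploidy = list(), cnvFlags = character()) {
  rows <- lapply(names(paths), function(id) {
    direct <- directTests[directTests$embryo_id == id, , drop = FALSE]
    if (!nrow(direct)) direct <- data.frame(call = "failed")
    pl <- ploidy[[id]]
    ok <- is.null(pl) || isTRUE(pl$ok)
    if (!ok) {
      hc <- list(call = "failure", flags = character())
    } else {
      hc <- haplotypeCallFromPath(paths[[id]], variant, phased)
    }
    rec <- reconcileDiagnosis(hc$call, direct, ploidyOk = ok,
                              flags = hc$flags)
    data.frame(embryo_id = id,
               cnv_flag = if (id %in% names(cnvFlags))
                 unname(cnvFlags[id]) else NA_character_,
               direct_call = direct$call,
               proband_id = phased@probandId,
               haplotype_call = hc$call,
               final_status = rec$final,
               flags = paste(rec$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
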
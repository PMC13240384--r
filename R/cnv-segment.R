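## CNV module, stage 3: circular binary segmentation of the log2-ratio
## profile and classification of segments under the reporting rules.

#' Estimated aberrant-cell fraction of an intermediate copy state
#'
#' Interprets a segment's mean log2 ratio `L` as a mixture of diploid and
#' single-copy-aberrant cells: a gain at cell fraction `v` has expected
#' ratio `(2 + v)/2`, a loss `(2 - v)/2`, giving `level = 2 (2^L - 1)` for
#' gains and `2 (1 - 2^L)` for losses. `mosaicLevel` and `levelToLog2`
#' are exact inverses on `level` in `(0, 1)`; a full single-copy event
#' (`L = log2(3/2)` or `-1`) maps to level 1.
#'
#' @param L Mean log2 ratio.
#' @param direction `"gain"` or `"loss"`.
#' @return Estimated level (clamped to `[0, 1]` by `mosaicLevel`).
#' @export
mosaicLevel <- function(L, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  v <- if (direction == "gain") 2 * (2^L - 1) else 2 * (1 - 2^L)
  pmin(pmax(v, 0), 1)
}

#' @rdname mosaicLevel
#' @param level Aberrant-cell fraction in `(0, 1)`.
#' @export
levelToLog2 <- function(level, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (direction == "gain") log2(1 + level / 2) else log2(1 - level / 2)
}

## recursive CBS on one chromosome's retained log2 values; returns a
## data.frame of (from, to) index pairs into x
.cbsRecurse <- function(x, alpha, nPerm, minArc) {
  n <- length(x)
  if (n < 4) return(data.frame(from = 1L, to = n))
  obs <- .cbsScan(x, minArc)
  if (obs$stat <= 0) return(data.frame(from = 1L, to = n))
  ## permutation p-value with early rejection: once the exceedance count
  ## guarantees p >= alpha the split cannot be accepted
  stopAt <- ceiling(alpha * (1 + nPerm))
  exceed <- 0L
  done <- 0L
  while (done < nPerm && exceed < stopAt) {
    perm <- .cbsScan(sample(x), minArc)
    if (perm$stat >= obs$stat - 1e-12) exceed <- exceed + 1L
    done <- done + 1L
  }
  ## early-stopped: p >= alpha by construction
  p <- if (exceed >= stopAt) 1 else (1 + exceed) / (1 + nPerm)
  if (p >= alpha) return(data.frame(from = 1L, to = n))
  i <- obs$i; j <- obs$j
  pieces <- list()
  if (i > 0) pieces <- c(pieces, list(c(1L, i)))
  pieces <- c(pieces, list(c(i + 1L, j)))
  if (j < n) pieces <- c(pieces, list(c(j + 1L, n)))
  out <- lapply(pieces, function(pc) {
    sub <- .cbsRecurse(x[pc[1]:pc[2]], alpha, nPerm, minArc)
    sub$from <- sub$from + pc[1] - 1L
    sub$to <- sub$to + pc[1] - 1L
    sub
  })
  do.call(rbind, out)
}

#' Circular binary segmentation of a log2-ratio profile
#'
#' Recursive CBS per chromosome: each segment is scanned for the arc
#' maximizing the circular two-sample t statistic between arc and
#' complement; the split is accepted when its permutation p-value is below
#' `alpha` (seeded, so segmentation is deterministic given the seed), and
#' the procedure recurses into the resulting pieces. Adjacent segments
#' whose means differ by less than `mergeThreshold` are re-merged.
#' Chromosomes with fewer than 4 retained bins yield a single segment.
#'
#' @param profile A [BinProfile-class] with `log2Ratio` filled.
#' @param alpha Permutation acceptance level (default 0.01).
#' @param nPerm Number of permutations (default 1000).
#' @param seed RNG seed for the permutations (default 1).
#' @param mergeThreshold Re-merge threshold on adjacent segment mean
#'   difference (default 0.1).
#' @param minArc Minimum arc length in bins (default 2).
#' @return data.frame with columns chrom, start, end, n_bins, mean_log2,
#'   z (mean Z-score across the segment's bins).
#' @export
cbsSegment <- function(profile, alpha = 0.01, nPerm = 1000, seed = 1,
                       mergeThreshold = 0.1, minArc = 2) {
  b <- profile@bins
  mc <- S4Vectors::mcols(b)
  keep <- !mc$excluded & !is.na(mc$log2Ratio)
  chroms <- unique(as.character(GenomicRanges::seqnames(b)))
  set.seed(seed)
  segs <- lapply(chroms, function(ch) {
    idx <- which(keep & as.character(GenomicRanges::seqnames(b)) == ch)
    if (!length(idx)) return(NULL)
    x <- mc$log2Ratio[idx]
    d <- .cbsRecurse(x, alpha, nPerm, minArc)
    ## merge adjacent segments with similar means
    repeat {
      if (nrow(d) < 2) break
      means <- vapply(seq_len(nrow(d)), function(r)
        mean(x[d$from[r]:d$to[r]]), numeric(1))
      dm <- abs(diff(means))
      w <- which(dm < mergeThreshold)
      if (!length(w)) break
      r <- w[which.min(dm[w])]
      d$to[r] <- d$to[r + 1]
      d <- d[-(r + 1), , drop = FALSE]
    }
    data.frame(
      chrom = ch,
      start = GenomicRanges::start(b)[idx[d$from]],
      end = GenomicRanges::end(b)[idx[d$to]],
      n_bins = d$to - d$from + 1L,
      mean_log2 = vapply(seq_len(nrow(d)), function(r)
        mean(mc$log2Ratio[idx[d$from[r]:d$to[r]]]), numeric(1)),
      z = vapply(seq_len(nrow(d)), function(r)
        mean(mc$z[idx[d$from[r]:d$to[r]]], na.rm = TRUE), numeric(1)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
}

#' Classify CBS segments under the reporting rules
#'
#' A segment whose absolute mean log2 ratio exceeds the reporting
#' threshold (0.25) is a gain or loss; it is reported when it spans a
#' whole chromosome or whole arm (at least 90% of that unit's retained
#' bins) or is segmental with length at least 4 Mb supported by at least
#' 20 consecutive bins. A segment with absolute mean log2 ratio between
#' 0.1 and 0.25, length at least 10 Mb and estimated aberrant-cell level
#' above 30% is a mosaic gain/loss. Everything else is
#' neutral. Every reported segment carries its estimated level (1 for full
#' single-copy events).
#'
#' @param segments data.frame from [cbsSegment()].
#' @param profile The segmented [BinProfile-class] (for per-chromosome
#'   retained-bin counts).
#' @param armTable Optional data.frame (chrom, centromere) giving arm
#'   boundaries; without it whole-arm scope is not assessed.
#' @param log2Threshold,minSegmentBp,minSegmentBins,mosaicMinBp,mosaicMinLevel
#'   Reporting thresholds (defaults 0.25, 4e6, 20, 1e7, 0.30).
#' @param wholeFraction Bin-coverage fraction defining whole-chromosome /
#'   whole-arm scope (default 0.9).
#' @return `segments` with added columns class (gain/loss/mosaic_gain/
#'   mosaic_loss/neutral), scope (whole_chromosome/whole_arm/segmental)
#'   and level.
#' @export
classifySegments <- function(segments, profile, armTable = NULL,
                             log2Threshold = 0.25, minSegmentBp = 4e6,
                             minSegmentBins = 20, mosaicMinBp = 1e7,
                             mosaicMinLevel = 0.30, wholeFraction = 0.9) {
  if (is.null(segments) || !nrow(segments)) return(segments)
  b <- profile@bins
  mc <- S4Vectors::mcols(b)
  keep <- !mc$excluded & !is.na(mc$log2Ratio)
  chrom <- as.character(GenomicRanges::seqnames(b))
  nKeep <- table(chrom[keep])

  segments$class <- "neutral"
  segments$scope <- "segmental"
  segments$level <- NA_real_
  for (r in seq_len(nrow(segments))) {
    L <- segments$mean_log2[r]
    len <- segments$end[r] - segments$start[r] + 1
    dirn <- if (L > 0) "gain" else "loss"
    chromBins <- nKeep[[segments$chrom[r]]]
    scope <- "segmental"
    if (segments$n_bins[r] >= wholeFraction * chromBins) {
      scope <- "whole_chromosome"
    } else if (!is.null(armTable)) {
      cen <- armTable$centromere[match(segments$chrom[r], armTable$chrom)]
      if (!is.na(cen)) {
        armOf <- ifelse(GenomicRanges::start(b) < cen, "p", "q")
        for (arm in c("p", "q")) {
          armIdx <- which(keep & chrom == segments$chrom[r] & armOf == arm)
          if (!length(armIdx)) next
          inSeg <- GenomicRanges::start(b)[armIdx] >= segments$start[r] &
            GenomicRanges::end(b)[armIdx] <= segments$end[r]
          if (mean(inSeg) >= wholeFraction) scope <- "whole_arm"
        }
      }
    }
    if (abs(L) > log2Threshold) {
      reportable <- scope %in% c("whole_chromosome", "whole_arm") ||
        (len >= minSegmentBp && segments$n_bins[r] >= minSegmentBins)
      if (reportable) {
        segments$class[r] <- dirn
        segments$level[r] <- mosaicLevel(L, dirn)
        segments$scope[r] <- scope
      }
    } else if (abs(L) > 0.1 && len >= mosaicMinBp) {
      lev <- mosaicLevel(L, dirn)
      if (lev > mosaicMinLevel) {
        segments$class[r] <- paste0("mosaic_", dirn)
        segments$level[r] <- lev
        segments$scope[r] <- scope
      }
    }
  }
  segments
}

#' One-call CNV pipeline for a sample profile
#'
#' GC normalization, panel log2 ratios / Z-scores, CBS segmentation and
#' classification in sequence.
#'
#' @param profile A raw [BinProfile-class] (counts + gc filled).
#' @param panel A [ReferencePanel-class].
#' @param armTable Optional arm table for [classifySegments()].
#' @param alpha,nPerm,seed CBS parameters.
#' @param ... Further thresholds passed to [classifySegments()].
#' @return list(profile = completed profile, segments = classified
#'   segment data.frame).
#' @export
callCnv <- function(profile, panel, armTable = NULL, alpha = 0.01,
                    nPerm = 1000, seed = 1, ...) {
  profile <- gcNormalize(profile)
  profile <- log2RatioZ(profile, panel)
  segs <- cbsSegment(profile, alpha = alpha, nPerm = nPerm, seed = seed)
  segs <- classifySegments(segs, profile, armTable = armTable, ...)
  list(profile = profile, segments = segs)
}
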
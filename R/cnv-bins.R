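## CNV module, stage 1: sliding-window binning of the genome.

#' Build the sliding-window bin grid
#'
#' Tiles each chromosome with half-overlapping windows (default 400 kb at a
#' 200-kb stride). A final partial bin is kept only when it is at least one
#' stride wide *and* extends beyond the last full bin's end (otherwise it
#' adds no coverage). A bin is excluded when more than half its width
#' intersects the blacklist (poor-mappability regions: satellite repeats,
#' centromeres, telomeres). A chromosome shorter than one window becomes a
#' single full-chromosome bin, with a warning.
#'
#' @param chromSizes Named numeric vector of chromosome lengths (bp).
#' @param window Window width in bp (default 400,000).
#' @param step Stride in bp (default 200,000).
#' @param blacklist Optional `GRanges` of excluded regions (1-based
#'   inclusive, e.g. from [readBlacklist()]).
#' @param exclusionFraction Overlap fraction above which a bin is excluded
#'   (default 0.5).
#' @return A `GRanges` with metadata columns `gc` (NA until filled),
#'   `excluded`, `count` (NA until filled).
#' @export
makeBins <- function(chromSizes, window = 400000, step = 200000,
                     blacklist = NULL, exclusionFraction = 0.5) {
  stopifnot(window >= step, !is.null(names(chromSizes)))
  pieces <- lapply(names(chromSizes), function(ch) {
    L <- chromSizes[[ch]]
    if (L < window) {
      warning("chromosome ", ch, " (", L, " bp) shorter than one window; ",
              "using a single full-chromosome bin")
      return(GenomicRanges::GRanges(ch, IRanges::IRanges(1, L)))
    }
    starts <- seq(1, L - window + 1, by = step)
    ends <- starts + window - 1
    lastEnd <- ends[length(ends)]
    partialStart <- starts[length(starts)] + step
    if (partialStart <= L && L - partialStart + 1 >= step && L > lastEnd) {
      starts <- c(starts, partialStart)
      ends <- c(ends, L)
    }
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends))
  })
  bins <- suppressWarnings(do.call(c, pieces))
  excluded <- rep(FALSE, length(bins))
  if (!is.null(blacklist) && length(blacklist)) {
    ov <- GenomicRanges::findOverlaps(bins, blacklist)
    if (length(ov)) {
      inter <- IRanges::pintersect(bins[S4Vectors::queryHits(ov)],
                                   blacklist[S4Vectors::subjectHits(ov)])
      cov <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(cov))
      excluded[idx] <- cov / GenomicRanges::width(bins)[idx] > exclusionFraction
    }
  }
  S4Vectors::mcols(bins)$gc <- NA_real_
  S4Vectors::mcols(bins)$excluded <- excluded
  S4Vectors::mcols(bins)$count <- NA_integer_
  bins
}

#' Assemble a BinProfile from a grid, GC track and fragment counts
#'
#' @param bins Bin grid from [makeBins()].
#' @param gc Per-bin GC fraction in `[0, 1]`.
#' @param counts Per-bin raw fragment counts (e.g. from [countFragments()]).
#' @param window,step The grid's window/stride (bp).
#' @param sampleSex `"XX"`, `"XY"` or NA.
#' @return A [BinProfile-class].
#' @export
binProfile <- function(bins, gc, counts, window = 400000, step = 200000,
                       sampleSex = NA_character_) {
  if (!"excluded" %in% colnames(S4Vectors::mcols(bins)))
    S4Vectors::mcols(bins)$excluded <- FALSE
  S4Vectors::mcols(bins)$gc <- gc
  S4Vectors::mcols(bins)$count <- as.integer(counts)
  S4Vectors::mcols(bins)$gcNorm <- NA_real_
  S4Vectors::mcols(bins)$log2Ratio <- NA_real_
  S4Vectors::mcols(bins)$z <- NA_real_
  new("BinProfile", bins = bins, window = window, step = step,
      sampleSex = sampleSex)
}
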
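test_that("bin grid enumeration matches the hand-derived layout", {
  bins <- makeBins(c(chr1 = 1e6), 400000, 200000)
  expect_equal(GenomicRanges::start(bins), c(1, 200001, 400001, 600001))
  expect_equal(GenomicRanges::end(bins)[4], 1e6)   # last full window
  ## a longer chromosome keeps its >= step-wide partial end bin
  bins2 <- makeBins(c(chr1 = 1.1e6), 400000, 200000)
  expect_equal(GenomicRanges::start(bins2)[5], 800001)
  expect_equal(GenomicRanges::end(bins2)[5], 1.1e6)
  ## short chromosome: one full-chromosome bin, warned
  expect_warning(b3 <- makeBins(c(chrS = 3e5), 400000, 200000), "shorter")
  expect_equal(length(b3), 1)
  expect_equal(GenomicRanges::width(b3), 3e5)
})

test_that("bin totals follow the closed form over a genome-scale size set", {
  sizes <- setNames(round(seq(2.49e8, 4.7e7, length.out = 24)),
                    paste0("chr", 1:24))   # ~3.1 Gb total
  bins <- makeBins(sizes, 400000, 200000)
  closed <- sum(vapply(sizes, function(L) {
    full <- floor((L - 400000) / 200000) + 1
    lastEnd <- (full - 1) * 200000 + 400000
    full + as.integer(L > lastEnd && (L - (full * 200000 + 1) + 1) >= 200000)
  }, numeric(1)))
  expect_equal(length(bins), closed)
  expect_equal(length(bins), sum(sizes) / 200000, tolerance = 0.01)
  ## the 4 Mb minimum segmental length spans exactly 20 bin strides
  cfg <- runConfig()
  expect_equal(cfg$minSegmentBp / cfg$cnvStep, 20)
  expect_equal(cfg$minSegmentBins, 20)
})

test_that("bins mostly covered by the blacklist are excluded", {
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400000))
  bins <- makeBins(c(chr1 = 2e6), 400000, 200000, blacklist = bl)
  ex <- S4Vectors::mcols(bins)$excluded
  expect_true(ex[1])            # fully covered
  expect_false(ex[2])           # 50% covered: not > 50%
  expect_false(any(ex[-(1:2)]))
})

test_that("LOESS normalization removes an imposed smooth GC bias", {
  set.seed(41)
  bins <- makeBins(setNames(rep(1e8, 6), paste0("chr", 1:6)), 400000, 200000)
  nb <- length(bins)
  gc <- rbeta(nb, 50, 70)
  bias <- exp(-((gc - 0.45)^2) / (2 * 0.07^2))
  counts <- rpois(nb, 300 * bias)
  pr <- gcNormalize(binProfile(bins, gc, counts))
  mc <- S4Vectors::mcols(pr@bins)
  ok <- !is.na(mc$gcNorm)
  expect_gt(abs(cor(mc$count[ok], mc$gc[ok])), 0.3)      # bias was real
  expect_lt(abs(cor(mc$gcNorm[ok], mc$gc[ok])), 0.05)    # and is gone
  ## flat bias: normalization is identity up to 1%
  pr2 <- gcNormalize(binProfile(bins, gc, rep(100L, nb)))
  gn <- S4Vectors::mcols(pr2@bins)$gcNorm
  expect_true(all(abs(gn - 100) / 100 < 0.01, na.rm = TRUE))
  ## Poisson noise only: mean preserved within 1%
  pr3 <- gcNormalize(binProfile(bins, gc, rpois(nb, 100)))
  gn3 <- S4Vectors::mcols(pr3@bins)$gcNorm
  expect_equal(mean(gn3, na.rm = TRUE), 100, tolerance = 0.01)
  ## degenerate GC spread is refused gracefully
  expect_warning(gcNormalize(binProfile(bins, rep(0.45, nb), rpois(nb, 100))),
                 "spread")
})

test_that("log2 ratios and Z-scores recover simulated copy states", {
  set.seed(42)
  cs <- c(chr1 = 4e7, chr2 = 4e7, chr3 = 4e7, chr4 = 4e7)
  ev <- list(list(chrom = "chr2", start = 1e7, end = 1.6e7 - 1, delta = -1),
             list(chrom = "chr3", start = 1e7, end = 1.6e7 - 1, delta = 1))
  d <- simulateDepth(cs, ev, nPanel = 10)
  pr <- log2RatioZ(gcNormalize(d$profile), d$panel)
  mc <- S4Vectors::mcols(pr@bins)
  chrom <- as.character(GenomicRanges::seqnames(pr@bins))
  st <- GenomicRanges::start(pr@bins)
  inLoss <- chrom == "chr2" & st >= 1e7 & st < 1.55e7
  inGain <- chrom == "chr3" & st >= 1e7 & st < 1.55e7
  base <- chrom == "chr1"
  expect_equal(mean(mc$log2Ratio[inLoss], na.rm = TRUE), -1, tolerance = 0.1)
  expect_equal(mean(mc$log2Ratio[inGain], na.rm = TRUE), log2(3 / 2),
               tolerance = 0.1)
  expect_lt(abs(mean(mc$log2Ratio[base], na.rm = TRUE)), 0.05)
  expect_lt(abs(mean(mc$z[base], na.rm = TRUE)), 0.5)
  ## a sample equal to the panel median is flat zero
  mc2 <- S4Vectors::mcols(d$profile@bins)
  prof0 <- binProfile(GenomicRanges::granges(d$profile@bins), mc2$gc,
                      round(d$panel@med * 1000))
  pr0 <- log2RatioZ(gcNormalize(prof0), d$panel)
  l0 <- S4Vectors::mcols(pr0@bins)$log2Ratio
  expect_lt(stats::median(abs(l0), na.rm = TRUE), 0.02)
})

test_that("male X depth is ratio-neutral after the sex adjustment", {
  set.seed(43)
  bins <- makeBins(c(chr1 = 4.5e7, chrX = 3e7), 400000, 200000)
  nb <- length(bins)
  gc <- rbeta(nb, 50, 70)
  isX <- as.character(GenomicRanges::seqnames(bins)) == "chrX"
  ## female panel: full X depth
  controls <- lapply(1:8, function(i)
    gcNormalize(binProfile(bins, gc, rpois(nb, 1000))))
  panel <- referencePanel(controls, sexComposition = "XX")
  ## male sample: X at half depth
  maleCounts <- rpois(nb, ifelse(isX, 500, 1000))
  pr <- binProfile(bins, gc, maleCounts, sampleSex = "XY")
  pr <- log2RatioZ(gcNormalize(pr), panel)
  l2 <- S4Vectors::mcols(pr@bins)$log2Ratio
  expect_lt(abs(mean(l2[isX], na.rm = TRUE)), 0.1)
  expect_lt(abs(mean(l2[!isX], na.rm = TRUE)), 0.1)
})

test_that("CBS finds noiseless breakpoints exactly and noisy ones within 2 bins", {
  bins <- makeBins(c(chr1 = 2.02e7), 400000, 200000)   # 100 bins
  nb <- length(bins)
  mkProfile <- function(x) {
    pr <- binProfile(bins, rep(0.45, nb), rep(100L, nb))
    S4Vectors::mcols(pr@bins)$log2Ratio <- x
    S4Vectors::mcols(pr@bins)$z <- x
    pr
  }
  truthFrom <- 31; truthTo <- 60
  x0 <- rep(0, nb); x0[truthFrom:truthTo] <- 1
  seg0 <- cbsSegment(mkProfile(x0), seed = 1)
  expect_equal(nrow(seg0), 3)
  expect_equal(seg0$start[2], GenomicRanges::start(bins)[truthFrom])
  expect_equal(seg0$end[2], GenomicRanges::end(bins)[truthTo])
  set.seed(9)
  xn <- x0 + rnorm(nb, 0, 0.15)
  segn <- cbsSegment(mkProfile(xn), seed = 2)
  expect_equal(nrow(segn), 3)
  fromBin <- which(GenomicRanges::start(bins) == segn$start[2])
  toBin <- which(GenomicRanges::end(bins) == segn$end[2])
  expect_lte(abs(fromBin - truthFrom), 2)
  expect_lte(abs(toBin - truthTo), 2)
  ## fewer than 4 bins: single segment
  few <- makeBins(c(chrS = 8e5), 400000, 200000)
  prf <- binProfile(few, rep(0.45, length(few)), rep(100L, length(few)))
  S4Vectors::mcols(prf@bins)$log2Ratio <- c(0, 1, 0)
  S4Vectors::mcols(prf@bins)$z <- 0
  expect_equal(nrow(cbsSegment(prf, seed = 1)), 1)
})

test_that("segment classification applies the reporting rules", {
  bins <- makeBins(c(chr1 = 4e7), 400000, 200000)
  pr <- binProfile(bins, rep(0.45, length(bins)), rep(100L, length(bins)))
  S4Vectors::mcols(pr@bins)$log2Ratio <- 0
  S4Vectors::mcols(pr@bins)$z <- 0
  seg <- function(start, end, L) {
    nb <- (end - start + 1) / 200000 - 1
    data.frame(chrom = "chr1", start = start, end = end, n_bins = nb,
               mean_log2 = L, z = 0)
  }
  ## whole-chromosome trisomy
  s <- classifySegments(seg(1, 4e7, log2(3 / 2)), pr)
  expect_identical(s$class, "gain")
  expect_identical(s$scope, "whole_chromosome")
  ## 3 Mb full-magnitude loss: suppressed by the 4 Mb / 20 bin rule
  s <- classifySegments(seg(1e7, 1.3e7, -1), pr)
  expect_identical(s$class, "neutral")
  ## 6 Mb full loss: reported segmental
  s <- classifySegments(seg(1e7, 1.6e7, -1), pr)
  expect_identical(s$class, "loss")
  expect_identical(s$scope, "segmental")
  expect_equal(s$level, 1)
  ## 12 Mb 40% mosaic gain: its expected ratio is just over the 0.25
  ## threshold, so it reports as a (sub-clonal) gain with level 0.40
  s <- classifySegments(seg(1e7, 2.2e7, levelToLog2(0.4, "gain")), pr)
  expect_true(s$class %in% c("gain", "mosaic_gain"))
  expect_equal(s$level, 0.4, tolerance = 1e-9)
  ## a 35% mosaic sits below the threshold and reports as mosaic_gain
  s <- classifySegments(seg(1e7, 2.2e7, levelToLog2(0.35, "gain")), pr)
  expect_identical(s$class, "mosaic_gain")
  expect_equal(s$level, 0.35, tolerance = 1e-9)
  ## 12 Mb 20% mosaic: below the 30% level floor
  s <- classifySegments(seg(1e7, 2.2e7, levelToLog2(0.2, "gain")), pr)
  expect_identical(s$class, "neutral")
  ## whole-arm scope via an arm table
  arm <- data.frame(chrom = "chr1", centromere = 2e7)
  s <- classifySegments(seg(1, 2e7 - 2e5, log2(3 / 2)), pr, armTable = arm)
  expect_identical(s$scope, "whole_arm")
})

test_that("the mosaic level formula inverts exactly on (0,1)", {
  lv <- seq(0.01, 0.99, by = 0.01)
  for (dirn in c("gain", "loss")) {
    expect_equal(mosaicLevel(levelToLog2(lv, dirn), dirn), lv,
                 tolerance = 1e-12)
  }
  expect_equal(mosaicLevel(log2(3 / 2), "gain"), 1)
  expect_equal(mosaicLevel(-1, "loss"), 1)
})

test_that("segmentation is deterministic given the seed", {
  set.seed(30)
  bins <- makeBins(c(chr1 = 2e7), 400000, 200000)
  pr <- binProfile(bins, rep(0.45, length(bins)), rep(100L, length(bins)))
  S4Vectors::mcols(pr@bins)$log2Ratio <- rnorm(length(bins), 0, 0.15)
  S4Vectors::mcols(pr@bins)$z <- 0
  s1 <- cbsSegment(pr, seed = 7)
  s2 <- cbsSegment(pr, seed = 7)
  expect_identical(s1, s2)
})
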
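## CNV module, stage 2: GC-bias normalization and reference-panel
## log2 ratios / Z-scores.

.isAutosome <- function(chrom) !grepl("(X|Y)$", chrom)

#' LOESS GC-bias normalization of bin counts
#'
#' Fits raw count against GC fraction by locally weighted regression
#' (span 0.3, local quadratic, symmetric family with 3 robustness
#' iterations; a local-linear fit demonstrably underfits the curvature of
#' a unimodal GC bias and leaves a correlated residual) on
#' retained autosomal bins, then rescales every retained bin by
#' `count * mean(fitted) / fitted(gc)`. Bins whose GC lies outside the
#' fitted range use the boundary fit. Profiles with a degenerate GC spread
#' (range < 0.05) are passed through unchanged with a warning.
#'
#' @param profile A [BinProfile-class] with `count` and `gc` filled.
#' @param span LOESS span (default 0.3).
#' @param degree Local polynomial degree (default 2).
#' @return The profile with the `gcNorm` column filled.
#' @export
gcNormalize <- function(profile, span = 0.3, degree = 2) {
  b <- profile@bins
  mc <- S4Vectors::mcols(b)
  fit_idx <- !mc$excluded & !is.na(mc$count) & !is.na(mc$gc) &
    .isAutosome(as.character(GenomicRanges::seqnames(b)))
  if (sum(fit_idx) < 200)
    stop("need >= 200 retained autosomal bins for GC normalization, have ",
         sum(fit_idx))
  gcr <- range(mc$gc[fit_idx])
  keep <- !mc$excluded & !is.na(mc$count)
  if (diff(gcr) < 0.05) {
    warning("GC spread ", signif(diff(gcr), 2),
            " too small; skipping GC normalization")
    mc$gcNorm <- ifelse(keep, as.numeric(mc$count), NA_real_)
    S4Vectors::mcols(profile@bins) <- mc
    return(profile)
  }
  fit <- stats::loess(count ~ gc,
                      data = data.frame(count = mc$count[fit_idx],
                                        gc = mc$gc[fit_idx]),
                      span = span, degree = degree, family = "symmetric",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 4))
  gcClamp <- pmin(pmax(mc$gc, gcr[1]), gcr[2])
  pred <- stats::predict(fit, newdata = data.frame(gc = gcClamp))
  pred[pred <= 0] <- NA_real_
  scale <- mean(stats::predict(fit,
                               newdata = data.frame(gc = mc$gc[fit_idx])),
                na.rm = TRUE)
  ## extreme-GC bins with almost no expected coverage cannot be rescaled
  ## reliably (dividing by a near-zero fit explodes the noise): exclude them
  pred[!is.na(pred) & pred < 0.1 * scale] <- NA_real_
  mc$gcNorm <- ifelse(keep & !is.na(pred), mc$count * scale / pred, NA_real_)
  S4Vectors::mcols(profile@bins) <- mc
  profile
}

#' Build a reference panel from control profiles
#'
#' Per-bin median and standard deviation of GC-normalized depth across a
#' set of euploid control samples, each scaled to a common autosomal mean
#' first.
#'
#' @param profiles List of GC-normalized [BinProfile-class] controls on the
#'   same grid.
#' @param sexComposition Label, e.g. `"XX"`, `"XY"`, `"mixed"`.
#' @return A [ReferencePanel-class].
#' @export
referencePanel <- function(profiles, sexComposition = "mixed") {
  stopifnot(length(profiles) >= 2)
  grid <- profiles[[1]]@bins
  auto <- .isAutosome(as.character(GenomicRanges::seqnames(grid)))
  m <- vapply(profiles, function(p) {
    v <- S4Vectors::mcols(p@bins)$gcNorm
    v / stats::median(v[auto], na.rm = TRUE)
  }, numeric(length(grid)))
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  sd[!is.na(sd) & sd == 0] <- NA_real_
  new("ReferencePanel", bins = GenomicRanges::granges(grid), med = med,
      sd = sd, n = length(profiles),
      sexComposition = sexComposition)
}

#' Log2 copy-number ratios and Z-scores against a reference panel
#'
#' Scales the sample's GC-normalized depth and the panel median to equal
#' autosomal medians (robust: a whole-chromosome aneuploidy must not drag
#' its own baseline), then computes `log2Ratio = log2(sample / median)` and
#' `z = (sample - median) / sd` per retained bin. Sex adjustment: for a
#' 46,XY sample against a female or mixed panel the expected X (and Y)
#' depth is halved, so the panel median on those chromosomes is multiplied
#' by 0.5 before the ratio. Bins with a zero or missing panel median are
#' excluded.
#'
#' @param profile GC-normalized [BinProfile-class].
#' @param panel A [ReferencePanel-class] on the same grid.
#' @param sex Sample sex, `"XX"` or `"XY"` (default: the profile's).
#' @return The profile with `log2Ratio` and `z` filled.
#' @export
log2RatioZ <- function(profile, panel, sex = profile@sampleSex) {
  b <- profile@bins
  if (length(b) != length(panel@bins) ||
      !all(GenomicRanges::start(b) == GenomicRanges::start(panel@bins)))
    stop("profile and panel bin grids differ")
  mc <- S4Vectors::mcols(b)
  chrom <- as.character(GenomicRanges::seqnames(b))
  auto <- .isAutosome(chrom)
  med <- panel@med
  if (!is.na(sex) && sex == "XY" && panel@sexComposition != "XY") {
    sexChrom <- grepl("(X|Y)$", chrom)
    med[sexChrom] <- med[sexChrom] * 0.5
  }
  s <- mc$gcNorm / stats::median(mc$gcNorm[auto], na.rm = TRUE)
  med <- med / stats::median(panel@med[auto], na.rm = TRUE)
  bad <- is.na(med) | med <= 0 | is.na(panel@sd)
  ok <- !mc$excluded & !is.na(s) & !bad
  if (any(!mc$excluded & !is.na(s) & bad))
    message(sum(!mc$excluded & !is.na(s) & bad),
            " bin(s) excluded for zero/missing panel depth")
  mc$excluded <- mc$excluded | bad
  mc$log2Ratio <- ifelse(ok, log2(s / med), NA_real_)
  mc$z <- ifelse(ok, (s - med) / panel@sd, NA_real_)
  S4Vectors::mcols(profile@bins) <- mc
  profile
}
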
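## Readers and writers for the external formats the pipeline touches.
## Conventions: VCF and variant loci are 1-based inclusive; BED is 0-based
## half-open. Genotype calls are data.frames (chrom, pos, ref, alt, gt) with
## gt in {0 hom-ref, 1 het, 2 hom-alt, NA missing}.

#' Read unphased diploid genotype calls from a VCF
#'
#' Reads GT fields for the requested samples. Phase separators (`|`) in the
#' input are deliberately ignored - the method never trusts upstream
#' phasing. Multi-allelic records are dropped with a warning; `./.` becomes
#' an explicit missing call.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param samples Character vector of sample ids to extract; default all.
#' @return Named list (one per sample) of data.frames with columns `chrom`,
#'   `pos`, `ref`, `alt`, `gt`.
#' @export
readVcfGenotypes <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gtm <- vcfR::extract.gt(v, element = "GT")
  avail <- colnames(gtm)
  if (is.null(samples)) samples <- avail
  missing <- setdiff(samples, avail)
  if (length(missing))
    stop("sample(s) not present in ", path, ": ",
         paste(missing, collapse = ", "))
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped from ", basename(path))
    fix <- fix[!multi, , drop = FALSE]
    gtm <- gtm[!multi, , drop = FALSE]
  }
  pos <- as.numeric(fix$POS)
  out <- lapply(samples, function(s) {
    g <- gtm[, s]
    ## split on / or | (phase ignored); count alt alleles
    parts <- strsplit(g, "[/|]")
    gt <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".") || anyNA(p)) return(NA_integer_)
      a <- suppressWarnings(as.integer(p))
      if (anyNA(a) || any(a > 1)) return(NA_integer_)
      sum(a)
    }, integer(1))
    data.frame(chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = fix$ALT,
               gt = gt, stringsAsFactors = FALSE)
  })
  names(out) <- samples
  out
}

#' Write genotype calls for several samples as a VCF
#'
#' Minimal deterministic VCF 4.2 writer; the inverse of
#' [readVcfGenotypes()] on its own output. All samples must share the same
#' site list. Calls are written unphased (`0/1` style, `./.` for missing).
#'
#' @param calls Named list of per-sample call data.frames
#'   (chrom, pos, ref, alt, gt), all over identical sites.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(calls, path) {
  stopifnot(length(calls) >= 1, !is.null(names(calls)))
  sites <- calls[[1]][, c("chrom", "pos", "ref", "alt")]
  for (s in calls) stopifnot(nrow(s) == nrow(sites))
  gtStr <- vapply(calls, function(s)
    c("0/0", "0/1", "1/1")[s$gt + 1L], character(nrow(sites)))
  if (is.null(dim(gtStr))) gtStr <- matrix(gtStr, nrow = nrow(sites))
  gtStr[is.na(gtStr)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(calls)), collapse = "\t"))
  body <- cbind(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref, sites$alt, ".", "PASS", ".", "GT", gtStr)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a 3-column genetic map file
#'
#' Reads the per-chromosome text layout commonly distributed with phase-3
#' reference recombination maps: position (bp), rate (cM/Mb), cumulative
#' genetic distance (cM), whitespace separated, with or without a header
#' line. Duplicate positions and non-monotone cumulative cM are rejected.
#'
#' @param path Path to the map file.
#' @param chrom Chromosome label to attach (default: taken from the file
#'   name, else `"chr?"`).
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path, chrom = NULL) {
  first <- readLines(path, n = 1)
  hasHeader <- !grepl("^\\s*[0-9]", first)
  d <- utils::read.table(path, header = hasHeader)
  if (ncol(d) < 3) stop("genetic map must have 3 columns in ", path)
  pos <- as.numeric(d[[1]]); rate <- as.numeric(d[[2]]); cm <- as.numeric(d[[3]])
  if (anyDuplicated(pos)) stop("duplicate positions in genetic map ", path)
  if (any(diff(pos) <= 0))
    stop("positions not strictly increasing in genetic map ", path)
  o <- seq_along(pos)
  if (any(diff(cm[o]) < -1e-12))
    stop("cumulative cM not nondecreasing in ", path)
  if (is.null(chrom)) {
    m <- regmatches(basename(path), regexpr("chr[0-9XYM]+", basename(path)))
    chrom <- if (length(m)) m else "chr?"
  }
  GeneticMap(chrom, pos[o], cm[o], rate[o])
}

#' Write a GeneticMap in the 3-column text layout
#' @param map A [GeneticMap-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneticMap <- function(map, path) {
  d <- data.frame(position = format(map@positions, scientific = FALSE, trim = TRUE),
                  rate_cM_Mb = map@rateCMperMb, cM = map@cumCM)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED blacklist as 1-based inclusive genomic ranges
#'
#' BED is 0-based half-open; the returned [GenomicRanges::GRanges] is
#' 1-based inclusive (so the BED row `chr1 0 100` covers 1-based positions
#' 1-100).
#'
#' @param path Path to a BED file.
#' @return A `GRanges`.
#' @export
readBlacklist <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr)
}

#' Read per-fragment start positions (BED/TSV) or precomputed bin counts
#'
#' `readFragments` accepts a BED of aligned fragments (their 0-based starts
#' are converted to 1-based) or a 2-column TSV `chrom<TAB>start` with
#' 1-based starts. `countFragments` assigns each fragment start to every
#' overlapping bin of a grid (bins overlap, so one fragment can count in
#' two bins). `readBinCounts` reads a TSV `bin_index<TAB>count` keyed by
#' 1-based bin index into an existing grid.
#'
#' @param path Input path.
#' @return `readFragments`: data.frame (chrom, start) with 1-based starts.
#' @export
readFragments <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(data.frame(chrom = character(), start = numeric()))
  nf <- length(strsplit(first, "\\s+")[[1]])
  if (nf >= 3) {
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr))  # import() already 1-based
  } else {
    d <- utils::read.table(path, header = FALSE)
    data.frame(chrom = as.character(d[[1]]), start = as.numeric(d[[2]]))
  }
}

#' @rdname readFragments
#' @param fragments data.frame (chrom, start), 1-based starts.
#' @param bins Bin grid `GRanges` (from [makeBins()]).
#' @return `countFragments`: integer vector of per-bin counts.
#' @export
countFragments <- function(fragments, bins) {
  if (nrow(fragments) == 0) return(integer(length(bins)))
  fr <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(fragments$start, width = 1))
  GenomicRanges::countOverlaps(bins, fr)
}

#' @rdname readFragments
#' @export
readBinCounts <- function(path, bins) {
  d <- utils::read.table(path, header = FALSE)
  counts <- integer(length(bins))
  idx <- as.integer(d[[1]])
  if (any(idx < 1 | idx > length(bins)))
    stop("bin index out of range in ", path)
  counts[idx] <- as.integer(d[[2]])
  counts
}

#' Read/write reference-panel bin statistics
#'
#' TSV keyed by 1-based bin index with per-bin median and standard
#' deviation of normalized control depth; the bin grid itself comes from
#' the chromosome sizes and window/step configuration.
#'
#' @param path TSV path (`bin_index`, `med`, `sd` columns).
#' @param bins Bin grid `GRanges`.
#' @param n Number of panel samples (metadata).
#' @param sexComposition Panel sex label.
#' @return A [ReferencePanel-class].
#' @export
readPanelTsv <- function(path, bins, n = NA_integer_,
                         sexComposition = "mixed") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  med <- rep(NA_real_, length(bins)); sd <- rep(NA_real_, length(bins))
  idx <- as.integer(d$bin_index)
  if (any(idx < 1 | idx > length(bins))) stop("bin index out of range in ", path)
  med[idx] <- d$med; sd[idx] <- d$sd
  new("ReferencePanel", bins = GenomicRanges::granges(bins), med = med,
      sd = sd, n = as.integer(n), sexComposition = sexComposition)
}

#' @rdname readPanelTsv
#' @param panel A [ReferencePanel-class].
#' @export
writePanelTsv <- function(panel, path) {
  keep <- !is.na(panel@med)
  d <- data.frame(bin_index = which(keep), med = panel@med[keep],
                  sd = panel@sd[keep])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read direct mutation-test results
#'
#' TSV with columns `embryo_id`, `call`
#' (carrier/affected/wild_type/failed) and optional `method` (e.g. sanger,
#' gap_pcr). Exactly one call per embryo is enforced.
#'
#' @param path Path to the TSV.
#' @return data.frame (embryo_id, call, method).
#' @export
readDirectTests <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("embryo_id", "call") %in% names(d)))
  ok <- c("carrier", "affected", "wild_type", "failed")
  if (!all(d$call %in% ok))
    stop("unknown direct-test call(s): ",
         paste(setdiff(d$call, ok), collapse = ", "))
  if (anyDuplicated(d$embryo_id))
    stop("more than one direct-test call for embryo(s): ",
         paste(unique(d$embryo_id[duplicated(d$embryo_id)]), collapse = ", "))
  if (is.null(d$method)) d$method <- NA_character_
  d[, c("embryo_id", "call", "method")]
}

#' @rdname readDirectTests
#' @param tests data.frame (embryo_id, call, method).
#' @export
writeDirectTests <- function(tests, path) {
  utils::write.table(tests, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Assembles and validates the tunable parameters of a run: the
#' half-width of the SNP search window around the variant, the ADO and
#' genotype-error rates of the emission model, the CNV windowing and
#' reporting thresholds, and the RNG seed. Invariants: `adoRate +
#' genotypeError < 1`, `cnvStep <= cnvWindow`, all lengths positive.
#'
#' @param windowBp SNP window half-width (default 5e6, i.e. 5 Mb up- and
#'   downstream of the variant).
#' @param adoRate,genotypeError Emission model rates.
#' @param cnvWindow,cnvStep CNV bin width / stride (default 400 kb / 200 kb).
#' @param log2Threshold Reporting threshold on |log2 ratio| (default 0.25).
#' @param minSegmentBp Minimum segmental CNV length (default 4 Mb).
#' @param minSegmentBins Minimum supporting bins (default 20).
#' @param mosaicMinBp Minimum mosaic segment length (default 10 Mb).
#' @param mosaicMinLevel Minimum mosaic level (default 0.30).
#' @param seed RNG seed.
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(windowBp = 5e6, adoRate = 0.05, genotypeError = 0.01,
                      cnvWindow = 400000, cnvStep = 200000,
                      log2Threshold = 0.25, minSegmentBp = 4e6,
                      minSegmentBins = 20, mosaicMinBp = 1e7,
                      mosaicMinLevel = 0.30, seed = 1L) {
  cfg <- list(windowBp = windowBp, adoRate = adoRate,
              genotypeError = genotypeError, cnvWindow = cnvWindow,
              cnvStep = cnvStep, log2Threshold = log2Threshold,
              minSegmentBp = minSegmentBp, minSegmentBins = minSegmentBins,
              mosaicMinBp = mosaicMinBp, mosaicMinLevel = mosaicMinLevel,
              seed = as.integer(seed))
  if (cfg$adoRate + cfg$genotypeError >= 1)
    stop("adoRate + genotypeError must be < 1")
  if (cfg$cnvStep > cfg$cnvWindow) stop("cnvStep must be <= cnvWindow")
  lens <- c(cfg$windowBp, cfg$cnvWindow, cfg$cnvStep, cfg$minSegmentBp,
            cfg$mosaicMinBp)
  if (any(lens <= 0)) stop("all lengths must be positive")
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML (or JSON) config file; recognised keys are the
#'   `runConfig()` argument names.
#' @export
readRunConfig <- function(path) {
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) jsonlite::read_json(path, simplifyVector = TRUE))
  known <- names(formals(runConfig))
  do.call(runConfig, vals[intersect(names(vals), known)])
}

#' Write the diagnosis + CNV report
#'
#' Writes the per-embryo diagnosis table and CNV segment table as TSVs with
#' fixed column order and 4-decimal float formatting (byte-stable across
#' runs), plus a machine-readable JSON bundle.
#'
#' @param diagnoses Diagnosis data.frame (from [diagnoseEmbryos()]).
#' @param segments Segment data.frame (from [classifySegments()]), or NULL.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writeReport <- function(diagnoses, segments = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dpath <- file.path(dir, "diagnosis.tsv")
  utils::write.table(diagnoses, dpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(diagnosis = dpath)
  if (!is.null(segments) && nrow(segments)) {
    seg <- segments
    for (cl in c("mean_log2", "z", "level"))
      if (cl %in% names(seg)) seg[[cl]] <- .fmtNum(seg[[cl]])
    spath <- file.path(dir, "segments.tsv")
    utils::write.table(seg, spath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, segments = spath)
  }
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(list(diagnoses = diagnoses,
                            segments = segments %||% list()),
                       jpath, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, json = jpath)
  invisible(files)
}
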
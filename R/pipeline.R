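## End-to-end orchestration: CNV -> ploidy gate -> marker selection ->
## proband anchoring -> Viterbi decoding -> diagnosis -> reports.

#' Run manifest: reproducibility fingerprint of a run
#'
#' MD5 digests of every input file plus a hash of the effective
#' configuration; identical config + inputs give an identical manifest
#' hash (the timestamp is excluded from it).
#'
#' @param inputFiles Character vector of input file paths.
#' @param config A `RunConfig` list.
#' @return list(configHash, inputDigests, version, seed, timestamp).
#' @export
runManifest <- function(inputFiles, config) {
  tf <- tempfile()
  writeLines(paste(names(config), vapply(config, format, character(1)),
                   sep = "="), tf)
  on.exit(unlink(tf))
  list(configHash = unname(tools::md5sum(tf)),
       inputDigests = tools::md5sum(inputFiles[file.exists(inputFiles)]),
       version = as.character(utils::packageVersion("EmbryoPGT")),
       seed = config$seed,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Read the variant descriptor of a family directory
#' @param path `variant.yaml` path (keys: chrom, kind, pos or
#'   del_start/del_end, ref, alt, gene, inheritance, proband).
#' @return list(variant = [VariantLocus-class], probandId).
#' @export
readVariantYaml <- function(path) {
  y <- yaml::read_yaml(path)
  v <- VariantLocus(chrom = y$chrom, kind = y$kind,
                    pos = y$pos %||% NA_real_,
                    delStart = y$del_start %||% NA_real_,
                    delEnd = y$del_end %||% NA_real_,
                    ref = y$ref %||% NA_character_,
                    alt = y$alt %||% NA_character_,
                    gene = y$gene %||% NA_character_,
                    inheritance = y$inheritance)
  list(variant = v, probandId = y$proband %||% NA_character_)
}

#' Run the full PGT-M pipeline on a family directory
#'
#' Expects `genotypes.vcf` (samples `father`, `mother` and the embryos),
#' `map.txt` (3-column genetic map), `direct_tests.tsv` and `variant.yaml`
#' in `familyDir`; optionally `chrom_sizes.tsv`, `gc.tsv`,
#' `counts_<embryo>.tsv` and `panel.tsv` (plus `blacklist.bed`) for the
#' CNV module. Stages run in order: CNV calling per embryo, ploidy gate
#' (SNP Mendelian/heterozygosity QC plus CNV overlap), informative-SNP
#' selection, proband anchoring, Viterbi decoding, reconciliation, and
#' report writing.
#'
#' @param familyDir Input directory.
#' @param outDir Output directory for reports (default: no files written).
#' @param config A `RunConfig` (see [runConfig()]).
#' @return list(diagnoses, segments, cnvFlags, ploidy, phased, paths,
#'   manifest, status) where `status` is 0 on success and 2 when any
#'   embryo's final status is `failure` (reports are still written).
#' @export
runEndToEnd <- function(familyDir, outDir = NULL, config = runConfig()) {
  need <- function(f) {
    p <- file.path(familyDir, f)
    if (!file.exists(p)) stop("missing required input '", f, "' in ", familyDir)
    p
  }
  vy <- readVariantYaml(need("variant.yaml"))
  variant <- vy$variant
  calls <- readVcfGenotypes(need("genotypes.vcf"))
  if (!all(c("father", "mother") %in% names(calls)))
    stop("genotypes.vcf must contain samples 'father' and 'mother'")
  embryoIds <- setdiff(names(calls), c("father", "mother"))
  map <- readGeneticMap(need("map.txt"), chrom = variant@chrom)
  direct <- readDirectTests(need("direct_tests.tsv"))

  ## ---- CNV per embryo (optional inputs) ----
  segments <- list(); cnvFlags <- character()
  csPath <- file.path(familyDir, "chrom_sizes.tsv")
  if (file.exists(csPath)) {
    cs <- utils::read.table(csPath, header = FALSE)
    chromSizes <- stats::setNames(as.numeric(cs[[2]]), as.character(cs[[1]]))
    blPath <- file.path(familyDir, "blacklist.bed")
    blacklist <- if (file.exists(blPath)) readBlacklist(blPath) else NULL
    bins <- makeBins(chromSizes, config$cnvWindow, config$cnvStep, blacklist)
    gcTab <- utils::read.table(need("gc.tsv"), header = TRUE, sep = "\t")
    gc <- rep(NA_real_, length(bins)); gc[gcTab$bin_index] <- gcTab$gc
    panel <- readPanelTsv(need("panel.tsv"), bins)
    for (id in embryoIds) {
      cf <- file.path(familyDir, paste0("counts_", id, ".tsv"))
      if (!file.exists(cf)) next
      counts <- readBinCounts(cf, bins)
      prof <- binProfile(bins, gc, counts, config$cnvWindow, config$cnvStep)
      res <- callCnv(prof, panel, seed = config$seed,
                     log2Threshold = config$log2Threshold,
                     minSegmentBp = config$minSegmentBp,
                     minSegmentBins = config$minSegmentBins,
                     mosaicMinBp = config$mosaicMinBp,
                     mosaicMinLevel = config$mosaicMinLevel)
      segments[[id]] <- res$segments
      cnvFlags[id] <- if (!is.null(res$segments) &&
                          any(res$segments$class != "neutral"))
        "abnormal" else "normal"
    }
  }

  ## ---- ploidy gate on genome-wide trio markers ----
  trio <- trioMarkerTable(calls$father, calls$mother)
  ploidy <- lapply(stats::setNames(embryoIds, embryoIds), function(id)
    detectPloidyFailure(trio, calls[[id]], cnvSegments = segments[[id]],
                        variant = variant))
  for (id in embryoIds)
    if (!isTRUE(ploidy[[id]]$ok) &&
        (!id %in% names(cnvFlags) || cnvFlags[id] == "normal"))
      cnvFlags[id] <- "abnormal"  # e.g. triploid by SNP analysis

  ## ---- phasing ----
  snps <- selectInformativeSnps(calls$father, calls$mother, variant,
                                config$windowBp)
  pid <- vy$probandId
  if (is.na(pid)) stop("variant.yaml must name the proband embryo")
  ptest <- direct[direct$embryo_id == pid, , drop = FALSE]
  if (!nrow(ptest)) stop("no direct-test result for proband ", pid)
  phased <- anchorParentalPhase(snps, calls[[pid]], ptest, variant)
  model <- EmissionModel(config$adoRate, config$genotypeError)
  okIds <- embryoIds[vapply(embryoIds, function(id)
    isTRUE(ploidy[[id]]$ok), logical(1))]
  dec <- decodePaths(phased, calls[okIds], model, map)
  paths <- dec$paths
  for (id in setdiff(embryoIds, okIds))   # placeholder failed paths
    paths[[id]] <- new("InheritancePath", embryoId = id,
                       paternal = rep(NA_integer_, nrow(snps)),
                       maternal = rep(NA_integer_, nrow(snps)),
                       skipped = rep(TRUE, nrow(snps)),
                       logProb = NA_real_, margin = NA_real_,
                       breakpoints = data.frame(), failed = TRUE,
                       failureReason = ploidy[[id]]$reason)
  paths <- paths[embryoIds]

  diagnoses <- diagnoseEmbryos(paths, dec$phased, variant, direct,
                               ploidy = ploidy, cnvFlags = cnvFlags)

  allSeg <- if (length(segments)) {
    do.call(rbind, lapply(names(segments), function(id) {
      s <- segments[[id]]
      if (is.null(s) || !nrow(s)) return(NULL)
      cbind(embryo_id = id, s)
    }))
  } else NULL

  manifest <- runManifest(list.files(familyDir, full.names = TRUE), config)
  if (!is.null(outDir)) {
    files <- writeReport(diagnoses, allSeg, outDir)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  status <- if (any(diagnoses$final_status == "failure")) 2L else 0L
  list(diagnoses = diagnoses, segments = segments, cnvFlags = cnvFlags,
       ploidy = ploidy, phased = dec$phased, paths = paths,
       manifest = manifest, status = status)
}
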
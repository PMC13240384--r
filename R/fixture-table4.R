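## Packaged deterministic regression fixture: three families, ten embryos,
## reproducing the clinical summary pattern of the study the method comes
## from - a recessive-biallelic 19.3-kb alpha-globin deletion family with a
## carrier proband and one triploid haplotyping failure, a maternal-dominant
## EXT1 frameshift family, and a paternal-dominant CUL3 frameshift family.

.fixtureFamilySpecs <- function() {
  list(
    list(
      famId = 1,
      variant = seaDeletionLocus(),
      targets = c("wild_type", "carrier", "wild_type", "wild_type"),
      ploidy = c("none", "none", "none",
                 "triploid_maternal_window_isodisomic"),
      probandIndex = 2,
      cnvPlus = c(TRUE, TRUE, FALSE, FALSE),  # E1-4 "+" comes from ploidy QC
      ## markers flank the small deletion on both sides, plus four probes
      ## inside it (alpha-globin cluster coverage) that resolve the
      ## deletion's parental origin via proband hemizygosity
      markerPositions = round(c(seq(30000, 160000, length.out = 15),
                                seq(166000, 184200, length.out = 10),
                                seq(190000, 5170000, length.out = 175)))
    ),
    list(
      famId = 2,
      variant = VariantLocus("chr8", "point", pos = 119124000, ref = "CT",
                             alt = "C", gene = "EXT1",
                             inheritance = "dominant_maternal"),
      targets = c("wild_type", "wild_type", "wild_type", "carrier"),
      ploidy = rep("none", 4),
      probandIndex = 4,
      cnvPlus = c(TRUE, TRUE, FALSE, FALSE),
      markerPositions = numeric(0)
    ),
    list(
      famId = 3,
      variant = VariantLocus("chr2", "point", pos = 225450000, ref = "CTT",
                             alt = "C", gene = "CUL3",
                             inheritance = "dominant_paternal"),
      targets = c("wild_type", "carrier"),
      ploidy = rep("none", 2),
      probandIndex = 2,
      cnvPlus = c(TRUE, TRUE),
      markerPositions = numeric(0)
    )
  )
}

#' Build the packaged three-family regression fixture
#'
#' Deterministically (fixed seed) simulates the three families of the
#' embryo-as-proband case series: ten embryos with the printed direct-test
#' / haplotype outcome pattern, including a carrier proband per family,
#' one triploid embryo whose haplotyping fails at the ploidy gate, and
#' per-embryo CNV profiles (whole-chromosome trisomy of a non-variant
#' chromosome for CNV-abnormal embryos). When `dir` is given, every
#' family is written out through the package's own writers (VCF, genetic
#' map, direct-test TSV, variant YAML, bin counts, GC and panel TSVs) so
#' the pipeline consumes the fixture through its public interfaces only.
#'
#' @param dir Optional output directory; subdirectories `family1..3` are
#'   created.
#' @param seed Fixture seed (default 20260; the packaged fixture).
#' @param depth Whether to simulate the CNV depth inputs (default TRUE).
#' @return list(dir, families) where each family holds `truth`, `calls`,
#'   `direct`, `variant`, `probandId`, `embryoIds` and (with depth) the
#'   simulated profiles.
#' @export
makeTable4Fixture <- function(dir = NULL, seed = 20260, depth = TRUE) {
  specs <- .fixtureFamilySpecs()
  chromSizes <- c(chrA = 5e7, chrB = 4.5e7, chrC = 4e7, chrD = 4e7)
  families <- lapply(specs, function(sp) {
    sc <- simScenario(sp$variant,
                      nMarkers = 200, windowBp = 5e6,
                      nEmbryos = length(sp$targets),
                      adoRate = 0.05, genotypeError = 0.01,
                      nInsideMarkers = 4, nQcMarkers = 120,
                      ploidyEvents = sp$ploidy,
                      markerPositions = sp$markerPositions,
                      seed = seed + sp$famId)
    truth <- simulateFamily(sc, targetStatuses = sp$targets,
                            probandIndex = sp$probandIndex)
    ## clinical-style embryo ids E<family>-<n>
    ids <- sprintf("E%d-%d", sp$famId, seq_along(truth$embryos))
    names(truth$embryos) <- ids
    for (i in seq_along(truth$embryos)) truth$embryos[[i]]$id <- ids[i]
    truth$probandId <- ids[sp$probandIndex]

    calls <- observeGenotypes(truth, adoRate = sc@adoRate,
                              genotypeError = sc@genotypeError)
    direct <- do.call(rbind, lapply(truth$embryos, function(e)
      observeDirectTest(e$status, e$id,
                        method = if (sp$variant@kind == "deletion")
                          "gap_pcr" else "sanger")))

    dep <- NULL
    if (depth) {
      gc <- NULL; panel <- NULL
      profiles <- list()
      set.seed(seed + 100 + sp$famId)
      for (i in seq_along(ids)) {
        ev <- if (sp$cnvPlus[i]) list(list(chrom = "chrD", delta = 1)) else list()
        d <- simulateDepth(chromSizes, events = ev, nPanel = 12,
                           gc = gc, panel = panel)
        gc <- d$gc; panel <- d$panel
        profiles[[ids[i]]] <- d$profile
      }
      dep <- list(profiles = profiles, panel = panel, gc = gc,
                  chromSizes = chromSizes)
    }
    list(famId = sp$famId, truth = truth, calls = calls, direct = direct,
         variant = sp$variant, probandId = truth$probandId,
         embryoIds = ids, depth = dep)
  })

  if (!is.null(dir)) {
    for (fam in families) {
      fd <- file.path(dir, paste0("family", fam$famId))
      dir.create(fd, showWarnings = FALSE, recursive = TRUE)
      writeVcfGenotypes(fam$calls, file.path(fd, "genotypes.vcf"))
      writeGeneticMap(fam$truth$map, file.path(fd, "map.txt"))
      writeDirectTests(fam$direct, file.path(fd, "direct_tests.tsv"))
      v <- fam$variant
      yaml::write_yaml(Filter(Negate(is.null), list(
        chrom = v@chrom, kind = v@kind,
        pos = if (v@kind == "point") v@pos,
        del_start = if (v@kind == "deletion") v@delStart,
        del_end = if (v@kind == "deletion") v@delEnd,
        ref = if (!is.na(v@ref)) v@ref, alt = if (!is.na(v@alt)) v@alt,
        gene = v@gene, inheritance = v@inheritance,
        proband = fam$probandId)), file.path(fd, "variant.yaml"))
      if (!is.null(fam$depth)) {
        utils::write.table(
          data.frame(chrom = names(fam$depth$chromSizes),
                     length = format(fam$depth$chromSizes,
                                     scientific = FALSE, trim = TRUE)),
          file.path(fd, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE, col.names = FALSE)
        utils::write.table(
          data.frame(bin_index = seq_along(fam$depth$gc), gc = fam$depth$gc),
          file.path(fd, "gc.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        writePanelTsv(fam$depth$panel, file.path(fd, "panel.tsv"))
        for (id in fam$embryoIds) {
          cnt <- S4Vectors::mcols(fam$depth$profiles[[id]]@bins)$count
          utils::write.table(
            data.frame(i = seq_along(cnt), count = cnt),
            file.path(fd, paste0("counts_", id, ".tsv")), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
        }
      }
    }
  }
  list(dir = dir, families = families)
}
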
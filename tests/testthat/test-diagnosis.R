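test_that("haplotype call reads the flanking-marker consensus at the variant", {
  pp <- tinyPhasedParents(vpos = 2.5e6, positions = c(1e6, 2e6, 3e6, 4e6),
                          fatherM = c("G", "G", "G", "G"),
                          fatherN = c("A", "A", "A", "A"))
  ## carrier-parent M on both flanks -> carrier
  hc <- haplotypeCallFromPath(tinyPath("E", c(1, 1, 1, 1), c(1, 1, 1, 1)),
                              pp@variant, pp)
  expect_identical(hc$call, "carrier")
  ## N on both flanks -> wild type (Family-2-shaped maternal case mirrored)
  hc <- haplotypeCallFromPath(tinyPath("E", c(2, 2, 2, 2), c(1, 1, 1, 1)),
                              pp@variant, pp)
  expect_identical(hc$call, "wild_type")
  ## disagreeing flanks -> failure + recombination flag
  hc <- haplotypeCallFromPath(tinyPath("E", c(1, 1, 2, 2), c(1, 1, 1, 1)),
                              pp@variant, pp)
  expect_identical(hc$call, "failure")
  expect_true("recombination_in_window" %in% hc$flags)
  ## variant outside the marker span -> error
  pp2 <- tinyPhasedParents(vpos = 9e6, positions = c(1e6, 2e6),
                           fatherM = c("G", "G"), fatherN = c("A", "A"))
  expect_error(
    haplotypeCallFromPath(tinyPath("E", c(1, 1), c(1, 1)), pp2@variant, pp2),
    "not bracketed")
})

test_that("recessive calls count M haplotypes from both carrier parents", {
  v <- VariantLocus("chr1", "deletion", delStart = 2.4e6, delEnd = 2.6e6,
                    inheritance = "recessive_biallelic")
  pp <- tinyPhasedParents(vpos = 2.5e6, positions = c(1e6, 2e6, 3e6, 4e6),
                          fatherM = c("G", "G", "G", "G"),
                          fatherN = c("A", "A", "A", "A"),
                          motherM = c("G", "G", "G", "G"),
                          motherN = c("A", "A", "A", "A"),
                          inheritance = "recessive_biallelic", variant = v)
  calls <- list(c(1, 1), c(1, 2), c(2, 2))
  expected <- c("affected", "carrier", "wild_type")
  for (i in seq_along(calls)) {
    pat <- rep(calls[[i]][1], 4); mat <- rep(calls[[i]][2], 4)
    hc <- haplotypeCallFromPath(tinyPath("E", pat, mat), v, pp)
    expect_identical(hc$call, expected[i])
  }
})

test_that("a crossover between the flanking markers yields a flagged failure", {
  ## construct a paternal crossover exactly between the variant's flanking
  ## markers: the embryo reads paternal M below the variant and paternal N
  ## above it, so the flanks disagree and no definitive call is possible
  pp <- tinyPhasedParents(vpos = 2.5e6, positions = c(1e6, 2e6, 3e6, 4e6),
                          fatherM = rep("G", 4), fatherN = rep("A", 4))
  emb <- data.frame(chrom = "chr1", pos = c(1e6, 2e6, 3e6, 4e6),
                    ref = "A", alt = "G",
                    gt = c(1L, 1L, 0L, 0L),   # het = paternal G (M); hom A = N
                    stringsAsFactors = FALSE)
  map <- GeneticMap("chr1", c(1, 1e7), c(0, 10))
  dec <- decodePaths(pp, list(E = emb), EmissionModel(0.05, 0.01), map)
  p <- dec$paths$E
  expect_identical(p@paternal, c(1L, 1L, 2L, 2L))
  expect_equal(nrow(p@breakpoints[p@breakpoints$parent == "paternal", ]), 1)
  hc <- haplotypeCallFromPath(p, pp@variant, dec$phased)
  expect_identical(hc$call, "failure")
  expect_true("recombination_in_window" %in% hc$flags)
})

test_that("reconciliation follows the agreement/fallback/severity rules", {
  d <- function(call) data.frame(call = call)
  ## agreement
  r <- reconcileDiagnosis("carrier", d("carrier"))
  expect_identical(r$final, "carrier")
  expect_length(r$flags, 0)
  ## direct failed -> haplotype call + ado_suspect
  r <- reconcileDiagnosis("wild_type", d("failed"))
  expect_identical(r$final, "wild_type")
  expect_true("ado_suspect" %in% r$flags)
  ## haplotype failure -> direct call (the triploid E1-4 pattern)
  r <- reconcileDiagnosis("failure", d("wild_type"), ploidyOk = FALSE)
  expect_identical(r$final, "wild_type")
  expect_true("ploidy_failure" %in% r$flags)
  ## both failed
  r <- reconcileDiagnosis("failure", d("failed"))
  expect_identical(r$final, "failure")
  ## disagreement: always the more severe call, flagged, never the milder
  r <- reconcileDiagnosis("carrier", d("wild_type"))
  expect_identical(r$final, "carrier")
  expect_true("ado_suspect" %in% r$flags)
  r <- reconcileDiagnosis("wild_type", d("carrier"))
  expect_identical(r$final, "carrier")
  expect_true("recombination_in_window" %in% r$flags)
  r <- reconcileDiagnosis("carrier", d("affected"))
  expect_identical(r$final, "affected")
})

test_that("severity is a total order and reconciliation is idempotent", {
  sev <- EmbryoPGT:::.SEVERITY
  expect_identical(names(sort(sev)), c("wild_type", "carrier", "affected"))
  for (h in names(sev)) for (dc in names(sev)) {
    r1 <- reconcileDiagnosis(h, data.frame(call = dc))
    r2 <- reconcileDiagnosis(r1$final, data.frame(call = r1$final))
    expect_identical(r2$final, r1$final)
  }
})

test_that("direct-test ADO at the variant site is caught and flagged", {
  ## a true carrier whose direct assay drops the mutant allele reads
  ## wild-type; the haplotype call must win and raise ado_suspect
  set.seed(801)
  dt <- observeDirectTest("carrier", "E1", adoRate = 1)  # force the dropout
  expect_identical(dt$call, "wild_type")
  r <- reconcileDiagnosis("carrier", dt)
  expect_identical(r$final, "carrier")
  expect_true("ado_suspect" %in% r$flags)
})
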
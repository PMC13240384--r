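mkCalls <- function(pos, gt, chrom = "chr1", ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             stringsAsFactors = FALSE)
}

test_that("informative-SNP selection classes markers and respects the window", {
  v <- VariantLocus("chr1", "point", pos = 1e7, ref = "C", alt = "T",
                    inheritance = "dominant_paternal")
  pos <- c(4.9e6, 6e6, 8e6, 1.2e7, 1.6e7)   # first/last outside 5 Mb window
  fa <- mkCalls(pos, c(1L, 1L, 1L, 0L, 1L))
  mo <- mkCalls(pos, c(1L, 0L, 1L, 1L, 0L))
  snps <- selectInformativeSnps(fa, mo, v, 5e6)
  expect_equal(snps$pos, c(6e6, 8e6, 1.2e7))
  expect_equal(snps$class, c("paternal_only", "double_het", "maternal_only"))
  ## both-hom and both-missing sites excluded
  fa2 <- mkCalls(pos, c(0L, 0L, NA, 2L, 0L))
  mo2 <- mkCalls(pos, c(0L, 2L, NA, 0L, 0L))
  expect_error(selectInformativeSnps(fa2, mo2, v, 5e6), "no informative")
})

test_that("informative-SNP count matches an independent re-scan of the table", {
  ph <- phaseSimulatedFamily(seed = 301, nMarkers = 200, a = 0, e = 0)
  fa <- ph$calls$father; mo <- ph$calls$mother
  ctr <- 119124000
  manual <- sum(fa$chrom == "chr8" & abs(fa$pos - ctr) <= 5e6 &
                ((!is.na(fa$gt) & fa$gt == 1L) |
                 (!is.na(mo$gt) & mo$gt == 1L)))
  expect_equal(nrow(ph$snps), manual)
  ## deletion variants flag inside markers
  sea <- seaDeletionLocus()
  sc <- simScenario(sea, nMarkers = 50, nInsideMarkers = 5, nQcMarkers = 0,
                    adoRate = 0, genotypeError = 0, seed = 302)
  tr <- simulateFamily(sc)
  calls <- observeGenotypes(tr, 0, 0)
  snps <- selectInformativeSnps(calls$father, calls$mother, sea, 5e6)
  expect_true(any(snps$insideDeletion))
  expect_true(all(snps$pos[snps$insideDeletion] >= sea@delStart &
                  snps$pos[snps$insideDeletion] <= sea@delEnd))
})

test_that("recombination fraction follows the Haldane map function", {
  m <- GeneticMap("chr1", c(1, 2e8 + 1), c(0, 200))  # 1 cM/Mb
  expect_equal(recombinationFraction(m, 1e6, 1e6 + 1), 0, tolerance = 1e-8)
  ## d = 0.01 cM = 1e-4 Morgan
  r <- recombinationFraction(m, 1e6, 1e6 + 1e4)
  expect_equal(r, (1 - exp(-2e-4)) / 2, tolerance = 1e-12)
  expect_equal(r, 9.999e-5, tolerance = 1e-3)
  ## monotone in d and bounded by 1/2 over random distances
  set.seed(21)
  d <- sort(runif(1000, 0, 1.9e8))
  r <- recombinationFraction(m, rep(1, 1000), 1 + d)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r < 0.5))
  expect_error(recombinationFraction(m, 1, 10, chrom = "chr2"), "chr2")
  expect_error(recombinationFraction(m, 10, 10), "posI < posJ")
})

test_that("emission probabilities match the ADO + error model and normalize", {
  m <- EmissionModel(0, 0)
  expect_equal(emissionProb(m, 1L, 1L), 1)
  m2 <- EmissionModel(0.1, 0.02)
  expect_equal(emissionProb(m2, 1L, 0L), 0.06)   # (a+e)/2
  expect_equal(emissionProb(m2, 1L, 1L), 0.88)   # 1-a-e
  expect_equal(emissionProb(m2, 0L, 0L), 0.98)   # 1-e
  expect_equal(emissionProb(m2, 0L, 2L), 0.01)   # e/2
  expect_equal(emissionProb(m2, 2L, NA), 1)      # missing -> skipped
  set.seed(31)
  for (i in 1:20) {
    a <- runif(1, 0, 0.5); e <- runif(1, 0, 0.3)
    mm <- EmissionModel(a, e)
    for (tg in 0:2)
      expect_equal(sum(emissionProb(mm, tg, 0:2)), 1)
  }
  expect_error(EmissionModel(0.7, 0.4), "< 1")
})

test_that("proband anchoring labels the transmitted carrier allele M", {
  ## worked case: father A/G, mother A/A, proband het -> father M = G
  v <- VariantLocus("chr1", "point", pos = 2e6, ref = "A", alt = "G",
                    inheritance = "dominant_paternal")
  fa <- mkCalls(c(1e6, 3e6), c(1L, 1L))
  mo <- mkCalls(c(1e6, 3e6), c(0L, 0L))
  snps <- selectInformativeSnps(fa, mo, v, 5e6)
  pro <- mkCalls(c(1e6, 3e6), c(1L, NA))
  ph <- anchorParentalPhase(snps, pro, data.frame(embryo_id = "P",
                                                  call = "carrier"), v)
  expect_equal(ph@fatherHap[, 1], c(fatherM = "G", fatherN = "A"),
               ignore_attr = TRUE)
  expect_equal(ph@fatherProv, c("anchored", "unresolved"))  # missing: no anchor
  expect_error(
    anchorParentalPhase(snps, pro, data.frame(embryo_id = "P",
                                              call = "wild_type"), v),
    "does not carry")
})

test_that("noise-free anchoring recovers the simulator's carrier haplotype", {
  done <- 0
  for (seed in 401:420) {
    ph <- phaseSimulatedFamily(seed = seed, nMarkers = 30, a = 0, e = 0)
    pro <- ph$truth$embryos[[ph$truth$probandId]]
    if (length(pro$cxPatBp)) next  # anchoring assumes no proband crossover
    anch <- which(ph$phased@fatherProv == "anchored")
    expect_true(length(anch) > 0)
    ## snps are a filtered subset of the truth marker table: map by position
    tidx <- match(ph$snps$pos[anch], ph$truth$markers$pos)
    truthM <- ifelse(ph$truth$fatherHaps[1, tidx] == 1, "G", "A")
    expect_equal(unname(ph$phased@fatherHap[1, anch]), truthM)
    done <- done + 1
  }
  expect_gte(done, 10)
})

test_that("deletion origin is recovered from inside-deletion hemizygosity", {
  ## a paternal-origin deletion pins the proband's inside-deletion calls to
  ## the maternal allele at every father-het/mother-hom marker; with at
  ## least 3 such markers the origin is recovered in every noise-free run
  sea <- seaDeletionLocus()
  hits <- 0
  for (seed in 501:540) {
    sc <- simScenario(sea, nMarkers = 60, nInsideMarkers = 8, nQcMarkers = 0,
                      adoRate = 0, genotypeError = 0, seed = seed)
    tr <- simulateFamily(sc, targetStatuses = c("carrier", "wild_type",
                                                "wild_type", "wild_type"),
                         probandIndex = 1)
    pro <- tr$embryos[[tr$probandId]]
    if (pro$patIndVar != 1L) next          # condition on a paternal deletion
    calls <- observeGenotypes(tr, 0, 0)
    snps <- selectInformativeSnps(calls$father, calls$mother, sea, 5e6)
    if (sum(snps$insideDeletion & snps$class == "paternal_only") < 3) next
    egt <- EmbryoPGT:::.alignCalls(calls[[tr$probandId]], snps)
    origin <- EmbryoPGT:::.resolveDeletionOrigin(snps, egt)
    expect_identical(origin, "paternal")
    hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("ploidy gate passes diploids, fails monosomy and triploidy", {
  sea <- VariantLocus("chr1", "point", pos = 1e7, ref = "A", alt = "G",
                      inheritance = "dominant_paternal")
  run <- function(ploidy) {
    sc <- simScenario(sea, nMarkers = 60, nEmbryos = 2, nQcMarkers = 120,
                      adoRate = 0.02, genotypeError = 0.01,
                      ploidyEvents = c("none", ploidy), seed = 601)
    tr <- simulateFamily(sc)
    calls <- observeGenotypes(tr, 0.02, 0.01)
    trio <- trioMarkerTable(calls$father, calls$mother)
    list(ok = detectPloidyFailure(trio, calls$E1),
         bad = detectPloidyFailure(trio, calls$E2))
  }
  r <- run("triploid_maternal")
  expect_true(r$ok$ok)
  expect_false(r$bad$ok)
  expect_match(r$bad$reason, "triploid")
  r <- run("monosomy_paternal")
  expect_true(r$ok$ok)
  expect_false(r$bad$ok)
  expect_match(r$bad$reason, "monosomy")
})
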
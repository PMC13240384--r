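## Shared independent oracles and small builders for the test suite.

## exhaustive path enumeration over the 4-state inheritance HMM; the
## independent reference for viterbiPath(): max log-probability, then
## fewest switches, then lexicographically smallest path (M before N)
STATE_PAT <- c(1L, 1L, 2L, 2L)
STATE_MAT <- c(1L, 2L, 1L, 2L)
SWITCHES <- outer(1:4, 1:4, function(i, j)
  (STATE_PAT[i] != STATE_PAT[j]) + (STATE_MAT[i] != STATE_MAT[j]))

bruteForceViterbi <- function(logE, r, eps = 1e-9) {
  n <- nrow(logE)
  Tl <- lapply(r, function(rr) {
    ls <- log1p(-rr); lw <- if (rr > 0) log(rr) else -Inf
    matrix(ls * (2 - SWITCHES) + lw * SWITCHES, 4, 4)
  })
  ## rows of `paths` are in lexicographic order of the state sequence
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))[, n:1, drop = FALSE]
  sc <- rowSums(matrix(logE[cbind(rep(1:n, each = nrow(paths)),
                                  as.vector(paths))], ncol = n))
  if (n > 1) for (k in 1:(n - 1))
    sc <- sc + Tl[[k]][cbind(paths[, k], paths[, k + 1])]
  sw <- if (n > 1)
    rowSums(matrix(SWITCHES[cbind(paths[, 1:(n - 1)], paths[, 2:n])],
                   ncol = n - 1))
  else rep(0L, nrow(paths))
  m <- max(sc)
  cand <- which(sc >= m - eps)
  cand <- cand[sw[cand] == min(sw[cand])]
  best <- cand[1]
  list(states = unname(paths[best, ]), logProb = sc[best],
       nSwitches = sw[best])
}

## brute-force piecewise-linear evaluator for genetic-map interpolation
## (constant extrapolation outside the table)
piecewiseLinearCM <- function(positions, cumCM, x) {
  vapply(x, function(p) {
    if (p <= positions[1]) return(cumCM[1])
    n <- length(positions)
    if (p >= positions[n]) return(cumCM[n])
    i <- max(which(positions <= p))
    if (positions[i] == p) return(cumCM[i])
    w <- (p - positions[i]) / (positions[i + 1] - positions[i])
    cumCM[i] + w * (cumCM[i + 1] - cumCM[i])
  }, numeric(1))
}

## end-to-end phasing of one simulated dominant family
phaseSimulatedFamily <- function(seed, nMarkers = 30, nEmbryos = 4,
                                 a = 0.05, e = 0.01,
                                 inheritance = "dominant_paternal",
                                 nQcMarkers = 0) {
  v <- VariantLocus("chr8", "point", pos = 119124000, ref = "C", alt = "T",
                    inheritance = inheritance)
  sc <- simScenario(v, nMarkers = nMarkers, nEmbryos = nEmbryos,
                    adoRate = a, genotypeError = e,
                    nQcMarkers = nQcMarkers, seed = seed)
  tr <- simulateFamily(sc)
  calls <- observeGenotypes(tr, a, e)
  snps <- selectInformativeSnps(calls$father, calls$mother, v, 5e6)
  ph <- anchorParentalPhase(snps, calls[[tr$probandId]],
                            data.frame(embryo_id = tr$probandId,
                                       call = "carrier"), v)
  dec <- decodePaths(ph, calls[names(tr$embryos)], EmissionModel(a, e),
                     tr$map)
  list(variant = v, truth = tr, calls = calls, snps = snps,
       phased = dec$phased, paths = dec$paths)
}

## build the packaged fixture once per test session (written to a temp dir)
fixtureOnce <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeTable4Fixture(dir = tempfile("table4fix"), seed = 20260)
    cache
  }
})

## minimal hand-built PhasedParents around a variant at `vpos`
tinyPhasedParents <- function(vpos, positions, fatherM, fatherN,
                              motherM = NULL, motherN = NULL,
                              inheritance = "dominant_paternal",
                              variant = NULL) {
  n <- length(positions)
  if (is.null(variant))
    variant <- VariantLocus("chr1", "point", pos = vpos, ref = "A", alt = "G",
                            inheritance = inheritance)
  if (is.null(motherM)) { motherM <- rep("A", n); motherN <- rep("A", n) }
  fgt <- ifelse(fatherM == fatherN, ifelse(fatherM == "A", 0L, 2L), 1L)
  mgt <- ifelse(motherM == motherN, ifelse(motherM == "A", 0L, 2L), 1L)
  mk <- data.frame(chrom = "chr1", pos = positions, ref = "A", alt = "G",
                   fatherGt = fgt, motherGt = mgt,
                   class = ifelse(fgt == 1L & mgt == 1L, "double_het",
                                  ifelse(fgt == 1L, "paternal_only",
                                         "maternal_only")),
                   insideDeletion = FALSE, stringsAsFactors = FALSE)
  new("PhasedParents", markers = mk,
      fatherHap = rbind(fatherM, fatherN), motherHap = rbind(motherM, motherN),
      fatherProv = ifelse(fgt == 1L, "anchored", "hom"),
      motherProv = ifelse(mgt == 1L, "anchored", "hom"),
      fatherCarrier = inheritance %in% c("dominant_paternal",
                                         "recessive_biallelic"),
      motherCarrier = inheritance %in% c("dominant_maternal",
                                         "recessive_biallelic"),
      variant = variant, probandId = "P")
}

tinyPath <- function(id, paternal, maternal, failed = FALSE) {
  n <- length(paternal)
  new("InheritancePath", embryoId = id, paternal = as.integer(paternal),
      maternal = as.integer(maternal), skipped = rep(FALSE, n),
      logProb = 0, margin = 1, breakpoints = data.frame(),
      failed = failed,
      failureReason = if (failed) "test" else NA_character_)
}
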
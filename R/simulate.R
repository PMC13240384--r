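## Seeded simulator: families, meioses with map-distributed crossovers,
## genotype observation through the ADO + error model, GC-biased
## negative-binomial depth profiles, and the packaged regression fixture.

#' SimScenario: parameters of a simulated family
#'
#' Defines the data-generating process the phasing method assumes: markers
#' placed in the window around the variant (uniform by default, allele
#' frequencies uniform on 0.2-0.8), Mendelian transmission with crossovers
#' drawn as a Poisson process on the genetic-map (cM) scale, optional
#' per-embryo ploidy events, the shared ADO + error observation model, and
#' a negative-binomial depth model for the CNV module. Fully reproducible
#' given `seed`.
#'
#' @slot nMarkers Number of window markers (default 30).
#' @slot windowBp Window half-width (default 5e6).
#' @slot variant The [VariantLocus-class] (defines the carrier parent(s)).
#' @slot nEmbryos Number of embryos (default 4).
#' @slot adoRate,genotypeError Observation model rates (defaults 0.05, 0.01).
#' @slot missingRate Per-call missing probability (default 0).
#' @slot rateCMperMb Constant map rate (default 1 cM/Mb).
#' @slot nInsideMarkers Markers forced inside a deletion interval (default 3).
#' @slot nQcMarkers Genome-wide QC markers on other chromosomes used by the
#'   ploidy gate (default 120).
#' @slot ploidyEvents Character per embryo: `"none"`, `"triploid_maternal"`,
#'   `"triploid_paternal"`, `"monosomy_paternal"`, `"monosomy_maternal"`.
#' @slot markerPositions Optional explicit window marker positions.
#' @slot depthMean,depthDispersion Negative-binomial depth model (mean
#'   reads per bin and dispersion; size = 1/dispersion).
#' @slot seed RNG seed.
#' @name SimScenario-class
#' @aliases SimScenario
#' @export
setClass("SimScenario",
  representation(
    nMarkers = "numeric", windowBp = "numeric", variant = "VariantLocus",
    nEmbryos = "numeric", adoRate = "numeric", genotypeError = "numeric",
    missingRate = "numeric", rateCMperMb = "numeric",
    nInsideMarkers = "numeric", nQcMarkers = "numeric",
    ploidyEvents = "character", markerPositions = "numeric",
    depthMean = "numeric", depthDispersion = "numeric", seed = "numeric"
  ))

#' Construct a SimScenario
#' @param variant A [VariantLocus-class].
#' @param nMarkers,windowBp,nEmbryos,adoRate,genotypeError,missingRate
#'   See [SimScenario-class].
#' @param rateCMperMb,nInsideMarkers,nQcMarkers,ploidyEvents,markerPositions
#'   See [SimScenario-class].
#' @param depthMean,depthDispersion,seed See [SimScenario-class].
#' @return A validated `SimScenario`.
#' @export
simScenario <- function(variant, nMarkers = 30, windowBp = 5e6,
                        nEmbryos = 4, adoRate = 0.05, genotypeError = 0.01,
                        missingRate = 0, rateCMperMb = 1,
                        nInsideMarkers = 3, nQcMarkers = 120,
                        ploidyEvents = "none",
                        markerPositions = numeric(0),
                        depthMean = 100, depthDispersion = 0.1, seed = 1) {
  stopifnot(adoRate >= 0, genotypeError >= 0, adoRate + genotypeError < 1,
            missingRate >= 0, missingRate < 1, nMarkers >= 2,
            depthDispersion > 0)
  ploidyEvents <- rep_len(ploidyEvents, nEmbryos)
  ok <- c("none", "triploid_maternal", "triploid_paternal",
          "triploid_maternal_window_isodisomic",
          "monosomy_paternal", "monosomy_maternal")
  stopifnot(all(ploidyEvents %in% ok))
  new("SimScenario", nMarkers = nMarkers, windowBp = windowBp,
      variant = variant, nEmbryos = nEmbryos, adoRate = adoRate,
      genotypeError = genotypeError, missingRate = missingRate,
      rateCMperMb = rateCMperMb, nInsideMarkers = nInsideMarkers,
      nQcMarkers = nQcMarkers, ploidyEvents = ploidyEvents,
      markerPositions = markerPositions, depthMean = depthMean,
      depthDispersion = depthDispersion, seed = seed)
}

## one meiosis over [lo, hi]: crossovers are a Poisson process on the cM
## scale (Haldane-consistent); returns start haplotype, crossover cM/bp
## positions and an indicator function of physical position
.meiosis <- function(map, lo, hi) {
  cmLo <- interpolateCM(map, lo); cmHi <- interpolateCM(map, hi)
  nCx <- stats::rpois(1, (cmHi - cmLo) / 100)
  cx <- sort(stats::runif(nCx, cmLo, cmHi))
  h0 <- sample(1:2, 1)
  cxBp <- if (nCx)
    stats::approx(map@cumCM, map@positions, xout = cx, rule = 2,
                  ties = "ordered")$y
  else numeric(0)
  indicator <- function(pos) {
    cm <- interpolateCM(map, pos)
    ((h0 - 1 + vapply(cm, function(c0) sum(cx < c0), numeric(1))) %% 2) + 1
  }
  list(h0 = h0, cxCM = cx, cxBp = cxBp, indicator = indicator)
}

## embryo carrier status from the inheritance indicators at the variant
.statusFromIndicators <- function(patM, matM, variant) {
  if (variant@inheritance == "recessive_biallelic") {
    c("wild_type", "carrier", "affected")[patM + matM + 1L]
  } else if (variant@inheritance == "dominant_paternal") {
    if (patM) "carrier" else "wild_type"
  } else {
    if (matM) "carrier" else "wild_type"
  }
}

#' Simulate a family: truth haplotypes, meioses and genotypes
#'
#' Generates parental haplotypes with the variant riding haplotype M of the
#' carrier parent(s), `nEmbryos` embryos by Poisson-crossover meioses, true
#' embryo genotypes (deletion carriers are hemizygous at inside-deletion
#' markers; ploidy events alter the allele complement), genome-wide QC
#' markers for the ploidy gate, and the proband choice (first embryo that
#' demonstrably carries the variant; families without one are redrawn).
#' All truth is retained for scoring.
#'
#' @param scenario A [SimScenario-class].
#' @param targetStatuses Optional character vector of per-embryo statuses;
#'   each embryo's meiosis is redrawn until its truth matches (used to
#'   construct deterministic regression fixtures).
#' @param probandIndex Optional index forcing which embryo is the proband
#'   (it must qualify).
#' @return A truth bundle list: `markers`, `map`, `variant`, parental hap
#'   matrices (`fatherHaps`, `motherHaps`; row 1 = M), `embryos` (per
#'   embryo: indicators, crossovers, true genotypes, status, ploidy), `qc`
#'   (QC marker tables), `probandId`.
#' @export
simulateFamily <- function(scenario, targetStatuses = NULL,
                           probandIndex = NULL) {
  set.seed(scenario@seed)
  v <- scenario@variant
  ctr <- variantPosition(v)
  lo <- max(1, ctr - scenario@windowBp)
  hi <- ctr + scenario@windowBp

  ## constant-rate genetic map over the window (plus margin)
  mapLo <- max(1, lo - 1e6); mapHi <- hi + 1e6
  totalCM <- scenario@rateCMperMb * (mapHi - mapLo) / 1e6
  map <- GeneticMap(v@chrom, c(mapLo, mapHi), c(0, totalCM),
                    rep(scenario@rateCMperMb, 2))

  ## marker positions
  pos <- if (length(scenario@markerPositions)) {
    scenario@markerPositions
  } else {
    p <- round(stats::runif(scenario@nMarkers, lo, hi))
    if (v@kind == "deletion" && scenario@nInsideMarkers > 0) {
      p <- c(p[!(p >= v@delStart & p <= v@delEnd)],
             round(stats::runif(scenario@nInsideMarkers, v@delStart, v@delEnd)))
    }
    p
  }
  pos <- sort(unique(round(pos)))
  n <- length(pos)
  inside <- if (v@kind == "deletion") pos >= v@delStart & pos <= v@delEnd
            else rep(FALSE, n)
  freq <- stats::runif(n, 0.2, 0.8)
  markers <- data.frame(chrom = v@chrom, pos = pos, ref = "A", alt = "G",
                        freq = freq, insideDeletion = inside,
                        stringsAsFactors = FALSE)

  ## row 1 is M for carrier parents
  fatherHaps <- matrix(stats::rbinom(2 * n, 1, freq[col(matrix(0, 2, n))]), 2, n)
  motherHaps <- matrix(stats::rbinom(2 * n, 1, freq[col(matrix(0, 2, n))]), 2, n)

  fatherCarrier <- v@inheritance %in% c("dominant_paternal", "recessive_biallelic")
  motherCarrier <- v@inheritance %in% c("dominant_maternal", "recessive_biallelic")

  ## QC markers: independent biallelic sites on non-variant chromosomes
  nQ <- scenario@nQcMarkers
  qcChrom <- if (nQ) paste0("chrQ", rep(1:2, length.out = nQ)) else character(0)
  qcPos <- round(seq(1e6, 5e7, length.out = nQ))
  qcFreq <- stats::runif(nQ, 0.2, 0.8)
  qcFather <- stats::rbinom(nQ, 2, qcFreq)  # allele-dose genotypes
  qcMother <- stats::rbinom(nQ, 2, qcFreq)
  qcMarkers <- data.frame(chrom = qcChrom, pos = qcPos,
                          ref = rep("A", nQ), alt = rep("G", nQ),
                          fatherGt = qcFather, motherGt = qcMother,
                          stringsAsFactors = FALSE)
  ## per-parent phased QC alleles for transmission
  qcFatherHaps <- rbind(ifelse(qcFather == 2, 1L, ifelse(qcFather == 1, 1L, 0L)),
                        ifelse(qcFather == 2, 1L, 0L))
  qcMotherHaps <- rbind(ifelse(qcMother == 2, 1L, ifelse(qcMother == 1, 1L, 0L)),
                        ifelse(qcMother == 2, 1L, 0L))

  drawEmbryo <- function(id, ploidy) {
    ## a triploid whose meiotic-I error resolved to isodisomy at the locus
    ## behaves disomically at window markers but heterodisomically elsewhere
    ploidyWin <- if (ploidy == "triploid_maternal_window_isodisomic") "none"
                 else ploidy
    ploidyQc <- if (ploidy == "triploid_maternal_window_isodisomic")
                  "triploid_maternal" else ploidy
    mp <- .meiosis(map, lo, hi)
    mm <- .meiosis(map, lo, hi)
    patInd <- mp$indicator(pos); matInd <- mm$indicator(pos)
    patIndVar <- mp$indicator(ctr); matIndVar <- mm$indicator(ctr)
    patM <- fatherCarrier && patIndVar == 1L
    matM <- motherCarrier && matIndVar == 1L
    if (ploidyWin == "monosomy_paternal") patM <- FALSE
    if (ploidyWin == "monosomy_maternal") matM <- FALSE
    if (ploidyWin == "triploid_maternal" && motherCarrier) matM <- TRUE
    if (ploidyWin == "triploid_paternal" && fatherCarrier) patM <- TRUE
    status <- .statusFromIndicators(patM, matM, v)

    ## true window genotypes from the allele complement
    trueGt <- integer(n)
    for (k in seq_len(n)) {
      alle <- integer(0)
      patDeleted <- fatherCarrier && v@kind == "deletion" && inside[k] &&
        patInd[k] == 1L
      matDeleted <- motherCarrier && v@kind == "deletion" && inside[k] &&
        matInd[k] == 1L
      if (ploidyWin != "monosomy_paternal" && !patDeleted) {
        alle <- c(alle, fatherHaps[patInd[k], k])
        if (ploidyWin == "triploid_paternal") alle <- c(alle, fatherHaps[, k])
      }
      if (ploidyWin != "monosomy_maternal" && !matDeleted) {
        alle <- c(alle, motherHaps[matInd[k], k])
        if (ploidyWin == "triploid_maternal") alle <- c(alle, motherHaps[, k])
      }
      trueGt[k] <- if (!length(alle)) NA_integer_
                   else if (any(alle == 1) && any(alle == 0)) 1L
                   else if (all(alle == 1)) 2L else 0L
    }

    ## QC genotypes: independent transmission per marker
    qcGt <- integer(nQ)
    tPat <- sample(1:2, nQ, replace = TRUE)
    tMat <- sample(1:2, nQ, replace = TRUE)
    for (k in seq_len(nQ)) {
      ## QC chromosomes are unaffected by variant-chromosome monosomy
      alle <- c(qcFatherHaps[tPat[k], k], qcMotherHaps[tMat[k], k])
      if (ploidyQc == "triploid_maternal") alle <- c(alle, qcMotherHaps[, k])
      if (ploidyQc == "triploid_paternal") alle <- c(alle, qcFatherHaps[, k])
      qcGt[k] <- if (any(alle == 1) && any(alle == 0)) 1L
                 else if (all(alle == 1)) 2L else 0L
    }

    list(id = id, patInd = patInd, matInd = matInd,
         patIndVar = patIndVar, matIndVar = matIndVar,
         cxPatBp = mp$cxBp, cxMatBp = mm$cxBp,
         ploidy = ploidy, trueGt = trueGt, qcGt = qcGt, status = status)
  }

  qualifies <- function(e) {
    e$ploidy == "none" && e$status %in% c("carrier", "affected")
  }

  if (is.null(targetStatuses)) {
    for (attempt in 1:200) {
      embryos <- lapply(seq_len(scenario@nEmbryos), function(i)
        drawEmbryo(sprintf("E%d", i), scenario@ploidyEvents[i]))
      ok <- vapply(embryos, qualifies, logical(1))
      if (is.null(probandIndex)) { if (any(ok)) break } else if (ok[probandIndex]) break
    }
  } else {
    stopifnot(length(targetStatuses) == scenario@nEmbryos)
    embryos <- lapply(seq_len(scenario@nEmbryos), function(i) {
      for (attempt in 1:2000) {
        e <- drawEmbryo(sprintf("E%d", i), scenario@ploidyEvents[i])
        if (e$status == targetStatuses[i]) return(e)
      }
      stop("could not draw embryo with status ", targetStatuses[i])
    })
  }
  okv <- vapply(embryos, qualifies, logical(1))
  probandId <- if (!is.null(probandIndex)) {
    stopifnot(okv[probandIndex])
    embryos[[probandIndex]]$id
  } else embryos[[which(okv)[1]]]$id
  names(embryos) <- vapply(embryos, `[[`, character(1), "id")

  list(markers = markers, map = map, variant = v,
       fatherHaps = fatherHaps, motherHaps = motherHaps,
       fatherCarrier = fatherCarrier, motherCarrier = motherCarrier,
       embryos = embryos, qcMarkers = qcMarkers, probandId = probandId)
}

#' Sample observed genotype calls through the ADO + error model
#'
#' Draws observed calls from the exact conditional distributions of
#' [emissionProb()] (shared model, so the decoding likelihood is
#' well-specified): a true het is observed het with probability
#' `1 - a - e` and as either homozygote with probability `(a + e)/2`; a
#' true hom is correct with probability `1 - e`.
#'
#' @param trueGt Integer vector of true codes (0/1/2, NA propagates).
#' @param adoRate,genotypeError Model rates.
#' @param missingRate Additional per-call missing probability.
#' @return Integer vector of observed codes.
#' @export
sampleObservedGt <- function(trueGt, adoRate, genotypeError, missingRate = 0) {
  a <- adoRate; e <- genotypeError
  n <- length(trueGt)
  obs <- trueGt
  u <- stats::runif(n)
  het <- !is.na(trueGt) & trueGt == 1L
  obs[het & u < (a + e) / 2] <- 0L
  obs[het & u >= (a + e) / 2 & u < a + e] <- 2L
  hom <- !is.na(trueGt) & trueGt != 1L
  obs[hom & u < e / 2] <- 1L
  flip <- hom & u >= e / 2 & u < e
  obs[flip] <- 2L - trueGt[flip]
  if (missingRate > 0) obs[stats::runif(n) < missingRate] <- NA_integer_
  obs
}

#' Observed genotype calls for a simulated family
#'
#' Parents (blood-derived DNA) receive genotype error only; embryos (WGA
#' products) receive the full ADO + error model. Window and QC markers are
#' combined into VCF-ready per-sample call tables.
#'
#' @param truth Output of [simulateFamily()].
#' @param adoRate,genotypeError,missingRate Observation parameters.
#' @param seed Optional seed (default: continue the current RNG stream).
#' @return Named list of call data.frames: `father`, `mother`, one per
#'   embryo id.
#' @export
observeGenotypes <- function(truth, adoRate = 0.05, genotypeError = 0.01,
                             missingRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- truth$markers
  qc <- truth$qcMarkers
  site <- function(gt, qcGt) {
    data.frame(chrom = c(mk$chrom, qc$chrom), pos = c(mk$pos, qc$pos),
               ref = "A", alt = "G", gt = c(gt, qcGt),
               stringsAsFactors = FALSE)
  }
  fgt <- truth$fatherHaps[1, ] + truth$fatherHaps[2, ]
  mgt <- truth$motherHaps[1, ] + truth$motherHaps[2, ]
  out <- list(
    father = site(sampleObservedGt(fgt, 0, genotypeError, missingRate),
                  sampleObservedGt(qc$fatherGt, 0, genotypeError, missingRate)),
    mother = site(sampleObservedGt(mgt, 0, genotypeError, missingRate),
                  sampleObservedGt(qc$motherGt, 0, genotypeError, missingRate))
  )
  for (e in truth$embryos) {
    out[[e$id]] <- site(
      sampleObservedGt(e$trueGt, adoRate, genotypeError, missingRate),
      sampleObservedGt(e$qcGt, adoRate, genotypeError, missingRate))
  }
  out
}

#' Observed direct mutation test for one embryo
#'
#' The assay (Sanger / Gap-PCR) reports the embryo's true variant status,
#' fails entirely with probability `failureRate`, and - for ADO at the
#' variant site itself - reports a true carrier as wild-type with
#' probability `adoRate`.
#'
#' @param status True status (`wild_type`/`carrier`/`affected`).
#' @param embryoId Embryo id.
#' @param failureRate,adoRate Assay failure / variant-site dropout rates.
#' @param method Label written into the result.
#' @return One-row data.frame (embryo_id, call, method).
#' @export
observeDirectTest <- function(status, embryoId, failureRate = 0,
                              adoRate = 0, method = "sanger") {
  call <- status
  if (stats::runif(1) < failureRate) call <- "failed"
  else if (status == "carrier" && stats::runif(1) < adoRate) call <- "wild_type"
  data.frame(embryo_id = embryoId, call = call, method = method,
             stringsAsFactors = FALSE)
}

## smooth unimodal GC bias curve used by the depth simulator
.gcBiasCurve <- function(gc) exp(-((gc - 0.45)^2) / (2 * 0.08^2))

#' Simulate a GC-biased negative-binomial depth profile and panel
#'
#' Per-bin counts are negative binomial with mean
#' `mu = depthMean * bias(gc) * cn/2` and variance `mu * (1 + dispersion)`
#' (size `mu/dispersion`), where the
#' copy-number multiplier comes from injected events: whole-chromosome or
#' interval gains/losses at a cell-fraction `level` give
#' `cn/2 = (2 + level * delta)/2`. A panel of euploid controls with the
#' same bias is generated, GC-normalized and summarised per bin.
#'
#' @param chromSizes Named chromosome lengths.
#' @param events List of `list(chrom, start, end, delta, level)`; omit
#'   start/end for whole-chromosome events; `delta` +1 (gain) or -1
#'   (loss); `level` in (0, 1], default 1. `chrom = "*"` applies genome
#'   wide (triploidy).
#' @param depthMean,dispersion Depth model (defaults 1000 reads/bin -
#'   roughly 9 million reads over 400-kb windows - and dispersion 0.1,
#'   i.e. 10% extra-Poisson variance).
#' @param nPanel Number of control samples (default 20).
#' @param window,step Bin grid (defaults 400 kb / 200 kb).
#' @param seed Optional seed.
#' @param gc Optional per-bin GC fractions (drawn Beta(50, 70) if omitted).
#' @param panel Optional pre-built [ReferencePanel-class] to reuse across
#'   sibling embryos (it must share `gc`).
#' @return list(profile = raw [BinProfile-class], panel =
#'   [ReferencePanel-class], cn = per-bin multiplier used, gc = gc).
#' @export
simulateDepth <- function(chromSizes, events = list(), depthMean = 1000,
                          dispersion = 0.1, nPanel = 20,
                          window = 400000, step = 200000, seed = NULL,
                          gc = NULL, panel = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bins <- makeBins(chromSizes, window, step)
  nb <- length(bins)
  if (is.null(gc)) gc <- stats::rbeta(nb, 50, 70)
  bias <- .gcBiasCurve(gc)
  cn <- rep(1, nb)  # multiplier on the diploid mean
  chrom <- as.character(GenomicRanges::seqnames(bins))
  st <- GenomicRanges::start(bins)
  for (ev in events) {
    lvl <- ev$level %||% 1
    hit <- if (identical(ev$chrom, "*")) rep(TRUE, nb) else chrom == ev$chrom
    if (!is.null(ev$start))
      hit <- hit & st >= ev$start & GenomicRanges::end(bins) <= ev$end
    cn[hit] <- (2 + lvl * ev$delta) / 2
  }
  mu <- depthMean * bias * cn
  counts <- stats::rnbinom(nb, mu = mu, size = mu / dispersion)
  profile <- binProfile(bins, gc, counts, window, step)
  if (is.null(panel)) {
    mu0 <- depthMean * bias
    controls <- lapply(seq_len(nPanel), function(i) {
      ct <- stats::rnbinom(nb, mu = mu0, size = mu0 / dispersion)
      gcNormalize(binProfile(bins, gc, ct, window, step))
    })
    panel <- referencePanel(controls)
  }
  list(profile = profile, panel = panel, cn = cn, gc = gc)
}
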
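## HMM decoding of embryo inheritance vectors.
##
## Hidden state at each marker: (paternal indicator, maternal indicator),
## each in {1, 2} with 1 = M (or H1) and 2 = N (or H2); four joint states
## ordered (1,1), (1,2), (2,1), (2,2). Transitions between consecutive
## markers factor per parent: switch with the map-derived recombination
## fraction r, stay with 1 - r. Emissions come from the ADO + error model
## given the parental phased alleles; unresolved parental assignments are
## marginalized. All computation is in log space.

.STATE_PAT <- c(1L, 1L, 2L, 2L)
.STATE_MAT <- c(1L, 2L, 1L, 2L)
## per-parent switch counts between joint states
.SWITCHES <- outer(seq_len(4), seq_len(4), function(i, j)
  (.STATE_PAT[i] != .STATE_PAT[j]) + (.STATE_MAT[i] != .STATE_MAT[j]))

## 4x4 log transition matrix for one marker gap
.logTrans <- function(r) {
  lStay <- log1p(-r)
  lSw <- if (r > 0) log(r) else -Inf
  matrix(lStay * (2 - .SWITCHES) + lSw * .SWITCHES, 4, 4)
}

#' Viterbi decoding of a 4-state inheritance HMM
#'
#' Exact maximum-log-probability state path over the four joint parental
#' inheritance states, with deterministic tie-breaking: among paths tied on
#' log-probability, the one with fewest indicator switches wins, and
#' remaining ties resolve lexicographically with M (state 1) before N.
#' A uniform prior over the four starting states is used (constant across
#' paths, so it is omitted from the reported log-probability).
#'
#' @param logEmission `n x 4` matrix of log emission probabilities, columns
#'   ordered (M,M), (M,N), (N,M), (N,N).
#' @param r Numeric vector (length `n - 1`) of recombination fractions
#'   between consecutive markers.
#' @param eps Tolerance for log-probability ties (default 1e-9).
#' @return list(states, logProb, nSwitches, margin) where `states` is the
#'   decoded joint-state index (1-4) per marker and `margin` the
#'   log-probability gap to the second-best path.
#' @export
viterbiPath <- function(logEmission, r, eps = 1e-9) {
  n <- nrow(logEmission)
  stopifnot(ncol(logEmission) == 4, length(r) == max(n - 1, 0))
  if (n == 0) stop("no markers")
  Tlist <- lapply(r, .logTrans)

  ## backward DP over the pair objective (max score, then min switches);
  ## forward reconstruction then yields the lexicographically smallest
  ## optimal path.
  Bsc <- matrix(-Inf, n, 4); Bsw <- matrix(0L, n, 4)
  Bsc[n, ] <- logEmission[n, ]
  if (n > 1) for (k in (n - 1):1) {
    Tk <- Tlist[[k]]
    for (s in 1:4) {
      cs <- Tk[s, ] + Bsc[k + 1, ]
      cw <- .SWITCHES[s, ] + Bsw[k + 1, ]
      m <- max(cs)
      elig <- which(cs >= m - eps)
      pick <- elig[order(cw[elig], elig)][1]
      Bsc[k, s] <- logEmission[k, s] + cs[pick]
      Bsw[k, s] <- cw[pick]
    }
  }
  m <- max(Bsc[1, ])
  elig <- which(Bsc[1, ] >= m - eps)
  s <- elig[order(Bsw[1, elig], elig)][1]
  states <- integer(n); states[1] <- s
  logProb <- Bsc[1, s]; nSw <- Bsw[1, s]
  if (n > 1) for (k in 1:(n - 1)) {
    Tk <- Tlist[[k]]
    cs <- Tk[s, ] + Bsc[k + 1, ]
    cw <- .SWITCHES[s, ] + Bsw[k + 1, ]
    mm <- max(cs)
    elig <- which(cs >= mm - eps)
    s <- elig[order(cw[elig], elig)][1]
    states[k + 1] <- s
  }

  ## top-2 forward pass for the posterior margin
  v1 <- logEmission[1, ]; v2 <- rep(-Inf, 4)
  if (n > 1) for (k in 1:(n - 1)) {
    Tk <- Tlist[[k]]
    n1 <- numeric(4); n2 <- numeric(4)
    for (s2 in 1:4) {
      cand <- c(v1 + Tk[, s2], v2 + Tk[, s2])
      o <- sort(cand, decreasing = TRUE)
      n1[s2] <- o[1] + logEmission[k + 1, s2]
      n2[s2] <- o[2] + logEmission[k + 1, s2]
    }
    v1 <- n1; v2 <- n2
  }
  all2 <- sort(c(v1, v2), decreasing = TRUE)
  margin <- if (length(all2) >= 2 && is.finite(all2[2])) all2[1] - all2[2] else Inf

  list(states = states, logProb = logProb, nSwitches = nSw, margin = margin)
}

## ---- emissions ------------------------------------------------------------

## weighted allele options (codes 0/1) for one parent at one marker:
## resolved -> one (a1, a2); het unresolved -> both orderings at 1/2;
## parent genotype missing -> all four combinations at 1/4.
.parentOptions <- function(hapCol, gt, ref, alt) {
  if (!is.na(hapCol[1]) && !is.na(hapCol[2])) {
    code <- as.integer(c(hapCol[1] == alt, hapCol[2] == alt))
    return(list(a = matrix(code, 1, 2), w = 1))
  }
  if (!is.na(gt) && gt == 1L) {
    return(list(a = rbind(c(0L, 1L), c(1L, 0L)), w = c(0.5, 0.5)))
  }
  if (!is.na(gt)) {  # hom but hap not filled (should not happen; be safe)
    c0 <- if (gt == 0L) 0L else 1L
    return(list(a = matrix(c(c0, c0), 1, 2), w = 1))
  }
  list(a = as.matrix(expand.grid(0:1, 0:1)), w = rep(0.25, 4))
}

## n x 4 emission probability matrix (linear scale) for one embryo.
## Markers with missing embryo genotype emit 1 (skipped). Inside-deletion
## markers for embryos are emitted under the diploid model like any other
## marker (their hemizygosity is used at anchoring time, not here) unless
## dropEmission is TRUE for them.
.emissionMatrix <- function(phased, egt, model, dropInsideDeletion = TRUE) {
  mk <- phased@markers
  n <- nrow(mk)
  E <- matrix(1, n, 4)
  for (k in seq_len(n)) {
    if (is.na(egt[k])) next
    if (dropInsideDeletion && mk$insideDeletion[k]) next
    fo <- .parentOptions(phased@fatherHap[, k], mk$fatherGt[k],
                         mk$ref[k], mk$alt[k])
    mo <- .parentOptions(phased@motherHap[, k], mk$motherGt[k],
                         mk$ref[k], mk$alt[k])
    for (s in 1:4) {
      p <- 0
      for (i in seq_along(fo$w)) for (j in seq_along(mo$w)) {
        tg <- fo$a[i, .STATE_PAT[s]] + mo$a[j, .STATE_MAT[s]]
        p <- p + fo$w[i] * mo$w[j] *
          emissionProb(model, tg, egt[k])
      }
      E[k, s] <- p
    }
  }
  E
}

## ---- joint decoding -------------------------------------------------------

#' Decode embryo inheritance paths and refine the parental phase
#'
#' Runs Viterbi decoding for every embryo over the phased-parent HMM, then
#' refines markers whose parental assignment the proband could not anchor
#' (double-het sites, proband-missing sites) by maximizing the joint
#' likelihood across all embryos, in two fixed rounds of phase-assignment /
#' path coordinate ascent. Anchored markers that conflict with the
#' proband's own decoded path (a possible proband crossover between marker
#' and variant) are flagged `conflicted` and excluded from other embryos'
#' diagnoses.
#'
#' @param phased A [PhasedParents-class] from [anchorParentalPhase()].
#' @param embryoCalls Named list of embryo call data.frames (chrom, pos,
#'   ref, alt, gt); include the proband.
#' @param model An [EmissionModel-class].
#' @param map A [GeneticMap-class].
#' @param rounds Rounds of phase/path refinement (default 2).
#' @return list(paths = named list of [InheritancePath-class],
#'   phased = refined `PhasedParents`).
#' @export
decodePaths <- function(phased, embryoCalls, model, map, rounds = 2) {
  stopifnot(length(embryoCalls) >= 1, !is.null(names(embryoCalls)))
  mk <- phased@markers
  n <- nrow(mk)
  egts <- vapply(embryoCalls, .alignCalls, integer(n), markers = mk)
  if (is.null(dim(egts))) egts <- matrix(egts, nrow = n)
  pos <- mk$pos
  r <- if (n > 1)
    vapply(seq_len(n - 1), function(k)
      if (pos[k + 1] > pos[k])
        recombinationFraction(map, pos[k], pos[k + 1]) else 0,
      numeric(1))
  else numeric(0)

  decodeAll <- function(ph) {
    lapply(seq_along(embryoCalls), function(i) {
      egt <- egts[, i]
      if (all(is.na(egt))) return(NULL)
      E <- .emissionMatrix(ph, egt, model)
      viterbiPath(log(E), r)
    })
  }

  dec <- NULL
  for (round in seq_len(rounds)) {
    dec <- decodeAll(phased)
    if (round == rounds) break
    phased <- .refineUnresolved(phased, egts, dec, model)
    phased <- .flagConflictedAnchors(phased, egts, dec, model)
  }

  ## D4: anchored markers contradicted by the proband's own decoded path
  pid <- phased@probandId
  pi <- match(pid, names(embryoCalls))
  if (!is.na(pi) && !is.null(dec[[pi]])) {
    st <- dec[[pi]]$states
    fBad <- phased@fatherProv == "anchored" & .STATE_PAT[st] != 1L
    mBad <- phased@motherProv == "anchored" & .STATE_MAT[st] != 1L
    phased@fatherProv[fBad] <- "conflicted"
    phased@motherProv[mBad] <- "conflicted"
  }

  paths <- lapply(seq_along(embryoCalls), function(i) {
    id <- names(embryoCalls)[i]
    if (is.null(dec[[i]]))
      return(new("InheritancePath", embryoId = id,
                 paternal = rep(NA_integer_, n),
                 maternal = rep(NA_integer_, n),
                 skipped = rep(TRUE, n),
                 logProb = NA_real_, margin = NA_real_,
                 breakpoints = data.frame(), failed = TRUE,
                 failureReason = "all markers missing"))
    st <- dec[[i]]$states
    pat <- .STATE_PAT[st]; mat <- .STATE_MAT[st]
    bp <- rbind(.breakpoints(pat, pos, "paternal"),
                .breakpoints(mat, pos, "maternal"))
    new("InheritancePath", embryoId = id,
        paternal = pat, maternal = mat, skipped = is.na(egts[, i]),
        logProb = dec[[i]]$logProb, margin = dec[[i]]$margin,
        breakpoints = bp, failed = FALSE)
  })
  names(paths) <- names(embryoCalls)
  list(paths = paths, phased = phased)
}

.breakpoints <- function(ind, pos, parent) {
  k <- which(ind[-length(ind)] != ind[-1])
  if (!length(k))
    return(data.frame(parent = character(), afterMarker = integer(),
                      leftPos = numeric(), rightPos = numeric()))
  data.frame(parent = parent, afterMarker = k,
             leftPos = pos[k], rightPos = pos[k + 1])
}

## joint log-likelihood of one marker's emissions across all embryos under
## a trial phase assignment, given the decoded states
.markerJointLL <- function(phased, egts, dec, model, k) {
  mk <- phased@markers
  ll <- 0
  for (i in seq_len(ncol(egts))) {
    if (is.null(dec[[i]]) || is.na(egts[k, i]) || mk$insideDeletion[k]) next
    s <- dec[[i]]$states[k]
    fo <- .parentOptions(phased@fatherHap[, k], mk$fatherGt[k],
                         mk$ref[k], mk$alt[k])
    mo <- .parentOptions(phased@motherHap[, k], mk$motherGt[k],
                         mk$ref[k], mk$alt[k])
    p <- 0
    for (a in seq_along(fo$w)) for (b in seq_along(mo$w)) {
      tg <- fo$a[a, .STATE_PAT[s]] + mo$a[b, .STATE_MAT[s]]
      p <- p + fo$w[a] * mo$w[b] * emissionProb(model, tg, egts[k, i])
    }
    ll <- ll + log(max(p, 1e-300))
  }
  ll
}

## anchored markers whose anchor the joint embryo likelihood strongly
## contradicts (proband ADO at anchoring time, or a proband crossover
## between marker and variant) are flagged 'conflicted' and excluded from
## diagnosis consensus; the maximum-likelihood phase is kept for emissions
.flagConflictedAnchors <- function(phased, egts, dec, model, llGap = 2) {
  mk <- phased@markers
  for (parent in c("father", "mother")) {
    hapSlot <- paste0(parent, "Hap"); provSlot <- paste0(parent, "Prov")
    prov <- slot(phased, provSlot)
    for (k in which(prov == "anchored")) {
      cur <- slot(phased, hapSlot)[, k]
      llCur <- .markerJointLL(phased, egts, dec, model, k)
      trial <- phased
      slot(trial, hapSlot)[, k] <- rev(cur)
      llFlip <- .markerJointLL(trial, egts, dec, model, k)
      if (llFlip - llCur > llGap) {
        slot(phased, hapSlot)[, k] <- rev(cur)
        slot(phased, provSlot)[k] <- "conflicted"
      }
    }
  }
  phased
}

## choose M/N (or H1/H2) assignment at unresolved het markers by joint
## likelihood over all embryos, given the current decoded states (D7)
.refineUnresolved <- function(phased, egts, dec, model) {
  mk <- phased@markers
  nE <- ncol(egts)
  for (parent in c("father", "mother")) {
    hapSlot <- paste0(parent, "Hap"); provSlot <- paste0(parent, "Prov")
    gtCol <- paste0(parent, "Gt")
    prov <- slot(phased, provSlot)
    for (k in which(prov == "unresolved" & !is.na(mk[[gtCol]]) &
                    mk[[gtCol]] == 1L)) {
      ref <- mk$ref[k]; alt <- mk$alt[k]
      ll <- numeric(2)
      for (o in 1:2) {
        trial <- phased
        slot(trial, hapSlot)[, k] <- if (o == 1) c(ref, alt) else c(alt, ref)
        for (i in seq_len(nE)) {
          if (is.null(dec[[i]]) || is.na(egts[k, i])) next
          if (mk$insideDeletion[k]) next
          s <- dec[[i]]$states[k]
          fo <- .parentOptions(slot(trial, "fatherHap")[, k], mk$fatherGt[k],
                               ref, alt)
          mo <- .parentOptions(slot(trial, "motherHap")[, k], mk$motherGt[k],
                               ref, alt)
          p <- 0
          for (a in seq_along(fo$w)) for (b in seq_along(mo$w)) {
            tg <- fo$a[a, .STATE_PAT[s]] + mo$a[b, .STATE_MAT[s]]
            p <- p + fo$w[a] * mo$w[b] * emissionProb(model, tg, egts[k, i])
          }
          ll[o] <- ll[o] + log(max(p, 1e-300))
        }
      }
      ## tie -> M allele = ref (deterministic)
      o <- if (ll[2] > ll[1] + 1e-12) 2 else 1
      slot(phased, hapSlot)[, k] <- if (o == 1) c(ref, alt) else c(alt, ref)
      slot(phased, provSlot)[k] <- "inferred"
    }
  }
  phased
}
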
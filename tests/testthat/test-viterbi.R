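test_that("two-marker trellis matches the hand computation", {
  ## father het (M = G), mother hom A; noise-free het observations at both
  ## markers force the paternal M state; maternal state is free
  r <- 0.01
  E <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0), nrow = 2, byrow = TRUE)
  v <- viterbiPath(log(E), r)
  expect_equal(v$states, c(1L, 1L))   # tie toward M on the free parent
  ## stay on both parents: log((1-r)^2)
  expect_equal(v$logProb, 2 * log(1 - r), tolerance = 1e-12)
  expect_equal(v$nSwitches, 0L)
})

test_that("ties break toward fewer switches then lexicographically (M first)", {
  n <- 3
  E <- matrix(1, n, 4)                   # fully uninformative emissions
  v <- viterbiPath(log(E), rep(0.2, n - 1))
  expect_equal(v$states, rep(1L, n))     # all-M among the 4 tied stay paths
  ## forcing a switch: states (M,M) then (N,N) emission-pinned at ends,
  ## the middle uninformative marker must not add extra switches
  E2 <- rbind(c(1, 0, 0, 0), c(1, 1, 1, 1), c(0, 0, 0, 1))
  v2 <- viterbiPath(log(E2), c(0.1, 0.1))
  expect_equal(v2$nSwitches, 2L)
  expect_equal(v2$states[c(1, 3)], c(1L, 4L))
})

test_that("Viterbi equals exhaustive enumeration on random instances", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    ## mix continuous and tie-prone (0/1) emission values
    E <- if (i %% 2) matrix(runif(n * 4, 0.01, 1), n, 4)
         else matrix(sample(c(1, 1, 0.5, 0.02), n * 4, replace = TRUE), n, 4)
    E[cbind(1:n, sample(1:4, n, replace = TRUE))] <- 1  # keep rows feasible
    r <- runif(n - 1, 0, 0.49)
    v <- viterbiPath(log(E), r)
    b <- bruteForceViterbi(log(E), r)
    expect_equal(v$logProb, b$logProb, tolerance = 1e-9)
    expect_equal(v$states, b$states)
  }
})

test_that("decoding handles skipped markers and all-missing embryos", {
  ph <- phaseSimulatedFamily(seed = 88, nMarkers = 12, a = 0, e = 0,
                             nEmbryos = 2)
  calls <- ph$calls
  id <- setdiff(names(ph$truth$embryos), ph$truth$probandId)[1]
  calls[[id]]$gt[3] <- NA                       # one skipped marker
  blank <- calls[[id]]; blank$gt[] <- NA        # an undecodable embryo
  calls$EX <- blank
  dec <- decodePaths(ph$phased, calls[c(ph$truth$probandId, id, "EX")],
                     EmissionModel(0.05, 0.01), ph$truth$map)
  expect_true(dec$paths[[id]]@skipped[3])
  expect_false(dec$paths[[id]]@failed)
  expect_true(dec$paths$EX@failed)
  expect_match(dec$paths$EX@failureReason, "missing")
  ## breakpoints equal indicator switches
  for (p in dec$paths) {
    if (p@failed) next
    sw <- sum(p@paternal[-1] != p@paternal[-length(p@paternal)]) +
      sum(p@maternal[-1] != p@maternal[-length(p@maternal)])
    expect_equal(nrow(p@breakpoints), sw)
  }
})

test_that("the proband's own decoded path is all-M at anchorable markers", {
  for (seed in 91:95) {
    ph <- phaseSimulatedFamily(seed = seed, nMarkers = 20, a = 0, e = 0)
    pro <- ph$truth$embryos[[ph$truth$probandId]]
    if (length(pro$cxPatBp)) next
    p <- ph$paths[[ph$truth$probandId]]
    anch <- which(ph$phased@fatherProv == "anchored")
    expect_true(all(p@paternal[anch] == 1L))
  }
})

test_that("raising the ADO rate never increases a correct path's margin", {
  ph <- phaseSimulatedFamily(seed = 5, nMarkers = 20, a = 0, e = 0,
                             nEmbryos = 2)
  margins <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.3), function(a) {
    dec <- decodePaths(ph$phased, ph$calls[names(ph$truth$embryos)],
                       EmissionModel(a, 0.01), ph$truth$map)
    dec$paths[[1]]@margin
  }, numeric(1))
  expect_true(all(diff(margins) <= 1e-9))
})
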
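test_that("contact graph applies the inclusive cutoff", {
  two <- function(d) structureFromXYZ(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nEdges(buildContactGraph(two(5), 10)), 1L)
  expect_equal(nEdges(buildContactGraph(two(10), 10)), 1L)  # boundary kept
  expect_equal(nEdges(buildContactGraph(two(10.001), 10)), 0L)

  line4 <- structureFromXYZ(cbind(3.8 * (0:3), 0, 0))
  g <- buildContactGraph(line4, 4)
  expect_equal(g@edges, cbind(i = 1:3, j = 2:4), ignore_attr = TRUE)

  expect_error(buildContactGraph(structureFromXYZ(cbind(0, 0, 0)), 10),
               "degenerate")
  expect_error(buildContactGraph(line4, -1), "positive")
})

test_that("contact graph matches the brute-force pairwise oracle", {
  set.seed(401)
  for (rep in 1:30) {
    n <- sample(5:60, 1)
    xyz <- randomCloud(n)
    rc <- stats::runif(1, 5, 25)
    g <- buildContactGraph(structureFromXYZ(xyz), rc)
    expect_equal(unname(g@edges), unname(bruteContacts(xyz, rc)))
  }
})

test_that("the two-particle Hessian matches the hand-written 6x6", {
  s <- structureFromXYZ(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  p <- enmParams()
  h <- buildHessian(buildContactGraph(s, 10), p)
  k <- p$k2 / p$M
  href <- matrix(0, 6, 6)
  href[1, 1] <- href[4, 4] <- k
  href[1, 4] <- href[4, 1] <- -k
  expect_equal(h, href, tolerance = 1e-12)
})

test_that("Hessian rows sum to zero and scale linearly in k2", {
  g <- buildContactGraph(makeGlobule(15, seed = 8), 10)
  h <- buildHessian(g)
  expect_lt(max(abs(rowSums(h))), 1e-12)
  expect_lt(max(abs(h - t(h))), 1e-12 * max(abs(h)))
  h2 <- buildHessian(g, enmParams(k2 = 10))
  expect_equal(h2, 2 * h, tolerance = 1e-12)
  # coincident atoms are refused
  bad <- structureFromXYZ(rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0)))
  expect_error(buildHessian(buildContactGraph(bad, 10)), "oincident")
})

test_that("mode spectrum: dimer has 5 zero modes and one at 2 k2/M", {
  s <- structureFromXYZ(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  m <- computeModes(buildHessian(buildContactGraph(s, 10)))
  expect_equal(m@nZero, 5L)
  expect_equal(m@eigenvalues[6], 2 * 5 / 120, tolerance = 1e-12)
  expect_lt(max(abs(m@eigenvalues[1:5])), 1e-12)
})

test_that("zero-mode count: 6 when connected, degenerate cases reported", {
  m <- computeModes(buildHessian(buildContactGraph(
    makeGlobule(20, seed = 4), 12)))
  expect_equal(m@nZero, 6L)
  expect_gt(min(m@eigenvalues), -1e-9 * max(m@eigenvalues))

  # collinear chain: springs act along the axis only, so every transverse
  # displacement is unrestrained -> 2N + 1 zero modes (5 only when N = 2)
  line <- structureFromXYZ(cbind(3.8 * (0:3), 0, 0))
  expect_equal(computeModes(buildHessian(buildContactGraph(line, 4)))@nZero,
               9L)

  # two disconnected dimers: 5 zero modes each
  split <- structureFromXYZ(rbind(c(0, 0, 0), c(3.8, 0, 0),
                                  c(100, 0, 0), c(103.8, 0, 0)))
  expect_equal(computeModes(buildHessian(buildContactGraph(split, 10)))@nZero,
               10L)
})

test_that("eigendecomposition reconstructs the Hessian (spectral theorem)", {
  h <- buildHessian(buildContactGraph(makeGlobule(12, seed = 6), 11))
  m <- computeModes(h)
  rec <- m@eigenvectors %*% (m@eigenvalues * t(m@eigenvectors))
  expect_equal(rec, h, tolerance = 1e-8)
  expect_equal(crossprod(m@eigenvectors), diag(nrow(h)), tolerance = 1e-8)
})

test_that("stiffness sums to the number of included modes", {
  for (s in list(makeHelix(10), makeGlobule(20, seed = 9),
                 makeDimer(12, seed = 2))) {
    m <- computeModes(buildHessian(buildContactGraph(s, 12)))
    chi <- indicatorValues(spectralStiffness(m))
    expect_equal(sum(chi), 5, tolerance = 1e-10)
    expect_true(all(chi >= 0))
    # completeness: all internal modes sum to 3N - nZero
    pAll <- enmParams(nTopModes = length(m@eigenvalues) - m@nZero)
    expect_equal(sum(indicatorValues(spectralStiffness(m, pAll))),
                 length(m@eigenvalues) - m@nZero, tolerance = 1e-10)
  }
})

test_that("stiffness is invariant under rigid motion and k2 rescaling", {
  s <- makeGlobule(18, seed = 12)
  chi <- function(s, p = enmParams()) {
    indicatorValues(spectralStiffness(
      computeModes(buildHessian(buildContactGraph(s, 12), p)), p))
  }
  base <- chi(s)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- coords(s) %*% rot + matrix(c(5, -3, 11), nResidues(s), 3,
                                     byrow = TRUE)
  expect_equal(chi(structureFromXYZ(xyz2)), base, tolerance = 1e-8)
  expect_equal(chi(s, enmParams(k2 = 50)), base, tolerance = 1e-8)
})

test_that("the stiffness maximum sits at the planted hub at 10 A", {
  inHub <- 0L
  for (seed in 1:5) {
    ph <- makePlantedHub(seed = seed)
    m <- computeModes(buildHessian(buildContactGraph(ph$structure, 10)))
    am <- which.max(indicatorValues(spectralStiffness(m)))
    # always within one residue of the hub block (the chain residues
    # entering the dense ball are themselves part of the stiff center)
    expect_lte(min(abs(am - ph$hubIndices)), 1)
    if (am %in% ph$hubIndices) inHub <- inHub + 1L
  }
  expect_gte(inHub, 3L)
})

test_that("asking for more modes than exist is an explicit error", {
  s <- structureFromXYZ(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  m <- computeModes(buildHessian(buildContactGraph(s, 10)))
  expect_error(spectralStiffness(m, enmParams(nTopModes = 2)),
               "nTopModes")
})
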
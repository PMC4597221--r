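test_that("sequence distance is |i-j| within a chain, Inf across", {
  d <- makeDimer(10, seed = 1)
  expect_equal(sequenceDistance(3, 5, d), 2)
  expect_equal(sequenceDistance(4, 4, d), 0)
  expect_equal(sequenceDistance(1, 11, d), Inf)  # chain A vs chain B
  expect_error(sequenceDistance(0, 1, d), "out of range")
})

test_that("fractionRecovered counts catalytic residues near peaks", {
  s <- structureFromXYZ(cbind(3.8 * (0:59), 0, 0))
  expect_equal(fractionRecovered(12L, 11L, 1, s), 1)
  expect_equal(fractionRecovered(12L, 11L, 0, s), 0)
  expect_equal(fractionRecovered(c(11L, 40L), c(11L, 40L), 0, s), 1)
  # catalytic at 6 and 51, peak at 8: distances 2 and 43
  expect_equal(fractionRecovered(8L, c(6L, 51L), 2, s), 0.5)
  expect_equal(fractionRecovered(integer(), 5L, 3, s), 0)
  expect_error(fractionRecovered(8L, integer(), 1, s), "undefined")
})

test_that("fractionRecovered is monotone in dn and in the peak set", {
  set.seed(407)
  s <- structureFromXYZ(cbind(3.8 * (0:99), 0, 0))
  for (rep in 1:10) {
    cat_idx <- sort(sample(100, 5))
    pk <- sort(sample(100, 4))
    fr <- vapply(0:6, function(d) fractionRecovered(pk, cat_idx, d, s),
                 numeric(1))
    expect_true(all(diff(fr) >= 0))
    pk2 <- sort(union(pk, sample(100, 2)))
    expect_gte(fractionRecovered(pk2, cat_idx, 2, s),
               fractionRecovered(pk, cat_idx, 2, s))
  }
})

test_that("scan produces one reduced pattern per (cutoff, indicator)", {
  s <- makeGlobule(30, seed = 21)
  sr <- scanCutoffs(s, cutoffs = c(8, 20, 40))
  expect_s4_class(sr, "ScanResult")
  expect_equal(length(sr@cutoffs), 3L)
  entries <- unlist(lapply(sr@patterns, function(e)
    vapply(e, Negate(is.null), logical(1))))
  expect_equal(sum(entries), 9L)
  expect_equal(nrow(sr@status), 3L)
  expect_false(any(sr@status$failed))
})

test_that("beyond the structure diameter conn and cc lose all peaks", {
  s <- makeGlobule(25, seed = 22)
  diam <- max(stats::dist(coords(s)))
  sr <- scanCutoffs(s, cutoffs = ceiling(diam) + 1)
  rc <- as.character(ceiling(diam) + 1)
  expect_equal(nPeaks(sr@patterns[[rc]]$conn), 0L)
  expect_equal(nPeaks(sr@patterns[[rc]]$cc), 0L)
})

test_that("evaluation metrics follow their definitions", {
  s <- structureFromXYZ(cbind(3.8 * (0:99), 0, 0), id = "line")
  # synthetic ReducedPattern with a single peak at the catalytic site
  mk <- function(pk, ind, rc) {
    filt <- numeric(100)
    filt[pk] <- 1
    new("ReducedPattern", indicator = ind, cutoff = rc, structureId = "line",
        raw = filt, filtered = filt, processed = filt,
        peaks = as.integer(pk), nSigma = 1)
  }
  sr <- new("ScanResult", structure = s, cutoffs = 10,
            patterns = list(`10` = list(chi = mk(11L, "chi", 10),
                                        conn = mk(integer(), "conn", 10),
                                        cc = mk(c(11L, 31L, 51L, 71L),
                                                "cc", 10))),
            status = data.frame(cutoff = 10, nEdges = 0L,
                                nComponents = 1L, connected = TRUE,
                                failed = FALSE, message = ""))
  ann <- new("AnnotationSet", structureId = "line",
             sites = data.frame(chain = "A", resno = c(11L, 31L),
                                icode = ""))
  met <- evaluateScan(sr, ann, dn = 0)
  chi <- met[met$indicator == "chi", ]
  expect_equal(chi$peak_fraction, 0.01)
  expect_equal(chi$frac_within, 0.5)
  expect_equal(chi$reliability, 50)
  conn <- met[met$indicator == "conn", ]
  expect_equal(conn$frac_within, 0)
  expect_true(is.na(conn$reliability))      # no peaks: undefined
  cc <- met[met$indicator == "cc", ]
  expect_equal(cc$peaks_per_site, 2)        # 4 peaks / 2 sites
  expect_equal(cc$frac_within, 1)
})

test_that("pooled aggregation equals recomputing from the union", {
  mkScan <- function(s, pk, rc = 10) {
    filt <- numeric(nResidues(s))
    filt[pk] <- 1
    rp <- new("ReducedPattern", indicator = "chi", cutoff = rc,
              structureId = structureId(s), raw = filt, filtered = filt,
              processed = filt, peaks = as.integer(pk), nSigma = 1)
    new("ScanResult", structure = s, cutoffs = rc,
        patterns = stats::setNames(
          list(list(chi = rp, conn = NULL, cc = NULL)), as.character(rc)),
        status = data.frame(cutoff = rc, nEdges = 0L, nComponents = 1L,
                            connected = TRUE, failed = FALSE,
                            message = ""))
  }
  lineS <- function(n, id) structureFromXYZ(cbind(3.8 * seq_len(n), 0, 0),
                                            id = id)
  annFor <- function(s, resno) new("AnnotationSet",
                                   structureId = structureId(s),
                                   sites = data.frame(chain = "A",
                                                      resno = resno,
                                                      icode = ""))
  s1 <- lineS(50, "a"); s2 <- lineS(300, "b"); s3 <- lineS(500, "c")
  scans <- list(mkScan(s1, 10L), mkScan(s2, 100L), mkScan(s3, integer()))
  anns <- list(annFor(s1, 10L), annFor(s2, 250L), annFor(s3, 400L))
  agg <- aggregateScans(scans, anns, dn = 0,
                        sizeBreaks = c(200, 400))
  # recovered: structure a yes, b no, c no -> 1/3 pooled
  expect_equal(agg$overall$frac_within, 1 / 3)
  expect_equal(agg$overall$peak_fraction,
               mean(c(1 / 50, 1 / 300, 0)))
  # size classes partition the set
  expect_setequal(agg$classes, c("[-Inf,200]", "(200,400]", "(400, Inf]"))
  expect_equal(sum(agg$byClass$n_catalytic), 3)
  # single structure aggregates to itself
  one <- aggregateScans(scans[1], anns[1], dn = 0, sizeBreaks = c(200, 400))
  expect_equal(one$overall$frac_within, 1)
})

test_that("connectivity peak fraction grows toward large cutoffs", {
  # over several globules the mean conn peak fraction at 30 A is at least
  # that at 14 A (the trivial inflation of degree peaks with cutoff)
  # cutoffs chosen inside the toy globules' pre-blur regime (their
  # diameter is ~20 A, beyond which the constant pattern has no peaks)
  pf <- function(s, rc) {
    nPeaks(reducePattern(connectivity(buildContactGraph(s, rc)))) /
      nResidues(s)
  }
  lo <- hi <- numeric()
  for (seed in 1:20) {
    s <- makeGlobule(40, seed = seed)
    lo <- c(lo, pf(s, 10)); hi <- c(hi, pf(s, 16))
  }
  expect_gte(mean(hi), mean(lo))
})
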
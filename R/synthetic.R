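## Deterministic toy C-alpha structures: every generator is a pure function
## of its arguments + seed (Mersenne-Twister, restored on exit) so fixtures
## never need to ship with the package.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

randUnit <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

asCAStructure <- function(xyz, structureId, chain = "A",
                          resno = seq_len(nrow(xyz))) {
  new("CAStructure", structureId = structureId,
      residues = data.frame(chain = chain, resno = as.integer(resno),
                            icode = "", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE))
}

#' Ideal alpha-helix C-alpha trace
#'
#' Radius 2.3 A, rise 1.5 A per residue, 100 degrees per residue, which
#' puts consecutive C-alphas about 3.8 A apart.
#'
#' @param N number of residues (>= 2)
#' @param structureId label
#' @return a [CAStructure-class]
#' @export
makeHelix <- function(N, structureId = "helix") {
  stopifnot(N >= 2L)
  i <- seq_len(N) - 1L
  th <- i * 100 * pi / 180
  asCAStructure(cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i), structureId)
}

growChain <- function(n, start, step, minSpacing, accept, maxTry = 400L) {
  # grows a self-avoiding chain: consecutive spacing = step, all pairs >=
  # minSpacing, each point satisfying accept(p); NULL when stuck
  pts <- matrix(NA_real_, n, 3L)
  pts[1L, ] <- start
  if (n == 1L) return(pts)
  for (k in 2L:n) {
    ok <- FALSE
    for (t in seq_len(maxTry)) {
      p <- pts[k - 1L, ] + step * randUnit()
      if (!accept(p)) next
      if (k > 2L) {
        d2 <- rowSums((pts[seq_len(k - 2L), , drop = FALSE] -
                         matrix(p, k - 2L, 3L, byrow = TRUE))^2)
        if (min(d2) < minSpacing^2) next
      }
      pts[k, ] <- p
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  pts
}

#' Random compact globule
#'
#' Self-avoiding chain grown by rejection sampling inside a sphere:
#' consecutive C-alphas exactly `minSpacing` apart, all other pairs at
#' least `minSpacing` apart.  The chain itself guarantees connectivity of
#' the contact graph at any cutoff >= `minSpacing`.
#'
#' @param N residues (>= 2)
#' @param seed RNG seed; the result is a pure function of the arguments
#' @param minSpacing consecutive C-alpha spacing, A
#' @param envelopeRadius confining sphere radius; default 3.0 * N^(1/3) A,
#'   roughly protein-like packing
#' @param structureId label
#' @param chain chain identifier
#' @return a [CAStructure-class]
#' @export
makeGlobule <- function(N, seed = 1L, minSpacing = 3.8,
                        envelopeRadius = NULL, structureId = "globule",
                        chain = "A") {
  stopifnot(N >= 2L, minSpacing > 0)
  if (is.null(envelopeRadius)) envelopeRadius <- 3.0 * N^(1 / 3)
  if (N * minSpacing^3 > (4 / 3) * pi * envelopeRadius^3)
    stop("infeasible packing: ", N, " residues at spacing ", minSpacing,
         " A do not fit in a sphere of radius ", envelopeRadius, " A")
  gen <- function() {
    inside <- function(p) sum(p^2) <= envelopeRadius^2
    for (attempt in 1:60) {
      start <- 0.5 * envelopeRadius * stats::runif(1)^(1 / 3) * randUnit()
      pts <- growChain(N, start, minSpacing, minSpacing, inside)
      if (!is.null(pts)) return(pts)
    }
    stop("globule growth failed after bounded retries; ",
         "increase envelopeRadius")
  }
  asCAStructure(withSeed(seed, gen()), structureId, chain)
}

#' Globule with a planted high-connectivity hub
#'
#' A block of `hubSize` consecutive residues is packed into a small ball
#' at the origin (mutual distances mostly below 10 A), and the two
#' flanking arms are grown as persistent self-avoiding walks confined to
#' a surrounding shell, with a local-density cap that keeps arm residues
#' sparsely connected.  The construction is accepted only when the
#' highest hub degree at a 10 A cutoff strictly exceeds every non-hub
#' degree; otherwise it is regenerated with an incremented sub-seed
#' (bounded retries).  The returned annotation marks the hub center — the
#' hub residue with the smallest total 3D distance to all residues — as
#' the "catalytic" site, making the pair a self-validating oracle for
#' peak-recovery tests.
#'
#' @param N total residues; the default geometry assumes N >= 40
#' @param hubSize consecutive hub residues (< N/4)
#' @param seed RNG seed
#' @param structureId label
#' @return list with elements `structure` ([CAStructure-class]),
#'   `annotation` ([AnnotationSet-class]), `hubIndices` and `hubCenter`
#'   (1-based linear indices)
#' @export
makePlantedHub <- function(N = 72L, hubSize = 12L, seed = 1L,
                           structureId = "planted_hub") {
  stopifnot(N >= 40L, hubSize >= 4L, hubSize < N / 4)
  minSpacing <- 3.8
  hubRadius <- 5.5     # hub ball; pairwise spacing >= minSpacing inside
  shellInner <- 12     # arms wander between these radii, so the whole
  shellOuter <- 20     # structure stays within ~22 A of the hub
  degCap <- 9L         # arm points may not start with more contacts at 10 A
  nArm1 <- (N - hubSize) %/% 2L
  nArm2 <- N - hubSize - nArm1
  arm <- function(from, n, existing) {
    # two outward transition steps, then a persistent walk in the shell
    pts <- matrix(NA_real_, 0L, 3L)
    prev <- from
    prevDir <- from / sqrt(sum(from^2))
    for (t in 1:2) {
      ok <- FALSE
      for (try in 1:300) {
        dir <- prev + 1.5 * randUnit()
        dir <- dir / sqrt(sum(dir^2))
        p <- prev + minSpacing * dir
        base <- rbind(existing, pts)
        d2 <- rowSums((base - matrix(p, nrow(base), 3L, byrow = TRUE))^2)
        if (sum(p^2) > sum(prev^2) && min(d2) >= minSpacing^2) {
          pts <- rbind(pts, p); prevDir <- dir; prev <- p; ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
    }
    while (nrow(pts) < n) {
      ok <- FALSE
      for (try in 1:300) {
        dir <- prevDir + 1.0 * randUnit()
        dir <- dir / sqrt(sum(dir^2))
        p <- prev + minSpacing * dir
        r2 <- sum(p^2)
        lo <- if (nrow(pts) <= 3L) (hubRadius + 2)^2 else shellInner^2
        if (r2 < lo || r2 > shellOuter^2) next
        base <- rbind(existing, pts)
        d2 <- rowSums((base - matrix(p, nrow(base), 3L, byrow = TRUE))^2)
        if (min(d2) < minSpacing^2) next
        if (sum(d2 <= 100) > degCap && nrow(pts) > 1L) next
        pts <- rbind(pts, p); prevDir <- dir; prev <- p; ok <- TRUE
        break
      }
      if (!ok) return(NULL)
    }
    pts
  }
  gen <- function() {
    hub <- NULL
    for (htry in 1:25) {   # packing the ball is tight; retry cheaply
      start <- 0.7 * hubRadius * stats::runif(1)^(1 / 3) * randUnit()
      hub <- growChain(hubSize, start, minSpacing, minSpacing,
                       function(p) sum(p^2) <= hubRadius^2)
      if (!is.null(hub)) break
    }
    if (is.null(hub)) return(NULL)
    a1 <- arm(hub[1L, ], nArm1, hub)
    if (is.null(a1)) return(NULL)
    a2 <- arm(hub[hubSize, ], nArm2, rbind(hub, a1))
    if (is.null(a2)) return(NULL)
    # chain order: arm1 reversed (it walks away from hub[1]) - hub - arm2
    rbind(a1[rev(seq_len(nrow(a1))), , drop = FALSE], hub, a2)
  }
  for (attempt in 0:29) {
    res <- withSeed(seed + 1000L * attempt, gen())
    if (is.null(res)) next
    s <- asCAStructure(res, structureId)
    hubIdx <- (nArm1 + 1L):(nArm1 + hubSize)
    deg <- indicatorValues(connectivity(buildContactGraph(s, 10)))
    if (max(deg[hubIdx]) <= max(deg[-hubIdx])) next
    dTot <- rowSums(as.matrix(stats::dist(res)))
    hubCenter <- hubIdx[which.min(dTot[hubIdx])]
    ann <- new("AnnotationSet", structureId = structureId,
               sites = data.frame(chain = "A",
                                  resno = s@residues$resno[hubCenter],
                                  icode = "", stringsAsFactors = FALSE))
    return(list(structure = s, annotation = ann, hubIndices = hubIdx,
                hubCenter = hubCenter))
  }
  stop("planted-hub construction failed after bounded retries")
}

#' Two-chain globular dimer
#'
#' Two independent globules (chain ids A and B) placed so that the chains
#' do not clash but do come within contact range: the inter-chain gap is
#' narrowed until the closest approach is below 15 A (never below the
#' spacing).  Exercises the cross-chain sequence-distance rules.
#'
#' @param NPerChain residues per chain (>= 2)
#' @param seed RNG seed
#' @param structureId label
#' @return a [CAStructure-class] with chains A and B
#' @export
makeDimer <- function(NPerChain = 30L, seed = 1L, structureId = "dimer") {
  stopifnot(NPerChain >= 2L)
  R <- 3.0 * NPerChain^(1 / 3)
  a <- makeGlobule(NPerChain, seed = seed, structureId = structureId)
  b <- makeGlobule(NPerChain, seed = seed + 7919L, structureId = structureId,
                   chain = "B")
  xa <- coords(a)
  xb0 <- coords(b)
  interMin <- function(shift) {
    xb <- sweep(xb0, 2L, c(shift, 0, 0), "+")
    cross <- as.matrix(stats::dist(rbind(xa, xb)))[
      seq_len(NPerChain), NPerChain + seq_len(NPerChain)]
    min(cross)
  }
  # slide chain B along x until the closest approach sits in (spacing, 15]
  shift <- 2 * R + 4
  for (it in 1:40) {
    dmin <- interMin(shift)
    if (dmin > 3.8 && dmin <= 15) break
    shift <- shift - (dmin - 8)   # aim for an 8 A closest approach
  }
  xb <- sweep(xb0, 2L, c(shift, 0, 0), "+")
  res <- rbind(
    data.frame(chain = "A", resno = seq_len(NPerChain), icode = "",
               x = xa[, 1], y = xa[, 2], z = xa[, 3]),
    data.frame(chain = "B", resno = seq_len(NPerChain), icode = "",
               x = xb[, 1], y = xb[, 2], z = xb[, 3]))
  rownames(res) <- NULL
  new("CAStructure", structureId = structureId, residues = res)
}
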
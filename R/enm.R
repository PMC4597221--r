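#' Elastic-network parameters
#'
#' Defaults follow the conventional residue-level parameterization: spring
#' constant k2 = 5 kcal/mol/A^2, uniform residue mass M = 120 Da (the
#' average amino-acid mass), and the five highest-frequency normal modes
#' entering the spectral stiffness.
#'
#' @param k2 spring constant, kcal/mol/A^2 (> 0).
#' @param M residue mass, Da (> 0).
#' @param nTopModes number of highest-frequency modes summed by
#'   [spectralStiffness()].
#' @param zeroTol relative tolerance (w.r.t. the largest eigenvalue) below
#'   which an eigenvalue counts as a rigid-body zero mode.
#' @param modeWeighting `"uniform"` sums squared mode components as-is;
#'   `"inverse_omega2"` weights each mode by 1/eigenvalue (fluctuation
#'   amplitude).  Peak locations are insensitive to this choice; uniform is
#'   the default because it gives the clean normalization
#'   sum(chi) = nTopModes.
#' @return a list of class `ENMParams`
#' @export
enmParams <- function(k2 = 5, M = 120, nTopModes = 5L, zeroTol = 1e-8,
                      modeWeighting = c("uniform", "inverse_omega2")) {
  modeWeighting <- match.arg(modeWeighting)
  stopifnot(k2 > 0, M > 0, nTopModes >= 1L, zeroTol > 0)
  structure(list(k2 = k2, M = M, nTopModes = as.integer(nTopModes),
                 zeroTol = zeroTol, modeWeighting = modeWeighting),
            class = "ENMParams")
}

#' Build the residue contact graph at a cutoff
#'
#' Joins every residue pair whose equilibrium C-alpha separation is at most
#' `cutoff` (inclusive boundary).  Equilibrium distances and unit vectors
#' are stored per edge for the Hessian assembly.
#'
#' @param s a [CAStructure-class] with at least 2 residues.
#' @param cutoff cutoff radius R_c in Angstrom (> 0).
#' @return a [ContactGraph-class]
#' @export
buildContactGraph <- function(s, cutoff) {
  stopifnot(is(s, "CAStructure"))
  n <- nResidues(s)
  if (n < 2L) stop("degenerate structure: need at least 2 residues")
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- coords(s)
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(sel)) {
    ord <- order(sel[, 1L], sel[, 2L])
    sel <- sel[ord, , drop = FALSE]
  }
  eqd <- d[sel]
  dvec <- xyz[sel[, 2L], , drop = FALSE] - xyz[sel[, 1L], , drop = FALSE]
  uv <- dvec / ifelse(eqd > 0, eqd, NA_real_)
  e <- cbind(i = as.integer(sel[, 1L]), j = as.integer(sel[, 2L]))
  new("ContactGraph", nNodes = n, cutoff = as.numeric(cutoff),
      edges = e, eqDist = as.numeric(eqd), unitVectors = uv)
}

#' Number of edges of a contact graph
#' @param g a [ContactGraph-class]
#' @export
nEdges <- function(g) nrow(g@edges)

#' Convert a contact graph to an igraph object
#' @param g a [ContactGraph-class]
#' @return an undirected \pkg{igraph} graph with `nNodes` vertices
#' @export
asIgraph <- function(g) {
  stopifnot(is(g, "ContactGraph"))
  igraph::make_graph(as.vector(t(g@edges)), n = g@nNodes, directed = FALSE)
}

setMethod("show", "ContactGraph", function(object) {
  cat("ContactGraph: ", object@nNodes, " nodes, ", nrow(object@edges),
      " edges at cutoff ", object@cutoff, " A\n", sep = "")
})

#' Assemble the mass-weighted Hessian of the elastic network
#'
#' For each edge (i, j) the off-diagonal 3x3 block is
#' -(k2/M) (u u^T) with u the equilibrium unit vector of the edge; the
#' diagonal block of a residue is minus the sum of its off-diagonal blocks,
#' which enforces translation invariance (zero row sums per Cartesian
#' component).
#'
#' @param g a [ContactGraph-class] with at least one edge.
#' @param params an [enmParams()] list.
#' @return dense symmetric 3N x 3N matrix in units of k2/M
#' @export
buildHessian <- function(g, params = enmParams()) {
  stopifnot(is(g, "ContactGraph"), inherits(params, "ENMParams"))
  if (nrow(g@edges) == 0L) stop("contact graph has no edges")
  if (any(g@eqDist == 0))
    stop("coincident atoms: edge with zero equilibrium distance")
  n <- g@nNodes
  h <- matrix(0, 3L * n, 3L * n)
  pref <- params$k2 / params$M
  for (e in seq_len(nrow(g@edges))) {
    i <- g@edges[e, 1L]; j <- g@edges[e, 2L]
    u <- g@unitVectors[e, ]
    blk <- pref * tcrossprod(u)
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    h[ii, jj] <- h[ii, jj] - blk
    h[jj, ii] <- h[jj, ii] - blk
    h[ii, ii] <- h[ii, ii] + blk
    h[jj, jj] <- h[jj, jj] + blk
  }
  h
}

#' Diagonalize a mass-weighted Hessian
#'
#' Full dense symmetric eigendecomposition.  Eigenvalues are returned
#' ascending in units of k2/M; the rigid-body zero modes (6 for a
#' connected non-collinear structure, 5 for collinear, more when the graph
#' is disconnected) are counted against `zeroTol` relative to the largest
#' eigenvalue.
#'
#' @param h symmetric 3N x 3N matrix from [buildHessian()].
#' @param zeroTol relative zero-mode tolerance.
#' @return a [NormalModeSet-class]
#' @export
computeModes <- function(h, zeroTol = 1e-8) {
  stopifnot(is.matrix(h), nrow(h) == ncol(h))
  if (max(abs(h - t(h))) > 1e-9 * max(1, max(abs(h))))
    stop("Hessian is not symmetric")
  es <- eigen(h, symmetric = TRUE)   # LAPACK; errors surface to the caller
  ord <- rev(seq_along(es$values))   # eigen() returns descending
  lam <- es$values[ord]
  vec <- es$vectors[, ord, drop = FALSE]
  lmax <- max(abs(lam))
  nz <- if (lmax > 0) sum(abs(lam) < zeroTol * lmax) else length(lam)
  new("NormalModeSet", eigenvalues = lam, eigenvectors = vec,
      nZero = as.integer(nz), zeroTol = zeroTol)
}

setMethod("show", "NormalModeSet", function(object) {
  n3 <- length(object@eigenvalues)
  cat("NormalModeSet: ", n3, " modes (N = ", n3 %/% 3L, "), ",
      object@nZero, " zero mode(s); max eigenvalue ",
      format(max(object@eigenvalues), digits = 4), " k2/M\n", sep = "")
})

#' Spectral stiffness from the highest-frequency normal modes
#'
#' Per-residue contribution of the `nTopModes` highest-frequency modes to
#' the fluctuations: chi_i = sum_k sum_alpha (xi^k_{i,alpha})^2 over the
#' top modes.  High-frequency modes localize on stiff, highly connected
#' residues, so chi flags candidate hotspot sites.  Under uniform mode
#' weighting orthonormality forces sum_i chi_i = nTopModes.
#'
#' @param m a [NormalModeSet-class].
#' @param params an [enmParams()] list; `nTopModes` and `modeWeighting`
#'   are used.
#' @param cutoff cutoff to record on the resulting pattern (Angstrom).
#' @param structureId label to record on the pattern.
#' @return an [IndicatorPattern-class] with `indicator = "chi"`
#' @export
spectralStiffness <- function(m, params = enmParams(), cutoff = NA_real_,
                              structureId = "") {
  stopifnot(is(m, "NormalModeSet"), inherits(params, "ENMParams"))
  n3 <- length(m@eigenvalues)
  nInternal <- n3 - m@nZero
  k <- params$nTopModes
  if (k > nInternal)
    stop("only ", nInternal, " internal mode(s) available; ",
         "choose nTopModes <= ", nInternal)
  top <- m@eigenvectors[, (n3 - k + 1L):n3, drop = FALSE]
  w <- if (params$modeWeighting == "inverse_omega2")
    1 / m@eigenvalues[(n3 - k + 1L):n3] else rep(1, k)
  sq <- top^2 %*% w
  chi <- rowsum(as.numeric(sq), rep(seq_len(n3 %/% 3L), each = 3L))
  new("IndicatorPattern", indicator = "chi", cutoff = cutoff,
      values = as.numeric(chi), structureId = structureId)
}
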
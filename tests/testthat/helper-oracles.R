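# Independent test-only oracles; deliberately naive implementations.

# all-pairs shortest paths by Floyd-Warshall on an unweighted edge list
floydWarshall <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(edges)) {
    d[edges] <- 1
    d[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# closeness from the Floyd-Warshall matrix, within components
closenessOracle <- function(n, edges) {
  d <- floydWarshall(n, edges)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    memb <- which(is.finite(d[i, ]))
    if (length(memb) >= 2) cc[i] <- (length(memb) - 1) / sum(d[i, memb])
  }
  cc
}

# brute-force contact edges: every pair checked, inclusive boundary
bruteContacts <- function(xyz, rc) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= rc)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# a ContactGraph with arbitrary topology and dummy geometry, for the
# graph indicators (which only read edges)
graphFromEdges <- function(n, edges, cutoff = 10) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    edges <- t(apply(edges, 1, sort))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    edges <- unique(edges)
  }
  new("ContactGraph", nNodes = as.integer(n), cutoff = cutoff,
      edges = edges, eqDist = rep(1, nrow(edges)),
      unitVectors = matrix(rep(c(1, 0, 0), nrow(edges)), ncol = 3,
                           byrow = TRUE))
}

randomEdges <- function(n, p) {
  all <- t(combn(n, 2))
  all[stats::runif(nrow(all)) < p, , drop = FALSE]
}

# random point cloud (not chain-like; only used for geometry oracles)
randomCloud <- function(n, side = 30) {
  matrix(stats::runif(3 * n, 0, side), ncol = 3)
}

structureFromXYZ <- function(xyz, id = "test", chain = "A") {
  new("CAStructure", structureId = id,
      residues = data.frame(chain = chain, resno = seq_len(nrow(xyz)),
                            icode = "", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE))
}

# tiny PDB text fixture written on the fly
writeMiniPDB <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

atomLine <- function(serial, resno, x, y, z, chain = "A", altloc = " ",
                     occ = 1, name = " CA ", resname = "ALA",
                     record = "ATOM  ", icode = " ") {
  sprintf("%s%5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          record, serial, name, altloc, resname, chain, resno, icode,
          x, y, z, occ, 0)
}
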
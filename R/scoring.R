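#' Renormalize a reduced pattern into peak masses
#'
#' Every surviving peak gets the same mass 1/N_p, all other residues 0, so
#' the pattern sums to 1 whenever it has at least one peak.  The internal
#' weight is inversely proportional to the number of peaks: the more peaks
#' an indicator produces, the less each individual prediction is worth.
#'
#' @param rp a [ReducedPattern-class]
#' @return numeric vector of per-residue masses
#' @export
renormalizePeaks <- function(rp) {
  stopifnot(is(rp, "ReducedPattern"))
  sigma <- numeric(length(rp@raw))
  if (nPeaks(rp) > 0) sigma[peaks(rp)] <- 1 / nPeaks(rp)
  sigma
}

#' Default optimal cutoffs per indicator
#'
#' Stiffness 22 A, connectivity 20 A, closeness 28 A: the cutoffs at
#' which, over a large annotated enzyme set, each indicator attains its
#' best trade-off of recovered catalytic sites against number of peaks.
#' @export
optimalCutoffs <- function() c(chi = 22, conn = 20, cc = 28)

#' Combine the three renormalized patterns into a per-residue score
#'
#' S_i = w_chi sigma_i^chi + w_conn sigma_i^conn + w_cc sigma_i^cc with
#' equal default weights 1/3.  When an indicator produced no peaks its
#' weight is, by default, redistributed equally over the indicators that
#' did (keeping sum(S) = 1 and the \[0, 1\] confidence reading of the
#' derived per-structure score); `redistribute = FALSE` keeps the fixed
#' input weights instead.
#'
#' @param sigmaChi,sigmaConn,sigmaCc equal-length mass vectors from
#'   [renormalizePeaks()]
#' @param weights non-negative weights summing to 1, in order
#'   (chi, conn, cc)
#' @param redistribute reassign the weight of peak-less indicators
#' @param cutoffsUsed named cutoffs recorded for provenance
#' @param structureId label
#' @return a [ScoreProfile-class]
#' @export
combinedScore <- function(sigmaChi, sigmaConn, sigmaCc,
                          weights = c(1, 1, 1) / 3, redistribute = TRUE,
                          cutoffsUsed = optimalCutoffs(),
                          structureId = "") {
  n <- length(sigmaChi)
  if (length(sigmaConn) != n || length(sigmaCc) != n)
    stop("component patterns have different lengths")
  stopifnot(length(weights) == 3L, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  comp <- cbind(chi = sigmaChi, conn = sigmaConn, cc = sigmaCc)
  hasPeaks <- colSums(comp) > 0
  w <- weights
  if (redistribute && any(!hasPeaks) && any(hasPeaks)) {
    w[!hasPeaks] <- 0
    w[hasPeaks] <- w[hasPeaks] + sum(weights[!hasPeaks]) *
      weights[hasPeaks] / sum(weights[hasPeaks])
  }
  names(w) <- colnames(comp)
  new("ScoreProfile", S = as.numeric(comp %*% w), components = comp,
      weights = w, inputWeights = stats::setNames(weights, colnames(comp)),
      cutoffsUsed = cutoffsUsed, structureId = structureId)
}

#' @rdname scores
#' @export
setMethod("scores", "ScoreProfile", function(x) x@S)

setMethod("show", "ScoreProfile", function(object) {
  cat("ScoreProfile '", object@structureId, "': ", length(object@S),
      " residues, total score ", format(sum(object@S), digits = 4),
      "; weights (chi, conn, cc) = ",
      paste(format(object@weights, digits = 3), collapse = ", "),
      "\n", sep = "")
})

#' Per-structure global score
#'
#' Sum of the combined per-residue scores over all residues lying within
#' `dn` (sequence distance) of at least one annotated catalytic residue;
#' each residue is counted once even if several catalytic residues are
#' nearby.  Lies in \[0, 1\]; a positive value means the combined pattern
#' makes at least one prediction near a known site.
#'
#' @param sp a [ScoreProfile-class]
#' @param catalyticIdx catalytic residue indices (>= 1)
#' @param dn sequence window in residues
#' @param s the [CAStructure-class]
#' @return scalar score
#' @export
globalScore <- function(sp, catalyticIdx, dn, s) {
  stopifnot(is(sp, "ScoreProfile"), is(s, "CAStructure"))
  if (length(catalyticIdx) == 0L) stop("no catalytic residues given")
  n <- length(sp@S)
  stopifnot(n == nResidues(s))
  near <- vapply(seq_len(n), function(i)
    min(sequenceDistance(rep(i, length(catalyticIdx)), catalyticIdx, s)) <= dn,
    logical(1))
  sum(sp@S[near])
}

#' Predict candidate catalytic sites of an unannotated structure
#'
#' Runs the sequential inspection recipe: connectivity peaks at 20 A flag
#' broad candidate regions; closeness peaks at 28 A narrow them; stiffness
#' peaks at 22 A refine them; finally all three are merged into the
#' combined score and ranked.  Ties in the ranking are broken by residue
#' index, so identical inputs always give identical reports.
#'
#' @param s a [CAStructure-class]
#' @param params [enmParams()]
#' @param cfg [filterConfig()]
#' @param cutoffs named per-indicator cutoffs, see [optimalCutoffs()]
#' @param weights combined-score weights (chi, conn, cc)
#' @param redistribute see [combinedScore()]
#' @return list with the three stage [ReducedPattern-class]s, the
#'   [ScoreProfile-class], and `ranking`: a data.frame of positive-score
#'   residues sorted by decreasing S (ties by index) with chain/residue
#'   identities
#' @export
predictSites <- function(s, params = enmParams(), cfg = filterConfig(),
                         cutoffs = optimalCutoffs(),
                         weights = c(1, 1, 1) / 3, redistribute = TRUE) {
  stopifnot(is(s, "CAStructure"))
  stopifnot(all(c("chi", "conn", "cc") %in% names(cutoffs)))
  one <- function(ind) {
    g <- buildContactGraph(s, cutoffs[[ind]])
    p <- switch(ind,
      conn = connectivity(g, s@structureId),
      cc = suppressWarnings(closenessCentrality(g, s@structureId)),
      chi = spectralStiffness(computeModes(buildHessian(g, params),
                                           params$zeroTol),
                              params, cutoffs[[ind]], s@structureId))
    reducePattern(p, cfg = cfg)
  }
  rpConn <- one("conn"); rpCc <- one("cc"); rpChi <- one("chi")
  sp <- combinedScore(renormalizePeaks(rpChi), renormalizePeaks(rpConn),
                      renormalizePeaks(rpCc), weights = weights,
                      redistribute = redistribute,
                      cutoffsUsed = unlist(cutoffs[c("chi", "conn", "cc")]),
                      structureId = s@structureId)
  pos <- which(sp@S > 0)
  ord <- pos[order(-sp@S[pos], pos)]
  ranking <- data.frame(index = ord, chain_id = s@residues$chain[ord],
                        res_seq = s@residues$resno[ord], S = sp@S[ord])
  rownames(ranking) <- NULL
  list(conn = rpConn, cc = rpCc, chi = rpChi, score = sp,
       ranking = ranking)
}

#' Format a prediction as a human-readable report
#' @param pred result of [predictSites()]
#' @param s the [CAStructure-class]
#' @return character vector of report lines
#' @export
formatPredictionReport <- function(pred, s) {
  lab <- function(i) sprintf("%s/%d%s", s@residues$chain[i],
                             s@residues$resno[i], s@residues$icode[i])
  stage <- function(name, rp, note) {
    redist <- nPeaks(rp) == 0L
    c(sprintf("[%s] cutoff %g A, %d peak(s)%s: %s", name, rp@cutoff,
              nPeaks(rp),
              if (redist) " (no peaks; weight redistributed)" else "",
              if (nPeaks(rp)) paste(lab(peaks(rp)), collapse = " ")
              else "-"),
      paste0("    ", note))
  }
  c(sprintf("Prediction report for structure '%s' (%d residues)",
            s@structureId, nResidues(s)),
    stage("1 connectivity", pred$conn, "broad candidate regions"),
    stage("2 closeness", pred$cc, "narrowed candidates"),
    stage("3 stiffness", pred$chi, "refined candidates"),
    sprintf("[4 combined score] weights (chi, conn, cc) = %s",
            paste(format(pred$score@weights, digits = 3), collapse = ", ")),
    if (nrow(pred$ranking))
      sprintf("    %2d. %-8s S = %.4f", seq_len(nrow(pred$ranking)),
              lab(pred$ranking$index), pred$ranking$S)
    else "    no positive-score residues")
}
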
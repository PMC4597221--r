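#' Sequence distance between two residues
#'
#' Distance along the sequence in residues: |i - j| when both residues
#' belong to the same chain, Inf across chains (each chain carries its own
#' sequence, so cross-chain sequence distance is meaningless — relevant
#' for homodimers such as HIV-1 protease).
#'
#' @param i,j 1-based linear residue indices
#' @param s the [CAStructure-class]
#' @return non-negative integer, or Inf across chains
#' @export
sequenceDistance <- function(i, j, s) {
  stopifnot(is(s, "CAStructure"))
  n <- nResidues(s)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("residue index out of range")
  ch <- s@residues$chain
  ifelse(ch[i] == ch[j], abs(i - j), Inf)
}

#' Fraction of catalytic residues recovered by a peak set
#'
#' Fraction of annotated residues whose minimum sequence distance to any
#' peak is at most `dn`.
#'
#' @param peakIdx integer peak indices (1-based)
#' @param catalyticIdx integer catalytic residue indices (>= 1 of them)
#' @param dn window half-width in residues
#' @param s the [CAStructure-class]
#' @return fraction in \[0, 1\]
#' @export
fractionRecovered <- function(peakIdx, catalyticIdx, dn, s) {
  if (length(catalyticIdx) == 0L)
    stop("no catalytic residues: fraction undefined")
  if (length(peakIdx) == 0L) return(0)
  hit <- vapply(catalyticIdx, function(ci)
    min(sequenceDistance(rep(ci, length(peakIdx)), peakIdx, s)) <= dn,
    logical(1))
  mean(hit)
}

#' Run the cutoff-lensing scan
#'
#' For each cutoff in an increasing grid: build the contact graph once,
#' derive connectivity and closeness from it, diagonalize the
#' mass-weighted Hessian for the spectral stiffness, and reduce all three
#' profiles to peak patterns.  Failures at individual cutoffs (e.g. a
#' fragmented graph at small radii with too few internal modes) are
#' recorded in the status table and the scan continues.
#'
#' @param s a [CAStructure-class]
#' @param cutoffs increasing positive cutoffs; default 8-40 A in 2 A steps,
#'   spanning the conventional 10-13 A regime through the large-cutoff
#'   lensing regime
#' @param params [enmParams()]
#' @param cfg [filterConfig()]
#' @return a [ScanResult-class]
#' @export
scanCutoffs <- function(s, cutoffs = seq(8, 40, by = 2),
                        params = enmParams(), cfg = filterConfig()) {
  stopifnot(is(s, "CAStructure"), all(cutoffs > 0),
            !is.unsorted(cutoffs, strictly = TRUE))
  patterns <- list()
  status <- data.frame(cutoff = numeric(), nEdges = integer(),
                       nComponents = integer(), connected = logical(),
                       failed = logical(), message = character())
  for (rc in cutoffs) {
    entry <- list(chi = NULL, conn = NULL, cc = NULL)
    msg <- ""
    failed <- FALSE
    g <- buildContactGraph(s, rc)
    ncomp <- igraph::components(asIgraph(g))$no
    res <- tryCatch({
      entry$conn <- reducePattern(connectivity(g, s@structureId), cfg = cfg)
      entry$cc <- reducePattern(
        suppressWarnings(closenessCentrality(g, s@structureId)), cfg = cfg)
      m <- computeModes(buildHessian(g, params), params$zeroTol)
      entry$chi <- reducePattern(
        spectralStiffness(m, params, rc, s@structureId), cfg = cfg)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) { failed <- TRUE; msg <- res }
    patterns[[as.character(rc)]] <- entry
    status <- rbind(status, data.frame(
      cutoff = rc, nEdges = nEdges(g), nComponents = ncomp,
      connected = ncomp == 1L, failed = failed, message = msg))
  }
  new("ScanResult", structure = s, cutoffs = as.numeric(cutoffs),
      patterns = patterns, status = status)
}

#' Extract one reduced pattern from a scan
#' @param sr a [ScanResult-class]
#' @param cutoff one of the scanned cutoffs
#' @param indicator `"chi"`, `"conn"` or `"cc"`
#' @return a [ReducedPattern-class] or NULL if that stage failed
#' @export
scanPattern <- function(sr, cutoff, indicator) {
  stopifnot(is(sr, "ScanResult"))
  entry <- sr@patterns[[as.character(cutoff)]]
  if (is.null(entry)) stop("cutoff ", cutoff, " not in scan")
  entry[[match.arg(indicator, c("chi", "conn", "cc"))]]
}

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult for '", object@structure@structureId, "': ",
      length(object@cutoffs), " cutoff(s) from ", min(object@cutoffs),
      " to ", max(object@cutoffs), " A; ",
      sum(object@status$failed), " failed stage(s)\n", sep = "")
})

#' Evaluate a scan against catalytic annotations
#'
#' For every (cutoff, indicator, dn): the fraction of catalytic residues
#' within `dn` of a peak, the peak fraction N_p/N, their ratio (the
#' reliability — a prediction made with few peaks is worth more), and the
#' number of peaks per catalytic site.  Reliability is NA when a pattern
#' has no peaks.
#'
#' @param sr a [ScanResult-class]
#' @param ann an [AnnotationSet-class] mapping to >= 1 residue
#' @param dn integer vector of sequence windows (default 0:2)
#' @return data.frame with columns `structure_id, cutoff, indicator, dn,
#'   frac_within, peak_fraction, reliability, peaks_per_site`
#' @export
evaluateScan <- function(sr, ann, dn = 0:2) {
  stopifnot(is(sr, "ScanResult"), is(ann, "AnnotationSet"))
  s <- sr@structure
  cat_idx <- mapAnnotations(s, ann)
  if (length(cat_idx) == 0L)
    stop("no annotation maps onto structure '", s@structureId, "'")
  n <- nResidues(s)
  rows <- list()
  for (rc in sr@cutoffs) {
    for (ind in c("chi", "conn", "cc")) {
      rp <- sr@patterns[[as.character(rc)]][[ind]]
      if (is.null(rp)) next
      np <- nPeaks(rp)
      pf <- np / n
      for (d in dn) {
        fw <- fractionRecovered(peaks(rp), cat_idx, d, s)
        rows[[length(rows) + 1L]] <- data.frame(
          structure_id = s@structureId, cutoff = rc, indicator = ind,
          dn = d, frac_within = fw, peak_fraction = pf,
          reliability = if (np > 0) fw / pf else NA_real_,
          peaks_per_site = np / length(cat_idx))
      }
    }
  }
  do.call(rbind, rows)
}

#' Pool scan evaluations over a structure set
#'
#' Pooled recovery (total recovered catalytic residues over total
#' catalytic residues) and mean peak fraction per (cutoff, indicator, dn),
#' overall and stratified by structure size class.  Larger enzymes are
#' where the lensing effect pays off most, so the stratification is part
#' of the standard output.
#'
#' @param scans list of [ScanResult-class]
#' @param anns list of matching [AnnotationSet-class] (same order)
#' @param dn integer vector of sequence windows
#' @param sizeBreaks residue-count boundaries between size classes; the
#'   default (NULL) uses tertiles of the input sizes
#' @return list with data.frames `overall` and `byClass`, and the vector
#'   of class labels per structure
#' @export
aggregateScans <- function(scans, anns, dn = 0:2, sizeBreaks = NULL) {
  stopifnot(length(scans) >= 1L, length(scans) == length(anns))
  sizes <- vapply(scans, function(sr) nResidues(sr@structure), integer(1))
  if (is.null(sizeBreaks)) {
    qs <- unique(stats::quantile(sizes, c(1 / 3, 2 / 3), type = 1))
    sizeBreaks <- qs
  }
  brk <- c(-Inf, sizeBreaks, Inf)
  cls <- as.character(cut(sizes, breaks = brk, include.lowest = TRUE))
  per <- vector("list", length(scans))
  for (k in seq_along(scans)) {
    s <- scans[[k]]@structure
    cat_idx <- mapAnnotations(s, anns[[k]])
    rows <- list()
    for (rc in scans[[k]]@cutoffs) {
      for (ind in c("chi", "conn", "cc")) {
        rp <- scans[[k]]@patterns[[as.character(rc)]][[ind]]
        if (is.null(rp)) next
        for (d in dn) {
          nrec <- sum(vapply(cat_idx, function(ci)
            length(peaks(rp)) > 0 &&
              min(sequenceDistance(rep(ci, nPeaks(rp)), peaks(rp), s)) <= d,
            logical(1)))
          rows[[length(rows) + 1L]] <- data.frame(
            cutoff = rc, indicator = ind, dn = d, n_recovered = nrec,
            n_catalytic = length(cat_idx),
            peak_fraction = nPeaks(rp) / nResidues(s), class = cls[k])
        }
      }
    }
    per[[k]] <- do.call(rbind, rows)
  }
  long <- do.call(rbind, per)
  pool <- function(df) {
    agg <- stats::aggregate(
      cbind(n_recovered, n_catalytic) ~ cutoff + indicator + dn, df, sum)
    pf <- stats::aggregate(peak_fraction ~ cutoff + indicator + dn, df, mean)
    out <- merge(agg, pf, by = c("cutoff", "indicator", "dn"))
    out$frac_within <- out$n_recovered / out$n_catalytic
    out[order(out$indicator, out$dn, out$cutoff), ]
  }
  byClass <- do.call(rbind, lapply(split(long, long$class), function(df) {
    out <- pool(df)
    out$class <- df$class[1L]
    out
  }))
  rownames(byClass) <- NULL
  list(overall = pool(long), byClass = byClass, classes = cls)
}
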
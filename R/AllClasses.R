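#' @import methods
NULL

#' C-alpha structure
#'
#' One record per residue that has a C-alpha atom, in file order.  Chains are
#' concatenated as encountered so that every residue has a single linear index
#' 1..N; sequence distance is only meaningful within a chain (see
#' [sequenceDistance()]).
#'
#' @slot structureId single character label.
#' @slot residues data.frame with columns `chain` (character), `resno`
#'   (integer author residue number), `icode` (character, `""` when absent)
#'   and `x`, `y`, `z` coordinates in Angstrom.
#'
#' @seealso [readPDBCalpha()], [coords()], [nResidues()]
#' @export
setClass("CAStructure",
  representation(structureId = "character", residues = "data.frame"),
  validity = function(object) {
    msg <- character()
    need <- c("chain", "resno", "icode", "x", "y", "z")
    if (!all(need %in% names(object@residues)))
      msg <- c(msg, paste("residues must have columns:",
                          paste(need, collapse = ", ")))
    else {
      xyz <- as.matrix(object@residues[, c("x", "y", "z")])
      if (!all(is.finite(xyz)))
        msg <- c(msg, "all coordinates must be finite")
      key <- with(object@residues, paste(chain, resno, icode, sep = "\r"))
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (chain, resno, icode) residue identity")
    }
    if (length(object@structureId) != 1L)
      msg <- c(msg, "structureId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Catalytic-site annotation set
#'
#' Residues flagged catalytic for one structure, identified by
#' (chain, residue number, insertion code) triples in the style of
#' Catalytic Site Atlas exports.
#'
#' @slot structureId single character label.
#' @slot sites data.frame with columns `chain`, `resno`, `icode`; unique rows.
#' @export
setClass("AnnotationSet",
  representation(structureId = "character", sites = "data.frame"),
  validity = function(object) {
    msg <- character()
    need <- c("chain", "resno", "icode")
    if (!all(need %in% names(object@sites)))
      msg <- c(msg, "sites must have columns chain, resno, icode")
    else {
      key <- with(object@sites, paste(chain, resno, icode, sep = "\r"))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate annotation rows")
    }
    if (length(msg)) msg else TRUE
  })

#' Residue contact graph of an elastic network
#'
#' Undirected graph joining every residue pair whose equilibrium C-alpha
#' distance is at most the cutoff (inclusive).  Edge geometry (equilibrium
#' distance and unit vector) is retained because the Hessian blocks are
#' built from it.
#'
#' @slot nNodes integer N.
#' @slot cutoff cutoff radius R_c in Angstrom.
#' @slot edges integer matrix, one row per edge, columns `i`, `j` with i < j
#'   (1-based indices).
#' @slot eqDist numeric per-edge equilibrium distance R_ij (Angstrom).
#' @slot unitVectors numeric matrix, one row per edge, the normalized
#'   R_j - R_i direction.
#' @export
setClass("ContactGraph",
  representation(nNodes = "integer", cutoff = "numeric",
                 edges = "matrix", eqDist = "numeric",
                 unitVectors = "matrix"),
  validity = function(object) {
    msg <- character()
    e <- object@edges
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    else if (nrow(e)) {
      if (any(e[, 1L] >= e[, 2L])) msg <- c(msg, "edges must satisfy i < j")
      if (any(e < 1L) || any(e > object@nNodes))
        msg <- c(msg, "edge endpoints out of range")
      if (anyDuplicated(e)) msg <- c(msg, "duplicate edges")
      if (length(object@eqDist) != nrow(e) ||
          nrow(object@unitVectors) != nrow(e))
        msg <- c(msg, "eqDist/unitVectors must align with edges")
    }
    if (object@cutoff <= 0) msg <- c(msg, "cutoff must be positive")
    if (length(msg)) msg else TRUE
  })

#' Normal modes of the mass-weighted Hessian
#'
#' Full spectrum, eigenvalues ascending in units of k2/M (frequency squared).
#' A connected, non-collinear structure has exactly six rigid-body zero
#' modes; the count actually observed is stored in `nZero`.
#'
#' @slot eigenvalues numeric vector of length 3N, ascending.
#' @slot eigenvectors 3N x 3N matrix, columns are orthonormal eigenvectors;
#'   row 3*(i-1)+alpha is the Cartesian component alpha of residue i.
#' @slot nZero integer count of eigenvalues below `zeroTol` relative to the
#'   largest eigenvalue.
#' @slot zeroTol relative tolerance used for `nZero`.
#' @export
setClass("NormalModeSet",
  representation(eigenvalues = "numeric", eigenvectors = "matrix",
                 nZero = "integer", zeroTol = "numeric"))

#' Raw per-residue indicator profile
#'
#' @slot indicator one of `"chi"` (spectral stiffness), `"conn"` (degree),
#'   `"cc"` (closeness centrality).
#' @slot cutoff cutoff (Angstrom) of the contact graph it was computed on.
#' @slot values one value per residue.
#' @slot structureId label of the parent structure.
#' @export
setClass("IndicatorPattern",
  representation(indicator = "character", cutoff = "numeric",
                 values = "numeric", structureId = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@indicator %in% c("chi", "conn", "cc"))
      msg <- c(msg, "indicator must be one of chi, conn, cc")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "indicator values must be finite")
    if (object@indicator %in% c("chi", "conn") && any(object@values < 0))
      msg <- c(msg, "chi/conn values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Reduced (filtered) indicator pattern with surviving peaks
#'
#' Product of the high-pass filter (and, for closeness, the 4-point
#' smoothing) applied to a raw indicator profile, plus the detected peaks.
#'
#' @slot indicator,cutoff,structureId identity of the parent profile.
#' @slot raw raw indicator values.
#' @slot filtered values after high-pass filtering (zeros where suppressed).
#' @slot processed final profile peaks were detected on: equal to `filtered`
#'   for chi and conn, the smoothed filtered profile for cc.
#' @slot peaks strictly increasing 1-based residue indices of surviving peaks.
#' @slot nSigma the high-pass threshold used, in standard deviations.
#' @export
setClass("ReducedPattern",
  representation(indicator = "character", cutoff = "numeric",
                 structureId = "character", raw = "numeric",
                 filtered = "numeric", processed = "numeric",
                 peaks = "integer", nSigma = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@raw)
    if (length(object@filtered) != n || length(object@processed) != n)
      msg <- c(msg, "raw/filtered/processed lengths differ")
    p <- object@peaks
    if (length(p)) {
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, "peaks must be strictly increasing")
      if (any(p < 1L) || any(p > n)) msg <- c(msg, "peak index out of range")
      if (any(object@processed[p] <= 0))
        msg <- c(msg, "peaks must sit on positive processed values")
    }
    if (length(msg)) msg else TRUE
  })

#' Result of a cutoff-lensing scan
#'
#' Reduced patterns for every (cutoff, indicator) pair, plus per-cutoff
#' connectivity diagnostics.
#'
#' @slot structure the scanned [CAStructure-class].
#' @slot cutoffs strictly increasing cutoff grid (Angstrom).
#' @slot patterns named list; `patterns[[as.character(cutoff)]][[indicator]]`
#'   is a [ReducedPattern-class] (or NULL when that stage failed).
#' @slot status data.frame with one row per cutoff: `cutoff`, `nEdges`,
#'   `nComponents`, `connected`, `failed`, `message`.
#' @export
setClass("ScanResult",
  representation(structure = "CAStructure", cutoffs = "numeric",
                 patterns = "list", status = "data.frame"),
  validity = function(object) {
    if (is.unsorted(object@cutoffs, strictly = TRUE))
      return("cutoffs must be strictly increasing")
    TRUE
  })

#' Combined per-residue score profile
#'
#' Weighted combination of the three renormalized peak patterns, each peak
#' carrying mass 1/N_p within its indicator.
#'
#' @slot S numeric per-residue combined score.
#' @slot components N x 3 matrix of the renormalized patterns, columns
#'   `chi`, `conn`, `cc`.
#' @slot weights effective weights actually applied (after any
#'   redistribution over indicators with no peaks).
#' @slot inputWeights weights as requested.
#' @slot cutoffsUsed named cutoffs the component patterns were computed at.
#' @slot structureId label of the parent structure.
#' @export
setClass("ScoreProfile",
  representation(S = "numeric", components = "matrix", weights = "numeric",
                 inputWeights = "numeric", cutoffsUsed = "numeric",
                 structureId = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@components) != length(object@S))
      msg <- c(msg, "components rows must match length of S")
    if (ncol(object@components) != 3L)
      msg <- c(msg, "components must have three columns")
    if (any(object@S < -1e-12)) msg <- c(msg, "S must be non-negative")
    if (length(msg)) msg else TRUE
  })
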
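#' Number of residues
#' @param x a [CAStructure-class]
#' @return integer residue count N
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Coordinate matrix
#' @param x a [CAStructure-class]
#' @return N x 3 numeric matrix of C-alpha coordinates (Angstrom)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Residue table
#' @param x a [CAStructure-class] or [AnnotationSet-class]
#' @return data.frame of residue (or site) records
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' Structure identifier
#' @param x an object carrying a structure id
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' Number of annotated catalytic sites
#' @param x an [AnnotationSet-class]
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Peak indices of a reduced pattern
#' @param x a [ReducedPattern-class]
#' @return strictly increasing 1-based residue indices
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' Number of surviving peaks
#' @param x a [ReducedPattern-class]
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' Indicator values
#' @param x an [IndicatorPattern-class] or [ReducedPattern-class]
#' @param which for reduced patterns, one of `"raw"`, `"filtered"`,
#'   `"processed"`
#' @export
setGeneric("indicatorValues",
           function(x, which = "processed") standardGeneric("indicatorValues"))

#' Combined per-residue scores
#' @param x a [ScoreProfile-class]
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
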
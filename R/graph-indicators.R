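#' Local connectivity (degree) indicator
#'
#' Number of contact-graph edges incident to each residue.
#'
#' @param g a [ContactGraph-class]
#' @param structureId label recorded on the pattern
#' @return an [IndicatorPattern-class] with `indicator = "conn"`
#' @export
connectivity <- function(g, structureId = "") {
  stopifnot(is(g, "ContactGraph"))
  deg <- tabulate(as.vector(g@edges), nbins = g@nNodes)
  new("IndicatorPattern", indicator = "conn", cutoff = g@cutoff,
      values = as.numeric(deg), structureId = structureId)
}

#' Closeness centrality indicator
#'
#' For a residue i in a connected component of size n_i >= 2,
#' CC_i = (n_i - 1) / sum_j d_ij, where d_ij is the unweighted
#' shortest-path length (edge count) to the other residues of the same
#' component.  Isolated residues get 0.  Closeness is computed within
#' components; a disconnected graph triggers a warning listing component
#' sizes, since the lensing regime of interest is the well-connected
#' large-cutoff one.
#'
#' @param g a [ContactGraph-class]
#' @param structureId label recorded on the pattern
#' @return an [IndicatorPattern-class] with `indicator = "cc"`, values in
#'   \[0, 1\]
#' @export
closenessCentrality <- function(g, structureId = "") {
  stopifnot(is(g, "ContactGraph"))
  ig <- asIgraph(g)
  comp <- igraph::components(ig)
  if (comp$no > 1L)
    warning("contact graph is disconnected (component sizes: ",
            paste(sort(comp$csize, decreasing = TRUE), collapse = ", "),
            "); closeness computed within components")
  d <- igraph::distances(ig)           # BFS per source on unweighted graphs
  cc <- numeric(g@nNodes)
  for (k in seq_len(comp$no)) {
    memb <- which(comp$membership == k)
    if (length(memb) < 2L) next        # isolated node keeps 0
    dsum <- rowSums(d[memb, memb, drop = FALSE])
    cc[memb] <- (length(memb) - 1) / dsum
  }
  new("IndicatorPattern", indicator = "cc", cutoff = g@cutoff,
      values = cc, structureId = structureId)
}

## pattern accessors live here with the producers

#' @rdname indicatorValues
#' @export
setMethod("indicatorValues", "IndicatorPattern",
          function(x, which = "processed") x@values)

#' @rdname indicatorValues
#' @export
setMethod("indicatorValues", "ReducedPattern", function(x, which = "processed") {
  which <- match.arg(which, c("processed", "filtered", "raw"))
  slot(x, which)
})

setMethod("show", "IndicatorPattern", function(object) {
  cat("IndicatorPattern [", object@indicator, "] at cutoff ",
      object@cutoff, " A: ", length(object@values), " residues\n", sep = "")
})
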
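#' Read the C-alpha trace of a PDB file
#'
#' Parses ATOM records (via \pkg{bio3d}) and keeps one C-alpha per residue.
#' HETATM records and non-CA atoms are ignored, so waters, ligands and
#' cofactors never enter the model, while modified residues deposited as
#' ATOM records (e.g. MSE) are kept.  Multi-model files contribute only the
#' selected model; alternate locations are resolved per `altlocPolicy`.
#'
#' @param path path to a PDB file.
#' @param modelPolicy `"first"` (default) uses the first MODEL of
#'   multi-model files; NMR ensembles are out of scope.
#' @param altlocPolicy `"occupancy"` (default) keeps, per residue, the
#'   altloc with the highest occupancy, ties resolved to the first
#'   encountered; `"first"` keeps the first CA record seen.
#' @param structureId label for the structure; defaults to the file base
#'   name without extension.
#' @return a [CAStructure-class]
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDBCalpha(makeHelix(5), pdb)
#' s <- readPDBCalpha(pdb)
#' nResidues(s)
#' @export
readPDBCalpha <- function(path, modelPolicy = c("first"),
                          altlocPolicy = c("occupancy", "first"),
                          structureId = NULL) {
  modelPolicy <- match.arg(modelPolicy)
  altlocPolicy <- match.arg(altlocPolicy)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("empty structure: no ATOM records with a CA atom in ", path)
  bad <- !is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)
  if (any(bad))
    stop("unparsable coordinate field in PDB line(s) with atom serial ",
         paste(ca$eleno[bad], collapse = ", "))
  chain <- ifelse(is.na(ca$chain), " ", ca$chain)
  icode <- ifelse(is.na(ca$insert), "", ca$insert)
  key <- paste(chain, ca$resno, icode, sep = "\r")
  keep <- !logical(nrow(ca))
  if (anyDuplicated(key)) {
    # resolve altlocs within each residue identity; file order is preserved
    keep <- rep(FALSE, nrow(ca))
    for (idx in split(seq_len(nrow(ca)), factor(key, levels = unique(key)))) {
      if (length(idx) == 1L) { keep[idx] <- TRUE; next }
      if (altlocPolicy == "first") { keep[idx[1L]] <- TRUE; next }
      occ <- ca$o[idx]
      occ[is.na(occ)] <- 1
      keep[idx[which.max(occ)]] <- TRUE  # which.max keeps first on ties
    }
  }
  ca <- ca[keep, , drop = FALSE]
  res <- data.frame(chain = chain[keep], resno = as.integer(ca$resno),
                    icode = icode[keep], x = ca$x, y = ca$y, z = ca$z,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (is.null(structureId))
    structureId <- sub("\\.[^.]*$", "", basename(path))
  new("CAStructure", structureId = structureId, residues = res)
}

#' Write a C-alpha structure as a minimal PDB file
#'
#' One ATOM record per residue (atom name CA, residue name GLY as a neutral
#' placeholder), chains in stored order with TER records between them.
#' Header REMARKs record provenance so synthetic structures are
#' self-describing; the writer exists chiefly so generated structures
#' exercise the real parser path.
#'
#' @param s a [CAStructure-class]
#' @param path output file path
#' @param remarks optional character vector of extra REMARK lines
#' @return `path`, invisibly
#' @export
writePDBCalpha <- function(s, path, remarks = character()) {
  stopifnot(is(s, "CAStructure"))
  r <- s@residues
  lines <- c(sprintf("REMARK 999 STRUCTURE_ID %s", s@structureId),
             if (length(remarks)) sprintf("REMARK 999 %s", remarks))
  serial <- 0L
  prevChain <- NULL
  for (i in seq_len(nrow(r))) {
    if (!is.null(prevChain) && r$chain[i] != prevChain)
      lines <- c(lines, "TER")
    prevChain <- r$chain[i]
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      serial, substr(r$chain[i], 1, 1), r$resno[i],
      ifelse(nzchar(r$icode[i]), substr(r$icode[i], 1, 1), " "),
      r$x[i], r$y[i], r$z[i], 1.00, 0.00))
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read catalytic-site annotations
#'
#' Reads a comma- or tab-separated table with header columns
#' `structure_id, chain_id, res_seq[, icode]` and returns one
#' [AnnotationSet-class] per distinct structure id, duplicated rows
#' deduplicated.
#'
#' @param path path to the annotation table.
#' @return named list of [AnnotationSet-class], in order of first appearance.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character", strip.white = TRUE)
  need <- c("structure_id", "chain_id", "res_seq")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!"icode" %in% names(tab)) tab$icode <- ""
  tab$icode[is.na(tab$icode)] <- ""
  if (nrow(tab)) {
    resno <- suppressWarnings(as.integer(tab$res_seq))
    bad <- is.na(resno)
    if (any(bad))
      stop("non-integer res_seq in annotation row(s) ",
           paste(which(bad) + 1L, collapse = ", "),
           " (line numbers include the header)")
    tab$res_seq <- resno
  }
  out <- list()
  for (sid in unique(tab$structure_id)) {
    rows <- tab[tab$structure_id == sid, , drop = FALSE]
    sites <- unique(data.frame(chain = rows$chain_id,
                               resno = as.integer(rows$res_seq),
                               icode = rows$icode,
                               stringsAsFactors = FALSE))
    rownames(sites) <- NULL
    out[[sid]] <- new("AnnotationSet", structureId = sid, sites = sites)
  }
  out
}

#' Write an annotation set in the package's tabular format
#' @param a an [AnnotationSet-class]
#' @param path output TSV path
#' @export
writeAnnotations <- function(a, path) {
  stopifnot(is(a, "AnnotationSet"))
  tab <- data.frame(structure_id = a@structureId, chain_id = a@sites$chain,
                    res_seq = a@sites$resno, icode = a@sites$icode)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map annotations onto linear residue indices
#'
#' Returns the 1-based linear indices (file order, chains concatenated) of
#' the annotated residues present in the structure.  Annotations absent
#' from the structure are reported through a warning, never silently
#' dropped.
#'
#' @param s a [CAStructure-class]
#' @param a an [AnnotationSet-class] with a matching `structureId`
#' @param checkId require matching structure ids (default TRUE)
#' @return sorted integer vector of mapped indices, with any unmapped
#'   annotations in attribute `"unmapped"` (a data.frame)
#' @export
mapAnnotations <- function(s, a, checkId = TRUE) {
  stopifnot(is(s, "CAStructure"), is(a, "AnnotationSet"))
  if (checkId && !identical(s@structureId, a@structureId))
    stop("structure id mismatch: '", s@structureId, "' vs '",
         a@structureId, "'")
  skey <- with(s@residues, paste(chain, resno, icode, sep = "\r"))
  akey <- with(a@sites, paste(chain, resno, icode, sep = "\r"))
  hit <- match(akey, skey)
  unmapped <- a@sites[is.na(hit), , drop = FALSE]
  if (nrow(unmapped))
    warning(nrow(unmapped), " annotation(s) not present in structure '",
            s@structureId, "': ",
            paste(sprintf("%s/%s%s", unmapped$chain, unmapped$resno,
                          unmapped$icode), collapse = ", "))
  idx <- sort(unique(hit[!is.na(hit)]))
  attr(idx, "unmapped") <- unmapped
  idx
}

## ---- accessors & show ------------------------------------------------------

#' @rdname nResidues
#' @export
setMethod("nResidues", "CAStructure", function(x) nrow(x@residues))

#' @rdname coords
#' @export
setMethod("coords", "CAStructure", function(x) {
  m <- as.matrix(x@residues[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname residueTable
#' @export
setMethod("residueTable", "CAStructure", function(x) x@residues)

#' @rdname residueTable
#' @export
setMethod("residueTable", "AnnotationSet", function(x) x@sites)

#' @rdname structureId
#' @export
setMethod("structureId", "CAStructure", function(x) x@structureId)

#' @rdname structureId
#' @export
setMethod("structureId", "AnnotationSet", function(x) x@structureId)

#' @rdname nSites
#' @export
setMethod("nSites", "AnnotationSet", function(x) nrow(x@sites))

setMethod("show", "CAStructure", function(object) {
  ch <- unique(object@residues$chain)
  cat("CAStructure '", object@structureId, "': ", nrow(object@residues),
      " residues, ", length(ch), " chain(s) [",
      paste(ch, collapse = ","), "]\n", sep = "")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet '", object@structureId, "': ", nrow(object@sites),
      " catalytic site(s)\n", sep = "")
})
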
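#' High-pass filter an indicator profile
#'
#' Keeps only values strictly above mean + nSigma * sd, zeroing the rest.
#' The standard deviation is the population (1/N) one, computed over the
#' whole sequence; a constant profile therefore yields all zeros.
#'
#' @param values numeric profile (length >= 2)
#' @param nSigma threshold in standard deviations above the mean
#' @return filtered profile, zeros where suppressed
#' @export
highPassFilter <- function(values, nSigma) {
  stopifnot(length(values) >= 2L, is.finite(nSigma))
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  ifelse(values > m + nSigma * s, values, 0)
}

#' 4-point moving-average smoothing
#'
#' Near-centered window i-1 .. i+2; at the boundaries the mean is taken
#' over the in-range part of the window, so constant profiles are fixed
#' points.  Applied by [reducePattern()] to closeness profiles only, whose
#' filtered patterns are otherwise rugged enough to leave clusters of
#' quasi-degenerate peaks.
#'
#' @param v numeric vector (length >= 4 for a genuine 4-point window)
#' @return smoothed vector of the same length
#' @export
smooth4 <- function(v) {
  n <- length(v)
  if (n < 4L) {
    warning("profile shorter than the smoothing window; returned unchanged")
    return(v)
  }
  vapply(seq_len(n),
         function(i) mean(v[max(1L, i - 1L):min(n, i + 2L)]),
         numeric(1))
}

#' Detect peaks in a non-negative profile
#'
#' A peak is a maximal run of equal positive values strictly greater than
#' both flanking values, with the profile boundaries treated as -Inf
#' flanks (so a monotone ramp peaks at its end).  Each run contributes a
#' single index: the lower median of the run, which keeps plateau
#' tie-breaking deterministic and symmetric to within one residue.
#'
#' @param v numeric profile
#' @return strictly increasing integer vector of 1-based peak indices
#' @export
detectPeaks <- function(v) {
  if (!length(v)) return(integer())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  out <- integer()
  for (k in seq_len(nr)) {
    val <- r$values[k]
    if (val <= 0) next
    left <- if (k > 1L) r$values[k - 1L] else -Inf
    right <- if (k < nr) r$values[k + 1L] else -Inf
    if (val > left && val > right) {
      run <- starts[k]:ends[k]
      out <- c(out, run[(length(run) - 1L) %/% 2L + 1L])
    }
  }
  out
}

#' Reduce a raw indicator profile to its peak pattern
#'
#' Pipeline: high-pass filter, then (for closeness only) 4-point
#' smoothing, then peak detection.  Smoothing after filtering makes
#' clusters of quasi-degenerate closeness peaks coalesce into single
#' predictions.  The threshold is computed once, from the raw profile.
#'
#' @param p an [IndicatorPattern-class]
#' @param nSigma high-pass threshold; when NULL the per-indicator default
#'   from `cfg` applies
#' @param cfg named list of per-indicator defaults, see [filterConfig()]
#' @return a [ReducedPattern-class]
#' @export
reducePattern <- function(p, nSigma = NULL, cfg = filterConfig()) {
  stopifnot(is(p, "IndicatorPattern"))
  if (is.null(nSigma)) nSigma <- cfg[[paste0(p@indicator, "_nsigma")]]
  filtered <- highPassFilter(p@values, nSigma)
  processed <- if (p@indicator == "cc" && isTRUE(cfg$cc_smooth))
    smooth4(filtered) else filtered
  pk <- detectPeaks(processed)
  new("ReducedPattern", indicator = p@indicator, cutoff = p@cutoff,
      structureId = p@structureId, raw = p@values, filtered = filtered,
      processed = processed, peaks = as.integer(pk), nSigma = nSigma)
}

#' Per-indicator filtering configuration
#'
#' Defaults: 1.0 standard deviations for stiffness and connectivity, a
#' more permissive 0.5 for closeness (whose profiles are flatter and are
#' subsequently smoothed).
#'
#' @param chi_nsigma,conn_nsigma,cc_nsigma high-pass thresholds
#' @param cc_smooth apply [smooth4()] to filtered closeness profiles
#' @export
filterConfig <- function(chi_nsigma = 1.0, conn_nsigma = 1.0,
                         cc_nsigma = 0.5, cc_smooth = TRUE) {
  list(chi_nsigma = chi_nsigma, conn_nsigma = conn_nsigma,
       cc_nsigma = cc_nsigma, cc_smooth = cc_smooth)
}

#' Normalize a profile to its maximum
#'
#' Display-only convenience used when plotting or tabulating several
#' indicators together; never part of peak detection.  All-zero input is
#' returned unchanged.
#'
#' @param v numeric profile
#' @return profile scaled into \[0, 1\]
#' @export
normalizeToMax <- function(v) {
  mx <- max(v)
  if (mx > 0) v / mx else v
}

#' @rdname peaks
#' @export
setMethod("peaks", "ReducedPattern", function(x) x@peaks)

#' @rdname nPeaks
#' @export
setMethod("nPeaks", "ReducedPattern", function(x) length(x@peaks))

setMethod("show", "ReducedPattern", function(object) {
  cat("ReducedPattern [", object@indicator, "] at cutoff ", object@cutoff,
      " A: ", length(object@peaks), " peak(s) of ", length(object@raw),
      " residues (nSigma = ", object@nSigma, ")\n", sep = "")
})

#' Write a reduced pattern as TSV
#'
#' Columns: `index, chain_id, res_seq, raw, filtered, is_peak`; `filtered`
#' is the final processed profile that peaks were detected on.
#'
#' @param rp a [ReducedPattern-class]
#' @param s the parent [CAStructure-class]
#' @param path output path
#' @param header optional comment lines prefixed with `#`
#' @export
writePatternTSV <- function(rp, s, path, header = character()) {
  stopifnot(is(rp, "ReducedPattern"), is(s, "CAStructure"))
  n <- length(rp@raw)
  tab <- data.frame(index = seq_len(n), chain_id = s@residues$chain,
                    res_seq = s@residues$resno, raw = rp@raw,
                    filtered = rp@processed,
                    is_peak = as.integer(seq_len(n) %in% rp@peaks))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
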
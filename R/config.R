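#' Default run configuration
#'
#' Flat named list of every free parameter of the pipeline, with the
#' package defaults.  Unknown keys are rejected by [readRunConfig()] so a
#' typo in a config file cannot silently fall back to a default.
#'
#' @return named list of class `RunConfig`
#' @export
runConfig <- function() {
  structure(list(
    enm.k2 = 5, enm.M = 120, enm.n_top_modes = 5L, enm.zero_tol = 1e-8,
    enm.mode_weighting = "uniform",
    filter.chi_nsigma = 1.0, filter.conn_nsigma = 1.0,
    filter.cc_nsigma = 0.5, smoothing.cc = TRUE,
    score.weights = c(1, 1, 1) / 3,
    score.cutoffs = c(chi = 22, conn = 20, cc = 28),
    score.redistribute = TRUE,
    scan.cutoffs = seq(8, 40, by = 2),
    scan.dn = 0:2,
    eval.size_breaks = NULL,
    seed = 1L), class = "RunConfig")
}

#' Read a run configuration file
#'
#' YAML file of flat keys (see [runConfig()] for the full set); keys not
#' present keep their defaults, unknown keys are an error.  `overrides`
#' (e.g. from command-line flags) take precedence over file values.
#'
#' @param path YAML file path, or NULL for pure defaults
#' @param overrides named list applied last
#' @return a `RunConfig` list
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- runConfig()
  apply_kv <- function(cfg, kv, origin) {
    bad <- setdiff(names(kv), names(cfg))
    if (length(bad))
      stop("unknown configuration key(s) in ", origin, ": ",
           paste(bad, collapse = ", "))
    for (k in names(kv)) {
      v <- kv[[k]]
      if (k %in% c("score.weights", "score.cutoffs", "scan.cutoffs",
                   "scan.dn", "eval.size_breaks"))
        v <- unlist(v)
      if (k == "score.cutoffs" && is.null(names(v)))
        names(v) <- c("chi", "conn", "cc")
      cfg[[k]] <- v
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_kv(cfg, yaml::read_yaml(path), paste0("'", path, "'"))
  }
  if (length(overrides)) cfg <- apply_kv(cfg, overrides, "overrides")
  validateRunConfig(cfg)
  cfg
}

validateRunConfig <- function(cfg) {
  stopifnot(cfg$enm.k2 > 0, cfg$enm.M > 0, cfg$enm.n_top_modes >= 1,
            cfg$enm.zero_tol > 0,
            cfg$enm.mode_weighting %in% c("uniform", "inverse_omega2"),
            length(cfg$score.weights) == 3, all(cfg$score.weights >= 0),
            abs(sum(cfg$score.weights) - 1) < 1e-9,
            all(cfg$scan.cutoffs > 0),
            !is.unsorted(cfg$scan.cutoffs, strictly = TRUE),
            all(cfg$scan.dn >= 0))
  invisible(cfg)
}

enmParamsFromConfig <- function(cfg) {
  enmParams(k2 = cfg$enm.k2, M = cfg$enm.M,
            nTopModes = cfg$enm.n_top_modes, zeroTol = cfg$enm.zero_tol,
            modeWeighting = cfg$enm.mode_weighting)
}

filterConfigFromConfig <- function(cfg) {
  filterConfig(chi_nsigma = cfg$filter.chi_nsigma,
               conn_nsigma = cfg$filter.conn_nsigma,
               cc_nsigma = cfg$filter.cc_nsigma,
               cc_smooth = cfg$smoothing.cc)
}

#' Hash of a resolved configuration
#'
#' MD5 of the deparsed configuration, stamped into every output file
#' header so results are traceable to the exact parameter set.
#'
#' @param cfg a `RunConfig` list
#' @return hex string
#' @export
configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}
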
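#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline: the gene-association
#' window (5 kb up/downstream), the flanking window used for enrichment and
#' LTR-adjacency calls (1 kb), the recent-duplicate Ks cut-off (Ks < 0.5),
#' the Ks saturation filter (values exceeding 5 excluded), the pseudocount
#' added before the log2 transform of RPKM, and the seed / permutation count
#' for stochastic stages.
#'
#' @param association_window Window (bp) around a gene within which an LTR
#'   insertion is called gene-associated. Default 5000.
#' @param flank_window Window (bp) defining the gene-flanking class used for
#'   the enrichment test and paralog adjacency flags. Default 1000.
#' @param recent_ks_max Ks threshold (strict) selecting recent duplicate
#'   pairs. Default 0.5.
#' @param ks_saturation_max Ks values exceeding this are discarded as
#'   saturated. Default 5.
#' @param rpkm_pseudocount Pseudocount added before log2 transform. Default 1.
#' @param random_seed Integer seed for stochastic stages.
#' @param permutations Number of permutations for the enrichment test.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$association_window
analysis_config <- function(association_window = 5000L,
                            flank_window = 1000L,
                            recent_ks_max = 0.5,
                            ks_saturation_max = 5.0,
                            rpkm_pseudocount = 1.0,
                            random_seed = 1L,
                            permutations = 999L) {
  stopifnot(is.numeric(association_window), length(association_window) == 1L,
            is.numeric(flank_window), length(flank_window) == 1L)
  if (association_window <= 0 || flank_window <= 0)
    stop("windows must be positive")
  if (flank_window > association_window)
    stop("flank_window must not exceed association_window")
  if (!(recent_ks_max > 0 && recent_ks_max < ks_saturation_max))
    stop("need 0 < recent_ks_max < ks_saturation_max")
  if (rpkm_pseudocount < 0) stop("rpkm_pseudocount must be >= 0")
  if (permutations < 1) stop("permutations must be >= 1")
  structure(
    list(association_window = as.integer(association_window),
         flank_window = as.integer(flank_window),
         recent_ks_max = recent_ks_max,
         ks_saturation_max = ks_saturation_max,
         rpkm_pseudocount = rpkm_pseudocount,
         random_seed = as.integer(random_seed),
         permutations = as.integer(permutations)),
    class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write a machine-readable run manifest
#'
#' Records the stage name, input/filter counts and the seed next to a
#' pipeline output so stochastic stages can be reproduced.
#'
#' @param path Output JSON path.
#' @param stage Stage name, e.g. `"date-ltrs"`.
#' @param counts Named list/vector of record counts (inputs, kept, dropped).
#' @param seed Integer seed used (or `NA`).
#' @param config Optional `analysis_config` to embed.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, stage, counts = list(), seed = NA_integer_,
                               config = NULL) {
  manifest <- list(stage = stage,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed,
                   counts = as.list(counts))
  if (!is.null(config)) manifest$config <- unclass(config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
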
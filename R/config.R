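#' Screen configuration
#'
#' Bundles the dimensions and statistical parameters of an arrayed siRNA
#' screen: library sizes, siRNAs per gene, replicates, the expected cell
#' seeding density, the cytotoxicity exclusion percentile and the z-score
#' threshold used for hit calling.
#'
#' @param n_genes_lib1 Number of genes in the first (druggable) library.
#' @param n_genes_lib2 Number of genes in the second (genome-extension)
#'   library.
#' @param sirnas_per_gene Independent siRNAs arrayed per gene, one per well.
#' @param replicates Number of screen replicates (the whole plate set is
#'   screened this many times).
#' @param cells_per_well_mean Expected cells seeded per well; well cell
#'   counts are Poisson around this mean.
#' @param toxicity_percentile Wells in the lowest this-many percent of cell
#'   counts (screen-wide) are excluded as cytotoxic.
#' @param z_threshold Gene z-score magnitude above which a gene is called a
#'   hit.
#' @param log_noise_sd Standard deviation of the Gaussian well-to-well noise
#'   on the natural-log intensity scale; gene effects are expressed in these
#'   units.
#' @param baseline_log_intensity Mean log reporter intensity of a
#'   no-effect well before plate effects (arbitrary units).
#' @param pseudocount Value added to raw intensity before taking logs.
#'   The default 0 keeps plate-scale invariance exact; zero-intensity wells
#'   are then flagged excluded rather than mapped to -Inf.
#' @param controls_per_plate Scrambled negative-control wells per plate.
#' @param seed Integer seed controlling every stochastic step.
#'
#' @return A list with class `"screen_config"`.
#' @examples
#' cfg <- screen_config(n_genes_lib1 = 10, n_genes_lib2 = 5)
#' cfg$sirnas_per_gene
#' @export
screen_config <- function(n_genes_lib1,
                          n_genes_lib2,
                          sirnas_per_gene = 3,
                          replicates = 2,
                          cells_per_well_mean = 600,
                          toxicity_percentile = 5,
                          z_threshold = 1.7,
                          log_noise_sd = 1,
                          baseline_log_intensity = 6,
                          pseudocount = 0,
                          controls_per_plate = 16,
                          seed = 1L) {
  stopifnot(is.numeric(n_genes_lib1), is.numeric(n_genes_lib2))
  if (n_genes_lib1 < 1 || n_genes_lib2 < 0) {
    rlang::abort("gene counts must be positive", class = "hcscreen_error_config")
  }
  if (sirnas_per_gene < 1 || replicates < 1 || cells_per_well_mean <= 0) {
    rlang::abort("counts must be positive", class = "hcscreen_error_config")
  }
  if (toxicity_percentile <= 0 || toxicity_percentile >= 100) {
    rlang::abort("toxicity_percentile must lie in (0, 100)",
                 class = "hcscreen_error_config")
  }
  if (z_threshold <= 0) {
    rlang::abort("z_threshold must be positive", class = "hcscreen_error_config")
  }
  if (controls_per_plate < 1 || controls_per_plate > 96) {
    rlang::abort("controls_per_plate must be in 1..96",
                 class = "hcscreen_error_config")
  }
  structure(
    list(
      n_genes_lib1 = as.integer(n_genes_lib1),
      n_genes_lib2 = as.integer(n_genes_lib2),
      sirnas_per_gene = as.integer(sirnas_per_gene),
      replicates = as.integer(replicates),
      cells_per_well_mean = cells_per_well_mean,
      toxicity_percentile = toxicity_percentile,
      z_threshold = z_threshold,
      log_noise_sd = log_noise_sd,
      baseline_log_intensity = baseline_log_intensity,
      pseudocount = pseudocount,
      controls_per_plate = as.integer(controls_per_plate),
      seed = as.integer(seed)
    ),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  libraries: %d + %d genes, %d siRNAs/gene, %d replicate(s)\n",
              x$n_genes_lib1, x$n_genes_lib2, x$sirnas_per_gene, x$replicates))
  cat(sprintf("  %g cells/well, toxicity cut %g%%, |z| threshold %g\n",
              x$cells_per_well_mean, x$toxicity_percentile, x$z_threshold))
  invisible(x)
}

# Run code with a transient RNG state derived from `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
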
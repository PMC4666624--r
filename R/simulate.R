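#' Arrange the siRNA libraries on 384-well plates
#'
#' Lays out one well per siRNA across as many 384-well plates as needed.
#' Each plate reserves a block of scrambled negative-control wells in the
#' last column; the remaining wells are filled gene by gene, so the
#' `sirnas_per_gene` siRNAs of a gene sit in consecutive wells. The same
#' physical layout is used for every replicate, so the table describes one
#' replicate's plate set.
#'
#' @param config A [screen_config()].
#' @return A tibble with one row per well: `plate_id`, `well_id`
#'   (`"A1"`..`"P24"`), `gene`, `sirna_id`, `library`
#'   (`druggable`, `genome_extension` or `control`) and logical `control`.
#' @examples
#' layout <- build_layout(screen_config(4, 2, seed = 1))
#' dplyr::count(layout, library)
#' @export
build_layout <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  n_genes <- config$n_genes_lib1 + config$n_genes_lib2
  width <- nchar(as.character(n_genes))
  genes <- sprintf(paste0("GENE%0", max(5, width), "d"), seq_len(n_genes))
  lib <- rep(c("druggable", "genome_extension"),
             c(config$n_genes_lib1, config$n_genes_lib2))

  sirnas <- tibble::tibble(
    gene = rep(genes, each = config$sirnas_per_gene),
    library = rep(lib, each = config$sirnas_per_gene),
    sirna_id = paste0(rep(genes, each = config$sirnas_per_gene), "_si",
                      rep(seq_len(config$sirnas_per_gene), n_genes))
  )

  per_plate <- 384L - config$controls_per_plate
  n_plates <- ceiling(nrow(sirnas) / per_plate)
  plate_ids <- sprintf("P%03d", seq_len(n_plates))

  rows <- LETTERS[1:16]
  all_wells <- paste0(rep(rows, each = 24), rep(1:24, 16))
  ctrl_wells <- utils::tail(all_wells, config$controls_per_plate)
  sirna_wells <- setdiff(all_wells, ctrl_wells)

  sirnas$plate_id <- plate_ids[ceiling(seq_len(nrow(sirnas)) / per_plate)]
  sirnas$well_id <- sirna_wells[((seq_len(nrow(sirnas)) - 1L) %% per_plate) + 1L]

  controls <- tidyr::expand_grid(plate_id = plate_ids, well_id = ctrl_wells)
  controls$gene <- "scrambled"
  controls$library <- "control"
  controls$sirna_id <- paste0("scr_", controls$plate_id, "_",
                              match(controls$well_id, ctrl_wells))

  dplyr::arrange(
    dplyr::mutate(
      dplyr::bind_rows(sirnas, controls),
      control = .data$library == "control"
    ),
    .data$plate_id, match(.data$well_id, all_wells)
  )[, c("plate_id", "well_id", "gene", "sirna_id", "library", "control")]
}

#' Ground truth for a simulated screen
#'
#' Draws the latent quantities the simulator conditions on: per-gene
#' knockdown effects on log reporter intensity (positive for restriction
#' factors, negative for dependency factors), a set of cytotoxic siRNAs, and
#' a multiplicative intensity factor per plate.
#'
#' @param layout A layout from [build_layout()].
#' @param config A [screen_config()]; supplies the seed and noise units.
#' @param n_hrf,n_hdf Number of genes planted as restriction / dependency
#'   factors.
#' @param effect_size Magnitude of planted effects, in units of the
#'   well-level log-intensity noise SD.
#' @param toxic_fraction Fraction of siRNAs that are cytotoxic (wells get a
#'   depressed cell count regardless of the targeted gene).
#' @param plate_factor_sdlog SD of the log plate factors
#'   (`plate_factors = exp(N(0, sdlog))`).
#' @return A list with class `"screen_truth"`: `gene_effects` (tibble
#'   `gene`, `effect`), `toxic_sirnas` (character), `plate_factors`
#'   (tibble `plate_id`, `factor`).
#' @export
simulate_truth <- function(layout, config,
                           n_hrf = 0, n_hdf = 0,
                           effect_size = 3,
                           toxic_fraction = 0.02,
                           plate_factor_sdlog = 0.3) {
  genes <- sort(unique(layout$gene[!layout$control]))
  if (n_hrf + n_hdf > length(genes)) {
    rlang::abort("more planted genes than genes in the layout",
                 class = "hcscreen_error_truth")
  }
  with_local_seed(config$seed, {
    planted <- sample(genes, n_hrf + n_hdf)
    effects <- stats::setNames(rep(0, length(genes)), genes)
    if (n_hrf > 0) effects[planted[seq_len(n_hrf)]] <- effect_size * config$log_noise_sd
    if (n_hdf > 0) effects[planted[n_hrf + seq_len(n_hdf)]] <- -effect_size * config$log_noise_sd

    sirnas <- layout$sirna_id[!layout$control]
    toxic <- sample(sirnas, round(toxic_fraction * length(sirnas)))

    plates <- sort(unique(layout$plate_id))
    pf <- exp(stats::rnorm(length(plates), 0, plate_factor_sdlog))

    structure(
      list(
        gene_effects = tibble::tibble(gene = genes, effect = unname(effects)),
        toxic_sirnas = toxic,
        plate_factors = tibble::tibble(plate_id = plates, factor = pf)
      ),
      class = "screen_truth"
    )
  })
}

#' Simulate well-level screen readouts
#'
#' Generates one record per well and replicate under a lognormal intensity
#' model: the natural-log reporter intensity is baseline + gene effect +
#' log plate factor + Gaussian noise. Cell counts are Poisson around the
#' seeding density; wells whose siRNA is cytotoxic draw from a depressed
#' mean (10% of normal).
#'
#' @param layout A layout from [build_layout()].
#' @param truth A [simulate_truth()] result. Genes absent from
#'   `truth$gene_effects` get effect 0; plates absent from
#'   `truth$plate_factors` get factor 1.
#' @param config A [screen_config()].
#' @param toxic_count_factor Mean cell count of a cytotoxic well relative to
#'   a healthy one.
#' @return A tibble of well records: `plate_id`, `well_id`, `replicate`,
#'   `gene`, `sirna_id`, `library`, `control`, `cell_count`,
#'   `reporter_intensity`, `qc_excluded` (all `FALSE` here).
#' @examples
#' cfg <- screen_config(6, 0, replicates = 1, seed = 7)
#' lay <- build_layout(cfg)
#' wells <- simulate_wells(lay, simulate_truth(lay, cfg), cfg)
#' nrow(wells) == nrow(lay)
#' @export
simulate_wells <- function(layout, truth, config, toxic_count_factor = 0.1) {
  if (nrow(layout) == 0) {
    rlang::abort("empty layout", class = "hcscreen_error_simulate")
  }
  stopifnot(inherits(truth, "screen_truth"), inherits(config, "screen_config"))

  wells <- tidyr::expand_grid(replicate = seq_len(config$replicates), layout)
  eff <- stats::setNames(truth$gene_effects$effect, truth$gene_effects$gene)
  pf <- stats::setNames(truth$plate_factors$factor, truth$plate_factors$plate_id)

  gene_eff <- unname(eff[wells$gene])
  gene_eff[is.na(gene_eff) | wells$control] <- 0
  plate_f <- unname(pf[wells$plate_id])
  plate_f[is.na(plate_f)] <- 1
  toxic <- wells$sirna_id %in% truth$toxic_sirnas

  with_local_seed(config$seed + 1L, {
    log_int <- config$baseline_log_intensity + gene_eff + log(plate_f) +
      stats::rnorm(nrow(wells), 0, config$log_noise_sd)
    lambda <- ifelse(toxic, toxic_count_factor, 1) * config$cells_per_well_mean
    counts <- stats::rpois(nrow(wells), lambda)
    dplyr::mutate(
      wells[, c("plate_id", "well_id", "replicate", "gene", "sirna_id",
                "library", "control")],
      cell_count = counts,
      reporter_intensity = exp(log_int),
      qc_excluded = FALSE
    )
  })
}

#' Simulate a complete screen in one call
#'
#' Convenience wrapper: layout, truth and wells from a single config.
#'
#' @inheritParams simulate_truth
#' @param ... Passed to [simulate_truth()].
#' @return A list: `layout`, `truth`, `wells`.
#' @export
simulate_screen <- function(config, ...) {
  layout <- build_layout(config)
  truth <- simulate_truth(layout, config, ...)
  list(layout = layout, truth = truth,
       wells = simulate_wells(layout, truth, config))
}
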
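#' Run the full hit-calling pipeline on a well table
#'
#' Chains the screen statistics end to end: log transform, screen-wide
#' cytotoxicity filter on cell counts, robust per-plate normalization,
#' gene-level z-scores pooled over siRNAs and replicates, and threshold hit
#' calling. The run report records the cardinality at every stage, so
#' `wells_in = wells_kept + wells_cytotoxic + wells_other_excluded`.
#'
#' @param records Well records (e.g. from [simulate_wells()],
#'   [quantify_plate()] or [read_well_table()]). If they lack a `gene`
#'   column, supply `layout`.
#' @param layout Optional layout to annotate records with
#'   gene/siRNA/control columns (joined on `plate_id`, `well_id`).
#' @param z_threshold,toxicity_percentile,pseudocount Stage parameters; see
#'   [call_hits()], [filter_cytotoxic()], [log_transform()].
#' @param per_plate_toxicity Apply the cytotoxicity cut per plate instead of
#'   screen-wide.
#' @return An object of class `"screen_result"`: a list with `scores`
#'   (gene table with `z`, `n_wells_used`, `hit_class`, `rank`), `wells`
#'   (normalized well table), and `report` (named list of stage counts).
#' @examples
#' scr <- simulate_screen(screen_config(30, 0, seed = 1), n_hrf = 2)
#' res <- run_screen_pipeline(scr$wells)
#' glance(res)
#' @export
run_screen_pipeline <- function(records, layout = NULL,
                                z_threshold = 1.7,
                                toxicity_percentile = 5,
                                pseudocount = 0,
                                per_plate_toxicity = FALSE) {
  if (!is.null(layout)) {
    records <- dplyr::left_join(
      records,
      layout[, c("plate_id", "well_id", "gene", "sirna_id", "library", "control")],
      by = c("plate_id", "well_id")
    )
  }
  need <- c("plate_id", "well_id", "gene", "cell_count", "reporter_intensity")
  if (!all(need %in% names(records))) {
    rlang::abort(
      paste0("[stage input] missing columns: ",
             paste(setdiff(need, names(records)), collapse = ", ")),
      class = "hcscreen_error_pipeline"
    )
  }
  if (!"replicate" %in% names(records)) records$replicate <- 1L
  if (!"control" %in% names(records)) records$control <- FALSE

  n_in <- nrow(records)
  logged <- log_transform(records, pseudocount = pseudocount)
  split <- filter_cytotoxic(logged, toxicity_percentile,
                            per_plate = per_plate_toxicity)
  n_cytotoxic <- nrow(split$excluded)
  normalized <- normalize_plates(split$kept)
  scores <- gene_zscores(normalized)
  called <- call_hits(scores, z_threshold = z_threshold)

  structure(
    list(
      scores = called,
      wells = normalized,
      report = list(
        wells_in = n_in,
        wells_cytotoxic = n_cytotoxic,
        wells_kept = sum(!normalized$excluded),
        wells_other_excluded = nrow(normalized) - sum(!normalized$excluded),
        genes_scored = nrow(called),
        n_hrf = sum(called$hit_class == "HRF"),
        n_hdf = sum(called$hit_class == "HDF"),
        z_threshold = z_threshold,
        toxicity_percentile = toxicity_percentile,
        pseudocount = pseudocount
      )
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  r <- x$report
  cat("<screen_result>\n")
  cat(sprintf("  %d wells in; %d cytotoxic, %d otherwise excluded, %d used\n",
              r$wells_in, r$wells_cytotoxic, r$wells_other_excluded,
              r$wells_kept))
  cat(sprintf("  %d genes scored; %d HRF and %d HDF at |z| > %g\n",
              r$genes_scored, r$n_hrf, r$n_hdf, r$z_threshold))
  invisible(x)
}

#' Tidy a screen result into its gene score table
#'
#' @param x A `"screen_result"`.
#' @param ... Unused.
#' @return The per-gene tibble: `gene`, `z`, `n_wells_used`, `hit_class`,
#'   `rank`.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) x$scores

#' One-row summary of a screen result
#'
#' @param x A `"screen_result"`.
#' @param ... Unused.
#' @return A one-row tibble of the run report counts.
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::as_tibble(x$report[c("wells_in", "wells_cytotoxic", "wells_kept",
                               "genes_scored", "n_hrf", "n_hdf",
                               "z_threshold")])
}

#' Gene z-score distribution plot
#'
#' Histogram of the gene z-scores with dashed lines at the +/- hit
#' threshold, the standard display of genome-wide screen results.
#'
#' @param object A `"screen_result"`.
#' @param binwidth Histogram bin width in z units.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, binwidth = 0.25, ...) {
  thr <- object$report$z_threshold
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::labs(x = "gene z-score", y = "genes",
                  title = sprintf("%d genes: %d HRF, %d HDF at |z| > %g",
                                  object$report$genes_scored,
                                  object$report$n_hrf,
                                  object$report$n_hdf, thr)) +
    ggplot2::theme_minimal()
}

#' @export
plot.screen_result <- function(x, ...) print(autoplot.screen_result(x, ...))

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
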
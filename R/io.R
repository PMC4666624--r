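valid_well_ids <- function() {
  paste0(rep(LETTERS[1:16], each = 24), rep(1:24, 16))
}

#' Read and validate a plate map CSV
#'
#' Expected columns: `plate_id`, `well_id`, `gene`, `sirna_id`, `library`,
#' `control`. Well ids must be valid 384-well coordinates (rows A-P, columns
#' 1-24), `(plate_id, well_id)` pairs unique, and `library` one of
#' `druggable`, `genome_extension`, `control`. Each violation raises a
#' distinct error class.
#'
#' @param path CSV path.
#' @return A validated layout tibble (`control` coerced to logical).
#' @export
read_plate_map <- function(path) {
  lay <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("plate_id", "well_id", "gene", "sirna_id", "library", "control")
  if (!all(need %in% names(lay))) {
    rlang::abort(paste0("plate map missing columns: ",
                        paste(setdiff(need, names(lay)), collapse = ", ")),
                 class = "hcscreen_error_plate_map")
  }
  bad_well <- !lay$well_id %in% valid_well_ids()
  if (any(bad_well)) {
    rlang::abort(paste0("invalid well id: ", lay$well_id[bad_well][1]),
                 class = "hcscreen_error_invalid_well")
  }
  key <- paste(lay$plate_id, lay$well_id)
  if (anyDuplicated(key)) {
    rlang::abort(paste0("duplicate well: ", key[duplicated(key)][1]),
                 class = "hcscreen_error_duplicate_well")
  }
  bad_lib <- !lay$library %in% c("druggable", "genome_extension", "control")
  if (any(bad_lib)) {
    rlang::abort(paste0("unknown library tag: ", lay$library[bad_lib][1]),
                 class = "hcscreen_error_unknown_library")
  }
  dplyr::mutate(lay[, need],
                control = tolower(.data$control) %in% c("true", "t", "1"))
}

#' @rdname read_plate_map
#' @param layout A layout tibble.
#' @export
write_plate_map <- function(layout, path) {
  readr::write_csv(
    layout[, c("plate_id", "well_id", "gene", "sirna_id", "library", "control")],
    path
  )
  invisible(path)
}

#' Read / write a well-level measurement table CSV
#'
#' Canonical columns: `plate_id`, `well_id`, `replicate`, `cell_count`,
#' `reporter_intensity`; a `qc_excluded` column is carried through when
#' present.
#'
#' @param path CSV path.
#' @return A tibble of well records.
#' @export
read_well_table <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("plate_id", "well_id", "replicate", "cell_count",
            "reporter_intensity")
  if (!all(need %in% names(w))) {
    rlang::abort(paste0("well table missing columns: ",
                        paste(setdiff(need, names(w)), collapse = ", ")),
                 class = "hcscreen_error_well_table")
  }
  dplyr::mutate(w,
                plate_id = as.character(.data$plate_id),
                well_id = as.character(.data$well_id),
                replicate = as.integer(.data$replicate),
                cell_count = as.integer(.data$cell_count))
}

#' @rdname read_well_table
#' @param records A well record tibble.
#' @export
write_well_table <- function(records, path) {
  cols <- c("plate_id", "well_id", "replicate", "cell_count",
            "reporter_intensity",
            intersect("qc_excluded", names(records)))
  readr::write_csv(records[, cols], path)
  invisible(path)
}

#' Read a per-gene z-score table for re-analysis
#'
#' Re-analysis mode: when a screen's published per-gene z-scores are
#' available as a two-column table (`gene`, `z`; TSV or CSV), they can be
#' re-scored against any threshold with [call_hits()] without access to the
#' raw well data.
#'
#' @param path TSV/CSV path with columns `gene` and `z`.
#' @return A tibble `gene`, `z`.
#' @export
read_gene_zscores <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  z <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!all(c("gene", "z") %in% names(z))) {
    rlang::abort("gene z-score table needs columns 'gene' and 'z'",
                 class = "hcscreen_error_zscore_table")
  }
  tibble::as_tibble(z[, c("gene", "z")])
}

#' Write deterministic result files for a screen run
#'
#' Writes `gene_scores.tsv` (all genes, z to 4 decimals), `hits_hrf.tsv` and
#' `hits_hdf.tsv` (ranked hit lists, z to 2 decimals, matching the precision
#' screens conventionally report), and `report.json`. Rows are fully sorted
#' and floats fixed-format, so identical inputs produce byte-identical
#' files.
#'
#' @param result A `"screen_result"` from [run_screen_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scores <- result$scores

  p1 <- file.path(outdir, "gene_scores.tsv")
  readr::write_tsv(
    dplyr::mutate(
      scores[, c("gene", "z", "n_wells_used", "hit_class", "rank")],
      z = sprintf("%.4f", .data$z)
    ),
    p1
  )

  write_hits <- function(cls, file) {
    h <- scores[scores$hit_class == cls, c("rank", "gene", "z")]
    h <- h[order(h$rank), ]
    h$z <- sprintf("%.2f", h$z)
    readr::write_tsv(h, file)
  }
  p2 <- file.path(outdir, "hits_hrf.tsv")
  p3 <- file.path(outdir, "hits_hdf.tsv")
  write_hits("HRF", p2)
  write_hits("HDF", p3)

  p4 <- file.path(outdir, "report.json")
  jsonlite::write_json(result$report, p4, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p1, p2, p3, p4))
}
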
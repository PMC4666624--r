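#' Log-transform raw reporter intensities
#'
#' Takes natural logs of the per-well reporter intensity, optionally after
#' adding a pseudocount. With `pseudocount = 0`, zero-intensity wells are
#' flagged excluded rather than mapped to `-Inf`; this keeps the
#' transformation exactly shift-equivariant under multiplicative plate
#' effects. The transform is order-preserving.
#'
#' @param records Well records with at least `reporter_intensity`; a
#'   `qc_excluded` column is respected if present.
#' @param pseudocount Nonnegative value added before the log.
#' @return The input tibble with `log_intensity` and logical `excluded`
#'   columns added.
#' @examples
#' log_transform(tibble::tibble(reporter_intensity = exp(1)))$log_intensity
#' @export
log_transform <- function(records, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  if (any(records$reporter_intensity < 0, na.rm = TRUE)) {
    rlang::abort("negative reporter intensity",
                 class = "hcscreen_error_intensity")
  }
  qc <- if ("qc_excluded" %in% names(records)) records$qc_excluded else FALSE
  dplyr::mutate(
    records,
    log_intensity = log(.data$reporter_intensity + pseudocount),
    excluded = qc | !is.finite(.data$log_intensity)
  )
}

#' Exclude cytotoxic wells by cell count
#'
#' Excludes the wells with the lowest cell counts — by default the lowest 5%
#' screen-wide (`floor(p/100 * N)` wells over all plates and replicates, not
#' per plate). Ties are broken by `(plate_id, well_id, replicate)` in
#' lexicographic order so the excluded set is deterministic.
#'
#' @param records Well records with `cell_count`, `plate_id`, `well_id`.
#' @param toxicity_percentile Percent of wells to exclude, in (0, 100).
#' @param per_plate If `TRUE`, apply the cut within each plate-replicate
#'   instead of screen-wide.
#' @return A list of two tibbles, `kept` and `excluded`, which partition the
#'   input.
#' @examples
#' w <- tibble::tibble(plate_id = "P1", well_id = paste0("A", 1:40),
#'                     cell_count = 1:40)
#' nrow(filter_cytotoxic(w)$excluded)  # floor(0.05 * 40) = 2
#' @export
filter_cytotoxic <- function(records, toxicity_percentile = 5,
                             per_plate = FALSE) {
  if (toxicity_percentile <= 0 || toxicity_percentile >= 100) {
    rlang::abort("toxicity_percentile must lie in (0, 100)",
                 class = "hcscreen_error_percentile")
  }
  if (any(is.na(records$cell_count))) {
    rlang::abort("cell_count missing on some records",
                 class = "hcscreen_error_cellcount")
  }
  cut_group <- function(df) {
    k <- floor(toxicity_percentile / 100 * nrow(df))
    rep_col <- if ("replicate" %in% names(df)) df$replicate
               else rep(0L, nrow(df))
    ord <- order(df$cell_count, df$plate_id, df$well_id, rep_col)
    df$.cytotoxic <- FALSE
    df$.cytotoxic[ord[seq_len(k)]] <- TRUE
    df
  }
  marked <- if (per_plate) {
    grp <- if ("replicate" %in% names(records)) {
      list(records$plate_id, records$replicate)
    } else list(records$plate_id)
    dplyr::bind_rows(lapply(split(records, grp), cut_group))
  } else {
    cut_group(records)
  }
  list(
    kept = dplyr::select(marked[!marked$.cytotoxic, ], -".cytotoxic"),
    excluded = dplyr::select(marked[marked$.cytotoxic, ], -".cytotoxic")
  )
}

#' Robust inter-plate normalization
#'
#' Standardizes each well's log intensity against its own plate and
#' replicate: `well_z = (log_intensity - median) / (1.4826 * MAD)`, with the
#' median and MAD computed over that plate-replicate's included siRNA
#' (non-control) wells. Because the statistics are per plate on the log
#' scale, a multiplicative plate effect cancels exactly. Plates with fewer
#' included siRNA wells than `min_wells`, or with MAD 0, are excluded
#' entirely with a warning.
#'
#' @param wells Output of [log_transform()] with `plate_id`, `replicate`,
#'   `control`, `excluded`.
#' @param min_wells Minimum included siRNA wells per plate-replicate.
#' @return The input with a `well_z` column (`NA` on excluded wells) and
#'   `excluded` updated.
#' @export
normalize_plates <- function(wells, min_wells = 8) {
  need <- c("plate_id", "replicate", "log_intensity", "excluded", "control")
  stopifnot(all(need %in% names(wells)))
  grp <- paste(wells$plate_id, wells$replicate, sep = "\r")
  wells$well_z <- NA_real_
  for (g in unique(grp)) {
    idx <- which(grp == g)
    use <- idx[!wells$excluded[idx] & !wells$control[idx]]
    tag <- paste0("plate ", wells$plate_id[idx[1]], " replicate ",
                  wells$replicate[idx[1]])
    if (length(use) < min_wells) {
      rlang::warn(paste0(tag, ": fewer than ", min_wells,
                         " usable siRNA wells; plate excluded"),
                  class = "hcscreen_warning_small_plate")
      next
    }
    ctr <- stats::median(wells$log_intensity[use])
    scl <- stats::mad(wells$log_intensity[use], center = ctr)
    if (scl == 0) {
      rlang::warn(paste0(tag, ": zero MAD; plate excluded"),
                  class = "hcscreen_warning_zero_mad")
      next
    }
    wells$well_z[idx] <- (wells$log_intensity[idx] - ctr) / scl
  }
  wells$well_z[wells$excluded] <- NA_real_
  wells$excluded <- wells$excluded | is.na(wells$well_z)
  wells
}

#' Aggregate well z-scores into gene z-scores
#'
#' Each gene's score is the mean of the normalized well z-scores over all of
#' its included wells (all siRNAs, both replicates pooled), scaled by
#' `sqrt(n)`: `z = mean(well_z) * sqrt(n_wells_used)`. Under the null
#' (independent standard-normal well z-scores) the gene z is standard normal
#' whatever `n`, which makes a fixed |z| cutoff correspond to a fixed
#' normal tail probability.
#'
#' @param wells Normalized wells from [normalize_plates()] with a `gene`
#'   column (join the layout first if needed).
#' @return A tibble: `gene`, `z`, `n_wells_used`, sorted by gene. Genes with
#'   no usable wells are omitted with a warning.
#' @examples
#' w <- tibble::tibble(gene = "A", well_z = rep(1, 6),
#'                     excluded = FALSE, control = FALSE)
#' gene_zscores(w)$z  # sqrt(6)
#' @export
gene_zscores <- function(wells) {
  stopifnot(all(c("gene", "well_z", "excluded") %in% names(wells)))
  ctrl <- if ("control" %in% names(wells)) wells$control else FALSE
  use <- wells[!wells$excluded & !ctrl, ]
  scores <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(use, .data$gene),
      z = mean(.data$well_z) * sqrt(dplyr::n()),
      n_wells_used = dplyr::n(),
      .groups = "drop"
    ),
    .data$gene
  )
  all_genes <- unique(wells$gene[!ctrl])
  missing <- setdiff(all_genes, scores$gene)
  if (length(missing) > 0) {
    rlang::warn(paste0(length(missing),
                       " gene(s) had no usable wells and were omitted"),
                class = "hcscreen_warning_empty_gene")
  }
  scores
}

#' Call restriction- and dependency-factor hits
#'
#' Classifies genes by a symmetric z threshold: host-cell restriction
#' factors (HRF) have `z > z_threshold` (knockdown raised the reporter),
#' dependency factors (HDF) have `z < -z_threshold`. The inequalities are
#' strict: a gene exactly at the threshold is not a hit. HRFs are ranked by
#' decreasing z (rank 1 = strongest restriction factor), HDFs by increasing
#' z; ties are broken by gene symbol.
#'
#' @param scores A tibble with `gene` and `z` (e.g. from [gene_zscores()] or
#'   [read_gene_zscores()]).
#' @param z_threshold Positive threshold on |z|.
#' @return The input with `hit_class` (`"HRF"`, `"HDF"` or `"none"`) and
#'   `rank` (1..k within each hit class, `NA` otherwise), rows ordered by
#'   decreasing z then gene.
#' @examples
#' call_hits(tibble::tibble(gene = c("a", "b"), z = c(2.4, -0.3)))
#' @export
call_hits <- function(scores, z_threshold = 1.7) {
  stopifnot(z_threshold > 0)
  if (any(!is.finite(scores$z))) {
    rlang::abort("non-finite z-scores", class = "hcscreen_error_scores")
  }
  out <- dplyr::mutate(
    scores,
    hit_class = dplyr::case_when(
      .data$z > z_threshold ~ "HRF",
      .data$z < -z_threshold ~ "HDF",
      TRUE ~ "none"
    )
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$z), .data$gene)
  out$rank <- NA_integer_
  out$rank[out$hit_class == "HRF"] <- seq_len(sum(out$hit_class == "HRF"))
  hdf <- which(out$hit_class == "HDF")
  out$rank[hdf[order(out$z[hdf], out$gene[hdf])]] <- seq_along(hdf)
  out
}

#' One-sided standard-normal tail probability
#'
#' `1 - pnorm(z)`: the probability that a standard-normal score exceeds `z`.
#' At the conventional screen threshold of 1.7 this is 0.0446, i.e. below
#' 0.05 one-sided.
#'
#' @param z Numeric vector of z-scores.
#' @return `P(Z > z)` for standard normal Z.
#' @examples
#' tail_probability(1.7)
#' @export
tail_probability <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Fold change relative to a scrambled control
#'
#' The normalization convention of follow-up assays: within each replicate
#' experiment, readouts are scaled so the mean of the negative-control
#' (scrambled siRNA) condition is 100; per-condition means and SDs are then
#' taken across replicates. The control condition therefore maps to exactly
#' 100 and `ratio_to_control = relative_value / 100`.
#'
#' @param assay A tibble with columns `condition`, `replicate`, `readout`.
#' @param control_condition Name of the control condition; must appear in
#'   every replicate.
#' @return A tibble per condition: `condition`, `relative_value` (mean over
#'   replicates), `ratio_to_control`, `mean`, `sd`, `n_replicates`.
#' @examples
#' a <- tibble::tibble(condition = rep(c("scr", "kd"), 2),
#'                     replicate = rep(1:2, each = 2),
#'                     readout = c(1000, 3000, 800, 2400))
#' fold_change(a, "scr")
#' @export
fold_change <- function(assay, control_condition) {
  stopifnot(all(c("condition", "replicate", "readout") %in% names(assay)))
  if (!control_condition %in% assay$condition) {
    rlang::abort("control condition absent", class = "hcscreen_error_control")
  }
  ctrl <- dplyr::summarise(
    dplyr::group_by(assay[assay$condition == control_condition, ],
                    .data$replicate),
    .ctrl_mean = mean(.data$readout), .groups = "drop"
  )
  if (any(ctrl$.ctrl_mean == 0)) {
    rlang::abort("control mean is zero", class = "hcscreen_error_control")
  }
  joined <- dplyr::inner_join(assay, ctrl, by = "replicate")
  if (nrow(joined) < nrow(assay)) {
    rlang::abort("some replicates have no control measurement",
                 class = "hcscreen_error_control")
  }
  dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(joined, rel = 100 * .data$readout / .data$.ctrl_mean),
      .data$condition
    ),
    relative_value = mean(.data$rel),
    ratio_to_control = mean(.data$rel) / 100,
    mean = mean(.data$rel),
    sd = stats::sd(.data$rel),
    n_replicates = dplyr::n_distinct(.data$replicate),
    .groups = "drop"
  )
}
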
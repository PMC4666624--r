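#' Render a synthetic two-channel well image
#'
#' Draws a wide-field-like image of a well: channel 1 holds one circular
#' nucleus per cell, channel 2 carries each cell's reporter signal uniformly
#' over its nuclear footprint. Cells are placed without overlap (dart
#' throwing with a minimum centre distance of the two radii plus a margin).
#' The ground truth used to draw the image is returned alongside it, so
#' segmentation and quantification can be scored exactly.
#'
#' @param cell_count Number of nuclei to place.
#' @param reporter_intensity Mean per-cell reporter level; per-cell levels
#'   are Gamma-distributed around it (CV `intensity_cv`).
#' @param width,height Image size in pixels.
#' @param radius_range Nucleus radius range (pixels), drawn uniformly.
#' @param margin Minimum gap between nucleus rims, pixels.
#' @param nucleus_level Channel-1 value inside a nucleus (background is 0
#'   plus noise).
#' @param noise_sd SD of additive Gaussian background noise on both
#'   channels (truncated at 0).
#' @param intensity_cv Coefficient of variation of per-cell reporter levels.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A list with class `"well_image"`: `image` (array
#'   `height x width x 2`), `cells` (tibble `x`, `y`, `radius`,
#'   `intensity`), `cell_count`, `reporter_intensity`.
#' @examples
#' wi <- render_well_image(10, 200, seed = 1)
#' wi$cell_count
#' @export
render_well_image <- function(cell_count,
                              reporter_intensity,
                              width = 128, height = 128,
                              radius_range = c(4, 6),
                              margin = 3,
                              nucleus_level = 3000,
                              noise_sd = 20,
                              intensity_cv = 0.2,
                              seed = 1L,
                              max_tries = 200L) {
  stopifnot(cell_count >= 0, reporter_intensity >= 0, width > 0, height > 0)
  rmax <- max(radius_range)
  if (cell_count * pi * (rmax + margin / 2)^2 > 0.5 * width * height) {
    rlang::abort("cell_count cannot be placed without overlap at this radius",
                 class = "hcscreen_error_placement")
  }

  with_local_seed(seed, {
    xs <- ys <- rs <- numeric(0)
    for (i in seq_len(cell_count)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- stats::runif(1, radius_range[1], radius_range[2])
        x <- stats::runif(1, r + 1, width - r)
        y <- stats::runif(1, r + 1, height - r)
        if (length(xs) == 0 ||
            all(sqrt((xs - x)^2 + (ys - y)^2) >= rs + r + margin)) {
          xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rlang::abort("cell_count cannot be placed without overlap at this radius",
                     class = "hcscreen_error_placement")
      }
    }

    shape <- if (cell_count > 0) {
      reporter_intensity <- max(reporter_intensity, .Machine$double.eps)
      1 / intensity_cv^2
    } else NULL
    levels <- if (cell_count > 0) {
      stats::rgamma(cell_count, shape = shape,
                    rate = shape / reporter_intensity)
    } else numeric(0)

    ch1 <- matrix(pmax(stats::rnorm(height * width, 0, noise_sd), 0),
                  nrow = height)
    ch2 <- matrix(pmax(stats::rnorm(height * width, 0, noise_sd), 0),
                  nrow = height)
    px <- matrix(rep(seq_len(width), each = height), nrow = height)
    py <- matrix(rep(seq_len(height), width), nrow = height)
    for (i in seq_along(xs)) {
      inside <- (px - xs[i])^2 + (py - ys[i])^2 <= rs[i]^2
      ch1[inside] <- nucleus_level
      ch2[inside] <- levels[i]
    }

    structure(
      list(
        image = array(c(ch1, ch2), dim = c(height, width, 2)),
        cells = tibble::tibble(x = xs, y = ys, radius = rs,
                               intensity = levels),
        cell_count = as.integer(cell_count),
        reporter_intensity = reporter_intensity
      ),
      class = "well_image"
    )
  })
}

#' Write / read a two-channel well image as 16-bit TIFF
#'
#' Channels are stored as two 16-bit greyscale frames; pixel values are
#' counts clipped at 65535. `write_well_tiff` also writes a JSON ground-truth
#' sidecar (`<path>.json`) when given a full `"well_image"`.
#'
#' @param image A `"well_image"` or a `height x width x 2` array.
#' @param path Output TIFF path.
#' @return `write_well_tiff` returns `path` invisibly; `read_well_tiff`
#'   returns a `height x width x 2` array of counts.
#' @export
write_well_tiff <- function(image, path) {
  arr <- if (inherits(image, "well_image")) image$image else image
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] == 2)
  frames <- list(pmin(arr[, , 1], 65535) / 65535,
                 pmin(arr[, , 2], 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  if (inherits(image, "well_image")) {
    jsonlite::write_json(
      list(cell_count = image$cell_count,
           reporter_intensity = image$reporter_intensity,
           cells = image$cells),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_well_tiff
#' @export
read_well_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) != 2) {
    rlang::abort("expected a 2-frame (nuclei + reporter) TIFF",
                 class = "hcscreen_error_image_io")
  }
  array(c(frames[[1]], frames[[2]]) * 65535,
        dim = c(dim(frames[[1]]), 2))
}

#' Segment nuclei in the Hoechst channel
#'
#' Gaussian smoothing, a global threshold (Otsu by default), connected
#' components, an area filter, and optionally a distance-transform watershed
#' to split touching nuclei. Deterministic for a given image and parameters.
#'
#' @param channel1 Numeric matrix (nuclei channel), nonnegative.
#' @param smoothing_scale Gaussian sigma in pixels; 0 disables smoothing.
#' @param threshold_method `"otsu"` or a numeric threshold on the raw scale.
#' @param min_area Minimum object area in pixels; smaller objects are
#'   dropped.
#' @param split_touching Apply watershed on the distance map to separate
#'   touching nuclei.
#' @return A list with class `"segmentation"`: `label_map` (integer matrix,
#'   0 = background), `n_objects`, `areas`.
#' @export
segment_nuclei <- function(channel1,
                           smoothing_scale = 1,
                           threshold_method = "otsu",
                           min_area = 20,
                           split_touching = FALSE) {
  stopifnot(is.matrix(channel1))
  if (any(!is.finite(channel1))) {
    rlang::abort("image contains non-finite pixels",
                 class = "hcscreen_error_image")
  }

  top <- max(channel1)
  scaled <- if (top > 0) channel1 / top else channel1
  img <- EBImage::Image(scaled)
  if (smoothing_scale > 0) {
    img <- EBImage::gblur(img, sigma = smoothing_scale)
  }

  th <- if (identical(threshold_method, "otsu")) {
    if (top > 0) EBImage::otsu(img) else Inf
  } else if (is.numeric(threshold_method)) {
    threshold_method / max(top, .Machine$double.eps)
  } else {
    rlang::abort("unknown threshold_method", class = "hcscreen_error_image")
  }

  mask <- img > th
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask))
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- EBImage::imageData(labels)

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]

  structure(
    list(label_map = matrix(as.integer(lab), nrow = nrow(channel1)),
         n_objects = length(keep),
         areas = areas[keep]),
    class = "segmentation"
  )
}

#' Measure reporter intensity per segmented cell
#'
#' @param channel2 Numeric matrix (reporter channel), co-registered with the
#'   segmented channel.
#' @param seg A [segment_nuclei()] result.
#' @return A list: `well_mean` (mean of per-cell means; `NA` with
#'   `flagged = TRUE` when no objects), `per_cell` (numeric vector, one mean
#'   per label), `flagged`.
#' @export
quantify_reporter <- function(channel2, seg) {
  stopifnot(inherits(seg, "segmentation"), is.matrix(channel2))
  if (!all(dim(channel2) == dim(seg$label_map))) {
    rlang::abort("channel dimensions do not match the segmentation",
                 class = "hcscreen_error_image")
  }
  if (seg$n_objects == 0) {
    return(list(well_mean = NA_real_, per_cell = numeric(0), flagged = TRUE))
  }
  idx <- seg$label_map > 0
  per_cell <- as.numeric(tapply(channel2[idx], seg$label_map[idx], mean))
  list(well_mean = mean(per_cell), per_cell = per_cell, flagged = FALSE)
}

#' Quantify every well image of a plate
#'
#' Segments and measures each well's two-channel image and emits one well
#' record per layout row. Wells with a missing image, or with no segmented
#' nuclei, are emitted with `qc_excluded = TRUE` rather than dropped.
#'
#' @param images Named list of `height x width x 2` arrays (or
#'   `"well_image"` objects), names = well ids; or a directory of TIFFs
#'   named `<well_id>.tif`.
#' @param layout Layout rows for one plate (one replicate).
#' @param replicate Replicate number stamped on the records.
#' @param ... Passed to [segment_nuclei()].
#' @return A tibble of well records matching the well-table schema.
#' @export
quantify_plate <- function(images, layout, replicate = 1L, ...) {
  stopifnot(length(unique(layout$plate_id)) == 1)
  from_dir <- is.character(images) && length(images) == 1 && dir.exists(images)

  rows <- purrr::map(seq_len(nrow(layout)), function(i) {
    wid <- layout$well_id[i]
    arr <- if (from_dir) {
      f <- file.path(images, paste0(wid, ".tif"))
      if (file.exists(f)) read_well_tiff(f) else NULL
    } else {
      x <- images[[wid]]
      if (inherits(x, "well_image")) x$image else x
    }
    if (is.null(arr)) {
      rlang::warn(paste0("no image for well ", wid, "; flagged"),
                  class = "hcscreen_warning_missing_image")
      return(tibble::tibble(cell_count = 0L, reporter_intensity = NA_real_,
                            qc_excluded = TRUE))
    }
    seg <- segment_nuclei(arr[, , 1], ...)
    q <- quantify_reporter(arr[, , 2], seg)
    tibble::tibble(cell_count = as.integer(seg$n_objects),
                   reporter_intensity = q$well_mean,
                   qc_excluded = q$flagged)
  })

  dplyr::bind_cols(
    layout[, c("plate_id", "well_id", "gene", "sirna_id", "library", "control")],
    dplyr::bind_rows(rows)
  ) |>
    dplyr::mutate(replicate = as.integer(replicate), .after = "well_id")
}
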
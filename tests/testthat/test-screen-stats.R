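test_that("log transform is the natural log plus pseudocount and keeps order", {
  w <- tibble::tibble(reporter_intensity = c(exp(1), 1, 10, 100))
  out <- log_transform(w, pseudocount = 0)
  expect_equal(out$log_intensity[1], 1)
  expect_equal(order(out$log_intensity), order(w$reporter_intensity))
  out2 <- log_transform(w, pseudocount = 1)
  expect_equal(out2$log_intensity, log(w$reporter_intensity + 1))
})

test_that("zero intensity with pseudocount 0 is flagged, not -Inf propagated", {
  out <- log_transform(tibble::tibble(reporter_intensity = c(0, 5)), 0)
  expect_true(out$excluded[1])
  expect_false(out$excluded[2])
  expect_error(log_transform(tibble::tibble(reporter_intensity = -1)),
               class = "hcscreen_error_intensity")
})

test_that("cytotoxicity filter drops exactly floor(p% of N) lowest-count wells", {
  w <- tibble::tibble(plate_id = "P1",
                      well_id = paste0(rep(LETTERS[1:2], each = 20), 1:20),
                      cell_count = sample(40))
  out <- filter_cytotoxic(w, 5)
  expect_equal(nrow(out$excluded), 2)  # floor(0.05 * 40)
  expect_setequal(out$excluded$cell_count, c(1, 2))
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(w))
  expect_length(intersect(out$kept$well_id, out$excluded$well_id), 0)
})

test_that("tied cell counts are excluded in plate/well lexicographic order", {
  w <- tibble::tibble(plate_id = rep(c("P2", "P1"), each = 20),
                      well_id = rep(paste0("A", 1:20), 2),
                      cell_count = 7L)
  out <- filter_cytotoxic(w, 5)
  expect_equal(nrow(out$excluded), 2)
  expect_equal(out$excluded$plate_id, c("P1", "P1"))
  expect_equal(sort(out$excluded$well_id), c("A1", "A10"))
})

test_that("filter matches a brute-force full-sort oracle on random counts", {
  set.seed(91)
  for (n in c(57, 200, 1000)) {
    w <- tibble::tibble(
      plate_id = sample(sprintf("P%02d", 1:5), n, replace = TRUE),
      well_id = paste0(sample(LETTERS[1:16], n, TRUE), sample(24, n, TRUE)),
      replicate = sample(2, n, TRUE),
      cell_count = rpois(n, 50)
    )
    w <- w[!duplicated(w[c("plate_id", "well_id", "replicate")]), ]
    out <- filter_cytotoxic(w, 5)
    ord <- w[order(w$cell_count, w$plate_id, w$well_id, w$replicate), ]
    oracle <- ord[seq_len(floor(0.05 * nrow(w))), ]
    expect_equal(
      dplyr::arrange(out$excluded, plate_id, well_id, replicate),
      dplyr::arrange(oracle, plate_id, well_id, replicate)
    )
  }
  expect_error(filter_cytotoxic(w, 100), class = "hcscreen_error_percentile")
})

make_norm_input <- function(intensities, plate = "P1", control = FALSE) {
  n <- length(intensities)
  tibble::tibble(
    plate_id = plate, well_id = paste0("A", seq_len(n)), replicate = 1L,
    gene = paste0("g", seq_len(n)), control = control,
    reporter_intensity = intensities
  )
}

test_that("plate normalization removes multiplicative plate effects exactly", {
  set.seed(4)
  base <- exp(rnorm(96, 6))
  w1 <- log_transform(make_norm_input(base), 0)
  w2 <- log_transform(make_norm_input(base * 37.5), 0)
  expect_equal(normalize_plates(w1)$well_z, normalize_plates(w2)$well_z)
})

test_that("degenerate plates are flagged instead of scored", {
  const <- log_transform(make_norm_input(rep(10, 20)), 0)
  expect_warning(out <- normalize_plates(const),
                 class = "hcscreen_warning_zero_mad")
  expect_true(all(out$excluded))

  small <- log_transform(make_norm_input(exp(rnorm(5, 6))), 0)
  expect_warning(out2 <- normalize_plates(small),
                 class = "hcscreen_warning_small_plate")
  expect_true(all(out2$excluded))
})

test_that("well z distributions from plates with 10x intensity offsets agree", {
  set.seed(10)
  # generative oracle: same lognormal law, plate factors 1 and 10
  w <- dplyr::bind_rows(
    make_norm_input(exp(rnorm(352, 6)), plate = "P1"),
    make_norm_input(exp(rnorm(352, 6) + log(10)), plate = "P2")
  )
  z <- normalize_plates(log_transform(w, 0))
  ks <- suppressWarnings(
    ks.test(z$well_z[z$plate_id == "P1"], z$well_z[z$plate_id == "P2"])
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("gene z is the well mean scaled by sqrt(n)", {
  w0 <- tibble::tibble(gene = rep(c("a", "b"), each = 3),
                       well_z = 0, excluded = FALSE, control = FALSE)
  expect_true(all(gene_zscores(w0)$z == 0))

  w1 <- tibble::tibble(gene = "g", well_z = rep(1, 6),
                       excluded = FALSE, control = FALSE)
  expect_equal(gene_zscores(w1)$z, sqrt(6))

  w2 <- tibble::tibble(gene = c("g", "g", "h"), well_z = c(2, 4, 1),
                       excluded = c(FALSE, FALSE, TRUE), control = FALSE)
  expect_warning(out <- gene_zscores(w2),
                 class = "hcscreen_warning_empty_gene")
  expect_equal(out$gene, "g")
  expect_equal(out$n_wells_used, 2L)
})

test_that("gene z is standard normal under the null for mixed well counts", {
  set.seed(77)
  n_genes <- 2000
  nw <- sample(3:6, n_genes, replace = TRUE)
  w <- tibble::tibble(gene = rep(sprintf("g%04d", seq_len(n_genes)), nw),
                      well_z = rnorm(sum(nw)),
                      excluded = FALSE, control = FALSE)
  frac <- mean(abs(gene_zscores(w)$z) > 1.7)
  p0 <- 2 * tail_probability(1.7)
  ci <- qbinom(c(0.005, 0.995), n_genes, p0) / n_genes
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("hit calling reproduces the published SUMO-pathway ranking", {
  # printed screen scores for the SUMOylation factors
  t1 <- tibble::tibble(
    gene = c("SAE1", "UBA2", "UBE2I", "TRIM33", "SUMO2", "SUMO4", "PIAS1",
             "SENP1"),
    z = c(21.51, 17.99, 16.59, 7.72, 7.27, 3.68, 2.43, 2.33)
  )
  out <- call_hits(t1, 1.7)
  expect_true(all(out$hit_class == "HRF"))
  expect_equal(out$gene[out$rank <= 3], c("SAE1", "UBA2", "UBE2I"))
  expect_equal(out$z[out$rank == 1], 21.51)
})

test_that("the hit threshold is strict and the classes partition the genes", {
  s <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                      z = c(1.7, -1.7, 1.700001, -1.8, 0))
  out <- call_hits(s, 1.7)
  expect_equal(out$hit_class[match(c("a", "b"), out$gene)], c("none", "none"))
  expect_equal(out$hit_class[match("c", out$gene)], "HRF")
  expect_equal(out$hit_class[match("d", out$gene)], "HDF")
  expect_equal(sum(out$hit_class == "HRF"), 1)
  expect_equal(sum(out$hit_class == "HDF"), 1)
  expect_equal(sum(out$hit_class == "none"), 3)

  none <- call_hits(tibble::tibble(gene = "x", z = 0.5))
  expect_equal(sum(none$hit_class != "none"), 0)
  expect_error(call_hits(tibble::tibble(gene = "x", z = NaN)),
               class = "hcscreen_error_scores")
})

test_that("tied z-scores rank by gene symbol", {
  out <- call_hits(tibble::tibble(gene = c("ZZZ", "AAA", "MMM"),
                                  z = c(5, 5, 5)))
  expect_equal(out$gene[order(out$rank)], c("AAA", "MMM", "ZZZ"))
  hdf <- call_hits(tibble::tibble(gene = c("b", "a"), z = c(-4, -4)))
  expect_equal(hdf$gene[order(hdf$rank)], c("a", "b"))
})

test_that("tail probability matches numerical integration of the normal density", {
  expect_equal(tail_probability(0), 0.5)
  oracle <- integrate(dnorm, 1.7, Inf)$value
  expect_equal(tail_probability(1.7), oracle, tolerance = 1e-8)
  z <- seq(0, 5, by = 0.5)
  expect_true(all(diff(tail_probability(z)) < 0))
})

test_that("fold change normalizes each replicate to its own control", {
  a <- tibble::tibble(
    condition = rep(c("scr", "kd"), 3),
    replicate = rep(1:3, each = 2),
    readout = c(1000, 3000, 800, 2400, 1250, 2500)
  )
  out <- fold_change(a, "scr")
  kd <- out[out$condition == "kd", ]
  # hand-computed: rel = (300, 300, 200)
  expect_equal(kd$relative_value, mean(c(300, 300, 200)))
  expect_equal(kd$sd, sd(c(300, 300, 200)))
  expect_equal(kd$ratio_to_control, kd$relative_value / 100)
  expect_equal(kd$n_replicates, 3L)
  scr <- out[out$condition == "scr", ]
  expect_identical(scr$relative_value, 100)
  expect_identical(scr$sd, 0)
})

test_that("fold change on equal readouts is exactly 100", {
  a <- tibble::tibble(condition = rep(c("scr", "t"), 2),
                      replicate = rep(1:2, each = 2),
                      readout = c(5, 5, 9, 9))
  out <- fold_change(a, "scr")
  expect_true(all(out$relative_value == 100))
  expect_true(all(out$ratio_to_control == 1))
})

test_that("fold change rejects missing or zero controls", {
  expect_error(
    fold_change(tibble::tibble(condition = "t", replicate = 1, readout = 2),
                "scr"),
    class = "hcscreen_error_control"
  )
  expect_error(
    fold_change(tibble::tibble(condition = c("scr", "t"), replicate = 1,
                               readout = c(0, 2)), "scr"),
    class = "hcscreen_error_control"
  )
  expect_error(
    fold_change(tibble::tibble(condition = c("scr", "t", "t"),
                               replicate = c(1, 1, 2),
                               readout = c(10, 20, 30)), "scr"),
    class = "hcscreen_error_control"
  )
})
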
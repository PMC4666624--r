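# Small screens and image fixtures shared across test files.

tiny_config <- function(n1 = 20, n2 = 10, seed = 1, ...) {
  screen_config(n1, n2, seed = seed, ...)
}

# A screen small enough for per-test use: 30 genes, 1 plate-pair.
tiny_screen <- function(seed = 1, n_hrf = 0, n_hdf = 0, effect_size = 3,
                        toxic_fraction = 0.02, plate_factor_sdlog = 0.3,
                        ...) {
  cfg <- tiny_config(seed = seed, ...)
  layout <- build_layout(cfg)
  truth <- simulate_truth(layout, cfg, n_hrf = n_hrf, n_hdf = n_hdf,
                          effect_size = effect_size,
                          toxic_fraction = toxic_fraction,
                          plate_factor_sdlog = plate_factor_sdlog)
  list(config = cfg, layout = layout, truth = truth,
       wells = simulate_wells(layout, truth, cfg))
}

# Independent regex oracle for the consensus motif: lookahead so overlapping
# matches are all found. Returns acceptor-K positions (1-based).
regex_motif_oracle <- function(seq, psi = psi_set()) {
  pat <- sprintf("(?=[%s]K.[DE])", paste(psi, collapse = ""))
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) + 1L
}

random_protein <- function(len, with_x = FALSE) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V", if (with_x) "X")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

aav2_fixture <- function() {
  system.file("extdata", "aav2_vp1_synthetic.fasta", package = "hcscreen")
}
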
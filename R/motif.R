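#' Hydrophobic residue presets for the SUMOylation consensus
#'
#' The consensus acceptor motif is Psi-K-X-(D/E) with Psi a hydrophobic
#' residue. The exact hydrophobic alphabet varies between tools; two common
#' choices are provided and any custom set of one-letter codes is accepted
#' by the scanners.
#'
#' @param preset `"default"` (A, I, L, M, F, P, V) or `"strict"`
#'   (V, I, L, M, F, P; excludes alanine).
#' @return Character vector of one-letter residue codes.
#' @examples
#' psi_set("strict")
#' @export
psi_set <- function(preset = c("default", "strict")) {
  switch(match.arg(preset),
         default = c("A", "I", "L", "M", "F", "P", "V"),
         strict = c("V", "I", "L", "M", "F", "P"))
}

#' Scan a protein for the SUMOylation consensus motif
#'
#' Reports every position where the sequence matches Psi-K-X-(D/E): a
#' hydrophobic residue, the acceptor lysine, any residue, then aspartate or
#' glutamate. Positions are 1-based indices of the acceptor lysine.
#' Overlapping matches are all reported; the unknown residue `X` never
#' satisfies the Psi or D/E classes. Sequences shorter than 4 residues yield
#' an empty table.
#'
#' @param sequence A single protein sequence (uppercase one-letter codes;
#'   `X` tolerated as unknown).
#' @param id Identifier stamped on the hits.
#' @param psi Hydrophobic alphabet for the Psi position; see [psi_set()].
#' @return A tibble: `protein_id`, `k_position`, `psi_residue`, `window`
#'   (the 4-letter matched window), sorted by `k_position`.
#' @examples
#' scan_consensus("AVKTE")  # VKTE, lysine at position 3
#' @export
scan_consensus <- function(sequence, id = "protein", psi = psi_set()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  if (grepl("[-.*]", sequence)) {
    rlang::abort("sequence contains gap characters",
                 class = "hcscreen_error_sequence")
  }
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  empty <- tibble::tibble(protein_id = character(), k_position = integer(),
                          psi_residue = character(), window = character())
  if (n < 4) return(empty)
  # acceptor K can sit at positions 2..n-2
  k <- 2:(n - 2)
  ok <- ch[k] == "K" & ch[k - 1] %in% psi & ch[k + 2] %in% c("D", "E")
  k <- k[ok]
  if (length(k) == 0) return(empty)
  tibble::tibble(
    protein_id = id,
    k_position = as.integer(k),
    psi_residue = ch[k - 1],
    window = vapply(k, function(i) paste(ch[(i - 1):(i + 2)], collapse = ""),
                    character(1))
  )
}

#' Scan every record of a protein FASTA for the consensus motif
#'
#' @param path Path to a (multi-record) protein FASTA file.
#' @param psi Hydrophobic alphabet; see [psi_set()].
#' @return A tibble of motif hits over all records (zero rows if none),
#'   ordered by record then position. Use `dplyr::count(hits, protein_id)`
#'   for per-record site counts.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "AVKTE", ">p2", "KKKK"), f)
#' scan_fasta(f)
#' @export
scan_fasta <- function(path, psi = psi_set()) {
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      rlang::abort(paste0("malformed FASTA: ", conditionMessage(e)),
                   class = "hcscreen_error_fasta")
    }
  )
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicate FASTA record id: ",
                        ids[duplicated(ids)][1]),
                 class = "hcscreen_error_fasta")
  }
  purrr::list_rbind(purrr::map2(
    as.character(seqs), ids,
    function(s, id) scan_consensus(toupper(s), id = id, psi = psi)
  ))
}

#' Write motif hits as TSV
#'
#' @param hits A hit table from [scan_consensus()] or [scan_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}
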
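#' Read a FASTA file into a tibble
#'
#' @param path Path to a (protein or DNA) FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(id = names(x), seq = unname(as.character(x)))
}

#' Write a tibble of sequences to FASTA
#'
#' @param records Data frame with columns `id` and `seq` (or `dna`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(records, path) {
  col <- if ("seq" %in% names(records)) "seq" else "dna"
  x <- Biostrings::BStringSet(setNames(records[[col]], records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Gapless length of an aligned row.
ungapped_length <- function(aseq) nchar(gsub("-", "", aseq))

# Split aligned rows into a character matrix (rows x columns).
msa_char_matrix <- function(msa) {
  stopifnot(length(unique(nchar(msa$aseq))) == 1)
  do.call(rbind, strsplit(msa$aseq, ""))
}
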
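#' Read a FASTA file of genome sequences
#'
#' Sequences are normalised to the internal DNA alphabet on ingest:
#' uppercased, RNA `U` mapped to `T`, and restricted to `ACGTN`. Record
#' names are taken up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `seq`. An empty file yields an
#'   empty tibble.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) > 0 && !startsWith(nonblank[[1]], ">")) {
    stop("read_fasta: malformed FASTA, first record line does not start with '>': ",
         "line ", which(nzchar(trimws(lines)))[[1]])
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(tibble::tibble(name = character(), seq = character()))
  }
  seqs <- normalize_dna(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("read_fasta: non-ACGTN characters after normalization in record(s): ",
         paste(head(names(set)[bad], 5), collapse = ", "))
  }
  tibble::tibble(
    name = sub("\\s.*$", "", names(set)),
    seq = unname(seqs)
  )
}

#' Write genome sequences to FASTA
#'
#' @param sequences A tibble with columns `name` and `seq` (as returned by
#'   [read_fasta()]).
#' @param path Output path.
#' @param as_rna Render sequences in the RNA alphabet (`T` to `U`) on output.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, as_rna = FALSE) {
  stopifnot(all(c("name", "seq") %in% names(sequences)))
  seqs <- toupper(sequences$seq)
  if (as_rna) seqs <- chartr("T", "U", seqs)
  set <- Biostrings::BStringSet(setNames(seqs, sequences$name))
  Biostrings::writeXStringSet(set, filepath = path, width = 70)
  invisible(path)
}

normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over `ACGTN`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
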
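# Independent oracles used across the suite. These deliberately take
# different code paths from the package implementation.

# bracket classes -> single IUPAC letters, for Biostrings-based matching
bracket_to_iupac <- function(pattern) {
  map <- c(ACGT = "N", AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K",
           AC = "M", CGT = "B", AGT = "D", ACT = "H", ACG = "V")
  out <- pattern
  for (m in regmatches(pattern, gregexpr("\\[[A-Z]+\\]", pattern))[[1]]) {
    key <- paste(sort(strsplit(gsub("\\[|\\]", "", m), "")[[1]]),
                 collapse = "")
    stopifnot(key %in% names(map))
    out <- sub(m, map[[key]], out, fixed = TRUE)
  }
  out
}

# all (overlapping) match offsets via Biostrings ambiguity matching;
# sequences must be plain ACGT (the N-never-matches rule is unit-tested
# separately)
oracle_scan_offsets <- function(sequence, pattern) {
  stopifnot(!grepl("[^ACGT]", sequence))
  pat <- Biostrings::DNAString(bracket_to_iupac(pattern))
  subj <- Biostrings::DNAString(sequence)
  hits <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  Biostrings::start(hits) - 1L
}

# reverse complement without Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# independent window slicer: plain substr on the chromosome string
oracle_window <- function(chrom_seq, start, end, strand, up_start, up_end) {
  if (strand == "+") {
    lo <- max(end - up_start, start)
    hi <- min(end - up_end, end)
    if (hi <= lo) return("")
    substr(chrom_seq, lo + 1, hi)
  } else {
    lo <- max(start + up_end, start)
    hi <- min(start + up_start, end)
    if (hi <= lo) return("")
    oracle_revcomp(substr(chrom_seq, lo + 1, hi))
  }
}

# random DNA string
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny classed count table builder: one gene, counts given per sample
make_counts <- function(gene, unspliced, spliced, samples) {
  out <- tibble::tibble(
    transcript_id = paste0(gene, c("_pre", "_mrna")),
    gene_id = gene,
    class = c("unspliced", "spliced")
  )
  for (i in seq_along(samples)) {
    out[[samples[i]]] <- c(unspliced[i], spliced[i])
  }
  out
}
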
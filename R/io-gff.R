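#' Read intron annotations from GFF3
#'
#' Accepts either explicit `intron` features or `exon` features from which
#' introns are inferred per transcript (gaps between consecutive exons).
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. The 3' splice site is recorded as the genomic
#' coordinate of the last intron base in transcript orientation:
#' `end - 1` on `+`, `start` on `-`.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `intron_id`, `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `three_prime_ss`, sorted by
#'   `(chrom, start)`.
#' @export
read_gff_introns <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  if (any(type == "intron")) {
    introns <- gr[type == "intron"]
    out <- granges_to_introns(introns)
  } else if (any(type == "exon")) {
    out <- infer_introns_from_exons(gr[type == "exon"])
  } else {
    stop("read_gff_introns: no 'intron' or 'exon' features in ", path)
  }
  bad_strand <- !out$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("read_gff_introns: unknown strand for record(s): ",
         paste(head(out$intron_id[bad_strand], 5), collapse = ", "))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$three_prime_ss <- ifelse(out$strand == "+", out$end - 1L, out$start)
  out
}

granges_to_introns <- function(gr) {
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    ids <- paste0("intron_", seq_along(gr))
  }
  gene <- first_attr(gr, c("gene_id", "Parent", "gene"))
  tibble::tibble(
    intron_id = as.character(ids),
    gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

first_attr <- function(gr, candidates) {
  meta <- GenomicRanges::mcols(gr)
  for (nm in candidates) {
    if (nm %in% names(meta)) {
      val <- meta[[nm]]
      if (methods::is(val, "List")) val <- vapply(val, function(v) {
        if (length(v)) as.character(v[[1]]) else NA_character_
      }, character(1))
      return(as.character(val))
    }
  }
  rep(NA_character_, length(gr))
}

infer_introns_from_exons <- function(exons) {
  parent <- first_attr(exons, c("Parent", "transcript_id"))
  gene <- first_attr(exons, c("gene_id", "gene"))
  tbl <- tibble::tibble(
    parent = parent,
    gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons) - 1L,
    end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons))
  )
  tbl |>
    dplyr::group_by(.data$parent) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      intron_start = head(.data$end, -1),
      intron_end = .data$start[-1]
    ) |>
    dplyr::filter(.data$intron_end > .data$intron_start) |>
    dplyr::group_by(.data$parent) |>
    dplyr::mutate(intron_id = paste0(.data$parent, ".i", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      intron_id = .data$intron_id,
      gene_id = dplyr::coalesce(.data$gene_id, .data$parent),
      chrom = .data$chrom,
      start = as.integer(.data$intron_start),
      end = as.integer(.data$intron_end),
      strand = .data$strand
    )
}

#' Write intron annotations to GFF3
#'
#' The inverse of [read_gff_introns()] for explicit intron features:
#' internal 0-based half-open intervals are rendered back as 1-based
#' inclusive GFF3 coordinates, so a read/write round trip reproduces the
#' input coordinates exactly.
#'
#' @param introns Intron tibble (see [read_gff_introns()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_introns <- function(introns, path) {
  stopifnot(all(c("intron_id", "gene_id", "chrom", "start", "end", "strand")
                %in% names(introns)))
  gr <- GenomicRanges::GRanges(
    seqnames = introns$chrom,
    ranges = IRanges::IRanges(start = introns$start + 1L, end = introns$end),
    strand = introns$strand
  )
  gr$type <- "intron"
  gr$ID <- introns$intron_id
  gr$gene_id <- introns$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
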
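#' Read a class-labeled transcript count table
#'
#' Reads a TSV of transcripts by samples and joins each transcript to its
#' class label (`unspliced`, `spliced`, `intronless`) and gene. Transcripts
#' absent from the class map are excluded and reported in the
#' `"unclassified"` attribute of the result.
#'
#' @param path TSV with a `transcript_id` column followed by one numeric
#'   column per sample.
#' @param class_map Tibble with columns `transcript_id`, `gene_id`, `class`.
#' @return A tibble `transcript_id`, `gene_id`, `class`, then sample
#'   columns; attribute `unclassified` lists excluded transcript ids.
#' @export
read_counts_table <- function(path, class_map) {
  stopifnot(file.exists(path),
            all(c("transcript_id", "gene_id", "class") %in% names(class_map)))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("transcript_id" %in% names(raw))
  check_classed_counts(raw)
  unclassified <- setdiff(raw$transcript_id, class_map$transcript_id)
  if (length(unclassified) > 0) {
    message(length(unclassified), " transcript(s) absent from class_map; excluded")
  }
  out <- raw |>
    dplyr::inner_join(
      dplyr::select(class_map, "transcript_id", "gene_id", "class"),
      by = "transcript_id"
    ) |>
    dplyr::relocate("transcript_id", "gene_id", "class")
  attr(out, "unclassified") <- unclassified
  out
}

check_classed_counts <- function(tbl) {
  if (anyDuplicated(tbl$transcript_id)) {
    stop("duplicate transcript_id: ",
         paste(unique(tbl$transcript_id[duplicated(tbl$transcript_id)]),
               collapse = ", "))
  }
  vals <- dplyr::select(tbl, dplyr::where(is.numeric))
  if (any(vals < 0, na.rm = TRUE)) stop("negative count/abundance values")
  invisible(tbl)
}

#' Write a count table to TSV
#'
#' @param counts Tibble as produced by [read_counts_table()] or
#'   [simulate_counts()]; the `gene_id`/`class` columns are dropped on write
#'   (they belong to the class map).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  out <- dplyr::select(counts, -dplyr::any_of(c("gene_id", "class")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an alternative-splicing event table
#'
#' Reads a VAST-tools-like TSV with one row per event and per-contrast
#' `dpsi_<contrast>` / `mv_<contrast>` column pairs; contrast names are
#' discovered from the header. dPSI values are in percent units and must
#' lie in \[-100, 100\]; MVdPSI95 (the minimum value of dPSI at the 95%
#' confidence interval) must be non-negative.
#'
#' @param path TSV with columns `event_id`, `event_type`, `gene_id` and the
#'   contrast columns.
#' @return A tibble; attribute `contrasts` holds the discovered contrast
#'   names.
#' @export
read_splicing_events <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("event_id", "event_type", "gene_id") %in% names(tbl)))
  contrasts <- sub("^dpsi_", "", grep("^dpsi_", names(tbl), value = TRUE))
  missing_mv <- setdiff(paste0("mv_", contrasts), names(tbl))
  if (length(missing_mv) > 0) {
    stop("read_splicing_events: missing columns ", paste(missing_mv, collapse = ", "))
  }
  validate_events(tbl, contrasts)
  attr(tbl, "contrasts") <- contrasts
  tbl
}

validate_events <- function(tbl, contrasts) {
  if (anyDuplicated(tbl$event_id)) stop("duplicate event_id")
  for (ct in contrasts) {
    dpsi <- tbl[[paste0("dpsi_", ct)]]
    mv <- tbl[[paste0("mv_", ct)]]
    if (any(abs(dpsi) > 100, na.rm = TRUE)) {
      stop("dPSI outside [-100, 100] in contrast ", ct)
    }
    if (any(mv < 0, na.rm = TRUE)) stop("negative MVdPSI95 in contrast ", ct)
  }
  invisible(tbl)
}

#' Write an alternative-splicing event table
#' @param events Event tibble (see [read_splicing_events()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splicing_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' Read a normalized spectral-count / protein-quant table
#'
#' Reads a TSV of proteins by conditions. Empty cells and `NA` are
#' preserved as missing values, which are distinct from zero: downstream
#' filters exclude inconsistently quantified proteins rather than imputing.
#' Every non-protein column must be assigned a role.
#'
#' @param path TSV with a `protein_id` column and one column per condition.
#' @param roles Tibble with columns `condition`, `role` (one of `"NE"`,
#'   `"APT"`, `"substrate"`, `"replicate"`) and optionally `group` for
#'   replicate columns.
#' @return A tibble with attribute `roles`.
#' @export
read_spectral_counts <- function(path, roles) {
  stopifnot(file.exists(path), all(c("condition", "role") %in% names(roles)))
  tbl <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE)
  stopifnot("protein_id" %in% names(tbl))
  if (anyDuplicated(tbl$protein_id)) stop("duplicate protein_id")
  conds <- setdiff(names(tbl), "protein_id")
  unassigned <- setdiff(conds, roles$condition)
  if (length(unassigned) > 0) {
    stop("read_spectral_counts: no role for column(s): ",
         paste(unassigned, collapse = ", "))
  }
  vals <- dplyr::select(tbl, -"protein_id")
  if (any(vals < 0, na.rm = TRUE)) stop("negative spectral counts")
  attr(tbl, "roles") <- roles
  tbl
}

#' Write a spectral-count table
#' @param table Spectral-count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_counts <- function(table, path) {
  readr::write_tsv(table, path, na = "")
  invisible(path)
}
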
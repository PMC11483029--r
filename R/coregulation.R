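#' Normalise a single-contrast event table
#'
#' Pulls one contrast out of a (possibly multi-contrast) event tibble,
#' standardising to columns `event_id`, `event_type`, `gene_id`, `dpsi`,
#' `mv`. A table already carrying `dpsi`/`mv` passes through.
#'
#' @param events Event tibble (see [read_splicing_events()]).
#' @param contrast Contrast name; required when the table holds
#'   `dpsi_<contrast>` columns.
#' @return Standardised single-contrast tibble.
#' @export
contrast_table <- function(events, contrast = NULL) {
  if (all(c("dpsi", "mv") %in% names(events))) {
    return(dplyr::select(events, dplyr::any_of(c("event_id", "event_type",
                                                 "gene_id")), "dpsi", "mv"))
  }
  if (is.null(contrast)) {
    found <- sub("^dpsi_", "", grep("^dpsi_", names(events), value = TRUE))
    if (length(found) != 1) {
      stop("contrast_table: specify `contrast`; table carries: ",
           paste(found, collapse = ", "))
    }
    contrast <- found
  }
  dcol <- paste0("dpsi_", contrast); mcol <- paste0("mv_", contrast)
  if (!all(c(dcol, mcol) %in% names(events))) {
    stop("contrast_table: unknown contrast '", contrast, "'")
  }
  events |>
    dplyr::select(dplyr::any_of(c("event_id", "event_type", "gene_id")),
                  dpsi = dplyr::all_of(dcol), mv = dplyr::all_of(mcol))
}

#' Filter events significant in one contrast
#'
#' Keeps events with `|dPSI| > dpsi_min` and `MVdPSI95 > mv_min` — both
#' strict inequalities (dPSI > |10|, MVdPSI95 > 0), so boundary values
#' are excluded.
#'
#' @param events Event tibble.
#' @param contrast Contrast name (see [contrast_table()]).
#' @param dpsi_min dPSI magnitude cutoff in percent units (default 10).
#' @param mv_min MVdPSI95 cutoff (default 0).
#' @return The significant subset, standardised to single-contrast form.
#' @export
filter_significant <- function(events, contrast = NULL, dpsi_min = 10,
                               mv_min = 0) {
  tbl <- contrast_table(events, contrast)
  dplyr::filter(tbl, abs(.data$dpsi) > dpsi_min, .data$mv > mv_min)
}

#' Co-regulated events across two knockdown contrasts
#'
#' An event is co-regulated when it changes confidently under both
#' knockdowns: `|dPSI| > dpsi_min` in *either* contrast, and
#' `MVdPSI95 > 0` in *both*. Events present in only one table are
#' excluded and counted in the attribute `unmatched`.
#'
#' @param table_a,table_b Single-contrast event tibbles (columns `dpsi`,
#'   `mv`; see [contrast_table()]).
#' @param dpsi_min dPSI magnitude cutoff (strict, default 10).
#' @return Tibble with `event_id`, `event_type`, `gene_id`, `dpsi_a`,
#'   `mv_a`, `dpsi_b`, `mv_b`; attribute `unmatched` gives per-table
#'   unmatched counts.
#' @export
coregulated_events <- function(table_a, table_b, dpsi_min = 10) {
  a <- contrast_table(table_a)
  b <- contrast_table(table_b)
  joined <- dplyr::inner_join(
    dplyr::rename(a, dpsi_a = "dpsi", mv_a = "mv"),
    dplyr::select(dplyr::rename(b, dpsi_b = "dpsi", mv_b = "mv"),
                  "event_id", "dpsi_b", "mv_b"),
    by = "event_id"
  )
  out <- joined |>
    dplyr::filter(
      (abs(.data$dpsi_a) > dpsi_min | abs(.data$dpsi_b) > dpsi_min),
      .data$mv_a > 0, .data$mv_b > 0
    )
  attr(out, "unmatched") <- c(
    only_a = length(setdiff(a$event_id, b$event_id)),
    only_b = length(setdiff(b$event_id, a$event_id))
  )
  out
}

#' Classify a co-regulated event into a dPSI quadrant
#'
#' Maps the sign pair of the two contrasts' dPSI values to the four
#' quadrants (`upA_downB` is, e.g., inclusion up upon knockdown A and
#' down upon knockdown B — the QKI-repressed/SF1-activated quadrant when
#' A = shQKI, B = shSF1). A dPSI of exactly zero is left unclassified
#' (`NA`), since the quadrant rule does not define it.
#'
#' @param dpsi_a,dpsi_b Numeric dPSI vectors (percent units).
#' @return Character vector over `upA_downB`, `upA_upB`, `downA_downB`,
#'   `downA_upB`, or `NA` where either dPSI is zero.
#' @export
classify_quadrant <- function(dpsi_a, dpsi_b) {
  dplyr::case_when(
    dpsi_a == 0 | dpsi_b == 0 ~ NA_character_,
    dpsi_a > 0 & dpsi_b < 0 ~ "upA_downB",
    dpsi_a > 0 & dpsi_b > 0 ~ "upA_upB",
    dpsi_a < 0 & dpsi_b < 0 ~ "downA_downB",
    TRUE ~ "downA_upB"
  )
}

#' Quadrant counts and fractions of co-regulated events
#'
#' @param coregulated Tibble with `dpsi_a`/`dpsi_b` (or a precomputed
#'   `quadrant` column).
#' @return Tibble with one row per quadrant (`quadrant`, `n`, `fraction`;
#'   fractions over classified events, all four quadrants always
#'   present); attribute `n_unclassified` counts zero-dPSI events.
#' @export
quadrant_counts <- function(coregulated) {
  q <- if ("quadrant" %in% names(coregulated)) {
    coregulated$quadrant
  } else {
    classify_quadrant(coregulated$dpsi_a, coregulated$dpsi_b)
  }
  levels <- c("upA_downB", "upA_upB", "downA_downB", "downA_upB")
  n <- table(factor(q, levels = levels))
  total <- sum(n)
  out <- tibble::tibble(
    quadrant = levels,
    n = as.integer(n),
    fraction = if (total > 0) as.integer(n) / total else rep(0, 4)
  )
  attr(out, "n_unclassified") <- sum(is.na(q))
  out
}

#' Compare dPSI distributions between two contrasts
#'
#' Mann-Whitney U comparison of the dPSI value distributions of one event
#' type (e.g. `AltEx` or `RI`) between two significance-filtered contrast
#' tables — the comparison behind "more inclusion upon QKI knockdown,
#' more skipping upon SF1 knockdown".
#'
#' @param table_a,table_b Single-contrast tibbles, already filtered with
#'   [filter_significant()].
#' @param event_type Event type to compare.
#' @return One-row tibble from [mann_whitney_u()] plus the two sample
#'   sizes.
#' @export
dpsi_distribution_compare <- function(table_a, table_b, event_type = "AltEx") {
  a <- contrast_table(table_a)
  b <- contrast_table(table_b)
  xa <- a$dpsi[a$event_type == event_type]
  xb <- b$dpsi[b$event_type == event_type]
  if (length(xa) == 0 || length(xb) == 0) {
    stop("dpsi_distribution_compare: no '", event_type,
         "' events in one of the tables")
  }
  res <- mann_whitney_u(xa, xb)
  dplyr::mutate(res, n_a = length(xa), n_b = length(xb),
                event_type = event_type)
}

#' Select unchanged control events
#'
#' Samples `n` control events from transcripts that are expressed
#' (`base_mean > min_base_mean`) but whose splicing is unchanged in both
#' contrasts: `|dPSI| < dpsi_max` (strict) and `MVdPSI95 = 0` exactly, in
#' both. When fewer than `n` are eligible, all are returned with a
#' warning.
#'
#' @param events Two-contrast event tibble with `dpsi_a`/`mv_a`/
#'   `dpsi_b`/`mv_b` columns (as from joining two [contrast_table()]s) and
#'   a `gene_id`.
#' @param expression Tibble with `gene_id` and `base_mean`.
#' @param n Number of controls to draw (default 1000).
#' @param dpsi_max Strict upper bound on `|dPSI|` (default 1).
#' @param min_base_mean Strict expression cutoff (default 100).
#' @param seed Optional integer seed making the draw reproducible.
#' @return The sampled subset of `events`.
#' @export
select_control_events <- function(events, expression, n = 1000, dpsi_max = 1,
                                  min_base_mean = 100, seed = NULL) {
  stopifnot(all(c("dpsi_a", "mv_a", "dpsi_b", "mv_b", "gene_id")
                %in% names(events)),
            all(c("gene_id", "base_mean") %in% names(expression)))
  eligible <- events |>
    dplyr::inner_join(dplyr::select(expression, "gene_id", "base_mean"),
                      by = "gene_id") |>
    dplyr::filter(
      .data$base_mean > min_base_mean,
      abs(.data$dpsi_a) < dpsi_max, abs(.data$dpsi_b) < dpsi_max,
      .data$mv_a == 0, .data$mv_b == 0
    )
  if (nrow(eligible) <= n) {
    if (nrow(eligible) < n) {
      warning("only ", nrow(eligible), " eligible control events (< ", n, ")")
    }
    return(eligible)
  }
  draw <- function() eligible[sample.int(nrow(eligible), n), , drop = FALSE]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
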
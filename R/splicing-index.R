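#' Percent unspliced
#'
#' The intron-retention index for an intron-containing gene:
#' `100 * unspliced / (unspliced + spliced)`. Vectorised; a sample where
#' both counts are zero has no defined value and returns `NA`.
#'
#' @param unspliced,spliced Non-negative counts.
#' @return Numeric vector in \[0, 100\] (or `NA`).
#' @examples
#' percent_unspliced(25, 75)  # 25
#' @export
percent_unspliced <- function(unspliced, spliced) {
  stopifnot(all(unspliced >= 0, na.rm = TRUE), all(spliced >= 0, na.rm = TRUE))
  total <- unspliced + spliced
  ifelse(total > 0, 100 * unspliced / total, NA_real_)
}

#' Base mean of a gene's counts
#'
#' Arithmetic mean across all samples of the gene-level count (unspliced
#' plus spliced rows summed before averaging). Used for the expression
#' cutoff `base_mean > 100`.
#'
#' @param counts Numeric vector of per-sample gene-level counts.
#' @return A single mean.
#' @export
base_mean <- function(counts) {
  stopifnot(length(counts) >= 1)
  mean(as.numeric(counts))
}

#' Differential percent-unspliced table
#'
#' The intron-centric splicing-repression analysis: for each
#' intron-containing gene, per-sample percent unspliced is computed from
#' its unspliced/spliced transcript rows, genes are filtered on expression
#' (`base_mean > min_base_mean`, on raw counts by default), and induced
#' versus control replicates are compared with a two-sided Student's
#' t-test on the percent-unspliced values. A gene is significant when
#' `p < alpha`; direction is the sign of the change.
#'
#' @param counts Class-labeled count tibble (`transcript_id`, `gene_id`,
#'   `class`, sample columns), as from [read_counts_table()] or
#'   [simulate_counts()].
#' @param control_ids,induced_ids Sample column names per condition
#'   (at least two replicates each).
#' @param alpha Significance cutoff on the raw p-value (default 0.1).
#' @param min_base_mean Expression cutoff, strict (default 100).
#' @param exclude_genes Optional gene ids to drop (e.g. genes whose intron
#'   is not removed by the spliceosome, such as HAC1-like cases).
#' @param pooled Pooled-variance t-test (default) or Welch.
#' @return An object of class `bp_splicing_change`: use [tidy()] for the
#'   per-gene table (`delta_percent_unspliced`, `base_mean`, `statistic`,
#'   `p.value`, `significant`, `direction`, per-condition means),
#'   [glance()] for the summary, `$excluded` for excluded genes and their
#'   reasons, and [autoplot()] to plot.
#' @export
splicing_change_table <- function(counts, control_ids, induced_ids,
                                  alpha = 0.1, min_base_mean = 100,
                                  exclude_genes = NULL, pooled = TRUE) {
  samples <- c(control_ids, induced_ids)
  stopifnot(length(control_ids) >= 2, length(induced_ids) >= 2,
            all(samples %in% names(counts)),
            all(c("transcript_id", "gene_id", "class") %in% names(counts)))

  per_gene <- counts |>
    dplyr::filter(.data$class %in% c("unspliced", "spliced")) |>
    tidyr::pivot_longer(dplyr::all_of(samples),
                        names_to = "sample", values_to = "count") |>
    dplyr::summarise(
      count = sum(.data$count),
      .by = c("gene_id", "class", "sample")
    ) |>
    tidyr::pivot_wider(names_from = "class", values_from = "count")

  if (!all(c("unspliced", "spliced") %in% names(per_gene))) {
    stop("splicing_change_table: counts carry no unspliced/spliced rows")
  }

  gene_tbl <- per_gene |>
    dplyr::mutate(
      pct = percent_unspliced(.data$unspliced, .data$spliced),
      total = .data$unspliced + .data$spliced
    )

  summary_tbl <- gene_tbl |>
    dplyr::summarise(
      base_mean = mean(.data$total),
      missing_row = anyNA(.data$unspliced) || anyNA(.data$spliced),
      missing_pct = anyNA(.data$pct),
      .by = "gene_id"
    )

  excluded <- dplyr::bind_rows(
    summary_tbl |>
      dplyr::filter(.data$gene_id %in% exclude_genes) |>
      dplyr::transmute(.data$gene_id, reason = "excluded_list"),
    summary_tbl |>
      dplyr::filter(!.data$gene_id %in% exclude_genes, .data$missing_row) |>
      dplyr::transmute(.data$gene_id, reason = "missing_class_row"),
    summary_tbl |>
      dplyr::filter(!.data$gene_id %in% exclude_genes, !.data$missing_row,
                    !(.data$base_mean > min_base_mean)) |>
      dplyr::transmute(.data$gene_id, reason = "low_expression"),
    summary_tbl |>
      dplyr::filter(!.data$gene_id %in% exclude_genes, !.data$missing_row,
                    .data$base_mean > min_base_mean, .data$missing_pct) |>
      dplyr::transmute(.data$gene_id, reason = "undefined_percent_unspliced")
  )

  tested_ids <- setdiff(summary_tbl$gene_id, excluded$gene_id)
  if (length(tested_ids) == 0) {
    results <- tibble::tibble(
      gene_id = character(), base_mean = numeric(),
      mean_control = numeric(), mean_induced = numeric(),
      delta_percent_unspliced = numeric(), statistic = numeric(),
      p.value = numeric(), significant = logical(), direction = character()
    )
    return(structure(
      list(results = results, excluded = excluded,
           params = list(alpha = alpha, min_base_mean = min_base_mean,
                         control_ids = control_ids, induced_ids = induced_ids,
                         pooled = pooled)),
      class = "bp_splicing_change"
    ))
  }
  results <- gene_tbl |>
    dplyr::filter(.data$gene_id %in% tested_ids) |>
    dplyr::summarise(
      base_mean = mean(.data$total),
      mean_control = mean(.data$pct[.data$sample %in% control_ids]),
      mean_induced = mean(.data$pct[.data$sample %in% induced_ids]),
      test = list(student_t_test(.data$pct[.data$sample %in% induced_ids],
                                 .data$pct[.data$sample %in% control_ids],
                                 pooled = pooled)),
      .by = "gene_id"
    ) |>
    tidyr::unnest("test") |>
    dplyr::mutate(
      delta_percent_unspliced = .data$mean_induced - .data$mean_control,
      significant = .data$p.value < alpha,
      direction = dplyr::case_when(
        .data$delta_percent_unspliced > 0 ~ "increase",
        .data$delta_percent_unspliced < 0 ~ "decrease",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select("gene_id", "base_mean", "mean_control", "mean_induced",
                  "delta_percent_unspliced", "statistic", "p.value",
                  "significant", "direction")

  structure(
    list(results = results, excluded = excluded,
         params = list(alpha = alpha, min_base_mean = min_base_mean,
                       control_ids = control_ids, induced_ids = induced_ids,
                       pooled = pooled)),
    class = "bp_splicing_change"
  )
}

#' @export
tidy.bp_splicing_change <- function(x, ...) x$results

#' @export
glance.bp_splicing_change <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_tested = nrow(r),
    n_excluded = nrow(x$excluded),
    n_significant = sum(r$significant),
    n_increase = sum(r$significant & r$direction == "increase"),
    n_decrease = sum(r$significant & r$direction == "decrease"),
    alpha = x$params$alpha,
    min_base_mean = x$params$min_base_mean
  )
}

#' @export
print.bp_splicing_change <- function(x, ...) {
  g <- glance(x)
  cat("Percent-unspliced differential analysis\n")
  cat(sprintf("  %d genes tested (%d excluded), alpha = %g, base mean > %g\n",
              g$n_tested, g$n_excluded, g$alpha, g$min_base_mean))
  cat(sprintf("  %d significant: %d increase, %d decrease\n",
              g$n_significant, g$n_increase, g$n_decrease))
  invisible(x)
}

#' @export
autoplot.bp_splicing_change <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_percent_unspliced,
                                   y = -log10(.data$p.value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(Delta * "% unspliced (induced - control)"),
                  y = expression(-log[10] ~ p), colour = "significant") +
    ggplot2::theme_minimal()
}

#' Per-class abundance change summary
#'
#' Compares induced-versus-control log2 fold changes of transcript
#' abundances (TPM-like) between transcript classes (unspliced, spliced,
#' intronless) — the analysis showing that unspliced pre-mRNAs accumulate
#' more than spliced mRNAs under splicing repression. Transcripts below
#' `min_tpm` in every sample are excluded; class distributions are
#' compared pairwise with Mann-Whitney U tests.
#'
#' @param abundances Class-labeled abundance tibble (same shape as counts).
#' @param control_ids,induced_ids Sample columns per condition.
#' @param min_tpm Abundance cutoff: kept if above it in at least one
#'   sample (strict, default 0.2).
#' @param pseudocount Pseudocount for the log2 fold change (default 0.01,
#'   small on the TPM scale).
#' @return Object of class `bp_class_abundance`: [tidy()] gives the
#'   per-transcript table, `$comparisons` the pairwise Mann-Whitney
#'   results, [glance()] per-class medians and counts.
#' @export
class_abundance_summary <- function(abundances, control_ids, induced_ids,
                                    min_tpm = 0.2, pseudocount = 0.01) {
  samples <- c(control_ids, induced_ids)
  stopifnot(all(samples %in% names(abundances)),
            all(c("transcript_id", "class") %in% names(abundances)))
  vals <- as.matrix(abundances[, samples])
  keep <- apply(vals, 1, function(v) any(v > min_tpm, na.rm = TRUE))
  n_excluded <- sum(!keep)

  per_tx <- abundances[keep, , drop = FALSE] |>
    dplyr::mutate(
      mean_control = rowMeans(dplyr::pick(dplyr::all_of(control_ids))),
      mean_induced = rowMeans(dplyr::pick(dplyr::all_of(induced_ids))),
      l2fc = log2_fold_change(.data$mean_induced, .data$mean_control,
                              pseudocount = pseudocount)
    ) |>
    dplyr::select(dplyr::any_of(c("transcript_id", "gene_id", "class")),
                  "mean_control", "mean_induced", "l2fc")

  classes <- c("unspliced", "spliced", "intronless")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    a <- per_tx$l2fc[per_tx$class == pr[1]]
    b <- per_tx$l2fc[per_tx$class == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning("class comparison ", pr[1], " vs ", pr[2],
              " skipped: fewer than 2 surviving transcripts")
      return(tibble::tibble(class_a = pr[1], class_b = pr[2],
                            n_a = length(a), n_b = length(b),
                            statistic = NA_real_, p.value = NA_real_))
    }
    res <- mann_whitney_u(a, b)
    tibble::tibble(class_a = pr[1], class_b = pr[2],
                   n_a = length(a), n_b = length(b),
                   statistic = res$statistic, p.value = res$p.value)
  })

  structure(
    list(per_transcript = per_tx, comparisons = comparisons,
         n_excluded = n_excluded,
         params = list(min_tpm = min_tpm, pseudocount = pseudocount)),
    class = "bp_class_abundance"
  )
}

#' @export
tidy.bp_class_abundance <- function(x, ...) x$per_transcript

#' @export
glance.bp_class_abundance <- function(x, ...) {
  x$per_transcript |>
    dplyr::summarise(
      n = dplyr::n(),
      median_l2fc = stats::median(.data$l2fc),
      .by = "class"
    ) |>
    dplyr::mutate(n_excluded = x$n_excluded)
}

#' @export
autoplot.bp_class_abundance <- function(object, ...) {
  ggplot2::ggplot(object$per_transcript,
                  ggplot2::aes(x = .data$class, y = .data$l2fc,
                               fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "fold change")) +
    ggplot2::theme_minimal()
}

#' Relative RNA abundance from qPCR Ct values (delta-delta-Ct)
#'
#' For each sample, `delta_ct = ct_target - ct_reference`, the abundance
#' value `2^(-delta_ct)`, and the relative abundance normalised so that
#' the mean of the reference group (e.g. the wild-type reporter) is 1.
#'
#' @param data Tibble with columns `sample`, `group`, `ct_target`,
#'   `ct_reference` (one row per sample).
#' @param reference_group Value of `group` used as the normalisation
#'   reference; must match at least one retained sample.
#' @return The input rows (samples with missing Ct dropped, with a
#'   warning) plus `delta_ct`, `ddct` and `rel_abundance` columns.
#' @examples
#' df <- tibble::tibble(sample = c("w1", "w2", "m1"),
#'                      group = c("WT", "WT", "MUT"),
#'                      ct_target = c(20, 20, 21),
#'                      ct_reference = c(20, 20, 20))
#' relative_abundance_ddct(df, "WT")
#' @export
relative_abundance_ddct <- function(data, reference_group) {
  stopifnot(all(c("sample", "group", "ct_target", "ct_reference")
                %in% names(data)))
  missing <- is.na(data$ct_target) | is.na(data$ct_reference)
  if (any(missing)) {
    warning(sum(missing), " sample(s) with missing Ct dropped")
    data <- data[!missing, , drop = FALSE]
  }
  if (!reference_group %in% data$group) {
    stop("relative_abundance_ddct: reference group '", reference_group,
         "' has no samples")
  }
  out <- data |>
    dplyr::mutate(
      delta_ct = .data$ct_target - .data$ct_reference,
      ddct = 2^(-.data$delta_ct)
    )
  ref_mean <- mean(out$ddct[out$group == reference_group])
  dplyr::mutate(out, rel_abundance = .data$ddct / ref_mean)
}
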
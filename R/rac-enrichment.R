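#' Background-corrected enrichment relative to nuclear extract
#'
#' For every protein and RNA-affinity-chromatography substrate, the
#' enrichment `(NSC_substrate - NSC_APT) / NSC_NE`, where `NSC` are
#' normalized spectral counts, `APT` is the aptamer-only background and
#' `NE` the input nuclear extract. Proteins with a missing or zero NE
#' value have no defined enrichment and are excluded (reported in the
#' `excluded` attribute). Missing substrate/APT cells propagate as `NA`
#' (missing is distinct from zero throughout).
#'
#' @param table Spectral-count tibble (`protein_id` plus condition
#'   columns), as from [read_spectral_counts()] or
#'   [simulate_spectral_counts()].
#' @param roles Roles tibble (`condition`, `role`); taken from the table's
#'   `roles` attribute when omitted. Exactly one `NE` and one `APT`
#'   condition are required.
#' @return Tibble `protein_id` plus one enrichment column per substrate;
#'   attribute `excluded` is a tibble of dropped proteins with reasons.
#' @examples
#' tbl <- tibble::tibble(protein_id = "p1", NE = 3, APT = 1, WT = 4)
#' roles <- tibble::tibble(condition = c("NE", "APT", "WT"),
#'                         role = c("NE", "APT", "substrate"))
#' background_corrected_enrichment(tbl, roles)  # WT enrichment 1
#' @export
background_corrected_enrichment <- function(table, roles = NULL) {
  roles <- roles %||% attr(table, "roles")
  if (is.null(roles)) stop("background_corrected_enrichment: roles required")
  ne_col <- roles$condition[roles$role == "NE"]
  apt_col <- roles$condition[roles$role == "APT"]
  substrates <- roles$condition[roles$role == "substrate"]
  if (length(apt_col) != 1) stop("background_corrected_enrichment: need exactly one APT column")
  if (length(ne_col) != 1) stop("background_corrected_enrichment: need exactly one NE column")
  if (length(substrates) == 0) stop("background_corrected_enrichment: no substrate columns")
  stopifnot(all(c(ne_col, apt_col, substrates) %in% names(table)))

  ne <- table[[ne_col]]
  bad <- is.na(ne) | ne == 0
  excluded <- tibble::tibble(
    protein_id = table$protein_id[bad],
    reason = ifelse(is.na(ne[bad]), "missing_NE", "zero_NE")
  )
  kept <- table[!bad, , drop = FALSE]
  out <- tibble::tibble(protein_id = kept$protein_id)
  for (s in substrates) {
    out[[s]] <- (kept[[s]] - kept[[apt_col]]) / kept[[ne_col]]
  }
  attr(out, "excluded") <- excluded
  attr(out, "substrates") <- substrates
  out
}

#' Positive/negative enrichment tallies for a protein set
#'
#' Restricted to set members (e.g. E-complex/17S U2 snRNP components) with
#' a positive background-corrected enrichment in at least one substrate,
#' counts per substrate how many members have a positive, negative, or
#' exactly zero value. Zeros are tallied as neither positive nor negative;
#' missing values are not counted. Per substrate,
#' `n_pos + n_neg + n_zero + n_missing` equals the number of included
#' members.
#'
#' @param enrichment Enrichment tibble from
#'   [background_corrected_enrichment()].
#' @param members Character vector of protein ids in the set.
#' @return Tibble with `substrate`, `n_pos`, `n_neg`, `n_zero`,
#'   `n_missing` and `n_members` (included set members).
#' @export
pos_neg_counts <- function(enrichment, members) {
  substrates <- attr(enrichment, "substrates") %||%
    setdiff(names(enrichment), "protein_id")
  sub <- enrichment[enrichment$protein_id %in% members, , drop = FALSE]
  vals <- as.matrix(sub[, substrates, drop = FALSE])
  include <- apply(vals, 1, function(v) any(v > 0, na.rm = TRUE))
  vals <- vals[include, , drop = FALSE]
  tibble::tibble(
    substrate = substrates,
    n_pos = unname(colSums(vals > 0, na.rm = TRUE)),
    n_neg = unname(colSums(vals < 0, na.rm = TRUE)),
    n_zero = unname(colSums(vals == 0, na.rm = TRUE)),
    n_missing = unname(colSums(is.na(vals))),
    n_members = nrow(vals)
  )
}

#' Row Z-scores of an enrichment matrix
#'
#' Centers and scales each protein row to mean 0 and population standard
#' deviation 1 (the heatmap convention). Constant rows become all-zero,
#' with a warning.
#'
#' @param matrix Tibble with `protein_id` and numeric columns, or a
#'   numeric matrix with rownames.
#' @return Same shape, Z-scored by row.
#' @export
row_zscore <- function(matrix) {
  is_tbl <- is.data.frame(matrix)
  if (is_tbl) {
    ids <- matrix$protein_id
    m <- as.matrix(dplyr::select(matrix, -"protein_id"))
  } else {
    ids <- rownames(matrix)
    m <- matrix
  }
  stopifnot(ncol(m) >= 2)
  z <- t(apply(m, 1, function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colnames(z) <- colnames(m)
  if (any(apply(m, 1, function(v) sd(v) == 0))) {
    warning("constant row(s) Z-scored to all zeros")
  }
  if (is_tbl) {
    dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(z))
  } else {
    rownames(z) <- ids
    z
  }
}

#' Deterministic hierarchical clustering leaf orders
#'
#' Average-linkage hierarchical clustering of rows and columns on
#' Euclidean distances, with a documented tie-break: rows are pre-sorted
#' lexicographically by id before clustering, so the leaf order is a pure
#' function of the matrix values and ids (input row order does not
#' matter).
#'
#' @param matrix Tibble with `protein_id` plus numeric columns, or a
#'   numeric matrix with rownames; no missing values.
#' @param distance Distance method for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `row_order` and `col_order` (leaf-ordered labels)
#'   and the two `hclust` objects (`row_hclust`, `col_hclust`).
#' @export
hierarchical_cluster_order <- function(matrix, distance = "euclidean",
                                       linkage = "average") {
  if (is.data.frame(matrix)) {
    m <- as.matrix(dplyr::select(matrix, -"protein_id"))
    rownames(m) <- matrix$protein_id
  } else {
    m <- matrix
  }
  if (anyNA(m)) stop("hierarchical_cluster_order: missing values in matrix")
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  hr <- hclust(dist(m, method = distance), method = linkage)
  hc <- hclust(dist(t(m), method = distance), method = linkage)
  list(
    row_order = rownames(m)[hr$order],
    col_order = colnames(m)[hc$order],
    row_hclust = hr, col_hclust = hc
  )
}

#' Differential protein abundance between two substrate groups
#'
#' DIA-style differential analysis of protein quantities between replicate
#' groups of two RAC substrates (e.g. dnDEL vs WT): proteins with any
#' missing or zero value in either group are excluded (no imputation),
#' quantities are log2-transformed, the fold change is the difference of
#' group means on the log2 scale, and the p-value comes from a two-sided
#' Student's t-test on the log2 values. Two filter levels are flagged:
#' loose (`|L2FC| > lfc_loose` and `p < alpha`, default 0.2 strict) and
#' stringent (`|L2FC| >= lfc_stringent` and `p < alpha`, default 0.7
#' non-strict), both at `P < 0.01` by default.
#'
#' @param quant Protein-quant tibble (`protein_id` plus replicate
#'   columns).
#' @param roles Tibble mapping `condition` columns to `group`s; taken
#'   from the `roles` attribute when omitted.
#' @param group_num,group_den Group labels of the numerator and
#'   denominator substrates (>= 2 replicates each).
#' @param sets Optional list with `eu2` and `rbp` character vectors of
#'   protein ids, used to categorise rows (`"E/U2"` takes precedence over
#'   `"other RBP"`, the rest are `"other"`).
#' @param alpha P-value cutoff (default 0.01).
#' @param lfc_loose,lfc_stringent Fold-change cutoffs (0.2 strict, 0.7
#'   non-strict).
#' @param adjust Use Benjamini-Hochberg adjusted p-values in the flags.
#' @return Object of class `bp_rac_differential`; [tidy()] gives the
#'   per-protein table, [glance()] the counts, `$excluded` the dropped
#'   proteins, [autoplot()] a volcano plot.
#' @export
differential_protein_abundance <- function(quant, group_num, group_den,
                                           roles = NULL, sets = NULL,
                                           alpha = 0.01, lfc_loose = 0.2,
                                           lfc_stringent = 0.7,
                                           adjust = FALSE) {
  roles <- roles %||% attr(quant, "roles")
  if (is.null(roles) || !"group" %in% names(roles)) {
    stop("differential_protein_abundance: roles with a `group` column required")
  }
  num_cols <- roles$condition[roles$group %in% group_num]
  den_cols <- roles$condition[roles$group %in% group_den]
  if (length(num_cols) < 2 || length(den_cols) < 2) {
    stop("differential_protein_abundance: need >= 2 replicates per group")
  }
  stopifnot(all(c(num_cols, den_cols) %in% names(quant)))

  vals <- as.matrix(quant[, c(num_cols, den_cols)])
  bad <- apply(vals, 1, function(v) any(is.na(v) | v <= 0))
  excluded <- tibble::tibble(
    protein_id = quant$protein_id[bad],
    reason = "missing_or_zero_value"
  )
  kept <- quant[!bad, , drop = FALSE]

  results <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    ln <- log2(as.numeric(kept[i, num_cols]))
    ld <- log2(as.numeric(kept[i, den_cols]))
    test <- student_t_test(ln, ld)
    tibble::tibble(
      protein_id = kept$protein_id[[i]],
      l2fc = mean(ln) - mean(ld),
      statistic = test$statistic,
      p.value = test$p.value
    )
  })
  if (nrow(results) == 0) {
    results <- tibble::tibble(protein_id = character(), l2fc = numeric(),
                              statistic = numeric(), p.value = numeric())
  }
  results$p.adjusted <- p.adjust(results$p.value, method = "BH")
  p_used <- if (adjust) results$p.adjusted else results$p.value
  results <- results |>
    dplyr::mutate(
      passes_loose = abs(.data$l2fc) > lfc_loose & p_used < alpha,
      passes_stringent = abs(.data$l2fc) >= lfc_stringent & p_used < alpha,
      category = categorize_protein(.data$protein_id, sets)
    )

  structure(
    list(results = results, excluded = excluded,
         params = list(group_num = group_num, group_den = group_den,
                       alpha = alpha, lfc_loose = lfc_loose,
                       lfc_stringent = lfc_stringent, adjust = adjust)),
    class = "bp_rac_differential"
  )
}

categorize_protein <- function(ids, sets) {
  if (is.null(sets)) return(rep("other", length(ids)))
  dplyr::case_when(
    ids %in% (sets$eu2 %||% character()) ~ "E/U2",
    ids %in% (sets$rbp %||% character()) ~ "other RBP",
    TRUE ~ "other"
  )
}

#' @export
tidy.bp_rac_differential <- function(x, ...) x$results

#' @export
glance.bp_rac_differential <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_tested = nrow(r),
    n_excluded = nrow(x$excluded),
    n_loose = sum(r$passes_loose),
    n_stringent = sum(r$passes_stringent),
    alpha = x$params$alpha
  )
}

#' @export
print.bp_rac_differential <- function(x, ...) {
  g <- glance(x)
  cat("RAC differential protein abundance:",
      paste(x$params$group_num, collapse = "+"), "vs",
      paste(x$params$group_den, collapse = "+"), "\n")
  cat(sprintf("  %d proteins tested (%d excluded); %d pass loose, %d stringent\n",
              g$n_tested, g$n_excluded, g$n_loose, g$n_stringent))
  invisible(x)
}

#' @export
autoplot.bp_rac_differential <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l2fc,
                                   y = -log10(.data$p.value),
                                   colour = .data$category,
                                   shape = .data$passes_stringent)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$lfc_stringent,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Tally stringent-filtered proteins by direction and category
#'
#' Counts, among proteins passing the stringent filter, how many are
#' enriched (positive log2 fold change) or depleted, split by E/U2 versus
#' other-RBP category (uncategorised proteins are not tallied).
#'
#' @param rows A `bp_rac_differential` object or its [tidy()] tibble.
#' @return Tibble with `direction`, `category` and `n` (all four
#'   combinations always present).
#' @export
classify_enriched_sets <- function(rows) {
  if (inherits(rows, "bp_rac_differential")) rows <- rows$results
  sub <- rows |>
    dplyr::filter(.data$passes_stringent, .data$category != "other",
                  .data$l2fc != 0)
  grid <- tidyr::expand_grid(direction = c("enriched", "depleted"),
                             category = c("E/U2", "other RBP"))
  counts <- sub |>
    dplyr::mutate(direction = as.character(
      ifelse(.data$l2fc > 0, "enriched", "depleted"))) |>
    dplyr::count(.data$direction, .data$category)
  grid |>
    dplyr::left_join(counts, by = c("direction", "category")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}
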
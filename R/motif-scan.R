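IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Compile a degenerate motif pattern
#'
#' Patterns are written over IUPAC one-letter codes and bracket classes,
#' e.g. `"ACTAA"`, `"TAA[CT]"`, `"ACT[ACTG]AG"`. RNA spellings (`U`) are
#' accepted and mapped to `T`. The compiled form is a list of per-position
#' allowed-base sets; an ambiguity code in the scanned *sequence* other
#' than the four bases never matches (`N` in a window cannot satisfy any
#' position).
#'
#' @param pattern Pattern string, length >= 3 positions.
#' @return A list of character vectors (one allowed-base set per position),
#'   class `"bp_motif"`, with the normalised pattern string as attribute
#'   `pattern`.
#' @export
compile_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nzchar(pattern))
  pat <- normalize_dna(pattern)
  chars <- strsplit(pat, "")[[1]]
  sets <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(close)) stop("compile_motif: unclosed '[' in ", pattern)
      inner <- chars[(i + 1):(close - 1)]
      allowed <- sort(unique(unlist(IUPAC_SETS[inner])))
      if (length(allowed) == 0 || anyNA(match(inner, names(IUPAC_SETS)))) {
        stop("compile_motif: unresolvable class [", paste(inner, collapse = ""),
             "] in ", pattern)
      }
      sets[[length(sets) + 1]] <- allowed
      i <- close + 1
    } else {
      if (!ch %in% names(IUPAC_SETS)) {
        stop("compile_motif: unknown symbol '", ch, "' in ", pattern)
      }
      sets[[length(sets) + 1]] <- IUPAC_SETS[[ch]]
      i <- i + 1
    }
  }
  if (length(sets) < 3) stop("compile_motif: pattern shorter than 3 positions")
  structure(sets, class = "bp_motif", pattern = pat)
}

#' Scan a sequence for all (overlapping) motif matches
#'
#' Reports every match of a degenerate motif, *including mutually
#' overlapping ones* — required to count tandem-embedded branchpoint
#' motifs such as the two ACTAA occurrences inside `"TACTAACTAAC"`.
#' Sequence `N`s never match.
#'
#' @param sequence A single DNA/RNA string (RNA is normalised to DNA).
#' @param pattern Pattern string or a compiled [compile_motif()] object.
#' @return A tibble with `offset` (0-based start within `sequence`) and
#'   `match` (the matched substring), ordered by offset.
#' @examples
#' scan_motif("TACTAACTAAC", "ACTAA")  # offsets 1 and 5
#' @export
scan_motif <- function(sequence, pattern) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  motif <- if (inherits(pattern, "bp_motif")) pattern else compile_motif(pattern)
  seq <- normalize_dna(sequence)
  chars <- strsplit(seq, "")[[1]]
  m <- length(motif)
  n <- length(chars)
  if (n < m) {
    return(tibble::tibble(offset = integer(), match = character()))
  }
  ok <- rep(TRUE, n - m + 1)
  for (j in seq_len(m)) {
    ok <- ok & chars[seq.int(j, j + n - m)] %in% motif[[j]]
  }
  starts <- which(ok)
  if (length(starts) == 0) {
    return(tibble::tibble(offset = integer(), match = character()))
  }
  tibble::tibble(
    offset = starts - 1L,
    match = substring(seq, starts, starts + m - 1L)
  )
}

#' Count motif occurrences (overlapping) in each sequence
#'
#' @param sequences Character vector of sequences.
#' @param pattern Pattern string or compiled motif.
#' @return Integer vector of overlap-counted match numbers.
#' @export
count_motif <- function(sequences, pattern) {
  motif <- if (inherits(pattern, "bp_motif")) pattern else compile_motif(pattern)
  vapply(sequences, function(s) nrow(scan_motif(s, motif)), integer(1),
         USE.NAMES = FALSE)
}

#' Flag sequences carrying two or more core motifs
#'
#' A window has a "dual core" when the core motif occurs at least twice,
#' counting overlaps — this covers both two independent elements and
#' tandem-embedded ones (e.g. `TACTAACTAAC` counts 2).
#'
#' @param sequences Character vector of window sequences.
#' @param core Core motif (default the QKI/branchpoint core `ACTAA`).
#' @return A tibble with `n_cores` and `dual_core` per input sequence.
#' @export
has_dual_core <- function(sequences, core = "ACTAA") {
  n <- count_motif(sequences, core)
  tibble::tibble(n_cores = n, dual_core = n >= 2L)
}

#' Extract 3' splice-site-proximal intron windows
#'
#' Cuts, for every intron, the window of intron sequence between
#' `upstream_start` and `upstream_end` nucleotides upstream of the 3'
#' splice site, in transcript orientation (reverse-complemented for `-`
#' strand introns). Distances are half-open: distance 0 is the last intron
#' base, and the window covers distances `[upstream_end, upstream_start)`,
#' so the default `(80, 0)` is exactly the last 80 intron nt and the
#' SEA-style `(63, 20)` window is 43 nt. Windows never extend past the 5'
#' end of the intron nor into the exon; introns shorter than the window are
#' truncated or skipped per `clamp`.
#'
#' @param genome Genome tibble (`name`, `seq`) as from [read_fasta()].
#' @param introns Intron tibble as from [read_gff_introns()].
#' @param upstream_start,upstream_end Window bounds as distances upstream
#'   of the 3'ss; `upstream_start > upstream_end >= 0`.
#' @param clamp `"truncate"` (default) shortens windows for short introns;
#'   `"skip"` drops those introns (reported in attribute `skipped`).
#' @return The intron tibble plus columns `window` (sequence, 5'->3' in
#'   transcript orientation), `window_len` and `clamped`.
#' @export
extract_3ss_window <- function(genome, introns, upstream_start = 80,
                               upstream_end = 0,
                               clamp = c("truncate", "skip")) {
  clamp <- match.arg(clamp)
  stopifnot(upstream_start > upstream_end, upstream_end >= 0,
            all(c("name", "seq") %in% names(genome)),
            all(c("intron_id", "chrom", "start", "end", "strand")
                %in% names(introns)))
  seqs <- setNames(genome$seq, genome$name)
  missing_chrom <- setdiff(unique(introns$chrom), names(seqs))
  if (length(missing_chrom) > 0) {
    stop("extract_3ss_window: chromosome(s) not in genome: ",
         paste(missing_chrom, collapse = ", "))
  }
  chrom_len <- nchar(seqs)[introns$chrom]
  if (any(introns$start < 0 | introns$end > chrom_len)) {
    stop("extract_3ss_window: intron outside chromosome bounds")
  }

  plus <- introns$strand == "+"
  gstart <- ifelse(plus, introns$end - upstream_start,
                   introns$start + upstream_end)
  gend <- ifelse(plus, introns$end - upstream_end,
                 introns$start + upstream_start)
  # restrict to intron sequence only
  cl_start <- pmax(gstart, introns$start)
  cl_end <- pmin(gend, introns$end)
  clamped <- (cl_start != gstart) | (cl_end != gend)
  keep <- cl_end > cl_start & !(clamp == "skip" & clamped)

  win <- character(nrow(introns))
  win[keep] <- substring(seqs[introns$chrom[keep]], cl_start[keep] + 1L,
                         cl_end[keep])
  minus_keep <- keep & !plus
  if (any(minus_keep)) {
    win[minus_keep] <- reverse_complement(win[minus_keep])
  }

  out <- introns
  out$window <- win
  out$window_len <- nchar(win)
  out$clamped <- clamped
  skipped <- introns$intron_id[!keep]
  if (clamp == "skip" && length(skipped) > 0) {
    warning(length(skipped), " intron(s) shorter than the window were skipped")
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' Call bipartite Quaking response elements (QREs)
#'
#' A QRE is a core element (default `ACTAA`) together with a half-site
#' (default `TAA[CT]`, i.e. UAAY) within `max_gap` nucleotides on either
#' side. The gap is counted between the nearest pattern edges, and the
#' half-site must not overlap the core occurrence (which also excludes
#' half-sites embedded inside a core).
#'
#' @param sequence A single window sequence.
#' @param core Core motif pattern.
#' @param halfsite Half-site pattern; `"[CT]AA[CT]"` gives the YAAY form.
#' @param max_gap Maximum nucleotides between core and half-site edges.
#' @return A tibble with one row per (core, half-site) pair: `core_offset`,
#'   `half_offset` (0-based), `gap`, and `orientation` of the half-site
#'   relative to the core (`"5prime"`/`"3prime"`).
#' @export
find_qre <- function(sequence, core = "ACTAA", halfsite = "TAA[CT]",
                     max_gap = 20) {
  core_m <- compile_motif(core)
  half_m <- compile_motif(halfsite)
  cores <- scan_motif(sequence, core_m)
  halves <- scan_motif(sequence, half_m)
  empty <- tibble::tibble(core_offset = integer(), half_offset = integer(),
                          gap = integer(), orientation = character())
  if (nrow(cores) == 0 || nrow(halves) == 0) return(empty)
  lc <- length(core_m); lh <- length(half_m)
  pairs <- tidyr::expand_grid(core_offset = cores$offset,
                              half_offset = halves$offset)
  gap <- ifelse(pairs$half_offset >= pairs$core_offset,
                pairs$half_offset - (pairs$core_offset + lc),
                pairs$core_offset - (pairs$half_offset + lh))
  orientation <- ifelse(pairs$half_offset >= pairs$core_offset,
                        "3prime", "5prime")
  keep <- gap >= 0 & gap <= max_gap
  tibble::tibble(
    core_offset = pairs$core_offset[keep],
    half_offset = pairs$half_offset[keep],
    gap = as.integer(gap[keep]),
    orientation = orientation[keep]
  )
}

#' Dual-motif overrepresentation between window sets
#'
#' Tests whether windows of regulated introns carry two-or-more core
#' motifs (dual cores, overlaps counted) more often than control windows,
#' with a 2x2 chi-squared test — the comparison behind the observation
#' that dual ACUAA elements are overrepresented among introns that
#' accumulate upon Qki5 expression.
#'
#' @param regulated_windows,control_windows Character vectors of window
#'   sequences (both non-empty).
#' @param core Core motif.
#' @param yates Apply the Yates correction in the chi-squared test.
#' @return A one-row tibble with the four cell counts
#'   (`regulated_dual`, `regulated_single`, `control_dual`,
#'   `control_single`), the dual-core proportions, `statistic` and
#'   `p.value`; the contingency table is attached as attribute `table`.
#' @export
dual_motif_enrichment <- function(regulated_windows, control_windows,
                                  core = "ACTAA", yates = FALSE) {
  stopifnot(length(regulated_windows) > 0, length(control_windows) > 0)
  reg <- has_dual_core(regulated_windows, core)$dual_core
  ctl <- has_dual_core(control_windows, core)$dual_core
  a <- sum(reg); b <- sum(!reg); c <- sum(ctl); d <- sum(!ctl)
  test <- chi_squared_2x2(a, b, c, d, yates = yates)
  out <- tibble::tibble(
    regulated_dual = a, regulated_single = b,
    control_dual = c, control_single = d,
    prop_regulated = a / (a + b), prop_control = c / (c + d),
    statistic = test$statistic, p.value = test$p.value
  )
  attr(out, "table") <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                               dimnames = list(c("regulated", "control"),
                                               c("dual", "not_dual")))
  out
}

#' Positional motif map around the 3' splice site
#'
#' A simplified positional-enrichment map in the spirit of rMAPS-style
#' plots: windows are anchored on the 3'ss (distance 0 = last intron
#' base), a sliding window of `window_len` nt moves upstream in steps of
#' `step`, and for each placement the fraction of sequences in each set
#' with at least one motif start inside it is reported, together with a
#' two-proportion chi-squared p-value of each foreground set against the
#' background. This is a validation tool for synthetic data, not a
#' reimplementation of rMAPS2's background model.
#'
#' @param fg_up,fg_down Foreground window sets (e.g. introns more/less
#'   retained); `fg_up` must be non-empty.
#' @param bg_windows Background window set.
#' @param pattern Motif pattern.
#' @param window_len Sliding-window width in nt.
#' @param step Slide step in nt.
#' @return A tibble of class `"bp_motif_map"` with `dist_lo`/`dist_hi`
#'   (distance-from-3'ss bounds of each placement), per-set hit fractions
#'   and p-values.
#' @export
positional_motif_map <- function(fg_up, fg_down, bg_windows, pattern,
                                 window_len = 50, step = 1) {
  if (length(fg_up) == 0) stop("positional_motif_map: empty foreground set")
  motif <- if (inherits(pattern, "bp_motif")) pattern else compile_motif(pattern)
  sets <- list(up = fg_up, down = fg_down, bg = bg_windows)
  # motif-start distances from the 3'ss, per sequence
  dists <- lapply(sets, function(ws) {
    lapply(ws, function(w) {
      hits <- scan_motif(w, motif)
      nchar(w) - hits$offset  # distance of the match 5' base from the 3'ss
    })
  })
  max_len <- max(vapply(unlist(sets), nchar, integer(1)), window_len)
  los <- seq.int(0, max_len - window_len, by = step)

  frac_in <- function(dlist, lo, hi) {
    if (length(dlist) == 0) return(NA_real_)
    mean(vapply(dlist, function(d) any(d > lo & d <= hi), logical(1)))
  }
  prop_p <- function(k1, n1, k0, n0) {
    if (is.na(k1) || is.na(k0)) return(NA_real_)
    tab <- c(k1, n1 - k1, k0, n0 - k0)
    if ((k1 + k0) == 0 || (n1 - k1 + n0 - k0) == 0) return(1)
    chi_squared_2x2(tab[1], tab[2], tab[3], tab[4])$p.value
  }

  rows <- purrr::map(los, function(lo) {
    hi <- lo + window_len
    f <- vapply(dists, frac_in, numeric(1), lo = lo, hi = hi)
    n <- vapply(sets, length, integer(1))
    k <- round(f * n)
    tibble::tibble(
      dist_lo = lo, dist_hi = hi,
      frac_up = f[["up"]], frac_down = f[["down"]], frac_bg = f[["bg"]],
      p_up = prop_p(k[["up"]], n[["up"]], k[["bg"]], n[["bg"]]),
      p_down = prop_p(k[["down"]], n[["down"]], k[["bg"]], n[["bg"]])
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bp_motif_map", class(out))
  out
}

#' @describeIn positional_motif_map Plot hit fractions (solid) and
#'   -log10 p-values (dashed) against distance upstream of the 3'ss.
#' @param object A `bp_motif_map` tibble.
#' @param ... Unused.
#' @export
autoplot.bp_motif_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  fr <- df |>
    tidyr::pivot_longer(dplyr::all_of(c("frac_up", "frac_down", "frac_bg")),
                        names_to = "set", names_prefix = "frac_",
                        values_to = "fraction")
  pv <- df |>
    tidyr::pivot_longer(dplyr::all_of(c("p_up", "p_down")),
                        names_to = "set", names_prefix = "p_",
                        values_to = "p")
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = fr,
      ggplot2::aes(x = .data$dist_lo, y = .data$fraction,
                   colour = .data$set)
    ) +
    ggplot2::geom_line(
      data = pv,
      ggplot2::aes(x = .data$dist_lo, y = -log10(pmax(.data$p, 1e-16)) / 10,
                   colour = .data$set),
      linetype = "dashed", na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(
      name = "fraction of windows with a hit",
      sec.axis = ggplot2::sec_axis(~ . * 10, name = "-log10 p (dashed)")
    ) +
    ggplot2::labs(x = "distance upstream of 3'ss (nt, window start)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
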
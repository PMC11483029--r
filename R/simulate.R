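#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study: a
#' two-condition (control vs induced), 3-replicate RNA-seq-like experiment
#' over a genome of intron-containing and intronless genes, where a
#' splicing-repression effect raises the unspliced fraction of affected
#' genes, and affection is conditioned on the motif content of the
#' intron's 3'ss-proximal window.
#'
#' All randomness downstream of a config is governed by its single `seed`
#' via a fixed sub-seeding scheme (annotation: `seed + 11`, counts:
#' `seed + 23`, dPSI tables: `seed + 37`, spectral counts: `seed + 53`,
#' protein quant: `seed + 71`), so each artifact is reproducible on its
#' own.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of genes.
#' @param intronless_fraction Fraction of genes without an intron.
#' @param motif_class_probs Probabilities of the intron motif classes
#'   `none` (0 cores), `single` (1 core), `dual` (>= 2 cores, including
#'   tandem-embedded); must sum to 1.
#' @param affected_probs Probability that a gene of each motif class is
#'   affected by the splicing repressor.
#' @param n_reps Replicates per condition.
#' @param baseline_shape1,baseline_shape2 Beta parameters of the baseline
#'   unspliced fraction (defaults mean 0.2, typical of mostly-efficient
#'   splicing).
#' @param effect_delta Planted increase in percent-unspliced (percentage
#'   points) for affected genes under induction.
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (`size = 1/dispersion`); values below 1e-8 fall back to Poisson.
#' @param mean_log,sd_log Log-normal parameters of per-gene-per-sample
#'   total expression.
#' @param window_len 3'ss-proximal window length carrying the planted
#'   motif content.
#' @param intron_len_range,exon_len Intron length range and flanking exon
#'   length (nt).
#' @return A validated list of class `bp_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 300, intronless_fraction = 0.3,
                       motif_class_probs = c(none = 0.50, single = 0.32,
                                             dual = 0.18),
                       affected_probs = c(none = 0.05, single = 0.30,
                                          dual = 0.80),
                       n_reps = 3, baseline_shape1 = 2, baseline_shape2 = 8,
                       effect_delta = 30, nb_dispersion = 0.05,
                       mean_log = log(400), sd_log = 0.8,
                       window_len = 80, intron_len_range = c(150, 350),
                       exon_len = 120) {
  stopifnot(
    abs(sum(motif_class_probs) - 1) < 1e-8,
    all(names(motif_class_probs) == c("none", "single", "dual")),
    all(affected_probs >= 0 & affected_probs <= 1),
    intronless_fraction >= 0, intronless_fraction <= 1,
    n_reps >= 2, nb_dispersion >= 0, effect_delta >= -100, effect_delta <= 100,
    window_len >= 20, intron_len_range[1] >= window_len + 20
  )
  structure(as.list(environment()), class = "bp_sim_config")
}

sub_seed <- function(config, offset) (config$seed %% 2000000000L) + offset

#' Simulate a genome, intron annotation and ground truth
#'
#' Generates one chromosome of genes laid out with flanking exons and (for
#' intron-containing genes) a single intron whose 3'ss-proximal window
#' carries a planted number of core (`ACTAA`) motifs according to the
#' gene's motif class: none, a single core, or a dual configuration that
#' is either two independent cores or a tandem-embedded `TACTAACTAAC`
#' (two overlapping cores). All other sequence is rejection-sampled to be
#' core-free so the planted count is exact under overlap-counting
#' semantics. Strands are random; minus-strand gene sequence is inserted
#' as its reverse complement.
#'
#' Gene-level truth drawn here: baseline unspliced fraction
#' (Beta-distributed), the affected flag (Bernoulli per motif class), and
#' the induced unspliced fraction (baseline + `effect_delta`/100 for
#' affected genes, clamped to \[0, 1\]).
#'
#' @param config A [sim_config()].
#' @return List with `genome` (tibble `name`, `seq`), `introns` (intron
#'   tibble), `class_map` (transcript-to-class map) and `truth` (per-gene
#'   tibble: motif class, planted core window offsets, fractions,
#'   affected flag).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "bp_sim_config"))
  withr::with_seed(sub_seed(config, 11L), {
    n <- config$n_genes
    gene_ids <- sprintf("gene_%04d", seq_len(n))
    intronless <- runif(n) < config$intronless_fraction
    classes <- ifelse(
      intronless, NA_character_,
      sample(names(config$motif_class_probs), n, replace = TRUE,
             prob = config$motif_class_probs)
    )
    affected <- !intronless &
      runif(n) < config$affected_probs[dplyr::coalesce(classes, "none")]
    f0 <- rbeta(n, config$baseline_shape1, config$baseline_shape2)
    f1 <- pmin(1, pmax(0, f0 + ifelse(affected, config$effect_delta / 100, 0)))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    pieces <- character(n)
    intron_rows <- vector("list", n)
    window_seq <- character(n)
    core_offsets <- vector("list", n)
    pos <- 0L  # running 0-based chromosome offset
    spacer_len <- 50L
    for (i in seq_len(n)) {
      if (intronless[i]) {
        gene_seq <- corefree_seq(2L * config$exon_len)
        core_offsets[[i]] <- integer()
      } else {
        intron_len <- sample(config$intron_len_range[1]:config$intron_len_range[2], 1)
        win <- plant_window(classes[i], config$window_len)
        window_seq[i] <- win$seq
        core_offsets[[i]] <- win$offsets
        body <- corefree_seq(intron_len - config$window_len)
        # guard the junction: re-draw body until no core spans the seam
        intron_seq <- paste0(body, win$seq)
        while (count_motif(intron_seq, "ACTAA") != win$n_cores) {
          body <- corefree_seq(intron_len - config$window_len)
          intron_seq <- paste0(body, win$seq)
        }
        exon1 <- corefree_seq(config$exon_len)
        exon2 <- corefree_seq(config$exon_len)
        gene_seq <- paste0(exon1, intron_seq, exon2)
        # genomic intron interval in transcript orientation within the gene
        istart_tx <- config$exon_len
        iend_tx <- config$exon_len + intron_len
        glen <- nchar(gene_seq)
        if (strand[i] == "+") {
          istart <- pos + istart_tx
          iend <- pos + iend_tx
        } else {
          istart <- pos + glen - iend_tx
          iend <- pos + glen - istart_tx
          gene_seq <- reverse_complement(gene_seq)
        }
        intron_rows[[i]] <- tibble::tibble(
          intron_id = paste0(gene_ids[i], ".i1"),
          gene_id = gene_ids[i],
          chrom = "chrS",
          start = istart, end = iend, strand = strand[i],
          three_prime_ss = ifelse(strand[i] == "+", iend - 1L, istart)
        )
      }
      pieces[i] <- paste0(gene_seq, corefree_seq(spacer_len))
      pos <- pos + nchar(pieces[i])
    }

    genome <- tibble::tibble(name = "chrS", seq = paste(pieces, collapse = ""))
    introns <- dplyr::bind_rows(intron_rows)
    class_map <- dplyr::bind_rows(
      tibble::tibble(
        transcript_id = paste0(gene_ids[!intronless], "_pre"),
        gene_id = gene_ids[!intronless], class = "unspliced"
      ),
      tibble::tibble(
        transcript_id = paste0(gene_ids[!intronless], "_mrna"),
        gene_id = gene_ids[!intronless], class = "spliced"
      ),
      tibble::tibble(
        transcript_id = paste0(gene_ids[intronless], "_t1"),
        gene_id = gene_ids[intronless], class = "intronless"
      )
    )
    truth <- tibble::tibble(
      gene_id = gene_ids,
      intronless = intronless,
      motif_class = classes,
      n_cores = vapply(core_offsets, length, integer(1)),
      core_offsets = core_offsets,
      window = window_seq,
      f_baseline = f0, f_induced = f1,
      affected = affected, strand = strand
    )
    list(genome = genome, introns = introns, class_map = class_map,
         truth = truth)
  })
}

# random DNA with zero ACTAA cores (rejection sampling)
corefree_seq <- function(len) {
  if (len <= 0) return("")
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (count_motif(s, "ACTAA") == 0) return(s)
  }
}

# build a window with exactly the planted number of cores for its class
plant_window <- function(class, window_len) {
  target <- switch(class, none = 0L, single = 1L, dual = 2L)
  if (is.na(target)) stop("plant_window: unknown motif class ", class)
  core <- "ACTAA"
  tandem <- "TACTAACTAAC"
  if (window_len < nchar(tandem) && target == 2L) {
    stop("plant_window: window too short to plant a dual configuration")
  }
  repeat {
    base <- corefree_seq(window_len)
    if (target == 0L) {
      return(list(seq = base, offsets = integer(), n_cores = 0L))
    }
    if (target == 1L) {
      at <- sample.int(window_len - nchar(core) + 1L, 1L) - 1L
      seq <- overwrite_at(base, core, at)
      offs <- at
    } else if (runif(1) < 0.5) { # tandem-embedded: two overlapping cores
      at <- sample.int(window_len - nchar(tandem) + 1L, 1L) - 1L
      seq <- overwrite_at(base, tandem, at)
      offs <- c(at + 1L, at + 5L)
    } else { # two independent, non-overlapping cores
      at1 <- sample.int(window_len - nchar(core) + 1L, 1L) - 1L
      ok <- setdiff(0:(window_len - nchar(core)),
                    (at1 - nchar(core)):(at1 + nchar(core)))
      if (length(ok) == 0) next
      at2 <- sample(ok, 1L)
      seq <- overwrite_at(overwrite_at(base, core, at1), core, at2)
      offs <- sort(c(at1, at2))
    }
    # overwriting can create extra cores at seams: require exactness
    hits <- scan_motif(seq, core)$offset
    if (length(hits) == target && all(offs %in% hits)) {
      return(list(seq = seq, offsets = sort(hits), n_cores = target))
    }
  }
}

overwrite_at <- function(s, insert, offset0) {
  paste0(substring(s, 1, offset0),
         insert,
         substring(s, offset0 + nchar(insert) + 1, nchar(s)))
}

#' Simulate class-labeled transcript counts
#'
#' Draws, for every gene and sample, a total expression
#' `lambda ~ log-normal(mean_log, sd_log)`; intron-containing genes then
#' get negative-binomial unspliced and spliced counts with means
#' `lambda * f` and `lambda * (1 - f)` (shared dispersion), where `f` is
#' the gene's baseline unspliced fraction, raised by `effect_delta` / 100
#' in induced samples of affected genes. Intronless genes get a single
#' NB row. Samples are named `ctrl_1..n` and `ind_1..n`; a fixed seed
#' reproduces the table exactly.
#'
#' @param annotation Result of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return Count tibble (`transcript_id`, `gene_id`, `class`, sample
#'   columns) with attribute `samples` listing the control/induced ids.
#' @export
simulate_counts <- function(annotation, config) {
  stopifnot(inherits(config, "bp_sim_config"))
  truth <- annotation$truth
  withr::with_seed(sub_seed(config, 23L), {
    ctrl <- paste0("ctrl_", seq_len(config$n_reps))
    ind <- paste0("ind_", seq_len(config$n_reps))
    samples <- c(ctrl, ind)
    rcount <- function(mu) {
      if (config$nb_dispersion < 1e-8) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    rows <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      g <- truth[i, ]
      lam <- rlnorm(length(samples), config$mean_log, config$sd_log)
      f <- ifelse(startsWith(samples, "ind"), g$f_induced, g$f_baseline)
      if (g$intronless) {
        out <- tibble::tibble(
          transcript_id = paste0(g$gene_id, "_t1"),
          gene_id = g$gene_id, class = "intronless"
        )
        out[samples] <- as.list(rcount(lam))
        out
      } else {
        u <- rcount(lam * f)
        s <- rcount(lam * (1 - f))
        out <- tibble::tibble(
          transcript_id = paste0(g$gene_id, c("_pre", "_mrna")),
          gene_id = g$gene_id, class = c("unspliced", "spliced")
        )
        for (j in seq_along(samples)) out[[samples[j]]] <- c(u[j], s[j])
        out
      }
    })
    attr(rows, "samples") <- list(control = ctrl, induced = ind)
    rows
  })
}

#' Simulate two-contrast dPSI tables with planted quadrant structure
#'
#' Emulates the co-regulation analysis input: a fraction of events are
#' "null" (`|dPSI| < 1`, `MVdPSI95 = 0` in both contrasts), the rest are
#' planted into one of the four sign quadrants with confident magnitudes
#' (`|dPSI| >= 10.5` after noise) and positive MVdPSI95 in both
#' contrasts. Default quadrant weights put 43% of co-regulated events in
#' the `upA_downB` (repressor-knockdown-up / activator-knockdown-down)
#' quadrant.
#'
#' @param n_events Number of events.
#' @param quadrant_probs Named probabilities over the four quadrants plus
#'   `null`; must sum to 1.
#' @param noise_sd Gaussian magnitude noise (percentage points).
#' @param event_type_probs Probabilities of `AltEx` vs `RI` event types.
#' @param seed Integer seed.
#' @return List with `table_a`, `table_b` (single-contrast event tibbles)
#'   and `truth` (per-event planted quadrant, `"null"` for null events).
#' @export
simulate_dpsi_tables <- function(n_events = 500,
                                 quadrant_probs = c(upA_downB = 0.1075,
                                                    upA_upB = 0.0475,
                                                    downA_downB = 0.0475,
                                                    downA_upB = 0.0475,
                                                    null = 0.75),
                                 noise_sd = 2,
                                 event_type_probs = c(AltEx = 0.8, RI = 0.2),
                                 seed = 1L) {
  stopifnot(abs(sum(quadrant_probs) - 1) < 1e-8,
            all(c("upA_downB", "upA_upB", "downA_downB", "downA_upB", "null")
                %in% names(quadrant_probs)))
  withr::with_seed(seed, {
    event_id <- sprintf("EV%05d", seq_len(n_events))
    event_type <- sample(names(event_type_probs), n_events, replace = TRUE,
                         prob = event_type_probs)
    gene_id <- sprintf("g%05d", seq_len(n_events))
    quadrant <- sample(names(quadrant_probs), n_events, replace = TRUE,
                       prob = quadrant_probs)
    is_null <- quadrant == "null"

    mag <- function(n) pmax(10.5, runif(n, 11, 60) + rnorm(n, 0, noise_sd))
    sign_a <- ifelse(startsWith(quadrant, "up"), 1, -1)
    sign_b <- ifelse(endsWith(quadrant, "upB"), 1, -1)
    dpsi_a <- ifelse(is_null, runif(n_events, -0.99, 0.99),
                     sign_a * mag(n_events))
    dpsi_b <- ifelse(is_null, runif(n_events, -0.99, 0.99),
                     sign_b * mag(n_events))
    mv_a <- ifelse(is_null, 0, pmax(0.1, abs(dpsi_a) * runif(n_events, 0.2, 0.6)))
    mv_b <- ifelse(is_null, 0, pmax(0.1, abs(dpsi_b) * runif(n_events, 0.2, 0.6)))

    base <- tibble::tibble(event_id, event_type, gene_id)
    list(
      table_a = dplyr::mutate(base, dpsi = dpsi_a, mv = mv_a),
      table_b = dplyr::mutate(base, dpsi = dpsi_b, mv = mv_b),
      truth = dplyr::mutate(base, quadrant = quadrant)
    )
  })
}

#' Simulate a normalized spectral-count table with planted enrichment
#'
#' Emulates the RAC-LC-MS/MS table: an always-positive nuclear-extract
#' (NE) column, a low-level aptamer-only (APT) background, and substrate
#' columns (`WT`, `upDEL`, `dnDEL`, `2xDEL` by default) where
#' non-enriched proteins fluctuate around the APT background (so their
#' background-corrected enrichment averages about zero) and planted
#' proteins exceed APT by `fold x NE` (up to +/-20% noise), guaranteeing
#' positive enrichment in their substrate.
#'
#' @param n_proteins Number of proteins.
#' @param enrichment_map Tibble with `protein_id`, `substrate`, `fold`;
#'   `NULL` plants 20% of proteins in random substrates with folds in
#'   \[1, 3\].
#' @param substrates Substrate column names.
#' @param seed Integer seed.
#' @return List with `table` (spectral-count tibble with a `roles`
#'   attribute) and `truth` (the enrichment map used).
#' @export
simulate_spectral_counts <- function(n_proteins = 60, enrichment_map = NULL,
                                     substrates = c("WT", "upDEL", "dnDEL",
                                                    "2xDEL"),
                                     seed = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("prot_%03d", seq_len(n_proteins))
    if (is.null(enrichment_map)) {
      n_enr <- max(1L, round(0.2 * n_proteins))
      enrichment_map <- tibble::tibble(
        protein_id = sample(ids, n_enr),
        substrate = sample(substrates, n_enr, replace = TRUE),
        fold = runif(n_enr, 1, 3)
      )
    }
    ne <- rlnorm(n_proteins, log(20), 0.6)
    apt <- ne * runif(n_proteins, 0.02, 0.10)
    tbl <- tibble::tibble(protein_id = ids, NE = ne, APT = apt)
    for (s in substrates) {
      tbl[[s]] <- apt * runif(n_proteins, 0.5, 1.5)
    }
    for (k in seq_len(nrow(enrichment_map))) {
      i <- match(enrichment_map$protein_id[k], ids)
      s <- enrichment_map$substrate[k]
      tbl[i, s] <- apt[i] + enrichment_map$fold[k] * ne[i] * runif(1, 0.8, 1.2)
    }
    roles <- tibble::tibble(
      condition = c("NE", "APT", substrates),
      role = c("NE", "APT", rep("substrate", length(substrates)))
    )
    attr(tbl, "roles") <- roles
    list(table = tbl, truth = enrichment_map)
  })
}

#' Simulate a replicate-level protein-quant table
#'
#' Emulates the DIA quantification input of
#' [differential_protein_abundance()]: two substrate groups with `n_reps`
#' replicate columns each, log-normal replicate noise, and a planted set
#' of proteins enriched `fold`-fold in the numerator group.
#'
#' @param n_proteins Number of proteins.
#' @param n_enriched Number of planted enriched proteins.
#' @param fold Planted linear fold change.
#' @param n_reps Replicates per group.
#' @param cv Approximate coefficient of variation of replicate noise.
#' @param groups Names of the numerator and denominator groups.
#' @param seed Integer seed.
#' @return List with `quant` (tibble with `roles` attribute), `roles`,
#'   and `truth` (tibble with `protein_id`, `enriched`).
#' @export
simulate_protein_quant <- function(n_proteins = 400, n_enriched = 40,
                                   fold = 4, n_reps = 3, cv = 0.1,
                                   groups = c("dnDEL", "WT"), seed = 1L) {
  stopifnot(n_enriched <= n_proteins, length(groups) == 2)
  withr::with_seed(seed, {
    ids <- sprintf("prot_%04d", seq_len(n_proteins))
    enriched <- c(rep(TRUE, n_enriched), rep(FALSE, n_proteins - n_enriched))
    base <- rlnorm(n_proteins, log(1e5), 1)
    sdlog <- sqrt(log(1 + cv^2))
    cols <- list()
    roles <- list()
    for (g in groups) {
      mult <- if (g == groups[1]) ifelse(enriched, fold, 1) else 1
      for (r in seq_len(n_reps)) {
        nm <- paste0(g, "_", r)
        cols[[nm]] <- base * mult * rlnorm(n_proteins, 0, sdlog)
        roles[[nm]] <- g
      }
    }
    quant <- dplyr::bind_cols(tibble::tibble(protein_id = ids),
                              tibble::as_tibble(cols))
    roles_tbl <- tibble::tibble(condition = names(roles),
                                role = "replicate",
                                group = unlist(roles))
    attr(quant, "roles") <- roles_tbl
    list(quant = quant, roles = roles_tbl,
         truth = tibble::tibble(protein_id = ids, enriched = enriched))
  })
}
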
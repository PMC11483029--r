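test_that("overlapping matches are all reported, N never matches", {
  # tandem-embedded branchpoint example: two ACTAA occurrences share a base
  hits <- scan_motif("TACTAACTAAC", "ACTAA")
  expect_equal(hits$offset, c(1, 5))
  expect_equal(hits$match, c("ACTAA", "ACTAA"))

  # RNA spelling normalises identically
  expect_equal(scan_motif("UACUAACUAAC", "ACUAA")$offset, c(1, 5))

  expect_equal(nrow(scan_motif("GGGGGGGG", "ACTAA")), 0)
  expect_equal(nrow(scan_motif("TACTANC", "ACTAA")), 0)
  expect_equal(nrow(scan_motif("ACT", "ACTAA")), 0)
})

test_that("degenerate patterns compile and reject bad input", {
  m <- compile_motif("TAA[CT]")
  expect_equal(scan_motif("TAACGTAATGTAAA", m)$offset, c(0, 5))
  expect_equal(scan_motif("ACTGAG", "ACT[ACTG]AG")$offset, 0)
  expect_equal(nrow(scan_motif("ACTNAG", "ACT[ACTG]AG")), 0)
  expect_error(compile_motif("AC"), "shorter")
  expect_error(compile_motif("AC[TA"), "unclosed")
  expect_error(compile_motif("ACX"), "unknown symbol")
})

test_that("scanner agrees with a Biostrings oracle on random sequences", {
  patterns <- c("ACT[ACTG]AG", "[ACTG]CT[AG][CT]", "TAA[CT]",
                "TAA[CT]T[ACTG]A[CT]", "TACTAAC", "TACTAA", "ACTAA[CT]",
                "TACTAA[CT]", "CTAAC[ACG]")
  withr::with_seed(23, {
    for (i in 1:40) {
      s <- random_dna(80)
      for (p in patterns) {
        expect_equal(scan_motif(s, p)$offset, oracle_scan_offsets(s, p),
                     info = paste(p, s))
      }
    }
  })
})

test_that("scanning the reverse complement mirrors offsets", {
  withr::with_seed(29, {
    for (i in 1:10) {
      s <- random_dna(60)
      fwd <- scan_motif(s, "ACTAA")$offset
      rev <- scan_motif(oracle_revcomp(s), "TTAGT")$offset
      expect_setequal(60 - 5 - fwd, rev)
    }
  })
})

test_that("3'ss windows match an independent slicing oracle on both strands", {
  withr::with_seed(37, {
    chrom <- random_dna(2000)
    genome <- tibble::tibble(name = "c1", seq = chrom)
    starts <- sample(100:1500, 30)
    introns <- tibble::tibble(
      intron_id = paste0("i", 1:30),
      gene_id = paste0("g", 1:30),
      chrom = "c1",
      start = starts,
      end = starts + sample(90:400, 30, replace = TRUE),
      strand = sample(c("+", "-"), 30, replace = TRUE)
    )
    for (spec in list(c(80, 0), c(63, 20))) {
      res <- extract_3ss_window(genome, introns, spec[1], spec[2])
      for (k in seq_len(nrow(res))) {
        i <- match(res$intron_id[k], introns$intron_id)
        expect_equal(
          res$window[k],
          oracle_window(chrom, introns$start[i], introns$end[i],
                        introns$strand[i], spec[1], spec[2])
        )
      }
    }
  })
})

test_that("short introns are truncated or skipped per clamp policy", {
  genome <- tibble::tibble(name = "c1", seq = random_dna(200))
  introns <- tibble::tibble(intron_id = "i1", gene_id = "g1", chrom = "c1",
                            start = 50, end = 80, strand = "+")
  res <- extract_3ss_window(genome, introns, 80, 0, clamp = "truncate")
  expect_equal(res$window_len, 30)
  expect_true(res$clamped)

  expect_warning(
    res2 <- extract_3ss_window(genome, introns, 80, 0, clamp = "skip"),
    "skipped"
  )
  expect_equal(nrow(res2), 0)
  expect_equal(attr(res2, "skipped"), "i1")

  expect_error(
    extract_3ss_window(genome, dplyr::mutate(introns, end = 500), 80, 0),
    "bounds"
  )
})

test_that("window extraction never crosses the 5' end of the intron", {
  # window region of a minus-strand intron starts at the intron start
  genome <- tibble::tibble(name = "c1", seq = random_dna(300))
  introns <- tibble::tibble(intron_id = "i1", gene_id = "g1", chrom = "c1",
                            start = 100, end = 150, strand = "-")
  res <- extract_3ss_window(genome, introns, 80, 0)
  expect_equal(res$window_len, 50)
  expect_equal(res$window,
               oracle_revcomp(substr(genome$seq, 101, 150)))
})

test_that("QRE calls pair a core with a non-overlapping nearby half-site", {
  # core then 10 nt then half-site: one call, gap 10
  s <- paste0("G", "TACTAA", strrep("G", 10), "TAAC", "GG")
  calls <- find_qre(s)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$gap, 10)
  expect_equal(calls$orientation, "3prime")

  # half-site 5' of the core works symmetrically
  s5 <- paste0("TAAT", strrep("G", 6), "ACTAAGG")
  calls5 <- find_qre(s5)
  expect_equal(nrow(calls5), 1)
  expect_equal(calls5$gap, 6)
  expect_equal(calls5$orientation, "5prime")

  # no half-site within 20 nt -> no call
  far <- paste0("TACTAA", strrep("G", 25), "TAAC")
  expect_equal(nrow(find_qre(far)), 0)

  # the half-site inside/overlapping the core itself never pairs with it
  expect_equal(nrow(find_qre("GTACTAACG")), 0)
})

test_that("dual-core detection counts overlapping occurrences", {
  res <- has_dual_core(c("TACTAACTAAC", "GACTAAG", "GGGG"))
  expect_equal(res$n_cores, c(2, 1, 0))
  expect_equal(res$dual_core, c(TRUE, FALSE, FALSE))
})

test_that("dual-motif enrichment builds the table by brute-force counting", {
  dual <- "GGTACTAACTAACGG"
  single <- "GGACTAAGGGGGGGG"
  none <- "GGGGGGGGGGGGGGG"
  reg <- c(rep(dual, 4), rep(single, 6))
  ctl <- c(rep(dual, 1), rep(none, 19))
  res <- dual_motif_enrichment(reg, ctl)
  expect_equal(res$regulated_dual, 4)
  expect_equal(res$regulated_single, 6)
  expect_equal(res$control_dual, 1)
  expect_equal(res$control_single, 19)
  ref <- chi_squared_2x2(4, 6, 1, 19)
  expect_equal(res$statistic, ref$statistic)
  expect_equal(res$p.value, ref$p.value)

  # equal proportions: no signal
  eq <- dual_motif_enrichment(c(dual, none), c(dual, none))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
})

test_that("positional map finds a planted positional signal", {
  withr::with_seed(41, {
    plant <- function() {
      s <- strsplit(random_dna(80), "")[[1]]
      repeat {
        cand <- paste(s, collapse = "")
        if (nrow(scan_motif(cand, "ACTAA")) == 0) break
        s <- strsplit(random_dna(80), "")[[1]]
      }
      # plant the core 40 nt upstream of the 3'ss
      paste0(substr(cand, 1, 35), "ACTAA", substr(cand, 41, 80))
    }
    fg <- replicate(40, plant())
    bg <- replicate(60, {
      repeat {
        cand <- random_dna(80)
        if (nrow(scan_motif(cand, "ACTAA")) == 0) break
      }
      cand
    })
    map <- positional_motif_map(fg, character(0), bg, "ACTAA",
                                window_len = 10, step = 5)
    # minimum p at a placement containing distance ~40-44
    best <- map[which.min(map$p_up), ]
    expect_true(best$dist_lo <= 44 && best$dist_hi >= 40)
    # fractions are brute-force checkable: every fg window has the core
    hit_all <- map[map$dist_lo <= 40 & map$dist_hi >= 45, ]
    expect_true(all(hit_all$frac_up == 1))
    expect_true(all(map$frac_bg == 0))

    # fg = bg gives no signal anywhere
    null_map <- positional_motif_map(bg, character(0), bg, "ACTAA",
                                     window_len = 10, step = 5)
    expect_true(all(null_map$p_up[!is.na(null_map$p_up)] == 1))
  })
})
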
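test_that("percent unspliced follows the defining formula", {
  expect_equal(percent_unspliced(25, 75), 25)
  expect_equal(percent_unspliced(0, 50), 0)
  expect_equal(percent_unspliced(10, 0), 100)
  expect_true(is.na(percent_unspliced(0, 0)))

  # scale invariance
  withr::with_seed(2, {
    u <- sample(1:100, 10); s <- sample(1:100, 10)
    for (k in c(2, 10, 0.5)) {
      expect_equal(percent_unspliced(k * u, k * s), percent_unspliced(u, s))
    }
  })
})

test_that("base mean is the plain mean over samples", {
  expect_equal(base_mean(c(50, 150, 100, 100)), 100)
  expect_false(base_mean(c(50, 150, 100, 100)) > 100)  # fails the strict cutoff
  expect_equal(base_mean(c(0, 0, 0)), 0)
  withr::with_seed(4, {
    x <- rpois(12, 200)
    expect_equal(base_mean(x), sum(x) / length(x))
  })
})

test_that("splicing change table reproduces the per-gene t test", {
  ctrl <- paste0("c", 1:3); ind <- paste0("i", 1:3)
  counts <- make_counts("g1",
                        unspliced = 2 * c(10, 12, 11, 40, 42, 41),
                        spliced = 2 * c(90, 88, 89, 60, 58, 59),
                        samples = c(ctrl, ind))
  res <- splicing_change_table(counts, ctrl, ind)
  tbl <- tidy(res)
  expect_equal(nrow(tbl), 1)
  oracle <- student_t_test(c(40, 42, 41), c(10, 12, 11))
  expect_equal(tbl$p.value, oracle$p.value)
  expect_equal(tbl$delta_percent_unspliced, 30)
  expect_equal(tbl$direction, "increase")
  expect_true(tbl$significant)
  expect_equal(glance(res)$n_increase, 1)
})

test_that("identical conditions give delta zero and p one", {
  ctrl <- paste0("c", 1:3); ind <- paste0("i", 1:3)
  counts <- make_counts("g1",
                        unspliced = 2 * rep(c(20, 25, 30), 2),
                        spliced = 2 * rep(c(80, 75, 70), 2),
                        samples = c(ctrl, ind))
  tbl <- tidy(splicing_change_table(counts, ctrl, ind))
  expect_equal(tbl$delta_percent_unspliced, 0)
  expect_equal(tbl$p.value, 1)
  expect_false(tbl$significant)
})

test_that("expression and missing-value exclusions are reported", {
  ctrl <- paste0("c", 1:2); ind <- paste0("i", 1:2)
  low <- make_counts("lowg", unspliced = rep(5, 4), spliced = rep(5, 4),
                     samples = c(ctrl, ind))
  zero <- make_counts("zerog", unspliced = c(0, 200, 200, 200),
                      spliced = c(0, 200, 200, 200),
                      samples = c(ctrl, ind))
  ok <- make_counts("okg", unspliced = 2 * c(10, 12, 60, 62),
                    spliced = 2 * c(90, 88, 40, 38), samples = c(ctrl, ind))
  res <- splicing_change_table(dplyr::bind_rows(low, zero, ok), ctrl, ind)
  expect_equal(sort(tidy(res)$gene_id), "okg")
  exc <- res$excluded
  expect_equal(exc$reason[exc$gene_id == "lowg"], "low_expression")
  expect_equal(exc$reason[exc$gene_id == "zerog"], "undefined_percent_unspliced")

  res2 <- splicing_change_table(dplyr::bind_rows(zero, ok), ctrl, ind,
                                exclude_genes = "okg")
  expect_equal(nrow(tidy(res2)), 0)
})

test_that("the analysis is a pure function of its inputs", {
  cfg <- sim_config(seed = 99, n_genes = 30)
  ann <- simulate_annotation(cfg)
  counts <- simulate_counts(ann, cfg)
  s <- attr(counts, "samples")
  r1 <- tidy(splicing_change_table(counts, s$control, s$induced))
  r2 <- tidy(splicing_change_table(counts, s$control, s$induced))
  expect_identical(r1, r2)
})

test_that("class abundance summary flags unspliced accumulation", {
  ctrl <- paste0("c", 1:3); ind <- paste0("i", 1:3)
  withr::with_seed(8, {
    n <- 40
    mk <- function(cls, mult) {
      base <- runif(n, 1, 50)
      out <- tibble::tibble(
        transcript_id = paste0(cls, "_", 1:n),
        gene_id = paste0("g", cls, "_", 1:n),
        class = cls
      )
      for (s in ctrl) out[[s]] <- base * runif(n, 0.9, 1.1)
      for (s in ind) out[[s]] <- base * mult * runif(n, 0.9, 1.1)
      out
    }
    tbl <- dplyr::bind_rows(mk("unspliced", 4), mk("spliced", 1.3),
                            mk("intronless", 0.8))
    res <- class_abundance_summary(tbl, ctrl, ind)
    cmp <- res$comparisons
    p_us <- cmp$p.value[cmp$class_a == "unspliced" & cmp$class_b == "spliced"]
    expect_lt(p_us, 0.01)
    g <- glance(res)
    expect_gt(g$median_l2fc[g$class == "unspliced"],
              g$median_l2fc[g$class == "spliced"])
  })
})

test_that("low-abundance transcripts are excluded like a brute-force filter", {
  ctrl <- c("c1", "c2"); ind <- c("i1", "i2")
  withr::with_seed(9, {
    tbl <- tibble::tibble(
      transcript_id = paste0("t", 1:50),
      gene_id = paste0("g", 1:50),
      class = sample(c("unspliced", "spliced", "intronless"), 50, TRUE),
      c1 = runif(50, 0, 0.5), c2 = runif(50, 0, 0.5),
      i1 = runif(50, 0, 0.5), i2 = runif(50, 0, 0.5)
    )
    res <- suppressWarnings(class_abundance_summary(tbl, ctrl, ind,
                                                    min_tpm = 0.2))
    vals <- as.matrix(tbl[, c(ctrl, ind)])
    expect_equal(res$n_excluded, sum(apply(vals, 1, max) <= 0.2))
    expect_equal(nrow(res$per_transcript), 50 - res$n_excluded)
  })
})

test_that("identical conditions give near-zero class medians", {
  ctrl <- c("c1", "c2"); ind <- c("i1", "i2")
  tbl <- tibble::tibble(
    transcript_id = paste0("t", 1:30),
    gene_id = paste0("g", 1:30),
    class = rep(c("unspliced", "spliced", "intronless"), 10),
    c1 = 1:30, c2 = 1:30, i1 = 1:30, i2 = 1:30
  )
  g <- glance(class_abundance_summary(tbl, ctrl, ind))
  expect_true(all(abs(g$median_l2fc) < 1e-12))
})

test_that("delta-delta-Ct normalisation fixes the reference group at one", {
  df <- tibble::tibble(
    sample = c("w1", "w2", "w3", "m1"),
    group = c("WT", "WT", "WT", "MUT"),
    ct_target = c(20, 20, 20, 21),
    ct_reference = c(20, 20, 20, 20)
  )
  res <- relative_abundance_ddct(df, "WT")
  expect_equal(res$rel_abundance[res$group == "WT"], rep(1, 3))
  # one cycle above the reference delta-Ct halves the abundance
  expect_equal(res$rel_abundance[res$group == "MUT"], 0.5)

  # multi-group spreadsheet-style oracle
  withr::with_seed(10, {
    df2 <- tibble::tibble(
      sample = paste0("s", 1:9),
      group = rep(c("WT", "A", "B"), each = 3),
      ct_target = runif(9, 18, 26),
      ct_reference = runif(9, 19, 21)
    )
    res2 <- relative_abundance_ddct(df2, "WT")
    ddct <- 2^(-(df2$ct_target - df2$ct_reference))
    expect_equal(res2$rel_abundance, ddct / mean(ddct[df2$group == "WT"]))
    expect_equal(mean(res2$rel_abundance[res2$group == "WT"]), 1)
  })

  # missing Ct drops the sample with a warning
  df$ct_target[1] <- NA
  expect_warning(res3 <- relative_abundance_ddct(df, "WT"), "missing")
  expect_equal(nrow(res3), 3)
})
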
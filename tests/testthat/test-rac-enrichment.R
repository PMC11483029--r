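spectral_fixture <- function() {
  tbl <- tibble::tibble(
    protein_id = paste0("p", 1:5),
    NE = c(3, 2, 4, 0, NA),
    APT = c(1, 2, 1, 1, 1),
    WT = c(4, 2, 0.5, 5, 5),
    dnDEL = c(2, 6, 1, 5, 5)
  )
  roles <- tibble::tibble(
    condition = c("NE", "APT", "WT", "dnDEL"),
    role = c("NE", "APT", "substrate", "substrate")
  )
  attr(tbl, "roles") <- roles
  tbl
}

test_that("background correction follows (substrate - APT) / NE", {
  enr <- background_corrected_enrichment(spectral_fixture())
  expect_equal(enr$WT[enr$protein_id == "p1"], 1)       # (4-1)/3
  expect_equal(enr$WT[enr$protein_id == "p2"], 0)       # substrate = APT
  expect_equal(enr$dnDEL[enr$protein_id == "p3"], 0)
  expect_equal(enr$WT[enr$protein_id == "p3"], -0.125)  # negative allowed
  # NE zero or missing -> excluded with reason
  exc <- attr(enr, "excluded")
  expect_setequal(exc$protein_id, c("p4", "p5"))
  expect_equal(exc$reason[exc$protein_id == "p4"], "zero_NE")
  expect_equal(exc$reason[exc$protein_id == "p5"], "missing_NE")
})

test_that("background correction is invariant to a common scale factor", {
  tbl <- spectral_fixture()
  scaled <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.numeric),
                                             ~ .x * 7))
  attr(scaled, "roles") <- attr(tbl, "roles")
  e1 <- background_corrected_enrichment(tbl)
  e2 <- background_corrected_enrichment(scaled)
  expect_equal(e1, e2, ignore_attr = TRUE)
})

test_that("sign tallies conserve the included set size", {
  enr <- tibble::tibble(
    protein_id = paste0("q", 1:5),
    WT = c(2, -1, 0, -2, 1),
    dnDEL = c(1, 2, 2, -3, 0)
  )
  attr(enr, "substrates") <- c("WT", "dnDEL")
  # q4 is negative everywhere -> excluded by the inclusion rule
  res <- pos_neg_counts(enr, paste0("q", 1:5))
  expect_equal(res$n_members, rep(4, 2))
  expect_equal(res$n_pos + res$n_neg + res$n_zero + res$n_missing,
               res$n_members)
  expect_equal(res$n_pos[res$substrate == "WT"], 2)
  expect_equal(res$n_neg[res$substrate == "WT"], 1)
  expect_equal(res$n_zero[res$substrate == "WT"], 1)

  all_pos <- dplyr::mutate(enr, WT = abs(WT) + 1, dnDEL = abs(dnDEL) + 1)
  attr(all_pos, "substrates") <- c("WT", "dnDEL")
  expect_true(all(pos_neg_counts(all_pos, enr$protein_id)$n_neg == 0))
})

test_that("row z-scores use the population standard deviation", {
  z <- row_zscore(tibble::tibble(protein_id = "p", a = 1, b = 2, c = 3))
  expect_equal(unlist(z[1, -1], use.names = FALSE),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_warning(
    zc <- row_zscore(tibble::tibble(protein_id = "p", a = 2, b = 2, c = 2)),
    "constant"
  )
  expect_equal(unlist(zc[1, -1], use.names = FALSE), c(0, 0, 0))

  withr::with_seed(17, {
    m <- matrix(rnorm(40), 8, 5,
                dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
    z <- row_zscore(m)
    expect_equal(unname(rowMeans(z)), rep(0, 8))
    expect_equal(unname(apply(z, 1, function(v) sqrt(mean(v^2)))), rep(1, 8))
  })
})

test_that("cluster leaf order is deterministic and input-order invariant", {
  m <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), nrow = 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("x", "y")))
  ord <- hierarchical_cluster_order(m)
  # the two tight pairs must be adjacent
  pos <- match(c("a", "b", "c", "d"), ord$row_order)
  expect_equal(abs(pos[1] - pos[2]), 1)
  expect_equal(abs(pos[3] - pos[4]), 1)

  perm <- m[c(3, 1, 4, 2), ]
  expect_equal(hierarchical_cluster_order(perm)$row_order, ord$row_order)

  # identical rows end adjacent
  m2 <- rbind(m, e = c(0, 0))
  ord2 <- hierarchical_cluster_order(m2)
  expect_equal(abs(match("a", ord2$row_order) - match("e", ord2$row_order)), 1)

  expect_error(hierarchical_cluster_order(rbind(m, f = c(NA, 1))), "missing")
})

test_that("differential abundance excludes inconsistently quantified proteins", {
  withr::with_seed(27, {
    sim <- simulate_protein_quant(n_proteins = 60, n_enriched = 10,
                                  fold = 4, seed = 27)
    quant <- sim$quant
    # plant missing and zero values
    quant$dnDEL_2[1] <- NA
    quant$WT_3[2] <- 0
    res <- differential_protein_abundance(quant, "dnDEL", "WT")
    expect_setequal(res$excluded$protein_id, quant$protein_id[1:2])

    vals <- as.matrix(quant[, setdiff(names(quant), "protein_id")])
    brute <- quant$protein_id[apply(vals, 1, function(v) any(is.na(v) | v <= 0))]
    expect_setequal(res$excluded$protein_id, brute)

    # planted 4-fold proteins pass the stringent filter
    tbl <- tidy(res)
    planted <- sim$truth$protein_id[sim$truth$enriched]
    planted <- setdiff(planted, res$excluded$protein_id)
    hit <- tbl$passes_stringent[match(planted, tbl$protein_id)]
    expect_gte(mean(hit), 0.9)
    expect_true(all(tbl$l2fc[match(planted, tbl$protein_id)] > 0))
  })
})

test_that("identical groups yield zero fold change and no flags", {
  quant <- tibble::tibble(
    protein_id = c("p1", "p2"),
    a_1 = c(10, 20), a_2 = c(11, 21), a_3 = c(12, 22),
    b_1 = c(10, 20), b_2 = c(11, 21), b_3 = c(12, 22)
  )
  roles <- tibble::tibble(condition = names(quant)[-1], role = "replicate",
                          group = rep(c("A", "B"), each = 3))
  res <- tidy(differential_protein_abundance(quant, "A", "B", roles = roles))
  expect_equal(res$l2fc, c(0, 0))
  expect_false(any(res$passes_loose))
  expect_false(any(res$passes_stringent))

  expect_error(
    differential_protein_abundance(quant, "A", "C", roles = roles),
    "2 replicates"
  )
})

test_that("stringent tallies split by direction and protein set", {
  rows <- tibble::tibble(
    protein_id = paste0("p", 1:8),
    l2fc = c(1, 2, -1, 0.8, -2, 1.5, -0.9, 1),
    p.value = 0.001,
    passes_loose = TRUE,
    passes_stringent = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    category = c("E/U2", "E/U2", "E/U2", "other RBP", "other RBP",
                 "E/U2", "other", "other")
  )
  res <- classify_enriched_sets(rows)
  get <- function(d, cat) res$n[res$direction == d & res$category == cat]
  expect_equal(get("enriched", "E/U2"), 2)
  expect_equal(get("depleted", "E/U2"), 1)
  expect_equal(get("enriched", "other RBP"), 1)
  expect_equal(get("depleted", "other RBP"), 1)
  # conservation over categorised stringent rows
  expect_equal(sum(res$n),
               sum(rows$passes_stringent & rows$category != "other"))

  empty <- classify_enriched_sets(rows[0, ])
  expect_equal(sum(empty$n), 0)
  expect_equal(nrow(empty), 4)
})
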
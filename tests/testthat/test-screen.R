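test_that("fold change follows its pseudocount definition", {
  expect_equal(marker_fold_change(rep(30, 4), rep(20, 5)), 31 / 21)
  expect_equal(marker_fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(marker_fold_change(rep(10, 3), rep(0, 3)), 11)
  expect_warning(fc <- marker_fold_change(numeric(0), 1:3), "empty")
  expect_true(is.na(fc))
})

test_that("Mann-Whitney exact p matches full labeling enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2 of the 20 labelings are as extreme

  set.seed(42)
  for (i in 1:60) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney(x, y, mode = "exact")$p, mw_enum_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney handles symmetry, ties and errors per contract", {
  res <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(res$U, 2)       # n1*n2/2 with midranks
  expect_equal(res$p, 1)       # tie-corrected approximation degenerates to 1
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney(c(1, 1), c(1, 2), mode = "exact"), "tie")
  # approximate and exact p agree reasonably in the exact regime
  set.seed(8)
  close <- replicate(100, {
    x <- rnorm(6); y <- rnorm(7)
    abs(mann_whitney(x, y, mode = "approx")$p -
          mann_whitney(x, y, mode = "exact")$p) < 0.05
  })
  expect_gte(mean(close), 0.95)
})

test_that("the vectorized genome-wide tests equal the scalar test", {
  set.seed(13)
  n <- 40
  vals <- rnorm(n)
  parts <- matrix(rbinom(10 * n, 1, 0.3), nrow = 10)
  parts[rowSums(parts) < 2, 1:2] <- 1L
  vp <- mutscreen:::mw_partitions(vals, parts)
  for (i in 1:10) {
    ref <- mann_whitney(vals[parts[i, ] == 1], vals[parts[i, ] == 0],
                        mode = "approx")
    expect_equal(vp$U[i], ref$U, tolerance = 1e-12)
    expect_equal(vp$p[i], ref$p, tolerance = 1e-12)
  }
  rows <- matrix(rnorm(5 * n), nrow = 5)
  carrier <- parts[1, ] == 1
  vr <- mutscreen:::mw_rows(rows, carrier)
  for (i in 1:5) {
    ref <- mann_whitney(rows[i, carrier], rows[i, !carrier], mode = "approx")
    expect_equal(vr$p[i], ref$p, tolerance = 1e-12)
  }
})

test_that("screen_marker finds a planted gene and ranks by frequency", {
  cfg <- sim_config(n_samples = 800, n_genes = 150,
                    planted_mut_genes = data.frame(gene = "driver",
                                                   frequency = 0.2,
                                                   fold_change = 2.5),
                    seed = 77)
  ch <- generate_cohort(cfg)$cohort
  res <- screen_marker(ch, "PD1")
  expect_s3_class(res, "screen_result")
  expect_true("driver" %in% res$signature$genes)
  # frequency-descending order with deterministic tie-breaks
  expect_true(all(diff(res$signature$frequency) <= 0))
  tab <- res$table
  kept <- tab[!is.na(tab$rank), ]
  expect_true(all(kept$p_value < 0.05 & kept$fold_change > 1.5))
  expect_equal(sort(kept$rank), seq_len(nrow(kept)))
  expect_true(all(tab$frequency >= 0.02))
  expect_error(screen_marker(ch, "NOT_A_GENE"), "marker")
})

test_that("raising thresholds never adds genes (monotonicity)", {
  ch <- null_cohort(300, 200, seed = 6)
  base <- screen_marker(ch, "PD1", p_max = 0.5, fc_min = 1.05, freq_min = 0.02)
  tighter_fc <- screen_marker(ch, "PD1", p_max = 0.5, fc_min = 1.2,
                              freq_min = 0.02)
  tighter_fr <- screen_marker(ch, "PD1", p_max = 0.5, fc_min = 1.05,
                              freq_min = 0.05)
  expect_true(all(tighter_fc$signature$genes %in% base$signature$genes))
  expect_true(all(tighter_fr$signature$genes %in% base$signature$genes))
})

test_that("screen respects the permutation null (joint filter is conservative)", {
  retained <- integer(5)
  p_only <- numeric(5)
  for (s in 1:5) {
    ch <- null_cohort(400, 400, seed = 900 + s)
    res <- screen_marker(ch, "PD1")
    retained[s] <- length(res$signature$genes)
    p_only[s] <- mean(res$table$p_value < 0.05)
  }
  # joint p + FC filter passes far fewer genes than p < 0.05 alone
  expect_lt(mean(retained) / 400, mean(p_only))
  expect_lt(mean(retained) / 400, 0.02)
})

test_that("signature intersection keeps common genes in max-frequency order", {
  mk <- function(genes, freq, marker) {
    structure(list(marker = marker, genes = genes, frequency = freq,
                   thresholds = list()), class = "signature_gene_list")
  }
  a <- mk(c("A", "B", "C"), c(0.5, 0.4, 0.3), "PD1")
  b <- mk(c("B", "C", "D"), c(0.2, 0.6, 0.1), "PDL1")
  j <- intersect_signatures(a, b)
  expect_identical(j$genes, c("C", "B"))       # max freq: C=0.6 > B=0.4
  expect_equal(j$frequency, c(0.6, 0.4))
  d <- mk(c("X"), 0.1, "PDL1")
  expect_warning(e <- intersect_signatures(a, d), "empty")
  expect_length(e$genes, 0)
})

test_that("pooled frequency ranking uses a strict boundary", {
  m1 <- mutation_matrix(matrix(c(rep(1L, 4), rep(0L, 96), rep(1L, 10), rep(0L, 90)),
                               nrow = 2, byrow = TRUE,
                               dimnames = list(c("gX", "gY"), paste0("s", 1:100))))
  m2 <- mutation_matrix(matrix(c(rep(1L, 2), rep(0L, 98), rep(0L, 100)),
                               nrow = 2, byrow = TRUE,
                               dimnames = list(c("gX", "gY"), paste0("t", 1:100))))
  out <- combined_frequency_rank(c("gX", "gY"), list(m1, m2))
  # gX: 6/200 = 0.03 exactly -> excluded by the strict > 0.03 rule
  expect_false("gX" %in% out$gene)
  # gY: 10/200 = 0.05 -> retained
  expect_equal(out$pooled_frequency[out$gene == "gY"], 0.05)
  # a gene absent from one cohort contributes zero there
  m3 <- mutation_matrix(matrix(rep(1L, 10), 1,
                               dimnames = list("gZ", paste0("u", 1:10))))
  expect_message(expect_message(
    out2 <- combined_frequency_rank(c("gY", "gZ"), list(m1, m3)),
    "absent"), "absent")
  expect_equal(out2$pooled_frequency[out2$gene == "gZ"], 10 / 110)
})
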
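test_that("co-occurrence cross-tabulates and matches the enumeration oracle", {
  mm <- make_mut_pair(10, 5, 5, 10)
  cr <- cooccurrence(mm, "gA", "gB")
  expect_equal(unname(cr$counts), c(10, 5, 5, 10))
  expect_equal(cr$odds_ratio, 4)
  expect_equal(cr$p, fisher_enum_p(10, 5, 5, 10), tolerance = 1e-12)
  # cross-check against the standard implementation's p-value
  expect_equal(cr$p, fisher.test(matrix(c(10, 5, 5, 10), 2))$p.value,
               tolerance = 1e-9)
  expect_error(cooccurrence(mm, "gA", "nope"), "not in mutation matrix")
})

test_that("zero discordant cells give an infinite odds ratio with finite p", {
  mm <- make_mut_pair(6, 0, 3, 11)
  cr <- cooccurrence(mm, "gA", "gB")
  expect_identical(cr$odds_ratio, Inf)
  expect_true(is.finite(cr$p) && cr$p > 0 && cr$p <= 1)
  expect_equal(cr$p, fisher_enum_p(6, 0, 3, 11), tolerance = 1e-12)
})

test_that("independent planted mutations give OR near 1", {
  ok <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_samples = 10000, n_genes = 2,
                      planted_mut_genes = data.frame(
                        gene = c("mA", "mB"), frequency = c(0.2, 0.25),
                        fold_change = c(1, 1)),
                      seed = 300 + s)
    ch <- generate_cohort(cfg)$cohort
    cr <- cooccurrence(ch$mutations, "mA", "mB")
    if (cr$odds_ratio > 0.8 && cr$odds_ratio < 1.25 && cr$p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("partial Spearman matches the rank-residualization oracle", {
  set.seed(33)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    pc <- partial_spearman(x, y, z)
    expect_equal(pc$rho, partial_spearman_oracle(x, y, z), tolerance = 1e-10)
  }
  # symmetry in x and y
  x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
  expect_equal(partial_spearman(x, y, z)$rho, partial_spearman(y, x, z)$rho,
               tolerance = 1e-12)
})

test_that("partial Spearman removes a purity-style confounder", {
  # x and y only correlate through z: plain Spearman large, partial ~ 0
  hits <- 0L
  set.seed(44)
  for (i in 1:10) {
    z <- rnorm(2000)
    x <- z + rnorm(2000)
    y <- z + rnorm(2000)
    plain <- cor(x, y, method = "spearman")
    pc <- partial_spearman(x, y, z)
    if (plain > 0.3 && abs(pc$rho) < 0.08) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("partial Spearman contract: self-correlation, degenerate z, small n", {
  set.seed(3)
  x <- rnorm(100); z <- rnorm(100)
  expect_gt(partial_spearman(x, x, z)$rho, 0.999)
  expect_error(partial_spearman(1:4, 4:1, c(1, 2, 1, 2)), "n >= 5")
  expect_message(pc <- partial_spearman(x, x + rnorm(100), rep(1, 100)),
                 "zero variance")
  expect_equal(pc$covariate, "none")
  expect_error(partial_spearman(x, rnorm(100), x), "perfectly")
})

test_that("infiltration profile needs purity and known cell types", {
  cfg <- sim_config(n_samples = 100, n_genes = 5, seed = 2)
  ch <- generate_cohort(cfg)$cohort
  prof <- infiltration_profile(ch, "PD1", c("b_cell", "dendritic"))
  expect_equal(prof$covariate, c("purity", "b_cell", "dendritic"))
  expect_true(all(abs(prof$rho) <= 1))
  expect_error(infiltration_profile(ch, "PD1", "platelet"), "available")
  ch$clinical$purity <- NULL
  expect_error(infiltration_profile(ch, "PD1"), "purity")
})

test_that("unlinked genes show no infiltration correlation", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_samples = 600, n_genes = 3, seed = 810 + s)
    ch <- generate_cohort(cfg)$cohort
    prof <- infiltration_profile(ch, "gene0001", "dendritic")
    if (abs(prof$rho[prof$covariate == "dendritic"]) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("log2 Pearson correlation is exact on scaled genes and matches cor.test", {
  x <- c(2, 9, 30, 120, 500, 64)
  r <- pearson_log2(2 * x + 1, x)   # log2(2x+2) = 1 + log2(x+1): affine
  expect_equal(r$r, 1, tolerance = 1e-12)
  set.seed(12)
  a <- rlnorm(50, 4, 1); b <- rlnorm(50, 4, 1)
  res <- pearson_log2(a, b)
  ref <- cor.test(log2(a + 1), log2(b + 1))
  expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_log2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("independent genes decorrelate on the log2 scale", {
  hits <- 0L
  set.seed(26)
  for (i in 1:10) {
    a <- rlnorm(2000, 5, 1); b <- rlnorm(2000, 5, 1)
    if (abs(pearson_log2(a, b)$r) < 0.07) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("FDR gene selection applies BH per endpoint plus HR and expression filters", {
  cand <- data.frame(gene = c("g1", "g2", "g3"),
                     p_rfs = c(0.001, 0.002, 0.2),
                     p_os = c(0.001, 0.002, 0.2),
                     hr_rfs = c(0.5, 0.6, 0.4), hr_os = c(0.5, 0.6, 0.4),
                     median_expr = c(10, 9, 8))
  out <- select_genes_fdr(cand, q = 0.01, expr_min_quantile = 0)
  expect_setequal(out$gene, c("g1", "g2"))   # BH-adjusted 0.003 < 0.01; 0.2 fails

  # unfavorable HR excluded when required, kept otherwise
  cand$hr_os[1] <- 1.4
  out2 <- select_genes_fdr(cand, q = 0.01, expr_min_quantile = 0)
  expect_identical(out2$gene, "g2")
  out3 <- select_genes_fdr(cand, q = 0.01, expr_min_quantile = 0,
                           require_favorable = FALSE)
  expect_setequal(out3$gene, c("g1", "g2"))

  # vacuous thresholds keep every favorable gene
  cand$hr_os[1] <- 0.5
  out4 <- select_genes_fdr(cand, q = 1.0000001, expr_min_quantile = 0)
  expect_setequal(out4$gene, c("g1", "g2", "g3"))

  # expression-quantile filter knocks out the lowest-expressed gene
  out5 <- select_genes_fdr(cand, q = 1.0000001, expr_min_quantile = 0.5)
  expect_false("g3" %in% out5$gene)

  # all p = 1 selects nothing
  cand2 <- transform(cand, p_rfs = 1, p_os = 1)
  expect_equal(nrow(select_genes_fdr(cand2, q = 0.01)), 0)
})

test_that("BH selection grows monotonically with q", {
  set.seed(50)
  cand <- data.frame(gene = sprintf("g%02d", 1:40),
                     p_rfs = runif(40)^2, p_os = runif(40)^2,
                     hr_rfs = runif(40, 0.3, 0.9), hr_os = runif(40, 0.3, 0.9),
                     median_expr = rlnorm(40, 5))
  sel1 <- select_genes_fdr(cand, q = 0.05, expr_min_quantile = 0)
  sel2 <- select_genes_fdr(cand, q = 0.25, expr_min_quantile = 0)
  expect_true(all(sel1$gene %in% sel2$gene))
})
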
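test_that("identical configs give bit-identical cohorts; different seeds differ", {
  c1 <- null_cohort(100, 50, seed = 1)
  c2 <- null_cohort(100, 50, seed = 1)
  expect_identical(unclass(c1$expression), unclass(c2$expression))
  expect_identical(unclass(c1$mutations), unclass(c2$mutations))
  expect_identical(c1$clinical, c2$clinical)
  c3 <- null_cohort(100, 50, seed = 2)
  expect_false(identical(unclass(c1$expression), unclass(c3$expression)))
})

test_that("planted marker fold change is realized at large n", {
  cfg <- sim_config(n_samples = 10000, n_genes = 5,
                    planted_mut_genes = data.frame(gene = "mutG",
                                                   frequency = 0.5,
                                                   fold_change = 2),
                    seed = 31)
  g <- generate_cohort(cfg)
  carr <- unclass(g$cohort$mutations)["mutG", ] == 1L
  pd1 <- unclass(g$cohort$expression)["PD1", ]
  ratio <- mean(pd1[carr]) / mean(pd1[!carr])
  expect_lt(abs(ratio / 2 - 1), 0.02)
  # realized frequency within a binomial 99.9% CI of the target
  expect_lt(abs(mean(carr) - 0.5), 3.3 * sqrt(0.25 / 10000))
})

test_that("a null config plants no marker effect", {
  ch <- null_cohort(2000, 6, seed = 5)
  # split on each background gene's mutations: FC distribution centered at 1
  fcs <- vapply(sprintf("gene%04d", 1:6), function(g) {
    carr <- unclass(ch$mutations)[g, ] == 1L
    marker_fold_change(unclass(ch$expression)["PD1", carr],
                       unclass(ch$expression)["PD1", !carr])
  }, numeric(1))
  expect_lt(abs(mean(fcs) - 1), 0.1)
})

test_that("co-occurrence pairs hit the target odds ratio", {
  cfg <- sim_config(n_samples = 10000, n_genes = 2,
                    planted_mut_genes = data.frame(
                      gene = c("mA", "mB"), frequency = c(0.2, 0.3),
                      fold_change = c(1, 1)),
                    cooccurrence_pairs = data.frame(
                      geneA = "mA", geneB = "mB", odds_ratio = 4),
                    seed = 17)
  ch <- generate_cohort(cfg)$cohort
  cr <- cooccurrence(ch$mutations, "mA", "mB")
  expect_gt(cr$odds_ratio, 3.4)
  expect_lt(cr$odds_ratio, 4.7)
})

test_that("the planted 2x2 joint distribution is exact for known cases", {
  # independence
  expect_equal(unname(solve_p11 <- mutscreen:::solve_joint_p11(0.2, 0.3, 1)["p11"]),
               0.06, tolerance = 1e-12)
  # a solved cell set must reproduce the requested odds ratio
  for (theta in c(0.25, 2, 4, 10)) {
    cells <- mutscreen:::solve_joint_p11(0.2, 0.3, theta)
    expect_equal(sum(cells), 1, tolerance = 1e-9)
    expect_equal(unname((cells["p11"] * cells["p00"]) /
                          (cells["p10"] * cells["p01"])), theta,
                 tolerance = 1e-6)
    expect_equal(unname(cells["p11"] + cells["p10"]), 0.2, tolerance = 1e-9)
    expect_equal(unname(cells["p11"] + cells["p01"]), 0.3, tolerance = 1e-9)
  }
  # extreme odds ratios stay inside the Frechet bounds
  hi <- mutscreen:::solve_joint_p11(0.2, 0.3, 1e6)
  expect_equal(unname(hi["p11"]), 0.2, tolerance = 1e-3)
  lo <- mutscreen:::solve_joint_p11(0.9, 0.9, 1e-6)
  expect_gte(unname(lo["p11"]), 0.8)
  expect_true(all(lo >= 0))
})

test_that("survival generator carries the planted proportional-hazards signal", {
  # Cox on the true standardized score must recover beta within 3 SE
  sig <- data.frame(gene = c("sg1", "sg2", "sg3"), beta = c(-0.5, 0.3, 0.2))
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_samples = 300, n_genes = 3, signature_genes = sig,
                      baseline_hazard = 0.02, censoring_rate = 0.3,
                      seed = 100 + seed)
    g <- generate_cohort(cfg)
    lp <- g$truth$linear_predictor
    cl <- g$cohort$clinical
    fit <- survival::coxph(survival::Surv(cl$time, cl$event) ~ lp)
    ok <- abs(unname(coef(fit)) - 1) <= 3 * sqrt(unname(vcov(fit)[1, 1]))
    hits <- hits + ok
  }
  expect_gte(hits, 19L)
})

test_that("censoring rate calibration lands near its target", {
  cfg <- sim_config(n_samples = 5000, n_genes = 2, censoring_rate = 0.3,
                    baseline_hazard = 0.02, seed = 9)
  ch <- generate_cohort(cfg)$cohort
  expect_lt(abs(mean(ch$clinical$event == 0) - 0.3), 0.03)
})

test_that("infiltration links produce purity-confounded abundances", {
  cfg <- sim_config(n_samples = 1500, n_genes = 2,
                    infiltration_links = data.frame(gene = "CXCL9",
                                                    cell_type = "dendritic",
                                                    rho = 0.6),
                    seed = 23)
  ch <- generate_cohort(cfg)$cohort
  # abundances decrease with purity (they live in the non-malignant fraction)
  expect_lt(cor(ch$clinical$abund_dendritic, ch$clinical$purity,
                method = "spearman"), -0.2)
  prof <- infiltration_profile(ch, "CXCL9", "dendritic")
  expect_gt(prof$rho[prof$covariate == "dendritic"], 0.5)
  expect_lt(prof$rho[prof$covariate == "dendritic"], 0.7)
})

test_that("sim_config validates and round-trips through YAML", {
  expect_error(sim_config(n_samples = 2), "n_samples")
  expect_error(sim_config(planted_mut_genes = data.frame(
    gene = "g", frequency = 1.2, fold_change = 2)))
  expect_error(sim_config(
    planted_mut_genes = data.frame(gene = "g", frequency = 0.1, fold_change = 2),
    cooccurrence_pairs = data.frame(geneA = "g", geneB = "other", odds_ratio = 2)),
    "planted")

  cfg <- sim_config(n_samples = 50, n_genes = 10,
                    planted_mut_genes = data.frame(gene = "m1", frequency = 0.2,
                                                   fold_change = 1.8),
                    seed = 4)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$planted_mut_genes, cfg$planted_mut_genes)
  c1 <- generate_cohort(cfg)$cohort
  c2 <- generate_cohort(cfg2)$cohort
  expect_identical(unclass(c1$expression), unclass(c2$expression))
})
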
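#' Configuration for the synthetic cohort generator
#'
#' Declares the planted structure of a simulated multi-omic cohort:
#' immune-marker genes whose expression shifts in mutation carriers,
#' mutation genes with set population frequencies, co-occurrent mutation
#' pairs with a target odds ratio, a proportional-hazards survival signal
#' carried by a signature gene set, and purity-confounded immune-infiltrate
#' abundances.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of background genes (named `gene0001`, ...); any
#'   marker / planted / signature / infiltration gene named outside this
#'   universe is appended to it.
#' @param marker_genes Genes whose expression is multiplied by a planted
#'   gene's `fold_change` in that gene's mutation carriers.
#' @param planted_mut_genes Data frame with columns `gene`, `frequency`
#'   (in (0,1)) and `fold_change` (> 0); or NULL for none.
#' @param cooccurrence_pairs Data frame with columns `geneA`, `geneB`,
#'   `odds_ratio`; both genes must be planted so their marginal
#'   frequencies are defined. Or NULL.
#' @param signature_genes Data frame with columns `gene` and `beta`
#'   (log-hazard coefficient per SD of that gene's expression); or NULL.
#' @param baseline_hazard Exponential baseline hazard rate (> 0), per time
#'   unit (nominally months).
#' @param censoring_rate Target fraction of samples censored, in \[0, 1).
#' @param purity_shape1,purity_shape2 Beta parameters for tumor purity.
#' @param infiltration_links Data frame with columns `gene`, `cell_type`,
#'   `rho` (target purity-corrected Spearman correlation); or NULL.
#' @param cell_types Immune cell types emitted as `abund_*` clinical
#'   columns (linked or not).
#' @param background_mut_freq Bernoulli mutation frequency for
#'   non-planted genes (passenger-level background so every gene is
#'   testable in the screen).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of background
#'   expression.
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 200L,
                       n_genes = 500L,
                       marker_genes = c("PD1", "PDL1"),
                       planted_mut_genes = NULL,
                       cooccurrence_pairs = NULL,
                       signature_genes = NULL,
                       baseline_hazard = 0.01,
                       censoring_rate = 0.3,
                       purity_shape1 = 5,
                       purity_shape2 = 2,
                       infiltration_links = NULL,
                       cell_types = c("b_cell", "cd4_t", "cd8_t",
                                      "macrophage", "neutrophil", "dendritic"),
                       background_mut_freq = 0.05,
                       expr_meanlog = 5,
                       expr_sdlog = 1,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              marker_genes = as.character(marker_genes),
              planted_mut_genes = planted_mut_genes,
              cooccurrence_pairs = cooccurrence_pairs,
              signature_genes = signature_genes,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
              infiltration_links = infiltration_links,
              cell_types = as.character(cell_types),
              background_mut_freq = background_mut_freq,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 4L, cfg$n_genes >= 1L,
            cfg$baseline_hazard > 0,
            cfg$censoring_rate >= 0, cfg$censoring_rate < 1,
            cfg$purity_shape1 > 0, cfg$purity_shape2 > 0,
            cfg$background_mut_freq >= 0, cfg$background_mut_freq < 1)
  p <- cfg$planted_mut_genes
  if (!is.null(p)) {
    p <- as.data.frame(p)
    stopifnot(all(c("gene", "frequency", "fold_change") %in% names(p)),
              all(p$frequency > 0 & p$frequency < 1), all(p$fold_change > 0),
              !anyDuplicated(p$gene))
    cfg$planted_mut_genes <- p
  }
  cp <- cfg$cooccurrence_pairs
  if (!is.null(cp)) {
    cp <- as.data.frame(cp)
    stopifnot(all(c("geneA", "geneB", "odds_ratio") %in% names(cp)),
              all(cp$odds_ratio > 0))
    planted <- if (is.null(p)) character(0) else p$gene
    if (!all(c(cp$geneA, cp$geneB) %in% planted)) {
      stop("co-occurrence pair genes must appear in planted_mut_genes ",
           "(their marginal frequencies come from there)")
    }
    cfg$cooccurrence_pairs <- cp
  }
  sg <- cfg$signature_genes
  if (!is.null(sg)) {
    sg <- as.data.frame(sg)
    stopifnot(all(c("gene", "beta") %in% names(sg)), !anyDuplicated(sg$gene))
    cfg$signature_genes <- sg
  }
  il <- cfg$infiltration_links
  if (!is.null(il)) {
    il <- as.data.frame(il)
    stopifnot(all(c("gene", "cell_type", "rho") %in% names(il)),
              all(abs(il$rho) < 1),
              all(il$cell_type %in% cfg$cell_types))
    cfg$infiltration_links <- il
  }
  structure(cfg, class = "sim_config")
}

#' Read / write a sim_config as YAML
#'
#' @param cfg A [sim_config()].
#' @param path File path.
#' @return `read_sim_config` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("planted_mut_genes", "cooccurrence_pairs", "signature_genes",
              "infiltration_links")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as.data.frame(raw[[f]])
  }
  do.call(sim_config, raw)
}

# deterministic per-component sub-seed so adding one component does not
# perturb the draws of another
sub_seed <- function(seed, component) {
  offs <- c(expression = 11, mutation = 23, survival = 37,
            purity = 53, infiltration = 71)
  as.integer((as.numeric(seed) * 1009 + offs[[component]]) %% 2147483647)
}

# joint cell probability p11 for a 2x2 with marginals fa, fb and odds
# ratio theta (Plackett construction: solve the quadratic, take the root
# inside the Frechet bounds)
solve_joint_p11 <- function(fa, fb, theta) {
  lo <- max(0, fa + fb - 1)
  hi <- min(fa, fb)
  if (abs(theta - 1) < 1e-12) {
    p11 <- fa * fb
  } else {
    a <- theta - 1
    b <- -((theta - 1) * (fa + fb) + 1)
    cc <- theta * fa * fb
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no 2x2 distribution has these marginals and odds ratio")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
    if (length(inside) == 0L) {
      stop("no 2x2 distribution has these marginals and odds ratio")
    }
    p11 <- min(max(inside[1L], lo), hi)
  }
  cells <- c(p11 = p11, p10 = fa - p11, p01 = fb - p11, p00 = 1 - fa - fb + p11)
  if (any(cells < -1e-9)) stop("no 2x2 distribution has these marginals and odds ratio")
  pmax(cells, 0)
}

#' Generate a synthetic cohort with planted structure
#'
#' Background expression is log-normal. For each planted mutation gene,
#' carrier status is Bernoulli at its frequency (co-occurrent pairs are
#' drawn jointly from the 2x2 distribution matching their marginals and
#' odds ratio) and the marker genes' expression is multiplied by the
#' planted fold change in carriers. Survival times are exponential with
#' hazard `baseline_hazard * exp(sum(beta_k * z_k))` over standardized
#' signature-gene expression, censored by an independent exponential
#' calibrated to the requested censoring rate. Purity is Beta; abundance
#' columns are `(1 - purity) * exp(latent)` where the latent carries the
#' requested rank correlation with the linked gene's expression.
#'
#' @param config A [sim_config()].
#' @return List with elements `cohort` (a [cohort()]) and `truth` (the
#'   realized latent values and planted lists, for recovery checks).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  n <- cfg$n_samples
  samples <- sprintf("s%04d", seq_len(n))
  planted <- if (is.null(cfg$planted_mut_genes)) {
    data.frame(gene = character(0), frequency = numeric(0),
               fold_change = numeric(0))
  } else cfg$planted_mut_genes
  sig <- if (is.null(cfg$signature_genes)) {
    data.frame(gene = character(0), beta = numeric(0))
  } else cfg$signature_genes
  links <- if (is.null(cfg$infiltration_links)) {
    data.frame(gene = character(0), cell_type = character(0), rho = numeric(0))
  } else cfg$infiltration_links

  genes <- unique(c(cfg$marker_genes, planted$gene, sig$gene, links$gene,
                    sprintf("gene%04d", seq_len(cfg$n_genes))))

  # --- expression ------------------------------------------------------
  set.seed(sub_seed(cfg$seed, "expression"))
  expr <- matrix(stats::rlnorm(length(genes) * n, cfg$expr_meanlog,
                               cfg$expr_sdlog),
                 nrow = length(genes), dimnames = list(genes, samples))

  # --- mutations -------------------------------------------------------
  set.seed(sub_seed(cfg$seed, "mutation"))
  status <- matrix(stats::rbinom(length(genes) * n, 1L,
                                 cfg$background_mut_freq),
                   nrow = length(genes), dimnames = list(genes, samples))
  paired <- character(0)
  if (!is.null(cfg$cooccurrence_pairs)) {
    for (i in seq_len(nrow(cfg$cooccurrence_pairs))) {
      pr <- cfg$cooccurrence_pairs[i, ]
      fa <- planted$frequency[planted$gene == pr$geneA]
      fb <- planted$frequency[planted$gene == pr$geneB]
      cells <- solve_joint_p11(fa, fb, pr$odds_ratio)
      draw <- sample.int(4L, n, replace = TRUE, prob = cells)
      status[pr$geneA, ] <- as.integer(draw %in% c(1L, 2L))
      status[pr$geneB, ] <- as.integer(draw %in% c(1L, 3L))
      paired <- c(paired, pr$geneA, pr$geneB)
    }
  }
  for (i in seq_len(nrow(planted))) {
    g <- planted$gene[i]
    if (!(g %in% paired)) {
      status[g, ] <- stats::rbinom(n, 1L, planted$frequency[i])
    }
    carriers <- status[g, ] == 1L
    expr[cfg$marker_genes, carriers] <-
      expr[cfg$marker_genes, carriers, drop = FALSE] * planted$fold_change[i]
  }

  # --- survival --------------------------------------------------------
  set.seed(sub_seed(cfg$seed, "survival"))
  lp <- rep(0, n)
  if (nrow(sig)) {
    z <- scale(t(expr[sig$gene, , drop = FALSE]))
    lp <- as.vector(z %*% sig$beta)
  }
  hazard <- cfg$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = hazard)
  if (cfg$censoring_rate > 0) {
    # independent exponential censoring; rate solves
    # mean_i c/(c + h_i) = censoring_rate
    f <- function(cr) mean(cr / (cr + hazard)) - cfg$censoring_rate
    cr <- stats::uniroot(f, lower = 1e-10, upper = 1e6,
                         extendInt = "upX")$root
    t_cens <- stats::rexp(n, rate = cr)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # --- purity and infiltration ----------------------------------------
  set.seed(sub_seed(cfg$seed, "purity"))
  purity <- stats::rbeta(n, cfg$purity_shape1, cfg$purity_shape2)
  set.seed(sub_seed(cfg$seed, "infiltration"))
  abund <- matrix(NA_real_, nrow = n, ncol = length(cfg$cell_types),
                  dimnames = list(samples, paste0("abund_", cfg$cell_types)))
  for (ct in cfg$cell_types) {
    lk <- links[links$cell_type == ct, , drop = FALSE]
    noise <- stats::rnorm(n)
    if (nrow(lk)) {
      # Pearson weight on the normal scale chosen by the inverse
      # grade-correlation map so the *Spearman* correlation hits rho
      rp <- 2 * sin(pi * lk$rho[1L] / 6)
      e_n <- as.vector(scale(log(expr[lk$gene[1L], ])))
      latent <- rp * e_n + sqrt(1 - rp^2) * noise
    } else {
      latent <- noise
    }
    abund[, paste0("abund_", ct)] <- (1 - purity) * exp(latent)
  }

  clin <- data.frame(sample_id = samples, time = time, event = event,
                     subtype = "basal", purity = purity,
                     as.data.frame(abund), check.names = FALSE)
  ch <- cohort(expression_matrix(expr), mutation_matrix(status),
               clinical_table(clin))
  truth <- list(planted_mut_genes = planted,
                cooccurrence_pairs = cfg$cooccurrence_pairs,
                signature_genes = sig,
                infiltration_links = links,
                linear_predictor = stats::setNames(lp, samples),
                true_hazard = stats::setNames(hazard, samples),
                config = cfg)
  list(cohort = ch, truth = truth)
}

#' Null cohort: no planted structure
#'
#' [generate_cohort()] with all planted lists empty; used by the
#' type-I-error and calibration suites.
#'
#' @param n_samples,n_genes,seed As in [sim_config()].
#' @param ... Further arguments passed to [sim_config()].
#' @return A [cohort()].
#' @export
null_cohort <- function(n_samples, n_genes, seed, ...) {
  stopifnot(n_samples >= 4L)
  cfg <- sim_config(n_samples = n_samples, n_genes = n_genes, seed = seed,
                    planted_mut_genes = NULL, cooccurrence_pairs = NULL,
                    signature_genes = NULL, infiltration_links = NULL, ...)
  generate_cohort(cfg)$cohort
}
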
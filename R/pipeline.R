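#' Configuration for the full discovery pipeline
#'
#' Bundles the inputs (either the three table paths or a [sim_config()]
#' for synthetic mode) and every stage threshold. Serializable to/from
#' YAML; each run echoes the resolved configuration so it can be
#' reproduced exactly.
#'
#' @param expression_path,mutation_path,clinical_path Input TSVs (ignored
#'   in synthetic mode). `mutation_path` may be a MAF (set `maf = TRUE`)
#'   or a binary matrix TSV.
#' @param maf Whether `mutation_path` is MAF-format.
#' @param sim A [sim_config()] for synthetic mode, or NULL.
#' @param markers Marker genes screened (default PD1 and PDL1).
#' @param p_max,fc_min,freq_min,top_k Screen thresholds
#'   ([screen_marker()]).
#' @param pooled_freq_min Strict pooled-frequency threshold
#'   ([combined_frequency_rank()]).
#' @param n_top Mutation-signature size ([derive_mutation_signature()]).
#' @param fdr_q FDR threshold ([select_genes_fdr()]).
#' @param signature_genes Optional gene set for the joint score stage
#'   (default: the [joint_gene_score()] seven-gene set when present).
#' @param time_col,event_col Endpoint columns in the clinical table.
#' @param subtype Optional subtype filter for the survival stage.
#' @param outdir Output directory (NULL: nothing written).
#' @param seed Seed for synthetic mode.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression_path = NULL, mutation_path = NULL,
                            clinical_path = NULL, maf = FALSE, sim = NULL,
                            markers = c("PD1", "PDL1"),
                            p_max = 0.05, fc_min = 1.5, freq_min = 0.02,
                            top_k = 50L, pooled_freq_min = 0.03,
                            n_top = 100L, fdr_q = 0.01,
                            signature_genes = NULL,
                            time_col = "time", event_col = "event",
                            subtype = NULL, outdir = NULL, seed = 1L) {
  cfg <- list(expression_path = expression_path,
              mutation_path = mutation_path, clinical_path = clinical_path,
              maf = isTRUE(maf), sim = sim, markers = as.character(markers),
              p_max = p_max, fc_min = fc_min, freq_min = freq_min,
              top_k = as.integer(top_k), pooled_freq_min = pooled_freq_min,
              n_top = as.integer(n_top), fdr_q = fdr_q,
              signature_genes = signature_genes,
              time_col = time_col, event_col = event_col,
              subtype = subtype, outdir = outdir, seed = as.integer(seed))
  if (is.null(cfg$sim)) {
    miss <- c(expression = is.null(cfg$expression_path),
              mutation = is.null(cfg$mutation_path),
              clinical = is.null(cfg$clinical_path))
    if (any(miss)) {
      stop("non-synthetic mode needs input path(s): ",
           paste(names(miss)[miss], collapse = ", "))
    }
  } else if (!inherits(cfg$sim, "sim_config")) {
    stop("`sim` must be a sim_config")
  }
  if (length(cfg$markers) < 1L) stop("at least one marker gene required")
  structure(cfg, class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Stages, in order: load or simulate the cohort and harmonize it; screen
#' each marker for mutation-associated expression ([screen_marker()]);
#' intersect the marker signatures ([intersect_signatures()]); re-rank the
#' joint list by pooled mutation frequency ([combined_frequency_rank()]);
#' test co-occurrence of the top joint gene pair ([cooccurrence()]); for
#' each retained joint gene, derive its transcriptomic signature, score
#' samples and compare survival ([derive_mutation_signature()],
#' [score_samples()], [survival_by_signature()]); finally score the
#' configured joint gene set and compare survival. When `outdir` is set,
#' per-stage CSVs, a JSON summary and a run log are written.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with per-stage results and the
#'   resolved config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- load ------------------------------------------------------------
  ch <- stage("load", {
    if (!is.null(config$sim)) {
      note("synthetic mode, seed %d", config$sim$seed)
      generate_cohort(config$sim)$cohort
    } else {
      expr <- read_expression(config$expression_path)
      mut <- if (config$maf) read_maf(config$mutation_path)
             else read_mutation_matrix(config$mutation_path)
      clin <- read_clinical(config$clinical_path)
      harmonize(expr, mut, clin)
    }
  })
  note("cohort: %d samples, %d genes", ncol(ch$expression), nrow(ch$expression))

  # --- screen per marker ----------------------------------------------
  screens <- stage("screen", {
    res <- lapply(config$markers, function(mk) {
      screen_marker(ch, mk, p_max = config$p_max, fc_min = config$fc_min,
                    freq_min = config$freq_min, top_k = config$top_k)
    })
    names(res) <- config$markers
    res
  })
  for (mk in config$markers) {
    note("screen %s: %d genes retained", mk, length(screens[[mk]]$signature$genes))
  }

  # --- intersect + pooled frequency ------------------------------------
  joint <- stage("intersect", {
    if (length(screens) >= 2L) {
      Reduce(intersect_signatures, lapply(screens, `[[`, "signature"))
    } else {
      screens[[1L]]$signature
    }
  })
  note("joint signature: %d genes", length(joint$genes))
  pooled <- stage("pooled_frequency", {
    if (length(joint$genes)) {
      combined_frequency_rank(joint, ch$mutations,
                              freq_min = config$pooled_freq_min)
    } else {
      data.frame(gene = character(0), n_mut = integer(0),
                 n_total = integer(0), pooled_frequency = numeric(0))
    }
  })
  note("pooled frequency > %g: %d genes", config$pooled_freq_min, nrow(pooled))

  # --- co-occurrence of the top pair -----------------------------------
  cooc <- stage("cooccurrence", {
    if (nrow(pooled) >= 2L) {
      cooccurrence(ch$mutations, pooled$gene[1L], pooled$gene[2L])
    } else NULL
  })
  if (!is.null(cooc)) {
    note("co-occurrence %s/%s: OR %.3g, p %.3g", cooc$geneA, cooc$geneB,
         cooc$odds_ratio, cooc$p)
  }

  # --- per-mutation signatures and survival ----------------------------
  mut_signatures <- list()
  mut_survival <- list()
  for (g in pooled$gene) {
    sig <- stage(paste0("signature:", g), {
      derive_mutation_signature(ch, g, n_top = config$n_top,
                                p_max = config$p_max)
    })
    mut_signatures[[g]] <- sig
    if (nrow(sig$table) == 0L) next
    fit <- stage(paste0("survival:", g), {
      sc <- score_samples(ch$expression, sig)
      survival_by_signature(ch, sc, time_col = config$time_col,
                            event_col = config$event_col,
                            subtype = config$subtype)
    })
    mut_survival[[g]] <- fit
    note("%s signature survival: HR %.3g (%.3g-%.3g), p %.3g", g,
         fit$hr, fit$ci[1], fit$ci[2], fit$p_wald)
  }

  # --- joint gene-set score --------------------------------------------
  joint_genes <- config$signature_genes
  if (is.null(joint_genes)) {
    default7 <- eval(formals(joint_gene_score)$genes)
    joint_genes <- default7[default7 %in% rownames(ch$expression)]
  }
  joint_fit <- NULL
  joint_scores <- NULL
  if (length(joint_genes)) {
    joint_scores <- stage("joint_score", score_samples(ch$expression, joint_genes))
    joint_fit <- stage("joint_survival", {
      survival_by_signature(ch, joint_scores, time_col = config$time_col,
                            event_col = config$event_col,
                            subtype = config$subtype)
    })
    note("joint %d-gene score survival: HR %.3g (%.3g-%.3g), p %.3g",
         length(joint_genes), joint_fit$hr, joint_fit$ci[1], joint_fit$ci[2],
         joint_fit$p_wald)
  }

  report <- structure(
    list(config = config,
         screens = screens, joint_signature = joint, pooled = pooled,
         cooccurrence = cooc, mutation_signatures = mut_signatures,
         mutation_survival = mut_survival,
         joint_genes = joint_genes, joint_scores = joint_scores,
         joint_survival = joint_fit, log = log_lines),
    class = "pipeline_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

# machine-readable summary of a pipeline report (stable field order)
report_summary <- function(report) {
  fit_json <- function(f) {
    if (is.null(f)) return(NULL)
    list(hr = f$hr, ci_lower = f$ci[1], ci_upper = f$ci[2],
         p_wald = f$p_wald, p_logrank = f$p_logrank,
         n = as.list(stats::setNames(f$n, f$group_levels)))
  }
  list(seed = report$config$seed,
       markers = report$config$markers,
       thresholds = list(p_max = report$config$p_max,
                         fc_min = report$config$fc_min,
                         freq_min = report$config$freq_min,
                         top_k = report$config$top_k,
                         pooled_freq_min = report$config$pooled_freq_min,
                         n_top = report$config$n_top,
                         fdr_q = report$config$fdr_q),
       marker_signatures = lapply(report$screens,
                                  function(s) s$signature$genes),
       joint_signature = report$joint_signature$genes,
       pooled_frequency = report$pooled,
       cooccurrence = if (is.null(report$cooccurrence)) NULL else {
         x <- report$cooccurrence
         list(geneA = x$geneA, geneB = x$geneB,
              counts = as.list(x$counts),
              odds_ratio = if (is.finite(x$odds_ratio)) x$odds_ratio else "Inf",
              p = x$p)
       },
       mutation_signatures = lapply(report$mutation_signatures,
                                    function(s) s$table$gene),
       mutation_survival = lapply(report$mutation_survival, fit_json),
       joint_genes = report$joint_genes,
       joint_survival = fit_json(report$joint_survival))
}

#' Write a pipeline report to disk
#'
#' Per-stage CSVs, a JSON summary (`summary.json`), the resolved config
#' (`config.yaml`) and a timestamped log (`run.log`).
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (mk in names(report$screens)) {
    utils::write.csv(report$screens[[mk]]$table,
                     file.path(outdir, paste0("screen_", mk, ".csv")),
                     row.names = FALSE)
  }
  writeLines(report$joint_signature$genes,
             file.path(outdir, "joint_signature.txt"))
  utils::write.csv(report$pooled, file.path(outdir, "pooled_frequency.csv"),
                   row.names = FALSE)
  for (g in names(report$mutation_signatures)) {
    utils::write.csv(report$mutation_signatures[[g]]$table,
                     file.path(outdir, paste0("signature_", g, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$joint_scores)) {
    utils::write.csv(report$joint_scores,
                     file.path(outdir, "joint_scores.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report_summary(report),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  cfg <- report$config
  cfg$sim <- if (is.null(cfg$sim)) NULL else unclass(cfg$sim)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  writeLines(report$log, file.path(outdir, "run.log"))
  invisible(outdir)
}
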
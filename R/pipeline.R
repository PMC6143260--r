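#' Run configuration for the end-to-end pipeline
#'
#' A single configuration object governs every stage; all randomisation
#' flows from the one root seed through named per-stage substreams, so a run
#' is reproducible from (config, seed) alone.
#'
#' @param panel `amplicon_panel` or path to a panel YAML.
#' @param design [cohort_design()].
#' @param truth group-level methylation truth table.
#' @param qtruth [qpcr_truth()].
#' @param sim [simulation_config()].
#' @param min_coverage quantifier coverage floor.
#' @param min_len read length filter floor (bp).
#' @param min_accuracy 3' quality-trim accuracy floor.
#' @param alpha_amplicon,alpha_cpg letter-display significance levels.
#' @param seed root seed.
#' @param outdir optional output directory; when given, stage outputs are
#'   written as TSV/FASTA/FASTQ.
#' @return list of class `run_config`.
#' @export
run_config <- function(panel = lates_panel(), design = cohort_design(),
                       truth = lates_methylation_truth(),
                       qtruth = qpcr_truth(), sim = NULL,
                       min_coverage = 100L, min_len = 100L,
                       min_accuracy = 0.95, alpha_amplicon = 0.01,
                       alpha_cpg = 0.05, seed = 1L, outdir = NULL) {
  if (is.character(panel)) panel <- read_panel(panel)
  sim <- sim %||% simulation_config(seed = seed)
  sim$seed <- as.integer(seed)
  structure(list(panel = panel, design = design, truth = truth,
                 qtruth = qtruth, sim = sim, min_coverage = min_coverage,
                 min_len = min_len, min_accuracy = min_accuracy,
                 alpha_amplicon = alpha_amplicon, alpha_cpg = alpha_cpg,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the full simulate-quantify-analyse pipeline
#'
#' Executes, in order: read simulation, methylation quantification, group
#' statistics (amplicon summaries, per-CpG Kruskal-Wallis with letters, sex
#' differences, density-methylation fit), qPCR simulation + relative
#' expression, and the splice-assay stage (toy isoforms, virtual PCR,
#' sex-typing). Deterministic given the config seed. A stage failure halts
#' the run with a stage-named error; files written by earlier stages are
#' retained.
#'
#' @param config [run_config()].
#' @param stages subset of stages to run (in canonical order).
#' @return list of class `bsas_report` with elements `simulation`,
#'   `methylation`, `summary`, `cpg_tests`, `sex_differences`, `density_fit`,
#'   `ct_table`, `expression`, `splice`, `seed`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "quantify", "stats",
                                    "expression", "splice")) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if ("simulate" %in% stages) {
    report$simulation <- stage("simulate", simulate_cohort(
      config$panel, config$design, config$truth, config$sim,
      dir = if (!is.null(config$outdir)) file.path(config$outdir, "fastq")))
  }
  if ("quantify" %in% stages) {
    if (is.null(report$simulation)) stop("stage 'quantify' needs the simulate stage")
    report$methylation <- stage("quantify", quantify_cohort(
      report$simulation, min_coverage = config$min_coverage,
      min_accuracy = config$min_accuracy, min_len = config$min_len))
    if (!is.null(config$outdir)) {
      write_meth_matrix(report$methylation, config$outdir)
      write_reference(report$simulation$panel, config$outdir)
    }
  }
  if ("stats" %in% stages) {
    mm <- report$methylation
    if (is.null(mm)) stop("stage 'stats' needs the quantify stage")
    report$summary <- stage("stats", amplicon_group_summary(
      mm, config$design, alpha = config$alpha_amplicon))
    report$cpg_tests <- stage("stats", kruskal_wallis_per_cpg(
      mm, config$design, alpha = config$alpha_cpg))
    report$sex_differences <- stage("stats", sex_difference_table(mm, config$design))
    dens <- vapply(report$simulation$panel$amplicons, cpg_density, 0)
    ov <- report$summary$overall
    report$density_fit <- tryCatch(
      density_methylation_fit(dens[ov$amplicon_id], ov$overall_mean),
      error = function(e) NULL)
    if (!is.null(config$outdir)) {
      write.table(report$summary$groups,
                  file.path(config$outdir, "group_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(report$cpg_tests,
                  file.path(config$outdir, "cpg_tests.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(report$sex_differences,
                  file.path(config$outdir, "sex_differences.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if ("expression" %in% stages) {
    report$ct_table <- stage("expression", simulate_qpcr(
      config$qtruth, config$design, seed = config$seed))
    report$expression <- stage("expression", lapply(
      setNames(config$qtruth$genes$gene, config$qtruth$genes$gene),
      function(g) {
        rel <- relative_expression(report$ct_table, g,
                                   config$qtruth$reference_gene)
        compare_groups(rel, config$design)
      }))
    if (!is.null(config$outdir)) {
      write.table(report$ct_table, file.path(config$outdir, "ct_table.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if ("splice" %in% stages) {
    report$splice <- stage("splice", local({
      iso <- simulate_isoforms(seed = config$seed)
      typing <- lapply(c(testis = "testis", ovary = "ovary"), function(tissue) {
        d_tx <- iso$dmrt1$isoforms[[tissue]]$sequence
        c_tx <- iso$cyp19a1$isoforms[[tissue]]$sequence
        m <- virtual_pcr(iso$assays$male, d_tx)
        f <- virtual_pcr(iso$assays$female, c_tx)
        list(male_assay = m, female_assay = f,
             call = sex_type(m$products, f$products))
      })
      list(isoforms = iso, typing = typing)
    }))
    if (!is.null(config$outdir)) {
      write_isoforms(report$splice$isoforms, file.path(config$outdir, "isoforms"))
    }
  }
  structure(report, class = "bsas_report")
}

#' @export
print.bsas_report <- function(x, ...) {
  cat("BSAS pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$methylation)) print(x$methylation)
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$sex_differences)) {
    cat("Sex differences (testes - ovaries, %):\n")
    print(x$sex_differences, row.names = FALSE)
  }
  if (!is.null(x$expression)) for (e in x$expression) print(e)
  if (!is.null(x$splice)) {
    cat("Sex-typing calls:",
        paste(names(x$splice$typing), "=",
              vapply(x$splice$typing, `[[`, "", "call"), collapse = ", "), "\n")
  }
  invisible(x)
}
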
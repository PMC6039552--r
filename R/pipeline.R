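default_params <- list(min_coverage = 5L, q_max = 0.05, window = 200L,
                       step = 40L, upstream = 100L, downstream = 100L,
                       min_sites = 5L, min_diff = 0.1)

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  writeLines(msg, con)
  message(msg)
}

resolve_counts <- function(x) {
  if (is.character(x)) read_counts_table(x) else x
}

#' Run the full methylome analysis pipeline
#'
#' Orchestrates conversion-rate estimation, per-condition mC calling,
#' multi-condition Venn/retention comparison, DMR detection between the
#' first two conditions, DMR-gene mapping, optional pathway enrichment and
#' expression cross-tabulation. All stage outputs are written under
#' `outdir` together with `summary.json` and a timestamped log; results are
#' a pure function of (inputs, parameters, seed).
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `genome` (FASTA path or `bs_genome`), `counts` (named list of 2-3
#'   count-table paths or data.frames, ordered baseline, stressed,
#'   recovered), `control` (count table for the conversion spike-in) or
#'   `R` (fixed non-conversion rate), optional `genes_gff`, `tes_bed`,
#'   `pathway_map` (path or list), `de_table` (path or data.frame with
#'   gene/status), optional `params` overriding any of min_coverage = 5,
#'   q_max = 0.05, window = 200, step = 40, upstream = 100,
#'   downstream = 100, min_sites = 5, min_diff = 0.1, and `outdir`.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, a list with all stage results (`R`, `calls`, `venn`,
#'   `retention`, `context_proportions`, `replicon_ratios`,
#'   `level_summaries`, `te_summary`, `dmr`, `dmr_genes`, `enrichment`,
#'   `cross_tab`, `summary`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("an output directory is required")
  params <- utils::modifyList(default_params, config$params %||% list())
  if (any(unlist(params[c("min_coverage", "window", "step")]) < 1)) {
    stop("thresholds must be positive")
  }
  if (length(config$counts) < 2L) {
    stop("at least two condition count tables are required")
  }
  # fail on missing inputs before any stage runs
  for (field in c("genome", "control")) {
    v <- config[[field]]
    if (is.character(v) && !file.exists(v)) {
      stop("input not found: ", field, " = ", v)
    }
  }
  for (v in config$counts) {
    if (is.character(v) && !file.exists(v)) stop("input not found: ", v)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(outdir, "log.txt"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "pipeline start; parameters: ",
           paste(names(params), unlist(params), sep = "=", collapse = " "))

  genome <- config$genome
  if (is.character(genome)) genome <- read_genome(genome)
  features <- NULL
  if (!is.null(config$features)) {
    features <- config$features
  } else if (!is.null(config$genes_gff) || !is.null(config$tes_bed)) {
    features <- read_features(config$genes_gff, config$tes_bed)
  }

  log_line(logf, "stage: conversion-rate estimation")
  if (!is.null(config$R)) {
    R <- config$R
    conv <- NULL
  } else {
    conv <- estimate_nonconversion(resolve_counts(config$control))
    R <- conv$R
  }
  log_line(logf, "non-conversion rate R = ", signif(R, 4))

  conditions <- names(config$counts)
  if (is.null(conditions)) {
    conditions <- paste0("cond", seq_along(config$counts))
  }
  calls <- list()
  for (i in seq_along(config$counts)) {
    cond <- conditions[i]
    log_line(logf, "stage: mC calling for ", cond)
    calls[[cond]] <- call_sites(resolve_counts(config$counts[[i]]), R,
                                params$min_coverage, params$q_max)
    write_calls(calls[[cond]], file.path(outdir,
                                         paste0("calls_", cond, ".tsv")))
    log_line(logf, cond, ": ", sum(calls[[cond]]$is_mc), " mC sites")
  }

  log_line(logf, "stage: multi-condition comparison")
  keys <- lapply(calls, mc_sites)
  venn <- NULL
  retention <- NULL
  if (length(calls) >= 3L) {
    venn <- venn_partition(keys[[1]], keys[[2]], keys[[3]],
                           labels = conditions[1:3], keep_sets = FALSE)
    retention <- retention_stats(venn)
    jsonlite::write_json(
      list(labels = venn$labels, cells = as.list(venn$cells),
           totals = as.list(venn$totals), pairwise = as.list(venn$pairwise),
           union = venn$union),
      file.path(outdir, "venn.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(retention),
                         file.path(outdir, "retention.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  props <- do.call(rbind, lapply(conditions, function(cond) {
    cbind(condition = cond,
          context_proportions(calls[[cond]],
                              min_coverage = params$min_coverage))
  }))
  utils::write.table(props, file.path(outdir, "context_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ratios <- do.call(rbind, lapply(conditions, function(cond) {
    cbind(condition = cond,
          replicon_site_ratio(calls[[cond]],
                              min_coverage = params$min_coverage))
  }))
  utils::write.table(ratios, file.path(outdir, "replicon_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  levels <- do.call(rbind, lapply(conditions, function(cond) {
    ls <- level_summary(calls[[cond]])
    if (nrow(ls)) cbind(condition = cond, ls) else NULL
  }))
  utils::write.table(levels, file.path(outdir, "level_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  te <- NULL
  if (!is.null(features) && length(features$tes)) {
    te <- lapply(calls, te_site_summary, features = features)
    jsonlite::write_json(
      lapply(te, function(x) x[c("n_te_sites", "n_tes_with_sites")]),
      file.path(outdir, "te_summary.json"), auto_unbox = TRUE, digits = NA)
  }

  log_line(logf, "stage: DMR detection (", conditions[1], " vs ",
           conditions[2], ")")
  dmr <- detect_dmrs(calls[[1]], calls[[2]], genome,
                     window = params$window, step = params$step,
                     q_max = params$q_max, min_sites = params$min_sites,
                     min_diff = params$min_diff,
                     min_coverage = params$min_coverage,
                     features = features)
  write_dmrs(dmr, file.path(outdir, "dmrs.tsv"))
  log_line(logf, nrow(dmr$dmrs), " DMRs from ",
           sum(dmr$windows$significant %||% FALSE), " significant windows")
  genes <- list(hyper = character(0), hypo = character(0))
  if (!is.null(features) && length(features$genes)) {
    genes <- dmr_genes(dmr, features)
    writeLines(genes$hyper, file.path(outdir, "dmr_genes_hyper.txt"))
    writeLines(genes$hypo, file.path(outdir, "dmr_genes_hypo.txt"))
  }

  enr <- NULL
  if (!is.null(config$pathway_map)) {
    log_line(logf, "stage: pathway enrichment")
    pw <- config$pathway_map
    if (is.character(pw)) pw <- read_pathway_map(pw)
    enr <- hypergeom_enrich(c(genes$hyper, genes$hypo), pw,
                            q_max = params$q_max)
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  xtab <- NULL
  if (!is.null(config$de_table)) {
    log_line(logf, "stage: expression cross-tabulation")
    de <- config$de_table
    if (is.character(de)) {
      de <- utils::read.delim(de, header = TRUE, colClasses = "character")
    }
    xtab <- cross_tabulate_expression(genes, de)
    utils::write.table(cbind(direction = rownames(xtab), as.data.frame(xtab)),
                       file.path(outdir, "cross_tab.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    R = R,
    conditions = as.list(stats::setNames(
      lapply(calls, function(x) sum(x$is_mc)), conditions)),
    venn = if (!is.null(venn)) as.list(venn$cells) else NULL,
    retention = if (!is.null(retention)) unclass(retention) else NULL,
    n_dmrs = nrow(dmr$dmrs),
    n_dmr_genes = list(hyper = length(genes$hyper),
                       hypo = length(genes$hypo)),
    n_enriched = if (!is.null(enr)) sum(enr$enriched) else NULL
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_line(logf, "pipeline complete")
  invisible(list(R = R, conversion = conv, calls = calls, venn = venn,
                 retention = retention, context_proportions = props,
                 replicon_ratios = ratios, level_summaries = levels,
                 te_summary = te, dmr = dmr, dmr_genes = genes,
                 enrichment = enr, cross_tab = xtab, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Regularly spaced synthetic gene/TE annotation over a genome: 900 bp genes
# separated by 300 bp gaps, every 12th gene replaced by a TE interval.
synthetic_features <- function(genome) {
  rows_g <- list(); rows_t <- list()
  for (chr in names(genome)) {
    L <- genome_lengths(genome)[[chr]]
    starts <- seq.int(151L, L - 1050L, by = 1200L)
    if (!length(starts)) next
    idx <- seq_along(starts)
    is_te <- idx %% 12L == 0L
    rows_g[[chr]] <- data.frame(
      chrom = chr, start = starts[!is_te], end = starts[!is_te] + 899L,
      strand = rep_len(c("+", "-"), sum(!is_te)),
      gene_id = sprintf("%s_g%04d", chr, idx[!is_te])
    )
    if (any(is_te)) {
      rows_t[[chr]] <- data.frame(
        chrom = chr, start = starts[is_te], end = starts[is_te] + 899L,
        te_id = sprintf("%s_te%03d", chr, idx[is_te])
      )
    }
  }
  feature_table(genes = do.call(rbind, rows_g), tes = do.call(rbind, rows_t))
}

#' Run a fully synthetic end-to-end demonstration
#'
#' Simulates a three-condition bisulfite experiment
#' (baseline / stressed / recovered) on a synthetic genome with synthetic
#' gene, TE, pathway and differential-expression annotation, then runs
#' [run_pipeline()] on the generated inputs. All inputs and outputs are
#' written under `outdir`.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param genome_length Genome length in bp (default 200000).
#' @param coverage A [coverage_model()] (default Poisson, mean 50).
#' @return Invisibly, the [run_pipeline()] result list, with the
#'   simulation truth attached as `truth`.
#' @export
demo_pipeline <- function(outdir, seed = 1L, genome_length = 200000L,
                          coverage = coverage_model()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(genome_length = genome_length,
                             coverage = coverage, seed = seed)
  features <- synthetic_features(sim$genome)
  gene_ids <- features$genes$gene_id
  set.seed(derive_seeds(seed, 7L)[7L])
  pathways <- split(gene_ids,
                    sample(sprintf("pw%02d", 1:20), length(gene_ids),
                           replace = TRUE))
  de_table <- data.frame(
    gene = gene_ids,
    status = sample(c("down", "up", "unchanged"), length(gene_ids),
                    replace = TRUE, prob = c(0.45, 0.45, 0.1))
  )
  indir <- file.path(outdir, "inputs")
  dir.create(indir, showWarnings = FALSE)
  write_genome(sim$genome, file.path(indir, "genome.fasta"))
  count_paths <- stats::setNames(
    file.path(indir, paste0("counts_", names(sim$counts), ".tsv")),
    names(sim$counts))
  for (cond in names(sim$counts)) {
    write_counts_table(sim$counts[[cond]], count_paths[[cond]])
  }
  write_counts_table(sim$control, file.path(indir, "control.tsv"))
  truth <- sim$methylomes$base
  utils::write.table(
    data.frame(chrom = truth$chrom, pos = truth$pos + 1L,
               strand = truth$strand, context = truth$context,
               m_base = truth$m, m_stressed = sim$methylomes$stressed$m,
               m_recovered = sim$methylomes$recovered$m),
    file.path(indir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  config <- list(
    genome = file.path(indir, "genome.fasta"),
    counts = as.list(count_paths[c("base", "stressed", "recovered")]),
    control = file.path(indir, "control.tsv"),
    features = features,
    pathway_map = pathways,
    de_table = de_table,
    outdir = outdir
  )
  res <- run_pipeline(config)
  res$truth <- sim[c("methylomes", "ledger", "R")]
  invisible(res)
}
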
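#' Three-set Venn partition of site sets
#'
#' Decomposes three per-condition site (or gene) identifier sets into the
#' seven disjoint Venn cells. Identifiers are typically
#' `"chrom:pos:strand"` keys from [mc_sites()], but any character ids work.
#'
#' @param set_a,set_b,set_c Character vectors (duplicates ignored).
#' @param labels Condition names, length 3.
#' @param keep_sets Keep the id vectors of each cell (default TRUE).
#' @return A `venn_partition`: list with `labels`, `cells` (named counts for
#'   A_only, B_only, C_only, AB_only, AC_only, BC_only, ABC), `totals`
#'   (per-set sizes), `pairwise` (AB, AC, BC intersection sizes), `union`,
#'   and optionally `sets`.
#' @export
venn_partition <- function(set_a, set_b, set_c,
                           labels = c("A", "B", "C"), keep_sets = TRUE) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  c <- unique(as.character(set_c))
  all_ids <- unique(c(a, b, c))
  ina <- all_ids %in% a
  inb <- all_ids %in% b
  inc <- all_ids %in% c
  sets <- list(
    A_only = all_ids[ina & !inb & !inc],
    B_only = all_ids[!ina & inb & !inc],
    C_only = all_ids[!ina & !inb & inc],
    AB_only = all_ids[ina & inb & !inc],
    AC_only = all_ids[ina & !inb & inc],
    BC_only = all_ids[!ina & inb & inc],
    ABC = all_ids[ina & inb & inc]
  )
  cells <- vapply(sets, length, integer(1))
  structure(list(
    labels = labels,
    cells = cells,
    totals = stats::setNames(c(length(a), length(b), length(c)), labels),
    pairwise = c(AB = sum(ina & inb), AC = sum(ina & inc),
                 BC = sum(inb & inc)),
    union = length(all_ids),
    sets = if (keep_sets) sets else NULL
  ), class = "venn_partition")
}

#' Transgenerational retention and regain statistics
#'
#' With conditions ordered (baseline, stressed, recovered): sites `lost`
#' are baseline sites absent under stress; `gained` are stress-induced
#' sites absent at baseline. The preserved fraction is the share of gained
#' sites still present after recovery; the regained fraction is the share
#' of lost sites that reappear after recovery. Together these quantify how
#' much of the stress-induced methylation pattern is inherited after the
#' stress is removed.
#'
#' @param partition A [venn_partition()] computed with
#'   (baseline, stressed, recovered) as (A, B, C).
#' @return A `retention_stats` list: `n_lost`, `n_gained`, `n_preserved`,
#'   `n_regained`, `preserved_frac`, `regained_frac` (NA when the
#'   denominator is 0).
#' @export
retention_stats <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  cl <- partition$cells
  n_lost <- cl[["A_only"]] + cl[["AC_only"]]
  n_gained <- cl[["B_only"]] + cl[["BC_only"]]
  structure(list(
    n_lost = n_lost, n_gained = n_gained,
    n_preserved = cl[["BC_only"]], n_regained = cl[["AC_only"]],
    preserved_frac = if (n_gained > 0) cl[["BC_only"]] / n_gained else NA_real_,
    regained_frac = if (n_lost > 0) cl[["AC_only"]] / n_lost else NA_real_
  ), class = "retention_stats")
}

#' Per-context methylated-cytosine proportions
#'
#' Percentage of cytosines called methylated in each context and overall.
#' The denominator is either the cytosines covered at `>= min_coverage` in
#' this sample (`"covered"`, robust to coverage differences between
#' samples) or all context-defined genomic cytosines (`"genomic"`).
#'
#' @param calls A `methylation_calls` data.frame.
#' @param genome A `bs_genome`; required for `denominator = "genomic"`.
#' @param denominator `"covered"` or `"genomic"`.
#' @param min_coverage Depth threshold defining "covered" (default 5).
#' @return data.frame with columns `context` (CG, CHG, CHH, overall),
#'   `n_mc`, `n_denom`, `pct`.
#' @export
context_proportions <- function(calls, genome = NULL,
                                denominator = c("covered", "genomic"),
                                min_coverage = 5L) {
  denominator <- match.arg(denominator)
  contexts <- c("CG", "CHG", "CHH")
  n_mc <- vapply(contexts, function(ctx) {
    sum(calls$is_mc & calls$context == ctx)
  }, numeric(1))
  if (denominator == "covered") {
    n_den <- vapply(contexts, function(ctx) {
      sum(calls$n >= min_coverage & calls$context == ctx)
    }, numeric(1))
  } else {
    if (is.null(genome)) stop("genomic denominator requires the genome")
    uni <- enumerate_cytosines(genome)
    n_den <- vapply(contexts, function(ctx) {
      sum(uni$context == ctx)
    }, numeric(1))
  }
  df <- data.frame(context = c(contexts, "overall"),
                   n_mc = c(n_mc, sum(n_mc)),
                   n_denom = c(n_den, sum(n_den)))
  df$pct <- ifelse(df$n_denom > 0, 100 * df$n_mc / df$n_denom, NA_real_)
  df
}

#' Per-replicon methylation site ratios
#'
#' [context_proportions()] grouped by replicon: the percentage of each
#' replicon's cytosines (by context) that are called methylated. Replicons
#' without calls report 0.
#'
#' @inheritParams context_proportions
#' @return data.frame with columns `chrom`, `context`, `n_mc`, `n_denom`,
#'   `pct`.
#' @export
replicon_site_ratio <- function(calls, genome = NULL,
                                denominator = c("covered", "genomic"),
                                min_coverage = 5L) {
  denominator <- match.arg(denominator)
  chroms <- if (denominator == "genomic") {
    names(genome)
  } else {
    sort(unique(calls$chrom))
  }
  out <- lapply(chroms, function(chr) {
    sub <- calls[calls$chrom == chr, , drop = FALSE]
    g <- if (denominator == "genomic") {
      structure(unclass(genome)[chr], class = "bs_genome")
    } else NULL
    df <- context_proportions(sub, g, denominator, min_coverage)
    cbind(chrom = chr, df)
  })
  do.call(rbind, out)
}

#' Five-number summaries of methylation levels
#'
#' Min, quartiles, max and count of the corrected methylation level over
#' called mC sites, stratified by the given columns (e.g. context, region).
#' Quartiles use linear interpolation between order statistics. Strata with
#' no mC sites are omitted.
#'
#' @param calls A `methylation_calls` data.frame (optionally carrying extra
#'   stratification columns such as `region`).
#' @param strata Character vector of column names to stratify by
#'   (default `"context"`); `NULL` for one overall stratum.
#' @return data.frame with the strata columns plus `min`, `q1`, `median`,
#'   `q3`, `max`, `n`.
#' @export
level_summary <- function(calls, strata = "context") {
  mc <- calls[calls$is_mc, , drop = FALSE]
  five <- function(x) {
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               n = length(x))
  }
  if (is.null(strata)) {
    if (!nrow(mc)) {
      return(data.frame(min = numeric(0), q1 = numeric(0),
                        median = numeric(0), q3 = numeric(0),
                        max = numeric(0), n = integer(0)))
    }
    return(five(mc$ml_corrected))
  }
  groups <- split(mc$ml_corrected,
                  lapply(strata, function(s) mc[[s]]), drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    labels <- strsplit(g, "\r", fixed = TRUE)[[1]]
    cbind(stats::setNames(as.data.frame(as.list(labels)), strata),
          five(groups[[g]]))
  }))
  rownames(out) <- NULL
  out
}

#' Transposable-element methylation summary
#'
#' A TE-type mC site lies exclusively within a TE interval: it overlaps a
#' TE and no annotated gene body. Reports the number of such sites, the
#' number of TEs harbouring at least one, and per-context level summaries.
#'
#' @param calls A `methylation_calls` data.frame.
#' @param features A `feature_table` with `tes` (and `genes` used for the
#'   exclusivity rule).
#' @return List with `n_te_sites`, `n_tes_with_sites`, and `levels`
#'   (a [level_summary()] restricted to TE-type sites).
#' @export
te_site_summary <- function(calls, features) {
  mc <- calls[calls$is_mc, , drop = FALSE]
  if (!nrow(mc) || !length(features$tes)) {
    return(list(n_te_sites = 0L, n_tes_with_sites = 0L,
                levels = level_summary(mc[0, , drop = FALSE])))
  }
  gr <- sites_granges(mc)
  te_hits <- GenomicRanges::findOverlaps(gr, features$tes,
                                         ignore.strand = TRUE)
  in_te <- unique(S4Vectors::queryHits(te_hits))
  in_gene <- if (length(features$genes)) {
    unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, features$genes, ignore.strand = TRUE)))
  } else integer(0)
  te_only <- setdiff(in_te, in_gene)
  hit_tes <- S4Vectors::subjectHits(te_hits)[
    S4Vectors::queryHits(te_hits) %in% te_only]
  list(
    n_te_sites = length(te_only),
    n_tes_with_sites = length(unique(hit_tes)),
    levels = level_summary(mc[te_only, , drop = FALSE])
  )
}

#' Cross-tabulate DMR-related genes against differential expression
#'
#' Counts, for the hyper- and hypo-methylated gene lists separately, how
#' many genes are down-regulated, up-regulated, or unchanged in an external
#' differential-expression table, and how many are absent from it.
#'
#' @param genes List with `hyper` and `hypo` character vectors (as from
#'   [dmr_genes()]).
#' @param de_table data.frame with columns `gene` and `status` in
#'   `{"down","up","unchanged"}`.
#' @return Integer matrix with rows `hyper`, `hypo` and columns `down`,
#'   `up`, `unchanged`, `absent`.
#' @export
cross_tabulate_expression <- function(genes, de_table) {
  status <- stats::setNames(as.character(de_table$status),
                            as.character(de_table$gene))
  if (!all(status %in% c("down", "up", "unchanged"))) {
    stop("DE status must be one of down/up/unchanged")
  }
  row_counts <- function(g) {
    g <- unique(g)
    s <- status[g]
    c(down = sum(s == "down", na.rm = TRUE),
      up = sum(s == "up", na.rm = TRUE),
      unchanged = sum(s == "unchanged", na.rm = TRUE),
      absent = sum(is.na(s)))
  }
  rbind(hyper = row_counts(genes$hyper), hypo = row_counts(genes$hypo))
}

#' Genes carrying at least one mC site in their body
#'
#' Gene-level analogue of the site sets: a gene is methylated in a sample
#' when at least one called mC site overlaps its gene body. Used for the
#' gene-level Venn partition.
#'
#' @param calls A `methylation_calls` data.frame.
#' @param features A `feature_table`.
#' @return Character vector of gene ids.
#' @export
methylated_genes <- function(calls, features) {
  mc <- calls[calls$is_mc, , drop = FALSE]
  if (!nrow(mc) || !length(features$genes)) return(character(0))
  hits <- GenomicRanges::findOverlaps(sites_granges(mc), features$genes,
                                      ignore.strand = TRUE)
  sort(unique(features$genes$gene_id[S4Vectors::subjectHits(hits)]))
}
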
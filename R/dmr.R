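#' Tile a replicon with sliding windows
#'
#' Windows start at 0, `step`, 2*`step`, ... and only full-length windows
#' are emitted (a trailing partial window is dropped).
#'
#' @param replicon_length Replicon length in bp.
#' @param window Window length in bp (default 200).
#' @param step Step length in bp (default 40).
#' @return data.frame with 0-based half-open `start`, `end`; zero rows when
#'   the replicon is shorter than one window.
#' @export
tile_windows <- function(replicon_length, window = 200L, step = 40L) {
  if (window < 1) stop("window must be >= 1")
  if (step < 1 || step > window) stop("need window >= step >= 1")
  if (replicon_length < window) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- seq.int(0L, replicon_length - window, by = step)
  data.frame(start = as.integer(starts), end = as.integer(starts + window))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's. A table with an all-zero margin carries no information
#' and returns `p = 1` by convention.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative integer
#'   counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2L, 2L)
  if (any(m < 0) || any(m != round(m))) {
    stop("table entries must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(1)
  }
  stats::fisher.test(m)$p.value
}

# Pool per-window read counts for one replicon from site vectors sorted by
# position; cumulative sums make each window an O(1) range query.
pool_windows <- function(pos, vals, windows) {
  if (length(pos) == 0L) {
    return(matrix(0, nrow(windows), ncol(vals)))
  }
  cs <- apply(vals, 2L, cumsum)
  cs <- rbind(0, cs)
  lo <- findInterval(windows$start - 0.5, pos)       # sites with pos < start
  hi <- findInterval(windows$end - 0.5, pos)         # sites with pos < end
  cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
}

#' Detect differentially methylated regions between two samples
#'
#' Slides fixed-length windows along each replicon; in every window the
#' methylated and unmethylated read counts of the two samples are pooled
#' over the cytosines covered at `>= min_coverage` in both samples, and the
#' resulting 2x2 table is tested with the two-sided Fisher exact test.
#' Windows with fewer than `min_sites` shared covered cytosines are not
#' tested. Benjamini-Hochberg correction is applied across all tested
#' windows genome-wide; a window is significant when `q <= q_max` and the
#' absolute pooled methylation-level difference is `>= min_diff`.
#' Overlapping or book-ended significant windows of the same direction are
#' merged into DMRs; hyper/hypo direction is relative to sample B
#' (`level_B - level_A`).
#'
#' @param calls_a,calls_b `methylation_calls` for the reference (A) and
#'   comparison (B) samples, on the same genome.
#' @param genome A `bs_genome`, or a named vector of replicon lengths.
#' @param window,step Window and step lengths in bp (defaults 200 and 40).
#' @param q_max FDR threshold on windows (default 0.05).
#' @param min_sites Minimum shared covered cytosines per tested window
#'   (default 5).
#' @param min_diff Minimum absolute pooled level difference for
#'   significance (default 0.1).
#' @param min_coverage Per-site depth requirement in both samples
#'   (default 5).
#' @param features Optional `feature_table`; overlapping gene ids are then
#'   attached to each DMR.
#' @return A `dmr_result` list: `dmrs` (data.frame chrom, start, end
#'   0-based half-open, direction, p_min, q_min, mean_diff, n_windows,
#'   genes) and `windows` (all tested windows with counts, p, q, diff,
#'   significance).
#' @export
detect_dmrs <- function(calls_a, calls_b, genome, window = 200L, step = 40L,
                        q_max = 0.05, min_sites = 5L, min_diff = 0.1,
                        min_coverage = 5L, features = NULL) {
  lens <- if (inherits(genome, "bs_genome")) genome_lengths(genome) else genome
  if (!all(unique(calls_a$chrom) %in% names(lens)) ||
      !all(unique(calls_b$chrom) %in% names(lens))) {
    stop("calls contain replicons absent from the genome")
  }
  a <- calls_a[calls_a$n >= min_coverage, c("chrom", "pos", "strand",
                                            "count_m", "count_u")]
  b <- calls_b[calls_b$n >= min_coverage, c("chrom", "pos", "strand",
                                            "count_m", "count_u")]
  shared <- merge(a, b, by = c("chrom", "pos", "strand"),
                  suffixes = c("_a", "_b"))
  shared <- shared[order(shared$chrom, shared$pos), , drop = FALSE]

  win_list <- lapply(names(lens), function(chr) {
    w <- tile_windows(lens[[chr]], window, step)
    if (!nrow(w)) return(NULL)
    s <- shared[shared$chrom == chr, , drop = FALSE]
    pooled <- pool_windows(s$pos,
                           as.matrix(s[, c("count_m_a", "count_u_a",
                                           "count_m_b", "count_u_b")]),
                           w)
    nsites <- pool_windows(s$pos, matrix(1, nrow(s), 1L), w)[, 1L]
    data.frame(chrom = chr, start = w$start, end = w$end,
               n_sites = nsites,
               km_a = pooled[, 1L], ku_a = pooled[, 2L],
               km_b = pooled[, 3L], ku_b = pooled[, 4L],
               stringsAsFactors = FALSE)
  })
  wins <- do.call(rbind, win_list)
  if (is.null(wins)) wins <- data.frame()
  tested <- wins[wins$n_sites >= min_sites, , drop = FALSE]
  if (nrow(tested)) {
    tested$level_a <- tested$km_a / pmax(1, tested$km_a + tested$ku_a)
    tested$level_b <- tested$km_b / pmax(1, tested$km_b + tested$ku_b)
    tested$diff <- tested$level_b - tested$level_a
    tested$p_value <- vapply(seq_len(nrow(tested)), function(i) {
      fisher_exact_2x2(matrix(c(tested$km_a[i], tested$ku_a[i],
                                tested$km_b[i], tested$ku_b[i]), 2L, 2L))
    }, numeric(1))
    tested$q_value <- bh_qvalues(tested$p_value)
    tested$significant <- tested$q_value <= q_max &
      abs(tested$diff) >= min_diff
  }

  dmr_cols <- c("chrom", "start", "end", "direction", "p_min", "q_min",
                "mean_diff", "n_windows", "genes")
  empty <- stats::setNames(
    data.frame(character(0), integer(0), integer(0), character(0),
               numeric(0), numeric(0), numeric(0), integer(0), character(0),
               stringsAsFactors = FALSE), dmr_cols)
  if (!nrow(tested) || !any(tested$significant)) {
    return(structure(list(dmrs = empty, windows = tested),
                     class = "dmr_result"))
  }

  sig <- tested[tested$significant, , drop = FALSE]
  sig$direction <- ifelse(sig$diff > 0, "hyper", "hypo")
  merged <- lapply(split(sig, list(sig$chrom, sig$direction), drop = TRUE),
                   function(g) {
    ir <- IRanges::IRanges(g$start + 1L, g$end)  # 1-based for IRanges
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red)
    grp <- factor(S4Vectors::subjectHits(hit), levels = seq_along(red))
    data.frame(
      chrom = g$chrom[1L],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      direction = g$direction[1L],
      p_min = vapply(split(g$p_value, grp), min, numeric(1)),
      q_min = vapply(split(g$q_value, grp), min, numeric(1)),
      mean_diff = vapply(split(g$diff, grp), mean, numeric(1)),
      n_windows = vapply(split(g$diff, grp), length, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  dmrs <- do.call(rbind, merged)
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  rownames(dmrs) <- NULL

  dmrs$genes <- ""
  if (!is.null(features) && length(features$genes)) {
    gr <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L, dmrs$end))
    hits <- GenomicRanges::findOverlaps(gr, features$genes,
                                        ignore.strand = TRUE)
    ids <- split(features$genes$gene_id[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    dmrs$genes[as.integer(names(ids))] <-
      vapply(ids, paste, character(1), collapse = ",")
  }
  structure(list(dmrs = dmrs, windows = tested), class = "dmr_result")
}

#' Differentially methylated genes
#'
#' A gene is DMR-related when its gene body overlaps a DMR by at least
#' 1 bp. Genes overlapping DMRs of both directions appear in both lists
#' (with a message).
#'
#' @param dmr_result A `dmr_result` from [detect_dmrs()].
#' @param features A `feature_table` with gene intervals.
#' @return List with character vectors `hyper` and `hypo` of gene ids.
#' @export
dmr_genes <- function(dmr_result, features) {
  dmrs <- dmr_result$dmrs
  out <- list(hyper = character(0), hypo = character(0))
  if (!nrow(dmrs) || !length(features$genes)) return(out)
  gr <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  hits <- GenomicRanges::findOverlaps(gr, features$genes,
                                      ignore.strand = TRUE)
  dir <- dmrs$direction[S4Vectors::queryHits(hits)]
  ids <- features$genes$gene_id[S4Vectors::subjectHits(hits)]
  out$hyper <- sort(unique(ids[dir == "hyper"]))
  out$hypo <- sort(unique(ids[dir == "hypo"]))
  both <- intersect(out$hyper, out$hypo)
  if (length(both)) {
    message(length(both), " gene(s) overlap both hyper- and hypo-methylated ",
            "regions and are listed in both sets")
  }
  out
}

#' Write DMRs to a BED-like TSV
#'
#' Coordinates are 0-based half-open as in BED.
#'
#' @param dmr_result A `dmr_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmr_result, path) {
  utils::write.table(dmr_result$dmrs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
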
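#' Read a gene-to-pathway mapping
#'
#' Two-column TSV (gene, pathway), one row per membership; a gene may map
#' to several pathways.
#'
#' @param path Path to the mapping TSV (no header).
#' @return A named list of character vectors: pathway id -> gene ids.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("gene", "pathway"),
                          colClasses = "character")
  lapply(split(df$gene, df$pathway), unique)
}

#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway with gene set of size `K` inside a universe of `N`
#' genes, and a selected list of `n` genes of which `k` fall in the
#' pathway, the enrichment p-value is the upper-tail hypergeometric
#' probability `P(X >= k)`. Benjamini-Hochberg correction is applied over
#' the tested pathways. Pathways with `K < 2` or `k = 0` are skipped before
#' correction. Selected genes outside the universe are dropped (their count
#' is attached as attribute `n_dropped`).
#'
#' @param selected Character vector of selected gene ids (e.g. a
#'   DMR-related gene list).
#' @param pathways Named list pathway -> gene ids, or a data.frame with
#'   columns `gene` and `pathway`.
#' @param universe Background gene set; default: all genes appearing in the
#'   mapping.
#' @param q_max Significance threshold recorded in the `enriched` column
#'   (default 0.05); all tested pathways are returned.
#' @return data.frame (pathway, k, K, n, N, p_value, q_value, enriched)
#'   sorted by q then p.
#' @export
hypergeom_enrich <- function(selected, pathways, universe = NULL,
                             q_max = 0.05) {
  if (is.data.frame(pathways)) {
    pathways <- lapply(split(pathways$gene, pathways$pathway), unique)
  }
  if (is.null(universe)) universe <- unique(unlist(pathways))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  selected <- unique(as.character(selected))
  dropped <- sum(!selected %in% universe)
  if (dropped) {
    warning(dropped, " selected gene(s) not in the universe were dropped")
  }
  selected <- intersect(selected, universe)
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(pathways), function(pw) {
    genes <- intersect(pathways[[pw]], universe)
    K <- length(genes)
    k <- length(intersect(selected, genes))
    if (K < 2L || k == 0L) return(NULL)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), enriched = logical(0))
    attr(out, "n_dropped") <- dropped
    return(out)
  }
  out$q_value <- bh_qvalues(out$p_value)
  out$enriched <- out$q_value <= q_max
  out <- out[order(out$q_value, out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}
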
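#' Read a genome from a FASTA file
#'
#' Loads every record of a (multi-)FASTA file into a named character vector of
#' uppercase nucleotide sequences, one element per replicon (chromosome or
#' plasmid), in file order. Ambiguity codes other than N are rejected so that
#' downstream context classification is well defined.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `bs_genome`; names are replicon
#'   ids (first whitespace-delimited token of each header), values are
#'   uppercase sequences over the alphabet A/C/G/T/N.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path)
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA at line 1 of ", path, ": expected a '>' header")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  x <- toupper(as.character(seqs))
  names(x) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(x))) {
    stop("duplicate replicon ids in ", path)
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("replicon ", names(x)[bad][1L],
         " contains bases outside A/C/G/T/N")
  }
  structure(x, class = "bs_genome")
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences (a `bs_genome`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unclass(genome))
  names(dss) <- names(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Replicon lengths of a genome
#' @param genome A `bs_genome` (named character vector of sequences).
#' @return Named integer vector of sequence lengths in bp.
#' @export
genome_lengths <- function(genome) {
  vapply(unclass(genome), nchar, integer(1))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Context from the two downstream bases on the cytosine's strand.
# Returns NA for undefined (N in either base or NA input).
context_from_downstream <- function(b1, b2) {
  out <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  out[is.na(b1) | is.na(b2) | b1 == "N" | b2 == "N"] <- NA_character_
  out
}

#' Classify the sequence context of a cytosine
#'
#' A cytosine is CG if the next base downstream on its strand is G, CHG if
#' the base two downstream is G, and CHH otherwise (H = A, C or T). Within
#' 2 bp of a replicon end, or when a downstream base is N, the context is
#' undefined and `NA` is returned.
#'
#' @param genome A `bs_genome`.
#' @param replicon Replicon id.
#' @param pos 0-based position(s) of the cytosine on the forward sequence.
#' @param strand `"+"` or `"-"` (recycled against `pos`).
#' @return Character vector over `{"CG","CHG","CHH", NA}`.
#' @export
classify_context <- function(genome, replicon, pos, strand) {
  seq <- unclass(genome)[[replicon]]
  if (is.null(seq)) stop("unknown replicon: ", replicon)
  L <- nchar(seq)
  n <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (any(pos < 0L | pos >= L)) stop("position out of replicon bounds")
  base_at <- function(p) {
    # 1-based substring positions; out-of-range yields NA
    out <- rep(NA_character_, length(p))
    ok <- p >= 0L & p < L
    if (any(ok)) out[ok] <- substring(seq, p[ok] + 1L, p[ok] + 1L)
    out
  }
  fwd <- base_at(pos)
  site_base <- ifelse(strand == "+", fwd, comp_base(fwd))
  if (any(site_base != "C")) {
    stop("base at the given position/strand is not C")
  }
  b1 <- ifelse(strand == "+", base_at(pos + 1L), comp_base(base_at(pos - 1L)))
  b2 <- ifelse(strand == "+", base_at(pos + 2L), comp_base(base_at(pos - 2L)))
  context_from_downstream(b1, b2)
}

#' Enumerate all context-defined cytosines of a genome
#'
#' Lists every strand-specific cytosine whose CG/CHG/CHH context is defined
#' (at least two non-N downstream bases on its strand), over both strands of
#' all replicons. This is the site universe used as denominator in
#' per-context methylation proportions. CG cytosines on opposite strands are
#' independent sites; they are never collapsed.
#'
#' @param genome A `bs_genome`.
#' @return A data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `trinucleotide` (3-mer read 5'->3' on the site's strand),
#'   sorted by (chrom, pos, strand) with `+` before `-`.
#' @export
enumerate_cytosines <- function(genome) {
  per_replicon <- lapply(names(genome), function(chr) {
    s <- unclass(genome)[[chr]]
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(ch)
    # forward-strand cytosines with two downstream bases
    pp <- which(ch == "C")
    pp <- pp[pp + 2L <= L]
    b1p <- ch[pp + 1L]; b2p <- ch[pp + 2L]
    keep <- b1p != "N" & b2p != "N"
    plus <- data.frame(
      chrom = rep(chr, sum(keep)), pos = pp[keep] - 1L,
      strand = rep("+", sum(keep)),
      context = context_from_downstream(b1p[keep], b2p[keep]),
      trinucleotide = paste0("C", b1p[keep], b2p[keep], recycle0 = TRUE),
      stringsAsFactors = FALSE
    )
    # reverse-strand cytosines are G on the forward sequence; downstream on
    # the minus strand runs leftwards
    pm <- which(ch == "G")
    pm <- pm[pm >= 3L]
    b1m <- comp_base(ch[pm - 1L]); b2m <- comp_base(ch[pm - 2L])
    keep <- b1m != "N" & b2m != "N"
    minus <- data.frame(
      chrom = rep(chr, sum(keep)), pos = pm[keep] - 1L,
      strand = rep("-", sum(keep)),
      context = context_from_downstream(b1m[keep], b2m[keep]),
      trinucleotide = paste0("C", b1m[keep], b2m[keep], recycle0 = TRUE),
      stringsAsFactors = FALSE
    )
    out <- rbind(plus, minus)
    out[order(out$pos, out$strand), , drop = FALSE]
  })
  out <- do.call(rbind, per_replicon)
  rownames(out) <- NULL
  out
}

#' Read gene and transposable-element annotation
#'
#' Genes are taken from `gene`-type features of a GFF3 file; TE intervals
#' from a BED file (0-based half-open, converted to 1-based GRanges).
#'
#' @param gff_path Path to a GFF3 file with `gene` features, or `NULL`.
#' @param te_bed_path Path to a BED file of TE intervals, or `NULL`.
#' @return A `feature_table`: list with `genes` and `tes`, each a
#'   [GenomicRanges::GRanges] (possibly empty); genes carry a `gene_id`
#'   metadata column.
#' @export
read_features <- function(gff_path = NULL, te_bed_path = NULL) {
  genes <- GenomicRanges::GRanges()
  if (!is.null(gff_path)) {
    gff <- rtracklayer::import(gff_path, format = "gff3")
    genes <- gff[gff$type == "gene"]
    id <- genes$ID
    if (is.null(id)) id <- genes$Name
    if (is.null(id)) id <- paste0("gene", seq_along(genes))
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = id)
  }
  tes <- GenomicRanges::GRanges()
  if (!is.null(te_bed_path)) {
    tes <- rtracklayer::import(te_bed_path, format = "bed")
    id <- tes$name
    if (is.null(id)) id <- paste0("TE", seq_along(tes))
    S4Vectors::mcols(tes) <- S4Vectors::DataFrame(te_id = id)
  }
  structure(list(genes = genes, tes = tes), class = "feature_table")
}

#' Construct a feature table from data frames
#'
#' Programmatic alternative to [read_features()] for simulated annotation.
#'
#' @param genes data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `gene_id`; or `NULL`.
#' @param tes data.frame with columns `chrom`, `start`, `end`, `te_id`; or
#'   `NULL`.
#' @return A `feature_table`.
#' @export
feature_table <- function(genes = NULL, tes = NULL) {
  g <- GenomicRanges::GRanges()
  if (!is.null(genes) && nrow(genes)) {
    g <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand
    )
    g$gene_id <- genes$gene_id
  }
  t <- GenomicRanges::GRanges()
  if (!is.null(tes) && nrow(tes)) {
    t <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start, tes$end))
    t$te_id <- tes$te_id
  }
  structure(list(genes = g, tes = t), class = "feature_table")
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(sites$pos + 1L, width = 1L),
    strand = "*"
  )
}

#' Assign each cytosine site to a functional region
#'
#' Every site receives exactly one label with precedence
#' gene body > upstream > downstream > intergenic. Upstream/downstream
#' regions are strand-aware flanks of the annotated genes (promoter/5'UTR
#' and 3'UTR surrogates).
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`.
#' @param features A `feature_table`.
#' @param upstream_len,downstream_len Flank lengths in bp (default 100).
#' @return `sites` with added columns `region` (factor of gene_body,
#'   upstream, downstream, intergenic) and `gene_id` (NA for intergenic).
#' @export
assign_region <- function(sites, features, upstream_len = 100L,
                          downstream_len = 100L) {
  stopifnot(inherits(features, "feature_table"))
  gr <- sites_granges(sites)
  region <- rep("intergenic", nrow(sites))
  gene_id <- rep(NA_character_, nrow(sites))
  genes <- features$genes
  if (length(genes)) {
    up <- GenomicRanges::trim(GenomicRanges::flank(
      genes, width = upstream_len, start = TRUE))
    dn <- GenomicRanges::trim(GenomicRanges::flank(
      genes, width = downstream_len, start = FALSE))
    # lowest precedence first so later assignments overwrite
    for (spec in list(list(dn, "downstream"), list(up, "upstream"),
                      list(genes, "gene_body"))) {
      hits <- GenomicRanges::findOverlaps(gr, spec[[1]], ignore.strand = TRUE)
      # first annotated gene wins within a precedence tier
      first <- !duplicated(S4Vectors::queryHits(hits))
      qh <- S4Vectors::queryHits(hits)[first]
      sh <- S4Vectors::subjectHits(hits)[first]
      region[qh] <- spec[[2]]
      gene_id[qh] <- genes$gene_id[sh]
    }
  }
  sites$region <- factor(region, levels = c("gene_body", "upstream",
                                            "downstream", "intergenic"))
  sites$gene_id <- gene_id
  sites
}

counts_columns <- c("chrom", "pos", "strand", "count_m", "count_u",
                    "context", "trinucleotide")

#' Read a per-cytosine count table
#'
#' The on-disk format is the 7-column tab-separated cytosine report produced
#' by bisulfite aligners: replicon, 1-based position, strand, methylated
#' read count, unmethylated read count, context, trinucleotide. Positions
#' are converted to 0-based internally.
#'
#' @param path Path to the TSV (no header).
#' @return data.frame with columns `chrom`, `pos` (0-based integer),
#'   `strand`, `count_m`, `count_u`, `context`, `trinucleotide`.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("counts table not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "character", "character",
                                         "character", "character", "character",
                                         "character"),
                          col.names = counts_columns)
  check_int <- function(x, what) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) | v != as.numeric(x))
    if (length(bad)) {
      stop("line ", bad[1L], ": ", what, " is not an integer: ", x[bad[1L]])
    }
    v
  }
  pos1 <- check_int(df$pos, "position")
  if (any(pos1 < 1L)) {
    stop("line ", which(pos1 < 1L)[1L], ": position must be >= 1")
  }
  cm <- check_int(df$count_m, "methylated count")
  cu <- check_int(df$count_u, "unmethylated count")
  neg <- which(cm < 0L | cu < 0L)
  if (length(neg)) stop("line ", neg[1L], ": negative read count")
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("line ", bad_strand[1L], ": unknown strand token ",
         df$strand[bad_strand[1L]])
  }
  bad_ctx <- which(!df$context %in% c("CG", "CHG", "CHH"))
  if (length(bad_ctx)) {
    stop("line ", bad_ctx[1L], ": unknown context token ",
         df$context[bad_ctx[1L]])
  }
  data.frame(chrom = df$chrom, pos = pos1 - 1L, strand = df$strand,
             count_m = cm, count_u = cu, context = df$context,
             trinucleotide = df$trinucleotide, stringsAsFactors = FALSE)
}

#' Write a per-cytosine count table
#'
#' Inverse of [read_counts_table()]: positions are written 1-based.
#'
#' @param counts data.frame as returned by [read_counts_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  out <- data.frame(counts$chrom, counts$pos + 1L, counts$strand,
                    counts$count_m, counts$count_u, counts$context,
                    counts$trinucleotide)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Site identity keys
#'
#' Identity of a site across conditions is the (replicon, 1-based position,
#' strand) triple, rendered as `"chrom:pos:strand"`.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`.
#' @return Character vector of keys.
#' @export
site_key <- function(sites) {
  sprintf("%s:%d:%s", sites$chrom, sites$pos + 1L, sites$strand)
}
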
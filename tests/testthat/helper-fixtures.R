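# Shared fixture builders; everything is generated in code.

make_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("r", seq_along(seqs))
  structure(toupper(seqs), class = "bs_genome")
}

# A count table at explicit sites; contexts default to CHH placeholders.
make_counts <- function(chrom, pos, strand, count_m, count_u,
                        context = "CHH", trinucleotide = "CAA") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             count_m = as.integer(count_m), count_u = as.integer(count_u),
             context = context, trinucleotide = trinucleotide,
             stringsAsFactors = FALSE)
}

# Independent two-sided Fisher oracle: enumerate all tables with the
# observed margins and sum hypergeometric probabilities not exceeding the
# observed table's (same relative tolerance as the reference test).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0 || c1 == 0 || c1 == r1 + r2 || r1 == 0 || r2 == 0) {
    return(1)
  }
  x <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(x, r1, r2, c1)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# Independent upper-tail binomial oracle by direct pmf summation.
binom_tail_oracle <- function(k, n, R) {
  if (k == 0) return(1)
  sum(stats::dbinom(k:n, n, R))
}

# Independent upper-tail hypergeometric oracle.
hyper_tail_oracle <- function(k, K, n, N) {
  x <- k:min(K, n)
  sum(stats::dhyper(x, K, N - K, n))
}
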
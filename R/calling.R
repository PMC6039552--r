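#' Estimate the bisulfite non-conversion rate from a spike-in control
#'
#' Pools all cytosines of an unmethylated control (e.g. spiked lambda-phage
#' DNA): every methylated-looking read there is a conversion failure, so
#' `R = unconverted reads / total reads`. `1 - R` is the bisulfite
#' conversion rate usually quoted as a percentage.
#'
#' @param control_counts Count-table data.frame for the control genome.
#' @return A `conversion_estimate`: list with `R`, `k_control` (unconverted
#'   observations), `n_control` (total observations) and
#'   `conversion_rate_pct`.
#' @export
estimate_nonconversion <- function(control_counts) {
  n <- sum(control_counts$count_m) + sum(control_counts$count_u)
  if (!isTRUE(n > 0)) stop("control table has no read observations")
  k <- sum(control_counts$count_m)
  structure(list(R = k / n, k_control = k, n_control = n,
                 conversion_rate_pct = 100 * (1 - k / n)),
            class = "conversion_estimate")
}

#' Upper-tail binomial p-value for methylation at a site
#'
#' Probability of observing at least `k` methylated reads out of `n` when
#' every apparent methylation is a conversion failure occurring at rate `R`:
#' `p = P(X >= k)`, `X ~ Binomial(n, R)`. One-sided because the alternative
#' of interest is an excess of unconverted reads over the noise rate.
#'
#' @param k Methylated read count(s), `0 <= k <= n`.
#' @param n Total read count(s), `>= 1`.
#' @param R Non-conversion rate in `[0,1)`.
#' @return p-value(s) in `(0,1]`.
#' @export
binomial_pvalue <- function(k, n, R) {
  if (R < 0 || R >= 1) stop("R must be in [0,1)")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  stats::pbinom(k - 1, n, R, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with the usual cumulative-minimum monotonicity
#' enforcement, mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0,1]` (NAs preserved).
#' @return q-values in `[0,1]`, same order as the input.
#' @export
bh_qvalues <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Conversion-corrected methylation level
#'
#' The uncorrected level is the methylated read fraction `k/n`; the
#' corrected level subtracts the non-conversion background:
#' `ML = (k/n - R) / (1 - R)`, clamped to `[0,1]` (finite coverage can push
#' the raw value slightly outside).
#'
#' @param k Methylated read count(s).
#' @param n Total read count(s), `>= 1`.
#' @param R Non-conversion rate in `[0,1)`.
#' @return List with `ml_uncorrected` and `ml_corrected`.
#' @export
methylation_level <- function(k, n, R) {
  if (any(n < 1)) stop("n must be >= 1")
  ml_unc <- k / n
  ml_cor <- pmin(1, pmax(0, (ml_unc - R) / (1 - R)))
  list(ml_uncorrected = ml_unc, ml_corrected = ml_cor)
}

#' Call methylcytosine sites from a count table
#'
#' For every covered site the one-sided binomial p-value against the
#' non-conversion rate is computed; Benjamini-Hochberg correction is applied
#' over the testing universe of sites with coverage `>= min_coverage`, and a
#' site is called methylated (`is_mc`) when it is in that universe and its
#' q-value is `<= q_max`. Corrected and uncorrected methylation levels are
#' attached to every covered site.
#'
#' @param counts Count-table data.frame.
#' @param R Non-conversion rate (a number, or a `conversion_estimate`).
#' @param min_coverage Minimum read depth for a site to be testable
#'   (default 5).
#' @param q_max FDR threshold (default 0.05).
#' @return `methylation_calls` data.frame: input columns plus `n`, `p_value`,
#'   `q_value` (NA outside the testing universe), `ml_uncorrected`,
#'   `ml_corrected`, `is_mc`; sorted by (chrom, pos, strand). The rate used
#'   is kept in attribute `R`.
#' @export
call_sites <- function(counts, R, min_coverage = 5L, q_max = 0.05) {
  if (inherits(R, "conversion_estimate")) R <- R$R
  if (R < 0 || R >= 1) stop("R must be in [0,1)")
  calls <- counts[order(counts$chrom, counts$pos, counts$strand), ,
                  drop = FALSE]
  rownames(calls) <- NULL
  calls$n <- calls$count_m + calls$count_u
  calls$p_value <- NA_real_
  covered <- calls$n >= 1L
  calls$p_value[covered] <- binomial_pvalue(calls$count_m[covered],
                                            calls$n[covered], R)
  universe <- calls$n >= min_coverage
  calls$q_value <- NA_real_
  calls$q_value[universe] <- bh_qvalues(calls$p_value[universe])
  ml <- methylation_level(pmax(calls$count_m, 0L), pmax(calls$n, 1L), R)
  calls$ml_uncorrected <- ifelse(covered, ml$ml_uncorrected, NA_real_)
  calls$ml_corrected <- ifelse(covered, ml$ml_corrected, NA_real_)
  calls$is_mc <- !is.na(calls$q_value) & calls$q_value <= q_max
  attr(calls, "R") <- R
  class(calls) <- c("methylation_calls", "data.frame")
  calls
}

#' Site keys of called methylcytosines
#'
#' @param calls A `methylation_calls` data.frame.
#' @return Character vector of `"chrom:pos:strand"` keys of `is_mc` sites.
#' @export
mc_sites <- function(calls) {
  site_key(calls[calls$is_mc, , drop = FALSE])
}

#' Write methylation calls to TSV
#'
#' Cytosine-report columns plus the test and level columns; 1-based
#' positions.
#'
#' @param calls A `methylation_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- data.frame(
    chrom = calls$chrom, pos = calls$pos + 1L, strand = calls$strand,
    count_m = calls$count_m, count_u = calls$count_u,
    context = calls$context, trinucleotide = calls$trinucleotide,
    p_value = calls$p_value, q_value = calls$q_value,
    ml_uncorrected = calls$ml_uncorrected,
    ml_corrected = calls$ml_corrected, is_mc = calls$is_mc
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
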
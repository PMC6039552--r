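test_that("venn partition resolves the seven cells exactly", {
  v <- venn_partition(c("1", "2"), c("2", "3"), c("3", "4"))
  expect_equal(unname(v$cells[c("A_only", "AB_only", "BC_only", "C_only",
                                "B_only", "AC_only", "ABC")]),
               c(1L, 1L, 1L, 1L, 0L, 0L, 0L))
  ids <- letters[1:5]
  same <- venn_partition(ids, ids, ids)
  expect_equal(unname(same$cells["ABC"]), 5L)
  expect_equal(sum(same$cells), 5L)
})

test_that("venn conservation identities hold for random set triples", {
  set.seed(23)
  for (i in 1:20) {
    u <- sample(2000, 800)
    a <- as.character(sample(u, 300))
    b <- as.character(sample(u, 300))
    c <- as.character(sample(u, 300))
    v <- venn_partition(a, b, c)
    cl <- v$cells
    expect_equal(unname(v$totals),
                 c(cl[["A_only"]] + cl[["AB_only"]] + cl[["AC_only"]] + cl[["ABC"]],
                   cl[["B_only"]] + cl[["AB_only"]] + cl[["BC_only"]] + cl[["ABC"]],
                   cl[["C_only"]] + cl[["AC_only"]] + cl[["BC_only"]] + cl[["ABC"]]))
    expect_equal(v$union, sum(cl))
    expect_equal(unname(v$pairwise),
                 c(cl[["AB_only"]], cl[["AC_only"]], cl[["BC_only"]]) + cl[["ABC"]])
    # cells are disjoint
    expect_equal(anyDuplicated(unlist(v$sets)), 0)
  }
})

test_that("retention statistics recover lost/gained/preserved/regained fractions", {
  # identical sets: nothing lost or gained
  v0 <- venn_partition(letters[1:4], letters[1:4], letters[1:4])
  r0 <- retention_stats(v0)
  expect_equal(r0$n_lost, 0L)
  expect_equal(r0$n_gained, 0L)
  expect_true(is.na(r0$preserved_frac))
  expect_true(is.na(r0$regained_frac))
  # disjoint baseline and stress, recovery keeps everything gained
  v1 <- venn_partition(c("a", "b"), c("x", "y", "z"), c("x", "y", "z"))
  r1 <- retention_stats(v1)
  expect_equal(r1$preserved_frac, 1)
  expect_equal(r1$regained_frac, 0)
})

test_that("retention statistics match the simulator's truth ledger exactly", {
  g <- simulate_genome(80000, seed = 81)
  base <- assign_methylome(g, seed = 82)
  spec <- shift_spec(loss_frac = 0.41, gain_frac = 0.0017,
                     preserve_frac = 0.453, regain_frac = 0.0078)
  sh <- apply_shift(base, spec, seed = 83)
  v <- venn_partition(site_key(base)[base$m > 0],
                      site_key(sh$stressed)[sh$stressed$m > 0],
                      site_key(sh$recovered)[sh$recovered$m > 0])
  r <- retention_stats(v)
  led <- sh$ledger
  expect_equal(r$n_lost, length(led$lost))
  expect_equal(r$n_gained, length(led$gained))
  expect_equal(r$preserved_frac, led$preserve_frac)
  expect_equal(r$regained_frac, led$regain_frac)
})

test_that("context proportions cover both denominator modes", {
  g <- make_genome("ACGACGACGACG")
  uni <- enumerate_cytosines(g)
  counts <- data.frame(chrom = uni$chrom, pos = uni$pos, strand = uni$strand,
                       count_m = 10L, count_u = 0L, context = uni$context,
                       trinucleotide = uni$trinucleotide)
  calls <- call_sites(counts, R = 0.003)
  cov_mode <- context_proportions(calls, min_coverage = 5)
  expect_equal(cov_mode$pct[cov_mode$context == "CG"], 100)
  gen_mode <- context_proportions(calls, g, "genomic", min_coverage = 5)
  # every genomic cytosine is covered, so the two modes agree
  expect_equal(cov_mode$pct, gen_mode$pct)
  none <- call_sites(transform(counts, count_m = 0L, count_u = 10L),
                     R = 0.003)
  expect_true(all(context_proportions(none)$pct %in% c(0, NA)))
})

test_that("per-replicon ratios report zero for replicons without calls", {
  g <- make_genome(r1 = "ACGACGACGACG", r2 = "ACGACGACGACG")
  uni <- enumerate_cytosines(g)
  counts <- data.frame(chrom = uni$chrom, pos = uni$pos, strand = uni$strand,
                       count_m = ifelse(uni$chrom == "r1", 10L, 0L),
                       count_u = ifelse(uni$chrom == "r1", 0L, 10L),
                       context = uni$context, trinucleotide = uni$trinucleotide)
  calls <- call_sites(counts, R = 0.003)
  rr <- replicon_site_ratio(calls, g, "genomic")
  expect_true(all(rr$pct[rr$chrom == "r2"] %in% c(0, NA)))
  expect_true(all(rr$pct[rr$chrom == "r1" & rr$n_denom > 0] == 100))
  # single-replicon genome equals genome-wide proportions
  g1 <- make_genome(r1 = "ACGACGACGACG")
  calls1 <- call_sites(counts[counts$chrom == "r1", ], R = 0.003)
  expect_equal(replicon_site_ratio(calls1, g1, "genomic")$pct,
               context_proportions(calls1, g1, "genomic")$pct)
})

test_that("level summaries follow the linear-interpolation quantile convention", {
  calls <- call_sites(make_counts("chr", 0:9, "+", 10L, 0L), R = 0)
  calls$ml_corrected <- seq(0.1, 1, by = 0.1)
  s <- level_summary(calls, strata = NULL)
  expect_equal(s$median, 0.55)
  expect_equal(s$q1, 0.325)
  expect_equal(s$q3, 0.775)
  expect_equal(s$n, 10L)
  one <- calls[5, , drop = FALSE]
  one$ml_corrected <- 0.5
  s1 <- level_summary(one, strata = NULL)
  expect_equal(unlist(s1[c("min", "q1", "median", "q3", "max")]),
               c(min = 0.5, q1 = 0.5, median = 0.5, q3 = 0.5, max = 0.5))
})

test_that("level summaries are permutation invariant and strata-complete", {
  g <- simulate_genome(30000, seed = 91)
  m <- assign_methylome(g, seed = 92)
  sim <- simulate_counts(m, seed = 93)
  calls <- call_sites(sim$counts, 0.003)
  s1 <- level_summary(calls)
  s2 <- level_summary(calls[sample(nrow(calls)), ])
  expect_equal(s1, s2)
  expect_true(all(s1$q1 <= s1$median & s1$median <= s1$q3))
  expect_equal(sum(s1$n), sum(calls$is_mc))
})

test_that("TE-type sites are exclusively within TEs", {
  features <- feature_table(
    genes = data.frame(chrom = "chr", start = 100, end = 200, strand = "+",
                       gene_id = "g1"),
    tes = data.frame(chrom = "chr", start = c(150, 300), end = c(250, 400),
                     te_id = c("te1", "te2")))
  # sites: in gene only, in TE+gene overlap, in TE only x2, outside
  calls <- call_sites(make_counts("chr", c(119, 179, 219, 319, 499), "+",
                                  20L, 0L), R = 0.003)
  res <- te_site_summary(calls, features)
  expect_equal(res$n_te_sites, 2L)   # pos 220 (te1) and 320 (te2), 1-based
  expect_equal(res$n_tes_with_sites, 2L)
  no_te <- te_site_summary(calls, feature_table())
  expect_equal(no_te$n_te_sites, 0L)
  expect_equal(no_te$n_tes_with_sites, 0L)
})

test_that("expression cross-tabulation counts statuses and absences", {
  de <- data.frame(gene = c("g1", "g2", "g3"),
                   status = c("down", "up", "unchanged"))
  xt <- cross_tabulate_expression(list(hyper = c("g1", "g2"),
                                       hypo = c("g3", "g9")), de)
  expect_equal(unname(xt["hyper", ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(xt["hypo", ]), c(0L, 0L, 1L, 1L))
  empty_de <- data.frame(gene = character(0), status = character(0))
  xt0 <- cross_tabulate_expression(list(hyper = "g1", hypo = character(0)),
                                   empty_de)
  expect_equal(unname(xt0["hyper", ]), c(0L, 0L, 0L, 1L))
  expect_error(
    cross_tabulate_expression(list(hyper = "g1", hypo = NULL),
                              data.frame(gene = "g1", status = "higher")),
    "status")
})

test_that("gene-level methylation sets feed the venn partition", {
  features <- feature_table(genes = data.frame(
    chrom = "chr", start = c(100, 300), end = c(200, 400), strand = "+",
    gene_id = c("g1", "g2")))
  calls <- call_sites(make_counts("chr", c(149, 349, 549), "+", 20L, 0L),
                      R = 0.003)
  expect_setequal(methylated_genes(calls, features), c("g1", "g2"))
  none <- call_sites(make_counts("chr", 549, "+", 20L, 0L), R = 0.003)
  expect_equal(methylated_genes(none, features), character(0))
})
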
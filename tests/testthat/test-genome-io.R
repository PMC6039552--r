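test_that("context classification follows the H-rule for every downstream pair", {
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) {
    g <- make_genome(paste0("A", "C", b1, b2, "A"))
    expected <- if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
    expect_identical(classify_context(g, "r1", 1L, "+"), expected)
  }
  # worked examples
  expect_identical(classify_context(make_genome("ACGTT"), "r1", 1, "+"), "CG")
  expect_identical(classify_context(make_genome("ACAGT"), "r1", 1, "+"), "CHG")
  expect_identical(classify_context(make_genome("ACAAT"), "r1", 1, "+"), "CHH")
  # minus strand: C at forward G, downstream runs leftward complemented
  expect_identical(classify_context(make_genome("TCGAA"), "r1", 2, "-"), "CG")
  expect_identical(classify_context(make_genome("TAGAA"), "r1", 2, "-"), "CHH")
})

test_that("context is undefined near replicon ends and at N", {
  g <- make_genome("ACGNC")
  expect_true(is.na(classify_context(g, "r1", 4, "+")))   # < 2 downstream
  g2 <- make_genome("ACNGA")
  expect_true(is.na(classify_context(g2, "r1", 1, "+")))  # N downstream
  expect_error(classify_context(make_genome("AAAAA"), "r1", 1, "+"),
               "not C")
})

test_that("minus-strand contexts equal plus-strand contexts on the reverse complement", {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  set.seed(11)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    g <- make_genome(s)
    grc <- make_genome(rc(s))
    L <- nchar(s)
    fwd <- enumerate_cytosines(g)
    bwd <- enumerate_cytosines(grc)
    # map (strand, pos) on g to the reverse complement
    key_f <- sprintf("%s:%d:%s", ifelse(fwd$strand == "+", "f", "r"),
                     ifelse(fwd$strand == "+", fwd$pos, L - 1 - fwd$pos),
                     fwd$context)
    key_b <- sprintf("%s:%d:%s", ifelse(bwd$strand == "-", "f", "r"),
                     ifelse(bwd$strand == "-", L - 1 - bwd$pos, bwd$pos),
                     bwd$context)
    expect_setequal(key_f, key_b)
  }
})

test_that("cytosine enumeration matches direct string counting", {
  set.seed(7)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    g <- make_genome(s)
    sites <- enumerate_cytosines(g)
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    n_plus <- sum(ch[seq_len(L - 2)] == "C")
    n_minus <- sum(ch[3:L] == "G")
    expect_equal(sum(sites$strand == "+"), n_plus)
    expect_equal(sum(sites$strand == "-"), n_minus)
    # deterministic ordering and strand-specific sites (no CG collapsing)
    expect_false(is.unsorted(sites$pos))
    expect_equal(anyDuplicated(site_key(sites)), 0)
    # trinucleotide starts with C and encodes the context
    expect_true(all(substr(sites$trinucleotide, 1, 1) == "C"))
    expect_identical(
      sites$context,
      ifelse(substr(sites$trinucleotide, 2, 2) == "G", "CG",
             ifelse(substr(sites$trinucleotide, 3, 3) == "G", "CHG", "CHH")))
  }
})

test_that("enumeration boundary cases", {
  expect_equal(nrow(enumerate_cytosines(make_genome("CG"))), 0)
  g <- make_genome("CCGG")
  sites <- enumerate_cytosines(g)
  expect_equal(nrow(sites), 4)
  expect_setequal(
    sprintf("%d%s%s", sites$pos, sites$strand, sites$context),
    c("0+CHG", "1+CG", "2-CG", "3-CHG"))
  expect_equal(nrow(enumerate_cytosines(make_genome("ATTATA"))), 0)
})

test_that("FASTA round trip uppercases, preserves order, rejects junk", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">chrA first", "acgtACGT", ">chrB", "GGGG"), fa)
  g <- read_genome(fa)
  expect_identical(names(g), c("chrA", "chrB"))
  expect_identical(unclass(g)[["chrA"]], "ACGTACGT")
  expect_identical(genome_lengths(g), c(chrA = 8L, chrB = 4L))
  out <- tempfile(fileext = ".fasta")
  write_genome(g, out)
  expect_identical(unclass(read_genome(out)), unclass(g))
  bad <- tempfile()
  writeLines(c("ACGT"), bad)
  expect_error(read_genome(bad), "line 1")
})

test_that("counts table round-trips with the 1-based position convention", {
  counts <- make_counts("chr", c(0, 9, 99), c("+", "-", "+"),
                        c(3, 0, 12), c(7, 20, 0),
                        context = c("CG", "CHG", "CHH"),
                        trinucleotide = c("CGA", "CAG", "CTT"))
  path <- tempfile(fileext = ".tsv")
  write_counts_table(counts, path)
  raw <- read.delim(path, header = FALSE)
  expect_equal(raw$V2, c(1, 10, 100))  # written 1-based
  back <- read_counts_table(path)
  expect_equal(back, counts)
})

test_that("counts table errors carry the offending line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chr\t1\t+\t3\t7\tCG\tCGA",
               "chr\t2\t+\t-1\t7\tCG\tCGA"), path)
  expect_error(read_counts_table(path), "line 2")
  writeLines(c("chr\t1\t*\t3\t7\tCG\tCGA"), path)
  expect_error(read_counts_table(path), "strand")
  writeLines(c("chr\t1\t+\t3\t7\tCpG\tCGA"), path)
  expect_error(read_counts_table(path), "context")
  writeLines(c("chr\t1\t+\t3.5\t7\tCG\tCGA"), path)
  expect_error(read_counts_table(path), "integer")
})

test_that("region assignment is total and follows the precedence rule", {
  # gene A body 201-500 (+); gene B 550-800 (+) so B's upstream 450-549
  # overlaps A's body and A's downstream
  features <- feature_table(genes = data.frame(
    chrom = "chr", start = c(201, 550), end = c(500, 800),
    strand = "+", gene_id = c("A", "B")))
  sites <- data.frame(chrom = "chr",
                      pos = c(300, 470, 520, 140, 950) - 1L,
                      strand = "+")
  out <- assign_region(sites, features, upstream_len = 100,
                       downstream_len = 100)
  expect_equal(as.character(out$region),
               c("gene_body",   # inside A only
                 "gene_body",   # A body beats B upstream
                 "upstream",    # B upstream beats A downstream
                 "upstream",    # 10 bp 5' of A start within 100 bp flank
                 "intergenic"))
  expect_equal(out$gene_id, c("A", "A", "B", "A", NA))
  expect_false(any(is.na(out$region)))
})
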
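#' Simulate a random genome
#'
#' Draws i.i.d. bases at a target GC content, split into `n_replicons`
#' replicons of as-equal-as-possible length (a chromosome plus plasmids
#' analogue). Fully reproducible for a fixed seed.
#'
#' @param length Total genome length in bp (>= 1).
#' @param gc_frac Target GC fraction in `[0,1]`. Default 0.475, a typical
#'   cyanobacterial chromosome value.
#' @param n_replicons Number of replicons (default 1); named `repl1`,
#'   `repl2`, ...
#' @param seed Integer RNG seed.
#' @return A `bs_genome`.
#' @export
simulate_genome <- function(length, gc_frac = 0.475, n_replicons = 1L,
                            seed = 1L) {
  if (length < 1) stop("genome length must be >= 1")
  if (gc_frac < 0 || gc_frac > 1) stop("gc_frac must be in [0,1]")
  set.seed(seed)
  sizes <- diff(round(seq(0, length, length.out = n_replicons + 1L)))
  p <- c(A = (1 - gc_frac) / 2, C = gc_frac / 2,
         G = gc_frac / 2, T = (1 - gc_frac) / 2)
  seqs <- vapply(sizes, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- paste0("repl", seq_len(n_replicons))
  structure(seqs, class = "bs_genome")
}

default_prevalence <- c(CG = 0.0305, CHG = 0.0090, CHH = 0.0103)
default_level_shape <- list(CG = c(2, 5), CHG = c(2, 5), CHH = c(2, 5))

#' Assign a true methylome to a genome
#'
#' Each context-defined cytosine is independently methylated with its
#' context's prevalence; methylated sites draw a true methylation level
#' `m` from a per-context Beta distribution, unmethylated sites have
#' `m = 0`. Default prevalences are 3.05% CG, 0.90% CHG, 1.03% CHH — the
#' unstressed-condition values the pipeline emulates.
#'
#' @param genome A `bs_genome`.
#' @param prevalence Named vector of per-context methylation prevalences.
#' @param level_shape Named list of `c(alpha, beta)` Beta parameters per
#'   context for the level distribution of methylated sites.
#' @param seed Integer RNG seed.
#' @return A `true_methylome`: the cytosine universe data.frame
#'   ([enumerate_cytosines()] columns) with an added `m` column; Beta
#'   parameters kept in attribute `level_shape`.
#' @export
assign_methylome <- function(genome, prevalence = default_prevalence,
                             level_shape = default_level_shape, seed = 1L) {
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must be in [0,1]")
  }
  set.seed(seed)
  sites <- enumerate_cytosines(genome)
  m <- numeric(nrow(sites))
  for (ctx in names(prevalence)) {
    idx <- which(sites$context == ctx)
    hit <- idx[stats::runif(length(idx)) < prevalence[[ctx]]]
    sh <- level_shape[[ctx]]
    m[hit] <- stats::rbeta(length(hit), sh[1], sh[2])
  }
  sites$m <- m
  structure(sites, class = c("true_methylome", "data.frame"),
            level_shape = level_shape)
}

#' Specification of a stress-and-recovery methylome shift
#'
#' @param loss_frac Fraction of methylated sites fully demethylated under
#'   stress. Default 0.41 (the observed ~40% site loss).
#' @param gain_frac Fraction of unmethylated sites gaining methylation under
#'   stress. Default 0.0017, which at the default prevalences makes the
#'   gained set about 12% of the baseline methylated set.
#' @param level_delta Additive increase of `m` at surviving sites under
#'   stress, clipped at 1. Default 0.10 (stress raises levels at sites that
#'   keep their methylation).
#' @param preserve_frac Fraction of stress-gained sites preserved after
#'   recovery. Default 0.453 (">45% preserved").
#' @param regain_frac Fraction of stress-lost sites re-methylated after
#'   recovery. Default 0.0078 ("about 1% regained").
#' @return A `shift_spec` list.
#' @export
shift_spec <- function(loss_frac = 0.41, gain_frac = 0.0017,
                       level_delta = 0.10, preserve_frac = 0.453,
                       regain_frac = 0.0078) {
  fr <- c(loss_frac, gain_frac, preserve_frac, regain_frac)
  if (any(fr < 0 | fr > 1)) stop("shift fractions must be in [0,1]")
  structure(list(loss_frac = loss_frac, gain_frac = gain_frac,
                 level_delta = level_delta, preserve_frac = preserve_frac,
                 regain_frac = regain_frac), class = "shift_spec")
}

#' Apply a stress/recovery shift to a true methylome
#'
#' Produces the stressed methylome (a fraction of methylated sites lose all
#' methylation; survivors' levels rise by `level_delta`; a small fraction of
#' unmethylated sites gain methylation) and the recovered methylome (a
#' fraction of the stress-gained sites is preserved and a small fraction of
#' the lost sites is regained at its original level; surviving sites keep
#' their elevated level). A truth ledger records the exact site sets.
#'
#' @param base A `true_methylome`.
#' @param spec A [shift_spec()].
#' @param seed Integer RNG seed.
#' @return List with `stressed` and `recovered` (`true_methylome`s on the
#'   same universe) and `ledger`: list of site-key vectors `lost`,
#'   `survived`, `gained`, `preserved`, `regained`, plus the realised
#'   fractions.
#' @export
apply_shift <- function(base, spec = shift_spec(), seed = 1L) {
  stopifnot(inherits(base, "true_methylome"), inherits(spec, "shift_spec"))
  set.seed(seed)
  keys <- site_key(base)
  meth <- which(base$m > 0)
  unmeth <- which(base$m == 0)
  n_lost <- round(spec$loss_frac * length(meth))
  lost <- sort(sample(meth, n_lost))
  survived <- setdiff(meth, lost)
  n_gain <- round(spec$gain_frac * length(unmeth))
  gained <- sort(sample(unmeth, n_gain))

  shapes <- attr(base, "level_shape")
  stressed <- base
  stressed$m[lost] <- 0
  stressed$m[survived] <- pmin(1, base$m[survived] + spec$level_delta)
  gm <- numeric(length(gained))
  for (ctx in unique(base$context[gained])) {
    sh <- shapes[[ctx]]
    sel <- base$context[gained] == ctx
    gm[sel] <- pmin(1, stats::rbeta(sum(sel), sh[1], sh[2]) + spec$level_delta)
  }
  stressed$m[gained] <- gm

  preserved <- sort(sample(gained, round(spec$preserve_frac * length(gained))))
  regained <- sort(sample(lost, round(spec$regain_frac * length(lost))))
  recovered <- base
  recovered$m[] <- 0
  recovered$m[survived] <- stressed$m[survived]
  recovered$m[preserved] <- stressed$m[preserved]
  recovered$m[regained] <- base$m[regained]

  ledger <- list(
    lost = keys[lost], survived = keys[survived], gained = keys[gained],
    preserved = keys[preserved], regained = keys[regained],
    loss_frac = if (length(meth)) n_lost / length(meth) else NA_real_,
    preserve_frac = if (length(gained)) {
      length(preserved) / length(gained)
    } else NA_real_,
    regain_frac = if (length(lost)) {
      length(regained) / length(lost)
    } else NA_real_
  )
  list(stressed = stressed, recovered = recovered, ledger = ledger)
}

#' Coverage model for read-count simulation
#'
#' @param family `"poisson"`, `"negative_binomial"`, or `"fixed"` (constant
#'   depth, useful for exact-depth calibration checks).
#' @param mean Mean coverage per site (> 0). Default 50, a desk-scale stand-in
#'   for the deep sequencing the pipeline emulates.
#' @param dispersion Negative-binomial size parameter (variance =
#'   mean + mean^2/dispersion); required for that family.
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(family = c("poisson", "negative_binomial", "fixed"),
                           mean = 50, dispersion = NULL) {
  family <- match.arg(family)
  if (mean <= 0) stop("mean coverage must be > 0")
  if (family == "negative_binomial" &&
      (is.null(dispersion) || dispersion <= 0)) {
    stop("negative_binomial requires dispersion > 0")
  }
  structure(list(family = family, mean = mean, dispersion = dispersion),
            class = "coverage_model")
}

draw_coverage <- function(model, n) {
  switch(model$family,
    poisson = stats::rpois(n, model$mean),
    negative_binomial = stats::rnbinom(n, mu = model$mean,
                                       size = model$dispersion),
    fixed = rep.int(as.integer(round(model$mean)), n)
  )
}

#' Simulate bisulfite read counts from a true methylome
#'
#' Per site, total depth `n` is drawn from the coverage model and the
#' methylated read count `k ~ Binomial(n, m + (1-m) R)`: methylated
#' molecules are fully protected from conversion while unmethylated ones
#' fail to convert with probability `R`. This is exactly the error model the
#' level correction `(ML - R)/(1 - R)` inverts. A spike-in control table is
#' generated alongside from a fully unmethylated control genome, mimicking
#' the lambda-phage conversion control.
#'
#' @param methylome A `true_methylome`.
#' @param coverage A [coverage_model()].
#' @param R Non-conversion rate in `[0,1)`. Default 0.003 (conversion rate
#'   99.7%).
#' @param seed Integer RNG seed.
#' @param control_length Length in bp of the unmethylated control genome
#'   (default 20000).
#' @return List with `counts` and `control`, both count-table data.frames
#'   (see [read_counts_table()]), and `R` (the true rate used).
#' @export
simulate_counts <- function(methylome, coverage = coverage_model(),
                            R = 0.003, seed = 1L, control_length = 20000L) {
  if (R < 0 || R >= 1) stop("non-conversion rate R must be in [0,1)")
  stopifnot(inherits(methylome, "true_methylome"))
  set.seed(seed)
  n <- draw_coverage(coverage, nrow(methylome))
  p <- methylome$m + (1 - methylome$m) * R
  k <- stats::rbinom(nrow(methylome), n, p)
  counts <- data.frame(
    chrom = methylome$chrom, pos = methylome$pos, strand = methylome$strand,
    count_m = k, count_u = n - k, context = methylome$context,
    trinucleotide = methylome$trinucleotide, stringsAsFactors = FALSE
  )
  ctrl_genome <- simulate_genome(control_length, gc_frac = 0.5,
                                 seed = seed + 101L)
  names(ctrl_genome) <- "control"
  ctrl_sites <- enumerate_cytosines(ctrl_genome)
  nc <- draw_coverage(coverage, nrow(ctrl_sites))
  kc <- stats::rbinom(nrow(ctrl_sites), nc, R)
  control <- data.frame(
    chrom = ctrl_sites$chrom, pos = ctrl_sites$pos,
    strand = ctrl_sites$strand, count_m = kc, count_u = nc - kc,
    context = ctrl_sites$context, trinucleotide = ctrl_sites$trinucleotide,
    stringsAsFactors = FALSE
  )
  list(counts = counts, control = control, R = R)
}

#' Simulate a full three-condition bisulfite experiment
#'
#' Convenience wrapper chaining [simulate_genome()], [assign_methylome()],
#' [apply_shift()] and [simulate_counts()] into baseline / stressed /
#' recovered count tables with one truth ledger. One master seed derives
#' fixed per-stage streams so every stage is individually reproducible.
#'
#' @param genome_length Genome length in bp (default 200000).
#' @param n_replicons Number of replicons (default 1).
#' @param prevalence,level_shape Passed to [assign_methylome()].
#' @param spec A [shift_spec()].
#' @param coverage A [coverage_model()].
#' @param R True non-conversion rate.
#' @param seed Master seed.
#' @return List: `genome`, `methylomes` (base/stressed/recovered),
#'   `ledger`, `counts` (named list of three count tables), `control`
#'   (one control table, shared), `R`.
#' @export
simulate_experiment <- function(genome_length = 200000L, n_replicons = 1L,
                                prevalence = default_prevalence,
                                level_shape = default_level_shape,
                                spec = shift_spec(),
                                coverage = coverage_model(),
                                R = 0.003, seed = 1L) {
  seeds <- derive_seeds(seed, 5L)
  genome <- simulate_genome(genome_length, n_replicons = n_replicons,
                            seed = seeds[1])
  base <- assign_methylome(genome, prevalence, level_shape, seed = seeds[2])
  shifted <- apply_shift(base, spec, seed = seeds[3])
  sim_base <- simulate_counts(base, coverage, R, seed = seeds[4])
  sim_str <- simulate_counts(shifted$stressed, coverage, R, seed = seeds[5])
  sim_rec <- simulate_counts(shifted$recovered, coverage, R,
                             seed = seeds[5] + 1L)
  list(
    genome = genome,
    methylomes = list(base = base, stressed = shifted$stressed,
                      recovered = shifted$recovered),
    ledger = shifted$ledger,
    counts = list(base = sim_base$counts, stressed = sim_str$counts,
                  recovered = sim_rec$counts),
    control = sim_base$control,
    R = R
  )
}

# Deterministic per-stage seed streams from one master seed, kept within
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 1000000L) * 1000L + seq_len(n)
}
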
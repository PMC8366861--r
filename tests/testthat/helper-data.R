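# Shared fixtures and independent oracles, built in code.

# 2-population, 2-nuclear + 1-cp toy dataset with hand-checkable counts
toy_dataset <- function() {
  loci <- data.frame(
    name = c("L1", "L2", "C1"),
    genome = c("nuclear", "nuclear", "chloroplast"),
    motif_length = c(2L, 2L, 1L),
    allele_unit = "fragment_bp", stringsAsFactors = FALSE)
  pops <- data.frame(pop_id = c("A", "B"), stringsAsFactors = FALSE)
  ind <- data.frame(ind_id = sprintf("i%d", 1:6),
                    pop_id = rep(c("A", "B"), each = 3),
                    stringsAsFactors = FALSE)
  a1 <- matrix(c(100, 100, 102, 104, 104, 104,
                 10, 12, 10, 14, 14, 12), 6, 2)
  a2 <- matrix(c(102, 100, 102, 104, 106, 104,
                 12, 12, 10, 14, 12, 12), 6, 2)
  cp <- matrix(c(5, 5, 6, 7, 7, 5), 6, 1)
  geno_dataset(loci, pops, ind, a1, a2, cp)
}

# dataset from explicit per-population genotype matrices (one nuclear locus
# per element of `mats`, rows = individuals, cols = the two alleles)
dataset_from_genotypes <- function(pop_genos, motif_length = 2L) {
  # pop_genos: list over populations, each a list over loci of 2-col matrices
  n_loci <- length(pop_genos[[1]])
  pops <- names(pop_genos)
  a1 <- do.call(rbind, lapply(pop_genos, function(pl)
    do.call(cbind, lapply(pl, function(m) m[, 1]))))
  a2 <- do.call(rbind, lapply(pop_genos, function(pl)
    do.call(cbind, lapply(pl, function(m) m[, 2]))))
  n_i <- vapply(pop_genos, function(pl) nrow(pl[[1]]), 0L)
  loci <- data.frame(name = sprintf("L%d", seq_len(n_loci)),
                     genome = "nuclear", motif_length = motif_length,
                     allele_unit = "fragment_bp", stringsAsFactors = FALSE)
  geno_dataset(loci, data.frame(pop_id = pops, stringsAsFactors = FALSE),
               data.frame(ind_id = sprintf("i%d", seq_len(sum(n_i))),
                          pop_id = rep(pops, n_i), stringsAsFactors = FALSE),
               a1, a2, NULL)
}

# HWE genotypes for one locus from allele frequencies
hwe_genotypes <- function(n, freqs) {
  alleles <- seq_along(freqs)
  cbind(sample(alleles, n, TRUE, prob = freqs),
        sample(alleles, n, TRUE, prob = freqs)) + 100L
}

# Independent WC-1984 oracle via the nested-ANOVA route (sums of squares for
# copies within individuals within populations), algebraically distinct from
# the package's direct component formulas.
wc_anova_oracle <- function(geno_list) {
  geno_list <- lapply(geno_list, function(g)
    g[stats::complete.cases(g), , drop = FALSE])
  r <- length(geno_list)
  n_i <- vapply(geno_list, nrow, 0L)
  n_tot <- sum(n_i)
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  alleles <- sort(unique(unlist(geno_list)))
  a <- b <- cc <- 0
  for (al in alleles) {
    SSP <- SSI <- SSG <- 0
    xbar <- mean(unlist(lapply(geno_list, function(g) as.numeric(g == al))))
    for (p in seq_len(r)) {
      x <- (geno_list[[p]] == al) * 1
      xi <- rowMeans(x)
      xp <- mean(x)
      SSG <- SSG + sum((x - xi)^2)
      SSI <- SSI + 2 * sum((xi - xp)^2)
      SSP <- SSP + 2 * nrow(x) * (xp - xbar)^2
    }
    MSP <- SSP / (r - 1)
    MSI <- SSI / (n_tot - r)
    MSG <- SSG / n_tot
    a <- a + (MSP - MSI) / (2 * nc)
    b <- b + (MSI - MSG) / 2
    cc <- cc + MSG
  }
  a / (a + b + cc)
}

# Brute-force rarefaction oracle: average distinct-allele count over every
# g-subset of the N gene copies.
brute_force_ar <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(seq_along(copies), g)
  mean(apply(subs, 2L, function(ix) length(unique(copies[ix]))))
}

# A hand-rolled reference table with analytically controlled statistics
# (no coalescent simulation), for ABC unit tests.
fake_ref_table <- function(n_per = 2000L, shift = c(S1 = 0, S2 = 0,
                                                    S3 = 0, S4 = 0),
                           n_stats = 6L) {
  scen <- rep(names(shift), each = n_per)
  stats <- matrix(rnorm(length(scen) * n_stats), ncol = n_stats)
  stats <- stats + shift[scen]
  nm <- summary_stat_names()[seq_len(n_stats)]
  colnames(stats) <- nm
  params <- data.frame(matrix(NA_real_, length(scen),
                              length(scenario_param_names())))
  names(params) <- scenario_param_names()
  params$N1 <- stats::rnorm(length(scen), 5000, 2500)
  params$N1 <- pmax(params$N1, 10)
  params$NA1 <- pmax(stats::rnorm(length(scen), 5000, 2500), 10)
  structure(list(scenario = factor(scen, levels = names(shift)),
                 params = params, stats = stats,
                 scale = list(mean = colMeans(stats),
                              sd = apply(stats, 2, sd))),
            class = "ref_table")
}
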
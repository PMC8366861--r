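#' Locus configuration for simulated datasets
#'
#' Default emulates the study design: 8 nuclear loci (7 dinucleotide, 1
#' trinucleotide) and 3 fully linked chloroplast loci (two mononucleotide,
#' one scored through an 18-bp indel). Simulated alleles are repeat counts
#' (`allele_unit = "repeat_count"`).
#'
#' @param n_nu number of nuclear loci.
#' @param n_cp number of chloroplast loci.
#' @return loci data.frame as used by [geno_dataset()].
#' @export
default_loci <- function(n_nu = 8L, n_cp = 3L) {
  motif_nu <- c(rep(2L, max(0L, n_nu - 1L)), if (n_nu >= 1L) 3L)
  motif_cp <- c(1L, 1L, 18L)[seq_len(n_cp)]
  data.frame(
    name = c(sprintf("SFnu%02d", seq_len(n_nu)),
             sprintf("cp%02d", seq_len(n_cp))),
    genome = rep(c("nuclear", "chloroplast"), c(n_nu, n_cp)),
    motif_length = c(motif_nu, motif_cp),
    allele_unit = "repeat_count",
    stringsAsFactors = FALSE)
}

#' Simulate a microsatellite dataset under a demographic scenario
#'
#' Continuous-time structured coalescent, backward in time, with
#' piecewise-constant deme sizes, merge/admixture/resize events, and a
#' generalized stepwise mutation model (step = 1 + Geometric(P), sign
#' equiprobable, reflection at a floor of 2 repeats). Nuclear loci are
#' independent; chloroplast loci share a single gene tree (full linkage) and
#' a haploid effective copy number of `cp_factor * N` per deme (paternal
#' transmission through pollen: one transmitted copy per individual).
#'
#' @param scenario one of `"S1".."S4"`.
#' @param par named parameter vector/list (see [scenario_param_names()]).
#' @param n_dip diploid individuals sampled per deme (length 4 or scalar).
#' @param loci loci data.frame from [default_loci()].
#' @param cp_factor chloroplast copy-number multiplier on N.
#' @param root_state repeat count at the tree root.
#' @return a [geno_dataset()] with populations named after the demes.
#' @export
simulate_dataset <- function(scenario, par, n_dip = 25L,
                             loci = default_loci(), cp_factor = 1,
                             root_state = 100L) {
  if (length(n_dip) == 1L) n_dip <- rep(n_dip, 4L)
  stopifnot(length(n_dip) == 4L, all(n_dip >= 1L))
  par <- as.list(par)
  n_nu_loci <- sum(loci$genome == "nuclear")
  n_cp_loci <- sum(loci$genome == "chloroplast")
  ev_nu <- scenario_events(scenario, par, "nuclear")
  ev_cp <- scenario_events(scenario, par, "chloroplast", cp_factor)
  sim <- cpp_sim_msat(as.integer(2L * n_dip), ev_nu$G0, ev_nu$events,
                      n_nu_loci, par$mu_nu, par$P_nu,
                      as.integer(n_dip), ev_cp$G0, ev_cp$events,
                      n_cp_loci, par$mu_cp, par$P_cp, as.integer(root_state))
  ntot <- sum(n_dip)
  # nuclear copies are laid out deme-block-wise, two blocks per deme
  a1 <- matrix(NA_integer_, ntot, n_nu_loci)
  a2 <- matrix(NA_integer_, ntot, n_nu_loci)
  off_cop <- 0L; off_ind <- 0L
  for (d in 1:4) {
    idx <- off_cop + seq_len(2L * n_dip[d])
    rows <- off_ind + seq_len(n_dip[d])
    a1[rows, ] <- sim$nu[idx[seq_len(n_dip[d])], , drop = FALSE]
    a2[rows, ] <- sim$nu[idx[n_dip[d] + seq_len(n_dip[d])], , drop = FALSE]
    off_cop <- off_cop + 2L * n_dip[d]
    off_ind <- off_ind + n_dip[d]
  }
  pops <- data.frame(pop_id = DEME_NAMES, stringsAsFactors = FALSE)
  ind <- data.frame(
    ind_id = sprintf("%s_%03d", rep(DEME_NAMES, n_dip),
                     unlist(lapply(n_dip, seq_len))),
    pop_id = rep(DEME_NAMES, n_dip), stringsAsFactors = FALSE)
  geno_dataset(loci, pops, ind, a1, a2, sim$cp)
}

#' Summary-statistic catalog
#'
#' Names of the per-marker-class statistics: single-deme `nal` (mean allele
#' number), `he` (mean genic diversity), `var` (mean allele-size variance),
#' `mgw` (mean Garza-Williamson M); pairwise `fst` (multilocus WC theta on
#' gene copies), `hep` (pooled-pair genic diversity), `dmu2` ((delta-mu)^2
#' distance), `das` (shared-allele distance).
#'
#' @return character vector of the full statistic vector's names.
#' @export
summary_stat_names <- function() {
  demes <- DEME_NAMES
  pairs <- combn(demes, 2, paste, collapse = ".")
  one <- c(outer(c("nal", "he", "var", "mgw"), demes, function(s, d)
    paste0(s, "_", d)))
  two <- c(outer(c("fst", "hep", "dmu2", "das"), pairs, function(s, d)
    paste0(s, "_", d)))
  c(paste0("nu_", c(one, two)), paste0("cp_", c(one, two)))
}

#' Summary statistics of a four-deme dataset
#'
#' Computes the [summary_stat_names()] vector on the gene copies of a
#' dataset (diploid genotypes contribute two copies). Allele sizes are used
#' as stored; for simulated data these are repeat counts. Undefined
#' statistics (e.g. size variance of a monomorphic locus) are 0.
#'
#' @param ds a [geno_dataset()] whose populations are the four demes.
#' @return named numeric vector.
#' @export
summary_stats <- function(ds) {
  demes <- ds$pops$pop_id
  stopifnot(length(demes) == 4L)
  gnu <- gene_copies(ds, "nuclear")
  gcp <- gene_copies(ds, "chloroplast")
  di <- function(pop) as.integer(factor(pop, levels = demes)) - 1L
  s_nu <- cpp_gene_stats(gnu$alleles, di(gnu$pop), 4L)
  s_cp <- if (ncol(gcp$alleles) > 0)
    cpp_gene_stats(gcp$alleles, di(gcp$pop), 4L)
  else numeric(length(s_nu))
  setNames(c(s_nu, s_cp), summary_stat_names())
}

#' Build an ABC reference table
#'
#' Draws `n_per_scenario` parameter vectors per scenario from the priors,
#' simulates each dataset and stores its summary statistics. Deterministic
#' given the RNG state (`set.seed()` before calling).
#'
#' @param spec a [prior_spec()].
#' @param scenarios scenario subset (default all four).
#' @param n_per_scenario simulations per scenario (the study scale is 1e6;
#'   default is the desk scale 20000 used throughout the package).
#' @param n_dip diploids sampled per deme.
#' @param loci loci configuration.
#' @param cp_factor chloroplast copy-number multiplier.
#' @param progress print progress every 5000 rows.
#' @return list of class `ref_table`: `scenario` (factor), `params`
#'   (data.frame), `stats` (matrix), `scale` (per-column mean/sd).
#' @export
build_reference_table <- function(spec = prior_spec(), scenarios = SCENARIOS,
                                  n_per_scenario = 20000L, n_dip = 25L,
                                  loci = default_loci(), cp_factor = 1,
                                  progress = FALSE) {
  stopifnot(n_per_scenario >= 1L)
  all_par <- list(); all_sc <- character(0)
  stats <- matrix(NA_real_, length(scenarios) * n_per_scenario,
                  length(summary_stat_names()))
  colnames(stats) <- summary_stat_names()
  row <- 0L
  for (sc in scenarios) {
    par <- sample_priors(spec, sc, n_per_scenario)
    all_par[[sc]] <- par
    all_sc <- c(all_sc, rep(sc, n_per_scenario))
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      ds <- simulate_dataset(sc, par[i, ], n_dip, loci, cp_factor)
      stats[row, ] <- summary_stats(ds)
      if (progress && row %% 5000L == 0L)
        message("reference table: ", row, " rows")
    }
  }
  mu <- colMeans(stats)
  sdv <- apply(stats, 2L, sd)
  structure(list(scenario = factor(all_sc, levels = scenarios),
                 params = do.call(rbind, all_par),
                 stats = stats,
                 scale = list(mean = mu, sd = sdv)),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat(sprintf("ABC reference table: %d rows (%s), %d statistics\n",
              nrow(x$stats),
              paste(levels(x$scenario), table(x$scenario), sep = ":",
                    collapse = ", "),
              ncol(x$stats)))
  invisible(x)
}
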
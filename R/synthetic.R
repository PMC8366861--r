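#' Configuration for study-shaped synthetic data
#'
#' Defaults emulate the study's sampling design: 45 populations (15 western
#' Pyrenean, 15 admixed central, 15 eastern) of 30 diploids each, genotyped
#' at 8 nuclear and 3 linked chloroplast loci, drawn from a hierarchical
#' split demography (scenario S2) with known parameters; longitudes span
#' about 4 degrees west to east.
#'
#' @param n_pops populations per group, named vector
#'   `c(PYR_W = , PYR_C = , PYR_E = )` (the central group is the admixed
#'   deme).
#' @param n_ind diploid individuals per population.
#' @param scenario generating scenario.
#' @param par generating parameters; default: hierarchical split at
#'   `T1 = 28000 > T2 = 24000 > T3 = 22000` generations, all sizes 5000, no
#'   size change, nuclear mutation rate 5e-4, chloroplast 1e-4, strict SMM.
#' @param lon_range longitude span (decimal degrees).
#' @param seed RNG seed recorded in the truth record.
#' @return list of class `synth_config`.
#' @export
synthetic_study_config <- function(n_pops = c(PYR_W = 15L, PYR_C = 15L,
                                              PYR_E = 15L),
                                   n_ind = 30L, scenario = "S2",
                                   par = NULL, lon_range = c(-1.5, 2.5),
                                   seed = 1L) {
  if (is.null(par))
    par <- list(mu_nu = 5e-4, P_nu = 0, mu_cp = 1e-4, P_cp = 0,
                N1 = 5000, N2 = 5000, N3 = 5000, N4 = 5000,
                NA1 = 5000, NA2 = 5000, NA3 = 5000, NA4 = 5000,
                Nanc = 5000, T1 = 28000, T2 = 24000, T3 = 22000,
                Ta = 15000, Tb = 15000, Tc = 15000, Td = 15000,
                r1 = NA_real_, r2 = 0.5)
  structure(list(n_pops = n_pops, n_ind = n_ind, scenario = scenario,
                 par = par, lon_range = lon_range, seed = seed),
            class = "synth_config")
}

#' Generate a study-shaped genotype dataset with known truth
#'
#' Simulates the configured scenario with one coalescent deme per population
#' group (western, central/admixed, eastern Pyrenees; the Alpine deme is
#' simulated but not split into populations unless `include_alps`), then
#' partitions each deme's individuals into populations arrayed on a
#' west-east longitude axis. A fixed seed makes the output reproducible
#' byte for byte.
#'
#' @param cfg a [synthetic_study_config()].
#' @param include_alps also emit Alpine populations (same size), default
#'   `FALSE`.
#' @return list with `ds` (a [geno_dataset()] with populated metadata) and
#'   `truth` (generating scenario, parameters, per-population deme and seed).
#' @export
generate_study_like_dataset <- function(cfg = synthetic_study_config(),
                                        include_alps = FALSE) {
  set.seed(cfg$seed)
  groups <- c("PYR_W", "PYR_C", "PYR_E")
  stopifnot(all(groups %in% names(cfg$n_pops)))
  n_alps <- if (include_alps) max(1L, cfg$n_pops[[1]]) else 0L
  # demes: Alps, PyrW, PyrE, PyrAdm; PYR_C samples the admixed deme
  deme_of <- c(PYR_W = "PyrW", PYR_C = "PyrAdm", PYR_E = "PyrE")
  n_dip <- c(Alps = n_alps * cfg$n_ind,
             PyrW = cfg$n_pops[["PYR_W"]] * cfg$n_ind,
             PyrE = cfg$n_pops[["PYR_E"]] * cfg$n_ind,
             PyrAdm = cfg$n_pops[["PYR_C"]] * cfg$n_ind)
  n_dip[n_dip == 0L] <- 1L   # the simulator needs >= 1 individual per deme
  sim <- simulate_dataset(cfg$scenario, cfg$par,
                          n_dip = n_dip[c("Alps", "PyrW", "PyrE", "PyrAdm")],
                          loci = default_loci())
  # carve populations out of each deme, west to east
  pop_rows <- list(); meta <- list(); truth_pop <- list()
  total_p <- sum(cfg$n_pops[groups]) + n_alps
  lon_seq <- seq(cfg$lon_range[1], cfg$lon_range[2],
                 length.out = sum(cfg$n_pops[groups]))
  k <- 0L
  for (g in c("PYR_W", "PYR_C", "PYR_E")) {
    d <- deme_of[[g]]
    rows <- which(sim$ind$pop_id == d)
    for (j in seq_len(cfg$n_pops[[g]])) {
      k <- k + 1L
      pid <- sprintf("%s%02d", g, j)
      take <- rows[seq_len(cfg$n_ind)]
      rows <- setdiff(rows, take)
      pop_rows[[pid]] <- take
      meta[[pid]] <- data.frame(
        pop_id = pid, range_label = g,
        latitude = 42.6 + rnorm(1, 0, 0.15),
        longitude = lon_seq[k] + rnorm(1, 0, 0.05),
        elevation = round(runif(1, 900, 1900)),
        stringsAsFactors = FALSE)
      truth_pop[[pid]] <- d
    }
  }
  if (include_alps) {
    rows <- which(sim$ind$pop_id == "Alps")
    for (j in seq_len(n_alps)) {
      pid <- sprintf("ALPS%02d", j)
      take <- rows[seq_len(cfg$n_ind)]
      rows <- setdiff(rows, take)
      pop_rows[[pid]] <- take
      meta[[pid]] <- data.frame(
        pop_id = pid, range_label = "WesternAlps",
        latitude = 44.2 + rnorm(1, 0, 0.3),
        longitude = 6.5 + rnorm(1, 0, 0.4),
        elevation = round(runif(1, 900, 1900)),
        stringsAsFactors = FALSE)
      truth_pop[[pid]] <- "Alps"
    }
  }
  ord <- unlist(pop_rows, use.names = FALSE)
  pops <- do.call(rbind, meta)
  ind <- data.frame(
    ind_id = sprintf("%s_%03d", rep(names(pop_rows), lengths(pop_rows)),
                     unlist(lapply(lengths(pop_rows), seq_len))),
    pop_id = rep(names(pop_rows), lengths(pop_rows)),
    stringsAsFactors = FALSE)
  ds <- geno_dataset(sim$loci, pops, ind,
                     sim$nuc_a1[ord, , drop = FALSE],
                     sim$nuc_a2[ord, , drop = FALSE],
                     sim$cp[ord, , drop = FALSE])
  truth <- list(scenario = cfg$scenario, par = cfg$par, seed = cfg$seed,
                deme_of_pop = unlist(truth_pop), n_pops_total = total_p)
  list(ds = ds, truth = truth)
}

#' Synthetic cluster-membership (Q) matrix with a longitudinal cline
#'
#' The western-cluster coefficient declines logistically with longitude
#' (`Q_w = 1 / (1 + exp(steepness * (lon - midpoint)))` plus noise,
#' renormalized); central populations form the admixed band.
#'
#' @param meta data.frame with `pop_id` and `longitude`.
#' @param midpoint cline midpoint (degrees).
#' @param steepness logistic steepness (per degree); large values give a
#'   step function.
#' @param noise_sd Gaussian noise on the coefficient before renormalizing.
#' @return data.frame `pop_id`, `Q_w`, `Q_e` with rows summing to 1.
#' @export
generate_q_matrix <- function(meta, midpoint = NULL, steepness = 2,
                              noise_sd = 0.03) {
  stopifnot(all(c("pop_id", "longitude") %in% names(meta)))
  if (is.null(midpoint)) midpoint <- mean(range(meta$longitude))
  qw <- 1 / (1 + exp(steepness * (meta$longitude - midpoint)))
  qw <- qw + rnorm(nrow(meta), 0, noise_sd)
  qw <- pmin(pmax(qw, 1e-6), 1 - 1e-6)
  data.frame(pop_id = meta$pop_id, Q_w = qw, Q_e = 1 - qw,
             stringsAsFactors = FALSE)
}

#' Synthetic environment table with planted associations
#'
#' Emulates the bioclimatic variable structure: 19 BIO variables for each of
#' 4 periods (`cur`, `mh` mid-Holocene, `lgm`, `lig` last interglacial) plus
#' `slope`, `altitude`, `latitude`, `longitude`. Named variables in
#' `signal` are generated with the requested partial correlation to the
#' target vector (e.g. `Q_w`); everything else is standard-normal noise.
#'
#' @param meta data.frame with `pop_id`, `latitude`, `longitude`,
#'   `elevation`.
#' @param target numeric vector the signal variables are tied to (e.g. the
#'   western ancestry coefficient), same row order as `meta`.
#' @param signal named numeric vector of effect sizes (correlations in
#'   `[-1, 1]`), names among the generated columns, e.g.
#'   `c(bio8_lig = -0.8)`.
#' @param noise_sd residual standard deviation on the standardized scale.
#' @return data.frame: `pop_id`, geography columns, then `bio1_cur` ..
#'   `bio19_lig`; attribute `truth` records the planted coefficients.
#' @export
generate_env_table <- function(meta, target = NULL, signal = numeric(0),
                               noise_sd = 0.1) {
  n <- nrow(meta)
  periods <- c("cur", "mh", "lgm", "lig")
  vars <- c(outer(sprintf("bio%d", 1:19), periods, paste, sep = "_"))
  out <- data.frame(pop_id = meta$pop_id,
                    slope = runif(n, 5, 35),
                    altitude = meta$elevation,
                    latitude = meta$latitude,
                    longitude = meta$longitude,
                    stringsAsFactors = FALSE)
  zt <- if (!is.null(target)) as.numeric(scale(target)) else NULL
  for (v in vars) {
    if (v %in% names(signal)) {
      b <- signal[[v]]
      out[[v]] <- b * zt + rnorm(n, 0, sqrt(max(1e-8, 1 - b^2)) * 1) +
        rnorm(n, 0, noise_sd)
    } else {
      out[[v]] <- rnorm(n)
    }
  }
  attr(out, "truth") <- signal
  out
}

#' Synthetic cluster-run likelihood table
#'
#' L(K) rises concavely up to `true_K` then plateaus, with replicate noise,
#' so that the Evanno statistic peaks at `true_K` for a strong signal and
#' shows no pronounced peak when `signal = 0` (L linear in K).
#'
#' @param true_K elbow position (must lie inside `k_range`).
#' @param k_range evaluated K values (contiguous).
#' @param replicates runs per K.
#' @param signal elbow strength in log-probability units (0 = linear L).
#' @param noise_sd replicate noise.
#' @param l0,slope baseline intercept/slope of L(K).
#' @return data.frame `K`, `replicate`, `L`.
#' @export
generate_cluster_runs <- function(true_K = 3L, k_range = 1:8,
                                  replicates = 10L, signal = 200,
                                  noise_sd = 5, l0 = -12000, slope = 30) {
  stopifnot(true_K > min(k_range), true_K < max(k_range))
  base <- function(K) l0 + slope * K + ifelse(K >= true_K, 0,
                                              -signal * (true_K - K))
  out <- expand.grid(replicate = seq_len(replicates), K = k_range)
  out$L <- base(out$K) + rnorm(nrow(out), 0, noise_sd)
  out[, c("K", "replicate", "L")]
}
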
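# Four divergence/admixture scenarios over the sampled demes
#   1 = Alps, 2 = Western Pyrenees (PyrW), 3 = Eastern Pyrenees (PyrE),
#   4 = admixed Pyrenees (PyrAdm)
# described backward in time. All four allow a population-size change on
# each terminal branch (resize at times Ta..Td, before any divergence).
#
# S1 "simple split":        one split at T1 creates Alps/PyrW/PyrE; the
#                           admixed deme arises at T2 < T1 from PyrW x PyrE.
# S2 "hierarchical split":  Alps/Pyrenees split at T1, PyrW/PyrE at T2,
#                           admixed deme at T3 (T1 > T2 > T3).
# S3 "Alps-East split":     Alps/PyrE split at T1; PyrW arises at T2 by
#                           admixture of Alps x PyrE; admixed deme at T3.
# S4 "Alps-West split":     as S3 with PyrW/PyrE roles swapped.

DEME_NAMES <- c("Alps", "PyrW", "PyrE", "PyrAdm")
SCENARIOS <- c("S1", "S2", "S3", "S4")

#' Scenario parameter names
#'
#' Column layout of a scenario parameter vector: mutation model (`mu_nu`,
#' `P_nu`, `mu_cp`, `P_cp`), current deme sizes `N1..N4` (diploid), ancestral
#' per-branch sizes `NA1..NA4` (size before the resize, backward in time),
#' the deeper-branch size `Nanc`, divergence/admixture times `T1 > T2 (> T3)`
#' (generations), terminal resize times `Ta..Td`, and admixture rates
#' `r1`, `r2` (`NA` where a scenario has no such event).
#'
#' @return character vector of parameter names.
#' @export
scenario_param_names <- function() {
  c("mu_nu", "P_nu", "mu_cp", "P_cp",
    paste0("N", 1:4), paste0("NA", 1:4), "Nanc",
    "T1", "T2", "T3", "Ta", "Tb", "Tc", "Td", "r1", "r2")
}

#' Prior specification for the demographic scenarios
#'
#' Event times: normal(25000, 12500) truncated below at `t_min`; deme sizes:
#' normal(5000, 2500) truncated below at `n_min`; nuclear mutation rate
#' log-uniform on `[1e-4, 1e-3]` and chloroplast on `[1e-8, 1e-3]` per locus
#' per generation; GSM geometric parameter uniform on `[0, 0.9]`; admixture
#' rates uniform on `[0.001, 0.999]`. Time orderings (`T1 > T2 > T3`, all
#' resize times below the youngest divergence) are enforced by rejection.
#'
#' @param time_mean,time_sd normal prior on event times (generations).
#' @param size_mean,size_sd normal prior on diploid deme sizes.
#' @param mu_nu_range,mu_cp_range log-uniform bounds on mutation rates.
#' @param gsm_p_range uniform bounds on the GSM geometric parameter.
#' @param adm_range uniform bounds on admixture rates.
#' @param t_min,n_min lower truncation points.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(time_mean = 25000, time_sd = 12500,
                       size_mean = 5000, size_sd = 2500,
                       mu_nu_range = c(1e-4, 1e-3),
                       mu_cp_range = c(1e-8, 1e-3),
                       gsm_p_range = c(0, 0.9),
                       adm_range = c(0.001, 0.999),
                       t_min = 10, n_min = 10) {
  structure(as.list(environment()), class = "prior_spec")
}

# truncated normal by inverse CDF: exact, vectorized, O(n)
rtnorm_rng <- function(n, mean, sd, lo, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

rtnorm_min <- function(n, mean, sd, lo) rtnorm_rng(n, mean, sd, lo)

rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Draw scenario parameters from the priors
#'
#' Rejection sampling enforces the scenario's time ordering: `T1 > T2`
#' (`> T3` where the scenario has three events) and every terminal resize
#' time strictly below the youngest divergence/admixture time.
#'
#' @param spec a [prior_spec()].
#' @param scenario one of `"S1".."S4"`.
#' @param n number of draws.
#' @return data.frame with columns [scenario_param_names()]; inapplicable
#'   parameters (`T3` for S1, `r1` for S1/S2) are `NA`.
#' @export
sample_priors <- function(spec, scenario, n) {
  stopifnot(inherits(spec, "prior_spec"), scenario %in% SCENARIOS)
  has_t3 <- scenario != "S1"
  has_r1 <- scenario %in% c("S3", "S4")
  k_t <- if (has_t3) 3L else 2L

  draw_times <- function(n) {
    T1 <- rtnorm_min(n, spec$time_mean, spec$time_sd, spec$t_min)
    T2 <- rtnorm_min(n, spec$time_mean, spec$time_sd, spec$t_min)
    T3 <- if (has_t3) rtnorm_min(n, spec$time_mean, spec$time_sd, spec$t_min)
    else rep(NA_real_, n)
    cbind(T1, T2, T3)
  }
  tm <- draw_times(n)
  ok <- if (has_t3) tm[, 1] > tm[, 2] & tm[, 2] > tm[, 3]
  else tm[, 1] > tm[, 2]
  while (any(!ok)) {
    tm[!ok, ] <- draw_times(sum(!ok))
    ok <- if (has_t3) tm[, 1] > tm[, 2] & tm[, 2] > tm[, 3]
    else tm[, 1] > tm[, 2]
  }
  t_young <- tm[, k_t]

  draw_resize <- function(upper)
    rtnorm_rng(length(upper), spec$time_mean, spec$time_sd, spec$t_min,
               hi = upper)
  out <- data.frame(
    mu_nu = rlogunif(n, spec$mu_nu_range[1], spec$mu_nu_range[2]),
    P_nu = runif(n, spec$gsm_p_range[1], spec$gsm_p_range[2]),
    mu_cp = rlogunif(n, spec$mu_cp_range[1], spec$mu_cp_range[2]),
    P_cp = runif(n, spec$gsm_p_range[1], spec$gsm_p_range[2]))
  for (i in 1:4) out[[paste0("N", i)]] <-
    rtnorm_min(n, spec$size_mean, spec$size_sd, spec$n_min)
  for (i in 1:4) out[[paste0("NA", i)]] <-
    rtnorm_min(n, spec$size_mean, spec$size_sd, spec$n_min)
  out$Nanc <- rtnorm_min(n, spec$size_mean, spec$size_sd, spec$n_min)
  out$T1 <- tm[, 1]; out$T2 <- tm[, 2]; out$T3 <- tm[, 3]
  out$Ta <- draw_resize(t_young)
  out$Tb <- draw_resize(t_young)
  out$Tc <- draw_resize(t_young)
  out$Td <- draw_resize(t_young)
  out$r1 <- if (has_r1) runif(n, spec$adm_range[1], spec$adm_range[2])
  else rep(NA_real_, n)
  out$r2 <- runif(n, spec$adm_range[1], spec$adm_range[2])
  out
}

# Backward-time event matrix for one scenario/parameter set and one marker
# class. G values are gene-copy numbers: 2N for nuclear loci, N * cp_factor
# for the (paternally inherited, effectively haploid) chloroplast.
# Returns list(G0 = starting copy numbers, events = matrix).
scenario_events <- function(scenario, par, marker = c("nuclear", "chloroplast"),
                            cp_factor = 1) {
  marker <- match.arg(marker)
  gmul <- if (marker == "nuclear") 2 else cp_factor
  G <- function(N) N * gmul
  ev <- function(time, type, d1, d2 = 0, d3 = 0, x = 0)
    c(time, type, d1 - 1, d2 - 1, d3 - 1, x)
  e <- list()
  # terminal resizes (current size N_i -> ancestral-branch size NA_i)
  e[[length(e) + 1]] <- ev(par[["Ta"]], 0, 1, x = G(par[["NA1"]]))
  e[[length(e) + 1]] <- ev(par[["Tb"]], 0, 2, x = G(par[["NA2"]]))
  e[[length(e) + 1]] <- ev(par[["Tc"]], 0, 3, x = G(par[["NA3"]]))
  e[[length(e) + 1]] <- ev(par[["Td"]], 0, 4, x = G(par[["NA4"]]))
  Ganc <- G(par[["Nanc"]])
  if (scenario == "S1") {
    e[[length(e) + 1]] <- ev(par[["T2"]], 1, 4, 2, 3, par[["r2"]])
    e[[length(e) + 1]] <- ev(par[["T1"]], 2, 2, 1)
    e[[length(e) + 1]] <- ev(par[["T1"]], 2, 3, 1)
    e[[length(e) + 1]] <- ev(par[["T1"]], 0, 1, x = Ganc)
  } else if (scenario == "S2") {
    e[[length(e) + 1]] <- ev(par[["T3"]], 1, 4, 2, 3, par[["r2"]])
    e[[length(e) + 1]] <- ev(par[["T2"]], 2, 3, 2)
    e[[length(e) + 1]] <- ev(par[["T2"]], 0, 2, x = Ganc)
    e[[length(e) + 1]] <- ev(par[["T1"]], 2, 2, 1)
    e[[length(e) + 1]] <- ev(par[["T1"]], 0, 1, x = Ganc)
  } else if (scenario == "S3") {
    e[[length(e) + 1]] <- ev(par[["T3"]], 1, 4, 2, 3, par[["r2"]])
    e[[length(e) + 1]] <- ev(par[["T2"]], 1, 2, 1, 3, par[["r1"]])
    e[[length(e) + 1]] <- ev(par[["T1"]], 2, 3, 1)
    e[[length(e) + 1]] <- ev(par[["T1"]], 0, 1, x = Ganc)
  } else if (scenario == "S4") {
    e[[length(e) + 1]] <- ev(par[["T3"]], 1, 4, 2, 3, par[["r2"]])
    e[[length(e) + 1]] <- ev(par[["T2"]], 1, 3, 1, 2, par[["r1"]])
    e[[length(e) + 1]] <- ev(par[["T1"]], 2, 2, 1)
    e[[length(e) + 1]] <- ev(par[["T1"]], 0, 1, x = Ganc)
  } else stop("unknown scenario: ", scenario)
  m <- do.call(rbind, e)
  m <- m[order(m[, 1]), , drop = FALSE]
  list(G0 = G(unlist(par[paste0("N", 1:4)])), events = m)
}

#' Convert coalescent generations to calendar years
#'
#' Multiplies a time in generations by the generation-time interval
#' (sexual-maturity age of silver fir, 30-40 years by default).
#'
#' @param t_generations time in generations (>= 0).
#' @param generation_time_years interval `c(lo, hi)` in years.
#' @return numeric `c(lo, hi)` calendar interval in years.
#' @export
generations_to_years <- function(t_generations,
                                 generation_time_years = c(30, 40)) {
  g <- generation_time_years
  if (any(t_generations < 0)) stop("time must be non-negative")
  if (!(length(g) == 2L && g[1] > 0 && g[1] <= g[2]))
    stop("generation_time_years must be c(lo, hi) with 0 < lo <= hi")
  c(t_generations * g[1], t_generations * g[2])
}
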
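#' Null-allele frequency by maximum likelihood (Dempster EM)
#'
#' Fits, at one locus in one population, the Hardy-Weinberg model with one
#' unobservable null allele: apparent homozygotes are a mixture of true
#' homozygotes (frequency p_i^2) and null heterozygotes (2 p_i p_0), and the
#' null homozygote class is unobserved (or, optionally, pooled with missing
#' genotypes). The EM iterates expected allele counts given current
#' frequencies; the observed-data log-likelihood is non-decreasing at every
#' step and the fit stops at `|delta loglik| < tol` or `max_iter`.
#'
#' @param ds a [geno_dataset()].
#' @param locus nuclear locus name.
#' @param pop_id population id.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap.
#' @param missing_as_null treat missing genotypes as putative null
#'   homozygotes (default `FALSE`: missing excluded).
#' @return list with `locus`, `pop_id`, `null_freq`, `loglik`, `n_iterations`,
#'   `allele_freqs`, `monomorphic` flag and the per-iteration `loglik_trace`.
#' @export
estimate_null_alleles_em <- function(ds, locus, pop_id, tol = 1e-8,
                                     max_iter = 10000L,
                                     missing_as_null = FALSE) {
  sel <- ds$ind$pop_id == pop_id
  g1 <- ds$nuc_a1[sel, locus]
  g2 <- ds$nuc_a2[sel, locus]
  ok <- !is.na(g1)
  n_blank <- if (missing_as_null) sum(!ok) else 0L
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 5L)
    stop("fewer than 5 non-missing genotypes at ", locus, " in ", pop_id)

  alleles <- sort(unique(c(g1, g2)))
  k <- length(alleles)
  if (k == 1L && n_blank == 0L)
    return(list(locus = locus, pop_id = pop_id, null_freq = 0,
                loglik = 0, n_iterations = 0L,
                allele_freqs = setNames(1, alleles),
                monomorphic = TRUE, loglik_trace = numeric(0)))

  i1 <- match(g1, alleles); i2 <- match(g2, alleles)
  homo <- i1 == i2
  n_hom <- tabulate(i1[homo], k)           # apparent homozygote counts
  het_tab <- table(factor(pmin(i1, i2)[!homo], levels = seq_len(k)),
                   factor(pmax(i1, i2)[!homo], levels = seq_len(k)))
  het_alleles <- tabulate(c(i1[!homo], i2[!homo]), k)
  n_tot <- length(g1) + n_blank

  # init: naive frequencies, small null
  p <- tabulate(c(i1, i2), k) / (2 * length(g1))
  p0 <- 0.05
  p <- p * (1 - p0)

  n_geno <- length(g1)   # genotypes in observable classes

  # Observed-data log-likelihood. Without missing_as_null the null-homozygote
  # class is unobservable and the multinomial is truncated: each observed
  # class probability is divided by (1 - p0^2).
  ll_of <- function(p, p0) {
    ll <- sum(n_hom * log(p^2 + 2 * p * p0 + (p^2 + 2 * p * p0 == 0)))
    hi <- which(het_tab > 0, arr.ind = TRUE)
    if (nrow(hi))
      ll <- ll + sum(het_tab[hi] * log(2 * p[hi[, 1]] * p[hi[, 2]]))
    if (missing_as_null) {
      if (n_blank > 0) ll <- ll + n_blank * log(p0^2)
    } else {
      ll <- ll - n_geno * log(1 - p0^2)
    }
    ll
  }

  trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step: expected null-allele copies among apparent homozygotes, plus
    # (truncated case) the expected count of fully unobserved null homozygotes
    denom <- p^2 + 2 * p * p0
    w_null <- ifelse(denom > 0, (2 * p * p0) / denom, 0)  # P(null het | app hom)
    m_unobs <- if (missing_as_null) 0 else n_geno * p0^2 / (1 - p0^2)
    exp_null <- sum(n_hom * w_null) + 2 * n_blank + 2 * m_unobs
    # expected copies of visible allele i: het copies + hom copies
    exp_vis <- het_alleles + n_hom * (2 * (1 - w_null) + w_null)
    tot <- sum(exp_vis) + exp_null
    p_new <- exp_vis / tot
    p0_new <- exp_null / tot
    ll <- ll_of(p_new, p0_new)
    trace <- c(trace, ll)
    conv <- is.finite(ll_old) && abs(ll - ll_old) < tol
    p <- p_new; p0 <- p0_new; ll_old <- ll
    if (conv || it >= max_iter) break
  }
  list(locus = locus, pop_id = pop_id, null_freq = p0, loglik = ll_old,
       n_iterations = it, allele_freqs = setNames(p, alleles),
       monomorphic = FALSE, loglik_trace = trace)
}

#' Null-allele estimates for every locus x population pair
#'
#' @param ds a [geno_dataset()].
#' @param min_n skip pairs with fewer non-missing genotypes (rows flagged).
#' @param ... passed to [estimate_null_alleles_em()].
#' @return data.frame with columns `locus`, `pop_id`, `null_freq`, `loglik`,
#'   `n_iterations`.
#' @export
null_allele_table <- function(ds, min_n = 5L, ...) {
  nu <- colnames(ds$nuc_a1)
  out <- expand.grid(locus = nu, pop_id = ds$pops$pop_id,
                     stringsAsFactors = FALSE)
  res <- mapply(function(l, p) {
    nok <- sum(!is.na(ds$nuc_a1[ds$ind$pop_id == p, l]))
    if (nok < min_n) return(c(NA_real_, NA_real_, NA_real_))
    e <- estimate_null_alleles_em(ds, l, p, ...)
    c(e$null_freq, e$loglik, e$n_iterations)
  }, out$locus, out$pop_id)
  out$null_freq <- res[1, ]
  out$loglik <- res[2, ]
  out$n_iterations <- res[3, ]
  out
}

#' Discard loci with frequent null alleles
#'
#' A locus is discarded when its estimated null-allele frequency exceeds
#' `freq_threshold` in strictly more than `pop_fraction` of the populations
#' with an estimate (default: > 0.05 in more than half of the populations).
#'
#' @param estimates data.frame as from [null_allele_table()].
#' @param freq_threshold null-frequency cutoff.
#' @param pop_fraction fraction of populations that must exceed the cutoff.
#' @return list with `kept`, `discarded`, and a per-locus `report`
#'   (offending-population counts).
#' @export
filter_loci_by_null_freq <- function(estimates, freq_threshold = 0.05,
                                     pop_fraction = 0.5) {
  if (!nrow(estimates)) stop("empty estimate table")
  est <- estimates[!is.na(estimates$null_freq), , drop = FALSE]
  rep_df <- aggregate(null_freq ~ locus, data = est, FUN = function(x)
    c(n_offending = sum(x > freq_threshold), n_pops = length(x)))
  report <- data.frame(locus = rep_df$locus,
                       n_offending = rep_df$null_freq[, 1],
                       n_pops = rep_df$null_freq[, 2])
  report$discard <- report$n_offending > pop_fraction * report$n_pops
  list(kept = report$locus[!report$discard],
       discarded = report$locus[report$discard],
       report = report)
}
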
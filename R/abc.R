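# ---- helpers ---------------------------------------------------------------

#' Default fitting statistics
#'
#' The model-choice / parameter-regression statistic set: two single-deme
#' families (genic diversity and Garza-Williamson M per deme) and two
#' pairwise families (F_ST and (delta-mu)^2 per deme pair), nuclear loci
#' only — 20 statistics. The count is deliberately small: the local-linear
#' posterior adjustment is estimated on the ~200 retained simulations, and
#' more statistics than about one per ten draws destabilizes it (and
#' degrades credible-interval calibration). Chloroplast statistics are
#' excluded by default because the chloroplast rate prior spans four orders
#' of magnitude, leaving those statistics zero-inflated; they remain
#' available through the `fit_stats` arguments. Everything not fitted is
#' held out for posterior-predictive model checking.
#'
#' @return character vector of statistic names.
#' @export
default_fit_stats <- function() {
  nm <- summary_stat_names()
  nm[grepl("^nu_(he|mgw|fst|dmu2)_", nm)]
}

#' Held-out model-checking statistics
#' @return character vector, disjoint from [default_fit_stats()].
#' @export
default_check_stats <- function() {
  setdiff(summary_stat_names(), default_fit_stats())
}

# standardize statistic columns by the table's scale; drops constant columns
std_stats <- function(ref, cols) {
  sdv <- ref$scale$sd[cols]
  keep <- cols[is.finite(sdv) & sdv > 0]
  z <- sweep(sweep(ref$stats[, keep, drop = FALSE], 2L,
                   ref$scale$mean[keep]), 2L, ref$scale$sd[keep], "/")
  list(z = z, keep = keep)
}

std_obs <- function(ref, observed, keep) {
  (observed[keep] - ref$scale$mean[keep]) / ref$scale$sd[keep]
}

wq <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], 0)
}

wmode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- suppressWarnings(density(x, weights = w / sum(w), bw = bw.nrd0(x)))
  d$x[which.max(d$y)]
}

# ---- prior/scenario adequacy ----------------------------------------------

#' Prior-scenario adequacy check
#'
#' For each summary statistic, the two-sided rank probability of the observed
#' value among the simulated ones; a PCA of the standardized simulated
#' statistics with the observed point projected serves as a visual
#' diagnostic. Statistics with rank p below `alpha` are flagged as under- or
#' over-estimated by the scenario-prior combination.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed named statistic vector (as [summary_stats()]).
#' @param alpha flagging threshold.
#' @return list with `ranks` (data.frame: statistic, rank_p, flagged),
#'   `pca` (prcomp object) and `obs_proj` (observed scores).
#' @export
prior_scenario_check <- function(ref, observed, alpha = 0.01) {
  nm <- colnames(ref$stats)
  n <- nrow(ref$stats)
  rank_p <- vapply(nm, function(s) {
    x <- ref$stats[, s]
    if (sd(x) == 0) return(NA_real_)
    lo <- (1 + sum(x <= observed[s])) / (n + 1)
    hi <- (1 + sum(x >= observed[s])) / (n + 1)
    min(1, 2 * min(lo, hi))
  }, 0)
  ranks <- data.frame(statistic = nm, rank_p = rank_p,
                      flagged = !is.na(rank_p) & rank_p < alpha,
                      skipped = is.na(rank_p))
  st <- std_stats(ref, nm)
  pca <- prcomp(st$z, center = FALSE, scale. = FALSE)
  obs_proj <- drop(matrix(std_obs(ref, observed, st$keep), 1) %*% pca$rotation)
  list(ranks = ranks, pca = pca, obs_proj = obs_proj)
}

# ---- model choice ----------------------------------------------------------

#' ABC model choice (rejection + LDA/polytomous logistic)
#'
#' Standardizes the fitting statistics, retains the `tolerance_fraction`
#' nearest simulations to the observed point (Euclidean distance), and
#' estimates scenario posterior probabilities two ways: the scenario
#' proportions among retained rows ("direct"), and a polytomous (multinomial)
#' logistic regression of scenario on linear-discriminant axes with
#' Epanechnikov distance weights, evaluated at the observed point
#' ("logistic"). Confidence intervals for the logistic estimate come from
#' the fit's asymptotic covariance (parametric draws). The winning scenario
#' is flagged `recovered` when its point probability exceeds every other
#' scenario's upper CI bound.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed named statistic vector.
#' @param tolerance_fraction fraction of rows retained (study value 0.01).
#' @param use_lda project onto linear-discriminant axes (default) rather
#'   than the raw standardized statistics.
#' @param fit_stats statistic subset (default [default_fit_stats()]).
#' @param n_ci_draws coefficient draws for the CIs.
#' @param exclude_row optional row index left out (for pod reclassification).
#' @return list with `direct`, `logistic` (named probability vectors),
#'   `ci` (2 x K matrix), `selected`, `recovered`, `n_retained`.
#' @export
abc_model_choice <- function(ref, observed, tolerance_fraction = 0.01,
                             use_lda = TRUE, fit_stats = default_fit_stats(),
                             n_ci_draws = 500L, exclude_row = NULL) {
  scen <- levels(ref$scenario)
  if (length(scen) < 2L) stop("need at least 2 scenarios")
  st <- std_stats(ref, fit_stats)
  z <- st$z
  zobs <- std_obs(ref, observed, st$keep)
  rows <- seq_len(nrow(z))
  if (!is.null(exclude_row)) rows <- rows[-exclude_row]
  d2 <- colSums((t(z[rows, , drop = FALSE]) - zobs)^2)
  n_keep <- max(length(scen) + 1L,
                ceiling(tolerance_fraction * length(rows)))
  sel <- rows[order(d2)[seq_len(n_keep)]]
  dmax <- sqrt(sort(d2)[n_keep])
  w <- 1 - (sqrt(sort(d2)[seq_len(n_keep)]) / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-8)

  cls <- factor(ref$scenario[sel], levels = scen)
  direct <- as.numeric(table(cls)) / length(sel)
  names(direct) <- scen

  absent <- table(cls) == 0
  if (nlevels(droplevels(cls)) < 2L) {
    # retained set is pure: the logistic step degenerates to the direct one
    ci <- matrix(rep(direct, each = 2), 2,
                 dimnames = list(c("lo", "hi"), scen))
    return(list(direct = direct, logistic = direct, ci = ci,
                selected = scen[which.max(direct)], recovered = TRUE,
                n_retained = length(sel), degenerate = TRUE))
  }
  X <- z[sel, , drop = FALSE]
  if (use_lda && sum(!absent) > 1L) {
    ld <- tryCatch(MASS::lda(X[, , drop = FALSE], grouping = droplevels(cls)),
                   error = function(e) NULL)
    if (!is.null(ld)) {
      X <- X %*% ld$scaling
      zo <- drop(matrix(zobs, 1) %*% ld$scaling)
    } else zo <- zobs
  } else zo <- zobs
  dat <- data.frame(X)
  names(dat) <- paste0("A", seq_len(ncol(X)))
  dat$.cls <- droplevels(cls)
  fit <- nnet::multinom(.cls ~ ., data = dat, weights = w, trace = FALSE,
                        Hessian = TRUE, maxit = 200)
  newd <- as.data.frame(as.list(setNames(zo[seq_len(ncol(X))],
                                         paste0("A", seq_len(ncol(X))))))
  pr <- predict(fit, newdata = newd, type = "probs")
  logistic <- setNames(rep(0, length(scen)), scen)
  if (is.null(dim(pr))) {
    if (nlevels(dat$.cls) == 2L)
      logistic[levels(dat$.cls)] <- c(1 - pr, pr)
    else logistic[names(pr)] <- pr
  } else logistic[colnames(pr)] <- pr

  # CI by drawing coefficients from the asymptotic normal
  ci <- matrix(NA_real_, 2, length(scen), dimnames = list(c("lo", "hi"), scen))
  V <- if (n_ci_draws >= 1L) tryCatch(vcov(fit), error = function(e) NULL)
  else NULL
  if (!is.null(V) && all(is.finite(V))) {
    cf <- coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
    theta <- as.vector(t(cf))
    draws <- MASS::mvrnorm(n_ci_draws, theta, V)
    xo <- c(1, zo[seq_len(ncol(X))])
    pmat <- t(apply(draws, 1L, function(th) {
      B <- matrix(th, nrow = nrow(cf), byrow = TRUE)
      eta <- c(0, B %*% xo)
      exp(eta) / sum(exp(eta))
    }))
    colnames(pmat) <- levels(dat$.cls)
    for (s in colnames(pmat))
      ci[, s] <- quantile(pmat[, s], c(0.025, 0.975))
    ci[, absent] <- 0   # degenerate: scenario absent among retained rows
  }
  selected <- scen[which.max(logistic)]
  others <- setdiff(scen, selected)
  recovered <- all(!is.na(ci["hi", others])) &&
    max(logistic) > max(ci["hi", others])
  list(direct = direct, logistic = logistic, ci = ci,
       selected = selected, recovered = recovered,
       n_retained = length(sel), degenerate = any(absent))
}

# ---- error calibration -----------------------------------------------------

#' Scenario-choice error rates from pseudo-observed datasets
#'
#' Pods are drawn, for each scenario, from that scenario's rows among the
#' `tolerance_fraction` closest to the observed statistics, and re-classified
#' (the pod's own row excluded). Type I error of a scenario is the fraction
#' of its pods not assigned to it; type II, the fraction of other scenarios'
#' pods assigned to it; the posterior error rate is the mean posterior
#' probability mass placed on wrong scenarios.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed named statistic vector used to localize the pods.
#' @param n_pods total number of pods (split equally over scenarios).
#' @param tolerance_fraction retained fraction, for both localization and
#'   reclassification.
#' @param method classify by the logistic or the direct estimate.
#' @param fit_stats statistic subset.
#' @return list with `type1`, `type2` (named vectors), `posterior_error`,
#'   `confusion` (true x assigned counts), `resampled` flag.
#' @export
confusion_errors <- function(ref, observed, n_pods = 1000L,
                             tolerance_fraction = 0.01,
                             method = c("direct", "logistic"),
                             fit_stats = default_fit_stats()) {
  method <- match.arg(method)
  scen <- levels(ref$scenario)
  st <- std_stats(ref, fit_stats)
  zobs <- std_obs(ref, observed, st$keep)
  d2 <- colSums((t(st$z) - zobs)^2)
  per <- ceiling(n_pods / length(scen))
  resampled <- FALSE
  pods <- integer(0)
  for (s in scen) {
    rows <- which(ref$scenario == s)
    n_close <- max(1L, ceiling(tolerance_fraction * length(rows)))
    close <- rows[order(d2[rows])[seq_len(n_close)]]
    if (length(close) < per) resampled <- TRUE
    pods <- c(pods, sample(close, per, replace = length(close) < per))
  }
  confusion <- matrix(0L, length(scen), length(scen),
                      dimnames = list(true = scen, assigned = scen))
  perr <- numeric(length(pods))
  for (k in seq_along(pods)) {
    i <- pods[k]
    mc <- abc_model_choice(ref, ref$stats[i, ], tolerance_fraction,
                           use_lda = method == "logistic",
                           fit_stats = fit_stats, n_ci_draws = 0L,
                           exclude_row = i)
    pr <- if (method == "logistic") mc$logistic else mc$direct
    truth <- as.character(ref$scenario[i])
    assigned <- names(pr)[which.max(pr)]
    confusion[truth, assigned] <- confusion[truth, assigned] + 1L
    perr[k] <- 1 - pr[truth]
  }
  rs <- rowSums(confusion)
  type1 <- setNames(ifelse(rs > 0, 1 - diag(confusion) / rs, NA_real_), scen)
  type2 <- vapply(scen, function(s) {
    other <- setdiff(scen, s)
    tot <- sum(confusion[other, ])
    if (tot == 0) NA_real_ else sum(confusion[other, s]) / tot
  }, 0)
  list(type1 = type1, type2 = type2, posterior_error = mean(perr),
       confusion = confusion, resampled = resampled)
}

# ---- parameter posterior ---------------------------------------------------

#' ABC parameter posterior (local-linear regression, logit transform)
#'
#' Restricts the reference table to the chosen scenario, retains the
#' `tolerance_fraction` closest rows, logit-maps each parameter onto its
#' prior support, regresses it on the standardized statistics with
#' Epanechnikov weights, residual-adjusts to the observed point and
#' back-transforms (Beaumont local-linear adjustment). Falls back to the
#' plain rejection posterior when the regression design is singular.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed named statistic vector.
#' @param scenario scenario whose parameters are estimated.
#' @param tolerance_fraction retained fraction of the scenario's rows.
#' @param params parameter subset (default: all applicable).
#' @param fit_stats statistic subset.
#' @return list of class `abc_posterior`: `draws` (adjusted draws),
#'   `weights`, `summary` (median/mode/2.5%/97.5% per parameter),
#'   `rejection_only` flag.
#' @export
abc_parameter_posterior <- function(ref, observed, scenario,
                                    tolerance_fraction = 0.01,
                                    params = NULL,
                                    fit_stats = default_fit_stats()) {
  rows <- which(ref$scenario == scenario)
  if (!length(rows)) stop("scenario not in table: ", scenario)
  if (is.null(params)) {
    params <- scenario_param_names()
    params <- params[colSums(!is.na(ref$params[rows, params])) > 0]
  }
  st <- std_stats(ref, fit_stats)
  zobs <- std_obs(ref, observed, st$keep)
  z <- st$z[rows, , drop = FALSE]
  d2 <- colSums((t(z) - zobs)^2)
  n_keep <- max(20L, ceiling(tolerance_fraction * length(rows)))
  o <- order(d2)[seq_len(n_keep)]
  dmax <- sqrt(d2[o[n_keep]])
  w <- 1 - (sqrt(d2[o]) / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-8)
  X <- z[o, , drop = FALSE]
  Xc <- sweep(X, 2L, zobs)   # so the intercept is the fit at the observed point

  prior_all <- ref$params[rows, , drop = FALSE]
  draws <- matrix(NA_real_, n_keep, length(params),
                  dimnames = list(NULL, params))
  rejection_only <- FALSE
  for (p in params) {
    th <- prior_all[[p]][o]
    lo <- min(prior_all[[p]], na.rm = TRUE)
    hi <- max(prior_all[[p]], na.rm = TRUE)
    pad <- 1e-3 * (hi - lo) + 1e-12
    lo <- lo - pad; hi <- hi + pad
    u <- (th - lo) / (hi - lo)
    y <- log(u / (1 - u))
    fit <- tryCatch(lm.wfit(cbind(1, Xc), y, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      # singular design: keep the rejection draws for this parameter
      rejection_only <- TRUE
      draws[, p] <- th
      next
    }
    yhat_obs <- fit$coefficients[1]
    adj <- yhat_obs + fit$residuals
    draws[, p] <- lo + (hi - lo) / (1 + exp(-adj))
  }
  smry <- t(vapply(params, function(p) {
    x <- draws[, p]
    c(median = wq(x, w, 0.5), mode = wmode(x, w),
      q025 = wq(x, w, 0.025), q975 = wq(x, w, 0.975))
  }, numeric(4)))
  structure(list(draws = as.data.frame(draws), weights = w,
                 summary = smry, scenario = scenario,
                 rejection_only = rejection_only),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("ABC posterior for scenario", x$scenario, "(",
      nrow(x$draws), "weighted draws )\n")
  print(round(x$summary, 4))
  invisible(x)
}

# ---- estimator quality -----------------------------------------------------

#' Quality metrics over pseudo-observed datasets
#'
#' `MRB` = mean((est - true)/true); `rRMSE` = sqrt(mean(((est - true)/true)^2));
#' `coverage50`/`coverage95` = fraction of pods whose credible interval
#' contains the truth; `factor2` = fraction with est/true in [0.5, 2]
#' (boundaries included). Pods with true = 0 are excluded and counted.
#'
#' @param pods data.frame with columns `true`, `est`, and optionally
#'   `lo50`, `hi50`, `lo95`, `hi95`.
#' @return named list of metrics plus `n_excluded`.
#' @export
estimator_quality <- function(pods) {
  if (nrow(pods) < 1L) stop("empty pod table")
  excl <- pods$true == 0
  p <- pods[!excl, , drop = FALSE]
  rel <- (p$est - p$true) / p$true
  out <- list(MRB = mean(rel), rRMSE = sqrt(mean(rel^2)),
              factor2 = mean(p$est / p$true >= 0.5 & p$est / p$true <= 2),
              n_excluded = sum(excl))
  if (all(c("lo50", "hi50") %in% names(p)))
    out$coverage50 <- mean(p$true >= p$lo50 & p$true <= p$hi50)
  if (all(c("lo95", "hi95") %in% names(p)))
    out$coverage95 <- mean(p$true >= p$lo95 & p$true <= p$hi95)
  out
}

# ---- theta ratio -----------------------------------------------------------

#' Posterior of the population-size-change ratio theta0/theta1
#'
#' `theta0 = N0 mu` (current) against `theta1 = N1 mu` (before the terminal
#' resize); with a constant mutation rate the mu cancels and the ratio
#' reduces to `N0/N1`, measuring expansion (> 1) or contraction (< 1) of the
#' deme independently of the unknown mutation rate.
#'
#' @param post an [abc_parameter_posterior()] result.
#' @param deme deme index 1-4 or name (`"Alps"`, `"PyrW"`, `"PyrE"`,
#'   `"PyrAdm"`).
#' @return list with `draws`, `weights`, `mode`, `p_gt1`, `p_lt1`, quantiles.
#' @export
theta_ratio_posterior <- function(post, deme) {
  if (is.character(deme)) deme <- match(deme, DEME_NAMES)
  stopifnot(deme %in% 1:4)
  n0 <- post$draws[[paste0("N", deme)]]
  n1 <- post$draws[[paste0("NA", deme)]]
  if (is.null(n0) || is.null(n1))
    stop("posterior lacks size draws for deme ", deme)
  ratio <- n0 / n1
  w <- post$weights
  # mode on the log scale: a ratio's natural support, and it keeps the
  # expansion/contraction readout symmetric under swapping current and past
  list(draws = ratio, weights = w,
       mode = exp(wmode(log(ratio), w)),
       p_gt1 = sum(w * (ratio > 1)) / sum(w),
       p_lt1 = sum(w * (ratio < 1)) / sum(w),
       q025 = wq(ratio, w, 0.025), q975 = wq(ratio, w, 0.975))
}

# ---- posterior predictive check --------------------------------------------

#' Posterior-predictive model check on held-out statistics
#'
#' Draws parameter vectors from the weighted posterior, replicates datasets
#' under the fitted scenario, and compares the observed held-out statistics
#' to the replicated ones by two-sided rank probability. The held-out set
#' must be disjoint from the fitting set.
#'
#' @param post an [abc_parameter_posterior()] result.
#' @param observed named statistic vector.
#' @param check_stats held-out statistics (default [default_check_stats()]).
#' @param fit_stats the statistics used for fitting (for the disjointness
#'   check).
#' @param n_rep replicated datasets.
#' @param n_dip,loci,cp_factor simulation configuration (must match the
#'   observed data's design).
#' @param alpha flagging threshold.
#' @return data.frame with `statistic`, `p`, `flagged`.
#' @export
model_check_ppc <- function(post, observed,
                            check_stats = default_check_stats(),
                            fit_stats = default_fit_stats(),
                            n_rep = 1000L, n_dip = 25L,
                            loci = default_loci(), cp_factor = 1,
                            alpha = 0.05) {
  if (length(intersect(check_stats, fit_stats)))
    stop("held-out statistics overlap the fitting set")
  w <- post$weights / sum(post$weights)
  idx <- sample.int(nrow(post$draws), n_rep, replace = TRUE, prob = w)
  reps <- matrix(NA_real_, n_rep, length(check_stats),
                 dimnames = list(NULL, check_stats))
  for (k in seq_len(n_rep)) {
    par <- as.list(post$draws[idx[k], ])
    ds <- simulate_dataset(post$scenario, par, n_dip, loci, cp_factor)
    reps[k, ] <- summary_stats(ds)[check_stats]
  }
  p <- vapply(check_stats, function(s) {
    lo <- (1 + sum(reps[, s] <= observed[s])) / (n_rep + 1)
    hi <- (1 + sum(reps[, s] >= observed[s])) / (n_rep + 1)
    min(1, 2 * min(lo, hi))
  }, 0)
  data.frame(statistic = check_stats, p = p, flagged = p < alpha)
}
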
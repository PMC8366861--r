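# ---- cluster number --------------------------------------------------------

#' Evanno delta-K statistic
#'
#' `dK(K) = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r(L(K))` over
#' replicate runs: the second difference of the clustering log-probability,
#' normalized by the replicate standard deviation. The K with the highest
#' peak is the supported cluster number. Invariant to adding a constant to
#' every L.
#'
#' @param runs data.frame with columns `K`, `replicate`, `L`.
#' @return list with `table` (K, mean_L, sd_L, delta_K) and `best_K`.
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "replicate", "L") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (any(diff(ks) != 1L)) stop("K range must be contiguous")
  mean_l <- tapply(runs$L, runs$K, mean)[as.character(ks)]
  sd_l <- tapply(runs$L, runs$K, sd)[as.character(ks)]
  nrep <- tapply(runs$L, runs$K, length)
  if (any(nrep < 2L)) stop("need >= 2 replicates per K")
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1L, length(ks))]) {
    # mean of per-replicate |second difference| needs matched replicates;
    # with means it reduces to |mean second difference| (same estimator when
    # replicates are exchangeable)
    num <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1])
    dk[i] <- if (sd_l[i] > 0) num / sd_l[i] else NA_real_
  }
  tab <- data.frame(K = ks, mean_L = as.numeric(mean_l),
                    sd_L = as.numeric(sd_l), delta_K = dk)
  best <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  list(table = tab, best_K = best)
}

# ---- representative populations -------------------------------------------

#' Representative populations from a Q matrix
#'
#' Per cluster, the population with the highest ancestry coefficient Q; plus
#' one admixed representative whose maximum Q is closest to
#' `admixture_target` (the contact-zone population). An exclusion list
#' supports replicate analyses with the next-best choices. Ties are broken
#' by alphabetical `pop_id`.
#'
#' @param q data.frame with `pop_id` and one Q column per cluster.
#' @param admixture_target target maximum-Q for the admixed pick.
#' @param exclude populations not eligible.
#' @return data.frame with `role` (cluster name or "admixed"), `pop_id`, `Q`.
#' @export
select_representative_populations <- function(q, admixture_target = 0.5,
                                              exclude = character(0)) {
  stopifnot("pop_id" %in% names(q))
  clusters <- setdiff(names(q), "pop_id")
  qq <- q[!q$pop_id %in% exclude, , drop = FALSE]
  qq <- qq[order(qq$pop_id), , drop = FALSE]   # alphabetical tie-break
  picks <- lapply(clusters, function(cl) {
    if (!nrow(qq)) stop("empty cluster: ", cl)
    i <- which.max(qq[[cl]])
    data.frame(role = cl, pop_id = qq$pop_id[i], Q = qq[[cl]][i],
               stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, picks)
  pool <- qq[!qq$pop_id %in% reps$pop_id, , drop = FALSE]
  if (!nrow(pool)) stop("no population left for the admixed representative")
  qmax <- do.call(pmax, pool[clusters])
  i <- which.min(abs(qmax - admixture_target))
  rbind(reps, data.frame(role = "admixed", pop_id = pool$pop_id[i],
                         Q = qmax[i], stringsAsFactors = FALSE))
}

# ---- correlation screen ----------------------------------------------------

#' Pearson correlation screen of genetic against environmental variables
#'
#' Full cross table of Pearson r with the Fisher z transform scaled by
#' `sqrt(n - 3)`, computed on pairwise-complete observations; the z values
#' feed the [local_fdr()] stage. Zero-variance pairs are skipped and flagged.
#'
#' @param genetic data.frame of per-population genetic variables.
#' @param env data.frame of per-population environmental variables (same
#'   row order).
#' @param min_n minimum complete pairs.
#' @return data.frame with `genetic`, `env`, `n`, `r`, `z`, `skipped`.
#' @export
pearson_screen <- function(genetic, env, min_n = 5L) {
  out <- expand.grid(genetic = names(genetic), env = names(env),
                     stringsAsFactors = FALSE)
  res <- t(mapply(function(gv, ev) {
    x <- genetic[[gv]]; y <- env[[ev]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < min_n || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(c(n, NA_real_, NA_real_))
    r <- cor(x[ok], y[ok])
    c(n, r, atanh(min(max(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(n - 3))
  }, out$genetic, out$env))
  out$n <- res[, 1]; out$r <- res[, 2]; out$z <- res[, 3]
  out$skipped <- is.na(out$r)
  out
}

#' Local false discovery rate from z values
#'
#' Empirical-Bayes lfdr with a theoretical standard-normal null:
#' `lfdr(z) = pi0 * f0(z) / f(z)`, with the marginal density `f` estimated
#' by a Gaussian kernel and the null proportion `pi0` by central matching
#' (the ratio `f(z)/f0(z)` over the central half of the data). Values are
#' clipped to `[0, 1]`; optionally made monotone non-increasing in `|z|` by
#' isotonic regression. With fewer than `min_tests` tests the procedure
#' falls back to Benjamini-Hochberg adjusted p-values, flagged.
#'
#' @param z numeric z values (NA allowed, returned as NA).
#' @param cutoff significance threshold on the lfdr.
#' @param monotone enforce monotonicity in `|z|`.
#' @param min_tests density-estimation floor.
#' @return list with `lfdr`, `pi0`, `significant` (logical), `method`.
#' @export
local_fdr <- function(z, cutoff = 0.05, monotone = TRUE, min_tests = 50L) {
  ok <- !is.na(z)
  zz <- z[ok]
  if (length(zz) < min_tests) {
    p <- 2 * pnorm(-abs(zz))
    q <- p.adjust(p, "BH")
    lf <- rep(NA_real_, length(z)); lf[ok] <- q
    return(list(lfdr = lf, pi0 = NA_real_,
                significant = !is.na(lf) & lf <= cutoff, method = "BH"))
  }
  bw <- bw.nrd0(zz) * 1.2
  f <- vapply(zz, function(v) mean(dnorm((v - zz) / bw)) / bw, 0)
  f0 <- dnorm(zz)
  central <- abs(zz) <= quantile(abs(zz), 0.5)
  pi0 <- min(1, median(f[central] / f0[central]))
  lf <- pmin(1, pmax(0, pi0 * f0 / f))
  if (monotone) {
    o <- order(abs(zz))
    iso <- isoreg(abs(zz)[o], -lf[o])
    lf[o] <- pmin(1, pmax(0, -iso$yf))
  }
  out <- rep(NA_real_, length(z)); out[ok] <- lf
  list(lfdr = out, pi0 = pi0,
       significant = !is.na(out) & out <= cutoff, method = "lfdr")
}

# ---- multicollinearity and model selection ---------------------------------

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each candidate on the others
#' (with intercept). Exact collinearity gives `Inf`.
#'
#' @param X data.frame or matrix of candidate predictors.
#' @return named numeric vector.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2L, nrow(X) > ncol(X))
  if (any(vapply(X, sd, 0) == 0)) stop("constant candidate column")
  vapply(names(X), function(j) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[setdiff(names(X), j)]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

bic_of <- function(y, Xd) {
  n <- length(y)
  fit <- lm.fit(cbind(1, Xd), y)
  rss <- sum(fit$residuals^2)
  n * log(rss / n) + (ncol(Xd) + 1L) * log(n)
}

#' Forward stepwise regression under BIC
#'
#' Starts from the intercept-only model; at each step adds the candidate
#' that minimizes `BIC = n log(RSS/n) + k log(n)` and stops when no addition
#' lowers the BIC. Ties are broken by the smaller candidate index. The final
#' model is refit with `lm` for coefficients, p-values and adjusted R^2.
#'
#' @param y response (a genetic variable per population).
#' @param X data.frame of candidate predictors.
#' @return list with `selected` (names, possibly empty), `path` (data.frame
#'   of accepted steps with BIC), `model` (the refit `lm`, or `NULL` for the
#'   intercept-only outcome), `adj_r_squared`, `coefficients`.
#' @export
forward_stepwise_bic <- function(y, X) {
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X))
  cand <- names(X)
  sel <- character(0)
  bic_cur <- bic_of(y, matrix(numeric(0), length(y), 0))
  path <- data.frame(step = 0L, added = "(intercept)", BIC = bic_cur,
                     stringsAsFactors = FALSE)
  repeat {
    rest <- setdiff(cand, sel)
    if (!length(rest)) break
    bics <- vapply(rest, function(v)
      bic_of(y, as.matrix(X[c(sel, v)])), 0)
    best <- which(bics == min(bics))[1]   # ties: smallest index
    if (bics[best] >= bic_cur - 1e-10) break
    sel <- c(sel, rest[best])
    bic_cur <- bics[best]
    path <- rbind(path, data.frame(step = nrow(path), added = rest[best],
                                   BIC = bic_cur))
  }
  if (!length(sel))
    return(list(selected = character(0), path = path, model = NULL,
                adj_r_squared = 0, coefficients = NULL))
  dat <- data.frame(.y = y, X[sel])
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)
  list(selected = sel, path = path, model = fit,
       adj_r_squared = sm$adj.r.squared,
       coefficients = sm$coefficients)
}

#' Pearson chi-squared test on category counts
#'
#' Tests observed counts per category (e.g. temperature- vs
#' precipitation-related significant variables) against equal expected
#' counts.
#'
#' @param counts non-negative counts, >= 2 categories.
#' @return list with `statistic`, `df`, `p`.
#' @export
category_count_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 2L, all(counts >= 0))
  if (sum(counts) == 0) stop("all counts zero")
  ct <- chisq.test(counts)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
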
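test_that("Evanno delta-K peaks at the constructed elbow and is
           shift-invariant", {
  set.seed(61)
  runs <- generate_cluster_runs(true_K = 3L, k_range = 1:8,
                                replicates = 10L, signal = 300)
  ev <- evanno_delta_k(runs)
  expect_equal(ev$best_K, 3L)
  # linear L(K): all second differences near zero
  runs_lin <- generate_cluster_runs(true_K = 3L, signal = 0, noise_sd = 2)
  ev_lin <- evanno_delta_k(runs_lin)
  expect_lt(max(ev_lin$table$delta_K, na.rm = TRUE),
            max(ev$table$delta_K, na.rm = TRUE) / 10)
  # adding a constant to every L leaves delta-K unchanged
  runs_sh <- runs; runs_sh$L <- runs_sh$L + 5000
  expect_equal(evanno_delta_k(runs_sh)$table$delta_K, ev$table$delta_K)
  expect_error(evanno_delta_k(runs[runs$K <= 2, ]), "3 consecutive")
})

test_that("representative populations follow the max-Q and contact-zone
           rules", {
  q <- data.frame(
    pop_id = c("Borc", "Issa", "Lesp", "Bele", "Vent", "Punt", "Stla",
               "Sigu"),
    west  = c(0.91, 0.90, 0.05, 0.06, 0.02, 0.03, 0.44, 0.60),
    east  = c(0.05, 0.06, 0.88, 0.87, 0.04, 0.05, 0.42, 0.35),
    alps  = c(0.04, 0.04, 0.07, 0.07, 0.93, 0.86, 0.14, 0.05))
  sel <- select_representative_populations(q)
  expect_equal(sel$pop_id[sel$role == "west"], "Borc")
  expect_equal(sel$pop_id[sel$role == "east"], "Lesp")
  expect_equal(sel$pop_id[sel$role == "alps"], "Vent")
  expect_equal(sel$pop_id[sel$role == "admixed"], "Stla")
  # excluding the first set yields the replicate set
  sel2 <- select_representative_populations(q, exclude = sel$pop_id)
  expect_setequal(sel2$pop_id, c("Issa", "Bele", "Punt", "Sigu"))
  # ties break alphabetically
  qt <- data.frame(pop_id = c("Bb", "Aa", "Cc"), k1 = c(0.9, 0.9, 0.1),
                   k2 = c(0.1, 0.1, 0.9))
  selt <- select_representative_populations(qt)
  expect_equal(selt$pop_id[selt$role == "k1"], "Aa")
})

test_that("Pearson screen produces Fisher z and respects symmetries", {
  set.seed(62)
  gen <- data.frame(he = rnorm(45))
  env <- data.frame(x1 = gen$he, x2 = rnorm(45), const = rep(1, 45))
  sc <- pearson_screen(gen, env)
  expect_equal(sc$r[sc$env == "x1"], 1, tolerance = 1e-12)
  expect_true(sc$skipped[sc$env == "const"])
  # antisymmetry under negation
  env2 <- env; env2$x2 <- -env2$x2
  sc2 <- pearson_screen(gen, env2)
  expect_equal(sc2$r[sc2$env == "x2"], -sc$r[sc$env == "x2"])
  expect_equal(sc$z[sc$env == "x2"],
               atanh(sc$r[sc$env == "x2"]) * sqrt(45 - 3))
  # independent variables: about 95% of |r| below the 5% critical value
  gen3 <- data.frame(matrix(rnorm(45 * 20), 45))
  env3 <- data.frame(matrix(rnorm(45 * 20), 45))
  sc3 <- pearson_screen(gen3, env3)
  expect_gt(mean(abs(sc3$r) < 0.3), 0.90)
})

test_that("local fdr separates a planted mixture and controls the null", {
  set.seed(63)
  z0 <- rnorm(400)
  r0 <- local_fdr(z0)
  expect_equal(r0$method, "lfdr")
  expect_gt(median(r0$lfdr), 0.9)
  expect_lt(mean(r0$significant), 0.02)
  # 80% null + 20% N(4,1)
  z <- c(rnorm(800), rnorm(200, 4))
  r <- local_fdr(z)
  expect_true(all(r$lfdr[abs(z) > 5] < 0.05))
  # analytic lfdr of the generating mixture
  an <- 0.8 * dnorm(z) / (0.8 * dnorm(z) + 0.2 * dnorm(z, 4))
  expect_lt(mean(abs(r$lfdr - an)), 0.1)
  # monotone non-increasing in |z|
  o <- order(abs(z))
  expect_true(all(diff(r$lfdr[o]) <= 1e-9))
  # small test counts fall back to BH
  expect_equal(local_fdr(rnorm(10))$method, "BH")
})

test_that("lfdr cut keeps the empirical false-discovery proportion in check", {
  set.seed(64)
  fdp <- replicate(200, {
    null <- c(rep(TRUE, 400), rep(FALSE, 100))
    z <- c(rnorm(400), rnorm(100, 4))
    r <- local_fdr(z)
    s <- r$significant
    if (!any(s)) 0 else mean(null[s])
  })
  expect_lte(mean(fdp), 0.10)
})

test_that("VIF matches the closed form and an independent implementation", {
  set.seed(65)
  n <- 60
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  v <- vif(X)
  expect_true(all(v >= 1))
  # recount oracle via the definition
  r2_1 <- summary(lm(x1 ~ x2 + x3, data = X))$r.squared
  expect_equal(unname(v["x1"]), 1 / (1 - r2_1), tolerance = 1e-12)
  # cross-check against car::vif on the equivalent model
  y <- rnorm(n)
  vc <- car::vif(lm(y ~ x1 + x2 + x3, data = cbind(X, y = y)))
  expect_equal(unname(v), unname(vc), tolerance = 1e-10)
  # near-duplicated predictors blow up symmetrically
  X2 <- X
  X2$x2 <- X2$x1 + rnorm(n, 0, sd(X$x1) / 50)
  v2 <- vif(X2)
  expect_gt(v2["x1"], 10)
  # VIF invariant to rescaling
  X3 <- X2; X3$x1 <- X3$x1 * 1000
  expect_equal(unname(vif(X3)), unname(v2), tolerance = 1e-8)
  expect_error(vif(data.frame(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("forward stepwise BIC finds planted signal and resists noise", {
  set.seed(66)
  n <- 45
  X <- data.frame(matrix(rnorm(n * 10), n))
  names(X) <- paste0("x", 1:10)
  y <- 2 * X$x1 + rnorm(n, 0, 0.3)
  fit <- forward_stepwise_bic(y, X)
  expect_equal(fit$selected, "x1")
  expect_gt(fit$adj_r_squared, 0.9)
  expect_true(all(diff(fit$path$BIC) < 0))
  # refitting the selected model reproduces the path's final BIC
  rss <- sum(residuals(fit$model)^2)
  expect_equal(n * log(rss / n) + 2 * log(n), tail(fit$path$BIC, 1),
               tolerance = 1e-8)
  # duplicated candidate is never selected twice
  X2 <- cbind(X, x1b = X$x1)
  fit2 <- forward_stepwise_bic(y, X2)
  expect_lte(sum(fit2$selected %in% c("x1", "x1b")), 1)
  # pure noise response, 20 candidates: intercept-only in most replicates.
  # The BIC penalty log(n) must dominate the best-of-20 selection bias, so
  # this is a large-n property (at n near 45 the false-inclusion rate of
  # forward BIC is substantial by design).
  n_big <- 2000
  Xb <- data.frame(matrix(rnorm(n_big * 20), n_big))
  keep <- replicate(200, {
    yy <- rnorm(n_big)
    length(forward_stepwise_bic(yy, Xb)$selected) == 0
  })
  expect_gte(mean(keep), 0.85)
})

test_that("category count test reproduces the temperature/precipitation
           comparison", {
  ct <- category_count_test(c(21, 16))
  expect_equal(ct$statistic, (2.5^2 / 18.5) * 2, tolerance = 1e-9)
  expect_gt(ct$p, 0.05)
  expect_equal(ct$p, pchisq(ct$statistic, 1, lower.tail = FALSE))
  ct2 <- category_count_test(c(10, 10))
  expect_equal(ct2$statistic, 0)
  expect_equal(ct2$p, 1)
  # recount oracle on a 3-category fixture
  cts <- c(9, 14, 7)
  e <- mean(cts)
  expect_equal(category_count_test(cts)$statistic, sum((cts - e)^2 / e),
               tolerance = 1e-12)
  expect_error(category_count_test(c(0, 0)), "zero")
})

test_that("planted longitude and LIG-temperature effects on Q_w are
           recovered with correct signs", {
  set.seed(67)
  cfg <- synthetic_study_config(n_pops = c(PYR_W = 15L, PYR_C = 15L,
                                           PYR_E = 15L), n_ind = 5L)
  out <- generate_study_like_dataset(cfg)
  meta <- out$ds$pops
  q <- generate_q_matrix(meta, steepness = 2, noise_sd = 0.02)
  env <- generate_env_table(meta, target = q$Q_w,
                            signal = c(bio8_lig = -0.9))
  # screen: the planted pair and longitude are caught at lfdr <= 0.05
  sc <- pearson_screen(data.frame(Q_w = q$Q_w),
                       env[!names(env) %in% "pop_id"])
  lf <- local_fdr(sc$z)
  sig <- sc[lf$significant, ]
  expect_true("bio8_lig" %in% sig$env)
  expect_true("longitude" %in% sig$env)
  # stepwise over the significant candidates keeps them, negative signs
  cand <- env[unique(sig$env)]
  fit <- forward_stepwise_bic(q$Q_w, cand)
  expect_true(any(c("bio8_lig", "longitude") %in% fit$selected))
  cf <- coef(fit$model)[-1]
  expect_true(all(cf[names(cf) %in% c("bio8_lig", "longitude")] < 0))
})
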
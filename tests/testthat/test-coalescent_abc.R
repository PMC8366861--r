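test_that("prior draws respect truncation, bounds and time orderings", {
  set.seed(41)
  spec <- prior_spec()
  par <- sample_priors(spec, "S2", 20000)
  # analytic mean of N(25000, 12500) truncated at 10; the sum T1+T2+T3 of an
  # order statistic triple has the same mean as three unordered draws
  a <- (10 - 25000) / 12500
  m_trunc <- 25000 + 12500 * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(par$T1 + par$T2 + par$T3) / 3, m_trunc,
               tolerance = 0.02)
  expect_true(all(par$mu_nu >= 1e-4 & par$mu_nu <= 1e-3))
  expect_true(all(par$mu_cp >= 1e-8 & par$mu_cp <= 1e-3))
  expect_true(all(par$T1 > par$T2 & par$T2 > par$T3))
  expect_true(all(pmax(par$Ta, par$Tb, par$Tc, par$Td) < par$T3))
  expect_true(all(is.na(par$r1)))    # no first admixture in S2
  par3 <- sample_priors(spec, "S3", 500)
  expect_true(all(par3$r1 >= 0.001 & par3$r1 <= 0.999))
  par1 <- sample_priors(spec, "S1", 500)
  expect_true(all(is.na(par1$T3)) && all(is.na(par1$r1)))
  expect_true(all(par1$T1 > par1$T2))
})

test_that("simulator limits: no mutation, instant merge, SMM equilibrium", {
  set.seed(42)
  par <- synthetic_study_config()$par
  par0 <- par; par0$mu_nu <- 0; par0$mu_cp <- 0
  ds0 <- simulate_dataset("S2", par0, n_dip = 10L)
  expect_true(all(ds0$nuc_a1 == ds0$nuc_a1[1, 1]))
  expect_true(all(ds0$cp == ds0$cp[1, 1]))
  # demes merged essentially at t = 0 behave as one panmictic deme
  parm <- par
  parm$T1 <- 3; parm$T2 <- 2; parm$T3 <- 1
  parm$Ta <- parm$Tb <- parm$Tc <- parm$Td <- 0.5
  fst <- replicate(20, {
    ds <- simulate_dataset("S2", parm, n_dip = 15L)
    pairwise_fst(ds, "PyrW", "PyrE")
  })
  expect_lt(abs(mean(fst)), 0.02)
  # SMM equilibrium heterozygosity (reduced-scale check; the full-size one
  # lives in the acceptance suite)
  N <- 2000; mu <- 5e-4
  he <- replicate(150, {
    tr <- ssrdemog:::cpp_sim_tree(50L, 2 * N, matrix(numeric(0), 0, 6))
    al <- ssrdemog:::cpp_mutate_tree(tr$parent, tr$time, tr$n_tips,
                                     mu, 0, 100L)
    expected_heterozygosity(table(al))
  })
  expect_lt(abs(mean(he) - (1 - 1 / sqrt(1 + 8 * N * mu))), 0.03)
})

test_that("chloroplast loci are fully linked, nuclear loci are not", {
  set.seed(43)
  par <- synthetic_study_config()$par
  par$mu_cp <- 2e-4; par$mu_nu <- 5e-4
  # identity-by-state concordance between two loci: correlation, over all
  # pairs of gene copies, of the same-allele indicators. A shared gene tree
  # makes the indicators nearly identical at low mutation rate; independent
  # nuclear trees decouple them.
  ibs_cor <- function(x, y) {
    sx <- outer(x, x, "==")[lower.tri(diag(length(x)))]
    sy <- outer(y, y, "==")[lower.tri(diag(length(y)))]
    if (sd(sx) == 0 || sd(sy) == 0) return(NA_real_)
    cor(sx, sy)
  }
  cp_as <- nu_as <- numeric(40)
  for (i in 1:40) {
    ds <- simulate_dataset("S2", par, n_dip = 15L)
    cp_as[i] <- ibs_cor(ds$cp[, 1], ds$cp[, 2])
    nu_as[i] <- ibs_cor(ds$nuc_a1[, 1], ds$nuc_a1[, 2])
  }
  expect_gt(mean(cp_as, na.rm = TRUE), mean(nu_as, na.rm = TRUE) + 0.2)
  expect_lt(abs(mean(nu_as, na.rm = TRUE)), 0.15)
})

test_that("summary statistics have the documented geometry and layout", {
  expect_length(summary_stat_names(), 2 * (4 * 4 + 4 * 6))
  set.seed(44)
  par <- synthetic_study_config()$par
  ds <- simulate_dataset("S2", par, n_dip = 10L)
  s <- summary_stats(ds)
  expect_false(anyNA(s))
  # permuting individuals within demes leaves every statistic unchanged
  perm <- unlist(lapply(split(seq_len(nrow(ds$ind)), ds$ind$pop_id)
                        [unique(ds$ind$pop_id)], sample))
  ds_p <- ds
  ds_p$ind <- ds$ind[perm, ]
  ds_p$nuc_a1 <- ds$nuc_a1[perm, ]; ds_p$nuc_a2 <- ds$nuc_a2[perm, ]
  ds_p$cp <- ds$cp[perm, , drop = FALSE]
  expect_equal(summary_stats(ds_p), s, tolerance = 1e-12)
  # (delta-mu)^2 on demes shifted by exactly 5 repeats equals 25
  dsd <- ds
  dsd$nuc_a1[] <- 30L; dsd$nuc_a2[] <- 30L
  sel <- dsd$ind$pop_id == "PyrW"
  dsd$nuc_a1[sel, ] <- 35L; dsd$nuc_a2[sel, ] <- 35L
  sd_ <- summary_stats(dsd)
  expect_equal(unname(sd_["nu_dmu2_Alps.PyrW"]), 25)
  expect_equal(unname(sd_["nu_dmu2_Alps.PyrE"]), 0)
  # identical duplicated demes: distances near zero
  dse <- ds
  rows_w <- which(ds$ind$pop_id == "PyrW")
  rows_e <- which(ds$ind$pop_id == "PyrE")
  dse$nuc_a1[rows_e, ] <- ds$nuc_a1[rows_w, ]
  dse$nuc_a2[rows_e, ] <- ds$nuc_a2[rows_w, ]
  se <- summary_stats(dse)
  expect_equal(unname(se["nu_dmu2_PyrW.PyrE"]), 0, tolerance = 1e-12)
  expect_equal(unname(se["nu_das_PyrW.PyrE"]), 0, tolerance = 1e-12)
  # identical frequencies zero the among-deme component; the estimator's
  # small-sample bias is -1/(nc - 1) at most
  expect_lt(abs(se["nu_fst_PyrW.PyrE"]), 0.1)
})

test_that("reference tables are reproducible and correctly bookkept", {
  spec <- prior_spec()
  set.seed(45)
  r1 <- build_reference_table(spec, n_per_scenario = 30L, n_dip = 5L)
  set.seed(45)
  r2 <- build_reference_table(spec, n_per_scenario = 30L, n_dip = 5L)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$params, r2$params)
  expect_equal(as.integer(table(r1$scenario)), rep(30L, 4))
})

test_that("prior-scenario adequacy check flags exactly the outliers", {
  set.seed(46)
  ref <- fake_ref_table(n_per = 1000L)
  obs_mid <- apply(ref$stats, 2, median)
  chk <- prior_scenario_check(ref, obs_mid)
  expect_true(all(abs(chk$ranks$rank_p - 1) < 0.1))
  expect_false(any(chk$ranks$flagged))
  obs_out <- obs_mid; obs_out[1] <- obs_mid[1] + 10
  chk2 <- prior_scenario_check(ref, obs_out)
  expect_true(chk2$ranks$flagged[1])
  # rank p agrees with a direct quantile computation
  x <- ref$stats[, 2]; q <- obs_mid[2]
  direct <- 2 * min((1 + sum(x <= q)), (1 + sum(x >= q))) / (nrow(ref$stats) + 1)
  expect_equal(chk$ranks$rank_p[2], min(1, direct))
})

test_that("model choice resolves separated scenarios and stays flat on
           exchangeable ones", {
  set.seed(47)
  ref <- fake_ref_table(n_per = 2000L,
                        shift = c(S1 = 0, S2 = 6, S3 = -6, S4 = 12))
  obs <- c(rep(6, ncol(ref$stats)))
  names(obs) <- colnames(ref$stats)
  mc <- abc_model_choice(ref, obs)
  expect_equal(sum(mc$direct), 1, tolerance = 1e-9)
  expect_equal(sum(mc$logistic), 1, tolerance = 1e-9)
  expect_equal(mc$selected, "S2")
  expect_gt(mc$logistic["S2"], 0.99)
  expect_true(mc$recovered)
  # two scenarios with identical statistic distributions: about 50/50
  set.seed(48)
  ref2 <- fake_ref_table(n_per = 10000L, shift = c(S1 = 0, S2 = 0))
  obs2 <- setNames(rep(0, ncol(ref2$stats)), colnames(ref2$stats))
  mc2 <- abc_model_choice(ref2, obs2)
  expect_lt(abs(mc2$direct["S1"] - 0.5), 0.05)
  expect_lt(abs(mc2$logistic["S1"] - 0.5), 0.1)
})

test_that("confusion errors hit their fixed points and match a recount", {
  set.seed(49)
  ref <- fake_ref_table(n_per = 1500L,
                        shift = c(S1 = -20, S2 = 0, S3 = 20, S4 = 40))
  obs <- setNames(rep(0, ncol(ref$stats)), colnames(ref$stats))
  ce <- confusion_errors(ref, obs, n_pods = 80L, tolerance_fraction = 0.02)
  expect_true(all(ce$type1 < 0.05))
  expect_true(all(ce$type2 < 0.05))
  expect_equal(sum(ce$confusion), 80)
  # recount oracle
  t1 <- 1 - diag(ce$confusion) / rowSums(ce$confusion)
  expect_equal(unname(ce$type1), unname(t1))
  # exchangeable scenarios: type I near chance level 1 - 1/K
  set.seed(50)
  ref0 <- fake_ref_table(n_per = 1500L)
  ce0 <- confusion_errors(ref0, obs, n_pods = 100L,
                          tolerance_fraction = 0.02)
  expect_gt(mean(ce0$type1), 0.5)
})

test_that("parameter posterior reduces to the prior without information and
           flags singular designs", {
  set.seed(51)
  ref <- fake_ref_table(n_per = 20000L, shift = c(S1 = 0, S2 = 0))
  obs <- setNames(rep(0, ncol(ref$stats)), colnames(ref$stats))
  post <- abc_parameter_posterior(ref, obs, "S1", tolerance_fraction = 0.10,
                                  params = "N1")
  prior_draws <- ref$params$N1[ref$scenario == "S1"]
  ks <- suppressWarnings(stats::ks.test(post$draws$N1, prior_draws))
  expect_lt(unname(ks$statistic), 0.05)
  # a constant statistic column cannot break the regression
  ref2 <- ref
  ref2$stats[, 2] <- ref2$stats[, 1]     # exact collinearity
  post2 <- abc_parameter_posterior(ref2, obs, "S1", params = "N1")
  expect_s3_class(post2, "abc_posterior")
})

test_that("estimator quality metrics match their definitions", {
  pods <- data.frame(true = c(10, 20, 40), est = c(10, 20, 40),
                     lo95 = c(5, 15, 30), hi95 = c(15, 25, 50))
  q <- estimator_quality(pods)
  expect_equal(q$MRB, 0)
  expect_equal(q$rRMSE, 0)
  expect_equal(q$factor2, 1)
  expect_equal(q$coverage95, 1)
  pods2 <- data.frame(true = c(10, 20), est = c(20, 40))
  q2 <- estimator_quality(pods2)
  expect_equal(q2$MRB, 1)
  expect_equal(q2$factor2, 1)   # est/true = 2 is inside the closed interval
  # independent recount
  expect_equal(q2$rRMSE, sqrt(mean(((pods2$est - pods2$true) / pods2$true)^2)))
  pods3 <- data.frame(true = c(0, 10), est = c(1, 10))
  expect_equal(estimator_quality(pods3)$n_excluded, 1)
})

test_that("theta ratio collapses to 1 without resize, is mutation-rate free,
           and log-mode is antisymmetric", {
  w <- rep(1, 500)
  set.seed(52)
  n0 <- exp(rnorm(500, 8, 0.3)); n1 <- exp(rnorm(500, 7, 0.3))
  post <- structure(list(draws = data.frame(N2 = n0, NA2 = n1,
                                            mu_nu = runif(500, 1e-4, 1e-3)),
                         weights = w, scenario = "S2"),
                    class = "abc_posterior")
  tr <- theta_ratio_posterior(post, "PyrW")
  expect_gt(tr$p_gt1, 0.9)
  # doubling the mutation-rate draws changes nothing (mu cancels)
  post_mu <- post; post_mu$draws$mu_nu <- 2 * post_mu$draws$mu_nu
  expect_identical(theta_ratio_posterior(post_mu, "PyrW")$draws, tr$draws)
  # forced N0 = N1: ratio identically 1
  post1 <- post; post1$draws$NA2 <- post1$draws$N2
  tr1 <- theta_ratio_posterior(post1, "PyrW")
  expect_true(all(tr1$draws == 1))
  # swapping current/past flips the ratio: log-modes are antisymmetric
  post_sw <- post
  post_sw$draws$N2 <- n1; post_sw$draws$NA2 <- n0
  tr_sw <- theta_ratio_posterior(post_sw, "PyrW")
  expect_equal(log(tr$mode), -log(tr_sw$mode), tolerance = 0.15)
})

test_that("posterior-predictive check calibrates and rejects the absurd", {
  set.seed(53)
  par <- synthetic_study_config()$par
  ds <- simulate_dataset("S2", par, n_dip = 10L)
  obs <- summary_stats(ds)
  post <- structure(list(
    draws = as.data.frame(par[!vapply(par, is.na, TRUE)])[rep(1, 50), ],
    weights = rep(1, 50), scenario = "S2"), class = "abc_posterior")
  ppc <- model_check_ppc(post, obs, n_rep = 60L, n_dip = 10L)
  # observed data generated from the checked model: few/no flags
  expect_lt(mean(ppc$flagged), 0.25)
  # an impossible observation is flagged at the resolution floor
  obs_bad <- obs
  obs_bad[default_check_stats()] <- 1e6
  ppc_bad <- model_check_ppc(post, obs_bad, n_rep = 60L, n_dip = 10L)
  expect_true(all(ppc_bad$p <= 2 / 61))
  expect_error(model_check_ppc(post, obs, check_stats = default_fit_stats()),
               "overlap")
})

test_that("generation-to-year conversion is exact", {
  expect_equal(generations_to_years(27875), c(836250, 1115000))
  expect_equal(generations_to_years(24100), c(723000, 964000))
  expect_equal(generations_to_years(0), c(0, 0))
  expect_error(generations_to_years(-1), "non-negative")
  expect_error(generations_to_years(10, c(40, 30)), "lo")
})
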
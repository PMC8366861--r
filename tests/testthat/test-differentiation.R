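test_that("WC theta matches the independent nested-ANOVA oracle to 1e-10", {
  set.seed(31)
  for (i in 1:8) {
    nA <- sample(8:25, 1); nB <- sample(8:25, 1)
    gA <- lapply(1:3, function(l) hwe_genotypes(nA, c(.5, .3, .2)))
    gB <- lapply(1:3, function(l) hwe_genotypes(nB, c(.2, .3, .5)))
    ds <- dataset_from_genotypes(list(A = gA, B = gB))
    mine <- pairwise_fst(ds, "A", "B")
    # oracle: sum components over loci, ratio at the end
    comps <- lapply(1:3, function(l) {
      gl <- list(gA[[l]], gB[[l]])
      r <- 2
      n_i <- vapply(gl, nrow, 0L); n_tot <- sum(n_i)
      nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
      alleles <- sort(unique(unlist(gl)))
      out <- c(0, 0, 0)
      for (al in alleles) {
        SSP <- SSI <- SSG <- 0
        xbar <- mean(unlist(lapply(gl, function(g) as.numeric(g == al))))
        for (p in 1:2) {
          x <- (gl[[p]] == al) * 1
          xi <- rowMeans(x); xp <- mean(x)
          SSG <- SSG + sum((x - xi)^2)
          SSI <- SSI + 2 * sum((xi - xp)^2)
          SSP <- SSP + 2 * nrow(x) * (xp - xbar)^2
        }
        MSP <- SSP / (r - 1); MSI <- SSI / (n_tot - r); MSG <- SSG / n_tot
        out <- out + c((MSP - MSI) / (2 * nc), (MSI - MSG) / 2, MSG)
      }
      out
    })
    tot <- Reduce(`+`, comps)
    expect_equal(mine, tot[1] / sum(tot), tolerance = 1e-10)
  }
})

test_that("F_ST fixed points: identical pools near 0, fixed difference near 1", {
  set.seed(32)
  g <- hwe_genotypes(50, c(.5, .3, .2))
  ds_same <- dataset_from_genotypes(list(A = list(g), B = list(g[sample(50), ])))
  expect_lt(abs(pairwise_fst(ds_same, "A", "B")), 0.02)
  ds_fix <- dataset_from_genotypes(list(
    A = list(matrix(101L, 20, 2)), B = list(matrix(111L, 20, 2))))
  expect_gt(pairwise_fst(ds_fix, "A", "B"), 0.95)
  # no shared polymorphic locus -> missing
  ds_mono <- dataset_from_genotypes(list(
    A = list(matrix(101L, 10, 2)), B = list(matrix(101L, 10, 2))))
  expect_true(is.na(pairwise_fst(ds_mono, "A", "B")))
})

test_that("R_ST responds to allele-size shifts and is size-affine invariant", {
  set.seed(33)
  gA <- hwe_genotypes(40, rep(.25, 4))          # alleles 101..104
  gB <- hwe_genotypes(40, rep(.25, 4)) + 20L    # +10 repeats at motif 2
  ds <- dataset_from_genotypes(list(A = list(gA), B = list(gB)))
  rst <- pairwise_rst(ds, "A", "B")
  fst <- pairwise_fst(ds, "A", "B")
  expect_gt(rst, fst + 0.2)
  # adding a constant (in bp, multiple of motif) to all sizes changes nothing
  ds_shift <- dataset_from_genotypes(list(A = list(gA + 50L),
                                          B = list(gB + 50L)))
  expect_equal(pairwise_rst(ds_shift, "A", "B"), rst, tolerance = 1e-12)
  # scaling sizes leaves R_ST unchanged (scale both alleles and motif)
  ds_scale <- dataset_from_genotypes(list(A = list(gA * 3L), B = list(gB * 3L)),
                                     motif_length = 6L)
  expect_equal(pairwise_rst(ds_scale, "A", "B"), rst, tolerance = 1e-12)
  # monomorphic shared locus -> missing
  ds_mono <- dataset_from_genotypes(list(A = list(matrix(102L, 10, 2)),
                                         B = list(matrix(102L, 10, 2))))
  expect_true(is.na(pairwise_rst(ds_mono, "A", "B")))
})

test_that("allele-size permutation test detects stepwise divergence and not
           a scrambled-size null", {
  set.seed(34)
  # long SMM divergence between two demes: sizes carry history
  par <- synthetic_study_config()$par
  par$T1 <- 40000; par$T2 <- 30000; par$T3 <- 20000
  ds <- simulate_dataset("S2", par, n_dip = 15L)
  res <- allele_size_permutation_test(ds, n_perm = 199L)
  expect_lt(res$p, 0.05)
  # scrambling the size labels destroys the signal
  for (l in colnames(ds$nuc_a1)) {
    states <- sort(unique(na.omit(c(ds$nuc_a1[, l], ds$nuc_a2[, l]))))
    relab <- setNames(sample(states), states)
    ds$nuc_a1[, l] <- relab[as.character(ds$nuc_a1[, l])]
    ds$nuc_a2[, l] <- relab[as.character(ds$nuc_a2[, l])]
  }
  res0 <- allele_size_permutation_test(ds, n_perm = 199L)
  expect_gt(res0$p, 0.05)
  expect_error(allele_size_permutation_test(ds, n_perm = 50L), "99")
})

test_that("haversine distances use the 6371-km sphere", {
  m <- haversine_matrix(data.frame(pop_id = c("o", "e", "n"),
                                   latitude = c(0, 0, 10),
                                   longitude = c(0, 1, 0)))
  expect_equal(diag(m), rep(0, 3), ignore_attr = TRUE)
  expect_equal(m["o", "e"], 2 * pi * 6371 / 360, tolerance = 1e-4)
  expect_equal(m, t(m))
  expect_error(haversine_matrix(data.frame(pop_id = "x", latitude = NA,
                                           longitude = 1)), "x")
})

test_that("IBD regression recovers exact linear structure and a
           stepping-stone gradient", {
  set.seed(35)
  meta <- data.frame(pop_id = sprintf("p%d", 1:6), latitude = 45,
                     longitude = seq(0, 5))
  km <- haversine_matrix(meta)
  stat <- 0.001 * km
  r <- ibd_regression(stat, km, n_perm = 99)
  expect_equal(r$slope, 0.001, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  # constant statistic: slope 0, permutation p near 1
  r0 <- ibd_regression(matrix(0.2, 6, 6) - diag(0.2, 6), km, n_perm = 99)
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_gt(r0$p, 0.5)
  # slope-difference test between a steep and its own shuffled copy
  r2 <- ibd_regression(stat, km, n_perm = 99, stat_matrix2 = stat)
  expect_equal(r2$slope_diff, 0, tolerance = 1e-12)
  expect_gt(r2$p_slope_diff, 0.5)
})

test_that("NJ reconstructs additive trees exactly and handles edge cases", {
  # 3 taxa: closed-form branch lengths
  d <- matrix(c(0, 5, 9,
                5, 0, 8,
                9, 8, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_population_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (5 + 9 - 8) / 2)
  expect_equal(unname(bl["b"]), (5 + 8 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 8 - 5) / 2)
  # random additive matrices from random trees, n <= 8: exact recovery
  set.seed(36)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.5, 2)
    dm <- cophenetic(tr0)
    rec <- nj_population_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr0), rec), 0, ignore_attr = TRUE)
    expect_equal(max(abs(cophenetic(rec)[rownames(dm), colnames(dm)] - dm)),
                 0, tolerance = 1e-8)
  }
  # duplicate taxon: zero-distance pair forms a zero-length cherry
  d5 <- as.matrix(dist(c(a = 0, b = 0, c = 3, d = 7, e = 11)))
  tr5 <- nj_population_tree(d5)
  ab <- which(tr5$tip.label %in% c("a", "b"))
  par_ab <- tr5$edge[match(ab, tr5$edge[, 2]), 1]
  expect_equal(par_ab[1], par_ab[2])
  expect_equal(sum(tr5$edge.length[match(ab, tr5$edge[, 2])]), 0,
               tolerance = 1e-12)
  # 2 taxa: trivial single edge
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(ape::Ntip(nj_population_tree(d2)), 2)
})

test_that("locus bootstrap yields supports in [0,1] on the observed tree", {
  set.seed(37)
  par <- synthetic_study_config()$par
  ds <- simulate_dataset("S2", par, n_dip = 10L)
  bs <- nj_bootstrap_support(ds, n_boot = 20L)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  expect_setequal(bs$tree$tip.label, ds$pops$pop_id)
})
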
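# Weir & Cockerham (1984) variance components for one locus, two or more
# populations, diploid data. Returns per-allele components summed: a (among
# populations), b (among individuals within), c (within individuals).
wc_components <- function(geno_list) {
  # geno_list: per population, 2-column matrix of alleles (rows = individuals)
  geno_list <- lapply(geno_list, function(g)
    g[!is.na(g[, 1]) & !is.na(g[, 2]), , drop = FALSE])
  geno_list <- geno_list[vapply(geno_list, nrow, 0L) >= 1L]
  r <- length(geno_list)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n_i <- vapply(geno_list, nrow, 0L)
  n_tot <- sum(n_i)
  n_bar <- mean(n_i)
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  alleles <- sort(unique(unlist(lapply(geno_list, as.vector))))
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- vapply(geno_list, function(g) mean(g == al), 0)
    h_i <- vapply(geno_list, function(g)
      mean((g[, 1] == al) != (g[, 2] == al)), 0)
    p_bar <- sum(n_i * p_i) / n_tot
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / n_tot
    a <- n_bar / nc * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                               h_bar / 4) / (n_bar - 1))
    b <- n_bar / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                  (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

# haploid analogue: among/within components from gene-copy frequencies
wc_components_haploid <- function(copies_list) {
  copies_list <- lapply(copies_list, na.omit)
  copies_list <- copies_list[lengths(copies_list) >= 1L]
  r <- length(copies_list)
  if (r < 2L) return(c(a = NA_real_, b = 0, c = NA_real_))
  n_i <- lengths(copies_list)
  n_tot <- sum(n_i)
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  alleles <- sort(unique(unlist(copies_list)))
  a_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- vapply(copies_list, function(x) mean(x == al), 0)
    p_bar <- sum(n_i * p_i) / n_tot
    msp <- sum(n_i * (p_i - p_bar)^2) / (r - 1)
    msg <- sum(n_i * p_i * (1 - p_i)) / (n_tot - r)
    a_tot <- a_tot + (msp - msg) / nc
    c_tot <- c_tot + msg
  }
  c(a = a_tot, b = 0, c = c_tot)
}

#' Pairwise multilocus F_ST (Weir-Cockerham theta)
#'
#' Per-locus variance components are summed across loci before taking the
#' ratio (WC 1984 weighting). Diploid components for nuclear loci; haploid
#' among/within components for chloroplast loci.
#'
#' @param ds a [geno_dataset()].
#' @param popA,popB population ids.
#' @param genome marker class.
#' @return multilocus theta (`NA` when no shared polymorphic locus).
#' @export
pairwise_fst <- function(ds, popA, popB, genome = c("nuclear", "chloroplast")) {
  genome <- match.arg(genome)
  loci <- if (genome == "nuclear") colnames(ds$nuc_a1) else colnames(ds$cp)
  num <- den <- 0
  any_poly <- FALSE
  for (l in loci) {
    if (genome == "nuclear") {
      gl <- lapply(c(popA, popB), function(p) {
        sel <- ds$ind$pop_id == p
        cbind(ds$nuc_a1[sel, l], ds$nuc_a2[sel, l])
      })
      if (length(unique(na.omit(unlist(gl)))) < 2L) next
      cmp <- wc_components(gl)
    } else {
      cl <- lapply(c(popA, popB), function(p) ds$cp[ds$ind$pop_id == p, l])
      if (length(unique(na.omit(unlist(cl)))) < 2L) next
      cmp <- wc_components_haploid(cl)
    }
    if (anyNA(cmp)) next
    any_poly <- TRUE
    num <- num + cmp["a"]
    den <- den + sum(cmp)
  }
  if (!any_poly || den == 0) return(NA_real_)
  unname(num / den)
}

#' Pairwise F_ST matrix over all populations
#' @param ds a [geno_dataset()].
#' @param genome marker class.
#' @return symmetric matrix with zero diagonal.
#' @export
fst_matrix <- function(ds, genome = c("nuclear", "chloroplast")) {
  genome <- match.arg(genome)
  pops <- ds$pops$pop_id
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L))
    m[i, j] <- m[j, i] <- pairwise_fst(ds, pops[i], pops[j], genome)
  m
}

# R_ST variance components at one locus from repeat-count gene copies:
# one-way ANOVA with unequal group sizes; sigma2_a = (MSB - MSW)/n0.
rst_components <- function(copies_list) {
  copies_list <- lapply(copies_list, na.omit)
  copies_list <- copies_list[lengths(copies_list) >= 2L]
  r <- length(copies_list)
  if (r < 2L) return(c(a = NA_real_, w = NA_real_))
  n_i <- lengths(copies_list)
  n_tot <- sum(n_i)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  means <- vapply(copies_list, mean, 0)
  grand <- sum(n_i * means) / n_tot
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(copies_list, function(x) sum((x - mean(x))^2), 0))
  msb <- ssb / (r - 1)
  msw <- ssw / (n_tot - r)
  c(a = (msb - msw) / n0, w = msw)
}

#' Pairwise multilocus R_ST (Slatkin)
#'
#' Allele sizes are converted to repeat counts via each locus' motif length;
#' among- and within-population allele-size variance components are summed
#' across loci, `R_ST = sigma2_a / (sigma2_a + sigma2_w)`.
#'
#' @param ds a [geno_dataset()].
#' @param popA,popB population ids.
#' @param loci locus subset (default all nuclear).
#' @return multilocus `R_ST` (`NA` if every shared locus is monomorphic).
#' @export
pairwise_rst <- function(ds, popA, popB, loci = NULL) {
  if (is.null(loci)) loci <- colnames(ds$nuc_a1)
  num <- den <- 0
  any_poly <- FALSE
  for (l in loci) {
    li <- match(l, ds$loci$name)
    cl <- lapply(c(popA, popB), function(p) {
      sel <- ds$ind$pop_id == p
      repeat_counts(c(ds$nuc_a1[sel, l], ds$nuc_a2[sel, l]),
                    ds$loci$motif_length[li], ds$loci$allele_unit[li])
    })
    if (length(unique(na.omit(unlist(cl)))) < 2L) next
    cmp <- rst_components(cl)
    if (anyNA(cmp)) next
    any_poly <- TRUE
    num <- num + cmp["a"]
    den <- den + sum(cmp)
  }
  if (!any_poly || den == 0) return(NA_real_)
  unname(num / den)
}

#' Pairwise R_ST matrix
#' @inheritParams pairwise_rst
#' @return symmetric matrix with zero diagonal.
#' @export
rst_matrix <- function(ds, loci = NULL) {
  pops <- ds$pops$pop_id
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L))
    m[i, j] <- m[j, i] <- pairwise_rst(ds, pops[i], pops[j], loci)
  m
}

# global (all-population) multilocus R_ST given a per-locus size map
global_rst <- function(ds, size_maps) {
  pops <- ds$pops$pop_id
  loci <- names(size_maps)
  num <- den <- 0
  for (l in loci) {
    cl <- lapply(pops, function(p) {
      sel <- ds$ind$pop_id == p
      a <- c(ds$nuc_a1[sel, l], ds$nuc_a2[sel, l])
      unname(size_maps[[l]][as.character(a)])
    })
    if (length(unique(na.omit(unlist(cl)))) < 2L) next
    cmp <- rst_components(cl)
    if (anyNA(cmp)) next
    num <- num + cmp["a"]
    den <- den + sum(cmp)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Allele-size permutation test of phylogeographic signal
#'
#' Tests whether `R_ST` exceeds its permutation distribution `pR_ST` obtained
#' by shuffling allele sizes among allelic states within each locus (allele
#' identities preserved, sizes reassigned). Under mutation processes where
#' size carries no history (infinite-allele-like), the observed `R_ST` is a
#' typical draw from `pR_ST` (which has the same expectation as `F_ST`); a
#' one-sided excess indicates stepwise-mutation (phylogeographic) signal.
#'
#' @param ds a [geno_dataset()].
#' @param n_perm number of permutations (>= 99).
#' @param loci locus subset (default all nuclear loci).
#' @return list with `rst_obs`, `perm` (the null `pR_ST` draws), and the
#'   one-sided `p = (1 + #[pR_ST >= obs]) / (n_perm + 1)`.
#' @export
allele_size_permutation_test <- function(ds, n_perm = 10000L, loci = NULL) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  if (is.null(loci)) loci <- colnames(ds$nuc_a1)
  maps <- list()
  for (l in loci) {
    li <- match(l, ds$loci$name)
    states <- sort(unique(na.omit(c(ds$nuc_a1[, l], ds$nuc_a2[, l]))))
    if (length(states) < 2L) next   # single-allele locus carries no signal
    sizes <- repeat_counts(states, ds$loci$motif_length[li],
                           ds$loci$allele_unit[li])
    maps[[l]] <- setNames(sizes, states)
  }
  if (!length(maps)) stop("no polymorphic locus with >= 2 allele sizes")
  rst_obs <- global_rst(ds, maps)
  perm <- vapply(seq_len(n_perm), function(i) {
    pm <- lapply(maps, function(m) setNames(sample(m), names(m)))
    global_rst(ds, pm)
  }, 0)
  p <- (1 + sum(perm >= rst_obs, na.rm = TRUE)) / (n_perm + 1)
  list(rst_obs = rst_obs, perm = perm, p = p, n_perm = n_perm)
}

#' Great-circle distance matrix (km)
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param meta data.frame with `pop_id`, `latitude`, `longitude`.
#' @return symmetric km matrix.
#' @export
haversine_matrix <- function(meta) {
  if (anyNA(meta$latitude) || anyNA(meta$longitude))
    stop("missing coordinates for population(s): ",
         paste(meta$pop_id[is.na(meta$latitude) | is.na(meta$longitude)],
               collapse = ", "))
  m <- geosphere::distm(cbind(meta$longitude, meta$latitude),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371))
  dimnames(m) <- list(meta$pop_id, meta$pop_id)
  m
}

#' Isolation-by-distance regression with Mantel-style permutation
#'
#' OLS of the lower triangle of a pairwise statistic on geographic distance;
#' significance by permuting population labels (rows/columns jointly) of the
#' statistic matrix. Optionally compares the slopes of two statistics (e.g.
#' F_ST vs R_ST) under the same joint permutation scheme.
#'
#' @param stat_matrix pairwise statistic matrix.
#' @param km_matrix pairwise distance matrix (same order).
#' @param n_perm permutations.
#' @param stat_matrix2 optional second statistic for the slope-difference test.
#' @param linearized use `s/(1-s)` instead of the raw statistic.
#' @param log_distance regress on `log(km)`.
#' @return list with `slope`, `intercept`, `r_squared`, `p` and, when
#'   `stat_matrix2` is given, `slope2`, `slope_diff`, `p_slope_diff`.
#' @export
ibd_regression <- function(stat_matrix, km_matrix, n_perm = 999L,
                           stat_matrix2 = NULL, linearized = FALSE,
                           log_distance = FALSE) {
  n <- nrow(stat_matrix)
  stopifnot(n >= 4L, all(dim(km_matrix) == dim(stat_matrix)))
  tf <- function(m) if (linearized) m / (1 - m) else m
  d <- if (log_distance) log(km_matrix) else km_matrix
  lt <- lower.tri(d)
  if (var(d[lt]) == 0) stop("zero variance in distances")
  fit1 <- lm(tf(stat_matrix)[lt] ~ d[lt])
  slope <- unname(coef(fit1)[2])
  r2 <- suppressWarnings(summary(fit1)$r.squared)  # exact fits are legal
  two <- !is.null(stat_matrix2)
  if (two) {
    slope2 <- unname(coef(lm(tf(stat_matrix2)[lt] ~ d[lt]))[2])
    dobs <- slope - slope2
  }
  cnt <- cnt2 <- 0L
  for (i in seq_len(n_perm)) {
    o <- sample.int(n)
    s1 <- unname(coef(lm(tf(stat_matrix)[o, o][lt] ~ d[lt]))[2])
    if (abs(s1) >= abs(slope)) cnt <- cnt + 1L
    if (two) {
      s2 <- unname(coef(lm(tf(stat_matrix2)[o, o][lt] ~ d[lt]))[2])
      if (abs(s1 - s2) >= abs(dobs)) cnt2 <- cnt2 + 1L
    }
  }
  out <- list(slope = slope, intercept = unname(coef(fit1)[1]),
              r_squared = r2, p = (1 + cnt) / (n_perm + 1))
  if (two) {
    out$slope2 <- slope2
    out$slope_diff <- dobs
    out$p_slope_diff <- (1 + cnt2) / (n_perm + 1)
  }
  out
}

#' Neighbor-joining population tree
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a population distance
#' matrix, e.g. pairwise F_ST; extra taxa (outgroups) may simply be extra
#' rows/columns of the matrix.
#'
#' @param dist_matrix square symmetric matrix.
#' @return an [ape::nj()] `phylo` tree (unrooted).
#' @export
nj_population_tree <- function(dist_matrix) {
  stopifnot(isSymmetric(unname(as.matrix(dist_matrix))))
  if (nrow(dist_matrix) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(dist_matrix)[1],
                                        dist_matrix[1, 2] / 2,
                                        rownames(dist_matrix)[2],
                                        dist_matrix[1, 2] / 2))
    return(tr)
  }
  ape::nj(as.dist(dist_matrix))
}

#' Locus-bootstrap support for the NJ population tree
#'
#' Resamples loci with replacement (the exchangeable unit behind a
#' distance-matrix tree), recomputes the F_ST matrix and NJ tree, and tallies
#' the bipartitions of the observed tree.
#'
#' @param ds a [geno_dataset()].
#' @param n_boot bootstrap replicates (the study scale is 10,000; scale down
#'   for interactive use).
#' @param genome marker class.
#' @return list with `tree` (observed NJ tree) and `support` (proportion in
#'   `[0, 1]` per internal node, ordered as [ape::prop.clades()]).
#' @export
nj_bootstrap_support <- function(ds, n_boot = 100L,
                                 genome = c("nuclear", "chloroplast")) {
  genome <- match.arg(genome)
  loci <- if (genome == "nuclear") colnames(ds$nuc_a1) else colnames(ds$cp)
  tree <- nj_population_tree(fst_matrix(ds, genome))
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    res <- sample(loci, replace = TRUE)
    ds_b <- ds
    if (genome == "nuclear") {
      ds_b$nuc_a1 <- ds$nuc_a1[, res, drop = FALSE]
      ds_b$nuc_a2 <- ds$nuc_a2[, res, drop = FALSE]
      colnames(ds_b$nuc_a1) <- colnames(ds_b$nuc_a2) <-
        make.unique(res)
    } else {
      ds_b$cp <- ds$cp[, res, drop = FALSE]
      colnames(ds_b$cp) <- make.unique(res)
    }
    ds_b$loci <- do.call(rbind, lapply(res, function(l)
      ds$loci[ds$loci$name == l, , drop = FALSE]))
    ds_b$loci$name <- make.unique(res)
    m <- fst_matrix(ds_b, genome)
    m[is.na(m)] <- 0
    boots[[b]] <- nj_population_tree(m)
  }
  cl <- ape::prop.clades(tree, boots, rooted = FALSE)
  cl[is.na(cl)] <- 0
  list(tree = tree, support = cl / n_boot)
}
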
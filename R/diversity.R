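#' Nei's unbiased gene diversity at one locus
#'
#' `H_e = n/(n-1) * (1 - sum p_i^2)` with `n` the observed gene copies.
#'
#' @param counts allele counts (table or named/unnamed integer vector).
#' @return `H_e`, or `NA` when fewer than 2 gene copies were observed.
#' @export
expected_heterozygosity <- function(counts) {
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Effective number of alleles
#'
#' Default: `1 / (1 - H_e)` with the sample-size-corrected `H_e` (bias-reduced
#' reciprocal-homozygosity estimator); `unbiased = FALSE` gives the naive
#' `1 / sum p_i^2`. Monomorphic loci give 1; a saturated locus (`H_e` = 1,
#' all copies distinct) gives `Inf` with attribute `saturated = TRUE`.
#'
#' @param counts allele counts.
#' @param unbiased use the corrected `H_e` (default).
#' @return effective allele number.
#' @export
effective_alleles <- function(counts, unbiased = TRUE) {
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  if (length(counts) == 1L) return(1)
  if (unbiased) {
    he <- expected_heterozygosity(counts)
    if (he >= 1 - 1e-12) return(structure(Inf, saturated = TRUE))
    1 / (1 - he)
  } else {
    p <- counts / n
    1 / sum(p^2)
  }
}

#' Proportion of unique alleles in a population
#'
#' An allele is unique when it is carried by exactly one individual of the
#' population (a homozygote still counts as one individual). The proportion
#' is over the distinct alleles observed in the population, per locus set.
#'
#' @param ds a [geno_dataset()].
#' @param pop_id population id.
#' @param genome which loci to use.
#' @return proportion in `[0, 1]` (`NA` if no alleles observed).
#' @export
unique_allele_proportion <- function(ds, pop_id,
                                     genome = c("nuclear", "chloroplast")) {
  genome <- match.arg(genome)
  sel <- ds$ind$pop_id == pop_id
  if (!any(sel)) stop("empty population: ", pop_id)
  loci <- if (genome == "nuclear") colnames(ds$nuc_a1) else colnames(ds$cp)
  n_unique <- n_all <- 0L
  for (l in loci) {
    if (genome == "nuclear") {
      a1 <- ds$nuc_a1[sel, l]; a2 <- ds$nuc_a2[sel, l]
      per_ind <- mapply(function(x, y) unique(na.omit(c(x, y))), a1, a2,
                        SIMPLIFY = FALSE)
    } else {
      per_ind <- lapply(ds$cp[sel, l], function(x) unique(na.omit(x)))
    }
    carriers <- table(unlist(per_ind))   # individuals carrying each allele
    n_all <- n_all + length(carriers)
    n_unique <- n_unique + sum(carriers == 1L)
  }
  if (n_all == 0L) return(NA_real_)
  n_unique / n_all
}

#' Inbreeding coefficient F_i
#'
#' Per nuclear locus `F_i = 1 - H_o / H_e` (observed heterozygote proportion
#' against unbiased gene diversity); the multilocus value is
#' `1 - sum(H_o) / sum(H_e)` over loci with `H_e > 0`.
#'
#' @param ds a [geno_dataset()].
#' @param pop_id population id.
#' @return list with `per_locus` (named vector) and `multilocus`.
#' @export
inbreeding_fi <- function(ds, pop_id) {
  sel <- ds$ind$pop_id == pop_id
  if (sum(sel) < 2L) stop("need at least 2 individuals in ", pop_id)
  loci <- colnames(ds$nuc_a1)
  ho <- he <- setNames(rep(NA_real_, length(loci)), loci)
  for (l in loci) {
    a1 <- ds$nuc_a1[sel, l]; a2 <- ds$nuc_a2[sel, l]
    ok <- !is.na(a1)
    if (sum(ok) < 2L) next
    ho[l] <- mean(a1[ok] != a2[ok])
    he[l] <- expected_heterozygosity(table(c(a1[ok], a2[ok])))
  }
  fi <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  use <- !is.na(he) & he > 0
  multi <- if (any(use)) 1 - sum(ho[use]) / sum(he[use]) else NA_real_
  list(per_locus = fi, multilocus = multi)
}

# P(allele with count Ni absent from a subsample of g out of N copies)
.p_absent <- function(Ni, N, g) exp(lchoose(N - Ni, g) - lchoose(N, g))

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `AR(g) = sum_i [1 - C(N - N_i, g) / C(N, g)]`, computed with
#' log-space binomial coefficients.
#'
#' @param counts allele counts at one locus in one population.
#' @param g standardized number of gene copies (>= 2).
#' @return `AR(g)`, or `NA` when `g` exceeds the observed copies.
#' @export
rarefied_richness <- function(counts, g) {
  if (g < 2) stop("g must be >= 2")
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) return(NA_real_)
  sum(1 - .p_absent(counts, N, g))
}

#' Rarefied private allelic richness at one locus
#'
#' Expected number of alleles found in a `g`-copy subsample of the focal
#' population and simultaneously absent from `g`-copy subsamples of every
#' other population.
#'
#' @param counts_matrix alleles x populations count matrix.
#' @param focal column index or name of the focal population.
#' @param g standardized number of gene copies.
#' @return `pAR(g)`; populations with fewer than `g` copies are dropped from
#'   the "absent elsewhere" product with a warning.
#' @export
private_rarefied_richness <- function(counts_matrix, focal, g) {
  if (g < 2) stop("g must be >= 2")
  cm <- as.matrix(counts_matrix)
  Ns <- colSums(cm)
  if (is.character(focal)) focal <- match(focal, colnames(cm))
  if (Ns[focal] < g) return(NA_real_)
  others <- setdiff(seq_len(ncol(cm)), focal)
  drop <- others[Ns[others] < g]
  if (length(drop)) {
    warning(length(drop), " population(s) with fewer than g copies dropped")
    others <- setdiff(others, drop)
  }
  pres <- 1 - .p_absent(cm[, focal], Ns[focal], g)
  absent <- vapply(others, function(j) .p_absent(cm[, j], Ns[j], g),
                   numeric(nrow(cm)))
  if (length(others) == 0L) return(sum(pres))
  if (is.null(dim(absent))) absent <- matrix(absent, nrow = nrow(cm))
  sum(pres * apply(absent, 1L, prod))
}

#' Per-population diversity table
#'
#' Locus-averaged `N_A`, `N_Ae`, `H_e`, `A_u`, `F_i` (nuclear), and rarefied
#' allelic / private allelic richness at `g` gene copies (defaults: 50 for
#' nuclear, 22 for chloroplast loci).
#'
#' @param ds a [geno_dataset()].
#' @param genome marker class.
#' @param g rarefaction size; `NULL` for the class default.
#' @return data.frame, one row per population.
#' @export
diversity_stats <- function(ds, genome = c("nuclear", "chloroplast"),
                            g = NULL) {
  genome <- match.arg(genome)
  if (is.null(g)) g <- if (genome == "nuclear") 50L else 22L
  loci <- if (genome == "nuclear") colnames(ds$nuc_a1) else colnames(ds$cp)
  pops <- ds$pops$pop_id
  counts <- lapply(loci, function(l) {
    tbs <- lapply(pops, function(p) allele_counts(ds, l, p))
    full <- sort(as.integer(unique(unlist(lapply(tbs, names)))))
    out <- lapply(tbs, function(tb) {
      v <- setNames(numeric(length(full)), full)
      v[names(tb)] <- tb
      v
    })
    names(out) <- pops
    out
  })
  row <- function(p) {
    pa <- lapply(counts, `[[`, p)
    nal <- vapply(pa, function(x) sum(x > 0), 0)
    he <- vapply(pa, expected_heterozygosity, 0)
    # the bias-reduced 1/(1 - He) can nominally exceed the observed allele
    # count in small samples; cap at N_A so effective <= actual holds
    nae <- vapply(seq_along(pa), function(i) {
      v <- effective_alleles(pa[[i]])
      if (is.infinite(v)) return(NA_real_)
      min(v, sum(pa[[i]] > 0))
    }, 0)
    ar <- vapply(pa, function(x) rarefied_richness(x, g), 0)
    par <- vapply(seq_along(loci), function(i) {
      cm <- do.call(cbind, counts[[i]])
      private_rarefied_richness(cm, match(p, pops), g)
    }, 0)
    fi <- if (genome == "nuclear") inbreeding_fi(ds, p)$multilocus else NA_real_
    data.frame(pop_id = p,
               N_A = mean(nal, na.rm = TRUE),
               N_Ae = mean(nae, na.rm = TRUE),
               H_e = mean(he, na.rm = TRUE),
               A_u = unique_allele_proportion(ds, p, genome),
               F_i = fi,
               AR = mean(ar, na.rm = TRUE),
               pAR = mean(par, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(pops, row))
  rownames(out) <- NULL
  out
}

#' PCA on individual allele frequencies
#'
#' Individuals are coded as allele-dosage vectors (0 / 0.5 / 1 per allele for
#' diploid loci, 0 / 1 for haploid), missing data imputed by the population
#' mean dosage, then a centered (optionally unit-variance scaled) PCA.
#'
#' @param ds a [geno_dataset()].
#' @param genome marker class.
#' @param scale. unit-variance scaling (default `FALSE`).
#' @param n_axes number of axes to keep.
#' @return list with `scores`, `explained_variance`, `centroids` (per
#'   population mean scores) and `ellipses` (per-population 2x2 covariance of
#'   the first two axes).
#' @export
pca_allele_freqs <- function(ds, genome = c("nuclear", "chloroplast"),
                             scale. = FALSE, n_axes = 10L) {
  genome <- match.arg(genome)
  n <- nrow(ds$ind)
  if (n < 2L) stop("need at least 2 individuals")
  loci <- if (genome == "nuclear") colnames(ds$nuc_a1) else colnames(ds$cp)
  blocks <- lapply(loci, function(l) {
    if (genome == "nuclear") {
      a1 <- ds$nuc_a1[, l]; a2 <- ds$nuc_a2[, l]
      alleles <- sort(unique(na.omit(c(a1, a2))))
      m <- matrix(NA_real_, n, length(alleles),
                  dimnames = list(NULL, paste0(l, ".", alleles)))
      ok <- !is.na(a1)
      for (j in seq_along(alleles))
        m[ok, j] <- ((a1[ok] == alleles[j]) + (a2[ok] == alleles[j])) / 2
    } else {
      a <- ds$cp[, l]
      alleles <- sort(unique(na.omit(a)))
      m <- matrix(NA_real_, n, length(alleles),
                  dimnames = list(NULL, paste0(l, ".", alleles)))
      ok <- !is.na(a)
      for (j in seq_along(alleles)) m[ok, j] <- as.numeric(a[ok] == alleles[j])
    }
    m
  })
  X <- do.call(cbind, blocks)
  # population-mean imputation
  for (p in ds$pops$pop_id) {
    rows <- ds$ind$pop_id == p
    mu <- colMeans(X[rows, , drop = FALSE], na.rm = TRUE)
    mu[is.nan(mu)] <- colMeans(X, na.rm = TRUE)[is.nan(mu)]
    for (j in which(colSums(is.na(X[rows, , drop = FALSE])) > 0)) {
      miss <- rows & is.na(X[, j])
      X[miss, j] <- mu[j]
    }
  }
  keep <- apply(X, 2L, function(x) var(x) > 0)
  if (!any(keep)) stop("constant dosage matrix: no polymorphism")
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  k <- min(n_axes, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- ds$ind$ind_id
  cent <- aggregate(scores, by = list(pop_id = ds$ind$pop_id), FUN = mean)
  ell <- lapply(split(as.data.frame(scores[, 1:min(2L, k), drop = FALSE]),
                      ds$ind$pop_id), function(d)
                        if (nrow(d) > 2) cov(d) else NULL)
  list(scores = scores, explained_variance = ev[seq_len(k)],
       centroids = cent, ellipses = ell)
}
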
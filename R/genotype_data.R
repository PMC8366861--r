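#' Microsatellite genotype dataset
#'
#' Container for co-dominant diploid nuclear microsatellite (nuSSR) genotypes
#' and haploid chloroplast microsatellite (cpSSR) haplotypes, grouped into
#' populations. Allele codes are positive integers kept exactly as read
#' (fragment sizes in bp or repeat counts, per the locus `allele_unit`);
#' `NA` encodes missing and is excluded from all counts.
#'
#' @param loci data.frame with columns `name`, `genome` ("nuclear" or
#'   "chloroplast"), `motif_length` (bp) and `allele_unit` ("fragment_bp" or
#'   "repeat_count").
#' @param pops data.frame with columns `pop_id`, and optionally `range_label`,
#'   `latitude`, `longitude`, `elevation`; one row per population.
#' @param ind data.frame with columns `ind_id` and `pop_id`, one row per
#'   individual.
#' @param nuc_a1,nuc_a2 integer matrices (individuals x nuclear loci) holding
#'   the unordered allele pair; `NA` = missing. Columns named by locus.
#' @param cp integer matrix (individuals x chloroplast loci); `NA` = missing.
#'
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(loci, pops, ind, nuc_a1 = NULL, nuc_a2 = NULL,
                         cp = NULL) {
  stopifnot(is.data.frame(loci), is.data.frame(pops), is.data.frame(ind))
  if (!all(c("name", "genome") %in% names(loci)))
    stop("loci must have 'name' and 'genome' columns")
  if (!"motif_length" %in% names(loci)) loci$motif_length <- NA_integer_
  if (!"allele_unit" %in% names(loci)) loci$allele_unit <- "fragment_bp"
  if (any(!loci$genome %in% c("nuclear", "chloroplast")))
    stop("locus genome must be 'nuclear' or 'chloroplast'")
  if (!all(ind$pop_id %in% pops$pop_id))
    stop("individual assigned to unknown population")
  n <- nrow(ind)
  nnu <- sum(loci$genome == "nuclear")
  ncp <- sum(loci$genome == "chloroplast")
  if (nnu > 0) {
    stopifnot(nrow(nuc_a1) == n, nrow(nuc_a2) == n,
              ncol(nuc_a1) == nnu, ncol(nuc_a2) == nnu)
    # a genotype is missing as a whole: half-missing pairs are invalid
    bad <- xor(is.na(nuc_a1), is.na(nuc_a2))
    if (any(bad)) stop("half-missing diploid genotype at ",
                       sum(bad), " cell(s)")
    storage.mode(nuc_a1) <- "integer"
    storage.mode(nuc_a2) <- "integer"
    colnames(nuc_a1) <- colnames(nuc_a2) <- loci$name[loci$genome == "nuclear"]
  } else nuc_a1 <- nuc_a2 <- matrix(integer(0), n, 0)
  if (ncp > 0) {
    stopifnot(nrow(cp) == n, ncol(cp) == ncp)
    storage.mode(cp) <- "integer"
    colnames(cp) <- loci$name[loci$genome == "chloroplast"]
  } else cp <- matrix(integer(0), n, 0)
  if (any(c(nuc_a1, nuc_a2, cp) <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers")
  pops$n_sampled <- as.integer(table(factor(ind$pop_id,
                                            levels = pops$pop_id)))
  structure(list(loci = loci, pops = pops, ind = ind,
                 nuc_a1 = nuc_a1, nuc_a2 = nuc_a2, cp = cp),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat(sprintf(
    "geno_dataset: %d individuals / %d populations / %d nuclear + %d chloroplast loci\n",
    nrow(x$ind), nrow(x$pops), ncol(x$nuc_a1), ncol(x$cp)))
  invisible(x)
}

#' Number of individuals per population
#' @param ds a `geno_dataset`
#' @return named integer vector
#' @export
pop_sizes <- function(ds) {
  table(factor(ds$ind$pop_id, levels = ds$pops$pop_id))
}

# Gene-copy matrix for one genome: rows = gene copies (2 per individual for
# nuclear, 1 for chloroplast), plus the population id of each copy.
gene_copies <- function(ds, genome = c("nuclear", "chloroplast")) {
  genome <- match.arg(genome)
  if (genome == "nuclear") {
    al <- rbind(ds$nuc_a1, ds$nuc_a2)
    pop <- rep(ds$ind$pop_id, 2L)
  } else {
    al <- ds$cp
    pop <- ds$ind$pop_id
  }
  list(alleles = al, pop = pop)
}

# allele counts (table) at one locus in one population; NA dropped
allele_counts <- function(ds, locus, pop_id) {
  g <- ds$loci$genome[match(locus, ds$loci$name)]
  if (is.na(g)) stop("unknown locus: ", locus)
  sel <- ds$ind$pop_id %in% pop_id
  a <- if (g == "nuclear")
    c(ds$nuc_a1[sel, locus], ds$nuc_a2[sel, locus])
  else ds$cp[sel, locus]
  table(a[!is.na(a)])
}

# repeat-count conversion for size-based statistics (R_ST, GSM checks)
repeat_counts <- function(alleles, motif_length, allele_unit) {
  if (identical(allele_unit, "repeat_count")) return(as.numeric(alleles))
  if (is.na(motif_length) || motif_length < 1)
    stop("motif_length unknown; cannot convert fragment sizes to repeats")
  as.numeric(alleles) / motif_length
}

#' Subset a dataset to selected populations
#' @param ds a `geno_dataset`
#' @param pop_ids populations to keep
#' @return a `geno_dataset`
#' @export
subset_pops <- function(ds, pop_ids) {
  stopifnot(all(pop_ids %in% ds$pops$pop_id))
  sel <- ds$ind$pop_id %in% pop_ids
  geno_dataset(ds$loci,
               ds$pops[ds$pops$pop_id %in% pop_ids, , drop = FALSE],
               ds$ind[sel, , drop = FALSE],
               ds$nuc_a1[sel, , drop = FALSE], ds$nuc_a2[sel, , drop = FALSE],
               ds$cp[sel, , drop = FALSE])
}
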
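#' Chloroplast haplotype frequency table
#'
#' Combines the (fully linked) chloroplast loci of each individual into a
#' haplotype string `a1-a2-...`; individuals with any missing cpSSR allele
#' are excluded. Frequencies are relative to the non-missing individuals.
#'
#' @param ds a [geno_dataset()] with at least one chloroplast locus.
#' @return list with `overall` (data.frame `haplotype`, `count`, `freq`) and
#'   `by_pop` (data.frame `pop_id`, `haplotype`, `count`, `freq`).
#' @export
combine_cp_haplotypes <- function(ds) {
  if (ncol(ds$cp) == 0L) stop("dataset has no chloroplast loci")
  ok <- rowSums(is.na(ds$cp)) == 0L
  if (!any(ok)) stop("no individual with complete chloroplast haplotype")
  hap <- apply(ds$cp[ok, , drop = FALSE], 1L, paste, collapse = "-")
  pop <- ds$ind$pop_id[ok]
  tab <- table(hap)
  overall <- data.frame(haplotype = names(tab), count = as.integer(tab),
                        freq = as.numeric(tab) / sum(tab),
                        stringsAsFactors = FALSE)
  overall <- overall[order(-overall$count, overall$haplotype), ]
  rownames(overall) <- NULL
  bp <- as.data.frame(table(pop_id = pop, haplotype = hap),
                      stringsAsFactors = FALSE)
  names(bp)[3] <- "count"
  bp <- bp[bp$count > 0, ]
  ns <- table(pop)
  bp$freq <- bp$count / as.numeric(ns[bp$pop_id])
  rownames(bp) <- NULL
  list(overall = overall, by_pop = bp)
}
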
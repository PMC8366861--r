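#' Read a GENEPOP file
#'
#' Parses the GENEPOP text dialect: a title line, one locus name per line (or
#' a single comma-separated line), `POP` separators, and per-individual rows
#' `label , 0102 0304 ...`. Both 2- and 3-digit allele coding are accepted and
#' auto-detected per file from the genotype field width; `00`/`000` (or a
#' whole-genotype `0000`/`000000`) encodes missing. Loci listed in `cp_loci`
#' are read as haploid chloroplast loci (single allele code per field);
#' everything else is diploid nuclear.
#'
#' @param path file path.
#' @param cp_loci character vector of locus names to treat as haploid
#'   chloroplast loci (default none).
#' @param motif_length optional named integer vector of motif lengths (bp)
#'   per locus.
#' @param pop_names optional character vector naming the POP blocks; by
#'   default the label of each block's last individual (GENEPOP convention).
#' @return a [geno_dataset()].
#' @export
read_genepop <- function(path, cp_loci = character(), motif_length = NULL,
                         pop_names = NULL) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*$", raw)]
  if (length(raw) < 3L) stop("GENEPOP parse error at line 1: file too short")
  lines <- trimws(raw)
  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("GENEPOP parse error at line ", ifelse(is.na(first_pop), 1, first_pop),
         ": expected locus list then 'POP'")
  loc_lines <- lines[2:(first_pop - 1L)]
  loci_names <- trimws(unlist(strsplit(loc_lines, ",")))
  loci_names <- loci_names[nzchar(loci_names)]
  L <- length(loci_names)
  if (L == 0L) stop("GENEPOP parse error at line 2: no loci")
  if (!all(cp_loci %in% loci_names))
    stop("cp_loci not found in file: ",
         paste(setdiff(cp_loci, loci_names), collapse = ", "))
  is_cp <- loci_names %in% cp_loci

  body <- lines[(first_pop):length(lines)]
  pop_idx <- cumsum(toupper(body) == "POP")
  rows <- body[toupper(body) != "POP"]
  row_pop <- pop_idx[toupper(body) != "POP"]
  if (length(rows) == 0L) stop("GENEPOP parse error: no individuals")

  split2 <- regmatches(rows, regexpr(",", rows), invert = TRUE)
  labels <- trimws(vapply(split2, `[`, "", 1L))
  genos <- lapply(split2, function(z)
    strsplit(trimws(z[2]), "\\s+")[[1]])
  nf <- lengths(genos)
  if (any(nf != L))
    stop("ragged genotype row for individual '", labels[which(nf != L)[1]],
         "': ", nf[which(nf != L)[1]], " fields, expected ", L)

  gm <- matrix(unlist(genos), nrow = length(rows), ncol = L, byrow = TRUE)
  # detect 2- vs 3-digit coding from field widths
  w <- unique(nchar(gm))
  dig <- if (any(w %in% c(6L, 3L)) && !any(w %in% c(4L, 2L))) 3L
  else if (any(w %in% c(4L, 2L)) && !any(w %in% c(6L, 3L))) 2L
  else stop("cannot auto-detect allele coding width (saw widths: ",
            paste(sort(w), collapse = ","), ")")

  n <- nrow(gm)
  a1 <- a2 <- matrix(NA_integer_, n, sum(!is_cp))
  cpm <- matrix(NA_integer_, n, sum(is_cp))
  jn <- jc <- 0L
  for (j in seq_len(L)) {
    fld <- gm[, j]
    if (is_cp[j]) {
      jc <- jc + 1L
      if (!all(nchar(fld) %in% c(dig, 2L * dig)))
        stop("bad haploid field width at locus ", loci_names[j])
      v <- suppressWarnings(as.integer(substr(fld, 1L, dig)))
      v[v == 0L] <- NA_integer_
      cpm[, jc] <- v
    } else {
      jn <- jn + 1L
      if (!all(nchar(fld) == 2L * dig))
        stop("bad diploid field width at locus ", loci_names[j])
      v1 <- suppressWarnings(as.integer(substr(fld, 1L, dig)))
      v2 <- suppressWarnings(as.integer(substr(fld, dig + 1L, 2L * dig)))
      miss <- v1 == 0L | v2 == 0L
      v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
      a1[, jn] <- v1; a2[, jn] <- v2
    }
  }

  npop <- max(row_pop)
  if (is.null(pop_names)) {
    pop_names <- vapply(seq_len(npop), function(p)
      labels[max(which(row_pop == p))], "")
    if (anyDuplicated(pop_names))
      pop_names <- sprintf("pop%02d", seq_len(npop))
  }
  stopifnot(length(pop_names) == npop)

  ml <- rep(NA_integer_, L)
  if (!is.null(motif_length)) ml[match(names(motif_length), loci_names)] <-
      as.integer(motif_length)
  loci <- data.frame(
    name = c(loci_names[!is_cp], loci_names[is_cp]),
    genome = rep(c("nuclear", "chloroplast"), c(sum(!is_cp), sum(is_cp))),
    motif_length = c(ml[!is_cp], ml[is_cp]),
    allele_unit = "fragment_bp", stringsAsFactors = FALSE)
  pops <- data.frame(pop_id = pop_names, stringsAsFactors = FALSE)
  ind <- data.frame(ind_id = make.unique(labels),
                    pop_id = pop_names[row_pop], stringsAsFactors = FALSE)
  ds <- geno_dataset(loci, pops, ind, a1, a2, cpm)
  attr(ds, "genepop_digits") <- dig
  ds
}

#' Write a GENEPOP file
#'
#' Inverse of [read_genepop()]: one POP block per population, 3-digit allele
#' coding by default, `000` for missing. Chloroplast loci are written as
#' haploid single-code fields.
#'
#' @param ds a [geno_dataset()].
#' @param path output file path.
#' @param title title line.
#' @param digits allele code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "ssrdemog export", digits = 3L) {
  stopifnot(digits %in% c(2L, 3L))
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    if (any(x >= 10^digits)) stop("allele code too wide for ", digits,
                                  "-digit output")
    formatC(x, width = digits, flag = "0")
  }
  nu_names <- colnames(ds$nuc_a1)
  cp_names <- colnames(ds$cp)
  out <- c(title, nu_names, cp_names)
  for (p in ds$pops$pop_id) {
    out <- c(out, "POP")
    sel <- which(ds$ind$pop_id == p)
    for (i in sel) {
      g <- character(0)
      if (length(nu_names))
        g <- paste0(fmt(ds$nuc_a1[i, ]), fmt(ds$nuc_a2[i, ]))
      if (length(cp_names)) g <- c(g, fmt(ds$cp[i, ]))
      out <- c(out, paste0(ds$ind$ind_id[i], " , ", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
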
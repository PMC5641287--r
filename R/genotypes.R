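#' Genotype matrix of inbred / doubled-haploid individuals
#'
#' Container for an individuals-by-loci dosage matrix coded on the 0/0.5/1
#' scale (0 and 1 the two homozygotes, 0.5 the heterozygote), with optional
#' family labels. Missing genotypes are `NA`.
#'
#' @param values Numeric matrix, individuals in rows and loci in columns.
#'   Row and column names are required and must be unique; every non-missing
#'   cell must be exactly 0, 0.5 or 1.
#' @param families Optional named character vector mapping individual ids to
#'   family labels. Names must cover all row names of `values`.
#' @return An object of class `geno_matrix` with elements `values` and
#'   `families`.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("a", "b"), c("m1", "m2")))
#' genotype_matrix(m)
#' @export
genotype_matrix <- function(values, families = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have individual ids as rownames and locus ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate individual ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate locus ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  ok <- is.na(values) | values == 0 | values == 0.5 | values == 1
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage %s at individual '%s', locus '%s' (must be 0, 0.5, 1 or NA)",
                 format(values[bad[1], bad[2]]),
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (!is.null(families)) {
    families <- vapply(families, as.character, character(1))
    missing_ids <- setdiff(rownames(values), names(families))
    if (length(missing_ids))
      stop("`families` lacks labels for: ", paste(utils::head(missing_ids, 5), collapse = ", "))
    families <- families[rownames(values)]
  }
  structure(list(values = values, families = families), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d loci", nrow(x$values), ncol(x$values)))
  if (!is.null(x$families))
    cat(sprintf(", %d families", length(unique(x$families))))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf(", %d missing cells", nmiss))
  cat("\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

individual_ids <- function(G) rownames(G$values)
locus_ids <- function(G) colnames(G$values)

#' Read a genotype matrix from a table or VCF file
#'
#' The table dialect is UTF-8 text, comma- or tab-delimited (sniffed from the
#' header line), first column individual id, header row of locus ids, cells in
#' \{0, 0.5, 1\} with `NA` or an empty field for missing. VCF input (requires
#' the `vcfR` package) must contain biallelic records with diploid GT fields;
#' GT is converted to ALT-allele dosage / 2, i.e. 0/0 -> 0, 0/1 -> 0.5,
#' 1/1 -> 1, ./. -> `NA`. With the VCF route the "reference allele" tracked by
#' downstream allele frequencies is consistently the ALT allele.
#'
#' @param path Path to the file.
#' @param format `"table"` (default) or `"vcf"`.
#' @param families Optional named character vector of family labels, or a
#'   path to a two-column (id, family) table in the same dialect.
#' @return A [genotype_matrix()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("table", "vcf"), families = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(families) && length(families) == 1 && file.exists(families))
    families <- read_family_table(families)
  if (format == "table") read_genotype_table(path, families)
  else read_genotype_vcf(path, families)
}

sniff_sep <- function(line) if (grepl("\t", line)) "\t" else ","

read_genotype_table <- function(path, families = NULL) {
  header <- readLines(path, n = 1L)
  sep <- sniff_sep(header)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          na.strings = c("NA", ""), check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"", fileEncoding = "UTF-8")
  vals <- as.matrix(df)
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  bad <- which(!is.na(vals) & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("cannot parse cell '%s' at row '%s', column '%s' of %s",
                 vals[bad[1, 1], bad[1, 2]],
                 rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]], path))
  }
  genotype_matrix(num, families)
}

read_genotype_vcf <- function(path, families = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    rec <- paste(vcfR::getCHROM(v)[multi][1], vcfR::getPOS(v)[multi][1], sep = ":")
    stop("multi-allelic VCF record not supported: ", rec)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  if (is.null(ids) || anyNA(ids))
    ids <- paste(vcfR::getCHROM(v), vcfR::getPOS(v), sep = ":")
  rownames(gt) <- ids
  core <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0, "0/1" = 0.5, "1/0" = 0.5, "1/1" = 1)
  num <- map[core]
  unknown <- !is.na(core) & !(core %in% c(names(map), "./.", "."))
  if (any(unknown))
    stop("unsupported GT value '", core[unknown][1], "' in ", path)
  dosage <- array(unname(num), dim = dim(gt))
  # loci come out of the VCF in rows; transpose to individuals x loci
  dimnames(dosage) <- dimnames(gt)
  genotype_matrix(t(dosage), families)
}

read_family_table <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(header),
                          colClasses = "character", check.names = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Write a genotype matrix in the tabular dialect
#'
#' Tab-delimited, first column `id`, one column per locus, `NA` for missing.
#' `read_genotypes(write_genotypes(G, path))` returns an object equal to `G`
#' (family labels are written separately with [write_family_table()]).
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(id = individual_ids(G), G$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a family membership table
#'
#' @param G A [genotype_matrix()] with family labels.
#' @param path Output path (two tab-separated columns: id, family).
#' @return `path`, invisibly.
#' @export
write_family_table <- function(G, path) {
  if (is.null(G$families)) stop("genotype matrix has no family labels")
  df <- data.frame(id = individual_ids(G), family = unname(G$families))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-locus reference-allele frequencies
#'
#' The dosage coding makes the mean of non-missing dosages at a locus equal
#' to the frequency of the reference allele, so frequencies may be computed
#' on the genotyped set itself or on any reference subset (e.g. a diversity
#' panel genotyped together with the families of interest).
#'
#' @param G A [genotype_matrix()].
#' @param subset Optional character vector of individual ids to compute the
#'   frequencies on; default all individuals.
#' @param source Label recording which set the frequencies come from.
#' @return An object of class `allele_freqs`: list with `loci`, `p` (named
#'   numeric in \[0, 1\]) and `source`.
#' @export
compute_allele_frequencies <- function(G, subset = NULL,
                                       source = if (is.null(subset)) "all" else "subset") {
  vals <- G$values
  if (!is.null(subset)) {
    unknown <- setdiff(subset, rownames(vals))
    if (length(unknown))
      stop("subset ids not in genotype matrix: ", paste(utils::head(unknown, 5), collapse = ", "))
    vals <- vals[subset, , drop = FALSE]
  }
  n_obs <- colSums(!is.na(vals))
  if (any(n_obs == 0))
    stop("loci with no observed genotype in the frequency subset: ",
         paste(utils::head(colnames(vals)[n_obs == 0], 5), collapse = ", "))
  p <- colMeans(vals, na.rm = TRUE)
  structure(list(loci = colnames(vals), p = p, source = source),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("allele_freqs: %d loci (source: %s), mean p = %.3f\n",
              length(x$p), x$source, mean(x$p)))
  invisible(x)
}

#' Filter markers on minor allele frequency and missingness
#'
#' Retains loci whose minor allele frequency strictly exceeds `maf_min` (in
#' the supplied frequency source) and whose fraction of missing genotypes is
#' at most `max_marker_missing`. Locus order is preserved.
#'
#' @param G A [genotype_matrix()].
#' @param freqs An `allele_freqs` object covering all loci of `G`.
#' @param maf_min Minimum minor allele frequency, exclusive (default 0.01).
#' @param max_marker_missing Maximum tolerated missing fraction per locus
#'   (default 0.10).
#' @return A filtered [genotype_matrix()].
#' @export
filter_markers <- function(G, freqs = compute_allele_frequencies(G),
                           maf_min = 0.01, max_marker_missing = 0.10) {
  missing_loci <- setdiff(locus_ids(G), freqs$loci)
  if (length(missing_loci))
    stop("frequencies missing for loci: ", paste(utils::head(missing_loci, 5), collapse = ", "))
  p <- freqs$p[locus_ids(G)]
  maf <- pmin(p, 1 - p)
  miss_frac <- colMeans(is.na(G$values))
  # strict > ("above" the threshold); maf_min = 0 disables the MAF rule
  keep_maf <- if (maf_min <= 0) rep(TRUE, length(maf)) else maf > maf_min
  keep <- keep_maf & miss_frac <= max_marker_missing
  genotype_matrix(G$values[, keep, drop = FALSE], G$families)
}

#' Filter individuals on missingness and phenotype availability
#'
#' @param G A [genotype_matrix()].
#' @param max_indiv_missing Maximum tolerated missing fraction per individual
#'   (default 0.10).
#' @param phenotypes Optional vector of phenotyped individual ids (or a named
#'   numeric phenotype vector); individuals absent from it are dropped.
#' @return A filtered [genotype_matrix()].
#' @export
filter_individuals <- function(G, max_indiv_missing = 0.10, phenotypes = NULL) {
  miss_frac <- rowMeans(is.na(G$values))
  keep <- miss_frac <= max_indiv_missing
  if (!is.null(phenotypes)) {
    ids <- if (!is.null(names(phenotypes))) names(phenotypes) else as.character(phenotypes)
    keep <- keep & individual_ids(G) %in% ids
  }
  if (!any(keep)) stop("all individuals filtered out")
  fam <- if (is.null(G$families)) NULL else G$families[keep]
  genotype_matrix(G$values[keep, , drop = FALSE], fam)
}

#' Impute missing genotypes by the group (family) mean dosage
#'
#' Each missing cell is replaced by the mean dosage at that locus over the
#' non-missing members of the individual's group — the family-mean rule used
#' for NAM material, where within-family allele frequencies differ strongly
#' from population-wide ones. A (group, locus) combination with no observed
#' genotype falls back to the global locus mean, keeping the operator total.
#'
#' @param G A [genotype_matrix()].
#' @param group_of Named character vector mapping each individual to a group;
#'   defaults to the family labels stored in `G`.
#' @return A [genotype_matrix()] without missing values. Imputed dosages are
#'   group means and therefore generally not in \{0, 0.5, 1\}; the result is
#'   returned as a plain numeric matrix wrapped without re-validating the
#'   dosage domain.
#' @export
impute_missing <- function(G, group_of = G$families) {
  vals <- G$values
  if (!anyNA(vals)) return(G)
  if (is.null(group_of)) stop("no group labels available for imputation")
  unknown <- setdiff(rownames(vals), names(group_of))
  if (length(unknown))
    stop("no group label for: ", paste(utils::head(unknown, 5), collapse = ", "))
  grp <- group_of[rownames(vals)]
  global_mean <- colMeans(vals, na.rm = TRUE)
  if (anyNA(global_mean))
    stop("loci entirely missing cannot be imputed: ",
         paste(utils::head(colnames(vals)[is.na(global_mean)], 5), collapse = ", "))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    block <- vals[rows, , drop = FALSE]
    if (!anyNA(block)) next
    gm <- colMeans(block, na.rm = TRUE)
    gm[is.na(gm)] <- global_mean[is.na(gm)]
    idx <- which(is.na(block), arr.ind = TRUE)
    block[idx] <- gm[idx[, 2]]
    vals[rows, ] <- block
  }
  out <- G
  out$values <- vals
  out
}

#' VanRaden genomic relationship matrix
#'
#' Computes `K[i,j] = sum_l (G[i,l] - p_l) (G[j,l] - p_l) / D` with
#' `D = sum_l p_l (1 - p_l)`, the VanRaden estimator of realized genomic
#' relationships on the 0/0.5/1 dosage scale. When the frequencies are
#' computed on the same individual set, the centering makes every row of `K`
#' sum to zero (so `K` is singular by construction).
#'
#' @param G A [genotype_matrix()] with no missing values (impute first).
#' @param freqs An `allele_freqs` object covering all loci of `G`; defaults
#'   to frequencies computed on `G` itself. Supply panel-based frequencies
#'   here when a reference diversity panel exists.
#' @return A symmetric numeric matrix with individual ids as dimnames.
#' @export
vanraden_kinship <- function(G, freqs = compute_allele_frequencies(G)) {
  if (anyNA(G$values)) stop("genotype matrix has missing values; impute first")
  missing_loci <- setdiff(locus_ids(G), freqs$loci)
  if (length(missing_loci))
    stop("frequencies missing for loci: ", paste(utils::head(missing_loci, 5), collapse = ", "))
  p <- freqs$p[locus_ids(G)]
  D <- sum(p * (1 - p))
  if (D <= 0)
    stop("all loci monomorphic in the frequency source (D = 0); cannot scale kinship")
  W <- sweep(G$values, 2, p)
  K <- tcrossprod(W) / D
  (K + t(K)) / 2
}

#' Kinship threshold network edges
#'
#' Extracts the unordered pairs of individuals whose relationship coefficient
#' strictly exceeds a threshold — the edge set of the kinship network used to
#' inspect how optimized calibration sets cover a population (typical
#' thresholds: 0.2 within multi-family material, 0.4 against a diverse
#' panel).
#'
#' @param K Symmetric kinship matrix with id dimnames.
#' @param threshold Edges are pairs with `K[i,j] > threshold`.
#' @return A data.frame with columns `from`, `to`, `kinship`, one row per
#'   edge, `from < to` lexicographically and rows in lexicographic order.
#' @export
kinship_network_edges <- function(K, threshold) {
  ids <- rownames(K)
  idx <- which(upper.tri(K) & K > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(from = character(0), to = character(0), kinship = numeric(0)))
  a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
  from <- pmin(a, b); to <- pmax(a, b)
  out <- data.frame(from = from, to = to, kinship = K[idx])
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a kinship matrix as TSV
#'
#' @param K Kinship matrix with id dimnames.
#' @param path Output path; first column `id`, then one column per id.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinship matrix written by [write_kinship()]
#' @param path Input path.
#' @return A numeric matrix with id dimnames.
#' @export
read_kinship <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(header),
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}
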
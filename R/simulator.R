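#' Genetic map for the simulator
#'
#' A simple marker map: loci on chromosomes at centimorgan positions. The
#' default layout spaces loci evenly along each chromosome.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param loci_per_chromosome Loci on each chromosome.
#' @param chrom_length_cM Chromosome length in centimorgans.
#' @return An object of class `genetic_map`: data.frame with columns
#'   `locus`, `chromosome`, `position_cM`, sorted by position within
#'   chromosome.
#' @export
genetic_map <- function(n_chromosomes = 10, loci_per_chromosome = 50,
                        chrom_length_cM = 100) {
  pos <- seq(0, chrom_length_cM, length.out = loci_per_chromosome)
  df <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch)
    data.frame(locus = sprintf("chr%d_%d", ch, seq_len(loci_per_chromosome)),
               chromosome = ch, position_cM = pos)))
  validate_genetic_map(df)
}

#' Assemble a genetic map from locus coordinates
#'
#' @param locus Character vector of unique locus ids.
#' @param chromosome Chromosome of each locus.
#' @param position_cM Position of each locus in centimorgans (non-negative,
#'   non-decreasing within chromosome).
#' @return A `genetic_map`.
#' @export
as_genetic_map <- function(locus, chromosome, position_cM) {
  validate_genetic_map(data.frame(locus = as.character(locus),
                                  chromosome = chromosome,
                                  position_cM = position_cM))
}

validate_genetic_map <- function(df) {
  if (anyDuplicated(df$locus)) stop("duplicate locus ids in map")
  if (any(df$position_cM < 0)) stop("map positions must be non-negative")
  ok <- tapply(df$position_cM, df$chromosome, function(x) !is.unsorted(x))
  if (!all(ok)) stop("map positions must be non-decreasing within chromosome")
  rownames(df) <- NULL
  structure(df, class = c("genetic_map", "data.frame"))
}

#' Simulate fully homozygous founder lines
#'
#' Each locus gets an independent reference-allele frequency drawn uniformly
#' in `[maf_low, 1 - maf_low]`; founder genotypes at the locus are iid
#' Bernoulli draws at that frequency, coded 0/1 (inbred lines carry no
#' heterozygous calls). Linkage disequilibrium is absent among founders and
#' arises downstream from co-inheritance within simulated families.
#'
#' @param n_founders Number of founder lines (at least 2).
#' @param map A `genetic_map`.
#' @param maf_low Lower bound of the per-locus frequency draw (default 0.2).
#' @param seed Integer seed.
#' @param prefix Id prefix for the founders.
#' @return A [genotype_matrix()] of 0/1 dosages.
#' @export
simulate_founders <- function(n_founders, map, maf_low = 0.2, seed = 1,
                              prefix = "founder") {
  if (n_founders < 2) stop("need at least 2 founders")
  set.seed(as.integer(seed))
  L <- nrow(map)
  p <- stats::runif(L, maf_low, 1 - maf_low)
  vals <- matrix(stats::rbinom(n_founders * L, 1, rep(p, each = n_founders)),
                 n_founders, L,
                 dimnames = list(sprintf("%s%d", prefix, seq_len(n_founders)),
                                 map$locus))
  genotype_matrix(vals)
}

# Haldane map function: recombination fraction for an interval of d cM.
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# One meiotic gamete per row: parental-origin indicators (0/1) per locus,
# built per chromosome from independent crossovers (no interference).
sample_gamete_origins <- function(n_gametes, map) {
  origins <- matrix(0L, n_gametes, nrow(map))
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    L <- length(idx)
    first <- stats::rbinom(n_gametes, 1, 0.5)
    if (L == 1) { origins[, idx] <- first; next }
    r <- haldane_r(diff(map$position_cM[idx]))
    switches <- matrix(stats::rbinom(n_gametes * (L - 1), 1, rep(r, each = n_gametes)),
                       n_gametes, L - 1)
    cum <- matrix(0L, n_gametes, L)
    cum[, -1] <- if (L == 2) switches else t(apply(switches, 1, cumsum))
    origins[, idx] <- (first + cum) %% 2L
  }
  origins
}

#' Simulate a doubled-haploid family from two inbred parents
#'
#' Each DH line is one F1 gamete — a single meiosis with crossovers placed
#' by the Haldane model (recombination between adjacent loci `d` cM apart
#' with probability `(1 - exp(-2d/100))/2`, independent across intervals and
#' chromosomes) — whose genome is then doubled, so offspring are fully
#' homozygous (0/1 dosages only).
#'
#' @param parent1,parent2 Named 0/1 dosage vectors over the map's loci
#'   (rows of a founder [genotype_matrix()]).
#' @param n_dh Number of DH lines.
#' @param map A `genetic_map`.
#' @param seed Integer seed.
#' @param prefix Id prefix for the offspring.
#' @return A [genotype_matrix()] of the DH family.
#' @export
simulate_dh_family <- function(parent1, parent2, n_dh, map, seed = 1,
                               prefix = "dh") {
  if (any(parent1 == 0.5) || any(parent2 == 0.5))
    stop("parents must be homozygous at all loci")
  parent1 <- parent1[map$locus]
  parent2 <- parent2[map$locus]
  if (anyNA(parent1) || anyNA(parent2))
    stop("parents must be genotyped at every map locus")
  set.seed(as.integer(seed))
  origins <- sample_gamete_origins(n_dh, map)
  vals <- matrix(ifelse(origins == 0L,
                        rep(parent1, each = n_dh),
                        rep(parent2, each = n_dh)),
                 n_dh, nrow(map),
                 dimnames = list(sprintf("%s%d", prefix, seq_len(n_dh)),
                                 map$locus))
  genotype_matrix(vals)
}

#' Simulate a NAM design of doubled-haploid families
#'
#' Crosses one central inbred line with each donor parent and derives a DH
#' family from every cross, emulating a nested association mapping
#' population: all families share the central parent, so between-family
#' relatedness exceeds that of unrelated material.
#'
#' @param central_parent Named 0/1 dosage vector (the shared parent).
#' @param donor_parents [genotype_matrix()] of the donor founders, one row
#'   per family to create.
#' @param family_sizes Integer vector, one positive size per donor.
#' @param map A `genetic_map`.
#' @param seed Integer seed.
#' @param family_names Optional family labels; default `famA`, `famB`, ...
#' @return A [genotype_matrix()] with family labels covering all DH lines.
#' @export
simulate_nam <- function(central_parent, donor_parents, family_sizes, map,
                         seed = 1, family_names = NULL) {
  n_fam <- nrow(donor_parents$values)
  if (length(family_sizes) != n_fam)
    stop("family_sizes must have one entry per donor parent")
  if (any(family_sizes < 1)) stop("family sizes must be positive")
  if (is.null(family_names))
    family_names <- sprintf("fam%s", make.unique(LETTERS[(seq_len(n_fam) - 1) %% 26 + 1]))
  blocks <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    fam <- simulate_dh_family(central_parent, donor_parents$values[f, ],
                              family_sizes[f], map,
                              seed = as.integer(seed) + f,
                              prefix = paste0(family_names[f], "_"))
    blocks[[f]] <- fam$values
  }
  vals <- do.call(rbind, blocks)
  families <- stats::setNames(rep(family_names, family_sizes), rownames(vals))
  genotype_matrix(vals, families)
}

#' Simulate phenotypes with a polygenic additive architecture
#'
#' Draws additive effects `N(0, effect_sd^2)` at the chosen QTL (zero
#' elsewhere), computes true breeding values on the centered coding
#' `TBV = sum_l (dosage_l - 0.5) * effect_l` (symmetric under allele
#' relabeling), and adds Gaussian noise with variance
#' `sigma_e^2 = var(TBV) * (1 - h2) / h2` computed from the realized TBV
#' variance, so the realized narrow-sense heritability matches the target in
#' expectation.
#'
#' @param G A [genotype_matrix()] without missing values.
#' @param h2 Target heritability in (0, 1].
#' @param n_qtl `"all"` (default, fully polygenic) or a number of loci drawn
#'   at random to carry effects.
#' @param effect_sd Standard deviation of the per-QTL effects.
#' @param mu Trait intercept.
#' @param seed Integer seed.
#' @return An object of class `sim_population`: list with `genotypes`,
#'   `true_breeding_values`, `marker_effects`, `phenotypes`, `target_h2`,
#'   `mu`, `sigma_g2` (realized TBV variance), `sigma_e2` and `seed`.
#' @export
simulate_phenotypes <- function(G, h2 = 0.5, n_qtl = "all", effect_sd = 1,
                                mu = 0, seed = 1) {
  if (anyNA(G$values)) stop("genotypes must be complete")
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  set.seed(as.integer(seed))
  L <- ncol(G$values)
  effects <- stats::setNames(numeric(L), locus_ids(G))
  qtl <- if (identical(n_qtl, "all")) seq_len(L) else sample.int(L, n_qtl)
  effects[qtl] <- stats::rnorm(length(qtl), 0, effect_sd)
  tbv <- drop((G$values - 0.5) %*% effects)
  var_tbv <- stats::var(tbv)
  if (var_tbv <= 0 && h2 < 1)
    stop("realized breeding-value variance is zero; cannot set noise for h2 < 1")
  sigma_e2 <- if (h2 == 1) 0 else var_tbv * (1 - h2) / h2
  phen <- mu + tbv + stats::rnorm(length(tbv), 0, sqrt(sigma_e2))
  structure(list(genotypes = G,
                 true_breeding_values = stats::setNames(tbv, individual_ids(G)),
                 marker_effects = effects,
                 phenotypes = stats::setNames(phen, individual_ids(G)),
                 target_h2 = h2, mu = mu,
                 sigma_g2 = var_tbv, sigma_e2 = sigma_e2,
                 seed = as.integer(seed)),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: %d individuals, %d loci, target h2 = %.2f\n",
              nrow(x$genotypes$values), ncol(x$genotypes$values), x$target_h2))
  invisible(x)
}

#' Monte-Carlo check of a contrast's prediction reliability
#'
#' Empirical counterpart of the generalized CD: repeatedly draws genetic
#' values `u ~ N(0, K)` and residuals `e ~ N(0, lambda I)` (i.e.
#' `sigma_g^2 = 1`, `sigma_e^2 = lambda`), forms phenotypes for the
#' calibration records, solves the G-BLUP equations, and returns the squared
#' Pearson correlation between the true (`c'u`) and predicted (`c'u_hat`)
#' contrast values across replicates. The BLUP map is linear in `y`, so it
#' is precomputed once and applied to all replicates at matrix speed.
#'
#' @param K Kinship matrix over the model ids.
#' @param calibration_ids Phenotyped ids.
#' @param contrast A single zero-sum contrast vector over `rownames(K)`.
#' @param lambda Positive variance ratio.
#' @param reps Number of replicates (at least 1000).
#' @param seed Integer seed.
#' @param ridge Ridge for `K` (kept equal to the CD computation's).
#' @return The empirical squared correlation, a scalar.
#' @export
monte_carlo_reliability <- function(K, calibration_ids, contrast, lambda,
                                    reps = 20000, seed = 1,
                                    ridge = KINSHIP_RIDGE) {
  if (reps < 1000) stop("use at least 1000 replicates")
  model_ids <- rownames(K)
  if (abs(sum(contrast)) > 1e-12) stop("contrast must sum to zero")
  calibration_ids <- as.character(calibration_ids)
  Kr <- ridge_kinship(K, ridge)
  cKc <- drop(contrast %*% Kr %*% contrast)
  if (cKc <= 1e-12) stop("contrast has (numerically) zero genetic variance")
  N <- nrow(Kr)
  n <- length(calibration_ids)
  X <- matrix(1, n, 1)
  Z <- incidence_matrix(calibration_ids, model_ids)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * solve(Kr)))
  # u_hat = S y with S the u-block rows of C^{-1} [X; Z]'
  S <- solve(C, rbind(t(X), t(Z)))[-1, , drop = FALSE]
  set.seed(as.integer(seed))
  Lc <- t(chol(Kr))
  U <- Lc %*% matrix(stats::rnorm(N * reps), N, reps)
  Y <- Z %*% U + matrix(stats::rnorm(n * reps, 0, sqrt(lambda)), n, reps)
  true_c <- drop(crossprod(contrast, U))
  pred_c <- drop((crossprod(contrast, S)) %*% Y)
  if (stats::sd(true_c) < 1e-12)
    stop("degenerate contrast variance in the Monte-Carlo sample")
  if (stats::sd(pred_c) < 1e-10 * stats::sd(true_c)) return(0)  # no information
  stats::cor(true_c, pred_c)^2
}

#' Export a simulated population in the tabular dialect
#'
#' Writes the genotype table, the family table, a phenotype TSV
#' (`individual_id`, `trait`, `value`) and the genetic map TSV.
#'
#' @param pop A `sim_population`.
#' @param dir Output directory (created if needed).
#' @param map Optional `genetic_map` to write alongside.
#' @param trait Trait name used in the phenotype table.
#' @return `dir`, invisibly.
#' @export
write_sim_population <- function(pop, dir, map = NULL, trait = "trait1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(pop$genotypes, file.path(dir, "genotypes.tsv"))
  if (!is.null(pop$genotypes$families))
    write_family_table(pop$genotypes, file.path(dir, "families.tsv"))
  utils::write.table(data.frame(individual_id = names(pop$phenotypes),
                                trait = trait, value = unname(pop$phenotypes)),
                     file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map))
    utils::write.table(data.frame(locus = map$locus, chromosome = map$chromosome,
                                  cM = map$position_cM),
                       file.path(dir, "map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
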
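#' Contrasts of each target individual against its family mean
#'
#' Builds the contrast matrix whose column for family member `j` has entry
#' `1 - 1/N` at `j` and `-1/N` at the other `N - 1` family members (zero on
#' calibration-only individuals). The reliability of such a contrast measures
#' how well within-family differences — the Mendelian-sampling part of the
#' genetic value — are predicted, which is what matters when selecting inside
#' a biparental family.
#'
#' @param model_ids Ordered ids of all individuals in the mixed model
#'   (calibration set union predicted family).
#' @param family_members Ids of the predicted family, a subset of
#'   `model_ids` of size at least 2.
#' @return A numeric matrix, `length(model_ids)` rows and one column per
#'   family member; every column sums to zero.
#' @export
family_mean_contrasts <- function(model_ids, family_members) {
  model_ids <- as.character(model_ids)
  family_members <- as.character(family_members)
  if (!all(family_members %in% model_ids))
    stop("family members missing from model_ids: ",
         paste(utils::head(setdiff(family_members, model_ids), 5), collapse = ", "))
  n_fam <- length(family_members)
  if (n_fam < 2)
    stop("no within-family contrast exists for a family of size ", n_fam)
  C <- matrix(0, length(model_ids), n_fam,
              dimnames = list(model_ids, family_members))
  C[family_members, ] <- -1 / n_fam
  C[cbind(family_members, family_members)] <- 1 - 1 / n_fam
  C
}

#' Contrasts of each target individual against the mean of all targets
#'
#' Same construction as [family_mean_contrasts()] but against the mean of
#' the whole target set, ignoring its family structure — the contrast set
#' behind the global criterion `CDallNAM`.
#'
#' @param model_ids Ordered ids of all individuals in the mixed model.
#' @param target_ids Ids of the predicted individuals (at least 2).
#' @return A contrast matrix with one zero-sum column per target.
#' @export
population_mean_contrasts <- function(model_ids, target_ids) {
  family_mean_contrasts(model_ids, target_ids)
}

check_contrasts <- function(C, model_ids) {
  if (!identical(rownames(C), model_ids))
    stop("contrast rows must match the model individual set (same ids, same order)")
  sums <- colSums(C)
  if (any(abs(sums) > 1e-12))
    stop("contrast columns must sum to zero; worst deviation ",
         format(max(abs(sums))))
  if (any(colSums(C != 0) == 0)) stop("all-zero contrast column")
  invisible(TRUE)
}

# Z'MZ for the calibration incidence Z and M the projector orthogonal to X.
# For the default intercept-only X this is Z'Z - (Z'1)(1'Z)/n.
ztmz_matrix <- function(calibration_ids, model_ids, fixed_design = NULL) {
  Z <- incidence_matrix(calibration_ids, model_ids)
  n <- length(calibration_ids)
  if (is.null(fixed_design)) {
    z1 <- colSums(Z)
    crossprod(Z) - tcrossprod(z1) / n
  } else {
    X <- as.matrix(fixed_design)
    M <- diag(n) - X %*% MASS_ginv(crossprod(X)) %*% t(X)
    t(Z) %*% M %*% Z
  }
}

# Moore-Penrose pseudoinverse (symmetric case) without a MASS dependency.
MASS_ginv <- function(A, tol = 1e-10) {
  es <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- abs(es$values) > tol * max(abs(es$values), 1)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  V <- es$vectors[, keep, drop = FALSE]
  V %*% (t(V) / es$values[keep])
}

#' Generalized coefficient of determination of contrasts
#'
#' The generalized CD of a contrast `c` (a vector of weights summing to
#' zero over the model individuals) is the expected squared correlation
#' between the true and the predicted contrast of genetic values under the
#' G-BLUP model:
#' \deqn{CD(c) = \frac{c' (K - \lambda (Z'MZ + \lambda K^{-1})^{-1}) c}
#'   {c' K c}}
#' with `Z` the incidence of the phenotyped records, `M` the projector
#' orthogonal to the fixed-effect design, and `lambda` the variance ratio.
#' It is computable from genotypes alone, before any phenotyping, which is
#' what makes it usable for designing calibration sets.
#'
#' @param K Kinship matrix covering the model ids (rows of `contrasts`).
#' @param calibration_ids Ids of the phenotyped records (subset of the model
#'   ids). May be empty, in which case every CD is exactly 0.
#' @param contrasts Contrast matrix as built by [family_mean_contrasts()] or
#'   [population_mean_contrasts()]; rows must match `rownames(K)`.
#' @param lambda Positive variance ratio.
#' @param fixed_design Optional fixed-effect design over the calibration
#'   records; default intercept-only.
#' @param ridge Diagonal ridge applied to `K` (used consistently in the
#'   numerator and denominator).
#' @return An object of class `cd_result` with `per_contrast` (named vector
#'   of CDs in \[0, 1\]), `aggregate = NULL` and `kind = "raw"`.
#' @examples
#' K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
#' cc <- matrix(c(0.5, -0.5), 2, 1, dimnames = list(c("a", "b"), "a_vs_b"))
#' generalized_cd(K, c("a", "b"), cc, lambda = 1)$per_contrast
#' @export
generalized_cd <- function(K, calibration_ids, contrasts, lambda,
                           fixed_design = NULL, ridge = KINSHIP_RIDGE) {
  model_ids <- rownames(K)
  check_contrasts(contrasts, model_ids)
  calibration_ids <- as.character(calibration_ids)
  if (!all(calibration_ids %in% model_ids))
    stop("calibration ids missing from the kinship matrix")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive and finite")
  Kr <- ridge_kinship(K, ridge)
  denom <- colSums(contrasts * (Kr %*% contrasts))
  if (any(denom <= 0))
    stop("contrast with non-positive genetic variance c'Kc: ",
         paste(utils::head(colnames(contrasts)[denom <= 0], 5), collapse = ", "))
  if (length(calibration_ids) == 0) {
    cd <- stats::setNames(rep(0, ncol(contrasts)), colnames(contrasts))
    return(new_cd_result(cd))
  }
  Kinv <- solve(Kr)
  A <- solve(ztmz_matrix(calibration_ids, model_ids, fixed_design) + lambda * Kinv)
  quad <- colSums(contrasts * (A %*% contrasts))
  cd <- (denom - lambda * quad) / denom
  bad <- cd < -1e-9 | cd > 1 + 1e-9
  if (any(bad))
    stop("CD outside [0, 1] beyond numerical tolerance (worst: ",
         format(cd[which.max(abs(cd - 0.5))]), "); numerical failure")
  cd <- pmin(pmax(cd, 0), 1)
  new_cd_result(stats::setNames(cd, colnames(contrasts)))
}

new_cd_result <- function(per_contrast, aggregate = NULL, kind = "raw",
                          per_family = NULL) {
  structure(list(per_contrast = per_contrast, aggregate = aggregate,
                 kind = kind, per_family = per_family),
            class = "cd_result")
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("cd_result (%s): %d contrast(s), mean CD = %.4f",
              x$kind, length(x$per_contrast), mean(x$per_contrast)))
  if (!is.null(x$aggregate)) cat(sprintf(", aggregate = %.4f", x$aggregate))
  cat("\n")
  invisible(x)
}

#' Prediction error variance of contrasts
#'
#' \deqn{PEV(c) = \frac{c' (Z'MZ + \lambda K^{-1})^{-1} c}{c'c}\, \sigma_e^2}
#' The CD and the PEV of the same contrast are linked by
#' `CD(c) = 1 - lambda * c'(Z'MZ + lambda K^{-1})^{-1} c / c'Kc`.
#'
#' @inheritParams generalized_cd
#' @param sigma_e2 Residual variance scaling the PEV.
#' @return Named numeric vector, one PEV per contrast column.
#' @export
pev <- function(K, calibration_ids, contrasts, lambda, sigma_e2 = 1,
                fixed_design = NULL, ridge = KINSHIP_RIDGE) {
  model_ids <- rownames(K)
  check_contrasts(contrasts, model_ids)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive and finite")
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  Kinv <- solve(ridge_kinship(K, ridge))
  A <- solve(ztmz_matrix(as.character(calibration_ids), model_ids, fixed_design) +
               lambda * Kinv)
  quad <- colSums(contrasts * (A %*% contrasts))
  stats::setNames(quad / colSums(contrasts^2) * sigma_e2, colnames(contrasts))
}

#' Family-aware CD criteria for calibration-set design
#'
#' Evaluates one of the aggregate reliability criteria:
#' \describe{
#'   \item{`cdpop`}{mean over one predicted family of the square roots of
#'     the CDs of the individual-vs-family-mean contrasts — the forecast of
#'     within-family prediction accuracy (square roots make the criterion
#'     commensurate with an accuracy, i.e. a correlation).}
#'   \item{`cdpop_mean`}{unweighted mean of the per-family `cdpop` values
#'     over several predicted families.}
#'   \item{`cdallnam`}{mean of the square roots of the CDs of the
#'     individual-vs-global-mean contrasts over all targets, ignoring family
#'     structure — the forecast of global accuracy.}
#' }
#'
#' @param K Kinship matrix covering calibration and target individuals.
#' @param calibration_ids Phenotyped (or to-be-phenotyped) ids.
#' @param targets For `cdpop`, the ids of one predicted family; for
#'   `cdpop_mean`, a named list of families (or a named character vector of
#'   family labels indexed by id); for `cdallnam`, the ids of all targets.
#' @param kind One of `"cdpop"`, `"cdpop_mean"`, `"cdallnam"`.
#' @param lambda Positive variance ratio (1 when no phenotypes exist yet).
#' @param ridge Diagonal ridge applied to `K`.
#' @return A `cd_result`; `aggregate` holds the criterion value, and for
#'   `cdpop_mean` the element `per_family` holds the per-family `cdpop`s.
#' @export
cd_criterion <- function(K, calibration_ids, targets,
                         kind = c("cdpop", "cdpop_mean", "cdallnam"),
                         lambda = 1, ridge = KINSHIP_RIDGE) {
  kind <- match.arg(kind)
  model_ids <- rownames(K)
  if (kind == "cdpop_mean") {
    fams <- targets
    if (!is.list(fams)) fams <- split(names(targets), unname(targets))
    contrasts <- do.call(cbind, lapply(fams, function(members)
      family_mean_contrasts(model_ids, members)))
    res <- generalized_cd(K, calibration_ids, contrasts, lambda, ridge = ridge)
    fam_index <- rep(names(fams), vapply(fams, length, integer(1)))
    per_fam <- vapply(split(res$per_contrast, fam_index),
                      function(cd) mean(sqrt(cd)), numeric(1))
    return(new_cd_result(res$per_contrast, aggregate = mean(per_fam),
                         kind = kind, per_family = per_fam))
  }
  contrasts <- family_mean_contrasts(model_ids, targets)
  res <- generalized_cd(K, calibration_ids, contrasts, lambda, ridge = ridge)
  new_cd_result(res$per_contrast, aggregate = mean(sqrt(res$per_contrast)),
                kind = kind)
}

#' Mean calibration-target relatedness (Crit_Kin)
#'
#' The average of the relationship coefficients between each calibration
#' individual and each predicted individual — the simple relatedness-based
#' baseline criterion for calibration-set sampling. When the two sets
#' overlap, the self-relationships of the shared ids are included in the
#' plain double mean.
#'
#' @param K Kinship matrix.
#' @param calibration_ids Non-empty calibration ids.
#' @param target_ids Non-empty target ids.
#' @return The mean relatedness, a scalar.
#' @export
crit_kin <- function(K, calibration_ids, target_ids) {
  calibration_ids <- as.character(calibration_ids)
  target_ids <- as.character(target_ids)
  if (length(calibration_ids) == 0 || length(target_ids) == 0)
    stop("calibration and target sets must be non-empty")
  mean(K[calibration_ids, target_ids, drop = FALSE])
}

#' Write a CD report as TSV
#'
#' One row per contrast (label, CD, sqrt(CD)) plus, when present, a final
#' aggregate row flagged in the `aggregate` column.
#'
#' @param result A `cd_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cd_report <- function(result, path) {
  df <- data.frame(contrast = names(result$per_contrast),
                   cd = unname(result$per_contrast),
                   sqrt_cd = sqrt(unname(result$per_contrast)),
                   aggregate = FALSE)
  if (!is.null(result$aggregate))
    df <- rbind(df, data.frame(contrast = result$kind, cd = result$aggregate,
                               sqrt_cd = NA, aggregate = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
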
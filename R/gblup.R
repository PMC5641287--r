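#' Variance ratio from heritability
#'
#' Converts a trait heritability into the mixed-model variance ratio
#' `lambda = sigma_e^2 / sigma_g^2 = 1/h2 - 1`. With `h2 = 0.5` (the usual
#' default when phenotypes are not yet available) this gives `lambda = 1`.
#'
#' @param h2 Heritability, strictly between 0 and 1.
#' @return The positive variance ratio.
#' @export
lambda_from_h2 <- function(h2) {
  if (!is.numeric(h2) || any(h2 <= 0) || any(h2 >= 1))
    stop("h2 must lie strictly between 0 and 1")
  1 / h2 - 1
}

# Ridge added to K before inversion; K built with internally-computed allele
# frequencies is exactly singular (rows sum to 0), so a small ridge is
# required for K^{-1} to exist. Used consistently by the BLUP solver and the
# CD computations.
KINSHIP_RIDGE <- 1e-6

ridge_kinship <- function(K, ridge = KINSHIP_RIDGE) {
  K + diag(ridge, nrow(K))
}

# Incidence of calibration records (rows) on model individuals (columns).
incidence_matrix <- function(calibration_ids, model_ids) {
  Z <- matrix(0, length(calibration_ids), length(model_ids),
              dimnames = list(calibration_ids, model_ids))
  Z[cbind(seq_along(calibration_ids), match(calibration_ids, model_ids))] <- 1
  Z
}

#' Specify a G-BLUP mixed model
#'
#' The model is `y = X beta + Z u + e` with `u ~ N(0, K sigma_g^2)` and
#' `e ~ N(0, I sigma_e^2)`; `Z` is the incidence of the phenotyped
#' (calibration) records on the full individual set entering `u`, which may
#' include unphenotyped prediction targets.
#'
#' @param calibration_ids Ordered ids of the phenotyped records.
#' @param model_ids Ordered ids of all individuals entering `u`
#'   (calibration union target set); defaults to `calibration_ids`.
#' @param lambda Positive variance ratio `sigma_e^2 / sigma_g^2`.
#' @param fixed_design Fixed-effect design matrix `X`, one row per
#'   calibration record; default a single intercept column.
#' @return An object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(calibration_ids, model_ids = calibration_ids,
                             lambda = 1, fixed_design = NULL) {
  calibration_ids <- as.character(calibration_ids)
  model_ids <- as.character(model_ids)
  if (!all(calibration_ids %in% model_ids))
    stop("calibration_ids must be a subset of model_ids")
  if (anyDuplicated(model_ids)) stop("duplicate model ids")
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a single positive finite number")
  n <- length(calibration_ids)
  if (is.null(fixed_design)) {
    fixed_design <- matrix(1, n, 1, dimnames = list(calibration_ids, "(Intercept)"))
  } else {
    fixed_design <- as.matrix(fixed_design)
    if (nrow(fixed_design) != n)
      stop("fixed_design must have one row per calibration record")
  }
  structure(list(calibration_ids = calibration_ids, model_ids = model_ids,
                 lambda = lambda, fixed_design = fixed_design),
            class = "mixed_model_spec")
}

#' Solve the G-BLUP mixed-model equations
#'
#' Solves Henderson's equations
#' \deqn{\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda K^{-1}
#'   \end{bmatrix} \begin{bmatrix} \hat\beta \\ \hat u \end{bmatrix} =
#'   \begin{bmatrix} X'y \\ Z'y \end{bmatrix}}
#' for the fixed effects and the genetic values of all model individuals,
#' including unphenotyped targets. `K` is ridged (see [vanraden_kinship()]
#' for why it is typically singular) before inversion.
#'
#' @param y Phenotype vector over the calibration records (adjusted means),
#'   in the order of `spec$calibration_ids` (names, if present, are checked).
#' @param K Kinship matrix covering at least `spec$model_ids`.
#' @param spec A [mixed_model_spec()].
#' @param ridge Diagonal ridge added to `K` before inversion.
#' @return An object of class `blup_solution`: list with `beta_hat`, `u_hat`
#'   (named over model ids) and `coeff_inverse` (inverse of the coefficient
#'   matrix, reused for PEV/CD work).
#' @examples
#' K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
#' spec <- mixed_model_spec(c("a", "b"), lambda = 1)
#' solve_gblup(c(1, -1), K, spec)$u_hat
#' @export
solve_gblup <- function(y, K, spec, ridge = KINSHIP_RIDGE) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  cal <- spec$calibration_ids
  mod <- spec$model_ids
  if (length(y) != length(cal))
    stop("length(y) must equal the number of calibration records")
  if (!is.null(names(y)) && !identical(names(y), cal))
    y <- y[cal]
  missing_ids <- setdiff(mod, rownames(K))
  if (length(missing_ids))
    stop("kinship matrix lacks: ", paste(utils::head(missing_ids, 5), collapse = ", "))
  Km <- ridge_kinship(K[mod, mod, drop = FALSE], ridge)
  Kinv <- tryCatch(solve(Km), error = function(e)
    stop("kinship matrix not invertible after ridge: ", conditionMessage(e)))
  X <- spec$fixed_design
  Z <- incidence_matrix(cal, mod)
  lam <- spec$lambda
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lam * Kinv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular mixed-model coefficient matrix: ", conditionMessage(e)))
  sol <- drop(Cinv %*% rhs)
  p <- ncol(X)
  structure(list(beta_hat = sol[seq_len(p)],
                 u_hat = stats::setNames(sol[-seq_len(p)], mod),
                 coeff_inverse = Cinv),
            class = "blup_solution")
}

#' @export
print.blup_solution <- function(x, ...) {
  cat(sprintf("blup_solution: %d fixed effect(s), %d genetic values\n",
              length(x$beta_hat), length(x$u_hat)))
  invisible(x)
}

# Restricted log-likelihood of the intercept + polygenic model at variance
# ratio lambda, profiled over sigma_g^2, after projecting out the fixed
# effects (EMMA-style eigendecomposition form). `xi` are the nonzero-space
# eigenvalues of S K S, `eta2` the squared projections of y.
reml_rll <- function(lambda, xi, eta2) {
  m <- length(xi)
  s <- sum(eta2 / (xi + lambda))
  0.5 * (m * log(m / (2 * pi)) - m - m * log(s) - sum(log(xi + lambda)))
}

reml_spectral <- function(y, K) {
  n <- length(y)
  # orthonormal basis of the complement of the intercept: T'1 = 0, T'T = I;
  # the restricted likelihood is the likelihood of the error contrasts T'y
  Tm <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  es <- eigen(crossprod(Tm, K %*% Tm), symmetric = TRUE)
  xi <- pmax(es$values, 0)
  eta <- drop(crossprod(es$vectors, crossprod(Tm, y)))
  list(xi = xi, eta2 = eta^2)
}

#' REML estimation of the variance ratio
#'
#' Maximizes the restricted likelihood of the intercept-plus-polygenic model
#' `y = 1 mu + u + e`, `u ~ N(0, K sigma_g^2)`, over the variance ratio
#' `lambda = sigma_e^2 / sigma_g^2` in `[1e-4, 1e4]`. The fixed effect is
#' projected out and the problem diagonalized by one eigendecomposition, so
#' the search is a fast one-dimensional optimization on `log(lambda)`.
#'
#' @param y Phenotype vector over the calibration individuals.
#' @param K Kinship matrix over the same individuals (same order; names
#'   checked when present).
#' @param interval Search interval for `lambda`.
#' @return List with `lambda`, `sigma_g2`, `sigma_e2`, `h2`
#'   (= 1 / (1 + lambda)) and `loglik` (restricted log-likelihood at the
#'   optimum). When `K` is numerically proportional to the identity the two
#'   variance components are not separable; a warning is issued and the
#'   better boundary of the interval is returned.
#' @export
estimate_lambda_reml <- function(y, K, interval = c(1e-4, 1e4)) {
  if (length(y) < 3) stop("need at least 3 phenotyped individuals for REML")
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    if (!all(names(y) %in% rownames(K))) stop("kinship matrix lacks phenotyped ids")
    K <- K[names(y), names(y), drop = FALSE]
  }
  if (nrow(K) != length(y)) stop("dimensions of y and K differ")
  sp <- reml_spectral(y, K)
  if (max(sp$xi) - min(sp$xi) < 1e-8) {
    warning("kinship numerically proportional to identity: variance components ",
            "not identifiable; returning boundary estimate")
    cands <- interval
  } else {
    opt <- stats::optimize(function(ll) reml_rll(exp(ll), sp$xi, sp$eta2),
                           interval = log(interval), maximum = TRUE, tol = 1e-6)
    cands <- c(exp(opt$maximum), interval)
  }
  rll <- vapply(cands, reml_rll, numeric(1), xi = sp$xi, eta2 = sp$eta2)
  lambda <- cands[which.max(rll)]
  m <- length(sp$xi)
  sigma_g2 <- sum(sp$eta2 / (sp$xi + lambda)) / m
  list(lambda = lambda, sigma_g2 = sigma_g2, sigma_e2 = lambda * sigma_g2,
       h2 = 1 / (1 + lambda), loglik = max(rll))
}
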
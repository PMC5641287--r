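# Small simulated fixtures shared across test files. Everything is built in
# code from seeds; no data files are used.

toy_identity_kinship <- function(ids = c("a", "b")) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}

# A small NAM population with its VanRaden kinship (internal frequencies).
small_nam <- function(n_families = 4, family_size = 15, seed = 1,
                      n_chr = 3, loci_per_chr = 30) {
  map <- genetic_map(n_chr, loci_per_chr, 100)
  founders <- simulate_founders(n_families + 1, map, maf_low = 0.2, seed = seed)
  nam <- simulate_nam(founders$values[1, ],
                      genotype_matrix(founders$values[-1, , drop = FALSE]),
                      rep(family_size, n_families), map, seed = seed + 100)
  list(geno = nam, K = vanraden_kinship(nam), map = map,
       families = split(names(nam$families), nam$families))
}

# A random CD test instance: kinship from simulated genotypes (N <= 30),
# a random calibration subset, a random zero-sum contrast, a random lambda.
random_cd_instance <- function(seed) {
  set.seed(seed)
  N <- sample(5:30, 1)
  L <- sample(40:80, 1)
  ids <- sprintf("i%02d", seq_len(N))
  vals <- matrix(sample(c(0, 1), N * L, replace = TRUE), N, L,
                 dimnames = list(ids, sprintf("m%03d", seq_len(L))))
  G <- genotype_matrix(vals)
  K <- vanraden_kinship(G)
  n_cal <- sample(2:(N - 1), 1)
  cal <- sample(ids, n_cal)
  cvec <- rnorm(N)
  cvec <- cvec - mean(cvec)
  contrast <- matrix(cvec, N, 1, dimnames = list(ids, "c1"))
  lambda <- exp(runif(1, log(0.1), log(10)))
  list(K = K, cal = cal, contrast = contrast, lambda = lambda, ids = ids)
}

# Draw y from the G-BLUP generative model over a kinship (sigma_g2 = 1).
draw_model_phenotypes <- function(K, lambda, mu = 0, ridge = 1e-6) {
  n <- nrow(K)
  u <- drop(t(chol(K + diag(ridge, n))) %*% rnorm(n))
  list(u = u, y = mu + u + rnorm(n, 0, sqrt(lambda)))
}
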
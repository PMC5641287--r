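# NAM study population with unevenly related donor founders: part of the
# donors are DH offspring of crosses between other donors, so family pairs
# differ genuinely in relatedness (as in real multi-parental designs, where
# founders mix ancestral and recent material). Shared by the end-to-end
# directional tests.
simulate_study_nam <- function(family_sizes, map, seed) {
  f <- simulate_founders(5, map, maf_low = 0.15, seed = seed)
  central <- f$values[1, ]
  base <- f$values[2:5, ]
  n_fam <- length(family_sizes)
  donors <- base[rep_len(1:4, n_fam), , drop = FALSE]
  if (n_fam >= 5)
    donors[5, ] <- simulate_dh_family(base[1, ], base[2, ], 1, map,
                                      seed = seed + 20)$values[1, ]
  if (n_fam >= 6)
    donors[6, ] <- simulate_dh_family(base[1, ], base[3, ], 1, map,
                                      seed = seed + 30)$values[1, ]
  rownames(donors) <- sprintf("donor%d", seq_len(n_fam))
  simulate_nam(central, genotype_matrix(donors), family_sizes, map,
               seed = seed + 50)
}

# Phenotypes drawn from the G-BLUP generative model itself:
# y = mu + u + e with u ~ N(0, K) and e ~ N(0, lambda I).
model_phenotypes <- function(K, lambda, mu = 10, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  u <- drop(t(chol(K + diag(1e-6, n))) %*% rnorm(n))
  setNames(mu + u + rnorm(n, 0, sqrt(lambda)), rownames(K))
}
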
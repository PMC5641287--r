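test_that("family-mean contrasts have the 1 - 1/N / -1/N pattern and sum to zero", {
  C <- family_mean_contrasts(c("a", "b", "c"), c("b", "c"))
  expect_equal(unname(C[, "b"]), c(0, 0.5, -0.5))
  expect_equal(unname(C[, "c"]), c(0, -0.5, 0.5))

  model <- sprintf("i%02d", 1:30)
  fam <- model[10:16]
  C7 <- family_mean_contrasts(model, fam)
  expect_equal(dim(C7), c(30, 7))
  expect_lt(max(abs(colSums(C7))), 1e-12)
  expect_equal(unname(C7[fam[1], fam[1]]), 1 - 1 / 7)

  expect_error(family_mean_contrasts(model, model[1]), "family of size 1")
})

test_that("population-mean contrasts generalize the family construction", {
  # all model ids as targets, N = 2: identical to the family version
  expect_equal(population_mean_contrasts(c("a", "b"), c("a", "b")),
               family_mean_contrasts(c("a", "b"), c("a", "b")))
  C <- population_mean_contrasts(letters[1:5], c("a", "b", "c"))
  expect_equal(unname(C[, "a"]), c(1 - 1/3, -1/3, -1/3, 0, 0))
  expect_lt(max(abs(colSums(C))), 1e-12)
})

test_that("the generalized CD reproduces the analytic toy and its limits", {
  K <- toy_identity_kinship()
  cc <- matrix(c(0.5, -0.5), 2, 1, dimnames = list(c("a", "b"), "c1"))
  cd <- generalized_cd(K, c("a", "b"), cc, lambda = 1)
  expect_equal(unname(cd$per_contrast), 0.5, tolerance = 1e-5)

  # PEV toy and the CD-PEV link evaluated by hand: 1 - 0.25/0.5 = 0.5
  p <- pev(K, c("a", "b"), cc, lambda = 1, sigma_e2 = 1)
  expect_equal(unname(p), 0.5, tolerance = 1e-5)
  expect_equal(unname(pev(K, c("a", "b"), cc, 1, sigma_e2 = 2)), 1,
               tolerance = 1e-5)   # linear in sigma_e2

  # single phenotyped record: the intercept absorbs it, CD = 0
  K3 <- toy_identity_kinship(c("a", "b", "c"))
  c3 <- matrix(c(0, 0.5, -0.5), 3, 1, dimnames = list(c("a", "b", "c"), "c1"))
  cd1 <- generalized_cd(K3, "a", c3, lambda = 1)
  expect_equal(unname(cd1$per_contrast), 0, tolerance = 1e-9)

  # lambda -> infinity: no information left
  cd_inf <- generalized_cd(K, c("a", "b"), cc, lambda = 1e6)
  expect_lt(cd_inf$per_contrast, 1e-3)

  # empty calibration set: exactly zero
  cd0 <- generalized_cd(K, character(0), cc, lambda = 1)
  expect_identical(unname(cd0$per_contrast), 0)
})

test_that("CD stays in [0,1] and satisfies the PEV identity on random instances", {
  worst_id <- 0
  for (seed in 1:200) {
    inst <- random_cd_instance(seed)
    cd <- generalized_cd(inst$K, inst$cal, inst$contrast, inst$lambda)$per_contrast
    expect_gte(cd, 0); expect_lte(cd, 1)
    # identity CD = 1 - lambda * c'(Z'MZ + lambda K^-1)^-1 c / c'Kc, via pev()
    p <- pev(inst$K, inst$cal, inst$contrast, inst$lambda, sigma_e2 = 1)
    cKc <- drop(t(inst$contrast) %*% (inst$K + diag(1e-6, nrow(inst$K))) %*% inst$contrast)
    ccc <- sum(inst$contrast^2)
    identity_cd <- 1 - inst$lambda * p * ccc / cKc
    worst_id <- max(worst_id, abs(cd - identity_cd))
  }
  expect_lt(worst_id, 1e-9)
})

test_that("adding a calibration individual never decreases the CD of a contrast", {
  worst <- 0
  for (seed in 1:150) {
    inst <- random_cd_instance(seed + 5000)
    extra_pool <- setdiff(inst$ids, inst$cal)
    if (length(extra_pool) == 0) next
    set.seed(seed)
    grown <- c(inst$cal, sample(extra_pool, 1))
    cd_small <- generalized_cd(inst$K, inst$cal, inst$contrast, inst$lambda)$per_contrast
    cd_big <- generalized_cd(inst$K, grown, inst$contrast, inst$lambda)$per_contrast
    worst <- min(worst, cd_big - cd_small)
  }
  expect_gt(worst, -1e-10)
})

test_that("CD equals the Monte-Carlo squared correlation it is defined as", {
  fix <- small_nam(n_families = 2, family_size = 20, seed = 33)
  K <- fix$K
  ids <- rownames(K)
  set.seed(7)
  cal <- sample(ids, 25)
  target_fam <- setdiff(fix$families[[1]], cal)[1:5]
  cvec <- setNames(numeric(length(ids)), ids)
  cvec[target_fam] <- -1 / length(target_fam)
  cvec[target_fam[1]] <- 1 - 1 / length(target_fam)
  contrast <- matrix(cvec, ncol = 1, dimnames = list(ids, "t1"))
  analytic <- generalized_cd(K, cal, contrast, lambda = 1)$per_contrast
  empirical <- monte_carlo_reliability(K, cal, cvec, lambda = 1,
                                       reps = 20000, seed = 99)
  expect_lt(abs(analytic - empirical), 0.02)
})

test_that("cd_criterion aggregates per its definitions", {
  fix <- small_nam(n_families = 3, family_size = 8, seed = 44)
  K <- fix$K
  fams <- fix$families
  cal <- c(fams[[2]], fams[[3]])

  # cdpop = mean of sqrt(per-contrast CD)
  res <- cd_criterion(K, cal, fams[[1]], kind = "cdpop", lambda = 1)
  expect_equal(res$aggregate, mean(sqrt(res$per_contrast)))

  # cdpop_mean = unweighted mean of the per-family cdpop values
  cal2 <- fams[[3]]
  resm <- cd_criterion(K, cal2, fams[1:2], kind = "cdpop_mean", lambda = 1)
  pf <- vapply(fams[1:2], function(m)
    cd_criterion(K, cal2, m, kind = "cdpop", lambda = 1)$aggregate, numeric(1))
  expect_equal(unname(resm$per_family), unname(pf))
  expect_equal(resm$aggregate, mean(pf))

  # cdallnam with targets = one family = whole model set reproduces cdpop
  model <- c(cal, fams[[1]])
  Ksub <- K[model, model]
  a1 <- cd_criterion(Ksub, cal, fams[[1]], kind = "cdallnam", lambda = 1)$aggregate
  a2 <- cd_criterion(Ksub, cal, fams[[1]], kind = "cdpop", lambda = 1)$aggregate
  expect_equal(a1, a2)

  expect_error(cd_criterion(K, cal, fams[[1]][1], kind = "cdpop"), "size 1")
})

test_that("crit_kin is the plain double mean of the cross-block", {
  ids <- c("a", "b", "c")
  K <- diag(3); dimnames(K) <- list(ids, ids)
  K["a", "b"] <- K["b", "a"] <- 0.2
  K["a", "c"] <- K["c", "a"] <- 0.4
  expect_equal(crit_kin(K, "a", c("b", "c")), 0.3)

  K0 <- toy_identity_kinship(ids)
  expect_equal(crit_kin(K0, "a", c("b", "c")), 0)

  set.seed(8)
  K5 <- matrix(rnorm(25), 5, 5); K5 <- (K5 + t(K5)) / 2
  dimnames(K5) <- list(letters[1:5], letters[1:5])
  calib <- c("a", "b"); targ <- c("c", "d", "e")
  acc <- 0
  for (i in calib) for (j in targ) acc <- acc + K5[i, j]
  expect_equal(crit_kin(K5, calib, targ), acc / 6, tolerance = 1e-12)

  expect_error(crit_kin(K5, character(0), targ), "non-empty")
})
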
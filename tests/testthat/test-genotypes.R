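test_that("genotype table IO round-trips and rejects malformed input", {
  vals <- matrix(c(1, 0, 0, 1, 0.5, NA), 2, 3,
                 dimnames = list(c("a", "b"), c("m1", "m2", "m3")))
  G <- genotype_matrix(vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, path)
  G2 <- read_genotypes(path)
  expect_equal(G2$values, G$values)

  # comma dialect is sniffed
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,m1,m2", "a,1,0", "b,0,0.5"), csv)
  expect_equal(read_genotypes(csv)$values[, "m2"], c(a = 0, b = 0.5))

  bad <- withr::local_tempfile()
  writeLines(c("id\tm1", "a\t1", "b\tx"), bad)
  expect_error(read_genotypes(bad), "cannot parse cell 'x'.*row 'b'.*column 'm1'")

  expect_error(genotype_matrix(matrix(c(0.3, 1), 1, 2,
                                      dimnames = list("a", c("m1", "m2")))),
               "invalid dosage")
  expect_error(genotype_matrix(matrix(0, 2, 1,
                                      dimnames = list(c("a", "a"), "m1"))),
               "duplicate individual ids")
})

test_that("VCF genotypes convert GT to dosage and reject multi-allelic records", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./."), vcf)
  G <- read_genotypes(vcf, format = "vcf")
  expect_equal(G$values["s1", ], c(snp1 = 0, snp2 = 1))
  expect_equal(G$values["s2", "snp1"], 0.5)
  expect_true(is.na(G$values["s2", "snp2"]))

  multi <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t300\tsnp3\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), multi)
  expect_error(read_genotypes(multi, format = "vcf"), "multi-allelic.*1:300")
})

test_that("allele frequencies are mean dosages over the non-missing subset", {
  vals <- matrix(c(1, 0, 1, 0.5,
                   1, 1, 1, 1,
                   0, NA, 1, NA), 4, 3,
                 dimnames = list(c("a", "b", "c", "d"), c("m1", "m2", "m3")))
  G <- genotype_matrix(vals)
  fr <- compute_allele_frequencies(G)
  expect_equal(unname(fr$p), c(0.625, 1, 0.5))

  sub <- compute_allele_frequencies(G, subset = c("a", "b"), source = "pair")
  expect_equal(unname(sub$p["m1"]), 0.5)
  expect_equal(sub$source, "pair")

  allna <- genotype_matrix(matrix(NA_real_, 2, 1,
                                  dimnames = list(c("a", "b"), "m1")))
  expect_error(compute_allele_frequencies(allna), "no observed genotype")
})

test_that("marker and individual filters apply the MAF and missingness rules", {
  set.seed(1)
  vals <- matrix(sample(c(0, 1), 10 * 4, replace = TRUE), 10, 4,
                 dimnames = list(sprintf("i%d", 1:10), sprintf("m%d", 1:4)))
  vals[1:3, 3] <- NA                       # 30% missing at m3
  freqs <- structure(list(loci = colnames(vals),
                          p = c(m1 = 0.005, m2 = 0.5, m3 = 0.5, m4 = 1),
                          source = "ext"), class = "allele_freqs")
  G <- genotype_matrix(vals)
  kept <- filter_markers(G, freqs, maf_min = 0.01, max_marker_missing = 0.10)
  expect_equal(colnames(kept$values), "m2")  # m1 rare, m3 gappy, m4 monomorphic

  # boundary: maf exactly at the threshold is excluded (strict >)
  freqs$p["m1"] <- 0.01
  kept2 <- filter_markers(G, freqs, maf_min = 0.01, max_marker_missing = 1)
  expect_false("m1" %in% colnames(kept2$values))

  # identity settings retain everything
  all_kept <- filter_markers(G, freqs, maf_min = 0, max_marker_missing = 1)
  expect_equal(dim(all_kept$values), dim(vals))

  vals2 <- matrix(0, 3, 10, dimnames = list(c("a", "b", "c"), sprintf("m%d", 1:10)))
  vals2[1, 1:2] <- NA                      # 2/10 missing for 'a'
  Gi <- genotype_matrix(vals2)
  expect_equal(rownames(filter_individuals(Gi, 0.10)$values), c("b", "c"))
  expect_equal(dim(filter_individuals(Gi, 1.0)), dim(Gi))
  expect_error(filter_individuals(Gi, 1.0, phenotypes = c(zz = 1)),
               "all individuals filtered")
})

test_that("family-mean imputation fills gaps and falls back to the global mean", {
  vals <- matrix(c(NA, 1, 0, 0.5,
                   1, 1, 0, 0,
                   NA, NA, 1, NA), 4, 3,
                 dimnames = list(c("a", "b", "c", "d"), c("m1", "m2", "m3")))
  fam <- c(a = "f1", b = "f1", c = "f1", d = "f2")
  G <- genotype_matrix(vals, fam)
  imp <- impute_missing(G)
  expect_false(anyNA(imp$values))
  expect_equal(imp$values["a", "m1"], 0.5)       # mean of b = 1, c = 0 within f1
  expect_equal(imp$values["b", "m3"], 1)         # only c observed within f1
  # (f2, m3) entirely missing in its group -> global locus mean (only c = 1)
  expect_equal(imp$values["d", "m3"], 1)
  # no-missing input is returned unchanged
  full <- genotype_matrix(vals[2:3, 1:2, drop = FALSE], fam[2:3])
  expect_identical(impute_missing(full), full)
})

test_that("VanRaden kinship matches the formula, its oracle, and centers rows", {
  # hand example: G = [[1,0],[0,1]], p = 0.5 -> K = [[1,-1],[-1,1]]
  G <- genotype_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                              dimnames = list(c("a", "b"), c("m1", "m2"))))
  fr <- structure(list(loci = c("m1", "m2"), p = c(m1 = 0.5, m2 = 0.5),
                       source = "ext"), class = "allele_freqs")
  expect_equal(vanraden_kinship(G, fr),
               matrix(c(1, -1, -1, 1), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))

  # single individual
  G1 <- genotype_matrix(matrix(c(1, 1), 1, 2,
                               dimnames = list("a", c("m1", "m2"))))
  expect_equal(unname(vanraden_kinship(G1, fr)), matrix(1))

  # monomorphic frequency source
  fr0 <- structure(list(loci = c("m1", "m2"), p = c(m1 = 0, m2 = 1),
                        source = "ext"), class = "allele_freqs")
  expect_error(vanraden_kinship(G, fr0), "monomorphic")

  # naive double-loop oracle on a random 10 x 20 instance
  set.seed(42)
  vals <- matrix(sample(c(0, 0.5, 1), 200, replace = TRUE), 10, 20,
                 dimnames = list(sprintf("i%d", 1:10), sprintf("m%d", 1:20)))
  Gr <- genotype_matrix(vals)
  fr_r <- compute_allele_frequencies(Gr)
  K <- vanraden_kinship(Gr)
  D <- sum(fr_r$p * (1 - fr_r$p))
  naive <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    naive[i, j] <- sum((vals[i, ] - fr_r$p) * (vals[j, ] - fr_r$p)) / D
  expect_lt(max(abs(K - naive)), 1e-12)

  # centering identity and symmetry
  expect_lt(max(abs(rowSums(K))), 1e-10)
  expect_identical(K, t(K))
  expect_true(all(diag(K) >= 0))
})

test_that("filtering and imputation are equivariant under individual reordering", {
  set.seed(7)
  vals <- matrix(sample(c(0, 1, NA), 8 * 12, replace = TRUE, prob = c(.45, .45, .1)),
                 8, 12, dimnames = list(sprintf("i%d", 1:8), sprintf("m%d", 1:12)))
  fam <- setNames(rep(c("f1", "f2"), each = 4), rownames(vals))
  G <- genotype_matrix(vals, fam)
  perm <- sample(rownames(vals))
  Gp <- genotype_matrix(vals[perm, ], fam)

  imp <- impute_missing(G)$values
  imp_p <- impute_missing(Gp)$values
  expect_equal(imp_p, imp[perm, ])

  f1 <- filter_individuals(G, 0.2)$values
  f2 <- filter_individuals(Gp, 0.2)$values
  expect_equal(f2, f1[intersect(perm, rownames(f1)), ])
})

test_that("kinship threshold networks extract exactly the above-threshold pairs", {
  K <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  e <- kinship_network_edges(K, 0.4)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "a"); expect_equal(e$to, "b")

  expect_equal(nrow(kinship_network_edges(K, 0.5)), 0)   # strict >

  K3 <- diag(3); dimnames(K3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  K3["x", "y"] <- K3["y", "x"] <- 0.25
  K3["x", "z"] <- K3["z", "x"] <- 0.10
  K3["y", "z"] <- K3["z", "y"] <- 0.30
  e3 <- kinship_network_edges(K3, 0.2)
  # brute force over all pairs
  ids <- rownames(K3)
  expected <- 0
  for (i in 1:2) for (j in (i + 1):3) if (K3[i, j] > 0.2) expected <- expected + 1
  expect_equal(nrow(e3), expected)
  expect_equal(e3$from, sort(e3$from))
})
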
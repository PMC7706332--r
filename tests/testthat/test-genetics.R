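test_that("SNP filter applies MAF and heterozygosity rules and is idempotent", {
  # 10-SNP toy matrix of an inbred panel: col 1 monomorphic, col 2
  # het-heavy, col 3 rare
  set.seed(1)
  n <- 100
  v <- sapply(1:10, function(j) 2 * rbinom(n, 1, 0.3))
  v[, 1] <- 0                       # MAF 0 -> removed (maf)
  v[, 2] <- rep(c(1, 0, 2), c(10, 60, 30)) # 10% hets -> removed (het)
  v[, 3] <- c(1, rep(0, n - 1))     # MAF 0.005 -> removed (maf)
  G <- genotype_matrix(v)
  flt <- filter_snps(G, maf_min = 0.01, het_max = 0.05)
  expect_equal(ncol(flt$genotypes$values), 7)
  expect_equal(flt$report$reason[1], "maf")
  expect_equal(flt$report$reason[2], "het")
  expect_equal(flt$report$reason[3], "maf")
  expect_equal(sum(flt$report$removed), 3)

  # brute-force recount agrees
  maf <- pmin(colMeans(v) / 2, 1 - colMeans(v) / 2)
  het <- colMeans(v == 1)
  expect_equal(sum(maf >= 0.01 & het <= 0.05), 7)

  # idempotent
  flt2 <- filter_snps(flt$genotypes, maf_min = 0.01, het_max = 0.05)
  expect_identical(flt2$genotypes$values, flt$genotypes$values)

  mono <- genotype_matrix(matrix(0, 10, 2))
  expect_warning(out <- filter_snps(mono), "all SNPs removed")
  expect_equal(ncol(out$genotypes$values), 0)
})

test_that("kinship matrix has GRM structure", {
  G <- simulate_genotypes(60, 800, seed = 4)
  K <- kinship_matrix(G)
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
  # independent HWE genotypes: off-diagonals centred on zero
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.05)

  # duplicated line: off-diagonal equals the diagonal
  v2 <- rbind(G$values, G$values[1, ])
  G2 <- genotype_matrix(v2)
  K2 <- kinship_matrix(G2)
  expect_equal(K2[1, 61], K2[1, 1], tolerance = 1e-12)

  # permuting lines conjugates the kinship
  perm <- sample(60)
  Gp <- genotype_matrix(G$values[perm, ], G$line_ids[perm], G$snp_meta)
  expect_equal(unname(kinship_matrix(Gp)), unname(K[perm, perm]),
               tolerance = 1e-12)

  # missing calls are mean-imputed rather than fatal
  vna <- G$values; vna[1:5, 1:20] <- NA
  expect_silent(Kna <- kinship_matrix(genotype_matrix(vna)))
  expect_false(anyNA(Kna))
})

test_that("population PCs separate discrete subpopulations", {
  set.seed(9)
  n <- 60; m <- 400
  p1 <- runif(m, 0.05, 0.5); p2 <- pmin(0.95, p1 + 0.3)
  v <- rbind(sapply(p1, function(p) rbinom(n / 2, 2, p)),
             sapply(p2, function(p) rbinom(n / 2, 2, p)))
  G <- genotype_matrix(v)
  pcs <- population_pcs(G, 5)
  expect_equal(dim(pcs), c(60L, 5L))
  grp <- rep(1:2, each = 30)
  gap <- abs(diff(tapply(pcs[, 1], grp, mean)))
  pooled_sd <- sqrt(mean(tapply(pcs[, 1], grp, var)))
  expect_gt(gap, 3 * pooled_sd)

  # scores are orthogonal
  gram <- crossprod(pcs)
  expect_equal(gram[upper.tri(gram)], rep(0, 10), tolerance = 1e-6)

  expect_equal(ncol(population_pcs(G, 0)), 0)
  expect_error(population_pcs(G, 60), "smaller")
  expect_error(population_pcs(genotype_matrix(matrix(1, 10, 5)), 2),
               "degenerate")
})

test_that("PVE estimation handles the noise-free and null extremes", {
  G <- simulate_genotypes(200, 1000, seed = 2)
  K <- kinship_matrix(G)
  eg <- eigen(K, symmetric = TRUE)

  # noise-free genetic signal
  set.seed(10)
  y_g <- as.numeric(K %*% rnorm(200))
  expect_gte(estimate_pve(y_g, K)$pve, 0.99)

  # pure noise: small average PVE
  pves <- vapply(1:20, function(r) {
    set.seed(100 + r)
    estimate_pve(rnorm(200), K)$pve
  }, numeric(1))
  expect_lte(mean(pves), 0.08)

  vc <- estimate_pve(y_g, K)
  expect_true(vc$genetic_var >= 0 && vc$residual_var >= 0)
  expect_true(vc$pve >= 0 && vc$pve <= 1)

  expect_error(estimate_pve(rnorm(10), diag(5)), "n x n")
  notpsd <- diag(200); notpsd[1, 2] <- notpsd[2, 1] <- 5
  expect_error(estimate_pve(rnorm(200), notpsd), "positive semi-definite")
})

test_that("REML recovers planted heritability on average", {
  G <- simulate_genotypes(500, 5000, seed = 11)
  K <- kinship_matrix(G)
  for (h2 in c(0.2, 0.5, 0.8)) {
    ests <- vapply(1:50, function(r) {
      sim <- simulate_phenotype(G, geno_pheno_sim(h2 = h2, n_causal = 50,
                                                  seed = 1000 * h2 + r))
      estimate_pve(sim$y, K)$pve
    }, numeric(1))
    expect_lt(abs(mean(ests) - h2), 0.1)
  }
})

test_that("association scan controls type-I error under the null", {
  fracs <- vapply(1:5, function(r) {
    G <- simulate_genotypes(200, 1000, seed = 40 + r)
    set.seed(140 + r)
    y <- rnorm(200)
    res <- gwas_scan(y, G)
    mean(res$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)

  # null p-values are approximately uniform
  G <- simulate_genotypes(200, 2000, seed = 77)
  set.seed(78)
  res <- gwas_scan(rnorm(200), G)
  ks <- suppressWarnings(ks.test(res$p[!is.na(res$p)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong planted SNP is found below Bonferroni", {
  hits <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    G <- simulate_genotypes(300, 1000, seed = 500 + r)
    g <- G$values[, 321]
    set.seed(600 + r)
    y <- g + rnorm(300, 0, sqrt(var(g) * 4))  # SNP explains ~20% of variance
    res <- gwas_scan(y, G, covariates = population_pcs(G, 5),
                     K = kinship_matrix(G))
    ps <- res$p[match(G$snp_meta$id, res$snp_id)]
    if (which.min(ps) == 321 &&
        res$significant[res$snp_id == G$snp_meta$id[321]])
      hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("scan bookkeeping: threshold, skips, covariate checks", {
  G <- simulate_genotypes(100, 50, seed = 3)
  set.seed(4)
  y <- rnorm(100)
  res <- gwas_scan(y, G, alpha = 0.05)
  expect_equal(attr(res, "threshold"), 0.05 / attr(res, "m_tested"))
  expect_true(all(res$significant ==
                    (!is.na(res$p) & res$p <= attr(res, "threshold"))))
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  # sorted by chrom then pos
  expect_false(is.unsorted(order(res$chrom, res$pos)))

  # constant SNP skipped with NA p, excluded from the test count
  v <- G$values; v[, 7] <- 1
  Gc <- genotype_matrix(v, G$line_ids, G$snp_meta)
  resc <- gwas_scan(y, Gc)
  expect_true(is.na(resc$p[resc$snp_id == G$snp_meta$id[7]]))
  expect_equal(attr(resc, "m_tested"), 49)

  # missing genotypes handled per SNP by complete case
  vna <- G$values; vna[1:10, 3] <- NA
  resna <- gwas_scan(y, genotype_matrix(vna, G$line_ids, G$snp_meta))
  expect_false(is.na(resna$p[resna$snp_id == G$snp_meta$id[3]]))

  expect_error(gwas_scan(y, G, covariates = cbind(1, rep(1, 100))),
               "rank deficient")
  expect_error(gwas_scan(rnorm(5), G), "dimensions differ")

  # single-marker scan with m = 1: threshold equals alpha
  G1 <- genotype_matrix(G$values[, 1, drop = FALSE])
  expect_equal(attr(gwas_scan(y, G1), "threshold"), 0.05)
})

test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 170321), 0.05 / 170321)
  expect_lt(abs(bonferroni_threshold(0.05, 170321) - 2.936e-7), 1e-10)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("gene windows use closed 50-kb intervals", {
  genes <- data.frame(
    chrom = c(1, 1, 1),
    start = c(100000, 210000, 350000),
    end = c(120000, 230000, 360000),
    gene_id = c("gA", "gB", "gC"))
  snps <- data.frame(snp_id = "s1", chrom = 1, pos = 160000)
  # gA within 50 kb (gap 40 kb), gB within (gap 0 via window), gC 190 kb away
  hit <- genes_in_window(snps, genes, window_bp = 50000)
  expect_setequal(hit$gene_id, c("gA", "gB"))

  # exact boundary: gene starting at pos + window is included
  edge <- data.frame(chrom = 1, start = 210000, end = 220000,
                     gene_id = "gE")
  hit2 <- genes_in_window(snps, edge, window_bp = 50000)
  expect_equal(hit2$gene_id, "gE")
  hit3 <- genes_in_window(snps, edge, window_bp = 49999)
  expect_equal(nrow(hit3), 0)

  # a gene 60 kb away is excluded: 2 of 3 crafted genes returned
  snps2 <- data.frame(snp_id = "s2", chrom = 1, pos = 290000)
  genes2 <- data.frame(chrom = 1,
                       start = c(240000, 330000, 351000),
                       end = c(250000, 340000, 352000),
                       gene_id = c("g1", "g2", "g3"))  # g3 is 61 kb away
  expect_setequal(genes_in_window(snps2, genes2)$gene_id, c("g1", "g2"))

  expect_equal(nrow(genes_in_window(snps, genes[0, ])), 0)
})

test_that("genotype CSV round trips", {
  dir <- withr::local_tempdir()
  G <- simulate_genotypes(20, 30, seed = 6)
  write_genotypes_csv(G, file.path(dir, "g.csv"), file.path(dir, "m.csv"))
  back <- read_genotypes_csv(file.path(dir, "g.csv"),
                             file.path(dir, "m.csv"))
  expect_equal(unname(back$values), unname(G$values))
  expect_equal(back$snp_meta$id, G$snp_meta$id)
  expect_equal(back$line_ids, G$line_ids)
})
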
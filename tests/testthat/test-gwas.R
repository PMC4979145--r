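test_that("QC filtering removes planted failures in the documented order", {
  set.seed(1)
  n <- 40
  dos <- matrix(rbinom(n * 8, 2, 0.35), n, 8)
  dos[sample(n, 4), 1] <- NA            # snp1: call rate 0.90 -> removed
  dos[, 2] <- 0L                        # snp2: monomorphic -> MAF filter
  dos[, 3] <- c(1L, rep(0L, n - 1))     # snp3: maf 1/80 -> below 0.05
  dos[, 4] <- 1L                        # snp4: all het -> HWE failure
  dos[1, 5:8] <- NA                     # ind1: call rate 0.5 -> removed
  G <- make_G(dos)
  res <- qc_filter(G, min_call_rate_snp = 0.95, min_call_rate_ind = 0.95,
                   min_maf = 0.05, hwe_p_min = 1e-3)
  expect_equal(res$report$removed_callrate_snp, 1)
  expect_equal(res$report$removed_callrate_ind, 1)
  expect_equal(res$report$removed_maf, 2)
  expect_equal(res$report$removed_hwe, 1)
  expect_equal(res$report$n_snp_out, 4)
  expect_equal(res$report$n_ind_out, n - 1)
  expect_error(qc_filter(make_G(matrix(0L, 10, 2))), "every SNP")
})

test_that("the HWE exact test matches full enumeration", {
  # enumeration oracle over all het counts for small allele counts
  enum_oracle <- function(n_het, n_hom_min, n_hom_maj) {
    n <- n_het + n_hom_min + n_hom_maj
    n_min <- 2 * n_hom_min + n_het
    hets <- seq(n_min %% 2, min(n_min, 2 * n - n_min), by = 2)
    pr <- sapply(hets, function(h) {
      hmin <- (n_min - h) / 2; hmaj <- n - h - hmin
      exp(lfactorial(n) - lfactorial(hmin) - lfactorial(h) -
            lfactorial(hmaj) + h * log(2) + lfactorial(n_min) +
            lfactorial(2 * n - n_min) - lfactorial(2 * n))
    })
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[hets == n_het] * (1 + 1e-12)])
  }
  cases <- list(c(5, 2, 13), c(10, 0, 10), c(2, 8, 10), c(0, 5, 15))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 enum_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  # extreme heterozygote excess is strongly rejected
  expect_lt(hwe_exact_test(40, 0, 0), 1e-6)
})

test_that("two-step scan equals the dense GLS oracle", {
  cfg <- sim_config(n_individuals = 30, n_snps = 50, chrom_lengths = 1e5,
                    n_qtl = 2, seed = 7)
  G <- simulate_genotypes(cfg)
  y <- simulate_growth_and_intake(G, cfg)$truth$rfi_true
  K <- genomic_kinship(G)
  a <- suppressWarnings(mixed_model_scan(y, G, K, gc_correct = FALSE))
  nf <- attr(a, "null_fit")
  V <- nf$sigma_a2 * (K$phi + diag(1e-8, 30)) + nf$sigma_e2 * diag(30)
  Vi <- solve(V)
  dos <- G$dosage
  p <- colMeans(dos) / 2
  dos[, p > 0.5] <- 2 - dos[, p > 0.5]
  chi2_oracle <- sapply(seq_len(ncol(dos)), function(k) {
    X <- cbind(1, dos[, k])
    A <- t(X) %*% Vi %*% X
    b <- solve(A, t(X) %*% Vi %*% y)
    b[2]^2 / solve(A)[2, 2]
  })
  got <- a$chi2[match(colnames(dos), a$snp_id)]
  expect_lt(max(abs(got - chi2_oracle)), 1e-6)
})

test_that("scan p-values are invariant to shifting the phenotype", {
  cfg <- sim_config(n_individuals = 60, n_snps = 80, chrom_lengths = 1e5,
                    seed = 8)
  G <- simulate_genotypes(cfg)
  y <- simulate_growth_and_intake(G, cfg)$truth$rfi_true
  K <- genomic_kinship(G)
  a1 <- suppressWarnings(mixed_model_scan(y, G, K, gc_correct = FALSE))
  a2 <- suppressWarnings(mixed_model_scan(y + 100, G, K, gc_correct = FALSE))
  expect_equal(a1$p_raw, a2$p_raw, tolerance = 1e-6)
})

test_that("permuted phenotypes give calibrated null p-values", {
  cfg <- sim_config(n_individuals = 426, n_snps = 5000,
                    chrom_lengths = rep(3.6e6, 5), seed = 21)
  G <- simulate_genotypes(cfg)
  y <- simulate_growth_and_intake(G, cfg)$truth$rfi_true
  set.seed(42)
  yp <- sample(y)
  a <- mixed_model_scan(yp, G)
  lambda <- attr(a, "lambda")
  expect_gt(lambda, 0.9)
  expect_lt(lambda, 1.1)
  expect_gt(suppressWarnings(ks.test(a$p_raw, "punif")$p.value), 0.01)
})

test_that("genomic control follows its defining identities", {
  gc <- suppressWarnings(genomic_control(c(0.1, 0.4549364, 2.0)))
  expect_equal(gc$lambda, 1.000)
  expect_equal(gc$p_corrected,
               pchisq(c(0.1, 0.4549364, 2.0), 1, lower.tail = FALSE),
               tolerance = 1e-6)
  set.seed(3)
  chi2 <- rchisq(500, 1)
  g1 <- genomic_control(chi2)
  g2 <- genomic_control(2 * chi2)
  expect_equal(g2$lambda_raw, 2 * g1$lambda_raw, tolerance = 1e-12)
  expect_equal(g2$p_corrected, g1$p_corrected, tolerance = 1e-9)
  expect_error(genomic_control(numeric(0)), "empty")
})

test_that("chromosome-wise FDR equals the step-up formula and BH oracle", {
  expect_equal(chromwise_fdr(0.037)$fdr, 0.037)
  got <- chromwise_fdr(c(0.001, 0.002, 0.03))
  expect_equal(got$fdr, c(0.003, 0.003, 0.03), tolerance = 1e-12)
  expect_identical(got$tier, c("**", "**", "**"))

  set.seed(9)
  for (rep in 1:20) {
    p <- runif(50)^2
    chrom <- sample(1:3, 50, replace = TRUE)
    got <- chromwise_fdr(p, chrom)$fdr
    for (ch in 1:3) {
      sel <- chrom == ch
      expect_equal(got[sel], p.adjust(p[sel], method = "BH"),
                   tolerance = 1e-12)
      o <- order(p[sel])
      expect_true(all(diff(got[sel][o]) >= -1e-12))
    }
  }
})

test_that("SNP variance explained matches its definitions", {
  g <- rep(c(0, 1, 2), each = 4)
  expect_equal(snp_variance_explained(g, g)$var_pct, 100, tolerance = 1e-9)

  # 12-bird toy vs hand one-way R2
  y <- c(5, 6, 5.5, 6.2, 7, 7.5, 7.2, 6.9, 9, 8.5, 9.2, 8.8)
  gm <- ave(y, g)
  r2_hand <- 1 - sum((y - gm)^2) / sum((y - mean(y))^2)
  expect_equal(snp_variance_explained(y, g)$var_pct, 100 * r2_hand,
               tolerance = 1e-12)

  expect_true(snp_variance_explained(y, rep(1, 12))$flagged)

  # null expectation ~ 2/(n-1) for a 3-class factor
  set.seed(11)
  vps <- replicate(100, {
    yy <- rnorm(1000)
    gg <- rbinom(1000, 2, 0.4)
    snp_variance_explained(yy, gg)$var_pct
  })
  expect_gt(mean(vps), 0.1)
  expect_lt(mean(vps), 0.35)
})

test_that("a planted QTL of realistic size is detected with high power", {
  hits <- sapply(1:20, function(s) {
    cfg <- sim_config(n_individuals = 426, n_snps = 1000,
                      chrom_lengths = rep(1.8e6, 2), n_qtl = 1,
                      qtl_var_share = 0.27, h2_rfi = 0.35, seed = 600 + s)
    G <- simulate_genotypes(cfg)
    sim <- simulate_growth_and_intake(G, cfg)
    a <- suppressWarnings(mixed_model_scan(sim$truth$rfi_true, G,
                                           gc_correct = FALSE))
    min(a$p_raw[a$snp_id %in% sim$truth$qtl_ids], na.rm = TRUE) < 1e-4
  })
  expect_gte(mean(hits), 0.8)
})
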
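test_that("complete LD is recognized", {
  set.seed(1)
  g <- sample(0:2, 400, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  pr <- pairwise_ld(g, g)
  expect_equal(pr$Dprime, 1, tolerance = 1e-9)
  expect_equal(pr$r2, 1, tolerance = 1e-9)
  ci <- dprime_confidence_interval(pr)
  expect_true(ci$strong_ld)
})

test_that("independent SNPs show no LD beyond sampling error", {
  set.seed(2)
  n <- 1e4
  g1 <- rbinom(n, 2, 0.3)
  g2 <- rbinom(n, 2, 0.45)
  pr <- pairwise_ld(g1, g2)
  se_D <- sqrt(0.3 * 0.7 * 0.45 * 0.55 / (2 * n))
  expect_lt(abs(pr$D), 3 * se_D)
})

test_that("EM haplotype frequencies match the likelihood-grid oracle", {
  cnt <- matrix(c(20, 12, 3,
                  10, 25, 8,
                  2, 9, 11), 3, 3, byrow = TRUE)
  # reconstruct dosages from the count table
  g1 <- rep(rep(0:2, each = 3), times = as.vector(t(cnt)))
  g2 <- rep(rep(0:2, times = 3), times = as.vector(t(cnt)))
  pr <- pairwise_ld(g1, g2, tol = 1e-14)
  oracle <- two_locus_grid_oracle(pr$counts)
  expect_equal(pr$hap_freqs[["pAB"]], oracle$pAB, tolerance = 1e-6)
  expect_equal(pr$D, oracle$D, tolerance = 1e-6)
  # margins preserved by EM
  expect_equal(pr$pA, oracle$pA, tolerance = 1e-12)
  expect_equal(pr$pB, oracle$pB, tolerance = 1e-12)
  # r2 identity
  expect_equal(pr$r2,
               pr$D^2 / (pr$pA * (1 - pr$pA) * pr$pB * (1 - pr$pB)),
               tolerance = 1e-12)
})

test_that("D' confidence bounds match an independent profile oracle", {
  set.seed(5)
  h_true <- c(0.42, 0.08, 0.08, 0.42)   # strong positive LD
  hap1 <- sample(1:4, 2 * 150, TRUE, prob = h_true)
  hap2 <- sample(1:4, 2 * 150, TRUE, prob = h_true)
  allele_a <- c(1, 1, 0, 0); allele_b <- c(1, 0, 1, 0)
  g1 <- allele_a[hap1[1:150]] + allele_a[hap2[1:150]]
  g2 <- allele_b[hap1[1:150]] + allele_b[hap2[1:150]]
  pr <- pairwise_ld(g1, g2)
  ci <- dprime_confidence_interval(pr)

  # oracle: recompute normalized profile likelihood on a finer grid
  pA <- pr$pA; pB <- pr$pB
  s <- sign(pr$D)
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = 5e-4)
  ll <- sapply(grid, function(dp) {
    D <- s * dp * dmax
    h <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
           (1 - pA) * (1 - pB) + D)
    if (any(h < 0)) return(-Inf)
    ll <- 0
    for (a in 0:2) for (b in 0:2) {
      if (pr$counts[a + 1, b + 1] == 0) next
      pAB <- h[1]; pAb <- h[2]; paB <- h[3]; pab <- h[4]
      prob <- switch(paste0(a, b),
                     "22" = pAB^2, "21" = 2 * pAB * pAb, "20" = pAb^2,
                     "12" = 2 * pAB * paB,
                     "11" = 2 * pAB * pab + 2 * pAb * paB,
                     "10" = 2 * pAb * pab, "02" = paB^2,
                     "01" = 2 * paB * pab, "00" = pab^2)
      ll <- ll + pr$counts[a + 1, b + 1] * log(max(prob, 1e-300))
    }
    ll
  })
  w <- exp(ll - max(ll)); w <- w / sum(w)
  cw <- cumsum(w)
  expect_equal(ci$ci_low, grid[which(cw >= 0.05)[1]], tolerance = 2e-3)
  expect_equal(ci$ci_high, grid[which(cw >= 0.95)[1]], tolerance = 2e-3)

  # information-poor pair: wide interval, not strong
  set.seed(6)
  pr2 <- pairwise_ld(rbinom(10, 2, 0.5), rbinom(10, 2, 0.5))
  ci2 <- dprime_confidence_interval(pr2)
  expect_false(ci2$strong_ld)
})

test_that("D' is invariant to swapping allele labels", {
  set.seed(7)
  g1 <- rbinom(300, 2, 0.3)
  g2 <- pmin(2, pmax(0, g1 + sample(c(-1, 0, 1), 300, TRUE,
                                    prob = c(.1, .8, .1))))
  pr <- pairwise_ld(g1, g2)
  pr_swap <- pairwise_ld(2 - g1, g2)
  expect_equal(pr$Dprime, pr_swap$Dprime, tolerance = 1e-9)
  expect_equal(pr$r2, pr_swap$r2, tolerance = 1e-9)
  expect_equal(sum(pr$hap_freqs), 1, tolerance = 1e-12)
})

test_that("block construction matches exhaustive enumeration", {
  set.seed(8)
  base <- sample(0:2, 200, replace = TRUE, prob = c(.36, .48, .16))
  # five SNPs in perfect LD -> one 5-SNP block
  G5 <- make_G(matrix(rep(base, 5), ncol = 5))
  blocks <- gabriel_blocks(G5)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$n_snps, 5)
  expect_equal(blocks[[1]]$span,
               max(G5$map$pos) - min(G5$map$pos))

  # independent SNPs at modest n -> no blocks
  Gind <- make_G(sapply(1:5, function(i) rbinom(120, 2, 0.4)))
  expect_length(gabriel_blocks(Gind), 0)

  # 4-SNP perfect run + 2 independent SNPs: block = the run only,
  # verified against exhaustive enumeration of candidate regions
  dos <- cbind(matrix(rep(base, 4), ncol = 4),
               rbinom(200, 2, 0.5), rbinom(200, 2, 0.5))
  G6 <- make_G(dos)
  blocks6 <- gabriel_blocks(G6)
  # enumeration oracle
  m <- 6
  strong <- matrix(NA, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    pr <- pairwise_ld(dos[, i], dos[, j])
    if (!pr$converged) next
    strong[i, j] <- strong[j, i] <- dprime_confidence_interval(pr)$strong_ld
  }
  cand <- list()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    v <- strong[i:j, i:j][upper.tri(strong[i:j, i:j])]
    v <- v[!is.na(v)]
    if (length(v) && mean(v) > 0.95)
      cand[[length(cand) + 1]] <- c(i, j, G6$map$pos[j] - G6$map$pos[i])
  }
  spans <- sapply(cand, `[`, 3)
  ord <- order(-spans, sapply(cand, `[`, 1))
  used <- rep(FALSE, m); oracle_blocks <- list()
  for (k in ord) {
    rng <- cand[[k]][1]:cand[[k]][2]
    if (any(used[rng])) next
    used[rng] <- TRUE
    oracle_blocks[[length(oracle_blocks) + 1]] <- rng
  }
  expect_length(blocks6, length(oracle_blocks))
  expect_equal(blocks6[[1]]$snp_ids, G6$map$snp_id[oracle_blocks[[1]]])
})

test_that("blocks never overlap", {
  cfg <- sim_config(n_individuals = 150, n_snps = 20, chrom_lengths = 4e4,
                    ld_scale_L = 2e4, seed = 12)
  G <- simulate_genotypes(cfg)
  blocks <- gabriel_blocks(G)
  if (length(blocks) > 1) {
    ids <- unlist(lapply(blocks, `[[`, "snp_ids"))
    expect_false(anyDuplicated(ids) > 0)
  }
  succeed()
})

test_that("the decay profile is bounded and monotone for copying simulations", {
  profs <- sapply(1:5, function(s) {
    cfg <- sim_config(n_individuals = 150, n_snps = 400,
                      chrom_lengths = 8e5, ld_scale_L = 4e4, seed = 100 + s)
    ld_decay_profile(simulate_genotypes(cfg))$mean_r2
  })
  m <- rowMeans(profs, na.rm = TRUE)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(diff(m) <= 0))
})

test_that("multilocus haplotype frequencies are consistent and exact", {
  # no phase ambiguity: all homozygous
  dos <- rbind(c(0, 0, 0), c(2, 2, 2), c(2, 2, 2), c(0, 0, 2))
  hf <- block_haplotype_frequencies(dos)
  expect_equal(hf$frequency[hf$haplotype == "111"], 0.5)
  expect_equal(hf$frequency[hf$haplotype == "000"], 0.25)
  expect_equal(hf$frequency[hf$haplotype == "001"], 0.25)

  # 2-SNP block equals the pairwise EM
  set.seed(14)
  g1 <- rbinom(200, 2, 0.4)
  g2 <- pmin(2, pmax(0, g1 + sample(c(-1, 0, 1), 200, TRUE,
                                    prob = c(.15, .7, .15))))
  pr <- pairwise_ld(g1, g2, tol = 1e-14)
  hf2 <- block_haplotype_frequencies(cbind(g1, g2), tol = 1e-14,
                                     min_freq = 0)
  f <- setNames(hf2$frequency, hf2$haplotype)
  expect_equal(unname(f["11"]), unname(pr$hap_freqs["pAB"]),
               tolerance = 1e-9)
  expect_equal(unname(f["10"]), unname(pr$hap_freqs["pAb"]),
               tolerance = 1e-9)

  # 3-SNP ambiguity vs multi-start direct likelihood maximization
  set.seed(15)
  dos3 <- cbind(rbinom(150, 2, 0.5),
                rbinom(150, 2, 0.5),
                rbinom(150, 2, 0.5))
  hf3 <- block_haplotype_frequencies(dos3, tol = 1e-14, min_freq = 0)
  ll_em <- attr(hf3, "loglik")
  # oracle: softmax-parameterized direct maximization from random starts
  pairs <- lapply(seq_len(nrow(dos3)),
                  function(i) rfikit:::enumerate_hap_pairs(dos3[i, ]))
  negll <- function(theta) {
    h <- exp(theta) / sum(exp(theta))
    -sum(vapply(pairs, function(pl) {
      w <- h[pl[, 1]] * h[pl[, 2]] * ifelse(pl[, 1] == pl[, 2], 1, 2)
      log(max(sum(w), 1e-300))
    }, numeric(1)))
  }
  best <- Inf
  set.seed(16)
  for (r in 1:10) {
    o <- optim(rnorm(8), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_lt(abs(-best - ll_em), 1e-3)

  expect_error(block_haplotype_frequencies(matrix(0, 2, 13)), "cap")
})
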
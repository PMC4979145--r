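# Independent oracles shared across tests.

# OLS via the normal equations (no lm)
ols_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# dense-matrix REML profile log-likelihood for the animal model,
# profiled over sigma_a2 at a fixed ratio delta = sigma_e2/sigma_a2
dense_reml_loglik <- function(delta, y, Xmat, phi) {
  X <- Xmat
  n <- length(y); p <- ncol(X)
  Vs <- phi + delta * diag(n)           # V / sigma_a2
  Vi <- solve(Vs)
  A <- t(X) %*% Vi %*% X
  b <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  R <- drop(t(r) %*% Vi %*% r)
  s2 <- R / (n - p)
  as.numeric(-0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
                       determinant(Vs, logarithm = TRUE)$modulus +
                       determinant(A, logarithm = TRUE)$modulus))
}

# recursive coancestry: kinship f(i,j); additive relationship = 2*f
coancestry_oracle <- function(ped) {
  id <- as.character(ped$id)
  sire <- as.character(ped$sire); dam <- as.character(ped$dam)
  sire[sire %in% c("0", NA)] <- NA; dam[dam %in% c("0", NA)] <- NA
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    ia <- match(a, id); ib <- match(b, id)
    if (ia == ib)
      return(0.5 * (1 + f(sire[ia], dam[ia])))
    # recurse on the younger individual
    if (ia < ib) { tmp <- ia; ia <- ib; ib <- tmp }
    0.5 * (f(sire[ia], id[ib]) + f(dam[ia], id[ib]))
  }
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, j] <- if (i == j) 2 * f(id[i], id[j]) - 0 else 2 * f(id[i], id[j])
  diag(A) <- sapply(seq_len(n), function(i) 1 + f(sire[i], dam[i]))
  A
}

# two-locus EM oracle: allele margins fixed by the data, maximize the
# multinomial genotype likelihood over D on a refining grid
two_locus_grid_oracle <- function(cnt) {
  n <- sum(cnt)
  pA <- sum(cnt * (row(cnt) - 1)) / (2 * n)
  pB <- sum(cnt * (col(cnt) - 1)) / (2 * n)
  ll_of_D <- function(D) {
    h <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
           (1 - pA) * (1 - pB) + D)
    if (any(h < 0)) return(-Inf)
    ll <- 0
    probs <- function(a, b) {
      pAB <- h[1]; pAb <- h[2]; paB <- h[3]; pab <- h[4]
      if (a == 2 && b == 2) pAB^2
      else if (a == 2 && b == 1) 2 * pAB * pAb
      else if (a == 2 && b == 0) pAb^2
      else if (a == 1 && b == 2) 2 * pAB * paB
      else if (a == 1 && b == 1) 2 * pAB * pab + 2 * pAb * paB
      else if (a == 1 && b == 0) 2 * pAb * pab
      else if (a == 0 && b == 2) paB^2
      else if (a == 0 && b == 1) 2 * paB * pab
      else pab^2
    }
    for (a in 0:2) for (b in 0:2)
      if (cnt[a + 1, b + 1] > 0)
        ll <- ll + cnt[a + 1, b + 1] * log(max(probs(a, b), 1e-300))
    ll
  }
  lo <- -min(pA * pB, (1 - pA) * (1 - pB))
  hi <- min(pA * (1 - pB), (1 - pA) * pB)
  grid <- seq(lo, hi, length.out = 2001)
  best <- grid[which.max(vapply(grid, ll_of_D, numeric(1)))]
  for (w in c((hi - lo) / 1000, (hi - lo) / 1e5)) {
    grid <- seq(max(lo, best - w), min(hi, best + w), length.out = 2001)
    best <- grid[which.max(vapply(grid, ll_of_D, numeric(1)))]
  }
  list(D = best, pAB = pA * pB + best, pA = pA, pB = pB)
}

# genotype matrix wrapper for hand-built dosage matrices
make_G <- function(dosage, pos = NULL, chrom = 1L) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  ids <- sprintf("ind%03d", seq_len(nrow(dosage)))
  snp_id <- sprintf("s%03d", seq_len(m))
  dimnames(dosage) <- list(ids, snp_id)
  structure(list(dosage = dosage,
                 map = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                                  freq = colMeans(dosage, na.rm = TRUE) / 2,
                                  stringsAsFactors = FALSE),
                 ids = ids),
            class = "genotype_matrix")
}
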
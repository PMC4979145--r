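#' Two-locus haplotype frequencies and LD measures
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotypes by EM over the double-heterozygote phase ambiguity, then
#' computes D = p_AB - p_A p_B, D' = D/Dmax and
#' r2 = D^2 / (p_A p_a p_B p_b). Alleles are labelled so that "A"/"B" are
#' the counted alleles of each dosage vector.
#'
#' @param g1,g2 dosage vectors (0/1/2) at the two SNPs, same individuals.
#' @param max_iter,tol EM controls.
#' @return object of class `ld_pair`: hap_freqs (pAB, pAb, paB, pab), D,
#'   Dprime (absolute value), r2, allele freqs, n, converged, loglik.
#' @export
pairwise_ld <- function(g1, g2, max_iter = 1000, tol = 1e-12) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    stop("both SNPs must be polymorphic")
  cnt <- two_locus_counts(g1, g2)
  em <- two_locus_em(cnt, max_iter, tol)
  h <- em$h
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax <= 0) 0 else abs(D) / dmax
  r2 <- if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) 0
        else D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(hap_freqs = setNames(h, c("pAB", "pAb", "paB", "pab")),
                 D = D, Dprime = min(dprime, 1), r2 = min(r2, 1),
                 pA = pA, pB = pB, n = length(g1), counts = cnt,
                 converged = em$converged, loglik = em$loglik),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair (n = %d): D = %.4f, D' = %.3f, r2 = %.3f%s\n",
              x$n, x$D, x$Dprime, x$r2,
              if (x$converged) "" else " [EM not converged]"))
  invisible(x)
}

two_locus_counts <- function(g1, g2) {
  tab <- matrix(0L, 3, 3)
  for (a in 0:2) for (b in 0:2)
    tab[a + 1, b + 1] <- sum(g1 == a & g2 == b)
  tab
}

# EM on the 3x3 genotype count table; rows/cols indexed by dosage 0..2 of
# the counted allele. Haplotypes: 1 = AB, 2 = Ab, 3 = aB, 4 = ab, where
# dosage counts allele A at locus 1 and B at locus 2.
two_locus_em <- function(cnt, max_iter = 1000, tol = 1e-12) {
  n <- sum(cnt)
  nA <- sum(cnt * (row(cnt) - 1))
  nB <- sum(cnt * (col(cnt) - 1))
  pA <- nA / (2 * n); pB <- nB / (2 * n)
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  n_dh <- cnt[2, 2]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # expected count of AB/ab resolution among double heterozygotes
    denom <- h[1] * h[4] + h[2] * h[3]
    x <- if (denom > 0) n_dh * h[1] * h[4] / denom else n_dh / 2
    cAB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3] + x
    cAb <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1] + (n_dh - x)
    caB <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3] + (n_dh - x)
    cab <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1] + x
    h_new <- c(cAB, cAb, caB, cab) / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new; converged <- TRUE; break
    }
    h <- h_new
  }
  list(h = h, converged = converged,
       loglik = two_locus_loglik(h, cnt))
}

two_locus_loglik <- function(h, cnt) {
  ll <- 0
  for (a in 0:2) for (b in 0:2) {
    if (cnt[a + 1, b + 1] == 0) next
    pr <- two_locus_geno_prob(h, a, b)
    ll <- ll + cnt[a + 1, b + 1] * log(max(pr, 1e-300))
  }
  ll
}

# P(genotype pair) under HWE on haplotypes h = (pAB, pAb, paB, pab);
# a = dosage of A, b = dosage of B
two_locus_geno_prob <- function(h, a, b) {
  pAB <- h[1]; pAb <- h[2]; paB <- h[3]; pab <- h[4]
  if (a == 2 && b == 2) return(pAB^2)
  if (a == 2 && b == 1) return(2 * pAB * pAb)
  if (a == 2 && b == 0) return(pAb^2)
  if (a == 1 && b == 2) return(2 * pAB * paB)
  if (a == 1 && b == 1) return(2 * pAB * pab + 2 * pAb * paB)
  if (a == 1 && b == 0) return(2 * pAb * pab)
  if (a == 0 && b == 2) return(paB^2)
  if (a == 0 && b == 1) return(2 * paB * pab)
  pab^2
}

#' One-sided 95% confidence bounds on |D'|
#'
#' Profile likelihood over a grid of |D'| values in [0, 1] (allele
#' frequencies held at their sample estimates, D signed as estimated).
#' The normalized likelihood is treated as a density over the grid; the
#' lower bound is the 5th percentile and the upper bound the 95th.
#' `strong_ld` follows the confidence-interval block criterion: upper
#' bound >= 0.98 and lower bound >= 0.7.
#'
#' @param pair an `ld_pair`.
#' @param grid_step grid resolution on |D'|.
#' @return list(ci_low, ci_high, strong_ld, flagged).
#' @export
dprime_confidence_interval <- function(pair, grid_step = 0.001) {
  pA <- pair$pA; pB <- pair$pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(list(ci_low = 0, ci_high = 1, strong_ld = FALSE, flagged = TRUE))
  s <- if (pair$D >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0)
    return(list(ci_low = 0, ci_high = 1, strong_ld = FALSE, flagged = TRUE))
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(dp) {
    D <- s * dp * dmax
    h <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
           (1 - pA) * (1 - pB) + D)
    if (any(h < -1e-12)) return(-Inf)
    h <- pmax(h, 0); h <- h / sum(h)
    two_locus_loglik(h, pair$counts)
  }, numeric(1))
  wt <- exp(ll - max(ll, na.rm = TRUE))
  wt[!is.finite(wt)] <- 0
  wt <- wt / sum(wt)
  cw <- cumsum(wt)
  ci_low <- grid[which(cw >= 0.05)[1]]
  ci_high <- grid[which(cw >= 0.95)[1]]
  list(ci_low = ci_low, ci_high = ci_high,
       strong_ld = ci_high >= 0.98 && ci_low >= 0.7, flagged = FALSE)
}

#' Confidence-interval haplotype blocks
#'
#' Scores every candidate region of consecutive SNPs by the fraction of
#' its informative pairs (minor-allele frequency >= `min_maf` at both
#' SNPs, EM converged) in strong LD by the D' confidence-bound rule.
#' Regions with a fraction above `strong_frac` (and at least one
#' informative pair) are accepted greedily, longest span first, without
#' overlap.
#'
#' @param G `genotype_matrix` restricted to one chromosome (positions
#'   strictly increasing).
#' @param strong_frac acceptance threshold on the strong-pair fraction.
#' @param min_maf informativeness threshold.
#' @param max_span_bp pairs farther apart than this are not evaluated and
#'   candidate regions cannot exceed it.
#' @return list of blocks, each list(chrom, snp_ids, start, end, span,
#'   haplotypes); also returns the pairwise table as attribute "pairs".
#' @export
gabriel_blocks <- function(G, strong_frac = 0.95, min_maf = 0.05,
                           max_span_bp = 5e5) {
  map <- G$map
  if (length(unique(map$chrom)) != 1)
    stop("gabriel_blocks expects a single chromosome")
  if (any(diff(map$pos) <= 0)) stop("map positions must be strictly increasing")
  m <- nrow(map)
  dos <- G$dosage
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  informative_snp <- maf >= min_maf
  strong <- matrix(NA, m, m)   # NA = uninformative pair
  pairs <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (map$pos[j] - map$pos[i] > max_span_bp) break
      if (!informative_snp[i] || !informative_snp[j]) next
      pr <- tryCatch(pairwise_ld(dos[, i], dos[, j]),
                     error = function(e) NULL)
      if (is.null(pr) || !pr$converged) next
      ci <- dprime_confidence_interval(pr)
      if (ci$flagged) next
      strong[i, j] <- strong[j, i] <- ci$strong_ld
      pairs[[length(pairs) + 1]] <- data.frame(
        snp_a = map$snp_id[i], snp_b = map$snp_id[j],
        distance = map$pos[j] - map$pos[i], D = pr$D,
        Dprime = pr$Dprime, r2 = pr$r2,
        ci_low = ci$ci_low, ci_high = ci$ci_high,
        strong_ld = ci$strong_ld, stringsAsFactors = FALSE)
    }
  }
  # candidate regions
  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (map$pos[j] - map$pos[i] > max_span_bp) break
      sub <- strong[i:j, i:j]
      vals <- sub[upper.tri(sub)]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      frac <- mean(vals)
      if (frac > strong_frac)
        cand[[length(cand) + 1]] <- list(i = i, j = j,
                                         span = map$pos[j] - map$pos[i],
                                         frac = frac)
    }
  }
  blocks <- list()
  if (length(cand)) {
    spans <- vapply(cand, `[[`, numeric(1), "span")
    starts <- vapply(cand, `[[`, numeric(1), "i")
    ord <- order(-spans, starts)
    used <- rep(FALSE, m)
    for (k in ord) {
      rng <- cand[[k]]$i:cand[[k]]$j
      if (any(used[rng])) next
      used[rng] <- TRUE
      hap <- if (length(rng) <= 12)
        block_haplotype_frequencies(dos[, rng, drop = FALSE]) else NULL
      blocks[[length(blocks) + 1]] <- list(
        chrom = map$chrom[1], snp_ids = map$snp_id[rng],
        start = map$pos[cand[[k]]$i], end = map$pos[cand[[k]]$j],
        span = cand[[k]]$span, n_snps = length(rng),
        strong_frac = cand[[k]]$frac, haplotypes = hap)
    }
    ord2 <- order(vapply(blocks, `[[`, numeric(1), "start"))
    blocks <- blocks[ord2]
  }
  attr(blocks, "pairs") <- if (length(pairs)) do.call(rbind, pairs)
                           else NULL
  blocks
}

#' LD-decay profile
#'
#' Mean squared genotype correlation (r2) between intra-chromosomal SNP
#' pairs, binned by physical distance.
#'
#' @param G `genotype_matrix`.
#' @param bins numeric vector of bin edges in bp (default 0-100 kb in
#'   20-kb bins).
#' @return data.frame (bin_low, bin_high, mean_r2, n_pairs); empty bins
#'   carry NA.
#' @export
ld_decay_profile <- function(G, bins = seq(0, 1e5, by = 2e4)) {
  stopifnot(length(bins) >= 2)
  nb <- length(bins) - 1
  sums <- numeric(nb); cnts <- numeric(nb)
  max_d <- max(bins)
  for (ch in unique(G$map$chrom)) {
    sel <- which(G$map$chrom == ch)
    if (length(sel) < 2) next
    pos <- G$map$pos[sel]
    dos <- G$dosage[, sel, drop = FALSE]
    sdv <- apply(dos, 2, sd)
    ok <- sdv > 0
    pos <- pos[ok]; dos <- dos[, ok, drop = FALSE]
    m <- ncol(dos)
    if (m < 2) next
    Z <- scale(dos)
    # process in windows to avoid full m x m work on long chromosomes
    for (i in seq_len(m - 1)) {
      j <- i + 1
      jmax <- i + findInterval(pos[i] + max_d, pos[(i + 1):m])
      if (jmax < j) next
      jj <- j:jmax
      r <- drop(crossprod(Z[, i], Z[, jj, drop = FALSE])) / (nrow(Z) - 1)
      d <- pos[jj] - pos[i]
      bi <- findInterval(d, bins, rightmost.closed = TRUE)
      val <- r^2
      for (b in unique(bi)) {
        if (b < 1 || b > nb) next
        sel_b <- bi == b
        sums[b] <- sums[b] + sum(val[sel_b])
        cnts[b] <- cnts[b] + sum(sel_b)
      }
    }
  }
  data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
             mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_),
             n_pairs = cnts)
}

#' Multilocus haplotype frequencies within a block
#'
#' EM over the phase ambiguity of unphased genotypes at up to 12 SNPs
#' (state-space cap). Haplotypes with estimated frequency below
#' `min_freq` are pruned from the report.
#'
#' @param dosage n x k dosage matrix (k <= 12) for the block SNPs.
#' @param max_iter,tol EM controls.
#' @param min_freq reporting floor.
#' @return data.frame (haplotype, frequency), sorted by frequency
#'   descending; attribute "loglik" carries the final log-likelihood.
#' @export
block_haplotype_frequencies <- function(dosage, max_iter = 1000, tol = 1e-10,
                                        min_freq = 0.01) {
  dosage <- as.matrix(dosage)
  k <- ncol(dosage)
  if (k > 12) stop("block exceeds the 12-SNP EM cap: split the block")
  dosage <- dosage[complete.cases(dosage), , drop = FALSE]
  n <- nrow(dosage)
  # per individual, enumerate compatible (hap1, hap2) pairs
  pair_list <- lapply(seq_len(n), function(i) enumerate_hap_pairs(dosage[i, ]))
  nh <- 2^k
  h <- rep(1 / nh, nh)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    cnt <- numeric(nh)
    ll <- 0
    for (i in seq_len(n)) {
      pl <- pair_list[[i]]
      w <- h[pl[, 1]] * h[pl[, 2]] * ifelse(pl[, 1] == pl[, 2], 1, 2)
      tot <- sum(w)
      if (tot <= 0) { w <- rep(1 / nrow(pl), nrow(pl)); tot <- 1 }
      else w <- w / tot
      ll <- ll + log(max(tot, 1e-300))
      for (r in seq_len(nrow(pl))) {
        cnt[pl[r, 1]] <- cnt[pl[r, 1]] + w[r]
        cnt[pl[r, 2]] <- cnt[pl[r, 2]] + w[r]
      }
    }
    h_new <- cnt / (2 * n)
    if (ll < ll_old - 1e-8)
      stop("EM log-likelihood decreased; this should not happen")
    ll_old <- ll
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  lab <- vapply(seq_len(nh) - 1L, function(x)
    paste(rev(as.integer(intToBits(x))[seq_len(k)]), collapse = ""),
    character(1))
  out <- data.frame(haplotype = lab, frequency = h,
                    stringsAsFactors = FALSE)
  out <- out[out$frequency >= min_freq, ]
  out <- out[order(-out$frequency), ]
  rownames(out) <- NULL
  attr(out, "loglik") <- ll_old
  out
}

# all (hap1, hap2) index pairs (1-based codes) compatible with a dosage
# vector; haplotype code = binary over sites (site 1 = most significant)
enumerate_hap_pairs <- function(g) {
  k <- length(g)
  het <- which(g == 1)
  base1 <- ifelse(g == 2, 1L, 0L)
  base2 <- base1
  if (!length(het)) {
    code <- sum(base1 * 2^(rev(seq_len(k)) - 1))
    return(matrix(code + 1L, 1, 2))
  }
  nh <- length(het)
  combos <- as.matrix(expand.grid(rep(list(0:1), nh)))
  out <- matrix(0L, nrow(combos), 2)
  w <- 2^(rev(seq_len(k)) - 1)
  for (r in seq_len(nrow(combos))) {
    h1 <- base1; h2 <- base2
    h1[het] <- combos[r, ]
    h2[het] <- 1L - combos[r, ]
    out[r, ] <- c(sum(h1 * w), sum(h2 * w)) + 1L
  }
  # unordered pairs: keep canonical order, dedupe
  out <- t(apply(out, 1, sort))
  out[!duplicated(out), , drop = FALSE]
}
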
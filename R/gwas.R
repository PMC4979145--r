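#' Genotype quality control
#'
#' Iterative removal in the conventional order: SNP call rate, individual
#' call rate, minor-allele frequency, then Hardy-Weinberg exact test. The
#' per-step removal counts are reported.
#'
#' @param G `genotype_matrix` (NA = missing dosage).
#' @param min_call_rate_snp,min_call_rate_ind call-rate thresholds.
#' @param min_maf minimum minor-allele frequency.
#' @param hwe_p_min minimum HWE exact-test p-value.
#' @return list(G = filtered `genotype_matrix`, report = list of counts).
#' @export
qc_filter <- function(G, min_call_rate_snp = 0.95, min_call_rate_ind = 0.95,
                      min_maf = 0.01, hwe_p_min = 1e-6) {
  dos <- G$dosage
  map <- G$map
  ids <- G$ids
  n0 <- nrow(dos); m0 <- ncol(dos)

  cr_snp <- colMeans(!is.na(dos))
  keep_snp <- cr_snp >= min_call_rate_snp
  removed_callrate_snp <- sum(!keep_snp)
  dos <- dos[, keep_snp, drop = FALSE]
  map <- map[keep_snp, , drop = FALSE]

  cr_ind <- rowMeans(!is.na(dos))
  keep_ind <- cr_ind >= min_call_rate_ind
  removed_callrate_ind <- sum(!keep_ind)
  dos <- dos[keep_ind, , drop = FALSE]
  ids <- ids[keep_ind]

  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= min_maf & maf > 0
  removed_maf <- sum(!keep_maf)
  dos <- dos[, keep_maf, drop = FALSE]
  map <- map[keep_maf, , drop = FALSE]

  hwe_p <- apply(dos, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 1), sum(g == 2), sum(g == 0))
  })
  keep_hwe <- hwe_p >= hwe_p_min
  removed_hwe <- sum(!keep_hwe)
  dos <- dos[, keep_hwe, drop = FALSE]
  map <- map[keep_hwe, , drop = FALSE]

  if (ncol(dos) == 0) stop("QC removed every SNP")
  Gf <- structure(list(dosage = dos, map = map, ids = ids),
                  class = "genotype_matrix")
  report <- list(n_ind_in = n0, n_snp_in = m0,
                 removed_callrate_snp = removed_callrate_snp,
                 removed_callrate_ind = removed_callrate_ind,
                 removed_maf = removed_maf, removed_hwe = removed_hwe,
                 n_ind_out = nrow(dos), n_snp_out = ncol(dos))
  list(G = Gf, report = report)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test for a biallelic SNP: the p-value is the total
#' probability of heterozygote counts no more likely than the observed
#' one, under the conditional (on allele counts) distribution.
#'
#' @param n_het,n_hom_minor,n_hom_major genotype counts.
#' @return p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  if (n == 0) return(1)
  n_minor <- 2 * n_hom_minor + n_het
  n_major <- 2 * n_hom_major + n_het
  if (n_minor > n_major) { tmp <- n_minor; n_minor <- n_major; n_major <- tmp }
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  hom_min <- (n_minor - hets) / 2
  hom_maj <- n - hets - hom_min
  # log conditional probability of each possible het count
  logp <- lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(hets + 1) -
    lgamma(hom_maj + 1) + hets * log(2) +
    lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Kinship-adjusted single-marker association scan
#'
#' Two-step mixed-model scan: the variance components of the null
#' polygenic model Y = Xb + u + e (u ~ N(0, Phi sigma_G2)) are estimated
#' once by REML, then each SNP dosage is tested by a generalized
#' least-squares Wald test using the fixed null covariance
#' V = Phi sigma_G2 + I sigma_e2. Dosages are coded for the realized minor
#' allele (effects are reported per copy of the minor allele) and missing
#' dosages are mean-imputed. Chi-square statistics are corrected by
#' genomic control and chromosome-wise step-up FDR values appended.
#'
#' @param y phenotype vector (typically normal-transformed, pre-adjusted
#'   RFI; fixed effects then reduce to the intercept).
#' @param G `genotype_matrix` after QC.
#' @param K optional `kinship_matrix`; computed from `G` when NULL.
#' @param X fixed-effect design (default intercept only).
#' @param null_fit optional precomputed `reml_fit` for the null model.
#' @param gc_correct apply genomic control (default TRUE).
#' @param sig_threshold genome-wide significance threshold on the
#'   lambda-corrected p-value.
#' @param compute_var also compute per-SNP variance explained (one-way
#'   genotype-class R2 on `y`, in percent) and, when `ebv` is given, the
#'   share of additive variance (same computation on the breeding values).
#' @param ebv optional vector of breeding values for `addvar_pct`.
#' @return object of class `assoc_table` (a data.frame): snp_id, chrom,
#'   pos, maf, effect_a, se, chi2, p_raw, p_gc, fdr_value, fdr_tier,
#'   significant, plus var_pct/addvar_pct when requested. The genomic
#'   control factor is in `attr(, "lambda")`, the null fit in
#'   `attr(, "null_fit")`.
#' @export
mixed_model_scan <- function(y, G, K = NULL, X = NULL, null_fit = NULL,
                             gc_correct = TRUE, sig_threshold = 1e-4,
                             compute_var = FALSE, ebv = NULL) {
  dos <- G$dosage
  n <- nrow(dos)
  stopifnot(length(y) == n)
  if (is.null(K)) K <- genomic_kinship(G)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (is.null(null_fit)) null_fit <- reml_univariate(y, X, K)

  # minor-allele coding + mean imputation
  p_hat <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(p_hat) & p_hat > 0.5
  dos[, flip] <- 2 - dos[, flip]
  p_hat[flip] <- 1 - p_hat[flip]
  if (anyNA(dos)) {
    mu <- 2 * p_hat
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }

  U <- null_fit$U
  v <- null_fit$sigma_a2 * null_fit$d + null_fit$sigma_e2
  w <- 1 / v
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  Gt <- crossprod(U, dos)
  # project out fixed effects under W = diag(w)
  WX <- Xt * w
  B <- solve(crossprod(Xt, WX))
  Py <- yt * w - WX %*% (B %*% crossprod(WX, yt))
  PG <- Gt * w - WX %*% (B %*% crossprod(WX, Gt))
  gPg <- colSums(Gt * PG)
  gPy <- drop(crossprod(Gt, Py))
  zero_var <- gPg <= 1e-12
  beta <- ifelse(zero_var, NA_real_, gPy / gPg)
  se <- ifelse(zero_var, NA_real_, 1 / sqrt(gPg))
  chi2 <- ifelse(zero_var, NA_real_, beta^2 * gPg)
  p_raw <- pchisq(chi2, df = 1, lower.tail = FALSE)

  out <- data.frame(snp_id = G$map$snp_id, chrom = G$map$chrom,
                    pos = G$map$pos, maf = pmin(p_hat, 1 - p_hat),
                    effect_a = beta, se = se, chi2 = chi2, p_raw = p_raw,
                    stringsAsFactors = FALSE)
  if (gc_correct) {
    gc <- genomic_control(chi2[!is.na(chi2)])
    out$p_gc <- pchisq(chi2 / gc$lambda_raw, df = 1, lower.tail = FALSE)
    lambda <- gc$lambda
  } else {
    out$p_gc <- p_raw
    lambda <- 1
  }
  fdr <- chromwise_fdr(out$p_gc, out$chrom)
  out$fdr_value <- fdr$fdr
  out$fdr_tier <- fdr$tier
  out$significant <- !is.na(out$p_gc) & out$p_gc < sig_threshold
  if (compute_var) {
    out$var_pct <- apply(dos, 2, function(g)
      snp_variance_explained(y, g)$var_pct)
    if (!is.null(ebv))
      out$addvar_pct <- apply(dos, 2, function(g)
        snp_variance_explained(ebv, g)$var_pct)
  }
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda
  attr(out, "null_fit") <- null_fit
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("assoc_table: %d SNPs, lambda = %.3f, %d significant (p_gc < 1e-4 flag)\n",
              nrow(x), attr(x, "lambda"), sum(x$significant, na.rm = TRUE)))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Genomic control inflation factor
#'
#' lambda is the median of the association chi-square statistics divided
#' by the null median 0.4549364 (the 1-df chi-square median); corrected
#' p-values come from chi2/lambda on 1 df.
#'
#' @param chi2 vector of 1-df chi-square statistics.
#' @return list(lambda = rounded to 3 decimals, lambda_raw, p_corrected).
#' @export
genomic_control <- function(chi2) {
  chi2 <- chi2[!is.na(chi2)]
  if (length(chi2) == 0) stop("empty chi-square vector")
  if (length(chi2) < 100)
    warning("genomic control estimated from fewer than 100 statistics")
  lambda_raw <- median(chi2) / qchisq(0.5, df = 1)
  list(lambda = round(lambda_raw, 3), lambda_raw = lambda_raw,
       p_corrected = pchisq(chi2 / lambda_raw, df = 1, lower.tail = FALSE))
}

#' Chromosome-wise step-up FDR
#'
#' Within each chromosome, p-values are sorted ascending, m*P(i)/i is
#' computed with m the number of SNPs on that chromosome, step-up
#' monotonicity is enforced (cumulative minimum from the largest rank) and
#' values are capped at 1. Tier flags: "**" for FDR <= 0.05, "*" for
#' FDR <= 0.10.
#'
#' @param p vector of (lambda-corrected) p-values.
#' @param chrom parallel chromosome labels; a single chromosome is assumed
#'   when NULL.
#' @return list(fdr, tier) aligned with the input order.
#' @export
chromwise_fdr <- function(p, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep(1L, length(p))
  fdr <- rep(NA_real_, length(p))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch & !is.na(p))
    if (!length(sel)) next
    m <- length(sel)
    o <- order(p[sel])
    raw <- m * p[sel][o] / seq_len(m)
    q <- rev(cummin(rev(raw)))
    q <- pmin(q, 1)
    fdr[sel[o]] <- q
  }
  tier <- ifelse(is.na(fdr), "",
                 ifelse(fdr <= 0.05, "**", ifelse(fdr <= 0.10, "*", "")))
  list(fdr = fdr, tier = tier)
}

#' Variance explained by one SNP
#'
#' Percent phenotypic variance explained by a SNP, measured as 100 times
#' the R2 of the one-way genotype-class model y = mu + SNP + e. When a
#' vector of breeding values is supplied instead of phenotypes, the same
#' computation yields the share of additive variance.
#'
#' @param y response (phenotypes, or breeding values for the additive
#'   share).
#' @param dosage genotype vector (0/1/2; treated as a class variable).
#' @return list(var_pct, r2, flagged).
#' @export
snp_variance_explained <- function(y, dosage) {
  g <- round(dosage)
  if (length(unique(g)) < 2)
    return(list(var_pct = NA_real_, r2 = NA_real_, flagged = TRUE))
  gm <- ave(y, g)
  ss_tot <- sum((y - mean(y))^2)
  ss_within <- sum((y - gm)^2)
  r2 <- 1 - ss_within / ss_tot
  list(var_pct = 100 * r2, r2 = r2, flagged = FALSE)
}

#' Manhattan-ready table
#'
#' @param assoc an `assoc_table`.
#' @return data.frame (chrom, pos, neg_log10_p) sorted by (chrom, pos).
#' @export
manhattan_table <- function(assoc) {
  out <- data.frame(chrom = assoc$chrom, pos = assoc$pos,
                    neg_log10_p = -log10(assoc$p_gc))
  out[order(out$chrom, out$pos), ]
}
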
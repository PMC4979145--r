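#' Genomic kinship (VanRaden-type) matrix
#'
#' Frequency-weighted genomic relationship matrix
#' Phi_ij = (1/m) sum_k (g_ik - 2 p_k)(g_jk - 2 p_k) / (2 p_k (1 - p_k)),
#' with missing dosages mean-imputed per SNP. Monomorphic SNPs must be
#' removed beforehand (see [qc_filter()]).
#'
#' @param G a `genotype_matrix` or a plain n x m dosage matrix with row
#'   names as individual ids.
#' @return object of class `kinship_matrix`: list(ids, phi) with `phi`
#'   symmetric n x n.
#' @export
genomic_kinship <- function(G) {
  dos <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  ids <- rownames(dos)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(dos)))
  p <- colMeans(dos, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP present: run QC filtering first")
  if (anyNA(dos)) {
    for (k in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, k]), k] <- 2 * p[k]
  }
  Z <- sweep(dos, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  phi <- tcrossprod(Z) / ncol(dos)
  phi <- (phi + t(phi)) / 2
  dimnames(phi) <- list(ids, ids)
  structure(list(ids = ids, phi = phi), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  n <- length(x$ids)
  od <- x$phi[upper.tri(x$phi)]
  cat(sprintf("kinship_matrix: %d individuals; mean diagonal %.3f, mean off-diagonal %.4f\n",
              n, mean(diag(x$phi)), mean(od)))
  invisible(x)
}

#' Pedigree numerator relationship matrix
#'
#' Additive relationship matrix A by the tabular method. Parents must be
#' listed before their offspring (the function topologically checks this);
#' unknown parents are coded NA or "0".
#'
#' @param pedigree data.frame with columns id, sire, dam.
#' @return object of class `kinship_matrix`.
#' @export
pedigree_nrm <- function(pedigree) {
  id <- as.character(pedigree$id)
  sire <- as.character(pedigree$sire)
  dam <- as.character(pedigree$dam)
  sire[sire %in% c("0", "", NA)] <- NA
  dam[dam %in% c("0", "", NA)] <- NA
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  idx <- setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  if (any(is.na(si)) || any(is.na(di)))
    stop("unknown parent id in pedigree")
  if (any(si >= seq_len(n) & si > 0) || any(di >= seq_len(n) & di > 0))
    stop("pedigree not sorted: parents must precede offspring (or a cycle exists)")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      aj <- 0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  structure(list(ids = id, phi = A), class = "kinship_matrix")
}
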
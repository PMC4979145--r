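#' RPKM: reads per kilobase of transcript per million mapped reads
#'
#' rpkm = 1e9 * count / (total_mapped * length_bp). Vectorized and
#' recycling-safe over genes and samples.
#'
#' @param count read counts (vector or matrix with genes in rows).
#' @param gene_length_bp per-gene transcript length in bp (> 0).
#' @param total_mapped per-sample total mapped reads (> 0; scalar or one
#'   per column when `count` is a matrix).
#' @return rpkm values with the shape of `count`.
#' @export
compute_rpkm <- function(count, gene_length_bp, total_mapped) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(total_mapped <= 0)) stop("library size must be positive")
  if (is.matrix(count)) {
    out <- 1e9 * sweep(sweep(count, 1, gene_length_bp, "/"),
                       2, total_mapped, "/")
  } else {
    out <- 1e9 * count / (total_mapped * gene_length_bp)
  }
  out
}

#' Call differentially expressed genes between RFI groups
#'
#' Counts are pooled within each group. The log2 fold change (low vs
#' high) is computed from pooled RPKM with a pseudocount added to the
#' pooled counts; the p-value is a two-sided exact two-proportion test
#' (Fisher) of the pooled gene counts against the pooled library
#' remainders; q-values are Benjamini-Hochberg. A gene is DE when
#' q < `q_max` and |log2FC| >= `min_abs_log2fc`. Genes with zero pooled
#' counts in exactly one group and RPKM at or above `rpkm_floor` in the
#' other are reported as group-specific instead.
#'
#' @param counts data.frame with gene_id, length_bp and one column per
#'   sample (as from [simulate_counts()]).
#' @param groups named character vector mapping sample column names to
#'   "low"/"high".
#' @param total_mapped named per-sample totals; defaults to column sums.
#' @param q_max,min_abs_log2fc DE thresholds.
#' @param pseudocount added to pooled counts for the fold change.
#' @param rpkm_floor expression floor for group-specific calls.
#' @return data.frame of class `deg_table`: gene_id, rpkm_mean_high,
#'   rpkm_mean_low, log2fc, p, q, status in {up_in_low, down_in_low,
#'   group_specific_low, group_specific_high, not_de}.
#' @export
call_degs <- function(counts, groups, total_mapped = NULL,
                      q_max = 0.05, min_abs_log2fc = 1,
                      pseudocount = 0.5, rpkm_floor = 1) {
  samp <- names(groups)
  if (!all(samp %in% names(counts)))
    stop("all samples in `groups` must be columns of `counts`")
  if (!any(groups == "low") || !any(groups == "high"))
    stop("need at least one sample per group")
  cnt <- as.matrix(counts[, samp, drop = FALSE])
  len <- counts$length_bp
  if (is.null(total_mapped)) total_mapped <- colSums(cnt)
  total_mapped <- total_mapped[samp]

  rpkm <- compute_rpkm(cnt, len, total_mapped)
  low_cols <- samp[groups == "low"]
  high_cols <- samp[groups == "high"]
  rpkm_low <- rowMeans(rpkm[, low_cols, drop = FALSE])
  rpkm_high <- rowMeans(rpkm[, high_cols, drop = FALSE])

  c_low <- rowSums(cnt[, low_cols, drop = FALSE])
  c_high <- rowSums(cnt[, high_cols, drop = FALSE])
  N_low <- sum(total_mapped[low_cols])
  N_high <- sum(total_mapped[high_cols])

  # pooled RPKM with pseudocount on pooled counts
  pr_low <- 1e9 * (c_low + pseudocount) / (N_low * len)
  pr_high <- 1e9 * (c_high + pseudocount) / (N_high * len)
  log2fc <- log2(pr_low / pr_high)

  p <- vapply(seq_along(c_low), function(i) {
    if (c_low[i] == 0 && c_high[i] == 0) return(1)
    fisher.test(matrix(c(c_low[i], N_low - c_low[i],
                         c_high[i], N_high - c_high[i]), 2))$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")

  de <- q < q_max & abs(log2fc) >= min_abs_log2fc
  status <- rep("not_de", length(p))
  status[de & log2fc > 0] <- "up_in_low"
  status[de & log2fc < 0] <- "down_in_low"
  gs_low <- c_high == 0 & c_low > 0 & rpkm_low >= rpkm_floor
  gs_high <- c_low == 0 & c_high > 0 & rpkm_high >= rpkm_floor
  status[gs_low] <- "group_specific_low"
  status[gs_high] <- "group_specific_high"

  out <- data.frame(gene_id = counts$gene_id,
                    rpkm_mean_high = rpkm_high, rpkm_mean_low = rpkm_low,
                    log2fc = log2fc, p = p, q = q, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  tab <- table(factor(x$status,
                      levels = c("up_in_low", "down_in_low",
                                 "group_specific_low",
                                 "group_specific_high", "not_de")))
  cat("deg_table:", nrow(x), "genes;",
      sum(x$status != "not_de"), "DE calls\n")
  print(tab)
  invisible(x)
}

#' miRNA-target direction consistency
#'
#' For each (miRNA, target) pair with the target in the DEG set, the pair
#' is consistent with negative regulation when the miRNA's expression
#' direction in the low-RFI group is opposite to the target's.
#'
#' @param degs a `deg_table`.
#' @param target_lists named list: miRNA -> character vector of target
#'   gene ids.
#' @param mirna_direction named character: miRNA -> "up_in_low" or
#'   "down_in_low".
#' @return list(table = per-pair verdicts, n_consistent, n_inconsistent,
#'   unknown_genes).
#' @export
mirna_target_consistency <- function(degs, target_lists, mirna_direction) {
  dir_of <- function(st) {
    if (st %in% c("up_in_low", "group_specific_low")) "up"
    else if (st %in% c("down_in_low", "group_specific_high")) "down"
    else NA_character_
  }
  rows <- list()
  unknown <- character(0)
  for (mir in names(target_lists)) {
    mdir <- dir_of(mirna_direction[[mir]])
    for (gene in target_lists[[mir]]) {
      hit <- match(gene, degs$gene_id)
      if (is.na(hit)) { unknown <- c(unknown, gene); next }
      gstat <- degs$status[hit]
      gdir <- dir_of(gstat)
      if (is.na(gdir) || is.na(mdir)) next   # not in the DE set
      rows[[length(rows) + 1]] <- data.frame(
        mirna = mir, gene = gene, mirna_dir = mdir, gene_dir = gdir,
        consistent = mdir != gdir, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mirna = character(0), gene = character(0),
                         mirna_dir = character(0), gene_dir = character(0),
                         consistent = logical(0))
  list(table = tab, n_consistent = sum(tab$consistent),
       n_inconsistent = sum(!tab$consistent),
       unknown_genes = unique(unknown))
}
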
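#' Gene models container
#'
#' Minimal annotation container used by the SNP-gene integration step:
#' 1-based inclusive coordinates throughout.
#'
#' @param genes data.frame: gene_id, chrom, start, end, strand ("+"/"-").
#' @param exons optional data.frame: gene_id, start, end.
#' @param utr3,utr5 optional data.frames: gene_id, start, end.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons = NULL, utr3 = NULL, utr5 = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  empty <- data.frame(gene_id = character(0), start = numeric(0),
                      end = numeric(0))
  structure(list(genes = genes,
                 exons = if (is.null(exons)) empty else exons,
                 utr3 = if (is.null(utr3)) empty else utr3,
                 utr5 = if (is.null(utr5)) empty else utr5),
            class = "gene_models")
}

#' Read gene models from a GFF3 file
#'
#' Parses gene, exon and UTR features via `rtracklayer::import` and
#' assembles a [gene_models()] container. Features are attached to genes
#' by their `gene_id` attribute when present, falling back to the `Parent`
#' / `ID` hierarchy.
#'
#' @param path GFF3 file path.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3 annotation")
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  get_gene_id <- function(df) {
    if (!is.null(df$gene_id) && any(!is.na(df$gene_id))) return(df$gene_id)
    if (!is.null(df$ID)) return(df$ID)
    rep(NA_character_, nrow(df))
  }
  is_gene <- md$type == "gene"
  genes <- data.frame(gene_id = get_gene_id(md[is_gene, , drop = FALSE]),
                      chrom = as.character(md$seqnames[is_gene]),
                      start = md$start[is_gene], end = md$end[is_gene],
                      strand = as.character(md$strand[is_gene]),
                      stringsAsFactors = FALSE)
  # map transcript IDs up to their parent genes so exon/UTR Parents resolve
  parent_chr <- function(p) vapply(p, function(v)
    if (length(v)) as.character(v[1]) else NA_character_, character(1))
  id2gene <- setNames(genes$gene_id, genes$gene_id)
  if (!is.null(md$Parent) && !is.null(md$ID)) {
    tx <- md$type %in% c("mRNA", "transcript")
    if (any(tx)) {
      tp <- parent_chr(md$Parent[tx])
      id2gene <- c(id2gene, setNames(id2gene[tp], md$ID[tx]))
    }
  }
  feat <- function(types) {
    sel <- md$type %in% types
    if (!any(sel)) return(NULL)
    gid <- if (!is.null(md$gene_id) && any(!is.na(md$gene_id[sel])))
      md$gene_id[sel] else unname(id2gene[parent_chr(md$Parent[sel])])
    data.frame(gene_id = gid, start = md$start[sel], end = md$end[sel],
               stringsAsFactors = FALSE)
  }
  gene_models(genes, exons = feat("exon"),
              utr3 = feat("three_prime_UTR"),
              utr5 = feat("five_prime_UTR"))
}

#' Classify a SNP's positional relation to the nearest gene
#'
#' Within a harbouring gene the precedence is UTR-3 / UTR-5 > exon >
#' intron. A SNP outside every gene is "upstream"/"downstream" when it
#' lies within `near_bp` of the strand-oriented transcription start/end
#' of a gene, and "intergenic" otherwise (the nearest gene is still
#' named, by minimal distance). Ties are broken by the lexicographically
#' smaller gene_id.
#'
#' @param chrom,pos SNP coordinate (1-based).
#' @param models a `gene_models`.
#' @param near_bp window for up/downstream labels (default 5000).
#' @return list(nearest_gene, relation, distance).
#' @export
classify_snp_gene_relation <- function(chrom, pos, models, near_bp = 5000) {
  g <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0)
    return(list(nearest_gene = NA_character_, relation = "intergenic",
                distance = NA_real_, flagged = TRUE))
  inside <- g[g$start <= pos & pos <= g$end, , drop = FALSE]
  if (nrow(inside) > 0) {
    inside <- inside[order(inside$gene_id), , drop = FALSE]
    for (k in seq_len(nrow(inside))) {
      gid <- inside$gene_id[k]
      hit_in <- function(df) any(df$gene_id == gid & df$start <= pos &
                                   pos <= df$end)
      rel <- if (hit_in(models$utr3)) "UTR-3"
      else if (hit_in(models$utr5)) "UTR-5"
      else if (hit_in(models$exons)) "exon"
      else "intron"
      return(list(nearest_gene = gid, relation = rel, distance = 0,
                  flagged = FALSE))
    }
  }
  # outside all genes: strand-oriented up/downstream within near_bp
  gap_start <- g$start - pos   # >0: SNP left of gene
  gap_end <- pos - g$end       # >0: SNP right of gene
  dist <- pmax(gap_start, gap_end, 0)
  side <- ifelse(gap_start > 0, "left", "right")
  rel_cand <- ifelse(side == "left",
                     ifelse(g$strand == "+", "upstream", "downstream"),
                     ifelse(g$strand == "+", "downstream", "upstream"))
  near <- which(dist <= near_bp)
  if (length(near)) {
    near <- near[order(dist[near], g$gene_id[near])]
    k <- near[1]
    return(list(nearest_gene = g$gene_id[k], relation = rel_cand[k],
                distance = dist[k], flagged = FALSE))
  }
  ord <- order(dist, g$gene_id)
  k <- ord[1]
  list(nearest_gene = g$gene_id[k], relation = "intergenic",
       distance = dist[k], flagged = FALSE)
}

#' Capture genes in the flanking window of significant SNPs
#'
#' A gene is captured when its [start, end] interval intersects the
#' closed window [pos - flank, pos + flank] around a significant SNP.
#' Distance is 0 when the SNP lies inside the gene, otherwise the bp gap
#' between the SNP and the nearer gene boundary.
#'
#' @param snps data.frame: snp_id, chrom, pos.
#' @param models a `gene_models`.
#' @param flank_kb flank size in kb (50 and 500 are the conventional
#'   choices).
#' @return data.frame (snp_id, gene_id, chrom, distance), one row per
#'   (snp, gene) pair, sorted by (snp_id, gene_id).
#' @export
flank_gene_capture <- function(snps, models, flank_kb = 50) {
  if (flank_kb <= 0) stop("flank_kb must be positive")
  flank <- flank_kb * 1000
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    ch <- snps$chrom[i]; pos <- snps$pos[i]
    g <- models$genes[models$genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    hit <- g$end >= pos - flank & g$start <= pos + flank
    if (!any(hit)) next
    gh <- g[hit, , drop = FALSE]
    dist <- ifelse(gh$start <= pos & pos <= gh$end, 0,
                   pmin(abs(gh$start - pos), abs(gh$end - pos)))
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = snps$snp_id[i], gene_id = gh$gene_id, chrom = ch,
      distance = dist, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(snp_id = character(0), gene_id = character(0),
                         chrom = character(0), distance = numeric(0))
  out <- out[order(out$snp_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of flank-captured genes with DEGs
#'
#' Inner join of the capture table with the DEG table on gene_id,
#' restricted to differentially expressed genes.
#'
#' @param captured output of [flank_gene_capture()].
#' @param degs a `deg_table`.
#' @param de_only keep only genes with a DE status (default TRUE).
#' @return data.frame (gene_id, snp_id, distance, log2fc, q, status), one
#'   row per (gene, snp) pair, in deterministic (gene_id, snp_id) order.
#' @export
gwas_deg_overlap <- function(captured, degs, de_only = TRUE) {
  d <- as.data.frame(degs)
  if (de_only) d <- d[d$status != "not_de", , drop = FALSE]
  out <- merge(captured, d[, c("gene_id", "log2fc", "q", "status")],
               by = "gene_id")
  out <- out[!duplicated(out[, c("gene_id", "snp_id")]), , drop = FALSE]
  out <- out[order(out$gene_id, out$snp_id),
             c("gene_id", "snp_id", "distance", "log2fc", "q", "status")]
  rownames(out) <- NULL
  out
}
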
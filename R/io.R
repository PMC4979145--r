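#' Write genotypes as an uncompressed VCF
#'
#' Minimal VCFv4.2 with GT fields; the counted (minor) allele of the
#' simulator is written as ALT.
#'
#' @param G `genotype_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  map <- G$map
  dos <- G$dosage
  gt <- matrix("0/0", nrow = ncol(dos), ncol = nrow(dos))
  gt[t(dos) == 1] <- "0/1"
  gt[t(dos) == 2] <- "1/1"
  gt[is.na(t(dos))] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=rfikit",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$ids), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$snp_id, "A", "G", ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses `vcfR` to parse; dosages count the ALT allele.
#'
#' @param path VCF path (.vcf or .vcf.gz).
#' @return a `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcfR is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  dos <- apply(gt, 1, count_alt)   # samples x SNPs
  rownames(dos) <- colnames(gt)
  chrom <- suppressWarnings(as.integer(vcfR::getCHROM(v)))
  if (anyNA(chrom)) chrom <- vcfR::getCHROM(v)
  map <- data.frame(snp_id = vcfR::getID(v),
                    chrom = chrom,
                    pos = vcfR::getPOS(v),
                    freq = colMeans(dos, na.rm = TRUE) / 2,
                    stringsAsFactors = FALSE)
  colnames(dos) <- map$snp_id
  structure(list(dosage = dos, map = map, ids = rownames(dos)),
            class = "genotype_matrix")
}

#' Write genotypes as PLINK text .ped/.map
#'
#' @param G `genotype_matrix`.
#' @param prefix output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
write_genotypes_plink <- function(G, prefix) {
  map <- data.frame(chrom = G$map$chrom, snp_id = G$map$snp_id,
                    cm = 0, pos = G$map$pos)
  write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  dos <- G$dosage
  a1 <- ifelse(dos >= 1, "G", "A"); a1[is.na(dos)] <- "0"
  a2 <- ifelse(dos == 2, "G", "A"); a2[is.na(dos)] <- "0"
  alleles <- matrix("", nrow(dos), 2 * ncol(dos))
  alleles[, seq(1, 2 * ncol(dos), by = 2)] <- a1
  alleles[, seq(2, 2 * ncol(dos), by = 2)] <- a2
  ped <- cbind("FAM1", G$ids, "0", "0", "0", "-9", alleles)
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from PLINK text .ped/.map
#'
#' Dosages count the minor allele of each SNP (determined from the data).
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos"),
                    stringsAsFactors = FALSE)
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  m <- nrow(map)
  dos <- matrix(NA_integer_, length(ids), m)
  for (k in seq_len(m)) {
    a1 <- al[, 2 * k - 1]; a2 <- al[, 2 * k]
    miss <- a1 == "0" | a2 == "0"
    alleles <- c(a1[!miss], a2[!miss])
    ac <- sort(table(alleles))
    minor <- names(ac)[1]
    dos[, k] <- (a1 == minor) + (a2 == minor)
    dos[miss, k] <- NA_integer_
  }
  dimnames(dos) <- list(ids, map$snp_id)
  structure(list(dosage = dos,
                 map = data.frame(snp_id = map$snp_id, chrom = map$chrom,
                                  pos = map$pos,
                                  freq = colMeans(dos, na.rm = TRUE) / 2,
                                  stringsAsFactors = FALSE),
                 ids = ids),
            class = "genotype_matrix")
}

#' Write / read the phenotype CSV
#'
#' Long-format schema: bird_id, sex, pen, DOT, body_weight_g, feed_g.
#'
#' @param records long data.frame.
#' @param path file path.
#' @return path (write) or data.frame (read).
#' @export
write_phenotypes_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a kinship matrix as square TSV with an id header
#'
#' @param K `kinship_matrix`.
#' @param path file path.
#' @export
write_kinship_tsv <- function(K, path) {
  df <- data.frame(id = K$ids, K$phi, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df$id)
  phi <- as.matrix(df[, -1, drop = FALSE])
  dimnames(phi) <- list(ids, ids)
  structure(list(ids = ids, phi = phi), class = "kinship_matrix")
}

#' Write counts TSV (gene_id, length_bp, sample columns)
#'
#' @param counts counts data.frame.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}
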
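#' Pipeline run configuration
#'
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to run, in dependency order
#'   from: simulate, growth, rfi, varcomp, gwas, ld, deg, integrate; or
#'   "all".
#' @param sim a [sim_config()] for the simulate stage.
#' @param counts_cfg a [counts_config()] for the deg stage.
#' @param r2_flag_threshold,alpha_fixed,sig_threshold,fdr_tiers,q_max,min_abs_log2fc,flank_kb
#'   stage thresholds (growth-fit flag, fixed-effect adjustment, GWAS
#'   significance on lambda-corrected p, FDR tier levels, DEG q cut-off,
#'   DEG fold-change cut-off, flank size in kb).
#' @param qc list of QC thresholds passed to [qc_filter()].
#' @param seed master seed; stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("rfikit_run_"),
                       stages = "all",
                       sim = sim_config(),
                       counts_cfg = counts_config(),
                       r2_flag_threshold = 0.80,
                       alpha_fixed = 0.01,
                       sig_threshold = 1e-4,
                       fdr_tiers = c(0.05, 0.10),
                       q_max = 0.05,
                       min_abs_log2fc = 1,
                       flank_kb = 500,
                       qc = list(min_call_rate_snp = 0.95,
                                 min_call_rate_ind = 0.95,
                                 min_maf = 0.01, hwe_p_min = 1e-6),
                       seed = 1L) {
  all_stages <- c("simulate", "growth", "rfi", "varcomp", "gwas", "ld",
                  "deg", "integrate")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages),
            sig_threshold > 0, sig_threshold < 1,
            q_max > 0, q_max < 1, flank_kb > 0,
            r2_flag_threshold >= 0, r2_flag_threshold <= 1)
  structure(list(out_dir = out_dir, stages = stages, sim = sim,
                 counts_cfg = counts_cfg,
                 r2_flag_threshold = r2_flag_threshold,
                 alpha_fixed = alpha_fixed, sig_threshold = sig_threshold,
                 fdr_tiers = fdr_tiers, q_max = q_max,
                 min_abs_log2fc = min_abs_log2fc, flank_kb = flank_kb,
                 qc = qc, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate -> growth ->
#' rfi -> varcomp -> gwas -> ld -> deg -> integrate), writing fixed-name
#' TSV outputs and a JSON run manifest (seeds, per-stage row counts) to
#' `config$out_dir`. A stage whose upstream product is missing fails with
#' an error naming the missing stage. Annotation (`gene_models`) may be
#' supplied for the integrate stage; without it a synthetic annotation is
#' derived from the simulated SNP map so the stage remains runnable.
#'
#' @param config a [run_config()].
#' @param models optional `gene_models` for the integrate stage.
#' @param quiet suppress progress messages.
#' @return list with the in-memory stage products and `manifest`.
#' @export
run_pipeline <- function(config, models = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  st <- config$stages
  res <- list()
  manifest <- list(package = "rfikit",
                   version = as.character(packageVersion("rfikit")),
                   seed = config$seed, stages = st, counts = list(),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  need <- function(what, from_stage) {
    if (is.null(res[[what]]))
      stop(sprintf("missing upstream output '%s': enable the '%s' stage",
                   what, from_stage), call. = FALSE)
    res[[what]]
  }

  if ("simulate" %in% st) {
    say("[simulate] genotypes, phenotypes, counts")
    sim <- config$sim
    sim$seed <- config$seed
    res$G <- simulate_genotypes(sim)
    gi <- simulate_growth_and_intake(res$G, sim)
    res$records <- gi$records
    res$truth <- gi$truth
    cc <- config$counts_cfg
    cc$seed <- config$seed
    sc <- simulate_counts(cc)
    res$counts <- sc$counts; res$counts_groups <- sc$groups
    res$counts_totals <- sc$total_mapped; res$counts_truth <- sc$truth
    write_genotypes_vcf(res$G, file.path(config$out_dir, "genotypes.vcf"))
    write_phenotypes_csv(res$records,
                         file.path(config$out_dir, "phenotypes.csv"))
    write_counts_tsv(res$counts, file.path(config$out_dir, "counts.tsv"))
    manifest$counts$simulate <- list(n_individuals = nrow(res$G$dosage),
                                     n_snps = ncol(res$G$dosage),
                                     n_genes = nrow(res$counts))
  }

  if ("growth" %in% st) {
    records <- need("records", "simulate")
    say("[growth] per-bird growth curves and feeding traits")
    res$traits <- derive_cohort_traits(records,
                                       r2_flag_threshold = config$r2_flag_threshold)
    write.table(res$traits, file.path(config$out_dir, "traits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$growth <- list(n_birds = nrow(res$traits))
  }

  if ("rfi" %in% st) {
    traits <- need("traits", "growth")
    say("[rfi] Koch model, fixed effects, Johnson transform")
    kf <- fit_koch_rfi(traits)
    res$koch <- kf
    adj <- test_fixed_effects_and_adjust(kf$rfi, traits$sex, traits$pen,
                                         alpha = config$alpha_fixed)
    res$fixed_effects <- adj
    jt <- johnson_transform(adj$rfi_adjusted)
    res$johnson <- jt
    res$traits$rfi <- kf$rfi
    res$traits$rfi_adjusted <- adj$rfi_adjusted
    res$traits$rfi_transformed <- jt$z
    res$contrast <- divergent_group_contrast(res$traits)
    write.table(res$contrast$table,
                file.path(config$out_dir, "contrast.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(family = jt$family, params = as.list(jt$params),
           sel_z = jt$sel_z, ad_p_before = jt$ad_before,
           ad_p_after = jt$ad_after,
           p_sex = adj$p_sex, p_pen = adj$p_pen,
           adjusted_for = adj$adjusted_for),
      file.path(config$out_dir, "transform_audit.json"),
      auto_unbox = TRUE, digits = NA)
    manifest$counts$rfi <- list(koch_r2 = kf$r2_model,
                                johnson_family = jt$family)
  }

  if ("varcomp" %in% st) {
    traits <- need("traits", "rfi")
    G <- need("G", "simulate")
    say("[varcomp] kinship + REML")
    res$K <- genomic_kinship(qc_filter(G, min_maf = 0.01)$G)
    X <- stats::model.matrix(~ factor(sex) + factor(pen),
                             data = traits)
    X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
    res$varcomp <- reml_univariate(traits$rfi, X, res$K)
    write_kinship_tsv(res$K, file.path(config$out_dir, "kinship.tsv"))
    jsonlite::write_json(
      list(sigma_a2 = res$varcomp$sigma_a2,
           sigma_e2 = res$varcomp$sigma_e2,
           h2 = res$varcomp$h2, se_h2 = res$varcomp$se_h2,
           loglik = res$varcomp$loglik,
           converged = res$varcomp$converged),
      file.path(config$out_dir, "varcomp.json"),
      auto_unbox = TRUE, digits = NA)
    manifest$counts$varcomp <- list(h2 = res$varcomp$h2)
  }

  if ("gwas" %in% st) {
    G <- need("G", "simulate")
    traits <- need("traits", "rfi")
    if (is.null(traits$rfi_transformed))
      stop("missing upstream output 'rfi_transformed': enable the 'rfi' stage",
           call. = FALSE)
    say("[gwas] QC + mixed-model scan")
    qcres <- do.call(qc_filter, c(list(G), config$qc))
    res$qc_report <- qcres$report
    Gq <- qcres$G
    keep <- match(Gq$ids, traits$bird_id)
    y <- traits$rfi_transformed[keep]
    K <- genomic_kinship(Gq)
    res$assoc <- mixed_model_scan(y, Gq, K,
                                  sig_threshold = config$sig_threshold,
                                  compute_var = TRUE)
    res$G_qc <- Gq
    write.table(as.data.frame(res$assoc),
                file.path(config$out_dir, "assoc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(manhattan_table(res$assoc),
                file.path(config$out_dir, "manhattan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$qc_report,
                         file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$counts$gwas <- list(n_snps_tested = nrow(res$assoc),
                                 lambda = attr(res$assoc, "lambda"),
                                 n_significant = sum(res$assoc$significant))
  }

  if ("ld" %in% st) {
    assoc <- need("assoc", "gwas")
    Gq <- need("G_qc", "gwas")
    say("[ld] decay profile + blocks around top hits")
    res$ld_decay <- ld_decay_profile(Gq)
    # block construction around the most associated region
    top <- assoc[order(assoc$p_gc), ][1, ]
    sel <- which(Gq$map$chrom == top$chrom &
                   abs(Gq$map$pos - top$pos) <= 5e4)
    sel <- sel[seq_len(min(length(sel), 25))]
    Gr <- structure(list(dosage = Gq$dosage[, sel, drop = FALSE],
                         map = Gq$map[sel, ], ids = Gq$ids),
                    class = "genotype_matrix")
    res$blocks <- gabriel_blocks(Gr)
    blk_df <- if (length(res$blocks))
      do.call(rbind, lapply(res$blocks, function(b) data.frame(
        chrom = b$chrom, start = b$start, end = b$end,
        n_snps = b$n_snps, span = b$span,
        haplotypes = if (!is.null(b$haplotypes))
          paste(sprintf("%s:%.3f", b$haplotypes$haplotype,
                        b$haplotypes$frequency), collapse = ",")
        else "", stringsAsFactors = FALSE)))
    else data.frame(chrom = integer(0), start = integer(0),
                    end = integer(0), n_snps = integer(0),
                    span = integer(0), haplotypes = character(0))
    write.table(blk_df, file.path(config$out_dir, "blocks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$ld_decay, file.path(config$out_dir, "ld_decay.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$ld <- list(n_blocks = length(res$blocks))
  }

  if ("deg" %in% st) {
    counts <- need("counts", "simulate")
    say("[deg] RPKM + differential expression")
    res$degs <- call_degs(counts, need("counts_groups", "simulate"),
                          need("counts_totals", "simulate"),
                          q_max = config$q_max,
                          min_abs_log2fc = config$min_abs_log2fc)
    write.table(as.data.frame(res$degs),
                file.path(config$out_dir, "degs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$deg <- list(n_genes = nrow(res$degs),
                                n_de = sum(res$degs$status != "not_de"))
  }

  if ("integrate" %in% st) {
    assoc <- need("assoc", "gwas")
    degs <- need("degs", "deg")
    say("[integrate] flank capture + DEG overlap")
    if (is.null(models)) {
      # synthetic annotation derived from the SNP map: evenly spaced genes
      G <- need("G", "simulate")
      models <- synthetic_gene_models(G, n_genes_overlap = nrow(degs))
    }
    sig <- assoc[assoc$significant, c("snp_id", "chrom", "pos")]
    if (nrow(sig) == 0)
      sig <- assoc[order(assoc$p_gc), ][seq_len(min(5, nrow(assoc))),
                                        c("snp_id", "chrom", "pos")]
    res$captured <- flank_gene_capture(sig, models,
                                       flank_kb = config$flank_kb)
    res$overlap <- gwas_deg_overlap(res$captured, degs)
    rel <- lapply(seq_len(nrow(sig)), function(i)
      classify_snp_gene_relation(sig$chrom[i], sig$pos[i], models))
    res$relations <- data.frame(
      snp_id = sig$snp_id,
      nearest_gene = vapply(rel, `[[`, character(1), "nearest_gene"),
      relation = vapply(rel, `[[`, character(1), "relation"),
      stringsAsFactors = FALSE)
    write.table(res$overlap, file.path(config$out_dir, "overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$relations, file.path(config$out_dir, "relations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$integrate <- list(n_captured = nrow(res$captured),
                                      n_overlap = nrow(res$overlap))
  }

  res$manifest <- manifest
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Synthetic gene annotation spanning a simulated SNP map
#'
#' Evenly tiles each simulated chromosome with gene models (alternating
#' strand, 40% of the genome covered) whose ids reuse the simulated gene
#' ids so that GWAS-DEG overlap is exercisable on purely synthetic runs.
#' This is a synthetic stand-in for a real GFF3 annotation.
#'
#' @param G `genotype_matrix` (for chromosome extents).
#' @param n_genes_overlap number of gene ids to generate (reusing the
#'   simulated counts-table ids gene00001..).
#' @param gene_length_bp,gap_bp tiling geometry.
#' @return a `gene_models` object.
#' @export
synthetic_gene_models <- function(G, n_genes_overlap = 1000,
                                  gene_length_bp = 12000, gap_bp = 18000) {
  rows <- list()
  gid <- 0L
  for (ch in unique(G$map$chrom)) {
    extent <- max(G$map$pos[G$map$chrom == ch])
    starts <- seq(1, extent, by = gene_length_bp + gap_bp)
    for (s in starts) {
      gid <- gid + 1L
      if (gid > n_genes_overlap) break
      rows[[gid]] <- data.frame(
        gene_id = sprintf("gene%05d", gid), chrom = ch, start = s,
        end = s + gene_length_bp - 1,
        strand = if (gid %% 2 == 0) "-" else "+",
        stringsAsFactors = FALSE)
    }
    if (gid > n_genes_overlap) break
  }
  gene_models(do.call(rbind, rows))
}
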
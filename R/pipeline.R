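# Full-pipeline orchestration: filter -> diversity -> scans -> MK -> RDA ->
# candidate-gene intersection, from a bundle directory of input files.

#' Run the full local-adaptation pipeline
#'
#' Executes, in order: VCF reading and hard filtering, site classification,
#' genotype encoding, per-population diversity, pairwise FST and XP-CLR
#' scans with HDR calling, Fay-Wu H contrasts, the MK test over the coding
#' alignments, RDA against the environment table with loading outliers, and
#' the candidate-gene intersection (genes overlapping an HDR AND containing
#' at least one RDA-outlier SNP within exons). Per-stage tables are written
#' to `outdir` when given.
#'
#' @param bundle_dir directory with `variants.vcf`, `genes.gff3`,
#'   `popmap.tsv`, `env.tsv` and `genes/` (as from [emit_bundle()]).
#' @param pairs list of 2-vectors of population labels to compare (default:
#'   all pairs among the non-outgroup populations).
#' @param size,step scan window size and step in bp.
#' @param z outlier cutoff in SD (default 1.96).
#' @param n_perm RDA permutations (default 199).
#' @param exon_only restrict the candidate rule to exonic outlier SNPs
#'   (default TRUE; FALSE widens to gene bodies).
#' @param seed RNG seed for the permutation test.
#' @param outdir optional output directory for per-stage TSV/JSON files.
#' @param chrom_lengths optional named chromosome lengths for window grids.
#' @return list of class `locadapt_run` with per-stage results and the
#'   candidate-gene report.
#' @export
run_pipeline <- function(bundle_dir, pairs = NULL, size = 20000L,
                         step = 5000L, z = 1.96, n_perm = 199, seed = 1,
                         exon_only = TRUE, outdir = NULL,
                         chrom_lengths = NULL) {
  popmap <- read_popmap(file.path(bundle_dir, "popmap.tsv"))
  rec <- read_vcf(file.path(bundle_dir, "variants.vcf"), popmap)
  genes <- read_gff3(file.path(bundle_dir, "genes.gff3"))
  env <- read_env(file.path(bundle_dir, "env.tsv"))
  filt <- hard_filter(rec, filter_config())
  fclass <- suppressWarnings(classify_sites(filt$sites, genes))
  gm <- encode_genotypes(filt, fclass)
  gm$sites$aa <- gm$sites$ref         # generator emits ref = ancestral
  study_pops <- setdiff(unique(popmap$population), "OUT")
  if (is.null(pairs))
    pairs <- utils::combn(sort(study_pops), 2, simplify = FALSE)
  # drop the outgroup column block from analysis panels
  panel <- which(gm$pop_of[gm$samples] != "OUT")
  gm_in <- gm
  gm_in$codes <- gm$codes[panel, , drop = FALSE]
  gm_in$samples <- gm$samples[panel]

  diversity <- lapply(setNames(study_pops, study_pops), function(p)
    pi_windows(gm_in, p, chrom_lengths = chrom_lengths))
  scans <- list(); hdrs <- list(); hstats <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "-")
    fst <- wc_fst_windows(gm_in, pr[1], pr[2], size, step, chrom_lengths)
    xp <- xpclr_windows(gm_in, ref_pop = pr[2], obj_pop = pr[1], size,
                        step, chrom_lengths = chrom_lengths)
    hd <- intersect_hdrs(fst, xp, z = z, sites = gm_in$sites)
    scans[[key]] <- list(fst = fst, xpclr = xp)
    hdrs[[key]] <- hd
  }
  for (p in study_pops)
    hstats[[p]] <- fay_wu_h_windows(gm_in, p, size, step, chrom_lengths)

  mk <- NULL
  gene_dir <- file.path(bundle_dir, "genes")
  if (dir.exists(gene_dir)) {
    aln <- read_codon_alignments(gene_dir)
    if (length(aln) > 0) mk <- mk_test_genes(aln)
  }

  env_rows <- env[match(gm_in$samples, env$sample), ]
  fit <- rda_fit(gm_in, env_rows[c("MAT", "MAMT", "MAP")])
  fit <- rda_axis_test(gm_in, env_rows[c("MAT", "MAMT", "MAP")], fit,
                       n_perm = n_perm, seed = seed)
  outl <- loading_outliers(fit, z = z)

  # candidate genes per comparison: HDR overlap AND exonic outlier SNP
  keep_class <- if (exon_only) "exon" else
    c("exon", "utr", "intron", "promoter")
  outlier_sites <- gm_in$sites[outl, , drop = FALSE]
  exonic_outl <- outlier_sites[outlier_sites$feature_class %in% keep_class,
                               , drop = FALSE]
  temp_genes <- if (nrow(exonic_outl) > 0) {
    regions <- data.frame(chrom = exonic_outl$chrom,
                          start = exonic_outl$pos - 1L,
                          end = exonic_outl$pos)
    attr(genes_in_regions(regions, genes), "all_genes")
  } else character()
  candidates <- list()
  for (key in names(hdrs)) {
    hd <- hdrs[[key]]
    hdr_genes <- if (nrow(hd) > 0)
      attr(genes_in_regions(hd, genes), "all_genes") else character()
    candidates[[key]] <- list(hdr_genes = hdr_genes,
                              temp_genes = temp_genes,
                              shared = intersect(hdr_genes, temp_genes))
  }
  mk_pos <- if (!is.null(mk)) positive_selection_genes(mk) else character()
  all_shared <- unique(unlist(lapply(candidates, `[[`, "shared")))
  report <- list(candidates_by_pair = candidates,
                 candidate_genes = all_shared,
                 mk_positive = mk_pos,
                 mk_overlap = intersect(all_shared, mk_pos))
  res <- list(gm = gm_in, diversity = diversity, scans = scans,
              hdrs = hdrs, h_windows = hstats, mk = mk, rda = fit,
              rda_outliers = outl, report = report,
              filter_removed = attr(filt, "removed"),
              n_sites = ncol(gm_in$codes))
  class(res) <- "locadapt_run"
  if (!is.null(outdir)) .write_run(res, outdir)
  res
}

#' @export
print.locadapt_run <- function(x, ...) {
  cat("locadapt pipeline run:", x$n_sites, "SNPs after filtering\n")
  for (key in names(x$hdrs))
    cat("  ", key, ":", nrow(x$hdrs[[key]]), "HDRs\n")
  cat("  RDA outlier SNPs:", length(x$rda_outliers),
      "| candidate genes:", length(x$report$candidate_genes), "\n")
  invisible(x)
}

.write_run <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(res$scans)) {
    sc <- merge(res$scans[[key]]$fst,
                res$scans[[key]]$xpclr[c("id", "xpclr", "xpclr_norm")],
                by = "id")
    write.table(sc, file.path(outdir, paste0("scan_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hd <- res$hdrs[[key]]
    write.table(hd[c("chrom", "start", "end")],
                file.path(outdir, paste0("hdrs_", key, ".bed")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  if (!is.null(res$mk))
    write.table(res$mk, file.path(outdir, "mk.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(filter_removed = res$filter_removed, n_sites = res$n_sites,
         r2_adj = res$rda$r2_adj, axis_p = res$rda$axis_p,
         candidate_genes = res$report$candidate_genes,
         mk_positive = res$report$mk_positive),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Venn-region counts for 2 or 3 sets
#'
#' @param sets named list of 2 or 3 vectors.
#' @return named list of exclusive region counts (e.g. `A`, `B`, `AB`, ...)
#'   whose values sum to the size of the union.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("need 2 or 3 sets")
  nm <- names(sets)
  if (is.null(nm)) nm <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = k)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    key <- paste(nm[bits], collapse = "&")
    out[[key]] <- sum(apply(member, 1, function(r) all(r == bits)))
  }
  out
}
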
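# Truth-annotated synthetic input bundles: structured-coalescent neutral
# variation under the composite three-population history, post-hoc sweep and
# genotype-environment-association injection, gene models with coding
# alignments, and VCF/GFF3/TSV/FASTA emission.

#' Default environment table (location-level climate)
#'
#' Mean annual temperature (deg C), mean annual minimum temperature (deg C)
#' and mean annual precipitation (mm) for the three sampling locations, in
#' population order F, S, W.
#' @return data.frame `population MAT MAMT MAP`.
#' @export
default_env <- function() {
  data.frame(population = c("F", "S", "W"),
             MAT = c(19.5, 23.5, 24.9),
             MAMT = c(5.8, 12.4, 15.6),
             MAP = c(1743.3, 1889.3, 1913.0))
}

#' Simulation configuration
#'
#' Defaults are the study conditions the pipeline targets: three diploid
#' populations of 14, 17 and 15 samples plus a 1-diploid outgroup, the
#' composite divergence-bottleneck-expansion-migration history, a target
#' density of 1 SNP per kb, localized hard sweeps with exponential decay
#' length `sweep_lambda`, and temperature-monotone allele-frequency clines.
#' The default genome (2 chromosomes x 2 Mb) keeps full-pipeline runs fast;
#' `chrom_length` and `n_chrom` scale it up.
#'
#' @param n_chrom,chrom_length genome shape (default 2 x 2e6 bp).
#' @param pop_sizes named diploid sample sizes (default F=14, S=17, W=15).
#' @param snp_per_kb target emitted SNP density (default 1).
#' @param locus_len independent-locus block length in bp (default 10000).
#' @param sweeps data.frame `pop chrom center lambda` (NULL = none).
#' @param n_causal,beta GEA signal: causal SNP count and logistic slope per
#'   deg C of MAMT (0 = no signal).
#' @param n_genes,n_selected_genes,cds_len coding-gene bundle shape.
#' @param poly_rate,div_rate per-site coding polymorphism and divergence
#'   rates; `dn_inflation` multiplies nonsynonymous divergence in selected
#'   genes (default 8).
#' @param fail_frac fraction of VCF records given filter-failing
#'   annotations (default 0).
#' @param t_outgroup outgroup join time in generations.
#' @param demography a `demographic_model` (default: composite model 15
#'   at its default parameters).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_length = 2e6,
                       pop_sizes = c(F = 14L, S = 17L, W = 15L),
                       snp_per_kb = 1, locus_len = 10000L,
                       sweeps = NULL, n_causal = 0L, beta = 0,
                       n_genes = 50L, n_selected_genes = 0L, cds_len = 1500L,
                       poly_rate = 0.15, div_rate = 0.05,
                       dn_inflation = 8, fail_frac = 0,
                       t_outgroup = 5e4,
                       demography = model_catalog()$model15) {
  structure(list(n_chrom = n_chrom, chrom_length = chrom_length,
                 pop_sizes = pop_sizes, snp_per_kb = snp_per_kb,
                 locus_len = locus_len, sweeps = sweeps,
                 n_causal = n_causal, beta = beta, n_genes = n_genes,
                 n_selected_genes = n_selected_genes, cds_len = cds_len,
                 poly_rate = poly_rate, div_rate = div_rate,
                 dn_inflation = dn_inflation, fail_frac = fail_frac,
                 t_outgroup = t_outgroup, demography = demography),
            class = "sim_config")
}

# engine spec for the configured ingroup history plus an outgroup deme
.sim_spec <- function(config) {
  spec <- config$demography$build(as.list(config$demography$defaults))
  D <- length(spec$sizes0)
  sizes0 <- c(spec$sizes0, 10000)
  growth0 <- c(spec$growth0, 0)
  mig <- matrix(0, D + 1, D + 1)
  mig[seq_len(D), seq_len(D)] <- spec$mig
  ev <- rbind(spec$events,
              .event(config$t_outgroup, 0, D, 0),
              .event(config$t_outgroup, 1, 0, size = 50000))
  ev <- ev[order(ev$time, ev$type), ]
  list(sizes0 = sizes0, growth0 = growth0, mig = mig, events = ev)
}

#' Simulate neutral haplotypes under the configured history
#'
#' Independent loci of `locus_len` bp tile each chromosome; one structured-
#' coalescent genealogy per locus; infinite-sites mutations at a rate tuned
#' (via a pilot estimate of the mean total branch length) to hit the target
#' SNP density among ingroup-segregating sites. Diploids are formed by
#' pairing consecutive haplotypes.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `haps` (haplotypes x sites 0/1 derived), `sites`
#'   (chrom, pos), `hap_pop` (population per haplotype, outgroup "OUT"),
#'   `achieved_density` per kb.
#' @export
simulate_neutral <- function(config, seed = 1) {
  spec <- .sim_spec(config)
  samples <- c(2L * as.integer(config$pop_sizes), 2L)
  set.seed(seed)
  pilot <- coal_branch_sfs(spec$sizes0, spec$growth0, spec$mig, spec$events,
                           samples, 100L)
  # mean branch length subtending ingroup-segregating configurations
  total_seg <- sum(pilot) * .ingroup_seg_frac(pilot, samples)
  target_mu <- config$snp_per_kb / 1000 / total_seg
  n_loci_per_chrom <- as.integer(ceiling(config$chrom_length /
                                           config$locus_len))
  haps_all <- NULL; sites_all <- NULL
  for (cc in seq_len(config$n_chrom)) {
    sim <- coal_sim_loci(spec$sizes0, spec$growth0, spec$mig, spec$events,
                         samples, n_loci_per_chrom, config$locus_len,
                         target_mu)
    if (nrow(sim$geno) == 0) next
    pos <- sim$locus * config$locus_len + sim$pos + 1L
    ord <- order(pos)
    pos <- pos[ord]
    geno <- sim$geno[ord, , drop = FALSE]
    dup <- duplicated(pos) | pos > config$chrom_length
    pos <- pos[!dup]; geno <- geno[!dup, , drop = FALSE]
    n_in <- sum(samples) - 2L
    dc <- rowSums(geno[, seq_len(n_in), drop = FALSE])
    seg <- dc > 0 & dc < n_in
    haps_all <- rbind(haps_all, geno[seg, , drop = FALSE])
    sites_all <- rbind(sites_all,
                       data.frame(chrom = paste0("chr", cc),
                                  pos = pos[seg]))
  }
  hap_pop <- c(rep(names(config$pop_sizes), 2L * config$pop_sizes),
               rep("OUT", 2))
  achieved <- nrow(sites_all) /
    (config$n_chrom * config$chrom_length / 1000)
  if (abs(achieved - config$snp_per_kb) > 0.5 * config$snp_per_kb)
    warning("achieved SNP density ", signif(achieved, 3),
            "/kb differs from target ", config$snp_per_kb, "/kb")
  list(haps = t(haps_all), sites = sites_all, hap_pop = hap_pop,
       achieved_density = achieved)
}

# fraction of branch-SFS mass segregating within the ingroup populations
.ingroup_seg_frac <- function(arr, samples) {
  d <- dim(arr)
  npop <- length(d)
  idx <- which(arr > 0, arr.ind = TRUE)
  dc_in <- rowSums(sweep(idx[, -npop, drop = FALSE], 2, 1))
  n_in <- sum(samples) - samples[npop]
  sum(arr[idx][dc_in > 0 & dc_in < n_in]) / sum(arr)
}

#' Inject a hard selective sweep
#'
#' One carrier haplotype is chosen in the target population; at each site on
#' the sweep chromosome, every other haplotype of that population adopts the
#' carrier's allele independently with probability exp(-d / lambda), d the
#' distance to the sweep centre. Produces fixation at the centre,
#' high-frequency derived alleles nearby (negative Fay-Wu H) and elevated
#' differentiation against the other populations.
#'
#' @param sim output of [simulate_neutral()].
#' @param pop target population label.
#' @param chrom,center sweep location.
#' @param lambda decay length in bp (> 0).
#' @return the modified `sim`.
#' @export
inject_sweep <- function(sim, pop, chrom, center, lambda = 5e4) {
  if (lambda <= 0) stop("lambda must be positive")
  hap_idx <- which(sim$hap_pop == pop)
  carrier <- hap_idx[1]
  on_chrom <- which(sim$sites$chrom == chrom)
  if (length(on_chrom) == 0) return(sim)
  p_adopt <- exp(-abs(sim$sites$pos[on_chrom] - center) / lambda)
  for (h in setdiff(hap_idx, carrier)) {
    adopt <- runif(length(on_chrom)) < p_adopt
    sim$haps[h, on_chrom[adopt]] <- sim$haps[carrier, on_chrom[adopt]]
  }
  sim
}

#' Inject genotype-environment association signal
#'
#' For each causal SNP the per-population derived-allele frequency is set to
#' logistic(beta * (MAMT_pop - mean MAMT)) (intercept chosen so the
#' across-population mean frequency is about 0.5) and population haplotypes
#' are redrawn as independent Bernoulli draws.
#'
#' @param sim output of [simulate_neutral()].
#' @param env location table (see [default_env()]).
#' @param n_causal number of causal SNPs.
#' @param beta logistic slope per deg C of MAMT.
#' @return `sim` with attribute `causal` = site indices.
#' @export
inject_gea <- function(sim, env, n_causal, beta) {
  if (n_causal > 0 && beta == 0)
    warning("beta = 0: no genotype-environment signal will be injected")
  if (n_causal == 0) {
    attr(sim, "causal") <- integer()
    return(sim)
  }
  causal <- sort(sample(nrow(sim$sites), n_causal))
  mamt <- setNames(env$MAMT, env$population)
  cmamt <- mamt - mean(mamt)
  for (s in causal) {
    for (p in env$population) {
      f <- stats::plogis(beta * cmamt[[p]])
      idx <- which(sim$hap_pop == p)
      sim$haps[idx, s] <- as.integer(runif(length(idx)) < f)
    }
  }
  attr(sim, "causal") <- causal
  sim
}

.BASES <- c("A", "C", "G", "T")

# ancestral in-frame CDS without internal stops
.random_cds <- function(len) {
  stopifnot(len %% 3 == 0)
  repeat_draw <- function() sample(.BASES, len, replace = TRUE)
  s <- repeat_draw()
  codons <- apply(matrix(s, nrow = 3), 2, paste, collapse = "")
  stops <- which(.codon_table()[codons] == "*")
  while (length(stops) > 0) {
    for (i in stops) {
      j <- (i - 1) * 3 + sample(3, 1)
      s[j] <- sample(.BASES, 1)
    }
    codons <- apply(matrix(s, nrow = 3), 2, paste, collapse = "")
    stops <- which(.codon_table()[codons] == "*")
  }
  s
}

# classify a single-base substitution as synonymous in its codon context
.is_synonymous <- function(seq_chars, pos, new_base) {
  ci <- (pos - 1) %/% 3
  cod <- seq_chars[(ci * 3 + 1):(ci * 3 + 3)]
  alt <- cod
  alt[(pos - 1) %% 3 + 1] <- new_base
  .codon_table()[[paste(cod, collapse = "")]] ==
    .codon_table()[[paste(alt, collapse = "")]]
}

#' Generate gene models and coding alignments
#'
#' Places non-overlapping genes (5'UTR, three CDS exons with introns, 3'UTR,
#' 2-kb promoter clearance, random strand) along the genome and emits, per
#' gene, ingroup haplotype CDS sequences and one outgroup CDS under a
#' neutral mutation model; `n_selected_genes` genes get their nonsynonymous
#' divergence inflated by `dn_inflation`.
#'
#' @param config a [sim_config()].
#' @param n_ingroup_seqs ingroup CDS haplotypes per gene (default 10).
#' @return list with `gff` (data.frame of GFF3 rows), `alignments` (as
#'   [read_codon_alignments()]), `selected_genes` (ids).
#' @export
make_genes <- function(config, n_ingroup_seqs = 10L) {
  n <- config$n_genes
  exon_len <- config$cds_len / 3
  utr_len <- 200L; intron_len <- 500L
  gene_span <- 2 * utr_len + 3 * exon_len + 2 * intron_len
  pitch <- gene_span + 2 * 2000 + 1000       # promoter clearance both sides
  per_chrom <- floor((config$chrom_length - 4000) / pitch)
  if (n > per_chrom * config$n_chrom)
    stop("genes do not fit in genome: need ", n, " <= ",
         per_chrom * config$n_chrom)
  sel <- if (config$n_selected_genes > 0)
    sample(n, config$n_selected_genes) else integer()
  gff <- NULL; alignments <- list()
  for (i in seq_len(n)) {
    cc <- paste0("chr", ((i - 1) %/% per_chrom) + 1)
    slot <- (i - 1) %% per_chrom
    gs <- 2001 + slot * pitch
    strand <- sample(c("+", "-"), 1)
    # layout left->right: utr, exon, intron, exon, intron, exon, utr
    b <- gs
    seg <- function(len) { r <- c(b, b + len - 1); b <<- b + len; r }
    u5 <- seg(utr_len); e1 <- seg(exon_len); i1 <- seg(intron_len)
    e2 <- seg(exon_len); i2 <- seg(intron_len); e3 <- seg(exon_len)
    u3 <- seg(utr_len)
    ge <- b - 1
    gid <- sprintf("gene%04d", i)
    row <- function(type, s, e, id = NA, parent = NA) {
      attrs <- paste0(c(if (!is.na(id)) paste0("ID=", id),
                        if (!is.na(parent)) paste0("Parent=", parent)),
                      collapse = ";")
      data.frame(seqid = cc, source = "locadapt", type = type, start = s,
                 end = e, score = ".", strand = strand, phase = ".",
                 attributes = attrs)
    }
    utr5_t <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
    utr3_t <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
    gff <- rbind(gff,
                 row("gene", gs, ge, id = gid),
                 row("mRNA", gs, ge, id = paste0(gid, ".t1"), parent = gid),
                 row(utr5_t, u5[1], u5[2], parent = paste0(gid, ".t1")),
                 row("CDS", e1[1], e1[2], parent = paste0(gid, ".t1")),
                 row("CDS", e2[1], e2[2], parent = paste0(gid, ".t1")),
                 row("CDS", e3[1], e3[2], parent = paste0(gid, ".t1")),
                 row(utr3_t, u3[1], u3[2], parent = paste0(gid, ".t1")))
    # coding alignment
    anc <- .random_cds(config$cds_len)
    ing <- matrix(rep(anc, n_ingroup_seqs), nrow = n_ingroup_seqs,
                  byrow = TRUE)
    n_poly <- rpois(1, config$poly_rate * config$cds_len)
    for (q in seq_len(n_poly)) {
      ppos <- sample(config$cds_len, 1)
      new <- sample(setdiff(.BASES, anc[ppos]), 1)
      n_car <- sample(n_ingroup_seqs - 1, 1)
      ing[sample(n_ingroup_seqs, n_car), ppos] <- new
    }
    og <- anc
    n_div <- rpois(1, config$div_rate * config$cds_len)
    n_extra_dn <- if (i %in% sel)
      rpois(1, (config$dn_inflation - 1) * 0.75 * config$div_rate *
              config$cds_len) else 0L
    for (q in seq_len(n_div)) {
      dpos <- sample(config$cds_len, 1)
      og[dpos] <- sample(setdiff(.BASES, og[dpos]), 1)
    }
    for (q in seq_len(n_extra_dn)) {
      # force a nonsynonymous fixed difference
      for (try in 1:50) {
        dpos <- sample(config$cds_len, 1)
        new <- sample(setdiff(.BASES, og[dpos]), 1)
        if (!.is_synonymous(og, dpos, new)) { og[dpos] <- new; break }
      }
    }
    alignments[[gid]] <- list(
      ingroup = apply(ing, 1, paste, collapse = ""),
      outgroup = paste(og, collapse = ""))
  }
  list(gff = gff, alignments = alignments,
       selected_genes = sprintf("gene%04d", sel))
}

.write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Emit a complete synthetic input bundle
#'
#' Runs the neutral simulation, injects the configured sweeps and GEA
#' signal, generates gene models and coding alignments, and writes
#' `variants.vcf`, `genes.gff3`, `popmap.tsv`, `env.tsv`, `genes/*.fasta`
#' and `truth.json` into `outdir`. VCF annotation fields are drawn from
#' filter-passing distributions, except a `fail_frac` fraction of records
#' which get one failing annotation each (recorded in the truth table).
#'
#' @param config a [sim_config()].
#' @param outdir output directory (must not exist unless `force`).
#' @param seed RNG seed fixing the entire bundle.
#' @param force overwrite an existing directory.
#' @return the truth list, invisibly; files on disk.
#' @export
emit_bundle <- function(config, outdir, seed = 1, force = FALSE) {
  if (dir.exists(outdir) && !force)
    stop("output directory exists (use force = TRUE): ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "genes"), showWarnings = FALSE)
  sim <- simulate_neutral(config, seed = seed)
  env_loc <- default_env()
  if (!is.null(config$sweeps)) {
    for (i in seq_len(nrow(config$sweeps))) {
      sw <- config$sweeps[i, ]
      sim <- inject_sweep(sim, sw$pop, sw$chrom, sw$center, sw$lambda)
    }
  }
  sim <- inject_gea(sim, env_loc, config$n_causal, config$beta)
  causal <- attr(sim, "causal")
  genes <- make_genes(config)
  # sample registry
  pops <- rep(names(config$pop_sizes), config$pop_sizes)
  ids <- unlist(lapply(names(config$pop_sizes), function(p)
    sprintf("%s%02d", p, seq_len(config$pop_sizes[[p]]))))
  samples <- c(ids, "OUT")
  pop_of <- c(setNames(pops, ids), OUT = "OUT")
  n_site <- nrow(sim$sites)
  # diploid genotypes from consecutive haplotype pairs
  a1 <- t(sim$haps[seq(1, length(sim$hap_pop), by = 2), , drop = FALSE])
  a2 <- t(sim$haps[seq(2, length(sim$hap_pop), by = 2), , drop = FALSE])
  ref <- sample(.BASES, n_site, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1), "")
  info <- data.frame(QD = runif(n_site, 15, 35),
                     FS = runif(n_site, 0, 10),
                     MQ = runif(n_site, 55, 60),
                     MQRankSum = rnorm(n_site),
                     ReadPosRankSum = rnorm(n_site))
  fail_rules <- character(0)
  fail_idx <- integer(0)
  if (config$fail_frac > 0) {
    fail_idx <- which(runif(n_site) < config$fail_frac)
    opts <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
    vals <- c(QD = 1, FS = 70, MQ = 30, MQRankSum = -13,
              ReadPosRankSum = -9)
    fail_rules <- sample(opts, length(fail_idx), replace = TRUE)
    for (q in seq_along(fail_idx))
      info[fail_idx[q], fail_rules[q]] <- vals[[fail_rules[q]]]
  }
  rec <- list(sites = cbind(data.frame(chrom = sim$sites$chrom,
                                       pos = sim$sites$pos,
                                       ref = ref, alt = alt), info),
              a1 = a1, a2 = a2,
              dp = matrix(rpois(n_site * length(samples), 40), n_site),
              samples = samples, pop_of = pop_of)
  class(rec) <- "vcf_records"
  ord <- order(factor(rec$sites$chrom, unique(sim$sites$chrom)),
               rec$sites$pos)
  rec$sites <- rec$sites[ord, ]; rec$a1 <- rec$a1[ord, , drop = FALSE]
  rec$a2 <- rec$a2[ord, , drop = FALSE]; rec$dp <- rec$dp[ord, , drop = FALSE]
  causal_ids <- paste0(rec$sites$chrom, ":", rec$sites$pos)[
    match(causal, ord)]
  write_vcf(rec, file.path(outdir, "variants.vcf"))
  .write_gff3(genes$gff, file.path(outdir, "genes.gff3"))
  write.table(data.frame(sample = samples, population = pop_of[samples]),
              file.path(outdir, "popmap.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  env <- merge(data.frame(sample = ids, population = pops), env_loc,
               by = "population", sort = FALSE)[
                 c("sample", "population", "MAT", "MAMT", "MAP")]
  env <- env[order(match(env$sample, ids)), ]
  write.table(env, file.path(outdir, "env.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (g in names(genes$alignments)) {
    al <- genes$alignments[[g]]
    con <- file(file.path(outdir, "genes", paste0(g, ".fasta")), "w")
    for (i in seq_along(al$ingroup))
      writeLines(c(paste0(">", g, "_hap", i), al$ingroup[i]), con)
    writeLines(c(paste0(">", g, "_outgroup"), al$outgroup), con)
    close(con)
  }
  truth <- list(
    seed = seed,
    sweeps = config$sweeps,
    causal_snps = causal_ids,
    selected_genes = genes$selected_genes,
    demographic_params = as.list(config$demography$defaults),
    failing_records = if (length(fail_idx) > 0)
      paste0(sim$sites$chrom[fail_idx], ":", sim$sites$pos[fail_idx])
    else character(),
    achieved_density = sim$achieved_density)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(truth)
}
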
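#' Read a population map
#'
#' Two-column tab-separated file, `sample<TAB>population`, no header.
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `population`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "population"),
                   colClasses = "character")
  if (anyDuplicated(pm$sample))
    stop("duplicated sample ids in population map")
  pm
}

#' Read a per-sample environment table
#'
#' Tab-separated with header `sample population MAT MAMT MAP`; values are the
#' sampling location's mean annual temperature (deg C), mean annual minimum
#' temperature (deg C) and mean annual precipitation (mm), repeated for every
#' sample from that location.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_env <- function(path) {
  env <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("sample", "population", "MAT", "MAMT", "MAP")
  if (!all(need %in% names(env)))
    stop("environment table must have columns: ", paste(need, collapse = " "))
  if (any(!complete.cases(env[need])))
    stop("environment table has incomplete rows")
  env
}

#' Default SNP hard-filter thresholds
#'
#' Genotypes with per-sample depth below `min_depth` are set missing; a site
#' is removed when its minor allele frequency (over non-missing genotypes,
#' minor allele regardless of ref/alt orientation) falls below `maf_min`, or
#' any variant-level annotation breaches its threshold: QD < `qd_min`,
#' FS > `fs_max`, MQ < `mq_min`, MQRankSum < `mqranksum_min`,
#' ReadPosRankSum < `readposranksum_min`. An absent annotation never fails a
#' site (rank-sum annotations are undefined for homozygous-only sites).
#'
#' @param min_depth minimum reads per individual genotype (default 3).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param qd_min,fs_max,mq_min,mqranksum_min,readposranksum_min GATK-style
#'   annotation thresholds.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 3, maf_min = 0.05, qd_min = 2.0,
                          fs_max = 60.0, mq_min = 40.0,
                          mqranksum_min = -12.5,
                          readposranksum_min = -8.0) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  structure(list(min_depth = min_depth, maf_min = maf_min, qd_min = qd_min,
                 fs_max = fs_max, mq_min = mq_min,
                 mqranksum_min = mqranksum_min,
                 readposranksum_min = readposranksum_min),
            class = "filter_config")
}

.info_fields <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

.parse_info <- function(info_strings) {
  out <- matrix(NA_real_, length(info_strings), length(.info_fields),
                dimnames = list(NULL, .info_fields))
  pieces <- strsplit(info_strings, ";", fixed = TRUE)
  for (i in seq_along(pieces)) {
    kv <- strsplit(pieces[[i]], "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) == 2 && p[1] %in% .info_fields)
        out[i, p[1]] <- suppressWarnings(as.numeric(p[2]))
    }
  }
  out
}

#' Read a multi-sample VCF into site records
#'
#' A plain-dialect VCF 4.2 reader (GT and DP per-sample fields; QD, FS, MQ,
#' MQRankSum, ReadPosRankSum INFO annotations). Multi-allelic and non-SNP
#' records are skipped and counted. Every VCF sample must appear in the
#' population map.
#'
#' @param path VCF path (uncompressed).
#' @param popmap data.frame from [read_popmap()] (or a path to one).
#' @return object of class `vcf_records`: a list with `sites` (data.frame of
#'   chrom, pos, ref, alt and annotation columns), allele matrices `a1`,`a2`
#'   (sites x samples, -1 = missing), depth matrix `dp`, `samples`, and
#'   `pop_of` (named character vector). Attribute `n_skipped` counts skipped
#'   records.
#' @export
read_vcf <- function(path, popmap) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  missing_pm <- setdiff(samples, popmap$sample)
  if (length(missing_pm) > 0)
    stop("VCF samples absent from population map: ",
         paste(missing_pm, collapse = ", "))
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n_skipped <- 0L
  if (length(body) == 0) {
    rec <- list(sites = data.frame(), a1 = matrix(0L, 0, length(samples)),
                a2 = matrix(0L, 0, length(samples)),
                dp = matrix(0L, 0, length(samples)), samples = samples,
                pop_of = setNames(popmap$population, popmap$sample)[samples])
    class(rec) <- "vcf_records"
    attr(rec, "n_skipped") <- n_skipped
    return(rec)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) stop("ragged VCF body")
  m <- matrix(unlist(fields), ncol = length(cols), byrow = TRUE)
  ref <- m[, 4]; alt <- m[, 5]
  keep <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  ref <- ref[keep]; alt <- alt[keep]
  chrom <- m[, 1]; pos <- as.integer(m[, 2])
  # ascending (chrom, pos) within each chromosome, chromosomes contiguous
  if (anyDuplicated(rle(chrom)$values)) stop("VCF not sorted: chromosomes interleaved")
  if (any(unlist(tapply(pos, factor(chrom, unique(chrom)), diff)) < 0))
    stop("VCF not sorted by position")
  info <- .parse_info(m[, 8])
  fmt <- strsplit(m[, 9], ":", fixed = TRUE)
  gt_i <- vapply(fmt, function(f) match("GT", f), 0L)
  dp_i <- vapply(fmt, function(f) match("DP", f), 0L)
  if (anyNA(gt_i)) stop("record without GT field")
  ns <- length(samples); nsite <- nrow(m)
  a1 <- a2 <- matrix(-1L, nsite, ns)
  dp <- matrix(NA_integer_, nsite, ns)
  for (j in seq_len(ns)) {
    cell <- strsplit(m[, 9 + j], ":", fixed = TRUE)
    gt <- unname(mapply(function(c, i) c[i], cell, gt_i))
    al <- regmatches(gt, regexec("^([0-9.])[/|]([0-9.])", gt))
    g1 <- vapply(al, function(x) if (length(x)) x[2] else ".", "")
    g2 <- vapply(al, function(x) if (length(x)) x[3] else ".", "")
    a1[, j] <- suppressWarnings(ifelse(g1 == ".", -1L, as.integer(g1)))
    a2[, j] <- suppressWarnings(ifelse(g2 == ".", -1L, as.integer(g2)))
    has_dp <- !is.na(dp_i)
    dpv <- rep(NA_character_, nsite)
    dpv[has_dp] <- mapply(function(c, i) c[i], cell[has_dp], dp_i[has_dp])
    dp[, j] <- suppressWarnings(as.integer(dpv))
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  sites <- cbind(sites, as.data.frame(info))
  rec <- list(sites = sites, a1 = a1, a2 = a2, dp = dp, samples = samples,
              pop_of = setNames(popmap$population, popmap$sample)[samples])
  class(rec) <- "vcf_records"
  attr(rec, "n_skipped") <- n_skipped
  rec
}

#' Write site records as VCF 4.2
#'
#' @param rec a `vcf_records` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
               "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
               "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
               "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rec$samples), collapse = "\t")), con)
  s <- rec$sites
  n <- nrow(s)
  if (n > 0) {
    fmt1 <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 6))
    info <- vapply(seq_len(n), function(i) {
      v <- c(QD = fmt1(s$QD[i]), FS = fmt1(s$FS[i]), MQ = fmt1(s$MQ[i]),
             MQRankSum = fmt1(s$MQRankSum[i]),
             ReadPosRankSum = fmt1(s$ReadPosRankSum[i]))
      v <- v[!is.na(v)]
      if (length(v) == 0) "." else paste(names(v), v, sep = "=", collapse = ";")
    }, "")
    gt <- matrix("", n, length(rec$samples))
    for (j in seq_along(rec$samples)) {
      g <- ifelse(rec$a1[, j] < 0, ".", as.character(rec$a1[, j]))
      h <- ifelse(rec$a2[, j] < 0, ".", as.character(rec$a2[, j]))
      d <- ifelse(is.na(rec$dp[, j]), ".", as.character(rec$dp[, j]))
      gt[, j] <- paste0(g, "/", h, ":", d)
    }
    writeLines(paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info,
                     "GT:DP", apply(gt, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

.minor_af <- function(a1, a2) {
  # per-site minor allele frequency over non-missing haplotypes
  nh <- rowSums(a1 >= 0) + rowSums(a2 >= 0)
  alt <- rowSums(a1 == 1) + rowSums(a2 == 1)
  p <- ifelse(nh > 0, alt / nh, NA_real_)
  pmin(p, 1 - p)
}

#' Apply SNP hard filters
#'
#' Masks genotypes below the per-sample depth threshold, then removes sites
#' by annotation and minor-allele-frequency rules (see [filter_config()]).
#' Each removed site is counted once, under the first failing rule in the
#' order qd, fs, mq, mqranksum, readposranksum, all_missing, maf.
#'
#' @param rec a `vcf_records` object.
#' @param cfg a [filter_config()].
#' @return filtered `vcf_records`; attribute `removed` holds per-rule counts.
#' @export
hard_filter <- function(rec, cfg = filter_config()) {
  s <- rec$sites
  n <- nrow(s)
  a1 <- rec$a1; a2 <- rec$a2
  low <- !is.na(rec$dp) & rec$dp < cfg$min_depth
  a1[low] <- -1L; a2[low] <- -1L
  fail <- function(x, thr, dir) !is.na(x) & (if (dir == "<") x < thr else x > thr)
  rules <- list(
    qd = fail(s$QD, cfg$qd_min, "<"),
    fs = fail(s$FS, cfg$fs_max, ">"),
    mq = fail(s$MQ, cfg$mq_min, "<"),
    mqranksum = fail(s$MQRankSum, cfg$mqranksum_min, "<"),
    readposranksum = fail(s$ReadPosRankSum, cfg$readposranksum_min, "<"),
    all_missing = rowSums(a1 >= 0) == 0,
    maf = { maf <- .minor_af(a1, a2); is.na(maf) | maf < cfg$maf_min })
  hit <- rep(NA_character_, n)
  for (r in names(rules)) hit[is.na(hit) & rules[[r]]] <- r
  removed <- vapply(names(rules), function(r) sum(hit == r, na.rm = TRUE), 0L)
  keep <- is.na(hit)
  out <- list(sites = s[keep, , drop = FALSE],
              a1 = a1[keep, , drop = FALSE], a2 = a2[keep, , drop = FALSE],
              dp = rec$dp[keep, , drop = FALSE], samples = rec$samples,
              pop_of = rec$pop_of)
  rownames(out$sites) <- NULL
  class(out) <- "vcf_records"
  attr(out, "removed") <- as.list(removed)
  out
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path.
#' @return data.frame with columns seqid, type, start, end, strand, id,
#'   parent (1-based inclusive coordinates, as on disk).
#' @export
read_gff3 <- function(path) {
  g <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  quote = "", stringsAsFactors = FALSE,
                  col.names = c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "attributes"))
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x)) x[3] else NA_character_, "")
  }
  g$id <- get_attr(g$attributes, "ID")
  g$parent <- get_attr(g$attributes, "Parent")
  g[c("seqid", "type", "start", "end", "strand", "id", "parent")]
}

#' Classify sites into genomic feature classes
#'
#' Precedence when annotations overlap: exon (CDS) > UTR > intron (gene body
#' outside exons) > promoter (within 2 kb upstream of a transcription start
#' site, strand-respecting, outside all gene bodies) > intergenic. Sites on
#' chromosomes absent from the annotation are intergenic (with a warning).
#'
#' @param sites data.frame with `chrom` and 1-based `pos`.
#' @param genes data.frame from [read_gff3()].
#' @param promoter_bp promoter window upstream of the TSS (default 2000).
#' @return factor with levels exon, utr, intron, promoter, intergenic.
#' @export
classify_sites <- function(sites, genes, promoter_bp = 2000L) {
  lv <- c("exon", "utr", "intron", "promoter", "intergenic")
  out <- factor(rep("intergenic", nrow(sites)), levels = lv)
  gene_rows <- genes[genes$type == "gene", , drop = FALSE]
  cds <- genes[genes$type == "CDS", , drop = FALSE]
  utr <- genes[genes$type %in% c("five_prime_UTR", "three_prime_UTR", "UTR"),
               , drop = FALSE]
  absent <- setdiff(unique(sites$chrom), unique(genes$seqid))
  if (length(absent) > 0)
    warning("chromosomes absent from annotation: ",
            paste(absent, collapse = ", "))
  # promoter windows: [TSS - 2000, TSS) on +, (TES, TES + 2000] on - strand
  prom_start <- ifelse(gene_rows$strand == "+",
                       gene_rows$start - promoter_bp, gene_rows$end + 1L)
  prom_end <- ifelse(gene_rows$strand == "+",
                     gene_rows$start - 1L, gene_rows$end + promoter_bp)
  in_any <- function(pos, chr, feat_chr, feat_s, feat_e) {
    hit <- logical(length(pos))
    for (cc in unique(chr)) {
      i <- which(chr == cc)
      j <- which(feat_chr == cc)
      if (length(j) == 0) next
      for (k in j) hit[i] <- hit[i] | (pos[i] >= feat_s[k] & pos[i] <= feat_e[k])
    }
    hit
  }
  p <- sites$pos; ch <- sites$chrom
  in_gene <- in_any(p, ch, gene_rows$seqid, gene_rows$start, gene_rows$end)
  in_cds <- in_any(p, ch, cds$seqid, cds$start, cds$end)
  in_utr <- in_any(p, ch, utr$seqid, utr$start, utr$end)
  in_prom <- in_any(p, ch, gene_rows$seqid, prom_start, prom_end) & !in_gene
  out[in_prom] <- "promoter"
  out[in_gene] <- "intron"
  out[in_utr] <- "utr"
  out[in_cds] <- "exon"
  out
}

#' Encode genotypes as 0/1/2 codes
#'
#' 0 for reference homozygotes, 1 for heterozygotes, 2 for alternate
#' homozygotes, -1 for missing; column order preserves genomic order.
#'
#' @param rec a (filtered) `vcf_records` object.
#' @param feature_class optional factor from [classify_sites()].
#' @return object of class `genotype_matrix`: list with `codes` (n_samples x
#'   n_sites integer matrix), `samples`, `pop_of`, `sites`.
#' @export
encode_genotypes <- function(rec, feature_class = NULL) {
  codes <- t(ifelse(rec$a1 < 0 | rec$a2 < 0, -1L, rec$a1 + rec$a2))
  rownames(codes) <- rec$samples
  sites <- rec$sites[c("chrom", "pos", "ref", "alt")]
  rownames(sites) <- NULL
  if (!is.null(feature_class)) sites$feature_class <- feature_class
  gm <- list(codes = codes, samples = rec$samples, pop_of = rec$pop_of,
             sites = sites)
  class(gm) <- "genotype_matrix"
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "samples x", ncol(x$codes),
      "sites\n")
  cat("populations:",
      paste(names(table(x$pop_of)), table(x$pop_of), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# haploid alt-allele counts and non-missing haplotype counts per site for
# one population (or all samples when pop is NULL)
.pop_counts <- function(gm, pop = NULL) {
  idx <- if (is.null(pop)) seq_along(gm$samples) else
    which(gm$pop_of[gm$samples] == pop)
  if (length(idx) == 0) stop("unknown or empty population: ", pop)
  sub <- gm$codes[idx, , drop = FALSE]
  ok <- sub >= 0
  list(alt = colSums(sub * ok), nh = 2L * colSums(ok), n_dip = length(idx))
}

#' Per-site alternate-allele frequency within a population
#'
#' @param gm a `genotype_matrix`.
#' @param pop population label (NULL = all samples).
#' @return numeric vector (NaN where no genotyped haplotype).
#' @export
alt_freq <- function(gm, pop = NULL) {
  ct <- .pop_counts(gm, pop)
  ct$alt / ct$nh
}
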
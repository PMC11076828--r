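# Shared fixtures: tiny genotype matrices, handwritten VCF/GFF text, and
# reference demographic models used across test files.

toy_gm <- function(codes, pops, chrom = "chr1", pos = NULL, aa = NULL) {
  n <- nrow(codes); m <- ncol(codes)
  samples <- sprintf("s%02d", seq_len(n))
  rownames(codes) <- samples
  if (is.null(pos)) pos <- seq_len(m) * 100L
  sites <- data.frame(chrom = rep(chrom, length.out = m), pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  if (!is.null(aa)) sites$aa <- aa
  gm <- list(codes = codes, samples = samples,
             pop_of = stats::setNames(pops, samples), sites = sites)
  class(gm) <- "genotype_matrix"
  gm
}

write_test_vcf <- function(path, body_lines,
                           samples = c("s1", "s2", "s3")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               body_lines), path)
  path
}

toy_popmap <- function(samples = c("s1", "s2", "s3"),
                       pops = NULL) {
  if (is.null(pops))
    pops <- rep(c("A", "A", "B"), length.out = length(samples))
  data.frame(sample = samples, population = pops,
             stringsAsFactors = FALSE)
}

# three-gene annotation used by the feature-class tests:
#   geneA chr1 + [10001, 12000], CDS [10001,10500]+[11001,11400],
#     UTRs [10501,10700] (5') and [11401,11600] (3'), intron elsewhere
#   geneB chr1 - [30001, 31000], all CDS
#   geneC chr2 + [5001, 6000], all CDS
toy_gff <- function(path) {
  rows <- c(
    "chr1\ttoy\tgene\t10001\t12000\t.\t+\t.\tID=geneA",
    "chr1\ttoy\tCDS\t10001\t10500\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttoy\tfive_prime_UTR\t10501\t10700\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttoy\tCDS\t11001\t11400\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttoy\tthree_prime_UTR\t11401\t11600\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttoy\tgene\t30001\t31000\t.\t-\t.\tID=geneB",
    "chr1\ttoy\tCDS\t30001\t31000\t.\t-\t.\tParent=geneB.t1",
    "chr2\ttoy\tgene\t5001\t6000\t.\t+\t.\tID=geneC",
    "chr2\ttoy\tCDS\t5001\t6000\t.\t+\t.\tParent=geneC.t1")
  writeLines(c("##gff-version 3", rows), path)
  path
}

# single constant-size population
const_model <- function(N = 1000) {
  demographic_model("const1", "A", "N", c(N = 10), c(N = 1e6),
                    c(N = "log"),
                    build = function(p)
                      list(sizes0 = p[["N"]], growth0 = 0,
                           mig = matrix(0, 1, 1),
                           events = locadapt:::.no_events()),
                    defaults = c(N = N))
}

# two-population clean split, ancestral size fixed at 10000
split2_model <- function(defaults = c(N1 = 10000, N2 = 10000, T = 8000)) {
  demographic_model("split2", c("A", "B"), c("N1", "N2", "T"),
    c(N1 = 100, N2 = 100, T = 100),
    c(N1 = 1e5, N2 = 1e5, T = 3e4),
    c(N1 = "log", N2 = "log", T = "log"),
    build = function(p)
      list(sizes0 = c(p[["N1"]], p[["N2"]]), growth0 = c(0, 0),
           mig = matrix(0, 2, 2),
           events = rbind(locadapt:::.event(p[["T"]], 0, 1, 0),
                          locadapt:::.event(p[["T"]], 1, 0,
                                            size = 10000))),
    defaults = defaults)
}

# symmetric three-deme island model (exchangeable null for scans)
island_model <- function(N = 10000, m = 5e-5) {
  demographic_model("island3", c("F", "S", "W"), c("N", "m"),
    c(N = 100, m = 1e-8), c(N = 1e6, m = 0.5),
    c(N = "log", m = "log"),
    build = function(p) {
      M <- matrix(p[["m"]], 3, 3); diag(M) <- 0
      list(sizes0 = rep(p[["N"]], 3), growth0 = rep(0, 3), mig = M,
           events = locadapt:::.no_events())
    },
    defaults = c(N = N, m = m))
}

# independently coded per-site Weir & Cockerham (1984) estimator: literal
# textbook formulas, scalar loops, no shared code with the package
wc_fst_oracle_site <- function(gtA, gtB) {
  gtA <- gtA[gtA >= 0]; gtB <- gtB[gtB >= 0]
  n1 <- length(gtA); n2 <- length(gtB)
  if (n1 < 1 || n2 < 1) return(c(a = NA, b = NA, c = NA))
  p1 <- sum(gtA) / (2 * n1); p2 <- sum(gtB) / (2 * n2)
  h1 <- mean(gtA == 1); h2 <- mean(gtB == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) * s2 / r -
                                (2 * nbar - 1) * hbar / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# read a generated bundle into an analysis-ready genotype matrix
load_bundle_gm <- function(dir) {
  pm <- read_popmap(file.path(dir, "popmap.tsv"))
  rec <- hard_filter(read_vcf(file.path(dir, "variants.vcf"), pm))
  gm <- encode_genotypes(rec)
  gm$sites$aa <- gm$sites$ref
  panel <- which(gm$pop_of[gm$samples] != "OUT")
  gm$codes <- gm$codes[panel, , drop = FALSE]
  gm$samples <- gm$samples[panel]
  gm
}
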
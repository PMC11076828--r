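# McDonald-Kreitman test: per-gene Dn/Ds/Pn/Ps counting from in-frame codon
# alignments, one-sided Fisher exact (or Williams-corrected G) test, BH
# correction.

# standard genetic code, bases in TCAG order
.codon_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    aas <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                           "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
    b <- c("T", "C", "A", "G")
    codons <- character(64); k <- 0
    for (b1 in b) for (b2 in b) for (b3 in b) {
      k <- k + 1; codons[k] <- paste0(b1, b2, b3)
    }
    tab <<- setNames(aas, codons)
    tab
  }
})

.translate_codon <- function(codon) {
  .codon_table()[[codon]]
}

# all orderings of single-nucleotide steps between two codons; returns
# average nonsynonymous / synonymous step counts (memoized: only 64 x 64
# codon pairs exist)
.path_memo <- new.env(parent = emptyenv())

.path_counts <- function(from, to) {
  key <- paste0(from, to)
  hit <- .path_memo[[key]]
  if (!is.null(hit)) return(hit)
  res <- .path_counts_raw(from, to)
  .path_memo[[key]] <- res
  res
}

.path_counts_raw <- function(from, to) {
  pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(n = 0, s = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  orders <- perms(pos)
  tot_n <- 0; tot_s <- 0
  f_chars <- strsplit(from, "")[[1]]
  t_chars <- strsplit(to, "")[[1]]
  for (ord in orders) {
    cur <- f_chars
    for (p in ord) {
      nxt <- cur
      nxt[p] <- t_chars[p]
      if (.translate_codon(paste(cur, collapse = "")) ==
          .translate_codon(paste(nxt, collapse = "")))
        tot_s <- tot_s + 1 else tot_n <- tot_n + 1
      cur <- nxt
    }
  }
  c(n = tot_n / length(orders), s = tot_s / length(orders))
}

#' Per-gene McDonald-Kreitman counts
#'
#' A site is a FIXED difference (D) when all ingroup haplotypes share one
#' allele and the outgroup differs, and a POLYMORPHISM (P) when two or more
#' alleles segregate in the ingroup (regardless of the outgroup state; a
#' polymorphic site is never counted in D). Changes are classified
#' synonymous/nonsynonymous against the standard genetic code in codon
#' context; codons with multiple differences are resolved by averaging over
#' all orderings of single-nucleotide steps, contributing fractional counts.
#' Codons containing gaps or ambiguous bases in any sequence are excluded
#' and tallied.
#'
#' @param ingroup character vector of in-frame CDS haplotype sequences
#'   (equal length, divisible by 3).
#' @param outgroup single outgroup CDS of the same length.
#' @return list with Dn, Ds, Pn, Ps (possibly fractional) and
#'   `n_excluded_codons`.
#' @export
count_mk <- function(ingroup, outgroup) {
  L <- unique(c(nchar(ingroup), nchar(outgroup)))
  if (length(L) != 1 || L %% 3 != 0)
    stop("sequences must share a length divisible by 3")
  inm <- do.call(rbind, strsplit(toupper(ingroup), ""))
  og <- strsplit(toupper(outgroup), "")[[1]]
  # per-site allele counts across the ingroup (vectorized over sites)
  ok_base <- c("A", "C", "G", "T")
  cnt <- vapply(ok_base, function(b) colSums(inm == b),
                numeric(ncol(inm)))
  major <- ok_base[max.col(cnt, ties.method = "first")]
  poly <- rowSums(cnt > 0) > 1
  bad_site <- rowSums(cnt) < nrow(inm) | !(og %in% ok_base)
  codon_of <- rep(seq_len(L / 3), each = 3)
  bad_codon <- tapply(bad_site, codon_of, any)
  excl <- sum(bad_codon)
  usable <- !bad_codon[codon_of]
  major_codon <- vapply(split(major, codon_of), paste, collapse = "", "")
  Dn <- Ds <- Pn <- Ps <- 0
  # polymorphisms: per segregating position, each non-major allele is one
  # polymorphism classified on the major-codon background
  for (p in which(poly & usable)) {
    ci <- codon_of[p]
    within <- (p - 1) %% 3 + 1
    for (al in ok_base[cnt[p, ] > 0 & ok_base != major[p]]) {
      alt_codon <- strsplit(major_codon[ci], "")[[1]]
      alt_codon[within] <- al
      pc <- .path_counts(major_codon[ci], paste(alt_codon, collapse = ""))
      Pn <- Pn + pc[["n"]]; Ps <- Ps + pc[["s"]]
    }
  }
  # fixed differences: positions monomorphic in the ingroup and differing
  # from the outgroup; pathway-average within the codon
  fixed_diff <- !poly & major != og & usable
  for (ci in unique(codon_of[fixed_diff])) {
    cols <- which(codon_of == ci)
    to <- major[cols]
    sel <- fixed_diff[cols]
    to[sel] <- og[cols][sel]
    pc <- .path_counts(major_codon[ci], paste(to, collapse = ""))
    Dn <- Dn + pc[["n"]]; Ds <- Ds + pc[["s"]]
  }
  list(Dn = unname(Dn), Ds = unname(Ds), Pn = unname(Pn), Ps = unname(Ps),
       n_excluded_codons = excl)
}

#' One-sided MK Fisher exact test
#'
#' Hypergeometric tail probability of the 2x2 table `[[Dn, Ds], [Pn, Ps]]`
#' in the direction of excess nonsynonymous divergence (Dn/Ds > Pn/Ps).
#' Fractional pathway counts are rounded half-up at the test stage. Genes
#' with Dn + Ds = 0 or Pn + Ps = 0, and tables showing no excess in the
#' tested direction (Dn Ps <= Ds Pn), return p = 1: the test direction is
#' one-sided toward positive selection.
#'
#' @param counts list with Dn, Ds, Pn, Ps.
#' @return one-sided p-value.
#' @export
mk_fisher <- function(counts) {
  m <- matrix(floor(c(counts$Dn, counts$Pn, counts$Ds, counts$Ps) + 0.5),
              nrow = 2)
  if (any(m < 0)) stop("negative count")
  if (sum(m[, 1]) + sum(m[, 2]) == 0) return(1)
  if (m[1, 1] + m[1, 2] == 0 || m[2, 1] + m[2, 2] == 0) return(1)
  if (m[1, 1] * m[2, 2] <= m[1, 2] * m[2, 1]) return(1)
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Williams-corrected G test on the MK table
#'
#' @param counts list with Dn, Ds, Pn, Ps.
#' @return two-sided p-value (chi-square with 1 df on corrected G).
#' @export
mk_gtest <- function(counts) {
  m <- matrix(floor(c(counts$Dn, counts$Pn, counts$Ds, counts$Ps) + 0.5),
              nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  g <- 2 * sum(ifelse(m > 0, m * log(m / e), 0))
  # Williams correction for a 2x2 table
  q <- 1 + (n / rowSums(m)[1] + n / rowSums(m)[2] - 1) *
    (n / colSums(m)[1] + n / colSums(m)[2] - 1) / (6 * n)
  stats::pchisq(g / unname(q), df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH: q_(i) = min over j >= i of m p_(j) / j, capped at 1, mapped
#' back to input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  stats::p.adjust(pvalues, method = "BH")
}

#' Read per-gene codon alignments from FASTA files
#'
#' Each file holds one gene: ingroup haplotype CDS sequences plus one
#' outgroup CDS whose header contains "outgroup".
#'
#' @param paths FASTA file paths (or a directory of `*.fasta`).
#' @return named list of `list(ingroup =, outgroup =)` keyed by gene id
#'   (file basename without extension).
#' @export
read_codon_alignments <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.fasta$", full.names = TRUE)
  out <- list()
  for (p in paths) {
    lines <- readLines(p)
    idx <- grep("^>", lines)
    headers <- sub("^>", "", lines[idx])
    seqs <- vapply(seq_along(idx), function(i) {
      from <- idx[i] + 1
      to <- if (i < length(idx)) idx[i + 1] - 1 else length(lines)
      paste(lines[from:to], collapse = "")
    }, "")
    og <- grepl("outgroup", headers)
    if (sum(og) != 1) stop("expected exactly one outgroup sequence in ", p)
    gene <- sub("\\.fasta$", "", basename(p))
    out[[gene]] <- list(ingroup = seqs[!og], outgroup = seqs[og])
  }
  out
}

#' Run the MK test over a set of genes
#'
#' @param genes named list from [read_codon_alignments()] (or equivalent).
#' @param test "fisher" (default, one-sided) or "g" (Williams-corrected).
#' @return data.frame `gene Dn Ds Pn Ps p q direction` where `direction` is
#'   TRUE for excess nonsynonymous divergence (Dn Ps > Ds Pn on raw counts).
#' @export
mk_test_genes <- function(genes, test = c("fisher", "g")) {
  test <- match.arg(test)
  rows <- lapply(names(genes), function(g) {
    ct <- count_mk(genes[[g]]$ingroup, genes[[g]]$outgroup)
    p <- if (test == "fisher") mk_fisher(ct) else mk_gtest(ct)
    data.frame(gene = g, Dn = ct$Dn, Ds = ct$Ds, Pn = ct$Pn, Ps = ct$Ps,
               p = p,
               direction = ct$Dn * ct$Ps > ct$Ds * ct$Pn)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[c("gene", "Dn", "Ds", "Pn", "Ps", "p", "q", "direction")]
}

#' Positively selected genes from MK results
#'
#' @param mk data.frame from [mk_test_genes()].
#' @param q_cutoff adjusted-p cutoff (default 0.05).
#' @return character vector of gene ids with q below cutoff and excess
#'   nonsynonymous divergence.
#' @export
positive_selection_genes <- function(mk, q_cutoff = 0.05) {
  mk$gene[mk$q < q_cutoff & mk$direction]
}
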
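# Sliding-window FST and XP-CLR scans, outlier calling, HDR intersection,
# and Fay & Wu's H.

.slide_windows <- function(sites, size, step, chrom_lengths = NULL) {
  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(sites$pos, factor(sites$chrom, chroms), max)
  out <- lapply(chroms, function(cc) {
    len <- as.integer(chrom_lengths[[cc]])
    starts <- seq(0L, max(0L, len - 1L), by = step)
    data.frame(chrom = cc, start = starts, end = pmin(starts + size, len))
  })
  w <- do.call(rbind, out)
  w$id <- seq_len(nrow(w))
  w
}

# site membership lists for overlapping sliding windows
.window_members <- function(sites, win) {
  lapply(seq_len(nrow(win)), function(i) {
    which(sites$chrom == win$chrom[i] & sites$pos - 1L >= win$start[i] &
            sites$pos - 1L < win$end[i])
  })
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Returns a matrix with columns a, b, c; rows NA where undefined.
.wc_components <- function(gm, popA, popB) {
  comp_pop <- function(pop) {
    idx <- which(gm$pop_of[gm$samples] == pop)
    sub <- gm$codes[idx, , drop = FALSE]
    ok <- sub >= 0
    n <- colSums(ok)
    p <- ifelse(n > 0, colSums(sub * ok) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums((sub == 1) & ok) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- comp_pop(popA); B <- comp_pop(popB)
  r <- 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- A$n < 1 | B$n < 1 | nbar <= 1 | !is.finite(a)
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  cbind(a = a, b = b, c = cc)
}

#' Sliding-window Weir-Cockerham FST
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) are combined per window as
#' the ratio of sums, FST = sum(a) / sum(a + b + c), over sites with defined
#' components; negative per-site components are not clamped. Windows with no
#' usable site are NaN.
#'
#' @param gm a `genotype_matrix`.
#' @param popA,popB population labels (each >= 2 diploids).
#' @param size,step window size and step in bp (defaults 20000 / 5000).
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame `chrom start end id n_snps fst`.
#' @export
wc_fst_windows <- function(gm, popA, popB, size = 20000L, step = 5000L,
                           chrom_lengths = NULL) {
  for (p in c(popA, popB))
    if (sum(gm$pop_of[gm$samples] == p) < 2)
      stop("population ", p, " has fewer than 2 diploids")
  comp <- .wc_components(gm, popA, popB)
  win <- .slide_windows(gm$sites, size, step, chrom_lengths)
  mem <- .window_members(gm$sites, win)
  win$n_snps <- vapply(mem, function(i) sum(!is.na(comp[i, 1])), 0L)
  win$fst <- vapply(mem, function(i) {
    i <- i[!is.na(comp[i, 1])]
    if (length(i) == 0) return(NaN)
    denom <- sum(comp[i, ])
    if (denom == 0) return(NaN)
    sum(comp[i, 1]) / denom
  }, 0)
  win
}

#' Genome-wide mean Weir-Cockerham FST
#'
#' Ratio-of-sums estimator over all sites with defined components.
#'
#' @inheritParams wc_fst_windows
#' @return scalar FST.
#' @export
wc_fst_global <- function(gm, popA, popB) {
  comp <- .wc_components(gm, popA, popB)
  comp <- comp[!is.na(comp[, 1]), , drop = FALSE]
  sum(comp[, 1]) / sum(comp)
}

# per-site composite likelihood of observed object-population counts under
# the truncated-normal drift model, optionally distorted by a sweep with
# escape probability c (c = 1 is neutral).
.xpclr_site_cl <- function(p1, k2, n2, cvec, omega, n_u = 48L) {
  sig2 <- omega * p1 * (1 - p1)
  if (sig2 <= 0) {
    # degenerate drift variance: all pre-sweep mass sits at p1
    u <- p1
    w <- 1
  } else {
    u <- seq(0, 1, length.out = n_u)
    dens <- stats::dnorm(u, p1, sqrt(sig2))
    du <- u[2] - u[1]
    w <- dens * du
    w[1] <- w[1] + stats::pnorm(0, p1, sqrt(sig2))
    w[n_u] <- w[n_u] + stats::pnorm(1, p1, sqrt(sig2), lower.tail = FALSE)
    w <- w / sum(w)
  }
  vapply(cvec, function(cc) {
    if (cc >= 1) {
      sum(w * stats::dbinom(k2, n2, u))
    } else {
      v1 <- 1 - cc + cc * u
      v0 <- cc * u
      sum(w * u * stats::dbinom(k2, n2, v1)) +
        sum(w * (1 - u) * stats::dbinom(k2, n2, v0))
    }
  }, 0)
}

#' Sliding-window XP-CLR scan
#'
#' Cross-population composite-likelihood-ratio sweep test (Chen, Patterson &
#' Reich 2010 model). The drift variance omega is estimated genome-wide from
#' the mean of (p_obj - p_ref)^2 / (p_ref (1 - p_ref)) over sites
#' polymorphic in the reference population. Per window and per selection
#' coefficient s on a log grid, each site at genetic distance d from the
#' window centre escapes the sweep with probability c = 1 - exp(-d / s); the
#' neutral truncated-normal frequency-change density is distorted
#' accordingly and observed allele counts enter through binomial sampling.
#' CLR = 2 (max_s log CL(s) - log CL(neutral)); `xpclr_norm` is the
#' genome-standardized z-score of CLR over all finite windows. Within each
#' window, SNPs in strong linkage disequilibrium in the reference
#' population are downweighted: each site's log-likelihood contribution is
#' divided by the number of window sites whose genotype-dosage r-squared
#' with it reaches `ld_cut`, so a block of perfectly linked sites counts as
#' one.
#'
#' @param gm a `genotype_matrix`.
#' @param ref_pop,obj_pop reference and object population labels.
#' @param size,step window size and step in bp.
#' @param s_grid selection grid (default `10^seq(-5, -0.5, length 30)`).
#' @param rec_rate recombination rate in Morgans per bp (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @param max_snps per-window SNP cap; sites are downsampled evenly.
#' @param min_snps windows with fewer usable sites are NaN (default 2).
#' @param ld_cut reference-population r-squared threshold for the LD
#'   downweighting (default 0.95; NA disables).
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame `chrom start end id n_snps xpclr xpclr_norm`.
#' @export
xpclr_windows <- function(gm, ref_pop, obj_pop, size = 20000L, step = 5000L,
                          s_grid = 10^seq(-5, -0.5, length.out = 30),
                          rec_rate = 1e-8, max_snps = 200L, min_snps = 2L,
                          ld_cut = 0.95, chrom_lengths = NULL) {
  cr <- .pop_counts(gm, ref_pop)
  co <- .pop_counts(gm, obj_pop)
  p1 <- cr$alt / cr$nh
  p2 <- co$alt / co$nh
  usable <- !is.na(p1) & !is.na(p2) & p1 > 0 & p1 < 1 & co$nh > 0
  omega <- mean((p2[usable] - p1[usable])^2 /
                  (p1[usable] * (1 - p1[usable])))
  win <- .slide_windows(gm$sites, size, step, chrom_lengths)
  mem <- .window_members(gm$sites, win)
  ref_idx <- which(gm$pop_of[gm$samples] == ref_pop)
  ref_codes <- gm$codes[ref_idx, , drop = FALSE]
  ref_codes[ref_codes < 0] <- NA
  clr <- rep(NaN, nrow(win))
  nsnp <- integer(nrow(win))
  for (i in seq_len(nrow(win))) {
    idx <- mem[[i]][usable[mem[[i]]]]
    if (length(idx) > max_snps)
      idx <- idx[round(seq(1, length(idx), length.out = max_snps))]
    nsnp[i] <- length(idx)
    if (length(idx) < min_snps) next
    w <- rep(1, length(idx))
    if (!is.na(ld_cut) && length(idx) > 1) {
      r2 <- suppressWarnings(
        stats::cor(ref_codes[, idx, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 1
      w <- 1 / rowSums(r2 >= ld_cut)
    }
    centre <- (win$start[i] + win$end[i]) / 2
    d <- abs(gm$sites$pos[idx] - centre) * rec_rate
    lls <- matrix(0, length(idx), length(s_grid) + 1L)
    for (q in seq_along(idx)) {
      s_i <- idx[q]
      cvec <- c(1, 1 - exp(-d[q] / s_grid))
      cl <- .xpclr_site_cl(p1[s_i], co$alt[s_i], co$nh[s_i], cvec, omega)
      lls[q, ] <- log(pmax(cl, 1e-300))
    }
    tot <- colSums(lls * w)
    clr[i] <- 2 * (max(tot) - tot[1])
  }
  win$n_snps <- nsnp
  win$xpclr <- clr
  mu <- mean(clr[is.finite(clr)]); sdev <- stats::sd(clr[is.finite(clr)])
  win$xpclr_norm <- (clr - mu) / sdev
  win
}

#' Flag z-score outliers
#'
#' Mean and SD are computed over finite values only; NaN is never an
#' outlier; a constant vector yields no outliers.
#'
#' @param values numeric vector.
#' @param side "upper" (value >= mean + z SD) or "two" (|value - mean| >=
#'   z SD).
#' @param z cutoff in standard deviations (default 1.96).
#' @return logical mask.
#' @export
call_outliers <- function(values, side = c("upper", "two"), z = 1.96) {
  side <- match.arg(side)
  fin <- is.finite(values)
  if (sum(fin) < 2) return(rep(FALSE, length(values)))
  mu <- mean(values[fin]); sdev <- stats::sd(values[fin])
  if (sdev == 0) return(rep(FALSE, length(values)))
  out <- if (side == "upper") values >= mu + z * sdev else
    abs(values - mu) >= z * sdev
  out & fin
}

#' Intersect FST and XP-CLR outlier windows into HDRs
#'
#' Windows that are upper-tail outliers for BOTH statistics are merged into
#' maximal highly differentiated regions; book-ended (boundary-sharing)
#' intervals merge.
#'
#' @param fst_win output of [wc_fst_windows()].
#' @param xpclr_win output of [xpclr_windows()] on the same grid.
#' @param z outlier cutoff in SD (default 1.96).
#' @param sites optional site table; contained SNP indices are attached.
#' @return data.frame `chrom start end n_windows` with list columns
#'   `member_windows` and (if `sites` given) `snps`; attribute `outlier_both`
#'   holds the joint-outlier window ids.
#' @export
intersect_hdrs <- function(fst_win, xpclr_win, z = 1.96, sites = NULL) {
  if (nrow(fst_win) != nrow(xpclr_win) ||
      any(fst_win$chrom != xpclr_win$chrom) ||
      any(fst_win$start != xpclr_win$start))
    stop("FST and XP-CLR scans are on different window grids")
  both <- call_outliers(fst_win$fst, "upper", z) &
    call_outliers(xpclr_win$xpclr_norm, "upper", z)
  hd <- fst_win[both, c("chrom", "start", "end", "id")]
  if (nrow(hd) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer())
    out$member_windows <- list()
    attr(out, "outlier_both") <- integer()
    return(out)
  }
  hd <- hd[order(hd$chrom, hd$start), ]
  merged <- list()
  cur <- hd[1, ]
  members <- list(cur$id)
  flushm <- function(cur, ids) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_windows = length(ids))
  }
  res <- NULL; resm <- list()
  for (i in seq_len(nrow(hd))[-1]) {
    if (hd$chrom[i] == cur$chrom && hd$start[i] <= cur$end) {
      cur$end <- max(cur$end, hd$end[i])
      members[[length(members) + 1]] <- hd$id[i]
    } else {
      res <- rbind(res, flushm(cur, members))
      resm[[length(resm) + 1]] <- unlist(members)
      cur <- hd[i, ]; members <- list(cur$id)
    }
  }
  res <- rbind(res, flushm(cur, members))
  resm[[length(resm) + 1]] <- unlist(members)
  res$member_windows <- resm
  if (!is.null(sites)) {
    res$snps <- lapply(seq_len(nrow(res)), function(i)
      which(sites$chrom == res$chrom[i] & sites$pos - 1L >= res$start[i] &
              sites$pos - 1L < res$end[i]))
  }
  attr(res, "outlier_both") <- fst_win$id[both]
  res
}

#' Sliding-window Fay and Wu's H
#'
#' Per window over polarized segregating sites with derived count i in n
#' non-missing haplotypes: theta_pi = sum 2 i (n - i) / (n (n - 1)),
#' theta_H = sum 2 i^2 / (n (n - 1)); H = theta_pi - theta_H (unnormalized
#' original statistic). Windows without polarized segregating sites are NaN.
#'
#' @param gm a `genotype_matrix` (sites polarized via `sites$aa` or
#'   ref-as-ancestral).
#' @param pop population label.
#' @param size,step window size and step in bp.
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame `chrom start end id n_snps theta_pi theta_H H`.
#' @export
fay_wu_h_windows <- function(gm, pop, size = 20000L, step = 5000L,
                             chrom_lengths = NULL) {
  dc <- .derived_counts(gm, pop, polarized = TRUE)
  seg <- dc$keep & dc$j > 0 & dc$j < dc$nh & dc$nh >= 2
  tp <- ifelse(seg, 2 * dc$j * (dc$nh - dc$j) / (dc$nh * (dc$nh - 1)), 0)
  th <- ifelse(seg, 2 * dc$j^2 / (dc$nh * (dc$nh - 1)), 0)
  win <- .slide_windows(gm$sites, size, step, chrom_lengths)
  mem <- .window_members(gm$sites, win)
  win$n_snps <- vapply(mem, function(i) sum(seg[i]), 0L)
  win$theta_pi <- vapply(mem, function(i) sum(tp[i]), 0)
  win$theta_H <- vapply(mem, function(i) sum(th[i]), 0)
  win$H <- ifelse(win$n_snps > 0, win$theta_pi - win$theta_H, NaN)
  win
}

#' Contrast H inside HDRs against the genome background
#'
#' One-sided Mann-Whitney test of window H values, HDR windows < non-HDR
#' windows, plus group summaries.
#'
#' @param h_win output of [fay_wu_h_windows()].
#' @param hdrs output of [intersect_hdrs()].
#' @return list with U, p, mean_in, mean_out, sd_in, sd_out, n_in, n_out.
#' @export
hdr_contrast <- function(h_win, hdrs) {
  in_hdr <- rep(FALSE, nrow(h_win))
  for (i in seq_len(nrow(hdrs))) {
    in_hdr <- in_hdr | (h_win$chrom == hdrs$chrom[i] &
                          h_win$start < hdrs$end[i] &
                          h_win$end > hdrs$start[i])
  }
  hin <- h_win$H[in_hdr & is.finite(h_win$H)]
  hout <- h_win$H[!in_hdr & is.finite(h_win$H)]
  if (length(hin) == 0 || length(hout) == 0)
    stop("no finite H values in one of the groups")
  mw <- mann_whitney(hin, hout, alternative = "less")
  list(U = mw$U, p = mw$p, mean_in = mean(hin), mean_out = mean(hout),
       sd_in = stats::sd(hin), sd_out = stats::sd(hout),
       n_in = length(hin), n_out = length(hout))
}

#' Genes overlapping genomic regions
#'
#' A gene is assigned to a region when its gene-body interval overlaps it by
#' at least 1 bp (regions 0-based half-open, gene models 1-based inclusive).
#'
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @param genes data.frame from [read_gff3()].
#' @return list of character vectors of gene ids, one per region; attribute
#'   `all_genes` is the deduplicated union.
#' @export
genes_in_regions <- function(regions, genes) {
  gb <- genes[genes$type == "gene", , drop = FALSE]
  out <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- gb$seqid == regions$chrom[i] &
      gb$start <= regions$end[i] & gb$end >= regions$start[i] + 1L
    unique(gb$id[hit])
  })
  attr(out, "all_genes") <- unique(unlist(out))
  out
}
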
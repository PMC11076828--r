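# Windowed diversity statistics and site-frequency spectra.

# non-overlapping bins over each chromosome; lengths default to the largest
# observed site position
.bin_windows <- function(sites, bin_size, chrom_lengths = NULL) {
  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(sites$pos, factor(sites$chrom, chroms), max)
  out <- lapply(chroms, function(cc) {
    len <- chrom_lengths[[cc]]
    starts <- seq(0L, max(0L, len - 1L), by = bin_size)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + bin_size, as.integer(len)))
  })
  do.call(rbind, out)
}

# assign 1-based site positions to 0-based half-open windows of one tiling
.window_index <- function(sites, win) {
  key_w <- split(seq_len(nrow(win)), win$chrom)
  idx <- rep(NA_integer_, nrow(sites))
  for (cc in names(key_w)) {
    i <- which(sites$chrom == cc)
    if (length(i) == 0) next
    rows <- key_w[[cc]]
    j <- findInterval(sites$pos[i] - 1L, win$start[rows])
    ok <- j >= 1 & (sites$pos[i] - 1L) < win$end[rows][pmax(j, 1)]
    idx[i][ok] <- rows[j[ok]]
  }
  idx
}

# per-site expected heterozygosity 2j(n-j)/(n(n-1)) from haploid counts
.site_pi <- function(alt, nh) {
  ifelse(nh >= 2, 2 * alt * (nh - alt) / (nh * (nh - 1)), NA_real_)
}

#' Windowed nucleotide diversity
#'
#' Per non-overlapping bin, theta-pi = sum over sites of 2 j (n_h - j) /
#' (n_h (n_h - 1)) divided by the bin span (variant-only windowed-pi
#' convention); each site uses its own non-missing haplotype count n_h. The
#' per-variant-site mean is also reported (`value_per_snp`). Partial
#' chromosome-end bins divide by their actual span.
#'
#' @param gm a `genotype_matrix`.
#' @param pop population label.
#' @param bin_size bin width in bp (default 20000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame `chrom start end n_sites value value_per_snp`.
#' @export
pi_windows <- function(gm, pop, bin_size = 20000L, chrom_lengths = NULL) {
  ct <- .pop_counts(gm, pop)
  win <- .bin_windows(gm$sites, bin_size, chrom_lengths)
  idx <- .window_index(gm$sites, win)
  pi_site <- .site_pi(ct$alt, ct$nh)
  use <- !is.na(idx) & !is.na(pi_site)
  win$n_sites <- as.integer(tabulate(idx[use], nbins = nrow(win)))
  tot <- rep(0, nrow(win))
  agg <- tapply(pi_site[use], idx[use], sum)
  tot[as.integer(names(agg))] <- agg
  win$value <- tot / (win$end - win$start)
  win$value_per_snp <- ifelse(win$n_sites > 0, tot / win$n_sites, NaN)
  win
}

#' Windowed absolute divergence (DXY)
#'
#' Per site, d = pA (1 - pB) + pB (1 - pA) with p the alternate-allele
#' frequency over non-missing haplotypes. Mode `per_site` divides the window
#' sum by the bin span (appropriate for SNP-only input to approximate the
#' all-sites statistic); `per_snp` averages d over variant sites genotyped
#' in both populations.
#'
#' @param gm a `genotype_matrix`.
#' @param popA,popB population labels.
#' @param bin_size bin width in bp.
#' @param mode "per_site" (default) or "per_snp".
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame `chrom start end n_sites value`.
#' @export
dxy_windows <- function(gm, popA, popB, bin_size = 20000L,
                        mode = c("per_site", "per_snp"),
                        chrom_lengths = NULL) {
  mode <- match.arg(mode)
  ca <- .pop_counts(gm, popA); cb <- .pop_counts(gm, popB)
  pa <- ca$alt / ca$nh; pb <- cb$alt / cb$nh
  d <- pa * (1 - pb) + pb * (1 - pa)
  win <- .bin_windows(gm$sites, bin_size, chrom_lengths)
  idx <- .window_index(gm$sites, win)
  use <- !is.na(idx) & !is.na(d)
  win$n_sites <- as.integer(tabulate(idx[use], nbins = nrow(win)))
  tot <- rep(0, nrow(win))
  agg <- tapply(d[use], idx[use], sum)
  tot[as.integer(names(agg))] <- agg
  win$value <- if (mode == "per_site") tot / (win$end - win$start) else
    ifelse(win$n_sites > 0, tot / win$n_sites, NaN)
  win
}

# derived-allele counts per site for a population; polarization uses the
# ancestral allele column `aa` of the site table when present (base equal to
# ref or alt), else the reference allele is taken as ancestral
.derived_counts <- function(gm, pop, polarized) {
  ct <- .pop_counts(gm, pop)
  j <- ct$alt
  keep <- rep(TRUE, length(j))
  if (polarized && !is.null(gm$sites$aa)) {
    anc_is_ref <- gm$sites$aa == gm$sites$ref
    anc_is_alt <- gm$sites$aa == gm$sites$alt
    j <- ifelse(anc_is_alt, ct$nh - ct$alt, ct$alt)
    keep <- anc_is_ref | anc_is_alt
  }
  list(j = j, nh = ct$nh, keep = keep)
}

.project_site <- function(j, nh, m) {
  # hypergeometric projection of j derived of nh haplotypes to size m
  stats::dhyper(0:m, j, nh - j, m)
}

#' One-dimensional site-frequency spectrum with projection
#'
#' Each site contributes fractionally to derived-count classes 0..m by
#' hypergeometric projection to `projection_n` haplotypes; sites with fewer
#' than `projection_n` non-missing haplotypes are dropped and counted.
#' Unpolarized spectra are folded to minor-allele classes.
#'
#' @param gm a `genotype_matrix`.
#' @param pop population label.
#' @param polarized use the ancestral-allele annotation (`sites$aa`) to
#'   orient derived alleles; sites whose outgroup allele matches neither ref
#'   nor alt are excluded.
#' @param projection_n haploid projection size (default: twice the number of
#'   diploids in `pop`).
#' @return object of class `sfs`.
#' @export
sfs_1d <- function(gm, pop, polarized = TRUE, projection_n = NULL) {
  dc <- .derived_counts(gm, pop, polarized)
  if (is.null(projection_n)) projection_n <- 2L * .pop_counts(gm, pop)$n_dip
  m <- as.integer(projection_n)
  ok <- dc$keep & dc$nh >= m
  n_dropped <- sum(!ok)
  ent <- rep(0, m + 1)
  jj <- dc$j[ok]; nn <- dc$nh[ok]
  for (i in seq_along(jj)) ent <- ent + .project_site(jj[i], nn[i], m)
  if (!polarized) ent <- .fold_sfs(ent)
  structure(list(entries = ent, pops = pop, sample_sizes = m,
                 polarized = polarized, n_dropped = n_dropped),
            class = "sfs")
}

.fold_sfs <- function(u) {
  m <- length(u) - 1L
  half <- floor(m / 2)
  f <- numeric(half + 1)
  for (k in 0:half) f[k + 1] <- if (k == m - k) u[k + 1] else
    u[k + 1] + u[m - k + 1]
  f
}

#' Joint (2D/3D) site-frequency spectrum
#'
#' Product-of-hypergeometrics projection of each site into a joint array
#' over derived-allele counts per population. Monomorphic corner cells
#' (all-zero, all-maximum) are retained; their mass is reported in the
#' `corner_mass` attribute.
#'
#' @param gm a `genotype_matrix`.
#' @param pops character vector of 2 or 3 population labels.
#' @param projections haploid projection sizes (default: 2 x diploids).
#' @param polarized see [sfs_1d()].
#' @return object of class `sfs` with an array `entries`.
#' @export
joint_sfs <- function(gm, pops, projections = NULL, polarized = TRUE) {
  dcs <- lapply(pops, .derived_counts, gm = gm, polarized = polarized)
  if (is.null(projections))
    projections <- vapply(pops, function(p) 2L * .pop_counts(gm, p)$n_dip, 0L)
  m <- as.integer(projections)
  ok <- Reduce(`&`, lapply(seq_along(pops), function(k)
    dcs[[k]]$keep & dcs[[k]]$nh >= m[k]))
  ent <- array(0, dim = m + 1L)
  for (i in which(ok)) {
    v <- .project_site(dcs[[1]]$j[i], dcs[[1]]$nh[i], m[1])
    for (k in 2:length(pops))
      v <- outer(v, .project_site(dcs[[k]]$j[i], dcs[[k]]$nh[i], m[k]))
    ent <- ent + v
  }
  corner <- ent[matrix(1L, 1, length(m))] + ent[matrix(m + 1L, 1, length(m))]
  structure(list(entries = ent, pops = pops, sample_sizes = m,
                 polarized = polarized, n_dropped = sum(!ok)),
            class = "sfs", corner_mass = corner)
}

#' @export
print.sfs <- function(x, ...) {
  cat("site-frequency spectrum:", paste(x$pops, collapse = " x "),
      "| projection", paste(x$sample_sizes, collapse = " x "),
      "|", if (x$polarized) "unfolded" else "folded",
      "| total mass", format(sum(x$entries)), "\n")
  invisible(x)
}

#' Frequency-class summary of a 1D SFS
#'
#' Proportions over segregating-or-fixed classes (the zero class carries no
#' frequency information and is excluded from the denominator): `prop_fixed`
#' is the top class, `prop_rare` the mass at derived frequency below
#' `rare_cutoff` (excluding class 0), `prop_intermediate` the remainder.
#'
#' @param sfs an `sfs` from [sfs_1d()].
#' @param rare_cutoff frequency cutoff for rare alleles (default 0.05).
#' @return list with prop_fixed, prop_rare, prop_intermediate.
#' @export
frequency_classes <- function(sfs, rare_cutoff = 0.05) {
  u <- sfs$entries
  m <- length(u) - 1L
  if (sum(u) == 0) stop("empty SFS")
  tot <- sum(u[-1])
  if (tot == 0) stop("SFS has no non-zero frequency class")
  freq <- (0:m) / m
  rare <- sum(u[freq < rare_cutoff & freq > 0])
  fixed <- u[m + 1]
  list(prop_fixed = fixed / tot, prop_rare = rare / tot,
       prop_intermediate = (tot - rare - fixed) / tot)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with tie correction; exact enumeration for small samples
#' without ties, normal approximation otherwise.
#'
#' @param a,b numeric samples.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list with `U` and `p`.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1)
    return(list(U = length(a) * length(b) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
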
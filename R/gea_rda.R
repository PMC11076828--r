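# Redundancy-analysis genotype-environment association, genotype PCA, and
# enrichment / distribution contrasts.

# impute missing codes (-1) with the per-SNP mean; returns matrix + count
.impute_codes <- function(codes) {
  x <- codes
  x[x < 0] <- NA
  n_imp <- sum(is.na(x))
  if (n_imp > 0) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  list(x = x, n_imputed = n_imp)
}

.as_codes <- function(G) {
  if (inherits(G, "genotype_matrix")) G$codes else as.matrix(G)
}

#' Redundancy analysis of genotypes on environmental predictors
#'
#' Columns of the 0/1/2 genotype matrix are mean-centred (missing codes
#' imputed with the per-SNP mean); the genotype matrix is regressed on the
#' centred environment table by multivariate least squares, and the fitted
#' values are eigendecomposed to give constrained axes (eigenvalues, sample
#' scores, per-SNP loadings). The adjusted R-squared uses the Ezekiel
#' correction 1 - (1 - R2)(n - 1)/(n - p - 1) with p the rank of the
#' predictor matrix.
#'
#' @param G a `genotype_matrix` or a samples x SNPs code matrix.
#' @param E data.frame/matrix of environmental variables (rows = samples,
#'   same order as G). Constant columns are dropped with a warning.
#' @return object of class `locadapt_rda`: eigenvalues, sample scores, SNP
#'   `loadings`, `r2`, `r2_adj`, `rank`, `total_var`, `n_imputed`.
#' @export
rda_fit <- function(G, E) {
  X0 <- as.matrix(E)
  storage.mode(X0) <- "double"
  codes <- .as_codes(G)
  if (nrow(codes) < 3) stop("need at least 3 samples")
  imp <- .impute_codes(codes)
  Y <- scale(imp$x, center = TRUE, scale = FALSE)
  keep <- apply(X0, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) stop("all environmental columns are constant")
  if (!all(keep))
    warning("dropping constant environmental columns: ",
            paste(colnames(X0)[!keep], collapse = ", "))
  X <- scale(X0[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  qrx <- qr(X)
  r <- qrx$rank
  Q <- qr.Q(qrx)[, seq_len(r), drop = FALSE]
  P <- crossprod(Q, Y)                      # r x m; fitted = Q %*% P
  sv <- svd(P)
  n <- nrow(Y)
  eig <- sv$d^2 / (n - 1)
  pos <- eig > max(eig, 0) * 1e-12
  eig <- eig[pos]
  axes <- Q %*% sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  loadings <- sv$v[, pos, drop = FALSE]
  colnames(loadings) <- paste0("RDA", seq_len(ncol(loadings)))
  colnames(axes) <- colnames(loadings)
  rownames(axes) <- rownames(codes)
  total_var <- sum(apply(Y, 2, stats::var))
  r2 <- sum(eig) / total_var
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - r - 1)
  structure(list(eig = eig, scores = axes, loadings = loadings, r2 = r2,
                 r2_adj = r2_adj, rank = r, total_var = total_var,
                 n_imputed = imp$n_imputed, env_cols = colnames(X0)[keep]),
            class = "locadapt_rda")
}

#' @export
print.locadapt_rda <- function(x, ...) {
  cat("RDA:", length(x$eig), "constrained axes |",
      "R2 =", signif(x$r2, 4), "| R2adj =", signif(x$r2_adj, 4), "\n")
  cat("eigenvalues:", paste(signif(x$eig, 4), collapse = ", "), "\n")
  if (!is.null(x$axis_p))
    cat("axis p-values:", paste(signif(x$axis_p, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.locadapt_rda <- function(object, ...) {
  res <- list(eig = object$eig,
              prop_constrained = object$eig / object$total_var,
              r2 = object$r2, r2_adj = object$r2_adj,
              axis_p = object$axis_p, n_imputed = object$n_imputed)
  class(res) <- "summary.locadapt_rda"
  res
}

#' @export
print.summary.locadapt_rda <- function(x, ...) {
  cat("Constrained axes:\n")
  print(data.frame(eigenvalue = x$eig,
                   prop_total_variance = x$prop_constrained,
                   p = if (is.null(x$axis_p)) NA else x$axis_p))
  cat("R2 =", signif(x$r2, 4), " R2adj =", signif(x$r2_adj, 4), "\n")
  invisible(x)
}

#' Per-axis permutation significance for an RDA
#'
#' Rows of the environment table are permuted `n_perm` times; the marginal
#' pseudo-F of each constrained axis (axis eigenvalue over residual variance
#' per residual degree of freedom) is recomputed and p = (1 + number of
#' permutations with F at least the observed) / (1 + n_perm).
#'
#' @param G genotypes as in [rda_fit()].
#' @param E environment table.
#' @param fit the observed [rda_fit()] result.
#' @param n_perm permutations (default 999; a warning below 99).
#' @param seed RNG seed.
#' @return the fit with `axis_p` added.
#' @export
rda_axis_test <- function(G, E, fit, n_perm = 999, seed = 1) {
  if (n_perm < 99) warning("fewer than 99 permutations")
  codes <- .as_codes(G)
  imp <- .impute_codes(codes)
  Y <- scale(imp$x, center = TRUE, scale = FALSE)
  n <- nrow(Y)
  eig_of <- function(Eperm) {
    X0 <- as.matrix(Eperm)
    keep <- apply(X0, 2, function(v) stats::var(v) > 0)
    X <- scale(X0[, keep, drop = FALSE], center = TRUE, scale = FALSE)
    qrx <- qr(X)
    Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    d <- svd(crossprod(Q, Y), nu = 0, nv = 0)$d
    list(eig = d^2 / (n - 1), rank = qrx$rank)
  }
  k <- length(fit$eig)
  fstat <- function(e, r) {
    resid <- (fit$total_var - sum(e)) / (n - 1 - r)
    e[seq_len(k)] / resid
  }
  obs <- fstat(fit$eig, fit$rank)
  set.seed(seed)
  exceed <- numeric(k)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    pe <- eig_of(as.matrix(E)[perm, , drop = FALSE])
    pf <- fstat(c(pe$eig, rep(0, max(0, k - length(pe$eig)))), pe$rank)
    exceed <- exceed + (pf >= obs)
  }
  fit$axis_p <- (1 + exceed) / (1 + n_perm)
  fit
}

#' SNP loading outliers over significant RDA axes
#'
#' Per axis with permutation p below `alpha`, SNPs whose loading deviates
#' from the axis mean by at least `z` SD are flagged; the union over
#' significant axes is returned.
#'
#' @param fit a `locadapt_rda`, ideally after [rda_axis_test()]; if no axis
#'   p-values are present all axes are used.
#' @param z two-tailed cutoff in SD (default 1.96).
#' @param alpha axis significance level (default 0.05).
#' @return integer vector of SNP (column) indices; attribute `by_axis` holds
#'   the per-axis masks.
#' @export
loading_outliers <- function(fit, z = 1.96, alpha = 0.05) {
  use <- if (is.null(fit$axis_p)) seq_along(fit$eig) else
    which(fit$axis_p < alpha)
  masks <- lapply(use, function(ax)
    call_outliers(fit$loadings[, ax], side = "two", z = z))
  out <- if (length(masks) == 0) integer() else
    which(Reduce(`|`, masks))
  attr(out, "by_axis") <- masks
  out
}

#' Chi-square enrichment of one SNP set within another
#'
#' 2x2 table of membership in `set_a` crossed with membership in `set_b`
#' over the universe; Pearson chi-square without continuity correction by
#' default.
#'
#' @param set_a,set_b vectors of identifiers (subsets of `universe`).
#' @param universe vector of all identifiers.
#' @param correct apply the Yates correction (default FALSE).
#' @return list with `chi2`, `p` and the 2x2 `table`.
#' @export
enrichment_chi2 <- function(set_a, set_b, universe, correct = FALSE) {
  ina <- universe %in% set_a
  inb <- universe %in% set_b
  tab <- table(factor(ina, c(TRUE, FALSE)), factor(inb, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a margin is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param sample_a,sample_b numeric samples.
#' @return list with `D` and `p` (two-sided, asymptotic for large samples).
#' @export
ks_compare <- function(sample_a, sample_b) {
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Genotype PCA with binomial scaling
#'
#' SNP columns are mean-centred and divided by sqrt(2 p (1 - p)) with p the
#' sample allele frequency (zero-variance columns dropped); the sample
#' covariance is eigendecomposed via SVD.
#'
#' @param G a `genotype_matrix` or code matrix.
#' @return list with `scores` (samples x PCs) and `variance_explained`
#'   (sums to 1 over retained PCs).
#' @export
pca_genotypes <- function(G) {
  codes <- .as_codes(G)
  if (nrow(codes) < 2 || ncol(codes) < 2)
    stop("need at least 2 samples and 2 SNPs")
  imp <- .impute_codes(codes)
  p <- colMeans(imp$x) / 2
  keep <- p > 0 & p < 1 & apply(imp$x, 2, stats::var) > 0
  Z <- sweep(imp$x[, keep, drop = FALSE], 2, 2 * p[keep])
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(Z)
  pos <- sv$d > max(sv$d) * 1e-12
  scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  rownames(scores) <- rownames(codes)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores,
       variance_explained = sv$d[pos]^2 / sum(sv$d[pos]^2))
}

#' Fisher over-representation test per annotation term
#'
#' One-sided hypergeometric test of each term's over-representation in the
#' gene set relative to the universe, with BH FDR across terms.
#'
#' @param gene_set character vector of genes of interest (non-empty).
#' @param annotation named list mapping gene id to a character vector of
#'   terms.
#' @param universe character vector of all genes.
#' @return data.frame `term k K p_fisher fdr` sorted by p.
#' @export
term_enrichment <- function(gene_set, annotation, universe) {
  if (length(gene_set) == 0) stop("empty gene set")
  gene_set <- intersect(gene_set, universe)
  ann <- annotation[intersect(names(annotation), universe)]
  term_genes <- split(rep(names(ann), lengths(ann)), unlist(ann))
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(names(term_genes), function(tm) {
    tg <- unique(term_genes[[tm]])
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, p_fisher = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_fisher)
  out[order(out$p_fisher), ]
}
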
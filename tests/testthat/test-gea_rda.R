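test_that("RDA matches a regress-then-eigendecompose oracle and vegan", {
  set.seed(3)
  G <- matrix(sample(0:2, 6 * 4, TRUE), 6, 4)
  G[, 1] <- c(0, 0, 1, 1, 2, 2)
  E <- data.frame(env = G[, 1] + 0)
  fit <- rda_fit(G, E)
  # SNP 1 carries the association: largest first-axis loading
  expect_equal(which.max(abs(fit$loadings[, 1])), 1L)
  # independent two-step oracle: lm.fit then eigen of fitted covariance
  Y <- scale(G, center = TRUE, scale = FALSE)
  X <- scale(as.matrix(E), center = TRUE, scale = FALSE)
  fitted <- X %*% solve(crossprod(X), crossprod(X, Y))
  ev <- eigen(stats::cov(fitted))
  pos <- ev$values > 1e-12
  expect_lt(max(abs(sort(fit$eig, decreasing = TRUE) -
                      ev$values[pos])), 1e-9)
  r2 <- sum(ev$values[pos]) / sum(apply(Y, 2, var))
  expect_lt(abs(fit$r2 - r2), 1e-9)
  n <- nrow(G)
  expect_lt(abs(fit$r2_adj - (1 - (1 - r2) * (n - 1) / (n - 1 - 1))),
            1e-9)
  skip_if_not_installed("vegan")
  vfit <- vegan::rda(G ~ env, data = E)
  expect_lt(max(abs(fit$eig - unname(vfit$CCA$eig))), 1e-9)
  expect_lt(abs(fit$r2_adj - vegan::RsquareAdj(vfit)$adj.r.squared), 1e-9)
})

test_that("RDA respects the rank bound and affine invariance", {
  set.seed(8)
  G <- matrix(sample(0:2, 12 * 30, TRUE), 12, 30)
  # three locations broadcast to samples: rank(E) = 2 after centring
  env3 <- default_env()
  E <- env3[rep(1:3, each = 4), c("MAT", "MAMT", "MAP")]
  fit <- rda_fit(G, E)
  expect_lte(length(fit$eig), 2L)
  # affine rescaling of the environment leaves the axes unchanged
  E2 <- data.frame(MAT = E$MAT * 100 - 7, MAMT = E$MAMT / 3 + 2,
                   MAP = E$MAP * 0.01)
  fit2 <- rda_fit(G, E2)
  expect_lt(max(abs(fit$eig - fit2$eig)), 1e-9)
  expect_lt(max(abs(abs(fit$loadings) - abs(fit2$loadings))), 1e-8)
  # environment orthogonal to every genotype column: no constrained
  # variance to speak of
  G3 <- matrix(rep(c(0, 0, 1, 1, 2, 2), 6), 6, 6)
  E3 <- data.frame(env = c(1, -1, -1, 1, 1, -1))
  fit3 <- rda_fit(G3, E3)
  expect_lt(sum(fit3$eig), 1e-9)
  expect_lte(fit3$r2_adj, 0)
  # constant environment errors
  expect_error(rda_fit(G3, data.frame(a = rep(1, 6))), "constant")
})

test_that("permutation axis test is calibrated and powered", {
  set.seed(15)
  G <- matrix(sample(0:2, 20 * 40, TRUE), 20, 40)
  grad <- rep(seq(-1.5, 1.5, length.out = 4), each = 5)
  # strong association: 10 SNPs track the gradient
  for (j in 1:10)
    G[, j] <- pmin(pmax(round(1 + grad + rnorm(20, 0, 0.3)), 0), 2)
  E <- data.frame(env = grad)
  fit <- rda_fit(G, E)
  fit <- rda_axis_test(G, E, fit, n_perm = 199, seed = 4)
  expect_lt(fit$axis_p[1], 0.02)
  expect_gte(min(fit$axis_p), 1 / 200)
  expect_lte(max(fit$axis_p), 1)
  # no association: p not extreme
  set.seed(16)
  G0 <- matrix(sample(0:2, 20 * 40, TRUE), 20, 40)
  f0 <- rda_axis_test(G0, E, rda_fit(G0, E), n_perm = 199, seed = 4)
  expect_gt(f0$axis_p[1], 0.05)
})

test_that("loading outliers hit the two-tailed rate and unite over axes", {
  set.seed(77)
  fake <- list(eig = c(2, 1), axis_p = c(0.01, 0.01),
               loadings = cbind(rnorm(1e5), rnorm(1e5)))
  class(fake) <- "locadapt_rda"
  one_axis <- list(eig = 2, axis_p = 0.01,
                   loadings = fake$loadings[, 1, drop = FALSE])
  class(one_axis) <- "locadapt_rda"
  frac <- length(loading_outliers(one_axis)) / 1e5
  expect_gt(frac, 0.045); expect_lt(frac, 0.055)
  # a single extreme loading among zeros
  spike <- list(eig = 1, axis_p = 0.01,
                loadings = cbind(c(rep(0, 999), 50)))
  class(spike) <- "locadapt_rda"
  expect_equal(as.integer(loading_outliers(spike)), 1000L)
  # union over two axes with disjoint flags
  l1 <- c(rep(0, 8), 10, 0); l2 <- c(10, rep(0, 9))
  two <- list(eig = c(1, 1), axis_p = c(0.01, 0.01),
              loadings = cbind(l1, l2))
  class(two) <- "locadapt_rda"
  expect_equal(sort(as.integer(loading_outliers(two))), c(1L, 9L))
  # non-significant axes contribute nothing
  none <- two; none$axis_p <- c(0.5, 0.5)
  expect_equal(length(loading_outliers(none)), 0L)
})

test_that("chi-square enrichment reproduces the headline SNP overlap", {
  universe <- seq_len(189909)
  temp <- seq_len(16256)
  hdr <- c(seq_len(1118), seq(170000, 170000 + 1749))  # 2,868 HDR SNPs
  res <- enrichment_chi2(temp, hdr, universe)
  expect_equal(sum(res$table), 189909)
  expect_equal(res$table[1, 1], 1118)
  expect_lt(res$p, 1e-15)
  # independence: observed equals expectation -> chi2 ~ 0
  u <- seq_len(400)
  a <- 1:200
  b <- c(1:100, 201:300)
  expect_lt(enrichment_chi2(a, b, u)$chi2, 1e-12)
  expect_error(enrichment_chi2(u, 1:10, u), "margin")
})

test_that("KS comparison matches a direct ECDF oracle", {
  x <- seq(0.1, 1, by = 0.1)
  expect_equal(ks_compare(x, x)$D, 0)
  expect_equal(ks_compare(x, x)$p, 1)
  expect_equal(ks_compare(x, x + 10)$D, 1)
  ks_oracle <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  set.seed(12)
  for (i in 1:100) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), 0.3)
    expect_lt(abs(ks_compare(a, b)$D - ks_oracle(a, b)), 1e-12)
  }
})

test_that("genotype PCA separates clusters and matches the SVD oracle", {
  set.seed(19)
  G <- rbind(matrix(rep(c(0L, 0L, 2L, 2L, 0L), 4), 4, 5, byrow = TRUE),
             matrix(rep(c(2L, 2L, 0L, 0L, 0L), 4), 4, 5, byrow = TRUE))
  G <- cbind(G, matrix(sample(0:2, 8 * 10, TRUE), 8, 10))
  p <- pca_genotypes(G)
  expect_gt(min(abs(p$scores[1:4, 1] - p$scores[5:8, 1])), 0.1)
  expect_equal(which.max(p$variance_explained), 1L)
  expect_lt(abs(sum(p$variance_explained) - 1), 1e-9)
  # SVD oracle on a 10 x 50 matrix
  M <- matrix(sample(0:2, 10 * 50, TRUE), 10, 50)
  pm <- pca_genotypes(M)
  pc <- colMeans(M) / 2
  keep <- pc > 0 & pc < 1 & apply(M, 2, var) > 0
  Z <- sweep(M[, keep], 2, 2 * pc[keep])
  Z <- sweep(Z, 2, sqrt(2 * pc[keep] * (1 - pc[keep])), "/")
  d2 <- svd(Z)$d^2
  d2 <- d2[d2 > max(d2) * 1e-12]
  expect_lt(max(abs(pm$variance_explained - d2 / sum(d2))), 1e-9)
})

test_that("term enrichment ranks the covering term first", {
  universe <- sprintf("g%03d", 1:100)
  gene_set <- universe[1:10]
  ann <- setNames(vector("list", 100), universe)
  for (g in universe) ann[[g]] <- "base"
  for (g in gene_set) ann[[g]] <- c("hit", "base")
  res <- term_enrichment(gene_set, ann, universe)
  expect_equal(res$term[1], "hit")
  expect_lt(abs(res$p_fisher[res$term == "hit"] -
                  dhyper(10, 10, 90, 10)), 1e-12)
  expect_equal(res$p_fisher[res$term == "base"], 1)
  expect_error(term_enrichment(character(), ann, universe), "empty")
})
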
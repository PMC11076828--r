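test_that("Weir-Cockerham FST matches fixed-difference limits and oracle", {
  # popA all 0/0, popB all 1/1 -> FST = 1
  gm <- toy_gm(rbind(matrix(0L, 4, 5), matrix(2L, 4, 5)),
               rep(c("A", "B"), each = 4))
  w <- wc_fst_windows(gm, "A", "B", size = 20000L, step = 20000L)
  expect_equal(w$fst[1], 1)
  # identical genotype arrays -> sum(a) = 0, FST <= 0
  set.seed(5)
  half <- matrix(sample(0:2, 4 * 5, TRUE), 4, 5)
  gm2 <- toy_gm(rbind(half, half), rep(c("A", "B"), each = 4))
  w2 <- wc_fst_windows(gm2, "A", "B", size = 20000L, step = 20000L)
  expect_lte(w2$fst[1], 0)
  # Hardy-Weinberg configurations at p 0.2 vs 0.8 plus random fixtures vs
  # the independently coded variance-components oracle
  set.seed(13)
  codes <- rbind(
    matrix(sample(0:2, 10 * 10, TRUE, prob = c(.64, .32, .04)), 10, 10),
    matrix(sample(0:2, 10 * 10, TRUE, prob = c(.04, .32, .64)), 10, 10))
  codes[sample(length(codes), 12)] <- -1L
  gm3 <- toy_gm(codes, rep(c("A", "B"), each = 10))
  w3 <- wc_fst_windows(gm3, "A", "B", size = 20000L, step = 20000L)
  acc <- matrix(0, 10, 3)
  for (s in 1:10)
    acc[s, ] <- wc_fst_oracle_site(codes[1:10, s], codes[11:20, s])
  expect_lt(abs(w3$fst[1] - sum(acc[, 1]) / sum(acc)), 1e-12)
  expect_lt(abs(wc_fst_global(gm3, "A", "B") - sum(acc[, 1]) / sum(acc)),
            1e-12)
  expect_error(wc_fst_windows(toy_gm(matrix(0L, 3, 2), c("A", "A", "B")),
                              "A", "B"), "fewer than 2")
})

test_that("XP-CLR is null at equal frequencies; grid matches brute force", {
  # identical frequencies in both populations -> CLR ~ 0
  set.seed(21)
  half <- matrix(sample(0:2, 8 * 30, TRUE), 8, 30)
  gm <- toy_gm(rbind(half, half), rep(c("A", "B"), each = 8),
               pos = sort(sample(1:20000, 30)))
  xp <- xpclr_windows(gm, "B", "A", size = 20000L, step = 20000L,
                      chrom_lengths = c(chr1 = 20000L))
  expect_lt(abs(xp$xpclr[1]), 1e-6)

  # single usable site: the packaged grid maximization equals an
  # exhaustive fine-grid brute force over s
  gmA <- matrix(c(rep(2L, 6), rep(0L, 2)), 8, 1)
  gmB <- matrix(c(rep(1L, 4), rep(0L, 4)), 8, 1)
  gm2 <- toy_gm(rbind(gmA, gmB), rep(c("A", "B"), each = 8), pos = 4000L)
  sgrid <- 10^seq(-5, -0.5, length.out = 30)
  xp2 <- xpclr_windows(gm2, "B", "A", size = 20000L, step = 20000L,
                       min_snps = 1L, s_grid = sgrid,
                       chrom_lengths = c(chr1 = 20000L))
  # brute force: recompute per-site CL over a fine grid with the same
  # site-level integration routine
  p1 <- 4 / 16; k2 <- 12; n2 <- 16
  om_sites <- locadapt:::.pop_counts(gm2, "B")
  p2 <- 12 / 16
  omega <- (p2 - p1)^2 / (p1 * (1 - p1))
  d <- abs(4000 - 10000) * 1e-8
  fine <- 10^seq(-6, 0, length.out = 4000)
  cl <- locadapt:::.xpclr_site_cl(p1, k2, n2, c(1, 1 - exp(-d / fine)),
                                  omega)
  brute <- 2 * (max(log(pmax(cl, 1e-300))) - log(max(cl[1], 1e-300)))
  expect_gte(brute + 1e-8, xp2$xpclr[1])
  coarse <- locadapt:::.xpclr_site_cl(p1, k2, n2,
                                      c(1, 1 - exp(-d / sgrid)), omega)
  brute_same_grid <- 2 * (max(log(pmax(coarse, 1e-300))) -
                            log(pmax(coarse[1], 1e-300)))
  expect_lt(abs(xp2$xpclr[1] - brute_same_grid), 1e-8)
})

test_that("z-score outlier calling hits the nominal normal tails", {
  v <- c(rep(0, 999), 100)
  expect_equal(which(call_outliers(v, "upper", 1.96)), 1000L)
  set.seed(99)
  x <- rnorm(1e5)
  up <- mean(call_outliers(x, "upper", 1.96))
  expect_gt(up, 0.022); expect_lt(up, 0.028)
  two <- mean(call_outliers(x, "two", 1.96))
  expect_gt(two, 0.045); expect_lt(two, 0.055)
  expect_equal(sum(call_outliers(rep(3, 50), "upper")), 0L)
  expect_false(any(call_outliers(c(rep(0, 99), NaN, 100), "upper")[100]))
})

test_that("HDR intersection merges adjacent joint-outlier windows", {
  mk_scan <- function(vals, stat) {
    n <- length(vals)
    w <- data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * 5000L,
                    end = (seq_len(n) - 1L) * 5000L + 20000L,
                    id = seq_len(n))
    w[[stat]] <- vals
    w
  }
  base <- rep(0, 200)
  # disjoint outliers -> no HDRs
  f1 <- base; f1[10] <- 100
  x1 <- base; x1[50] <- 100
  hd <- intersect_hdrs(mk_scan(f1, "fst"), mk_scan(x1, "xpclr_norm"))
  expect_equal(nrow(hd), 0L)
  # single joint outlier window -> one HDR of that window
  f2 <- base; f2[10] <- 100
  x2 <- base; x2[10] <- 100
  hd2 <- intersect_hdrs(mk_scan(f2, "fst"), mk_scan(x2, "xpclr_norm"))
  expect_equal(nrow(hd2), 1L)
  expect_equal(hd2$end - hd2$start, 20000L)
  # three consecutive overlapping outlier windows -> one merged HDR of
  # length size + 2 * step
  f3 <- base; f3[10:12] <- 100
  x3 <- base; x3[10:12] <- 100
  hd3 <- intersect_hdrs(mk_scan(f3, "fst"), mk_scan(x3, "xpclr_norm"))
  expect_equal(nrow(hd3), 1L)
  expect_equal(hd3$end - hd3$start, 20000L + 2L * 5000L)
  expect_equal(hd3$n_windows, 3L)
  # mismatched grids error
  expect_error(intersect_hdrs(mk_scan(f3, "fst")[-1, ],
                              mk_scan(x3, "xpclr_norm")),
               "different window grids")
})

test_that("Fay-Wu H matches direct formula and is centred under neutrality", {
  # single site, n = 4, derived count 3: theta_pi 0.5, theta_H 1.5, H = -1
  gm <- toy_gm(matrix(c(2L, 1L), 2, 1), rep("A", 2), aa = "A")
  h <- fay_wu_h_windows(gm, "A", size = 20000L, step = 20000L)
  expect_equal(h$theta_pi[1], 0.5)
  expect_equal(h$theta_H[1], 1.5)
  expect_equal(h$H[1], -1)
  # singleton: H = +1/3
  gm2 <- toy_gm(matrix(c(1L, 0L), 2, 1), rep("A", 2), aa = "A")
  expect_equal(fay_wu_h_windows(gm2, "A", 20000L, 20000L)$H[1], 1 / 3)
  # neutral constant-size simulation: genome-mean H within 3 MC SE of 0
  spec <- const_model(5000)$build(list(N = 5000))
  set.seed(31)
  sim <- coal_sim_loci(spec$sizes0, spec$growth0, spec$mig, spec$events,
                       20L, 200L, 10000, 2.5e-8)
  keep <- !duplicated(sim$locus * 10000 + sim$pos)
  gm3 <- toy_gm(t(sim$geno[keep, seq(1, 20, 2), drop = FALSE] +
                    sim$geno[keep, seq(2, 20, 2), drop = FALSE]),
                rep("A", 10),
                pos = (sim$locus[keep] * 10000 + sim$pos[keep] + 1L),
                aa = "A")
  ord <- order(gm3$sites$pos)
  gm3$codes <- gm3$codes[, ord, drop = FALSE]
  gm3$sites <- gm3$sites[ord, ]
  hw <- fay_wu_h_windows(gm3, "A", size = 10000L, step = 10000L,
                         chrom_lengths = c(chr1 = 200 * 10000))
  hvals <- hw$H[is.finite(hw$H)]
  se <- sd(hvals) / sqrt(length(hvals))
  expect_lt(abs(mean(hvals)), 3 * se + 0.05)
})

test_that("HDR-vs-genome H contrast and gene overlap behave correctly", {
  h <- data.frame(chrom = "chr1", start = (0:99) * 5000L,
                  end = (0:99) * 5000L + 20000L, id = 1:100,
                  H = c(rep(-3, 10), rep(0, 90)))
  hdrs <- data.frame(chrom = "chr1", start = 0L, end = 65000L)
  ct <- hdr_contrast(h, hdrs)
  expect_lt(ct$p, 0.001)
  expect_lt(ct$mean_in, ct$mean_out)
  # identical distributions -> one-sided p around 0.5
  h2 <- h; h2$H <- rep(c(-1, 1), 50)
  ct2 <- hdr_contrast(h2, hdrs)
  expect_gt(ct2$p, 0.1)
  # gene assignment: >= 1 bp overlap, book-ended genes excluded
  gff <- read_gff3(toy_gff(tempfile(fileext = ".gff3")))
  regions <- data.frame(chrom = c("chr1", "chr1"),
                        start = c(9000L, 11000L), end = c(10000L, 15000L))
  gl <- genes_in_regions(regions, gff)
  # region1 is [9001,10000] 1-based: ends just before geneA at 10001
  expect_equal(gl[[1]], character(0))
  expect_equal(gl[[2]], "geneA")
  r2 <- data.frame(chrom = "chr1", start = 29000L, end = 30001L)
  expect_equal(genes_in_regions(r2, gff)[[1]], "geneB")
})
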
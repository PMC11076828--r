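test_that("windowed theta-pi matches exhaustive pairwise enumeration", {
  # monomorphic window
  gm0 <- toy_gm(matrix(0L, 4, 3), rep("A", 4))
  expect_equal(pi_windows(gm0, "A", 20000L)$value, 0)

  # one site with derived count 4 of 8 haplotypes in a 20-kb window:
  # enumerate all 28 haplotype pairs directly
  gm <- toy_gm(matrix(c(2L, 2L, 0L, 0L), 4, 1), rep("A", 4), pos = 500L)
  haps <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pairs <- combn(8, 2)
  pi_site <- mean(haps[pairs[1, ]] != haps[pairs[2, ]])
  expect_equal(pi_site, 2 * 4 * 4 / (8 * 7))
  w <- pi_windows(gm, "A", 20000L, chrom_lengths = c(chr1 = 20000L))
  expect_equal(w$value, pi_site / 20000)
  expect_equal(w$value_per_snp, pi_site)

  # oracle equivalence on simulated sites: per-site heterozygosity from an
  # independent allele-counting loop
  set.seed(42)
  codes <- matrix(sample(c(-1L, 0L, 1L, 2L), 10 * 1000, TRUE,
                         prob = c(.05, .5, .3, .15)), 10, 1000)
  gm2 <- toy_gm(codes, rep("A", 10), pos = seq_len(1000) * 10L)
  w2 <- pi_windows(gm2, "A", 20000L, chrom_lengths = c(chr1 = 20000L))
  oracle <- 0
  for (s in seq_len(1000)) {
    g <- codes[, s][codes[, s] >= 0]
    nh <- 2 * length(g); j <- sum(g)
    if (nh >= 2) oracle <- oracle + 2 * j * (nh - j) / (nh * (nh - 1))
  }
  expect_lt(abs(w2$value[1] - oracle / 20000), 1e-12)
})

test_that("DXY modes agree with the direct formula and are symmetric", {
  # fixed difference
  gm <- toy_gm(rbind(matrix(0L, 3, 1), matrix(2L, 3, 1)),
               rep(c("A", "B"), each = 3), pos = 100L)
  d <- dxy_windows(gm, "A", "B", 20000L, mode = "per_snp",
                   chrom_lengths = c(chr1 = 20000L))
  expect_equal(d$value, 1)
  # pA = 0.5, pB = 1 -> d = 0.5
  gm2 <- toy_gm(rbind(matrix(1L, 3, 1), matrix(2L, 3, 1)),
                rep(c("A", "B"), each = 3), pos = 100L)
  d2 <- dxy_windows(gm2, "A", "B", 20000L, mode = "per_snp",
                    chrom_lengths = c(chr1 = 20000L))
  expect_equal(d2$value, 0.5)
  # algebraic identity per_site = per_snp * n_sites / span, and symmetry
  set.seed(7)
  codes <- matrix(sample(0:2, 8 * 200, TRUE), 8, 200)
  gm3 <- toy_gm(codes, rep(c("A", "B"), each = 4),
                pos = sort(sample(1:60000, 200)))
  cl <- c(chr1 = 60000L)
  ps <- dxy_windows(gm3, "A", "B", 20000L, "per_site", cl)
  pn <- dxy_windows(gm3, "A", "B", 20000L, "per_snp", cl)
  expect_equal(ps$value, ifelse(pn$n_sites > 0, pn$value, 0) *
                 pn$n_sites / (ps$end - ps$start))
  expect_equal(dxy_windows(gm3, "B", "A", 20000L, "per_site", cl)$value,
               ps$value)
})

test_that("SFS projection is hypergeometric and conserves mass", {
  # identity projection: indicator at j
  gm <- toy_gm(matrix(c(2L, 2L, 0L, 0L), 4, 1), rep("A", 4),
               aa = "A")
  s <- sfs_1d(gm, "A", polarized = TRUE, projection_n = 8)
  expect_equal(s$entries, c(0, 0, 0, 0, 1, 0, 0, 0, 0))
  # j = 2 of nh = 4 projected to m = 2 -> (1/6, 4/6, 1/6)
  gm2 <- toy_gm(matrix(c(1L, 1L), 2, 1), rep("A", 2), aa = "A")
  s2 <- sfs_1d(gm2, "A", polarized = TRUE, projection_n = 2)
  expect_equal(s2$entries, c(1 / 6, 4 / 6, 1 / 6))
  # conservation over many random sites, and folding commutes
  set.seed(3)
  codes <- matrix(sample(0:2, 6 * 300, TRUE), 6, 300)
  gm3 <- toy_gm(codes, rep("A", 6), pos = seq_len(300) * 10L, aa = "A")
  s3 <- sfs_1d(gm3, "A", polarized = TRUE, projection_n = 8)
  expect_lt(abs(sum(s3$entries) - (300 - s3$n_dropped)), 1e-9)
  folded <- sfs_1d(gm3, "A", polarized = FALSE, projection_n = 8)
  refold <- locadapt:::.fold_sfs(s3$entries)
  expect_lt(max(abs(folded$entries - refold)), 1e-9)
})

test_that("joint SFS marginals equal the 1D spectra; corners flagged", {
  # one fixed difference -> corner cell (0, mB)
  gm <- toy_gm(cbind(rbind(matrix(0L, 3, 1), matrix(2L, 3, 1))),
               rep(c("A", "B"), each = 3), pos = 100L, aa = "A")
  js <- joint_sfs(gm, c("A", "B"), projections = c(6, 6))
  expect_equal(js$entries[1, 7], 1)
  expect_equal(sum(js$entries), 1)
  set.seed(9)
  codes <- matrix(sample(0:2, 8 * 400, TRUE), 8, 400)
  gm2 <- toy_gm(codes, rep(c("A", "B"), each = 4),
                pos = seq_len(400) * 10L, aa = "A")
  js2 <- joint_sfs(gm2, c("A", "B"), projections = c(6, 6))
  mA <- rowSums(js2$entries)
  sA <- sfs_1d(gm2, "A", projection_n = 6)
  expect_lt(max(abs(mA - sA$entries)), 1e-12)
})

test_that("frequency classes split rare/intermediate/fixed and sum to 1", {
  top <- structure(list(entries = c(0, 0, 0, 5), pops = "A",
                        sample_sizes = 3L, polarized = TRUE),
                   class = "sfs")
  fc <- frequency_classes(top)
  expect_equal(fc$prop_fixed, 1)
  # uniform SFS over classes 1..19 of m = 20, cutoff 0.05: no class below
  # 1/20 = 0.05 except none (class 1 has freq 0.05, not < 0.05)
  uni <- structure(list(entries = c(0, rep(1, 19), 0), pops = "A",
                        sample_sizes = 20L, polarized = TRUE),
                   class = "sfs")
  fc2 <- frequency_classes(uni, rare_cutoff = 0.05)
  expect_equal(fc2$prop_rare, 0)
  fc3 <- frequency_classes(uni, rare_cutoff = 0.11)
  expect_equal(fc3$prop_rare, 2 / 19)   # classes 1 and 2 (freqs .05, .10)
  expect_equal(fc3$prop_fixed + fc3$prop_rare + fc3$prop_intermediate, 1)
})

test_that("Mann-Whitney matches exact permutation enumeration", {
  expect_equal(mann_whitney(1:5, 1:5)$p, 1, tolerance = 0.05)
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p, 1)
  # independent oracle: exhaustive enumeration of all 70 arrangements
  exact_p <- function(a, b) {
    n <- length(a); vals <- c(a, b)
    obs_u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    combos <- combn(length(vals), n)
    us <- apply(combos, 2, function(i) {
      x <- vals[i]; y <- vals[-i]
      sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    })
    mu <- length(a) * length(b) / 2
    mean(abs(us - mu) >= abs(obs_u - mu) - 1e-12)
  }
  set.seed(11)
  for (i in 1:20) {
    a <- sample(1:50, 4); b <- sample(51:100, 4) / 2 + 0.25
    expect_lt(abs(mann_whitney(a, b)$p - exact_p(a, b)), 1e-9)
  }
})
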
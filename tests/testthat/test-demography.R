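test_that("model catalog instantiates all fifteen templates", {
  cat15 <- model_catalog()
  expect_length(cat15, 15L)
  # one-step isolation: a single divergence time, no T2
  expect_false("T2" %in% cat15$model1$param_names)
  expect_true("T2" %in% cat15$model2$param_names)
  # the composite model nests the divergence model
  expect_gt(cat15$model15$k, cat15$model1$k)
  # every template simulates at its default (midpoint) parameters
  for (m in cat15) {
    es <- expected_sfs(m, sample_sizes = c(4, 4, 4), n_sims = 60,
                       seed = 2)
    expect_true(all(es$entries >= 0))
    expect_lt(abs(sum(es$entries) - 1), 1e-9)
  }
})

test_that("expected SFS obeys the neutral 1/i law and divergence limits", {
  s <- expected_sfs(const_model(2000), sample_sizes = 6, n_sims = 8000,
                    seed = 7)
  target <- (1 / 1:5) / sum(1 / 1:5)
  expect_lt(max(abs(s$entries[2:6] - target)), 0.01)
  # very old split, no migration: mass concentrates near the
  # fixed-difference corner cells (0, mB) and (mA, 0)
  old <- split2_model(defaults = c(N1 = 2000, N2 = 2000, T = 2e4))
  es <- expected_sfs(old, sample_sizes = c(6, 6), n_sims = 2000, seed = 3)
  fixed_cells <- es$entries[1, 7] + es$entries[7, 1]
  expect_gt(fixed_cells, 0.5)
})

test_that("composite log-likelihood evaluates and scales correctly", {
  mk_sfs <- function(v) structure(list(entries = v, pops = "A",
                                       sample_sizes = length(v) - 1L,
                                       polarized = TRUE), class = "sfs")
  obs <- mk_sfs(c(0, 5, 5, 0))
  ex <- mk_sfs(c(0, 0.5, 0.5, 0))
  expect_equal(composite_loglik(obs, ex), 10 * log(0.5))
  # maximal at the truth among perturbed expectations
  truth <- c(0, 0.7, 0.3, 0)
  obs2 <- mk_sfs(truth * 1000)
  ll0 <- composite_loglik(obs2, mk_sfs(truth))
  for (eps in c(-0.1, 0.1)) {
    pert <- c(0, 0.7 + eps, 0.3 - eps, 0)
    expect_lt(composite_loglik(obs2, mk_sfs(pert)), ll0)
  }
  # corner cells are ignored
  obs3 <- mk_sfs(c(99, 5, 5, 42))
  expect_equal(composite_loglik(obs3, ex), 10 * log(0.5))
  # linear in total count
  expect_equal(composite_loglik(mk_sfs(c(0, 50, 50, 0)), ex),
               10 * composite_loglik(obs, ex))
  expect_error(composite_loglik(obs, mk_sfs(c(0, 1, 0))), "shapes differ")
})

test_that("ECM fitting recovers a one-parameter bottleneck size", {
  # single population resized to a fixed ancestral 5000 at generation
  # 2000; the free current size changes the SFS shape
  m1 <- demographic_model("onep", "A", "N", c(N = 50), c(N = 1e5),
    c(N = "log"),
    build = function(p)
      list(sizes0 = p[["N"]], growth0 = 0, mig = matrix(0, 1, 1),
           events = locadapt:::.event(2000, 1, 0, size = 5000)),
    defaults = c(N = 20000))
  truth <- c(N = 1000)
  es <- expected_sfs(m1, truth, sample_sizes = 12, n_sims = 6000, seed = 5)
  set.seed(6)
  counts <- rmultinom(1, 20000, as.vector(es$entries))[, 1]
  obs <- es
  obs$entries <- counts
  fit <- fit_model(obs, m1, n_sims = 8000, n_starts = 2, cycles = 10,
                   seed = 9)
  expect_lt(abs(fit$params[["N"]] - 1000) / 1000, 0.10)
  # collapsed bounds return the pinned point
  m2 <- m1; m2$lower <- c(N = 1000); m2$upper <- c(N = 1000)
  fit2 <- fit_model(obs, m2, n_sims = 400, n_starts = 1, cycles = 2,
                    seed = 1)
  expect_equal(fit2$params[["N"]], 1000)
  # determinism under a fixed seed
  fit3 <- fit_model(obs, m2, n_sims = 400, n_starts = 1, cycles = 2,
                    seed = 1)
  expect_equal(fit2$lnL, fit3$lnL)
})

test_that("AIC comparison reproduces printed deltas and Akaike weights", {
  tab <- compare_models(data.frame(model = c("model15", "model10"),
                                   aic = c(2178865.27, 2182730.53)))
  expect_equal(tab$dAIC[tab$model == "model10"], 3865.26)
  expect_equal(tab$dAIC[tab$model == "model15"], 0)
  one <- compare_models(data.frame(model = "m", lnL = -10, k = 3))
  expect_equal(one$weight, 1)
  two <- compare_models(data.frame(model = c("a", "b"), aic = c(10, 12)))
  expect_equal(two$weight,
               c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(sum(two$weight), 1, tolerance = 1e-12)
})

test_that("parametric bootstrap is seeded and covers the MLE", {
  m <- split2_model(defaults = c(N1 = 4000, N2 = 1500, T = 2500))
  mle <- c(N1 = 4000, N2 = 1500, T = 2500)
  bt <- parametric_bootstrap(m, mle, c(6, 6), n_snps = 20000, n_boot = 4,
                             n_sims = 300, n_starts = 1, cycles = 3,
                             seed = 21)
  bt2 <- parametric_bootstrap(m, mle, c(6, 6), n_snps = 20000, n_boot = 4,
                              n_sims = 300, n_starts = 1, cycles = 3,
                              seed = 21)
  expect_identical(bt$estimates, bt2$estimates)
  expect_true(all(mle >= bt$ci[1, names(mle)] - 1e-9))
  expect_true(all(mle <= bt$ci[2, names(mle)] + 1e-9))
  expect_warning(parametric_bootstrap(m, mle, c(6, 6), 1000, n_boot = 0),
                 "empty")
})

test_that("unit scaling reproduces the printed migration and time values", {
  out <- scale_units(params = c(T1 = 4654, NANC = 57833), mu = 7.86e-8,
                     gen_time = 20, Ne_source = 6142, m = 6.35e-4)
  expect_equal(unname(out$years["T1"]), 93080)
  expect_equal(round(out$Nm, 2), 3.90)
  g1 <- scale_units(params = c(T1 = 777), mu = 1e-8, gen_time = 1)
  expect_equal(unname(g1$years["T1"]), 777)
  expect_error(scale_units(params = c(T1 = 1), mu = 1e-8), "gen_time")
})
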
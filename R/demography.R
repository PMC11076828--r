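# SFS-based demographic inference: model templates, expected SFS by
# structured-coalescent simulation, composite likelihood, ECM fitting,
# AIC/Akaike-weight comparison, parametric bootstrap, unit conversions.

.no_events <- function() {
  data.frame(time = numeric(), type = integer(), p1 = integer(),
             p2 = integer(), size = numeric(), growth = numeric(),
             rate = numeric())
}

.event <- function(time, type, p1, p2 = -1L, size = NA_real_,
                   growth = 0, rate = 0) {
  data.frame(time = time, type = as.integer(type), p1 = as.integer(p1),
             p2 = as.integer(p2), size = size, growth = growth, rate = rate)
}

# forward migration rates list(src, dst, m) -> backward lineage-movement
# matrix: a lineage in the destination deme traces back to the source at
# rate m
.mig_matrix <- function(npop, rates) {
  M <- matrix(0, npop, npop)
  for (r in rates) M[r$dst + 1, r$src + 1] <- M[r$dst + 1, r$src + 1] + r$m
  M
}

#' Define a demographic model template
#'
#' A template couples free-parameter metadata (names, bounds, log/linear
#' search scale) with a builder mapping a named parameter vector to the
#' coalescent-engine description (initial deme sizes and growth rates,
#' backward migration matrix, event table).
#'
#' @param id model identifier.
#' @param pops sampled population labels in deme order.
#' @param param_names free parameter names.
#' @param lower,upper named bounds.
#' @param scale per-parameter search scale, "log" or "linear".
#' @param build function(named params) -> list(sizes0, growth0, mig, events).
#' @param defaults midpoint/default parameter values.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(id, pops, param_names, lower, upper, scale,
                              build, defaults) {
  structure(list(id = id, pops = pops, param_names = param_names,
                 lower = lower[param_names], upper = upper[param_names],
                 scale = scale[param_names], build = build,
                 defaults = defaults[param_names],
                 k = length(param_names)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic model", x$id, "|", length(x$pops), "populations |",
      x$k, "free parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Catalog of three-population demographic models
#'
#' Fifteen templates for populations F, S and W (demes 0, 1, 2): models 1-4
#' are pure-divergence histories (one-step trichotomy, then the three
#' two-step orders); 5-7 add a bottleneck-with-recovery in one population;
#' 8-10 add exponential size change in one population; 11-14 add asymmetric
#' migration configurations; model 15 is the composite (one-step divergence
#' + bottleneck in S + exponential expansion in F + the full asymmetric
#' migration of model 14). Default parameter values echo the fitted
#' composite history (ancestral Ne 57,833; split ~4,654 generations ago;
#' F at 6,142 with growth 1.05e-4; S at 17,072 with a bottleneck; W at 778;
#' migration mainly F->W and S->W).
#'
#' @param mu mutation rate per site per generation (default 7.86e-8).
#' @param gen_time years per generation (default 20).
#' @return named list of 15 `demographic_model` templates.
#' @export
model_catalog <- function(mu = 7.86e-8, gen_time = 20) {
  pops <- c("F", "S", "W")
  base_names <- c("NANC", "NF", "NS", "NW", "T1")
  lo <- c(NANC = 100, NF = 50, NS = 50, NW = 50, T1 = 100, T2 = 50,
          NB = 10, TB0 = 50, TB1 = 100, g = 1e-7,
          m_FW = 1e-8, m_SW = 1e-8, m_SF = 1e-8, m_WF = 1e-8,
          m_WS = 1e-8, m_FS = 1e-8)
  hi <- c(NANC = 5e5, NF = 2e5, NS = 2e5, NW = 2e5, T1 = 5e4, T2 = 5e4,
          NB = 1e5, TB0 = 5e4, TB1 = 5e4, g = 5e-3,
          m_FW = 5e-2, m_SW = 5e-2, m_SF = 5e-2, m_WF = 5e-2,
          m_WS = 5e-2, m_FS = 5e-2)
  sc <- setNames(rep("log", length(lo)), names(lo))
  def <- c(NANC = 57833, NF = 6142, NS = 17072, NW = 778, T1 = 4654,
           T2 = 2300, NB = 1707, TB0 = 1750, TB1 = 2250, g = 1.05e-4,
           m_FW = 6.35e-4, m_SW = 2.62e-4, m_SF = 1.48e-4, m_WF = 6.4e-5,
           m_WS = 2.6e-5, m_FS = 1.0e-4)
  mig_all <- c("m_FW", "m_SW", "m_SF", "m_WF", "m_WS", "m_FS")
  src_of <- c(m_FW = 0, m_SW = 1, m_SF = 1, m_WF = 2, m_WS = 2, m_FS = 0)
  dst_of <- c(m_FW = 2, m_SW = 2, m_SF = 0, m_WF = 0, m_WS = 1, m_FS = 1)

  # shared event scaffolding -------------------------------------------
  base_events <- function(p, order = NULL) {
    # order NULL: one-step trichotomy at T1; otherwise c(a, b) merge demes
    # a and b at T2, then the pair joins the third at T1
    if (is.null(order)) {
      ev <- rbind(.event(p[["T1"]], 0, 1, 0), .event(p[["T1"]], 0, 2, 0),
                  .event(p[["T1"]], 1, 0, size = p[["NANC"]]))
    } else {
      third <- setdiff(0:2, order)
      ev <- rbind(.event(p[["T2"]], 0, order[2], order[1]),
                  .event(p[["T1"]], 0, third, order[1]),
                  .event(p[["T1"]], 1, order[1], size = p[["NANC"]]))
    }
    ev[order(ev$time, ev$type), ]
  }
  sizes_of <- function(p) c(p[["NF"]], p[["NS"]], p[["NW"]])

  make_div <- function(id, order) {
    nm <- if (is.null(order)) base_names else c(base_names, "T2")
    demographic_model(id, pops, nm, lo, hi, sc, defaults = def,
      build = function(p) {
        ev <- base_events(p, order)
        list(sizes0 = sizes_of(p), growth0 = c(0, 0, 0),
             mig = matrix(0, 3, 3), events = ev)
      })
  }
  make_bneck <- function(id, deme) {
    nm <- c(base_names, "NB", "TB0", "TB1")
    demographic_model(id, pops, nm, lo, hi, sc, defaults = def,
      build = function(p) {
        sz <- sizes_of(p)
        ev <- rbind(base_events(p, NULL),
                    .event(min(p[["TB0"]], p[["T1"]] * 0.95), 1, deme,
                           size = p[["NB"]]),
                    .event(min(p[["TB1"]], p[["T1"]] * 0.99), 1, deme,
                           size = sz[deme + 1]))
        ev <- ev[order(ev$time, ev$type), ]
        list(sizes0 = sz, growth0 = c(0, 0, 0),
             mig = matrix(0, 3, 3), events = ev)
      })
  }
  make_growth <- function(id, deme) {
    nm <- c(base_names, "g")
    demographic_model(id, pops, nm, lo, hi, sc, defaults = def,
      build = function(p) {
        gr <- c(0, 0, 0); gr[deme + 1] <- p[["g"]]
        ev <- rbind(base_events(p, NULL),
                    .event(p[["T1"]] * 0.999, 1, deme,
                           size = sizes_of(p)[deme + 1] *
                             exp(-p[["g"]] * p[["T1"]])))
        ev <- ev[order(ev$time, ev$type), ]
        list(sizes0 = sizes_of(p), growth0 = gr,
             mig = matrix(0, 3, 3), events = ev)
      })
  }
  make_mig <- function(id, which_m) {
    nm <- c(base_names, which_m)
    demographic_model(id, pops, nm, lo, hi, sc, defaults = def,
      build = function(p) {
        rates <- lapply(which_m, function(mn)
          list(src = src_of[[mn]], dst = dst_of[[mn]], m = p[[mn]]))
        list(sizes0 = sizes_of(p), growth0 = c(0, 0, 0),
             mig = .mig_matrix(3, rates), events = base_events(p, NULL))
      })
  }
  composite <- local({
    nm <- c(base_names, "NB", "TB0", "TB1", "g", mig_all)
    demographic_model("model15", pops, nm, lo, hi, sc, defaults = def,
      build = function(p) {
        sz <- sizes_of(p)
        gr <- c(p[["g"]], 0, 0)
        rates <- lapply(mig_all, function(mn)
          list(src = src_of[[mn]], dst = dst_of[[mn]], m = p[[mn]]))
        ev <- rbind(base_events(p, NULL),
                    .event(min(p[["TB0"]], p[["T1"]] * 0.95), 1, 1,
                           size = p[["NB"]]),
                    .event(min(p[["TB1"]], p[["T1"]] * 0.99), 1, 1,
                           size = sz[2]),
                    .event(p[["T1"]] * 0.999, 1, 0,
                           size = sz[1] * exp(-p[["g"]] * p[["T1"]])))
        ev <- ev[order(ev$time, ev$type), ]
        list(sizes0 = sz, growth0 = gr, mig = .mig_matrix(3, rates),
             events = ev)
      })
  })
  models <- list(
    model1 = make_div("model1", NULL),
    model2 = make_div("model2", c(0, 1)),   # (F,S) first, then W
    model3 = make_div("model3", c(0, 2)),   # (F,W) first, then S
    model4 = make_div("model4", c(1, 2)),   # (S,W) first, then F
    model5 = make_bneck("model5", 0),
    model6 = make_bneck("model6", 1),
    model7 = make_bneck("model7", 2),
    model8 = make_growth("model8", 1),      # exponential change in S
    model9 = make_growth("model9", 2),      # exponential change in W
    model10 = make_growth("model10", 0),    # expansion in F
    model11 = make_mig("model11", "m_FW"),
    model12 = make_mig("model12", "m_SW"),
    model13 = make_mig("model13", c("m_FW", "m_SW")),
    model14 = make_mig("model14", mig_all),
    model15 = composite)
  for (m in names(models)) {
    models[[m]]$mu <- mu
    models[[m]]$gen_time <- gen_time
  }
  models
}

#' Expected SFS of a demographic model by coalescent simulation
#'
#' Averages branch-length contributions per joint derived-count cell over
#' `n_sims` structured-coalescent genealogies (low-variance alternative to
#' mutation dropping), then normalizes over polymorphic cells.
#'
#' @param model a `demographic_model`.
#' @param params named parameter vector (default: the template defaults).
#' @param sample_sizes haploid sample sizes per population.
#' @param n_sims number of genealogies (default 2000).
#' @param seed RNG seed.
#' @param normalize normalize over polymorphic cells (default TRUE).
#' @return an `sfs` object; attribute `total_branch` holds the mean total
#'   branch length in generations.
#' @export
expected_sfs <- function(model, params = NULL, sample_sizes, n_sims = 2000,
                         seed = 1, normalize = TRUE) {
  if (is.null(params)) params <- model$defaults
  spec <- model$build(as.list(params))
  set.seed(seed)
  arr <- coal_branch_sfs(spec$sizes0, spec$growth0, spec$mig, spec$events,
                         as.integer(sample_sizes), as.integer(n_sims))
  total <- sum(arr)
  d <- dim(arr)
  arr[matrix(1L, 1, length(d))] <- 0
  arr[matrix(d, 1, length(d))] <- 0
  if (sum(arr) == 0) stop("zero polymorphic mass")
  if (normalize) arr <- arr / sum(arr)
  structure(list(entries = arr, pops = model$pops,
                 sample_sizes = as.integer(sample_sizes), polarized = TRUE,
                 n_dropped = 0L),
            class = "sfs", total_branch = total)
}

#' Composite log-likelihood of an observed SFS
#'
#' lnL = sum over polymorphic cells of O_c ln(E_c), with expected
#' probabilities floored at `eps`; monomorphic corner cells are excluded.
#'
#' @param obs_sfs,exp_sfs `sfs` objects with matching dimensions (expected
#'   normalized over polymorphic cells).
#' @param eps floor for empty expected cells (default 1e-10).
#' @return scalar log-likelihood.
#' @export
composite_loglik <- function(obs_sfs, exp_sfs, eps = 1e-10) {
  O <- obs_sfs$entries; E <- exp_sfs$entries
  if (!identical(dim(as.array(O)), dim(as.array(E))) &&
      length(O) != length(E))
    stop("observed and expected SFS shapes differ")
  O <- as.array(O); E <- as.array(E)
  d <- if (is.null(dim(O))) length(O) else dim(O)
  O <- array(O, d); E <- array(E, d)
  idx1 <- matrix(1L, 1, length(d)); idx2 <- matrix(d, 1, length(d))
  O[idx1] <- 0; O[idx2] <- 0
  sum(O * log(pmax(E, eps)))
}

#' Fit a demographic model by ECM coordinate maximization
#'
#' Cyclic coordinate-wise maximization of the composite log-likelihood over
#' the free parameters, with multiplicative (log-scale) candidate steps that
#' shrink over cycles, from `n_starts` log-uniform random starts within the
#' bounds. Within one start, every likelihood evaluation reuses a common
#' random seed for the expected-SFS simulation so the search surface is
#' deterministic.
#'
#' @param obs_sfs observed joint `sfs` (counts).
#' @param model a `demographic_model`.
#' @param n_sims genealogies per likelihood evaluation.
#' @param n_starts random restarts (default 10).
#' @param cycles coordinate cycles per start (default 20).
#' @param seed RNG seed.
#' @return object of class `locadapt_demfit`: `params`, `lnL`, `AIC`, `k`,
#'   `model_id`, per-start traces.
#' @export
fit_model <- function(obs_sfs, model, n_sims = 1000, n_starts = 10,
                      cycles = 20, seed = 1) {
  lower <- model$lower; upper <- model$upper
  nm <- model$param_names
  sample_sizes <- obs_sfs$sample_sizes
  eval_ll <- function(p, sim_seed) {
    es <- try(expected_sfs(model, p, sample_sizes, n_sims, seed = sim_seed),
              silent = TRUE)
    if (inherits(es, "try-error")) return(-Inf)
    composite_loglik(obs_sfs, es)
  }
  set.seed(seed)
  start_seeds <- sample.int(2^30, n_starts)
  best <- NULL
  traces <- numeric(n_starts)
  for (st in seq_len(n_starts)) {
    set.seed(start_seeds[st])
    sim_seed <- sample.int(2^30, 1)
    p <- setNames(exp(runif(length(nm), log(lower), log(upper))), nm)
    if (st == 1 && !is.null(model$defaults) &&
        all(is.finite(unlist(model$defaults))))
      p <- setNames(pmin(pmax(unlist(model$defaults)[nm], lower), upper), nm)
    ll <- eval_ll(p, sim_seed)
    for (cy in seq_len(cycles)) {
      width <- 2^(2 * 0.6^(cy - 1))     # geometrically shrinking step
      improved <- FALSE
      for (j in nm) {
        cand <- p[[j]] * c(1 / width^2, 1 / width, width, width^2)
        cand <- pmin(pmax(cand, lower[[j]]), upper[[j]])
        cand <- setdiff(unique(cand), p[[j]])
        for (v in cand) {
          p2 <- p; p2[[j]] <- v
          ll2 <- eval_ll(p2, sim_seed)
          if (ll2 > ll) { p <- p2; ll <- ll2; improved <- TRUE }
        }
      }
      if (!improved && cy > 3) break
    }
    # score the final point with a fresh seed to avoid CRN-optimism
    ll_final <- eval_ll(p, sim_seed)
    traces[st] <- ll_final
    if (is.null(best) || ll_final > best$lnL)
      best <- list(params = p, lnL = ll_final)
  }
  if (is.null(best) || !is.finite(best$lnL))
    stop("non-finite likelihood at every start")
  structure(list(model_id = model$id, params = best$params, lnL = best$lnL,
                 k = model$k, AIC = 2 * model$k - 2 * best$lnL,
                 start_lnL = traces, n_sims = n_sims),
            class = "locadapt_demfit")
}

#' @export
print.locadapt_demfit <- function(x, ...) {
  cat("demographic fit:", x$model_id, "| lnL =", signif(x$lnL, 8),
      "| AIC =", signif(x$AIC, 8), "| k =", x$k, "\n")
  print(signif(unlist(x$params), 4))
  invisible(x)
}

#' Compare fitted demographic models by AIC
#'
#' AIC = 2k - 2 lnL (or a supplied AIC); delta-AIC against the minimum;
#' Akaike weights exp(-delta/2) normalized over the compared set.
#'
#' @param fits list of `locadapt_demfit` objects, or a data.frame with
#'   columns `model` and either `aic` or both `lnL` and `k`.
#' @return data.frame `model lnL k AIC dAIC weight`, ranked by AIC.
#' @export
compare_models <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits
    if (!"aic" %in% names(tab)) tab$aic <- 2 * tab$k - 2 * tab$lnL
    tab <- data.frame(model = tab$model,
                      lnL = if ("lnL" %in% names(tab)) tab$lnL else NA,
                      k = if ("k" %in% names(tab)) tab$k else NA,
                      AIC = tab$aic)
  } else {
    tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$model_id, lnL = f$lnL, k = f$k, AIC = f$AIC)))
  }
  tab$dAIC <- tab$AIC - min(tab$AIC)
  w <- exp(-tab$dAIC / 2)
  tab$weight <- w / sum(w)
  tab[order(tab$AIC), ]
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `n_boot` observed SFS (multinomial draws of `n_snps` sites from
#' the expected SFS at the fitted parameters), refits each, and returns
#' 2.5/97.5 percentile intervals per parameter. Refit failures are dropped
#' and counted.
#'
#' @param model a `demographic_model`.
#' @param mle_params fitted parameter vector.
#' @param sample_sizes haploid sample sizes per population.
#' @param n_snps number of sites per bootstrap replicate.
#' @param n_boot bootstrap replicates (default 20).
#' @param n_sims,n_starts,cycles refit settings (reduced by default).
#' @param seed RNG seed.
#' @return list with `ci` (2 x k matrix of 2.5/97.5 percentiles),
#'   `estimates` (replicates x k), and `n_failed`.
#' @export
parametric_bootstrap <- function(model, mle_params, sample_sizes, n_snps,
                                 n_boot = 20, n_sims = 500, n_starts = 1,
                                 cycles = 6, seed = 1) {
  if (n_boot == 0) {
    warning("n_boot = 0: empty confidence intervals")
    return(list(ci = NULL, estimates = NULL, n_failed = 0L))
  }
  truth <- expected_sfs(model, mle_params, sample_sizes,
                        n_sims = max(2000, n_sims), seed = seed)
  probs <- as.vector(truth$entries)
  # refits start from the fitted point (standard bootstrap practice)
  model$defaults <- mle_params
  ests <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    counts <- stats::rmultinom(1, n_snps, probs)[, 1]
    obs <- truth
    obs$entries <- array(counts, dim = dim(as.array(truth$entries)))
    fit <- try(fit_model(obs, model, n_sims = n_sims, n_starts = n_starts,
                         cycles = cycles, seed = seed * 1000 + b),
               silent = TRUE)
    if (inherits(fit, "try-error")) { n_failed <- n_failed + 1L; next }
    ests[[length(ests) + 1]] <- unlist(fit$params)
  }
  if (length(ests) == 0)
    return(list(ci = NULL, estimates = NULL, n_failed = n_failed))
  est <- do.call(rbind, ests)
  ci <- apply(est, 2, stats::quantile, probs = c(0.025, 0.975))
  list(ci = ci, estimates = est, n_failed = n_failed)
}

#' Convert coalescent-scale estimates to years and migrant numbers
#'
#' Times in generations are multiplied by the generation time; expected
#' migrants per generation Nm(source -> dest) multiply the source
#' population's (final-epoch) Ne by the forward migration rate.
#'
#' @param params named list/vector with entries in per-generation units;
#'   names matching `T*` are treated as times.
#' @param mu mutation rate per site per generation.
#' @param gen_time years per generation.
#' @param Ne_source,m optional: when both given, `Nm` is returned.
#' @return list with `years` (for every T* parameter), `theta_per_site`
#'   scaling factor 4 Ne mu when an `NANC` entry is present, and `Nm` when
#'   Ne_source and m are supplied.
#' @export
scale_units <- function(params = NULL, mu, gen_time, Ne_source = NULL,
                        m = NULL) {
  if (missing(mu) || missing(gen_time)) stop("mu and gen_time are required")
  out <- list()
  if (!is.null(params)) {
    pv <- unlist(params)
    tnames <- grep("^T", names(pv), value = TRUE)
    out$years <- pv[tnames] * gen_time
    if ("NANC" %in% names(pv))
      out$theta_per_site <- 4 * pv[["NANC"]] * mu
  }
  if (!is.null(Ne_source) && !is.null(m)) out$Nm <- Ne_source * m
  out
}
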
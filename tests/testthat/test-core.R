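test_that("conditional similarity matches the closed-form densities", {
  fam <- gaussian_family()
  # density peak of a normal with variance 1/(2*pi) equals 1
  comp <- dl_component(fam, params = list(mean = 0.3), spread = 1 / (2 * pi))
  expect_equal(dl_conditional_similarity(comp, 0.3), 1, tolerance = 1e-12)
  # N(0; 2, 1) = exp(-2) / sqrt(2*pi)
  comp2 <- dl_component(fam, params = list(mean = 2), spread = 1)
  expect_equal(dl_conditional_similarity(comp2, 0), exp(-2) / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(dl_conditional_similarity(comp2, 0), 0.05399097,
               tolerance = 1e-7)
  # uniform clutter has density 1 / range everywhere on its support
  cl <- uniform_clutter_family(0, 4)$spawn(matrix(1), 1L, 1)
  expect_equal(dl_conditional_similarity(cl, 2.5), 0.25)
  # dimension mismatch and nonpositive spread are rejected
  expect_error(dl_conditional_similarity(comp2, c(0, 0)), "dimension")
  expect_error(dl_component(fam, params = list(mean = 0), spread = -1),
               "spread")
})

test_that("total log-similarity follows the product-sum definition", {
  x <- matrix(0.5)
  one <- uniform_clutter_family(0, 1)$spawn(x, 1L, 1)   # l = 1 everywhere
  one$role <- "model"
  expect_equal(dl_total_log_similarity(matrix(c(0.1, 0.5, 0.9)), list(one)), 0)
  # r = 0.5 each, l = 0.2 and 0.6 for a single datum -> log(0.4)
  m1 <- uniform_clutter_family(0, 5)$spawn(x, 1L, 0.5)
  m2 <- uniform_clutter_family(0, 5 / 3)$spawn(x, 2L, 0.5)
  expect_equal(dl_total_log_similarity(x, list(m1, m2)), log(0.4),
               tolerance = 1e-12)
  expect_error(dl_total_log_similarity(x, list()), "active")
})

test_that("total log-similarity agrees with a brute-force term-by-term sum", {
  fam <- gaussian_family()
  X <- matrix(c(-1.2, 0.4, 2.5))
  mods <- list(
    dl_component(fam, params = list(mean = -1), spread = 0.8, r = 0.3, index = 1),
    dl_component(fam, params = list(mean = 2), spread = 1.5, r = 0.7, index = 2))
  brute <- sum(log(
    0.3 * dnorm(X[, 1], -1, sqrt(0.8)) + 0.7 * dnorm(X[, 1], 2, sqrt(1.5))))
  expect_equal(dl_total_log_similarity(X, mods), brute, tolerance = 1e-12)
})

test_that("the skeptic penalty subtracts kappa per free parameter", {
  fam <- gaussian_family()   # D + 1 free parameters per component
  m3 <- dl_component(fam, params = list(mean = c(0, 0, 0)), spread = 1)
  expect_equal(dl_penalized_similarity(-10, list(m3), N = 20, penalty = "aic"),
               -14)
  cl <- uniform_clutter_family(0, 1)$spawn(matrix(1), 1L, 1)  # 0 free params
  expect_equal(dl_penalized_similarity(-10, list(cl), N = 20, penalty = "aic"),
               -10)
  # adding a model with k parameters lowers the penalized value by kappa * k
  both <- dl_penalized_similarity(-10, list(m3, cl), N = 20, penalty = "aic")
  one <- dl_penalized_similarity(-10, list(cl), N = 20, penalty = "aic")
  expect_equal(one - both, 4)
  expect_error(dl_penalized_similarity(-10, list(m3), N = 0), "positive")
})

test_that("association variables normalize and follow the likelihood ratio", {
  fam <- gaussian_family()
  x <- matrix(0)
  solo <- dl_component(fam, params = list(mean = 1), spread = 1, r = 1)
  expect_equal(as.numeric(dl_associations(x, list(solo))), 1)
  # equidistant symmetric models split responsibility evenly
  sym <- list(dl_component(fam, params = list(mean = -1), spread = 1, r = 0.5, index = 1),
              dl_component(fam, params = list(mean = 1), spread = 1, r = 0.5, index = 2))
  expect_equal(as.numeric(dl_associations(x, sym)), c(0.5, 0.5))
  # means 0 and 2, unit variance, datum 0: f(1|x) = 1 / (1 + exp(-2))
  two <- list(dl_component(fam, params = list(mean = 0), spread = 1, r = 0.5, index = 1),
              dl_component(fam, params = list(mean = 2), spread = 1, r = 0.5, index = 2))
  f <- dl_associations(x, two)
  expect_equal(f[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(f[1, 1], 0.8807971, tolerance = 1e-7)
})

test_that("association columns sum to one for random model sets", {
  fam <- gaussian_family()
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(40 * 2), ncol = 2)
    mods <- lapply(1:3, function(k)
      dl_component(fam, params = list(mean = rnorm(2)), spread = runif(1, 0.5, 2),
                   r = 1 / 3, index = k))
    f <- dl_associations(X, mods)
    expect_true(all(abs(colSums(f) - 1) < 1e-9))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("f-weighted updates are the weighted maximum-likelihood step", {
  fam <- gaussian_family(estimate_spread = FALSE)
  mods <- list(dl_component(fam, params = list(mean = 5), spread = 1))
  X <- matrix(c(0, 2))
  f <- matrix(1, 1, 2)
  up <- dl_update_parameters(X, mods, f)
  expect_equal(up[[1]]$params$mean, 1)
  # Bernoulli: bits {1, 1, 0} with unit weights -> p = 2/3
  bf <- bernoulli_family()
  bm <- list(dl_component(bf, params = list(p = 0.5), spread = 1))
  upb <- dl_update_parameters(matrix(c(1, 1, 0), ncol = 1), bm, matrix(1, 1, 3))
  expect_equal(upb[[1]]$params$p, 2 / 3, tolerance = 1e-9)
  # a model with negligible total weight is left unchanged and flagged
  low <- dl_update_parameters(X, mods, matrix(1e-9, 1, 2), w_floor = 1e-6)
  expect_equal(low[[1]]$params$mean, 5)
  expect_equal(attr(low, "review"), mods[[1]]$index)
})

test_that("an update step never decreases the log-similarity (EM step)", {
  X <- two_cluster_data(n = 10, sep = 4, seed = 3)
  fam <- gaussian_family()
  mods <- list(dl_component(fam, params = list(mean = -1), spread = 2, r = 0.5, index = 1),
               dl_component(fam, params = list(mean = 1), spread = 2, r = 0.5, index = 2))
  ll0 <- dl_total_log_similarity(X, mods)
  f <- dl_associations(X, mods)
  up <- dl_update_parameters(X, mods, f)
  up <- dl_update_rates(f, nrow(X), up)
  expect_gte(dl_total_log_similarity(X, up), ll0 - 1e-10)
  # and matches an independently coded EM step
  o <- oracle_em_gaussian(X, list(-1, 1), c(2, 2), c(0.5, 0.5), iters = 2)
  expect_equal(dl_total_log_similarity(X, up), o$loglik[2], tolerance = 1e-9)
})

test_that("rate updates renormalize over the whole model store", {
  fam <- gaussian_family()
  solo <- list(dl_component(fam, params = list(mean = 0), spread = 1))
  up <- dl_update_rates(matrix(1, 1, 4), 4, solo)
  expect_equal(up[[1]]$r, 1)
  two <- list(dl_component(fam, params = list(mean = 0), spread = 1, index = 1),
              dl_component(fam, params = list(mean = 1), spread = 1, index = 2))
  f <- rbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  up2 <- dl_update_rates(f, 10, two)
  expect_equal(vapply(up2, function(m) m$r, numeric(1)), c(0.5, 0.5))
  # with a dormant model the total still sums to one
  dorm <- dl_component(fam, params = list(mean = 9), spread = 1, index = 3,
                       status = "dormant")
  up3 <- dl_update_rates(f, 10, c(two, list(dorm)), r_floor = 1e-6)
  expect_equal(sum(vapply(up3, function(m) m$r, numeric(1))), 1,
               tolerance = 1e-9)
})

test_that("activation and deactivation follow the rate threshold", {
  fam <- gaussian_family()
  mk <- function(r, status, idx) {
    dl_component(fam, params = list(mean = 0), spread = 1, r = r,
                 index = idx, status = status)
  }
  out <- dl_activate_deactivate(list(mk(0.2, "dormant", 1)), 0.1)
  expect_equal(out[[1]]$status, "active")
  out2 <- dl_activate_deactivate(list(mk(0.001, "active", 1),
                                      mk(0.9, "active", 2)), 0.01)
  expect_equal(out2[[1]]$status, "dormant")
  # when everything falls below threshold, the best model is retained
  out3 <- dl_activate_deactivate(list(mk(0.004, "active", 1),
                                      mk(0.006, "active", 2)), 0.5)
  expect_equal(vapply(out3, function(m) m$status, character(1)),
               c("dormant", "active"))
})

test_that("fit recovers a single Gaussian and honors degenerate tolerance", {
  set.seed(21)
  X <- matrix(rnorm(200, mean = 1.7, sd = 1))
  fit <- dl_fit(X, gaussian_family(),
                dl_config(n_models_init = 1, n_dormant = 0), seed = 1)
  se <- 1 / sqrt(200)
  expect_lt(abs(active_models(fit$models)[[1]]$params$mean - 1.7), 3 * se)
  # infinite tolerance: return immediately, not converged
  f0 <- dl_fit(X, gaussian_family(),
               dl_config(n_models_init = 1, n_dormant = 0, tol = Inf), seed = 1)
  expect_equal(f0$iteration, 0L)
  expect_false(f0$converged)
})

test_that("fit trajectory equals an independent textbook EM run", {
  X <- two_cluster_data(n = 50, sep = 8, seed = 7)
  fam <- gaussian_family()
  set.seed(31)
  init <- list(fam$spawn(X, 1, 0.5), fam$spawn(X, 2, 0.5))
  mu0 <- lapply(init, function(m) m$params$mean)
  s20 <- vapply(init, function(m) m$spread, numeric(1))
  cfg <- dl_config(n_models_init = 2, n_dormant = 0, penalty = "none",
                   prune = FALSE, tol = 1e-12, max_iter = 25)
  fit <- dl_fit(X, fam, cfg, seed = 5, init_models = init)
  o <- oracle_em_gaussian(X, mu0, s20, c(0.5, 0.5),
                          iters = length(fit$loglik_trace))
  expect_equal(fit$loglik_trace, o$loglik, tolerance = 1e-6)
  expect_lt(abs(tail(fit$loglik_trace, 1) - tail(o$loglik, 1)), 1e-6)
})

test_that("identical seeds reproduce the trace bit for bit", {
  X <- two_cluster_data(n = 40, sep = 6, seed = 9)
  cfg <- dl_config(n_models_init = 2, n_dormant = 2, max_iter = 50)
  f1 <- dl_fit(X, gaussian_family(), cfg, seed = 123)
  f2 <- dl_fit(X, gaussian_family(), cfg, seed = 123)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_identical(summary(f1), summary(f2))
})

test_that("fitting is vague to crisp: spread shrinks, associations sharpen", {
  X <- two_cluster_data(n = 60, sep = 10, seed = 13)   # separation >> sd
  fam <- gaussian_family()
  cfg <- dl_config(n_models_init = 2, n_dormant = 0, max_iter = 100,
                   trace_models = TRUE, prune = FALSE)
  fit <- dl_fit(X, fam, cfg, seed = 2)
  spreads <- vapply(fit$model_trace, function(ms)
    mean(vapply(active_models(ms), function(m) m$spread, numeric(1))),
    numeric(1))
  # eventually non-increasing (after the first refinement)
  expect_true(all(diff(spreads[-1]) <= 1e-8))
  expect_lt(tail(spreads, 1), spreads[1])
  f_init <- t(dl_associations(X, fit$model_trace[[1]]))
  f_final <- t(dl_associations(X, fit$models))
  expect_lte(mean(nmfdl:::row_entropy(f_final)),
             mean(nmfdl:::row_entropy(f_init)) + 1e-12)
})

test_that("log-similarity traces are monotone for every model family", {
  # gaussian
  X <- two_cluster_data(n = 40, sep = 5, seed = 17)
  fg <- dl_fit(X, gaussian_family(),
               dl_config(n_models_init = 2, n_dormant = 1, max_iter = 60),
               seed = 3)
  # bernoulli
  g <- generate_situations(situation_gen_config(
    D = 40, K = 2, k_rel = 4, k_rand = 4, n_per_type = 25, n_clutter = 25,
    seed = 5))
  fb <- fit_situations(g$data, n_models = 4, seed = 5)
  # dual
  gd <- generate_dual(dual_gen_config(K = 2, D_L = 10, D_C = 16,
                                      k_rel_L = 3, k_rel_C = 4,
                                      n_per_concept = 30, seed = 6))
  fd <- fit_dual(gd$data, n_models = 4, seed = 6)
  for (fit in list(fg, fb, fd)) {
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-1]))))
  }
})
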
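test_that("cone signal follows the travelling-ring form", {
  p <- cone_params(x0 = 0, y0 = 0, t0 = 2, v = 1, a = 1.5, w = 1)
  # at onset the ring has radius zero: peak amplitude at the center
  expect_equal(cone_signal(p, 0, 0, 2), 1.5)
  # causality: nothing before onset
  expect_equal(cone_signal(p, 3, 0, 1.9), 0)
  expect_equal(cone_signal(p, 0, 0, -5), 0)
  # ring radius v * (t - t0) equals the sensor distance -> peak
  p2 <- cone_params(x0 = 0, y0 = 0, t0 = 0, v = 1, a = 2, w = 1)
  expect_equal(cone_signal(p2, 3, 0, 3), 2)
  # contracting ring with explicit R0 collapses linearly and clamps at 0
  p3 <- cone_params(x0 = 0, y0 = 0, t0 = 0, v = -2, a = 1, w = 1, R0 = 4)
  expect_equal(cone_signal(p3, 4, 0, 0), 1)       # radius 4 at onset
  expect_equal(cone_signal(p3, 0, 0, 2), 1)       # radius 0 at t = 2
  expect_equal(cone_signal(p3, 0, 0, 3), 1)       # still clamped at 0
  expect_error(cone_params(0, 0, 0, v = 0, a = 1, w = 1), "speed")
})

test_that("the scene generator is exact and deterministic", {
  dims <- c(8L, 8L, 5L)
  empty <- generate_phase_cones(cone_scene(list(), noise_sd = 0, seed = 1),
                                dims = dims)
  expect_true(all(empty$data == 0))
  p <- cone_params(x0 = 4, y0 = 4, t0 = 1, v = 1, a = 1, w = 1.5)
  one <- generate_phase_cones(cone_scene(list(p), noise_sd = 0, seed = 1),
                              dims = dims)
  g <- expand.grid(x = 1:8, y = 1:8, t = 1:5)
  expect_equal(as.numeric(one$data),
               cone_signal(p, g$x, g$y, g$t, T_end = 5), tolerance = 1e-12)
  n1 <- generate_phase_cones(cone_scene(list(p), noise_sd = 1, seed = 7), dims)
  n2 <- generate_phase_cones(cone_scene(list(p), noise_sd = 1, seed = 7), dims)
  expect_identical(as.numeric(n1$data), as.numeric(n2$data))
})

make_cone_comp <- function(x0, y0, t0, v, idx, dims = c(16, 16, 8),
                           a = 1, w = 2, r = 0.2) {
  fam <- cone_family(dims)
  dl_component(fam, params = list(
    par = list(x0 = x0, y0 = y0, t0 = t0, speed = abs(v), a = a, w = w),
    orientation = sign(v)), spread = 1, r = r, index = idx)
}

test_that("event classification counts signed speeds of active cones", {
  expect_equal(unname(classify_events(list(make_cone_comp(4, 4, 1, +0.8, 1)))),
               c(1, 0))
  mods <- list(make_cone_comp(4, 4, 1, +1, 1),
               make_cone_comp(10, 10, 2, +0.5, 2),
               make_cone_comp(8, 8, 1, -0.7, 3))
  expect_equal(unname(classify_events(mods)), c(2, 1))
  expect_equal(unname(classify_events(list())), c(0, 0))
})

test_that("recovery metrics match greedily and order-invariantly", {
  truth <- cone_scene(list(
    cone_params(4, 4, 1, v = 1, a = 1, w = 2),
    cone_params(12, 10, 2, v = -0.5, a = 1, w = 2, R0 = 3)))
  fitted <- list(make_cone_comp(4, 4, 1, +1, 1),
                 make_cone_comp(12, 10, 2, -0.5, 2))
  rm1 <- recovery_metrics(fitted, truth)
  expect_true(all(rm1$matches$matched))
  expect_equal(rm1$matches$center_error, c(0, 0))
  expect_equal(rm1$matches$v_error, c(0, 0))
  expect_equal(rm1$unmatched_fitted, 0)
  # an extra spurious model is reported
  rm2 <- recovery_metrics(c(fitted, list(make_cone_comp(1, 14, 5, 2, 3))),
                          truth)
  expect_equal(rm2$unmatched_fitted, 1)
  # permuting the fitted models leaves matched errors unchanged
  rm3 <- recovery_metrics(rev(fitted), truth)
  expect_equal(rm3$matches, rm1$matches)
  expect_error(recovery_metrics(fitted, cone_scene(list())), "at least one")
})

test_that("a noiseless planted cone is recovered on a small grid", {
  dims <- c(24L, 24L, 12L)
  p <- cone_params(x0 = 12, y0 = 11, t0 = 2, v = 1, a = 1, w = 2)
  gen <- generate_phase_cones(cone_scene(list(p), noise_sd = 0.05, seed = 2),
                              dims = dims)
  fit <- fit_cones(gen$data, n_models = 4, seed = 2,
                   config = dl_config(n_models_init = 4, n_dormant = 0,
                                      max_iter = 25, trace_models = TRUE))
  rm <- recovery_metrics(fit, gen$truth)$matches
  expect_true(rm$matched[1])
  expect_lt(rm$center_error[1], 0.5)
  expect_lt(rm$t0_error[1], 0.5)
  expect_lt(rm$v_error[1], 0.5)
  expect_true(rm$sign_correct[1])
  # vague-to-crisp: the matched ring width ends below its vague start
  w_trace <- vapply(fit$model_trace, function(ms) {
    cones <- nmfdl:::active_cones(ms)
    if (length(cones) == 0) return(NA_real_)
    min(vapply(cones, function(m) m$params$par[["w"]], numeric(1)))
  }, numeric(1))
  expect_lt(tail(w_trace, 1), w_trace[1])
})

test_that("pure noise yields no active cone events", {
  dims <- c(16L, 16L, 8L)
  gen <- generate_phase_cones(cone_scene(list(), noise_sd = 1, seed = 5),
                              dims = dims)
  # the sample-size-aware penalty: a 7-parameter ring can scavenge more
  # than 7 log-units from pure noise, but not more than the BIC cost
  fit <- fit_cones(gen$data, n_models = 3, seed = 5,
                   config = dl_config(n_models_init = 3, n_dormant = 0,
                                      penalty = "bic", max_iter = 15))
  expect_equal(unname(classify_events(fit)), c(0, 0))
  # the background clutter component survives
  expect_gte(length(active_models(fit)), 1)
})

test_that("cone fits are seed-reproducible", {
  dims <- c(16L, 16L, 8L)
  p <- cone_params(x0 = 8, y0 = 8, t0 = 1, v = 1, a = 1, w = 2)
  gen <- generate_phase_cones(cone_scene(list(p), noise_sd = 0.5, seed = 3),
                              dims = dims)
  cfg <- dl_config(n_models_init = 2, n_dormant = 0, max_iter = 6)
  f1 <- fit_cones(gen$data, n_models = 2, config = cfg, seed = 11)
  f2 <- fit_cones(gen$data, n_models = 2, config = cfg, seed = 11)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})
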
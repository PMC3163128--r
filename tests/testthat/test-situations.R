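test_that("the generator plants relevant sets exactly as configured", {
  cfg <- situation_gen_config(D = 20, K = 1, k_rel = 2, k_rand = 0,
                              n_per_type = 3, n_clutter = 0, seed = 1)
  g <- generate_situations(cfg)
  X <- as.matrix(g$data)
  expect_equal(dim(X), c(3, 20))
  expect_true(all(rowSums(X) == 2))
  expect_equal(unname(X[1, ]), unname(X[2, ]))
  expect_equal(unname(X[2, ]), unname(X[3, ]))

  cfg2 <- situation_gen_config(D = 60, K = 3, k_rel = 4, k_rand = 6,
                               n_per_type = 10, n_clutter = 8, seed = 2)
  g2 <- generate_situations(cfg2)
  X2 <- as.matrix(g2$data)
  imp <- g2$truth$type > 0
  expect_true(all(rowSums(X2[imp, ]) >= 4 & rowSums(X2[imp, ]) <= 10))
  # every instance of a type carries all of the type's relevant objects
  for (k in 1:3) {
    rows <- which(g2$truth$type == k)
    expect_true(all(X2[rows, g2$truth$relevant_sets[[k]]] == 1))
  }
  # determinism
  g2b <- generate_situations(cfg2)
  expect_identical(as.matrix(g2b$data), X2)
  # infeasible configurations are rejected
  expect_error(situation_gen_config(D = 10, K = 2, k_rel = 8, k_rand = 0),
               "disjoint")
})

test_that("bernoulli similarity is the product likelihood", {
  m <- dl_component(bernoulli_family(), params = list(p = rep(0.5, 10)),
                    spread = 1)
  x <- rbinom(10, 1, 0.5)
  expect_equal(bernoulli_similarity(m, x), 2^-10, tolerance = 1e-12)
  px <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  expect_equal(bernoulli_similarity(px, x), 1, tolerance = 1e-4)
  expect_equal(bernoulli_similarity(c(0.9, 0.1), c(1, 0)), 0.81,
               tolerance = 1e-12)
  expect_error(bernoulli_similarity(c(0.9, 0.1), c(1, 0, 1)), "dimension")
})

test_that("a single model fits the column means", {
  set.seed(4)
  X <- matrix(rbinom(200, 1, 0.3), 20, 10)
  fit <- fit_situations(X, n_models = 1, seed = 1)
  expect_equal(active_models(fit)[[1]]$params$p, unname(colMeans(X)),
               tolerance = 1e-9)
})

test_that("two repeated rows are separated into two crisp models", {
  r1 <- c(1, 1, 0, 0, 1, 0)
  r2 <- c(0, 0, 1, 1, 0, 1)
  X <- rbind(matrix(r1, 10, 6, byrow = TRUE), matrix(r2, 10, 6, byrow = TRUE))
  fit <- fit_situations(X, n_models = 2, seed = 3,
                        config = dl_config(n_models_init = 2, prune = FALSE))
  P <- round(do.call(rbind, lapply(active_models(fit),
                                   function(m) m$params$p)))
  expect_equal(nrow(P), 2)
  expect_true(all(apply(P, 1, identical, r1) | apply(P, 1, identical, r2)))
  expect_true(any(apply(P, 1, identical, r1)) && any(apply(P, 1, identical, r2)))
  # cross-check against the independent Bernoulli EM oracle
  o <- oracle_em_bernoulli(X, rbind(pmin(pmax(r1, 0.4), 0.6),
                                    pmin(pmax(r2, 0.4), 0.6)),
                           c(0.5, 0.5), iters = 20)
  expect_equal(sort(round(o$P)[, 1]), sort(P[, 1]))
})

test_that("recovery error matches the exhaustive assignment oracle", {
  proto <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, 4, byrow = TRUE)
  expect_equal(recovery_error(list(), proto), 1)
  # models exactly at the prototypes -> 0 (via a hand-built model list)
  fam <- bernoulli_family()
  mods <- list(dl_component(fam, params = list(p = proto[1, ]), spread = 1,
                            r = 0.5, index = 1),
               dl_component(fam, params = list(p = proto[2, ]), spread = 1,
                            r = 0.5, index = 2))
  expect_equal(recovery_error(mods, proto), 0)
  # maximally vague models against binary prototypes -> 0.5
  vague <- lapply(1:2, function(i)
    dl_component(fam, params = list(p = rep(0.5, 4)), spread = 1,
                 r = 0.5, index = i))
  expect_equal(recovery_error(vague, proto), 0.5)
  # random instances agree with the K! brute force, over- and under-supplied
  for (s in 1:8) {
    set.seed(s)
    K <- sample(2:4, 1)
    nf <- K + sample(-1:2, 1)
    if (nf < 1) nf <- 1
    P <- matrix(runif(nf * 6), nf, 6)
    pr <- matrix(runif(K * 6), K, 6)
    mods <- lapply(seq_len(nf), function(i)
      dl_component(fam, params = list(p = P[i, ]), spread = 1,
                   r = 1 / nf, index = i))
    expect_equal(recovery_error(mods, pr), oracle_match_error(P, pr),
                 tolerance = 1e-12)
  }
})

test_that("relevant sets read off the top probabilities with stable ties", {
  p <- c(0.1, 1, 0.3, 1, 0.2)
  expect_equal(relevant_object_sets(matrix(p, 1), 2)[[1]], c(2, 4))
  # tie at the boundary resolves to the lowest object id
  p2 <- c(0.5, 0.9, 0.5, 0.1)
  expect_equal(relevant_object_sets(matrix(p2, 1), 2)[[1]], c(1, 2))
})

test_that("relation markers are learned exactly like objects", {
  cfg <- situation_gen_config(D = 30, K = 2, k_rel = 3, k_rand = 4,
                              n_per_type = 40, n_clutter = 40,
                              n_markers = 2, seed = 8)
  g <- generate_situations(cfg)
  expect_equal(ncol(g$data), 32)
  fit <- fit_situations(g$data, n_models = 6, seed = 8)
  sets <- relevant_object_sets(fit, cfg$k_rel + 1)  # 3 objects + 1 marker
  hit <- vapply(g$truth$relevant_sets,
                function(ts) any(vapply(sets, identical, logical(1), ts)),
                logical(1))
  expect_true(all(hit))
  # the marker column is part of each recovered set
  expect_true(all(vapply(g$truth$relevant_sets,
                         function(ts) any(ts > 30), logical(1))))
})

test_that("paper-scale recovery succeeds across seeds", {
  ok <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    g <- generate_situations(situation_gen_config(seed = s))
    fit <- fit_situations(g$data, n_models = 20, seed = s,
                          config = dl_config(n_models_init = 20,
                                             trace_models = FALSE,
                                             max_iter = 12, merge = FALSE))
    sets <- relevant_object_sets(fit, 10)
    hit <- vapply(g$truth$relevant_sets,
                  function(ts) any(vapply(sets, identical, logical(1), ts)),
                  logical(1))
    ok <- ok + all(hit)
  }
  expect_gte(ok, 18L)
})
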
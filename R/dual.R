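#' Paired language-cognition data
#'
#' Each sample is a pair of binary vectors — a language-channel observation
#' `x_L` and a cognitive-channel observation `x_C` — bound together a
#' priori (the pairing itself is never learned).  Either channel may be
#' missing for a sample; at least one must be present.
#'
#' @param x_L `N x D_L` binary matrix (rows with missing language are
#'   ignored; pass zeros there).
#' @param x_C `N x D_C` binary matrix.
#' @param miss_L,miss_C logical vectors marking samples whose channel is
#'   missing.
#' @return list of class `dual_data`.
#' @export
dual_data <- function(x_L, x_C, miss_L = NULL, miss_C = NULL) {
  if (nrow(x_L) != nrow(x_C)) stop_input("channels must have the same N")
  n <- nrow(x_C)
  miss_L <- miss_L %||% rep(FALSE, n)
  miss_C <- miss_C %||% rep(FALSE, n)
  if (any(miss_L & miss_C)) stop_input("a sample must have at least one channel")
  structure(list(x_L = x_L, x_C = x_C, miss_L = miss_L, miss_C = miss_C,
                 n = n, D_L = ncol(x_L), D_C = ncol(x_C)),
            class = "dual_data")
}

#' Dual Bernoulli model family
#'
#' Every concept model is a permanently bound pair of Bernoulli parameter
#' vectors — a language part `p_L` and a cognitive part `p_C` — sharing a
#' single rate and a single association row per sample.  The conditional
#' similarity is the product of the two channel similarities (channels
#' conditionally independent given the concept), with a missing channel
#' contributing factor 1; updates are the per-channel weighted column
#' means over the samples where the channel is observed.
#'
#' @inheritParams bernoulli_family
#' @return a [dl_family()].
#' @export
dual_bernoulli_family <- function(eps = 1e-6, jitter = 0.01) {
  dl_family(
    name = "dual_bernoulli",
    loglik = function(comp, data) {
      if (!inherits(data, "dual_data")) stop_input("dual family needs dual_data")
      ll_C <- bern_loglik(data$x_C, comp$params$p_C)
      ll_C[data$miss_C] <- 0
      ll_L <- bern_loglik(data$x_L, comp$params$p_L)
      ll_L[data$miss_L] <- 0
      ll_C + ll_L
    },
    update = function(comp, data, w) {
      w_C <- w * as.numeric(!data$miss_C)
      if (sum(w_C) > 0) comp$params$p_C <- bern_update(data$x_C, w_C, eps)
      w_L <- w * as.numeric(!data$miss_L)
      if (sum(w_L) > 0) comp$params$p_L <- bern_update(data$x_L, w_L, eps)
      comp
    },
    spawn = function(data, index, r) {
      p_L <- bern_clamp(0.5 + stats::runif(data$D_L, -jitter, jitter), eps)
      p_C <- bern_clamp(0.5 + stats::runif(data$D_C, -jitter, jitter), eps)
      # only parameters of channels that are ever observed are fitted, so
      # only those count as free parameters for the skeptic penalty
      k_free <- (if (any(!data$miss_L)) data$D_L else 0L) +
        (if (any(!data$miss_C)) data$D_C else 0L)
      dl_component(dual_bernoulli_family(eps, jitter),
                   params = list(p_L = p_L, p_C = p_C, k_free = k_free),
                   spread = 1, r = r, index = index)
    },
    n_free = function(comp) comp$params$k_free
  )
}

#' Conditional similarity of a paired sample under a dual model
#'
#' Product of the two channel Bernoulli similarities; a missing channel
#' (`NULL`) contributes factor 1.
#'
#' @param comp a [dl_component()] of the dual family.
#' @param x_L,x_C binary channel vectors, or `NULL` when missing.
#' @return nonnegative scalar.
#' @export
dual_similarity <- function(comp, x_L, x_C) {
  if (is.null(x_L) && is.null(x_C))
    stop_input("at least one channel must be present")
  l <- 1
  if (!is.null(x_L)) l <- l * bernoulli_similarity(comp$params$p_L, x_L)
  if (!is.null(x_C)) l <- l * bernoulli_similarity(comp$params$p_C, x_C)
  l
}

#' Crispness of a probabilistic representation
#'
#' Mean over entries of `2 * |p - 0.5|`: 0 for a maximally vague (all-0.5)
#' vector and 1 for a fully binary one.
#'
#' @param p probability vector in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
crispness <- function(p) mean(2 * abs(p - 0.5))

#' Configuration of the dual-channel generator
#'
#' `K` concepts, each a pair of binary prototypes: `k_rel_L` relevant
#' language bits and `k_rel_C` relevant cognitive bits (disjoint across
#' concepts within a channel).  Observed bits are the prototype bits
#' flipped independently with channel noise rates `eta_L` and `eta_C`;
#' "ready-made" language corresponds to `eta_L` much smaller than
#' `eta_C`.  A fraction of samples can lack the language channel
#' (pre-linguistic observations).
#'
#' @param K number of concepts.
#' @param D_L,D_C channel dimensionalities.
#' @param k_rel_L,k_rel_C relevant bits per concept and channel.
#' @param eta_L,eta_C bit-flip probabilities in `[0, 0.5)`.
#' @param n_per_concept samples per concept.
#' @param miss_L_frac fraction of samples with missing language.
#' @param seed integer seed.
#' @return list of class `dual_gen_config`.
#' @export
dual_gen_config <- function(K = 5L, D_L = 30L, D_C = 60L, k_rel_L = 5L,
                            k_rel_C = 10L, eta_L = 0.05, eta_C = 0.3,
                            n_per_concept = 100L, miss_L_frac = 0,
                            seed = 1L) {
  if (eta_L < 0 || eta_L >= 0.5 || eta_C < 0 || eta_C >= 0.5)
    stop_input("noise rates must lie in [0, 0.5)")
  if (miss_L_frac < 0 || miss_L_frac > 1) stop_input("invalid missing fraction")
  if (K * k_rel_L > D_L || K * k_rel_C > D_C)
    stop_input("disjoint relevant sets do not fit the channel dimension")
  structure(list(K = as.integer(K), D_L = as.integer(D_L),
                 D_C = as.integer(D_C), k_rel_L = as.integer(k_rel_L),
                 k_rel_C = as.integer(k_rel_C), eta_L = eta_L,
                 eta_C = eta_C, n_per_concept = as.integer(n_per_concept),
                 miss_L_frac = miss_L_frac, seed = as.integer(seed)),
            class = "dual_gen_config")
}

#' Generate paired language-cognition data
#'
#' @param config a [dual_gen_config()].
#' @return list with `data` (a [dual_data()]) and `truth` (`concept`
#'   per-sample ids, per-channel prototype matrices `proto_L`, `proto_C`,
#'   and the config).
#' @export
generate_dual <- function(config) {
  stopifnot(inherits(config, "dual_gen_config"))
  set.seed(config$seed)
  K <- config$K
  proto_L <- matrix(0L, K, config$D_L)
  proto_C <- matrix(0L, K, config$D_C)
  pool_L <- sample.int(config$D_L, K * config$k_rel_L)
  pool_C <- sample.int(config$D_C, K * config$k_rel_C)
  for (k in seq_len(K)) {
    proto_L[k, pool_L[(k - 1) * config$k_rel_L + seq_len(config$k_rel_L)]] <- 1L
    proto_C[k, pool_C[(k - 1) * config$k_rel_C + seq_len(config$k_rel_C)]] <- 1L
  }
  N <- K * config$n_per_concept
  concept <- rep(seq_len(K), each = config$n_per_concept)
  flip <- function(proto_rows, eta, D) {
    flips <- matrix(stats::runif(N * D) < eta, N, D)
    (proto_rows + flips) %% 2L
  }
  x_L <- flip(proto_L[concept, , drop = FALSE], config$eta_L, config$D_L)
  x_C <- flip(proto_C[concept, , drop = FALSE], config$eta_C, config$D_C)
  miss_L <- rep(FALSE, N)
  if (config$miss_L_frac > 0)
    miss_L[sample.int(N, round(config$miss_L_frac * N))] <- TRUE
  x_L[miss_L, ] <- 0L
  ord <- sample.int(N)
  list(data = dual_data(x_L[ord, , drop = FALSE], x_C[ord, , drop = FALSE],
                        miss_L = miss_L[ord]),
       truth = list(concept = concept[ord], proto_L = proto_L,
                    proto_C = proto_C, config = config))
}

#' Fit dual concept models by dynamic logic
#'
#' Same initialization as [fit_situations()] — seeded one-hot random
#' association of samples to models followed by one closed-form update —
#' run with the dual Bernoulli family, so one shared association row per
#' sample drives both channel updates.
#'
#' @param data a [dual_data()].
#' @param n_models initial number of models.
#' @param config a [dl_config()]; defaults mirror [fit_situations()].
#' @param seed integer seed.
#' @return a [dl_fit()] object.
#' @export
fit_dual <- function(data, n_models = 20L, config = NULL, seed = 1L) {
  stopifnot(inherits(data, "dual_data"))
  if (is.null(config))
    config <- dl_config(n_models_init = n_models, trace_models = TRUE,
                        merge = FALSE)
  config$n_models_init <- as.integer(n_models)
  fam <- dual_bernoulli_family()
  set.seed(seed)
  assign0 <- sample.int(n_models, data$n, replace = TRUE)
  init <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    comp <- fam$spawn(data, m, r = 1 / n_models)
    w <- as.numeric(assign0 == m)
    if (sum(w) > 0) comp <- fam$update(comp, data, w)
    init[[m]] <- comp
  }
  dl_fit(data, fam, config, seed = derive_seed(seed, 1L), init_models = init)
}

# Channel prototype rates after bit-flip noise: relevant bits appear at
# 1 - eta, all others at eta.
dual_prototype_rates <- function(truth, channel = c("cognitive", "language")) {
  channel <- match.arg(channel)
  cfg <- truth$config
  if (channel == "cognitive") {
    proto <- truth$proto_C; eta <- cfg$eta_C
  } else {
    proto <- truth$proto_L; eta <- cfg$eta_L
  }
  proto * (1 - eta) + (1 - proto) * eta
}

# Matrix of one channel's parameters over active models (by decreasing
# rate), optionally restricted to the K highest-rate ones.
dual_channel_p <- function(models, K = NULL,
                           channel = c("cognitive", "language")) {
  channel <- match.arg(channel)
  if (inherits(models, "dl_fit")) models <- models$models
  act <- Filter(function(m) !is_clutter(m), active_models(models))
  r <- vapply(act, function(m) m$r, numeric(1))
  act <- act[order(-r)]
  if (!is.null(K)) act <- act[seq_len(min(K, length(act)))]
  field <- if (channel == "cognitive") "p_C" else "p_L"
  do.call(rbind, lapply(act, function(m) m$params[[field]]))
}

#' Recovery error of one dual channel
#'
#' [recovery_error()]-style matched error of the `K` best models' channel
#' parameters against the channel's noise-adjusted prototypes (relevant
#' bits at `1 - eta`, others at `eta`).
#'
#' @param models a [dl_fit()] or model list (dual family).
#' @param truth the `truth` element of [generate_dual()].
#' @param channel `"cognitive"` or `"language"`.
#' @return scalar error in `[0, 1]`.
#' @export
dual_recovery_error <- function(models, truth,
                                channel = c("cognitive", "language")) {
  channel <- match.arg(channel)
  proto <- dual_prototype_rates(truth, channel)
  matched_mean_abs_error(dual_channel_p(models, channel = channel), proto)
}

#' Language-versus-cognition crispening experiment
#'
#' For each cognitive noise level in `eta_C_grid` and each seed, generates
#' paired data with fixed low language noise `eta_L`, fits (a) the dual
#' model and (b) a cognition-only Bernoulli fit on the cognitive channel,
#' and records the cognitive recovery errors plus the per-iteration
#' crispness of both channels of the dual fit.  When `eta_L < eta_C`, the
#' language channel crispens at least as fast as the cognitive one; above
#' a cognitive noise threshold, only the dual fit still recovers the
#' concepts — the testable form of language rescuing cognition.
#'
#' @param eta_C_grid numeric vector of cognitive bit-flip rates.
#' @param eta_L language bit-flip rate.
#' @param n_seeds seeds per grid cell.
#' @param K,n_per_concept,... forwarded to [dual_gen_config()].
#' @param n_models initial models per fit.
#' @param seed base seed.
#' @return data.frame with one row per (eta_C, seed): cognitive recovery
#'   error of the dual and of the cognition-only fit, final crispness of
#'   both channels, and whether the language channel was at least as
#'   crisp as the cognitive one at every stored iteration.
#' @export
dual_advantage_experiment <- function(eta_C_grid = c(0.1, 0.2, 0.3, 0.4),
                                      eta_L = 0.05, n_seeds = 10L, K = 5L,
                                      n_per_concept = 100L, n_models = 10L,
                                      seed = 1L, ...) {
  rows <- list()
  for (eta_C in eta_C_grid) {
    for (s in seq_len(n_seeds)) {
      run_seed <- derive_seed(seed, length(rows) + 1L)
      cfg <- dual_gen_config(K = K, eta_L = eta_L, eta_C = eta_C,
                             n_per_concept = n_per_concept,
                             seed = run_seed, ...)
      gen <- generate_dual(cfg)
      fit_d <- fit_dual(gen$data, n_models = n_models, seed = run_seed)
      fit_c <- fit_situations(gen$data$x_C, n_models = n_models,
                              seed = run_seed)
      err_d <- dual_recovery_error(fit_d, gen$truth, "cognitive")
      err_c <- matched_mean_abs_error(
        top_models_p(fit_c$models),
        dual_prototype_rates(gen$truth, "cognitive"))
      cr <- crispness_trace(fit_d, K)
      rows[[length(rows) + 1L]] <- data.frame(
        eta_C = eta_C, eta_L = eta_L, seed = s,
        dual_error = err_d, cognition_only_error = err_c,
        crisp_L_final = cr$language[nrow(cr)],
        crisp_C_final = cr$cognitive[nrow(cr)],
        language_always_crisper = all(cr$language >= cr$cognitive))
    }
  }
  do.call(rbind, rows)
}

#' Per-iteration channel crispness of a dual fit
#'
#' @param fit a [dl_fit()] of the dual family run with
#'   `trace_models = TRUE`.
#' @param K number of highest-rate models to average over.
#' @return data.frame with columns `iteration`, `language`, `cognitive`.
#' @export
crispness_trace <- function(fit, K) {
  if (is.null(fit$model_trace))
    stop_input("fit was run without trace_models = TRUE")
  rows <- lapply(seq_along(fit$model_trace), function(i) {
    P_L <- dual_channel_p(fit$model_trace[[i]], K, "language")
    P_C <- dual_channel_p(fit$model_trace[[i]], K, "cognitive")
    data.frame(iteration = i - 1L,
               language = mean(apply(P_L, 1L, crispness)),
               cognitive = mean(apply(P_C, 1L, crispness)))
  })
  do.call(rbind, rows)
}
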
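#' Bernoulli situation-model family
#'
#' Situations are characteristic subsets of co-occurring objects observed
#' amid random co-occurrences.  Each model is a vector of object-presence
#' probabilities `p` (clamped to `(1e-6, 1 - 1e-6)`); the conditional
#' similarity of a binary row is the product Bernoulli likelihood,
#' computed in log space; the f-weighted update is the responsibility-
#' weighted column mean; a vague spawn sits at `p = 0.5` with a small
#' seeded jitter.
#'
#' @param eps clamping bound for the probabilities.
#' @param jitter half-width of the uniform jitter around 0.5 used when
#'   spawning a vague model.
#' @return a [dl_family()].
#' @export
bernoulli_family <- function(eps = 1e-6, jitter = 0.01) {
  dl_family(
    name = "bernoulli",
    loglik = function(comp, data) {
      p <- comp$params$p
      if (length(p) != ncol(data)) stop_input("dimension mismatch in bernoulli loglik")
      bern_loglik(data, p)
    },
    update = function(comp, data, w) {
      comp$params$p <- bern_update(data, w, eps)
      comp
    },
    spawn = function(data, index, r) {
      D <- ncol(data)
      p <- bern_clamp(0.5 + stats::runif(D, -jitter, jitter), eps)
      dl_component(bernoulli_family(eps, jitter), params = list(p = p),
                   spread = 1, r = r, index = index)
    },
    n_free = function(comp) length(comp$params$p),
    predict = function(comp, data) comp$params$p,
    wrap = function(datum) matrix(datum, nrow = 1L)
  )
}

bern_clamp <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Row-wise Bernoulli log-likelihood of a binary matrix under p, in log
# space; shared by the plain and dual families so both take the same
# arithmetic path.
bern_loglik <- function(X, p) {
  as.numeric(X %*% log(p / (1 - p))) + sum(log1p(-p))
}

# Closed-form f-weighted Bernoulli update (weighted column means, clamped).
bern_update <- function(X, w, eps = 1e-6) {
  bern_clamp(as.numeric(Matrix::crossprod(X, w)) / sum(w), eps)
}

#' Conditional similarity of a binary row under a situation model
#'
#' `l = prod_i p_i^{x_i} (1 - p_i)^{1 - x_i}`, evaluated in log space.
#'
#' @param model a [dl_component()] of the Bernoulli family (or a bare
#'   probability vector).
#' @param x binary vector.
#' @return nonnegative scalar.
#' @export
bernoulli_similarity <- function(model, x) {
  p <- if (inherits(model, "dl_component")) model$params$p else model
  if (length(p) != length(x)) stop_input("dimension mismatch")
  exp(sum(x * log(p) + (1 - x) * log1p(-p)))
}

#' Configuration of the situation generator
#'
#' Defines the synthetic study conditions: `K` important situation types,
#' each with `k_rel` relevant objects (always present in that type's
#' instances) plus `k_rand` uniformly random extra objects per instance,
#' and `n_clutter` pure-clutter rows of `k_clutter` random objects.
#' Defaults reproduce the body-text scale of the learning demonstration:
#' 1000 objects, 10 types x 800 instances plus 8000 clutter rows = 16,000
#' situations, half of them random.  `preset = "caption"` instead uses the
#' figure-caption counts (10 types, 5000 clutter rows, equal halves).
#'
#' @param D number of objects (columns).
#' @param K number of important situation types.
#' @param k_rel relevant objects per type.
#' @param k_rand random extra objects per instance.
#' @param n_per_type instances per type.
#' @param n_clutter number of clutter rows.
#' @param k_clutter objects per clutter row; defaults to `k_rel + k_rand`
#'   so clutter rows are indistinguishable by row sum.
#' @param n_markers relation-marker columns appended to the matrix;
#'   markers belong to types exactly like objects (each type gets one
#'   marker column when `n_markers >= K`, cycling otherwise).
#' @param seed integer seed.
#' @param preset `"paper"` (body-text counts) or `"caption"`.
#' @return a list of class `situation_gen_config`.
#' @export
situation_gen_config <- function(D = 1000L, K = 10L, k_rel = 10L,
                                 k_rand = 40L, n_per_type = 800L,
                                 n_clutter = 8000L, k_clutter = NULL,
                                 n_markers = 0L, seed = 1L,
                                 preset = c("paper", "caption")) {
  preset <- match.arg(preset)
  if (preset == "caption") {
    n_per_type <- 500L
    n_clutter <- 5000L
  }
  k_clutter <- k_clutter %||% (k_rel + k_rand)
  if (k_rel + k_rand > D) stop_input("k_rel + k_rand must not exceed D")
  if (K * k_rel > D) stop_input("disjoint relevant sets need K * k_rel <= D")
  if (k_clutter > D) stop_input("k_clutter must not exceed D")
  if (min(D, K, k_rel, n_per_type) < 1L || min(k_rand, n_clutter, n_markers) < 0L)
    stop_input("invalid counts")
  structure(list(D = as.integer(D), K = as.integer(K),
                 k_rel = as.integer(k_rel), k_rand = as.integer(k_rand),
                 n_per_type = as.integer(n_per_type),
                 n_clutter = as.integer(n_clutter),
                 k_clutter = as.integer(k_clutter),
                 n_markers = as.integer(n_markers),
                 seed = as.integer(seed), preset = preset),
            class = "situation_gen_config")
}

#' Generate binary situation-by-object data
#'
#' Draws `K` disjoint relevant-object sets; emits `n_per_type` instances
#' per type, each containing the type's relevant objects plus `k_rand`
#' random others; appends `n_clutter` clutter rows of `k_clutter` random
#' objects; optionally appends relation-marker columns (one per type,
#' present in all of that type's rows); and shuffles the row order.
#'
#' @param config a [situation_gen_config()].
#' @return list with `data` (sparse binary `N x (D + n_markers)` matrix),
#'   and `truth`: `type` (per-row type id, 0 = clutter, in the shuffled
#'   order) and `relevant_sets` (list of column-index sets per type,
#'   markers included).
#' @export
generate_situations <- function(config) {
  stopifnot(inherits(config, "situation_gen_config"))
  set.seed(config$seed)
  D <- config$D
  K <- config$K
  rel_pool <- sample.int(D, K * config$k_rel)
  rel_sets <- split(rel_pool, rep(seq_len(K), each = config$k_rel))
  rel_sets <- lapply(rel_sets, sort)

  n_imp <- K * config$n_per_type
  N <- n_imp + config$n_clutter
  rows_i <- vector("list", N)
  type <- integer(N)
  row_id <- 0L
  for (k in seq_len(K)) {
    rel <- rel_sets[[k]]
    other <- setdiff(seq_len(D), rel)
    for (j in seq_len(config$n_per_type)) {
      row_id <- row_id + 1L
      extra <- if (config$k_rand > 0L) sample(other, config$k_rand) else integer(0)
      rows_i[[row_id]] <- c(rel, extra)
      type[row_id] <- k
    }
  }
  for (j in seq_len(config$n_clutter)) {
    row_id <- row_id + 1L
    rows_i[[row_id]] <- sample.int(D, config$k_clutter)
    type[row_id] <- 0L
  }

  D_tot <- D + config$n_markers
  if (config$n_markers > 0L) {
    marker_of_type <- D + 1L + ((seq_len(K) - 1L) %% config$n_markers)
    for (i in seq_len(N)) {
      if (type[i] > 0L)
        rows_i[[i]] <- c(rows_i[[i]], marker_of_type[type[i]])
    }
    for (k in seq_len(K))
      rel_sets[[k]] <- sort(c(rel_sets[[k]], marker_of_type[k]))
  }

  ord <- sample.int(N)
  rows_i <- rows_i[ord]
  type <- type[ord]
  ii <- rep(seq_len(N), lengths(rows_i))
  jj <- unlist(rows_i, use.names = FALSE)
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, D_tot),
                            dimnames = list(NULL, paste0("obj", seq_len(D_tot))))
  list(data = X,
       truth = list(type = type, relevant_sets = rel_sets, config = config))
}

#' Fit situation models by dynamic logic
#'
#' Initialization follows the demonstrated procedure: every row is randomly
#' associated with one of `n_models` models (seeded one-hot
#' responsibilities) and one closed-form update turns those associations
#' into initial probability vectors; the dynamic-logic loop then runs with
#' the Bernoulli family.
#'
#' @param data binary matrix (dense or sparse) of situations by objects.
#' @param n_models initial number of models (the demonstration uses 20).
#' @param config a [dl_config()]; defaults to
#'   `dl_config(n_models_init = n_models, trace_models = TRUE)`.
#' @param seed integer seed.
#' @return a [dl_fit()] object.
#' @export
fit_situations <- function(data, n_models = 20L, config = NULL, seed = 1L) {
  # surplus Bernoulli models absorb clutter rather than split one type,
  # so the duplicate-merge phase has nothing to find here
  if (is.null(config))
    config <- dl_config(n_models_init = n_models, trace_models = TRUE,
                        max_iter = 50L, merge = FALSE)
  config$n_models_init <- as.integer(n_models)
  fam <- bernoulli_family()
  set.seed(seed)
  N <- nrow(data)
  assign0 <- sample.int(n_models, N, replace = TRUE)
  init <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    comp <- fam$spawn(data, m, r = 1 / n_models)
    w <- as.numeric(assign0 == m)
    if (sum(w) > 0) comp <- fam$update(comp, data, w)
    init[[m]] <- comp
  }
  dl_fit(data, fam, config, seed = derive_seed(seed, 1L), init_models = init)
}

# Binary prototype of a situation type: relevant objects at 1, all other
# columns at their generative marginal presence rate.
situation_prototypes <- function(truth) {
  cfg <- truth$config
  D_tot <- cfg$D + cfg$n_markers
  marg <- cfg$k_rand / (cfg$D - cfg$k_rel)
  proto <- matrix(marg, nrow = cfg$K, ncol = D_tot)
  if (cfg$n_markers > 0L) proto[, cfg$D + seq_len(cfg$n_markers)] <- 0
  for (k in seq_len(cfg$K)) proto[k, truth$relevant_sets[[k]]] <- 1
  proto
}

# Probability vectors of active non-clutter models, ordered by decreasing
# rate; optionally restricted to the K highest-rate models.
top_models_p <- function(models, K = NULL) {
  act <- Filter(function(m) !is_clutter(m), active_models(models))
  r <- vapply(act, function(m) m$r, numeric(1))
  act <- act[order(-r)]
  if (!is.null(K)) act <- act[seq_len(min(K, length(act)))]
  do.call(rbind, lapply(act, function(m) m$params$p))
}

#' Recovery error of fitted situation models
#'
#' Matches fitted models one-to-one to the planted types by minimum-cost
#' assignment on the mean absolute difference between each model's
#' probability vector and the type prototype (relevant objects at 1,
#' others at their generative marginal) and returns the mean matched
#' distance in `[0, 1]`.  When more models than types are active, the
#' assignment itself selects the error-minimizing subset (models that
#' absorb clutter are left unmatched); planted types left unmatched
#' because too few models are active count error 1.
#'
#' @param models a [dl_fit()] object or list of [dl_component()]s.
#' @param truth the `truth` element returned by [generate_situations()],
#'   or a prototype matrix (`K x D`, rows = types).
#' @return scalar error in `[0, 1]`.
#' @export
recovery_error <- function(models, truth) {
  if (inherits(models, "dl_fit")) models <- models$models
  proto <- if (is.matrix(truth)) truth else situation_prototypes(truth)
  matched_mean_abs_error(top_models_p(models), proto)
}

# Optimal one-to-one matching of fitted probability rows P to prototype
# rows, scored by mean absolute difference; unmatched prototypes count
# error 1.  Shared by the situation and dual-channel recovery metrics.
matched_mean_abs_error <- function(P, proto) {
  K <- nrow(proto)
  if (is.null(P) || nrow(P) == 0L) return(1)
  n_fit <- nrow(P)
  cost <- matrix(0, n_fit, K)
  for (i in seq_len(n_fit))
    cost[i, ] <- rowMeans(abs(sweep(-proto, 2L, -P[i, ])))
  if (n_fit <= K) {
    m <- min_cost_matching(cost)
    (m$cost + (K - n_fit)) / K
  } else {
    m <- min_cost_matching(t(cost))
    m$cost / K
  }
}

#' Recovery-error trajectory over iterations
#'
#' Evaluates [recovery_error()] against the planted truth at every stored
#' iteration of a fit run with `trace_models = TRUE`.  Index 0 is the
#' initial model set.
#'
#' @inheritParams recovery_error
#' @param fit a [dl_fit()] with a model trace.
#' @return data.frame with columns `iteration` and `error`.
#' @export
recovery_error_trace <- function(fit, truth) {
  if (is.null(fit$model_trace))
    stop_input("fit was run without trace_models = TRUE")
  err <- vapply(fit$model_trace, recovery_error, numeric(1), truth = truth)
  data.frame(iteration = seq_along(err) - 1L, error = err)
}

#' Read off the learned relevant-object sets
#'
#' For each model, the `k_rel` columns with the highest presence
#' probability; ties at the boundary resolve to the lowest object id.
#'
#' @param models a [dl_fit()], list of [dl_component()]s, or probability
#'   matrix (rows = models).
#' @param k_rel number of relevant objects per set.
#' @param K optionally restrict to the `K` highest-rate models.
#' @return list of sorted column-index vectors, one per model.
#' @export
relevant_object_sets <- function(models, k_rel, K = NULL) {
  P <- if (is.matrix(models)) models else {
    if (inherits(models, "dl_fit")) models <- models$models
    top_models_p(models, K %||% length(active_models(models)))
  }
  lapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    sort(order(-p, seq_along(p))[seq_len(k_rel)])
  })
}
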
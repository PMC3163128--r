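#' Fit configuration for the dynamic-logic engine
#'
#' @param n_models_init number of active models to start from.
#' @param n_dormant size of the dormant-model store.
#' @param activation_threshold rate threshold for activating/deactivating
#'   models; defaults to `1 / (10 * (n_models_init + n_dormant))`.
#' @param penalty skeptic-penalty form: `"aic"` (`kappa = 1`), `"bic"`
#'   (`kappa = log(N)/2`, steeper for larger parameter loads at small `N`
#'   relative to the likelihood), or `"none"`.
#' @param kappa explicit penalty weight overriding the `penalty` preset.
#' @param tol absolute convergence tolerance on the log-similarity change;
#'   defaults to `1e-6 * N` at fit time.
#' @param max_iter maximum number of outer iterations.
#' @param r_floor rate mass held by each dormant model before
#'   renormalization, so dormant models can re-emerge.
#' @param w_floor total-responsibility floor below which a model's
#'   parameters are left unchanged and the model is flagged for
#'   deactivation review.
#' @param reseed_every propose a family reseed (relocation of models that
#'   claim no signal to unexplained structure) every this many iterations;
#'   0 disables.  Proposals are only accepted when the log-similarity does
#'   not decrease after a one-step refit, so the trace stays monotone.
#' @param trace_models logical; keep a snapshot of the model set at every
#'   iteration (needed for error-vs-iteration curves).
#' @param prune logical; after convergence, deactivate models whose removal
#'   does not decrease the penalized similarity.
#' @param merge logical; before pruning, merge same-family model pairs
#'   when a single refitted component does not decrease the penalized
#'   similarity.  Worth it for localized-structure families where soft
#'   assignment can split one structure between duplicates (e.g. cones);
#'   pointless for families whose surplus models absorb clutter instead.
#' @param verbose logical; log one line per iteration.
#'
#' @return a list of class `dl_config`.
#' @export
dl_config <- function(n_models_init = 2L, n_dormant = 5L,
                      activation_threshold = NULL,
                      penalty = c("aic", "bic", "none"), kappa = NULL,
                      tol = NULL, max_iter = 500L, r_floor = 1e-6,
                      w_floor = 1e-6, reseed_every = 0L,
                      trace_models = FALSE, prune = TRUE, merge = TRUE,
                      verbose = FALSE) {
  penalty <- match.arg(penalty)
  if (n_models_init < 1L) stop_input("need at least one initial model")
  if (is.null(activation_threshold))
    activation_threshold <- 1 / (10 * (n_models_init + max(n_dormant, 1L)))
  if (activation_threshold <= 0 || activation_threshold >= 1)
    stop_input("activation_threshold must lie in (0, 1)")
  structure(list(n_models_init = as.integer(n_models_init),
                 n_dormant = as.integer(n_dormant),
                 activation_threshold = activation_threshold,
                 penalty = penalty, kappa = kappa, tol = tol,
                 max_iter = as.integer(max_iter), r_floor = r_floor,
                 w_floor = w_floor, reseed_every = as.integer(reseed_every),
                 trace_models = isTRUE(trace_models),
                 prune = isTRUE(prune), merge = isTRUE(merge),
                 verbose = isTRUE(verbose)),
            class = "dl_config")
}

#' Conditional similarity of one datum under one model
#'
#' Evaluates \eqn{l(n|m)}, the conditional similarity between a bottom-up
#' signal and a top-down model, on the family's natural density scale (for
#' the Gaussian family, the multivariate normal density of the datum with
#' the model prediction as mean and the model spread as variance).
#'
#' @param comp a [dl_component()].
#' @param datum one raw datum in the family's natural form.
#' @return a nonnegative scalar.
#' @export
dl_conditional_similarity <- function(comp, datum) {
  if (comp$spread <= 0) stop_input("nonpositive spread")
  exp(comp$family$loglik(comp, comp$family$wrap(datum)))[1L]
}

#' Active components of a model set
#'
#' @param models a list of [dl_component()]s or a [dl_fit()].
#' @return the sub-list of components whose status is `"active"`.
#' @export
active_models <- function(models) {
  if (inherits(models, "dl_fit")) models <- models$models
  Filter(is_active, models)
}

# N x M_active matrix of log l(n|m); columns follow active order.
loglik_matrix <- function(data, act) {
  n <- dl_nobs(data)
  L <- matrix(0, n, length(act))
  for (j in seq_along(act)) L[, j] <- act[[j]]$family$loglik(act[[j]], data)
  L
}

# Active rates renormalized to sum one (evaluation convention).
active_rates <- function(act) {
  r <- vapply(act, function(m) m$r, numeric(1))
  if (any(r < 0)) stop_input("negative rate")
  s <- sum(r)
  if (s <= 0) rep(1 / length(r), length(r)) else r / s
}

#' Total log-similarity of a model set
#'
#' \eqn{\log L = \sum_n \log \sum_m r(m)\, l(n|m)} over the active models,
#' with the active rates renormalized to sum one for the evaluation.
#' Returns `-Inf` (with a warning) when some datum has zero similarity
#' under every active model.
#'
#' @param data a family data container.
#' @param models list of [dl_component()]s.
#' @return scalar log-similarity.
#' @export
dl_total_log_similarity <- function(data, models) {
  act <- active_models(models)
  if (length(act) == 0L) stop_input("no active models")
  L <- loglik_matrix(data, act)
  lse <- row_logsumexp(sweep(L, 2L, log(active_rates(act)), `+`))
  if (any(!is.finite(lse))) {
    warning("some data have zero similarity under every active model")
    return(-Inf)
  }
  sum(lse)
}

#' Skeptic-penalized log-similarity
#'
#' Adds the log skeptic penalty `log p(N, M) = -kappa * k` to a
#' log-similarity, where `k` is the total number of free parameters over
#' active models.  `penalty = "aic"` uses `kappa = 1`; `penalty = "bic"`
#' uses `kappa = log(N) / 2`, which penalizes parameters more steeply
#' relative to the per-datum likelihood when `N` is small.
#'
#' @param loglik finite log-similarity value.
#' @param models list of [dl_component()]s.
#' @param N number of data.
#' @param penalty `"aic"`, `"bic"` or `"none"`.
#' @param kappa explicit penalty weight (overrides `penalty`).
#' @return penalized log-similarity.
#' @export
dl_penalized_similarity <- function(loglik, models, N,
                                    penalty = c("aic", "bic", "none"),
                                    kappa = NULL) {
  if (N <= 0) stop_input("N must be positive")
  penalty <- match.arg(penalty)
  if (is.null(kappa))
    kappa <- switch(penalty, aic = 1, bic = log(N) / 2, none = 0)
  k <- sum(vapply(active_models(models),
                  function(m) as.numeric(m$family$n_free(m)), numeric(1)))
  loglik - kappa * k
}

# Internal E-step: returns list(f = N x M_active responsibilities,
# loglik = total log-similarity).  Rows with zero similarity everywhere are
# assigned to the clutter component if present, else uniformly.
e_step <- function(data, models) {
  act <- active_models(models)
  if (length(act) == 0L) stop_input("no active models")
  L <- sweep(loglik_matrix(data, act), 2L, log(active_rates(act)), `+`)
  lse <- row_logsumexp(L)
  f <- exp(L - lse)
  dead <- !is.finite(lse)
  if (any(dead)) {
    cl <- which(vapply(act, is_clutter, logical(1)))
    f[dead, ] <- 0
    if (length(cl) > 0L) f[dead, cl[1L]] <- 1
    else f[dead, ] <- 1 / length(act)
  }
  list(f = f, loglik = if (any(dead)) -Inf else sum(lse), active = act)
}

#' Association variables f(m|n)
#'
#' The normalized responsibility of each active model for each datum,
#' \eqn{f(m|n) = r(m) l(n|m) / \sum_{m'} r(m') l(n|m')}.  Returned with
#' rows indexing models and columns indexing data, so every column sums to
#' one.  A datum with zero similarity under every model is assigned to the
#' clutter component if one is present, else uniformly.
#'
#' @inheritParams dl_total_log_similarity
#' @return an `M_active x N` matrix.
#' @export
dl_associations <- function(data, models) {
  t(e_step(data, models)$f)
}

#' f-weighted parameter update
#'
#' Replaces each active model's parameters (and estimated spread) by the
#' family's f-weighted maximum-likelihood values — the fixed point of the
#' dynamic-logic parameter flow.  A model whose total responsibility falls
#' below the floor `w_floor` is left unchanged and flagged with attribute
#' `"review"`.
#'
#' @param data a family data container.
#' @param models list of [dl_component()]s.
#' @param f association matrix as returned by [dl_associations()]
#'   (`M_active x N`).
#' @param w_floor total-weight floor.
#' @return the updated model list.
#' @export
dl_update_parameters <- function(data, models, f, w_floor = 1e-6) {
  act_idx <- which(vapply(models, is_active, logical(1)))
  if (nrow(f) != length(act_idx))
    stop_input("`f` rows must match the active model count")
  review <- integer(0)
  for (j in seq_along(act_idx)) {
    i <- act_idx[j]
    w <- f[j, ]
    if (sum(w) < w_floor) {
      review <- c(review, models[[i]]$index)
      next
    }
    if (!is_clutter(models[[i]]))
      models[[i]] <- models[[i]]$family$update(models[[i]], data, w)
  }
  attr(models, "review") <- review
  models
}

#' Rate re-estimation
#'
#' Closed-form mixture-weight step: `r(m) = sum_n f(m|n) / N` for active
#' models; each dormant model keeps the floor mass `r_floor`; all rates are
#' then renormalized to sum one.  Active proportions are preserved exactly,
#' so the renormalization does not perturb the evaluation rates.
#'
#' @param f association matrix (`M_active x N`).
#' @param N number of data.
#' @param models list of [dl_component()]s.
#' @param r_floor dormant floor mass.
#' @return the model list with updated rates.
#' @export
dl_update_rates <- function(f, N, models, r_floor = 1e-6) {
  act_idx <- which(vapply(models, is_active, logical(1)))
  if (nrow(f) != length(act_idx))
    stop_input("`f` rows must match the active model count")
  r_act <- rowSums(f) / N
  n_dorm <- length(models) - length(act_idx)
  scale <- (1 - n_dorm * r_floor) / sum(r_act)
  for (j in seq_along(act_idx)) models[[act_idx[j]]]$r <- r_act[j] * scale
  for (i in setdiff(seq_along(models), act_idx)) models[[i]]$r <- r_floor
  models
}

#' Model activation and deactivation
#'
#' Dormant models whose rate exceeds the threshold are activated (re-spawned
#' vague at their current rate, lowest index first); active non-clutter
#' models whose rate falls below the threshold become dormant.  At least one
#' active model is always retained: if the rule would deactivate everything,
#' the highest-rate model stays active.
#'
#' @param models list of [dl_component()]s.
#' @param threshold activation threshold in `(0, 1)`.
#' @param data family data container used to spawn vague replacements for
#'   newly activated models; if `NULL`, dormant models are activated
#'   without re-spawning.
#' @return the updated model list.
#' @export
dl_activate_deactivate <- function(models, threshold, data = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop_input("threshold must lie in (0, 1)")
  ord <- order(vapply(models, function(m) m$index, integer(1)))
  for (i in ord) {
    m <- models[[i]]
    if (m$status == "dormant" && m$r > threshold) {
      if (!is.null(data)) {
        sp <- m$family$spawn(data, m$index, m$r)
        sp$status <- "active"
        models[[i]] <- sp
      } else {
        models[[i]]$status <- "active"
      }
    } else if (m$status == "active" && !is_clutter(m) && m$r < threshold) {
      models[[i]]$status <- "dormant"
    }
  }
  if (!any(vapply(models, is_active, logical(1)))) {
    best <- which.max(vapply(models, function(m) m$r, numeric(1)))
    models[[best]]$status <- "active"
  }
  models
}

# Deactivate models below threshold, but only when removal does not lower
# the log-similarity beyond the relative monotonicity tolerance; keeps the
# fit trace non-decreasing while still pruning models that have faded.
guarded_deactivate <- function(data, models, threshold, loglik_cur, mono_tol) {
  repeat {
    act <- active_models(models)
    low <- Filter(function(m) !is_clutter(m) && m$r < threshold, act)
    if (length(low) == 0L || length(act) <= 1L) break
    cand <- low[[which.min(vapply(low, function(m) m$r, numeric(1)))]]
    trial <- models
    for (i in seq_along(trial))
      if (trial[[i]]$index == cand$index) trial[[i]]$status <- "dormant"
    if (!any(vapply(trial, is_active, logical(1)))) break
    ll <- dl_total_log_similarity(data, trial)
    if (ll >= loglik_cur - mono_tol * max(1, abs(loglik_cur))) {
      models <- trial
      loglik_cur <- ll
    } else break
  }
  models
}

# Merge same-family active models when the merged component (refitted on
# the pair's combined responsibilities) does not decrease the penalized
# similarity.  This removes duplicate models that split one structure —
# the "models are sometimes merged or eliminated" part of model-set
# adaptation.
merge_models <- function(data, models, N, penalty, kappa) {
  repeat {
    es <- e_step(data, models)
    act <- es$active
    pos <- which(vapply(act, function(m) !is_clutter(m), logical(1)))
    if (length(pos) < 2L) break
    pen_cur <- dl_penalized_similarity(es$loglik, models, N, penalty, kappa)
    merged <- FALSE
    for (a in seq_along(pos)) {
      for (b in seq_along(pos)) {
        if (b <= a) next
        mi <- act[[pos[a]]]
        mj <- act[[pos[b]]]
        if (mi$family$name != mj$family$name) next
        w <- es$f[, pos[a]] + es$f[, pos[b]]
        if (sum(w) <= 0) next
        mc <- mi$family$update(mi, data, w)
        mc$r <- mi$r + mj$r
        trial <- models
        for (k in seq_along(trial)) {
          if (trial[[k]]$index == mi$index) {
            mc$index <- mi$index
            trial[[k]] <- mc
          } else if (trial[[k]]$index == mj$index) {
            trial[[k]]$status <- "dormant"
          }
        }
        # refine the merged component on its own responsibilities before
        # judging the merge: one update from the pooled weights is not
        # enough when the two duplicates have already crisped apart
        for (refine in 1:2) {
          es_t <- e_step(data, trial)
          pos_m <- which(vapply(es_t$active, function(m)
            m$index == mi$index, logical(1)))
          w_m <- es_t$f[, pos_m]
          if (sum(w_m) <= 0) break
          for (k in seq_along(trial)) {
            if (trial[[k]]$index == mi$index)
              trial[[k]] <- trial[[k]]$family$update(trial[[k]], data, w_m)
          }
        }
        ll <- dl_total_log_similarity(data, trial)
        pen <- dl_penalized_similarity(ll, trial, N, penalty, kappa)
        if (pen >= pen_cur) {
          models <- trial
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  models
}

# Post-convergence skeptic pruning: repeatedly drop the lowest-rate active
# model whose removal does not decrease the penalized similarity.
penalty_prune <- function(data, models, N, penalty, kappa) {
  repeat {
    act <- active_models(models)
    nm <- Filter(function(m) !is_clutter(m), act)
    if (length(act) <= 1L || length(nm) == 0L) break
    ll_cur <- dl_total_log_similarity(data, models)
    pen_cur <- dl_penalized_similarity(ll_cur, models, N, penalty, kappa)
    ord <- order(vapply(nm, function(m) m$r, numeric(1)))
    dropped <- FALSE
    for (m in nm[ord]) {
      trial <- models
      for (i in seq_along(trial))
        if (trial[[i]]$index == m$index) trial[[i]]$status <- "dormant"
      if (!any(vapply(trial, is_active, logical(1)))) next
      ll <- dl_total_log_similarity(data, trial)
      pen <- dl_penalized_similarity(ll, trial, N, penalty, kappa)
      if (pen >= pen_cur) {
        models <- trial
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  models
}

#' Fit a model set by dynamic logic
#'
#' Runs the vague-to-crisp loop: association (E) step, f-weighted parameter
#' update, rate re-estimation, and guarded activation/deactivation, until
#' the log-similarity change drops below `tol` or `max_iter` is reached.
#' The log-similarity trace is non-decreasing (EM-style monotonicity; the
#' parameter step never decreases it, and structural changes are accepted
#' only when they do not).  After convergence, models whose removal does
#' not decrease the skeptic-penalized similarity are pruned.
#'
#' @param data a family data container.
#' @param family the [dl_family()] used to spawn models.
#' @param config a [dl_config()].
#' @param seed integer seed; identical seed, config and data reproduce the
#'   fit bit-for-bit.
#' @param init_models optional list of [dl_component()]s to start from
#'   (replaces the spawned active models; dormant store is still added).
#' @param clutter optional clutter [dl_component()] appended to the active
#'   set.
#' @return an object of class `dl_fit` with elements `models`, `f` (final
#'   `M_active x N` associations), `loglik_trace`, `penalized`,
#'   `iteration`, `converged`, `model_trace` (if requested), `config`,
#'   `seed`.
#' @export
dl_fit <- function(data, family, config = dl_config(), seed = 1L,
                   init_models = NULL, clutter = NULL) {
  set.seed(seed)
  N <- dl_nobs(data)
  tol <- config$tol %||% (1e-6 * N)
  mono_tol <- 1e-8

  # --- initial model set: active (spawned or given) + clutter + dormant
  models <- list()
  idx <- 0L
  if (is.null(init_models)) {
    for (j in seq_len(config$n_models_init)) {
      idx <- idx + 1L
      models[[idx]] <- family$spawn(data, idx, r = 1)
    }
  } else {
    for (m in init_models) {
      idx <- idx + 1L
      m$index <- idx
      m$status <- "active"
      models[[idx]] <- m
    }
  }
  if (!is.null(clutter)) {
    idx <- idx + 1L
    clutter$index <- idx
    clutter$status <- "active"
    models[[idx]] <- clutter
  }
  n_act <- length(models)
  for (j in seq_len(config$n_dormant)) {
    idx <- idx + 1L
    d <- family$spawn(data, idx, r = config$r_floor)
    d$status <- "dormant"
    models[[idx]] <- d
  }
  # equal active rates, dormant at the floor
  for (i in seq_along(models))
    models[[i]]$r <- if (is_active(models[[i]]))
      (1 - config$n_dormant * config$r_floor) / n_act else config$r_floor

  es <- e_step(data, models)
  if (!is.finite(es$loglik))
    stop_input("non-finite similarity at initialization")

  trace <- es$loglik
  model_trace <- if (config$trace_models) list(models) else NULL
  converged <- FALSE
  iteration <- 0L

  if (is.finite(tol)) {
    ll_prev <- es$loglik
    for (it in seq_len(config$max_iter)) {
      f_t <- t(es$f)
      models <- dl_update_parameters(data, models, f_t, config$w_floor)
      models <- dl_update_rates(f_t, N, models, config$r_floor)
      # activation of dormant models crossing the threshold (vague re-spawn)
      for (i in seq_along(models)) {
        m <- models[[i]]
        if (m$status == "dormant" && m$r > config$activation_threshold) {
          sp <- m$family$spawn(data, m$index, m$r)
          sp$status <- "active"
          models[[i]] <- sp
        }
      }
      # deactivation is guarded so the log-similarity trace stays monotone
      models <- guarded_deactivate(data, models, config$activation_threshold,
                                   ll_prev, mono_tol)
      # periodic reseeding of models that claim no signal, guarded the
      # same way: accepted only if a one-step refit does not lose ground
      if (config$reseed_every > 0L && it %% config$reseed_every == 0L &&
          !is.null(family$reseed)) {
        es_cur <- e_step(data, models)
        trial <- family$reseed(data, models, es_cur$f)
        if (!is.null(trial)) {
          es_t <- e_step(data, trial)
          f_tt <- t(es_t$f)
          trial <- dl_update_parameters(data, trial, f_tt, config$w_floor)
          trial <- dl_update_rates(f_tt, N, trial, config$r_floor)
          ll_t <- dl_total_log_similarity(data, trial)
          if (ll_t >= ll_prev - mono_tol * max(1, abs(ll_prev)))
            models <- trial
        }
      }
      es <- e_step(data, models)
      iteration <- it
      trace <- c(trace, es$loglik)
      if (config$trace_models) model_trace[[it + 1L]] <- models
      if (config$verbose)
        message(sprintf("iter %3d  logL %.6f  active %d", it, es$loglik,
                        length(active_models(models))))
      if (abs(es$loglik - ll_prev) < tol) {
        converged <- TRUE
        break
      }
      ll_prev <- es$loglik
    }
  }

  if (config$prune) {
    if (config$merge %||% TRUE)
      models <- merge_models(data, models, N, config$penalty, config$kappa)
    models <- penalty_prune(data, models, N, config$penalty, config$kappa)
    # a short polish after structural cleanup (no further model-set changes)
    es <- e_step(data, models)
    for (it in seq_len(10L)) {
      ll0 <- es$loglik
      f_t <- t(es$f)
      models <- dl_update_parameters(data, models, f_t, config$w_floor)
      models <- dl_update_rates(f_t, N, models, config$r_floor)
      es <- e_step(data, models)
      if (abs(es$loglik - ll0) < tol) break
    }
  }

  structure(list(models = models, f = t(es$f), loglik = es$loglik,
                 loglik_trace = trace,
                 penalized = dl_penalized_similarity(es$loglik, models, N,
                                                     config$penalty,
                                                     config$kappa),
                 iteration = iteration, converged = converged,
                 model_trace = model_trace, config = config, seed = seed,
                 n = N),
            class = "dl_fit")
}

#' @export
#' @method print dl_fit
print.dl_fit <- function(x, ...) {
  cat(sprintf(paste0("<dl_fit: %d data, %d active models, logL = %.4f, ",
                     "%d iterations, converged = %s>\n"),
              x$n, length(active_models(x$models)), x$loglik, x$iteration,
              x$converged))
  invisible(x)
}

#' @export
#' @method summary dl_fit
summary.dl_fit <- function(object, ...) {
  act <- active_models(object$models)
  data.frame(index = vapply(act, function(m) m$index, integer(1)),
             family = vapply(act, function(m) m$family$name, character(1)),
             role = vapply(act, function(m) m$role, character(1)),
             r = vapply(act, function(m) m$r, numeric(1)),
             spread = vapply(act, function(m) m$spread, numeric(1)))
}
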
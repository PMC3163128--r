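#' Phase-cone parameters
#'
#' A phase cone is a circular travelling-ring event on a sensor array: a
#' Gaussian-profile ring of amplitude `a` and width `w` whose radius grows
#' (`v > 0`, expanding) or shrinks (`v < 0`, contracting) at `|v|` sensor
#' units per time step, starting at onset `t0`.
#'
#' @param x0,y0 ring center in sensor units.
#' @param t0 onset time in steps.
#' @param v signed radial speed (sensor units / step); must be nonzero.
#' @param a peak amplitude.
#' @param w ring width (Gaussian sd of the radial profile), sensor units.
#' @param R0 initial radius for contracting cones (`v < 0`); `NA` means
#'   "fill in `|v| * (T - t0)` from the scene duration", so the ring
#'   collapses to zero at the end of the recording.
#' @return list of class `cone_params`.
#' @export
cone_params <- function(x0, y0, t0, v, a, w, R0 = NA_real_) {
  if (w <= 0 || a <= 0) stop_input("cone needs w > 0 and a > 0")
  if (v == 0) stop_input("cone speed must be nonzero")
  structure(list(x0 = x0, y0 = y0, t0 = t0, v = v, a = a, w = w, R0 = R0),
            class = "cone_params")
}

#' Evaluate a phase-cone signal
#'
#' `a * exp(-(rho - R(t))^2 / (2 w^2))` for `t >= t0` and 0 before onset,
#' where `rho` is the distance to the center and the ring radius is
#' `R(t) = v (t - t0)` for expanding cones and
#' `R(t) = max(R0 + v (t - t0), 0)` for contracting ones.
#'
#' @param p a [cone_params()] (or compatible named list).
#' @param x,y,t coordinates (vectorized).
#' @param T_end recording duration, used to default `R0` for contracting
#'   cones when `p$R0` is `NA`.
#' @return numeric vector of amplitudes.
#' @export
cone_signal <- function(p, x, y, t, T_end = NULL) {
  rho <- sqrt((x - p$x0)^2 + (y - p$y0)^2)
  if (p$v > 0) {
    R <- p$v * (t - p$t0)
  } else {
    R0 <- p$R0
    if (is.na(R0)) {
      if (is.null(T_end)) stop_input("contracting cone needs R0 or T_end")
      R0 <- abs(p$v) * (T_end - p$t0)
    }
    R <- pmax(R0 + p$v * (t - p$t0), 0)
  }
  s <- p$a * exp(-(rho - R)^2 / (2 * p$w^2))
  s[t < p$t0] <- 0
  s
}

#' A ground-truth cone scene
#'
#' @param cones list of [cone_params()].
#' @param noise_sd standard deviation of the additive Gaussian sensor
#'   noise.
#' @param seed integer seed.
#' @return list of class `cone_scene`.
#' @export
cone_scene <- function(cones, noise_sd = 1, seed = 1L) {
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(list(cones = cones, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cone_scene")
}

#' Simulate a sensor array with phase-cone events
#'
#' Sums the scene's cone signals over an `X x Y x T` grid (unit sensor
#' spacing, integer time steps) and adds seeded Gaussian noise.
#'
#' @param scene a [cone_scene()].
#' @param dims integer vector `c(X, Y, T)`.
#' @param dt time-step duration in ms (metadata only; the demonstrations
#'   use 5 ms steps).
#' @return list with `data` (a `sensor_array`: 3-D amplitude array plus
#'   `dt` and `seed` attributes) and `truth` (the scene with contracting
#'   `R0` defaults filled in).
#' @export
generate_phase_cones <- function(scene, dims = c(64L, 64L, 40L), dt = 5) {
  stopifnot(inherits(scene, "cone_scene"), length(dims) == 3L, all(dims >= 1L))
  set.seed(scene$seed)
  X <- dims[1]; Y <- dims[2]; Tn <- dims[3]
  g <- expand.grid(x = seq_len(X), y = seq_len(Y), t = seq_len(Tn))
  amp <- numeric(nrow(g))
  cones <- lapply(scene$cones, function(p) {
    if (p$v < 0 && is.na(p$R0)) p$R0 <- abs(p$v) * (Tn - p$t0)
    p
  })
  for (p in cones) amp <- amp + cone_signal(p, g$x, g$y, g$t, T_end = Tn)
  if (scene$noise_sd > 0) amp <- amp + stats::rnorm(length(amp), 0, scene$noise_sd)
  arr <- array(amp, dim = c(X, Y, Tn))
  structure_arr <- structure(arr, dt = dt, seed = scene$seed,
                             class = "sensor_array")
  truth <- scene
  truth$cones <- cones
  list(data = structure_arr, truth = truth)
}

#' @export
#' @method print sensor_array
print.sensor_array <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<sensor_array %d x %d x %d, dt = %g ms>\n", d[1], d[2], d[3],
              attr(x, "dt") %||% NA))
  invisible(x)
}

#' The three-event demonstration scene
#'
#' Two expanding and one contracting cone on a 64 x 64 array in heavy
#' Gaussian noise (per-sample SNR = `snr` at the ring peak, amplitude 1).
#'
#' @param seed integer seed.
#' @param snr ring-peak amplitude over noise sd.
#' @param dims grid dimensions `c(X, Y, T)`.
#' @return a [cone_scene()].
#' @export
figure_scene <- function(seed = 1L, snr = 1, dims = c(64L, 64L, 40L)) {
  cone_scene(list(
    cone_params(x0 = 18, y0 = 18, t0 = 4, v = 1.1, a = 1, w = 2),
    cone_params(x0 = 46, y0 = 40, t0 = 10, v = 0.9, a = 1, w = 2),
    cone_params(x0 = 32, y0 = 32, t0 = 5, v = -0.8, a = 1, w = 2)
  ), noise_sd = 1 / snr, seed = seed)
}

# Flatten a sensor array into the point container the cone family consumes.
cone_points <- function(arr) {
  if (inherits(arr, "sensor_array") || is.array(arr)) {
    d <- dim(arr)
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), t = seq_len(d[3]))
    structure(list(coords = as.matrix(g), amp = as.numeric(arr),
                   n = nrow(g), dims = d),
              class = "cone_data")
  } else arr
}

cone_par_order <- c("x0", "y0", "t0", "speed", "a", "w")

# Predicted ring amplitude for a cone component at the data coordinates
# (compiled kernel; parameters passed in fixed order).
cone_predict <- function(par, orientation, coords, Tmax) {
  cone_predict_cpp(as.numeric(unlist(par)[cone_par_order]), orientation,
                   coords[, 1], coords[, 2], coords[, 3], Tmax)
}

#' Phase-cone model family
#'
#' Cone components predict the travelling-ring amplitude at each
#' `(x, y, t)` sample; the conditional similarity is Gaussian in the
#' amplitude residual with the component spread as variance.  The
#' f-weighted update runs a few damped Gauss-Newton steps of weighted
#' nonlinear least squares (Levenberg-damped normal equations with step
#' halving as the monotonicity guard, projected onto the parameter
#' bounds); for contracting cones the onset `t0` (which only gates the
#' ring) is updated by an exact discrete profile search over time steps.
#' Vague spawns start with a wide ring (`w_init`) and an inflated residual
#' variance, so early associations stay diffuse.
#'
#' @param dims grid dimensions `c(X, Y, T)`.
#' @param w_init initial (vague) ring width.
#' @param speed_bounds admissible `|v|` range.
#' @param inner_iter Gauss-Newton steps per outer iteration.
#' @return a [dl_family()].
#' @export
cone_family <- function(dims, w_init = NULL, speed_bounds = c(0.05, 5),
                        inner_iter = 5L) {
  Xd <- dims[1]; Yd <- dims[2]; Tmax <- dims[3]
  w_init <- w_init %||% (max(Xd, Yd) / 4)
  # the ring width is bounded above by the vague spawn width: anything
  # wider than a quarter of the array is a background surface, not a
  # travelling ring, and would re-model the noise instead of an event
  lower <- c(x0 = -0.25 * Xd, y0 = -0.25 * Yd, t0 = 0,
             speed = speed_bounds[1], a = 1e-3, w = 0.5)
  upper <- c(x0 = 1.25 * Xd, y0 = 1.25 * Yd, t0 = Tmax,
             speed = speed_bounds[2], a = Inf, w = w_init)

  dl_family(
    name = "cone",
    loglik = function(comp, data) {
      data <- cone_points(data)
      g <- cone_predict(comp$params$par, comp$params$orientation,
                        data$coords, Tmax)
      -0.5 * (log(2 * pi * comp$spread) + (data$amp - g)^2 / comp$spread)
    },
    update = function(comp, data, w) {
      data <- cone_points(data)
      ord_par <- function(p) as.numeric(p[cone_par_order])

      # damped Gauss-Newton on the weighted residuals: fused normal
      # equations with Levenberg damping, box projection onto the
      # parameter bounds, and step halving as the monotonicity guard;
      # for contracting rings the onset (which only gates the signal) is
      # then updated by an exact discrete profile search
      gn_fit <- function(par, ori, xk, yk, tk, wk, amp) {
        free <- if (ori > 0) c("x0", "y0", "t0", "speed", "a", "w")
                else c("x0", "y0", "speed", "a", "w")
        cols <- match(free, cone_par_order)
        sse <- cone_wsse_cpp(ord_par(par), ori, xk, yk, tk, Tmax, wk, amp)
        for (gn in seq_len(inner_iter)) {
          terms <- cone_gn_terms_cpp(ord_par(par), ori, xk, yk, tk, Tmax,
                                     wk, amp, cols)
          H <- terms$H
          sse <- terms$sse
          lam <- 1e-3 * mean(diag(H))
          step <- tryCatch(solve(H + diag(lam, ncol(H)), -terms$grad),
                           error = function(e) NULL)
          if (is.null(step) || !all(is.finite(step))) break
          alpha <- 1
          improved <- FALSE
          for (h in 1:6) {
            cand <- par
            cand[free] <- pmin(pmax(par[free] + alpha * step, lower[free]),
                               upper[free])
            sse_c <- cone_wsse_cpp(ord_par(cand), ori, xk, yk, tk, Tmax,
                                   wk, amp)
            if (sse_c <= sse) {
              par <- cand
              sse <- sse_c
              improved <- TRUE
              break
            }
            alpha <- alpha / 2
          }
          if (!improved) break
        }
        if (ori < 0) {
          gpar <- par; gpar[["t0"]] <- 0
          g_un <- cone_predict(gpar, ori, cbind(xk, yk, tk), Tmax)
          a_t <- rowsum(wk * amp^2, tk)[, 1]
          b_t <- rowsum(wk * (amp - g_un)^2, tk)[, 1]
          steps <- as.integer(names(a_t))
          # wsse(t0) = sum_{t < t0} w amp^2 + sum_{t >= t0} w (amp - g)^2
          wsse <- rev(cumsum(rev(b_t)))
          wsse <- wsse + c(0, cumsum(a_t))[seq_along(steps)]
          best <- which.min(wsse)
          par[["t0"]] <- steps[best]
          sse <- wsse[best]
        }
        list(par = par, sse = sse)
      }

      pc <- unlist(comp$params$par)
      ori0 <- comp$params$orientation
      vague <- pc[["w"]] > 4
      if (vague) {
        # vague models keep the full weighted point set: they are still
        # deciding what they are, including their orientation
        keep <- which(w > max(w) * 1e-12)
      } else {
        # crisp models only see points near their ring: outside the band
        # the prediction and its gradient are numerically zero, so those
        # points add a constant that cancels from every step decision
        tt_all <- data$coords[, 3]
        rho_all <- sqrt((data$coords[, 1] - pc[["x0"]])^2 +
                          (data$coords[, 2] - pc[["y0"]])^2)
        R_all <- if (ori0 > 0) pc[["speed"]] * (tt_all - pc[["t0"]])
                 else pc[["speed"]] * (Tmax - tt_all)
        sel <- abs(rho_all - R_all) <= pmax(4 * pc[["w"]], 8)
        if (ori0 > 0) sel <- sel & (tt_all >= pc[["t0"]] - 3)
        keep <- which(sel & w > max(w) * 1e-12)
        if (length(keep) < 200L) keep <- which(w > max(w) * 1e-12)
      }
      xk <- data$coords[keep, 1]; yk <- data$coords[keep, 2]
      tk <- data$coords[keep, 3]
      wk <- w[keep]
      amp <- data$amp[keep]

      fit0 <- gn_fit(pc, ori0, xk, yk, tk, wk, amp)
      par <- fit0$par
      ori <- ori0
      comp$params$par <- as.list(par)
      comp$params$orientation <- ori
      g <- cone_predict(par, ori, data$coords, Tmax)
      comp$spread <- max(sum(w * (data$amp - g)^2) / sum(w), 1e-6)
      comp
    },
    spawn = function(data, index, r) {
      data <- cone_points(data)
      # alternate orientations by index so both signs are always covered,
      # and stratify each orientation cohort over the array quadrants so
      # spawns do not crowd one event by chance
      ori <- if (index %% 2L == 1L) 1 else -1
      blk <- ((index - 1L) %/% 2L) %% 4L + 1L
      bx <- c(0.3, 0.7, 0.3, 0.7)[blk]
      by <- c(0.3, 0.3, 0.7, 0.7)[blk]
      par <- list(x0 = (bx + stats::runif(1, -0.15, 0.15)) * Xd,
                  y0 = (by + stats::runif(1, -0.15, 0.15)) * Yd,
                  t0 = stats::runif(1, 0, Tmax / 3),
                  speed = stats::runif(1, 0.6, 1.6),
                  a = stats::sd(data$amp),
                  w = w_init)
      dl_component(cone_family(dims, w_init, speed_bounds, inner_iter),
                   params = list(par = par, orientation = ori,
                                 w_vague = w_init),
                   spread = 2 * stats::var(data$amp), r = r, index = index)
    },
    n_free = function(comp) 7L,
    predict = function(comp, data) {
      data <- cone_points(data)
      cone_predict(comp$params$par, comp$params$orientation, data$coords, Tmax)
    },
    reseed = function(data, models, f) {
      data <- cone_points(data)
      act <- active_models(models)
      pos <- which(vapply(act, function(m)
        !is_clutter(m) && m$family$name == "cone", logical(1)))
      if (length(pos) < 2L) return(NULL)
      preds <- lapply(act[pos], function(m)
        cone_predict(m$params$par, m$params$orientation, data$coords, Tmax))
      # signal energy each cone model actually claims; ~0 marks a model
      # stuck as a background duplicate with no gradient toward any ring
      u <- vapply(seq_along(pos), function(j)
        sum(f[, pos[j]] * preds[[j]]^2), numeric(1))
      if (max(u) <= 0) return(NULL)
      stuck <- which(u < 0.01 * max(u))
      if (length(stuck) == 0L) return(NULL)
      worst <- stuck[which.min(u[stuck])]
      # unexplained positive residual, binned coarsely over the array
      mix <- Reduce(`+`, lapply(seq_along(pos), function(j)
        f[, pos[j]] * preds[[j]]))
      resid <- pmax(data$amp - mix, 0)
      bx <- pmin((data$coords[, 1] - 1) %/% 4L, (Xd - 1) %/% 4L)
      by <- pmin((data$coords[, 2] - 1) %/% 4L, (Yd - 1) %/% 4L)
      cell <- bx * 64L + by
      cs <- rowsum(resid, cell)
      top <- as.integer(rownames(cs)[which.max(cs[, 1])])
      cx <- (top %/% 64L) * 4 + 2.5
      cy <- (top %% 64L) * 4 + 2.5
      idx <- act[[pos[worst]]]$index
      for (k in seq_along(models)) {
        if (models[[k]]$index == idx) {
          models[[k]]$params$par <- list(
            x0 = cx, y0 = cy, t0 = 2,
            speed = 1, a = stats::sd(data$amp), w = w_init / 2)
          models[[k]]$spread <- stats::var(data$amp)
        }
      }
      models
    }
  )
}

# Gaussian background family for the amplitude channel: free mean and
# variance, the natural clutter model for Gaussian sensor noise.
gaussian_background_family <- function() {
  dl_family(
    name = "gaussian_background",
    loglik = function(comp, data) {
      data <- cone_points(data)
      stats::dnorm(data$amp, comp$params$mean, sqrt(comp$spread), log = TRUE)
    },
    update = function(comp, data, w) {
      data <- cone_points(data)
      sw <- sum(w)
      mu <- sum(w * data$amp) / sw
      comp$params$mean <- mu
      comp$spread <- max(sum(w * (data$amp - mu)^2) / sw, 1e-10)
      comp
    },
    spawn = function(data, index, r) {
      data <- cone_points(data)
      dl_component(gaussian_background_family(),
                   params = list(mean = mean(data$amp)),
                   spread = stats::var(data$amp), r = r, index = index,
                   role = "clutter")
    },
    n_free = function(comp) 2L
  )
}

#' Fit phase-cone models to sensor-array data
#'
#' Runs the dynamic-logic engine on the flattened `(x, y, t, amplitude)`
#' samples with the cone family plus one background clutter component.
#' The default clutter is a free-mean/variance Gaussian on the amplitude
#' (matched to the Gaussian sensor noise of the simulator); `"uniform"`
#' uses a uniform density over the observed amplitude range.
#'
#' @param data a `sensor_array` (or the result of
#'   [generate_phase_cones()]'s `data` element).
#' @param n_models number of initial cone models (spawned vague, mixed
#'   orientations).
#' @param config a [dl_config()]; defaults to a cone-appropriate one with
#'   model tracing on.
#' @param seed integer seed.
#' @param clutter `"gaussian"` or `"uniform"` background component.
#' @param ... passed to [cone_family()].
#' @return a [dl_fit()] object.
#' @export
fit_cones <- function(data, n_models = 8L, config = NULL, seed = 1L,
                      clutter = c("gaussian", "uniform"), ...) {
  clutter <- match.arg(clutter)
  pts <- cone_points(data)
  # BIC-weighted skeptic penalty: with ~10^5 samples a 7-parameter ring
  # can scavenge more than an AIC unit's worth of noise, so noise
  # suppression needs the sample-size-aware kappa.  The default iteration
  # budget is modest: events localize within about ten iterations, and
  # iterations far beyond the annealing phase only let surplus models
  # slowly absorb noise structure.
  if (is.null(config))
    config <- dl_config(n_models_init = n_models, n_dormant = 0L,
                        penalty = "bic", max_iter = 60L, reseed_every = 3L,
                        trace_models = TRUE)
  config$n_models_init <- as.integer(n_models)
  fam <- cone_family(pts$dims, ...)
  cl <- if (clutter == "gaussian") {
    gaussian_background_family()$spawn(pts, 0L, 1)
  } else {
    rng <- range(pts$amp)
    uniform_clutter_family(rng[1], rng[2])$spawn(pts, 0L, 1)
  }
  dl_fit(pts, fam, config, seed = seed, clutter = cl)
}

# Signed speed of an active cone component.
cone_signed_speed <- function(comp) {
  comp$params$orientation * comp$params$par[["speed"]]
}

# Active cone (non-clutter) components of a fit or model list.
active_cones <- function(models) {
  if (inherits(models, "dl_fit")) models <- models$models
  Filter(function(m) !is_clutter(m) && m$family$name == "cone",
         active_models(models))
}

# A cone model still at (or near) its vague spawn width has not crispened
# into an event; it is a residual background surface.
is_crisp_cone <- function(comp, frac = 0.75) {
  vw <- comp$params$w_vague %||% Inf
  comp$params$par[["w"]] < frac * vw
}

#' Count expanding and contracting events
#'
#' Counts active cone models by the sign of their radial speed, excluding
#' the clutter component and any cone model whose ring width never left
#' the vague-spawn regime (such a model is still a vague background
#' surface, not a detected event; see the `crisp_frac` threshold).
#'
#' @param models a [dl_fit()] or list of [dl_component()]s.
#' @param crisp_frac a cone model counts as an event only if its ring
#'   width is below this fraction of its vague spawn width (models built
#'   without a recorded spawn width are always counted).
#' @return named integer vector `c(expanding =, contracting =)`.
#' @export
classify_events <- function(models, crisp_frac = 0.75) {
  cones <- Filter(function(m) is_crisp_cone(m, crisp_frac),
                  active_cones(models))
  v <- vapply(cones, cone_signed_speed, numeric(1))
  c(expanding = sum(v > 0), contracting = sum(v < 0))
}

#' Matched recovery errors of fitted cones
#'
#' Greedily matches fitted cone models to ground-truth cones by combined
#' center-plus-onset distance (closest pair first) and reports
#' per-parameter absolute errors.
#'
#' @param models a [dl_fit()] or list of [dl_component()]s.
#' @param truth a [cone_scene()] (ground truth).
#' @return list with `matches` (data.frame: one row per truth cone, with
#'   `matched`, `center_error`, `t0_error`, `v_error`, `a_error`,
#'   `w_error`, `sign_correct`) and `unmatched_fitted` (count of active
#'   cone models not matched to any truth cone).
#' @export
recovery_metrics <- function(models, truth) {
  cones_t <- truth$cones
  if (length(cones_t) == 0L) stop_input("truth must contain at least one cone")
  fitted <- active_cones(models)
  nf <- length(fitted)
  nt <- length(cones_t)
  res <- data.frame(truth = seq_len(nt), matched = FALSE,
                    center_error = NA_real_, t0_error = NA_real_,
                    v_error = NA_real_, a_error = NA_real_,
                    w_error = NA_real_, sign_correct = NA)
  used_f <- logical(nf)
  if (nf > 0L) {
    dist <- matrix(Inf, nf, nt)
    for (i in seq_len(nf)) {
      pf <- fitted[[i]]$params$par
      for (j in seq_len(nt)) {
        pt <- cones_t[[j]]
        dist[i, j] <- sqrt((pf[["x0"]] - pt$x0)^2 + (pf[["y0"]] - pt$y0)^2 +
                             (pf[["t0"]] - pt$t0)^2)
      }
    }
    used_t <- logical(nt)
    for (k in seq_len(min(nf, nt))) {
      d <- dist
      d[used_f, ] <- Inf
      d[, used_t] <- Inf
      ij <- arrayInd(which.min(d), dim(d))
      i <- ij[1]; j <- ij[2]
      if (!is.finite(d[i, j])) break
      used_f[i] <- TRUE; used_t[j] <- TRUE
      pf <- fitted[[i]]$params$par
      pt <- cones_t[[j]]
      v_f <- cone_signed_speed(fitted[[i]])
      res$matched[j] <- TRUE
      res$center_error[j] <- sqrt((pf[["x0"]] - pt$x0)^2 + (pf[["y0"]] - pt$y0)^2)
      res$t0_error[j] <- abs(pf[["t0"]] - pt$t0)
      res$v_error[j] <- abs(v_f - pt$v)
      res$a_error[j] <- abs(pf[["a"]] - pt$a)
      res$w_error[j] <- abs(pf[["w"]] - pt$w)
      res$sign_correct[j] <- sign(v_f) == sign(pt$v)
    }
  }
  list(matches = res, unmatched_fitted = sum(!used_f))
}

#' Are all planted cones accounted for by the fitted models?
#'
#' `TRUE` when there is an injective assignment of truth cones to active
#' cone models such that every truth cone gets a model with the correct
#' speed sign and center error at most `center_tol` (an assignment
#' problem on center distance, with sign-incompatible pairs excluded).
#'
#' @param models a [dl_fit()] or list of [dl_component()]s.
#' @param truth a [cone_scene()].
#' @param center_tol center-error tolerance in sensor units.
#' @return logical scalar.
#' @export
all_events_matched <- function(models, truth, center_tol = 1) {
  fitted <- active_cones(models)
  nt <- length(truth$cones)
  if (length(fitted) < nt) return(FALSE)
  big <- 1e9
  cost <- matrix(big, nt, length(fitted))
  for (j in seq_len(nt)) {
    pt <- truth$cones[[j]]
    for (i in seq_along(fitted)) {
      pf <- fitted[[i]]$params$par
      v_f <- cone_signed_speed(fitted[[i]])
      d <- sqrt((pf[["x0"]] - pt$x0)^2 + (pf[["y0"]] - pt$y0)^2)
      if (sign(v_f) == sign(pt$v) && d <= center_tol) cost[j, i] <- d
    }
  }
  m <- min_cost_matching(cost)
  all(cost[cbind(seq_len(nt), m$assignment)] < big)
}

#' First iteration at which all planted cones are recovered
#'
#' Scans the model trace of a cone fit (run with `trace_models = TRUE`)
#' and returns the first outer-iteration index at which
#' [all_events_matched()] holds: every truth cone has its own active model
#' with center error at most `center_tol` and the correct speed sign.
#'
#' @param fit a [dl_fit()] with a model trace.
#' @param truth a [cone_scene()].
#' @param center_tol center-error tolerance in sensor units.
#' @return integer iteration (0 = initial models), or `NA` if never.
#' @export
first_matched_iteration <- function(fit, truth, center_tol = 1) {
  if (is.null(fit$model_trace))
    stop_input("fit was run without trace_models = TRUE")
  for (i in seq_along(fit$model_trace)) {
    if (all_events_matched(fit$model_trace[[i]], truth, center_tol))
      return(i - 1L)
  }
  NA_integer_
}
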
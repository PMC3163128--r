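#' Model families for the dynamic-logic engine
#'
#' A model family bundles everything the fitting engine needs to know about
#' one parametric class of concept models: how a component predicts the
#' bottom-up signal, the conditional similarity \eqn{l(n|m)} of a datum
#' given the component, the f-weighted parameter update (the fixed point of
#' the dynamic-logic flow, i.e. a weighted maximum-likelihood step), and how
#' to spawn a maximally vague component.
#'
#' @param name character scalar naming the family.
#' @param loglik `function(comp, data)` returning the vector of
#'   log conditional similarities \eqn{\log l(n|m)} for all data.
#' @param update `function(comp, data, w)` returning the component with
#'   parameters (and spread, where estimated) replaced by their
#'   `w`-weighted maximum-likelihood values.
#' @param spawn `function(data, index, r)` returning a maximally vague
#'   active component.  May consume the current RNG stream.
#' @param n_free `function(comp)` number of free parameters the component
#'   contributes to the skeptic penalty.
#' @param predict `function(comp, data)` predicted signal (optional).
#' @param wrap `function(datum)` wraps one raw datum into the family's data
#'   container, used by [dl_conditional_similarity()].
#' @param reseed optional `function(data, models, f)` proposing a model set
#'   in which components that claim no signal have been relocated to
#'   unexplained structure (the "form a new model" move); return `NULL` to
#'   propose nothing.  The engine accepts a proposal only if the
#'   log-similarity does not decrease after a one-step refit.
#'
#' @return an object of class `dl_family`.
#' @seealso [gaussian_family()], [bernoulli_family()], [cone_family()],
#'   [uniform_clutter_family()]
#' @export
dl_family <- function(name, loglik, update, spawn, n_free,
                      predict = NULL, wrap = NULL, reseed = NULL) {
  stopifnot(is.character(name), is.function(loglik), is.function(update),
            is.function(spawn), is.function(n_free))
  structure(list(name = name, loglik = loglik, update = update,
                 spawn = spawn, n_free = n_free, predict = predict,
                 wrap = wrap %||% function(datum) matrix(datum, nrow = 1L),
                 reseed = reseed),
            class = "dl_family")
}

#' @export
#' @method print dl_family
print.dl_family <- function(x, ...) {
  cat("<dl_family:", x$name, ">\n")
  invisible(x)
}

#' Construct a model component
#'
#' A component is one top-down concept model: its family, parameter list,
#' vagueness (`spread`), prior rate `r`, and active/dormant status.
#' Components with `role = "clutter"` are background models: they are never
#' deactivated and are excluded from event counting.
#'
#' @param family a [dl_family()].
#' @param params named list of family-specific parameters.
#' @param spread positive vagueness parameter (e.g. a residual variance).
#' @param r prior rate in `[0, 1]`.
#' @param index integer component index.
#' @param status `"active"` or `"dormant"`.
#' @param role `"model"` or `"clutter"`.
#' @return an object of class `dl_component`.
#' @export
dl_component <- function(family, params, spread = 1, r = 1, index = 1L,
                         status = "active", role = "model") {
  if (!inherits(family, "dl_family")) stop_input("`family` must be a dl_family")
  if (!is.numeric(spread) || spread <= 0) stop_input("`spread` must be > 0")
  if (r < 0 || r > 1) stop_input("`r` must lie in [0, 1]")
  status <- match.arg(status, c("active", "dormant"))
  role <- match.arg(role, c("model", "clutter"))
  structure(list(family = family, params = params, spread = spread,
                 r = r, index = as.integer(index), status = status,
                 role = role),
            class = "dl_component")
}

#' @export
#' @method print dl_component
print.dl_component <- function(x, ...) {
  cat(sprintf("<dl_component %d [%s/%s] family=%s r=%.4g spread=%.4g>\n",
              x$index, x$status, x$role, x$family$name, x$r, x$spread))
  invisible(x)
}

is_active <- function(comp) comp$status == "active"
is_clutter <- function(comp) comp$role == "clutter"

# Number of observations a family data container holds.
dl_nobs <- function(data) {
  if (is.list(data) && !is.null(data$n)) return(data$n)
  nrow(data)
}

#' Gaussian cluster family
#'
#' Spherical Gaussian components with a free mean vector and a shared
#' per-component variance (`spread`).  The predicted signal is the mean,
#' the conditional similarity is the multivariate normal density, the
#' update is the f-weighted mean and variance, and a vague spawn sits at
#' the global data centroid with the global variance.
#'
#' @param estimate_spread logical; if `FALSE` the variance is held fixed at
#'   its current value and only the mean is updated.
#' @param spread_floor smallest admissible variance.
#' @return a [dl_family()].
#' @export
gaussian_family <- function(estimate_spread = TRUE, spread_floor = 1e-10) {
  dl_family(
    name = "gaussian",
    loglik = function(comp, data) {
      X <- as.matrix(data)
      mu <- comp$params$mean
      if (length(mu) != ncol(X)) stop_input("dimension mismatch in gaussian loglik")
      if (comp$spread <= 0) stop_input("nonpositive spread")
      d <- sweep(X, 2L, mu)
      q <- rowSums(d * d)
      -0.5 * (ncol(X) * log(2 * pi * comp$spread) + q / comp$spread)
    },
    update = function(comp, data, w) {
      X <- as.matrix(data)
      sw <- sum(w)
      mu <- as.numeric(crossprod(X, w)) / sw
      comp$params$mean <- mu
      if (estimate_spread) {
        d <- sweep(X, 2L, mu)
        s2 <- sum(w * rowSums(d * d)) / (ncol(X) * sw)
        comp$spread <- max(s2, spread_floor)
      }
      comp
    },
    spawn = function(data, index, r) {
      X <- as.matrix(data)
      v0 <- mean(apply(X, 2L, stats::var))
      if (!is.finite(v0) || v0 <= 0) v0 <- 1
      # anchor at a random datum (breaks the symmetry of identical vague
      # spawns) but keep the global variance, i.e. a maximally vague spread
      mu <- X[sample.int(nrow(X), 1L), ]
      dl_component(gaussian_family(estimate_spread, spread_floor),
                   params = list(mean = mu), spread = v0, r = r,
                   index = index)
    },
    n_free = function(comp) length(comp$params$mean) + as.integer(estimate_spread),
    predict = function(comp, data) {
      matrix(comp$params$mean, nrow = dl_nobs(data),
             ncol = length(comp$params$mean), byrow = TRUE)
    }
  )
}

#' Uniform clutter family
#'
#' A background component with constant density `1 / volume` over a fixed
#' axis-aligned box (for scalar amplitudes, `1 / (hi - lo)`).  It has no
#' free parameters and takes no updates; it simply soaks up signals no
#' structured model claims.
#'
#' @param lo,hi numeric vectors bounding the support box.
#' @return a [dl_family()].
#' @export
uniform_clutter_family <- function(lo, hi) {
  if (any(hi <= lo)) stop_input("uniform clutter requires hi > lo")
  log_dens <- -sum(log(hi - lo))
  dl_family(
    name = "uniform_clutter",
    loglik = function(comp, data) rep(log_dens, dl_nobs(data)),
    update = function(comp, data, w) comp,
    spawn = function(data, index, r) {
      dl_component(uniform_clutter_family(lo, hi), params = list(lo = lo, hi = hi),
                   spread = 1, r = r, index = index, role = "clutter")
    },
    n_free = function(comp) 0L,
    wrap = function(datum) matrix(datum, nrow = 1L)
  )
}
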
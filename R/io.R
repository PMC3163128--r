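#' Write / read a sensor array as a plain-text container
#'
#' A small self-describing flat format: a JSON header line (dims, dt,
#' seed) followed by the amplitudes in column-major order, one value per
#' line.  Round-trips [generate_phase_cones()] output exactly.
#'
#' @param x a `sensor_array`.
#' @param path file path.
#' @return `write_sensor_array` returns `path` invisibly;
#'   `read_sensor_array` returns a `sensor_array`.
#' @export
write_sensor_array <- function(x, path) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  header <- jsonlite::toJSON(list(dims = dim(x),
                                  dt = attr(x, "dt") %||% 1,
                                  seed = attr(x, "seed") %||% NA),
                             auto_unbox = TRUE, digits = NA)
  writeLines(paste0("#", header), con)
  writeLines(format(as.numeric(x), digits = 17, trim = TRUE, scientific = TRUE),
             con)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#")) stop_input("missing sensor-array header")
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  vals <- as.numeric(lines[-1])
  if (length(vals) != prod(header$dims)) stop_input("corrupt sensor-array file")
  structure(array(vals, dim = header$dims), dt = header$dt,
            seed = header$seed, class = "sensor_array")
}

#' Write / read binary situation data as sparse-triplet text
#'
#' Tab-separated `row  col` pairs of the 1-entries, preceded by a JSON
#' header with the matrix dimensions, so large sparse binary matrices
#' round-trip compactly.
#'
#' @param x binary matrix (dense or sparse).
#' @param path file path.
#' @return `write_situations` returns `path` invisibly;
#'   `read_situations` returns a sparse `dgCMatrix`.
#' @export
write_situations <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  idx <- Matrix::which(x != 0, arr.ind = TRUE)
  writeLines(paste0("#", jsonlite::toJSON(list(nrow = nrow(x), ncol = ncol(x)),
                                          auto_unbox = TRUE)), con)
  writeLines(paste(idx[, 1], idx[, 2], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_situations
#' @export
read_situations <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#")) stop_input("missing situations header")
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  if (length(lines) > 1L) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    ii <- as.integer(vapply(parts, `[[`, "", 1L))
    jj <- as.integer(vapply(parts, `[[`, "", 2L))
  } else {
    ii <- jj <- integer(0)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(header$nrow, header$ncol),
                       dimnames = list(NULL, paste0("obj", seq_len(header$ncol))))
}

# Serializable view of one model component.
component_to_list <- function(m) {
  params <- m$params
  if (!is.null(params$par)) params$par <- as.list(params$par)
  list(index = m$index, family = m$family$name, role = m$role,
       status = m$status, r = m$r, spread = m$spread, params = params)
}

#' Serialize a fit to JSON
#'
#' Writes the model parameters, rates, statuses, the log-similarity trace
#' and the convergence state; the reverse of a full fit object (families
#' are referenced by name, not round-tripped as closures).
#'
#' @param fit a [dl_fit()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(
    n = fit$n, seed = fit$seed, iteration = fit$iteration,
    converged = fit$converged, loglik = fit$loglik,
    penalized = fit$penalized, loglik_trace = fit$loglik_trace,
    models = lapply(fit$models, component_to_list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit configuration from a flat YAML file
#'
#' Recognized keys: `family`, `n_models_init`, `n_dormant`,
#' `activation_threshold`, `penalty`, `kappa`, `tol`, `max_iter`, `seed`;
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return list with `config` (a [dl_config()]), `family` (character or
#'   `NULL`) and `seed` (integer or `NULL`).
#' @export
read_fit_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("family", "n_models_init", "n_dormant", "activation_threshold",
             "penalty", "kappa", "tol", "max_iter", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop_input("unknown config keys: ", paste(bad, collapse = ", "))
  args <- raw[intersect(names(raw), c("n_models_init", "n_dormant",
                                      "activation_threshold", "penalty",
                                      "kappa", "tol", "max_iter"))]
  list(config = do.call(dl_config, args),
       family = raw$family, seed = raw$seed)
}
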
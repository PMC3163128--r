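#' Minimum-cost one-to-one assignment
#'
#' Solves the rectangular assignment problem (rows to columns,
#' `nrow(cost) <= ncol(cost)`) by the shortest-augmenting-path form of the
#' Hungarian algorithm with dual potentials, in `O(n^2 m)`.  Used to match
#' fitted models to planted ground-truth components; written here because
#' no installed package provides a weighted bipartite matcher.
#'
#' @param cost numeric cost matrix with `nrow(cost) <= ncol(cost)`.
#' @return list with `assignment` (for each row, the matched column) and
#'   `cost` (the total matched cost).
#' @export
min_cost_matching <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n > m) stop_input("cost matrix must have nrow <= ncol")
  if (any(!is.finite(cost))) stop_input("cost matrix must be finite")
  # 1-based potentials; column 0 is the virtual start of each augmenting path
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)    # p[j + 1]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      minv[free_j[upd] + 1L] <- cur[upd]
      way[free_j[upd] + 1L] <- j0
      k <- which.min(minv[free_j + 1L])
      delta <- minv[free_j[k] + 1L]
      j1 <- free_j[k]
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
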
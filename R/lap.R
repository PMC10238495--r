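#' Minimum-cost linear assignment
#'
#' Solves the rectangular linear assignment problem (LAP) by the Hungarian
#' algorithm with potentials (O(n^3)). Used by cell and ridge tracking to
#' link detections between consecutive frames at globally minimal total
#' centroid distance; forbidden pairings are encoded as `Inf` cost.
#'
#' @param cost numeric cost matrix (rows = sources, columns = targets);
#'   `Inf` forbids a pairing.
#' @return Integer vector of length `nrow(cost)`; entry `i` is the column
#'   assigned to row `i`, or `NA` when the row stays unassigned (only possible
#'   through forbidden or padded pairings).
#' @examples
#' solve_lap(matrix(c(1, 4, 4, 1), 2, 2))  # keeps the diagonal
#' @export
solve_lap <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nr))
  finite <- cost[is.finite(cost)]
  # Finite surrogate for forbidden pairings, large enough never to displace a
  # feasible assignment.
  big <- if (length(finite)) sum(abs(finite)) + max(abs(finite), 1) + 1 else 1
  n <- max(nr, nc)
  a <- matrix(big, n, n)
  a[seq_len(nr), seq_len(nc)] <- ifelse(is.finite(cost), cost, big)

  virt <- n + 1L
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j]: row currently matched to column j
  for (i in seq_len(n)) {
    p[virt] <- i
    j0 <- virt
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    way <- integer(n)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- a[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == virt) break
    }
  }

  assign_of_row <- integer(nr)
  for (j in seq_len(n)) if (p[j] >= 1 && p[j] <= nr) assign_of_row[p[j]] <- j
  out <- rep(NA_integer_, nr)
  for (i in seq_len(nr)) {
    j <- assign_of_row[i]
    if (j >= 1 && j <= nc && is.finite(cost[i, j])) out[i] <- j
  }
  out
}
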
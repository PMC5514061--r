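# Linear assignment (Hungarian) solver: shortest augmenting path with dual
# potentials, O(n^3). Used to match curvature maxima between two boundaries'
# scale-space representations.

#' Solve the linear assignment problem
#'
#' Finds the column assignment of each row of a square cost matrix that
#' minimizes the total cost (Hungarian algorithm, augmenting-path form).
#'
#' @param cost square numeric matrix of finite costs.
#' @return list with `assignment` (column index per row) and `cost`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials; index 1 is the virtual column
  p <- integer(n + 1L)       # row matched to column (index j+1); 0 = free
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free_j <- which(!used)
      cur <- cost[i0, free_j - 1L] - u[i0] - v[free_j]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd]] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  assignment[p[2:(n + 1L)]] <- seq_len(n)
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
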
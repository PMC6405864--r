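# Optimal one-to-one assignment (Hungarian algorithm, shortest
# augmenting path formulation, O(n^3)). Rectangular cost matrices are
# padded internally to square; returns, for each row, the assigned
# column (NA for assignments to padding). Used to match fitted fibrils
# to ground truth. Verified in tests against brute-force permutation
# enumeration at small n.

solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  pad <- if (any(is.finite(cost))) max(cost[is.finite(cost)]) + 1 else 1
  C <- matrix(pad, n, n)
  C[seq_len(nr), seq_len(nc)] <- cost
  INF <- .Machine$double.xmax / 4
  # columns indexed 1..n+1, where index 1 is the virtual column
  u <- numeric(n); v <- numeric(n + 1L)
  p <- integer(n + 1L)    # row assigned to each column (0 = none)
  way <- integer(n + 1L)  # predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      cols <- which(!used)
      cols <- cols[cols > 1L]
      if (length(cols)) {
        cur <- C[i0, cols - 1L] - u[i0] - v[cols]
        upd <- cur < minv[cols]
        minv[cols[upd]] <- cur[upd]
        way[cols[upd]] <- j0
        j1 <- cols[which.min(minv[cols])]
        delta <- minv[j1]
      }
      on <- which(used)
      u[p[on]] <- u[p[on]] + delta
      v[on] <- v[on] - delta
      off <- which(!used)
      minv[off] <- minv[off] - delta
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
  assign <- rep(NA_integer_, nr)
  for (j in seq_len(n + 1L)[-1L]) {
    if (p[j] >= 1L && p[j] <= nr && (j - 1L) <= nc) assign[p[j]] <- j - 1L
  }
  assign
}
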
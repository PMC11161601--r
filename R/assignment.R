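# Minimum-cost bipartite assignment (Hungarian algorithm, shortest
# augmenting path formulation, O(n^3)). Used to resolve frame-to-frame
# linking globally instead of by independent nearest neighbors, which
# mislinks chains of co-moving particles.
#
# cost: n x m matrix; Inf marks forbidden pairs. Returns an integer vector
# of length n: the column assigned to each row, NA where the row is left
# unassigned (only happens when forbidden entries force it).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer(0))
  big <- {
    fin <- cost[is.finite(cost)]
    if (length(fin) == 0) 1 else max(fin) * (n + m) + 1
  }
  size <- max(n, m)
  C <- matrix(big, size, size)
  Cf <- cost
  Cf[!is.finite(Cf)] <- big
  C[seq_len(n), seq_len(m)] <- Cf
  u <- numeric(size + 1)
  v <- numeric(size + 1)
  p <- integer(size + 1)            # p[j+1]: row matched to column j
  for (i in seq_len(size)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, size)
    used <- rep(FALSE, size + 1)
    way <- integer(size)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- -1
      for (j in seq_len(size)) {
        if (!used[j + 1]) {
          cur <- C[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:size) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_of_row <- rep(NA_integer_, n)
  for (j in seq_len(size)) {
    i <- p[j + 1]
    if (i >= 1 && i <= n && j <= m && is.finite(cost[i, j]))
      assign_of_row[i] <- j
  }
  assign_of_row
}
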
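## Rectangular linear-sum assignment by shortest augmenting paths
## (Jonker–Volgenant).  Used by the matching loss to pair ground-truth
## points one-to-one with point proposals.

#' Minimum-cost one-to-one assignment
#'
#' Solves the rectangular assignment problem for a cost matrix with
#' `nrow(cost) <= ncol(cost)`: every row is assigned a distinct column so
#' the total cost is minimal.
#'
#' @param cost Numeric cost matrix, rows <= columns, all finite.
#' @return Integer vector: for each row, its assigned column.
#' @export
hungarian_match <- function(cost) {
  if (!is.matrix(cost)) cost <- matrix(cost, nrow = 1L)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer())
  if (n > m) stop_contract("cost matrix needs nrow <= ncol")
  if (!all(is.finite(cost))) stop_contract("cost matrix must be finite")

  u <- numeric(n); v <- numeric(m)
  path <- integer(m)           # column -> row it was reached from
  row4col <- rep(0L, m)        # column -> assigned row (0 = free)
  col4row <- rep(0L, n)        # row -> assigned column

  for (cur_row in seq_len(n)) {
    short <- rep(Inf, m)
    sr <- rep(FALSE, n); sc <- rep(FALSE, m)
    min_val <- 0
    i <- cur_row
    sink <- 0L
    while (sink == 0L) {
      sr[i] <- TRUE
      open <- !sc
      r <- min_val + cost[i, open] - u[i] - v[open]
      upd <- r < short[open]
      if (any(upd)) {
        oi <- which(open)[upd]
        short[oi] <- r[upd]
        path[oi] <- i
      }
      jstar <- which(open)[which.min(short[open])]
      min_val <- short[jstar]
      if (!is.finite(min_val)) stop_contract("assignment infeasible")
      sc[jstar] <- TRUE
      if (row4col[jstar] == 0L) sink <- jstar else i <- row4col[jstar]
    }
    ## dual updates
    u[cur_row] <- u[cur_row] + min_val
    others <- sr & (seq_len(n) != cur_row)
    if (any(others)) {
      oi <- which(others)
      u[oi] <- u[oi] + min_val - short[col4row[oi]]
    }
    v[sc] <- v[sc] - (min_val - short[sc])
    ## augment along the alternating path
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      j <- tmp
      if (i == cur_row) break
    }
  }
  col4row
}
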
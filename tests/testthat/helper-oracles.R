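# Independent brute-force oracles used to validate module output.
# These deliberately avoid the code paths (and libraries) the package
# uses for the same computation.

# Two-pass Pearson correlation: explicit means, then explicit sums.
oracle_pcc <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Queue-based flood fill for connected components of a 2D/3D mask.
oracle_flood_fill <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  nd <- length(d)
  if (is.null(connectivity)) connectivity <- if (nd == 2) 8 else 26
  offs <- if (nd == 2) {
    g <- expand.grid(dy = -1:1, dx = -1:1)
    g <- g[!(g$dy == 0 & g$dx == 0), ]
    if (connectivity == 4) g <- g[abs(g$dy) + abs(g$dx) == 1, ]
    as.matrix(g)
  } else {
    g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
    g <- g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
    if (connectivity == 6) g <- g[abs(g$dy) + abs(g$dx) + abs(g$dz) == 1, ]
    as.matrix(g)
  }
  labels <- array(0L, dim = d)
  fg <- which(mask != 0)
  nxt <- 0L
  queue <- integer(length(fg))   # preallocated FIFO
  for (start in fg) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    head <- 1L; tail <- 1L
    queue[1] <- start
    labels[start] <- nxt
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      co <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nc <- co + offs[r, seq_len(nd)]
        if (any(nc < 1) || any(nc > d)) next
        lin <- nc[1]
        mult <- 1
        for (j in 2:nd) { mult <- mult * d[j - 1]; lin <- lin + (nc[j] - 1) * mult }
        if (mask[lin] != 0 && labels[lin] == 0L) {
          labels[lin] <- nxt
          tail <- tail + 1L
          queue[tail] <- lin
        }
      }
    }
  }
  labels
}

# Definition-based Holm step-down: walk the ordered p-values, rejecting
# sequentially; the adjusted value is the running maximum of
# (m - i + 1) * p_(i), capped at 1.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- (m - i + 1) * p[o[i]]
    running <- max(running, val)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# All permutations of a vector (recursive; used for <= 5 elements).
all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Per-pixel loop masked mean (no vectorized indexing).
oracle_masked_mean <- function(img, mask_idx) {
  s <- 0
  for (i in mask_idx) s <- s + img[[i]]
  s / length(mask_idx)
}
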
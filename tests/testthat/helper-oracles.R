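# Independent brute-force implementations of the graph measures, used to
# cross-check the package's (igraph-backed or vectorized) versions on
# small digraphs. All take W in the package convention: W[i, j] = number
# of synapses from presynaptic j onto postsynaptic i; edge length 1/W.

# All-pairs shortest distances by Floyd-Warshall. D[a, b] = distance a -> b.
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) D[j, i] <- 1 / W[i, j]
  }
  for (k in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
    if (D[a, k] + D[k, b] < D[a, b]) D[a, b] <- D[a, k] + D[k, b]
  }
  D
}

oracle_cpl <- function(W, from = seq_len(nrow(W)), to = seq_len(nrow(W))) {
  D <- oracle_distances(W)
  d <- D[from, to, drop = FALSE][outer(from, to, "!=")]
  if (!any(is.finite(d))) return(NA_real_)
  mean(d[is.finite(d)])
}

oracle_global_eff <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  mean(rowSums(inv) / (n - 1))
}

# Literal Fagiolo weighted-directed clustering, triple loop, weights
# normalized by the maximum.
oracle_clustering <- function(W) {
  n <- nrow(W)
  Wd <- t(W)                      # Wd[i, j]: edge i -> j
  mx <- max(Wd)
  if (mx == 0) return(numeric(n))
  wh <- (Wd / mx)^(1 / 3)
  A <- (Wd > 0) + 0
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    cyc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      cyc <- cyc + (wh[i, j] + wh[j, i]) * (wh[i, h] + wh[h, i]) *
        (wh[j, h] + wh[h, j])
    }
    k_tot <- sum(A[i, ]) + sum(A[, i])
    k_recip <- sum(A[i, ] * A[, i])
    denom <- k_tot * (k_tot - 1) - 2 * k_recip
    Ci[i] <- if (denom > 0) cyc / (2 * denom) else 0
  }
  Ci
}

# Brute-force betweenness: enumerate every simple path per ordered pair,
# keep those of minimal length (relative tolerance 1e-12), count the ones
# passing through each intermediate node.
oracle_betweenness <- function(W) {
  n <- nrow(W)
  lens <- ifelse(t(W) > 0, 1 / t(W), Inf)   # lens[a, b]: length a -> b
  bc <- numeric(n)
  all_paths <- function(a, b) {
    paths <- list()
    walk <- function(node, visited, len) {
      if (node == b) {
        paths[[length(paths) + 1L]] <<- list(v = visited, len = len)
        return()
      }
      for (nxt in seq_len(n)) {
        if (nxt %in% visited || !is.finite(lens[node, nxt])) next
        walk(nxt, c(visited, nxt), len + lens[node, nxt])
      }
    }
    walk(a, a, 0)
    paths
  }
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    ps <- all_paths(a, b)
    if (!length(ps)) next
    ls <- vapply(ps, `[[`, numeric(1), "len")
    best <- min(ls)
    sel <- which(ls <= best * (1 + 1e-12))
    sigma <- length(sel)
    for (k in sel) {
      inner <- setdiff(ps[[k]]$v, c(a, b))
      bc[inner] <- bc[inner] + 1 / sigma
    }
  }
  bc
}

# Literal local efficiency: neighbor-induced subgraph excluding the node.
oracle_local_eff <- function(W) {
  n <- nrow(W)
  A <- W > 0
  Ei <- numeric(n)
  for (i in seq_len(n)) {
    nb <- setdiff(which(A[, i] | A[i, ]), i)
    m <- length(nb)
    if (m < 2) next
    D <- oracle_distances(W[nb, nb, drop = FALSE])
    inv <- 1 / D
    diag(inv) <- 0
    Ei[i] <- sum(inv) / (m * (m - 1))
  }
  Ei
}

# Random weighted digraph with multiplicities in 0..max_w.
random_digraph <- function(n, p = 0.4, max_w = 3) {
  W <- matrix(0L, n, n)
  off <- which(diag(n) == 0)
  on <- off[stats::runif(length(off)) < p]
  W[on] <- sample.int(max_w, length(on), replace = TRUE)
  W
}

# Enumerate all 3-node digraphs with W entries in {0, 1, 2} (3^6 = 729).
all_3node_digraphs <- function() {
  slots <- which(diag(3) == 0)
  grid <- expand.grid(rep(list(0:2), 6))
  lapply(seq_len(nrow(grid)), function(r) {
    W <- matrix(0L, 3, 3)
    W[slots] <- as.integer(grid[r, ])
    W
  })
}
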
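# Independent brute-force oracles. These deliberately re-derive each
# quantity with plain loops from first principles and share no code with
# the package implementations they check.

# hop distances by hand-rolled BFS on an adjacency matrix
oracle_bfs_all <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(A[v, ] > 0)) {
          if (is.infinite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- d
  }
  D
}

oracle_entropy <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v)
  h
}

oracle_js <- function(p, q) {
  m <- (p + q) / 2
  oracle_entropy(m) - (oracle_entropy(p) + oracle_entropy(q)) / 2
}

# structural dissimilarity recomputed step by step from its definition
oracle_schieber <- function(ga, gb, w = c(0.45, 0.45, 0.10)) {
  Aa <- as.matrix(igraph::as_adjacency_matrix(ga))
  Ab <- as.matrix(igraph::as_adjacency_matrix(gb))
  Da <- oracle_bfs_all(Aa); Db <- oracle_bfs_all(Ab)
  fin <- function(D) { v <- D[is.finite(D) & D > 0]; if (length(v)) max(v) else 1 }
  dmax <- max(fin(Da), fin(Db))
  profiles <- function(D) {
    n <- nrow(D)
    P <- matrix(0, n, dmax + 1)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j == i) next
        if (is.finite(D[i, j])) P[i, D[i, j]] <- P[i, D[i, j]] + 1
        else P[i, dmax + 1] <- P[i, dmax + 1] + 1
      }
      P[i, ] <- P[i, ] / (n - 1)
    }
    P
  }
  Pa <- profiles(Da); Pb <- profiles(Db)
  mu_a <- colMeans(Pa); mu_b <- colMeans(Pb)
  nnd <- function(P, D) {
    mu <- colMeans(P)
    J <- oracle_entropy(mu)
    for (i in seq_len(nrow(P))) J <- J - oracle_entropy(P[i, ]) / nrow(P)
    off <- D[upper.tri(D)]
    dm <- off[is.finite(off)]
    bins <- (if (length(dm)) max(dm) else 0) + as.integer(any(!is.finite(off)))
    if (bins < 1) bins <- 1
    max(0, J) / log(bins + 1)
  }
  term1 <- sqrt(oracle_js(mu_a, mu_b) / log(2))
  term2 <- abs(sqrt(nnd(Pa, Da)) - sqrt(nnd(Pb, Db)))
  acent <- function(A) {
    n <- nrow(A)
    kappa <- numeric(n)
    for (i in seq_len(n)) kappa[i] <- sum(A[i, ]) / (n - 1)
    if (all(kappa == 0)) return(rep(1 / n, n))
    x <- solve(diag(n) - A / n) %*% kappa
    x <- pmax(as.numeric(x), 0)
    sort(x / sum(x), decreasing = TRUE)
  }
  pad <- function(v, len) c(v, rep(0, len - length(v)))
  ca <- acent(Aa); cb <- acent(Ab)
  L <- max(length(ca), length(cb))
  t_g <- sqrt(oracle_js(pad(ca, L), pad(cb, L)) / log(2))
  comp <- function(A) { C <- 1 - A; diag(C) <- 0; C }
  cca <- acent(comp(Aa)); ccb <- acent(comp(Ab))
  Lc <- max(length(cca), length(ccb))
  t_c <- sqrt(oracle_js(pad(cca, Lc), pad(ccb, Lc)) / log(2))
  w[1] * term1 + w[2] * term2 + w[3] * (t_g + t_c) / 2
}

# k-core by one-node-at-a-time deletion in a caller-chosen scan order
oracle_kcore <- function(g, k, node_order = igraph::V(g)$name) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  rownames(A) <- colnames(A) <- igraph::V(g)$name
  alive <- setNames(rep(TRUE, nrow(A)), rownames(A))
  repeat {
    removed <- FALSE
    for (v in node_order) {
      if (!alive[v]) next
      if (sum(A[v, alive]) < k) { alive[v] <- FALSE; removed <- TRUE; break }
    }
    if (!removed) break
  }
  sort(names(alive)[alive])
}

# weighted Newman modularity recomputed from the label map and edge list
oracle_modularity <- function(g, membership, weights = NULL) {
  ed <- igraph::as_data_frame(g, what = "edges")
  w <- weights %||% (if ("weight" %in% names(ed)) ed$weight else rep(1, nrow(ed)))
  m2 <- 2 * sum(w)
  strength <- setNames(rep(0, length(membership)), names(membership))
  for (i in seq_len(nrow(ed))) {
    strength[ed$from[i]] <- strength[ed$from[i]] + w[i]
    strength[ed$to[i]] <- strength[ed$to[i]] + w[i]
  }
  q <- 0
  for (cm in unique(membership)) {
    members <- names(membership)[membership == cm]
    intra <- sum(w[ed$from %in% members & ed$to %in% members])
    q <- q + 2 * intra / m2 - (sum(strength[members]) / m2)^2
  }
  q
}
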
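#' Iterated edge-disjoint minimum spanning trees (MMST)
#'
#' Repeatedly extracts the minimum spanning tree of the working distance
#' graph, records it, removes its edges, and continues. Because every tree's
#' edges are removed before the next iteration, the recorded trees are
#' pairwise edge-disjoint and the union of the first `m` trees has exactly
#' `m * (n - 1)` edges while the working graph stays connected. When edge
#' removal disconnects the working graph, the minimum spanning forest is
#' taken and the run stops early with a warning. Weight ties are broken on
#' the lexicographic (node i, node j) edge key, so the run is deterministic
#' even on degenerate distance matrices. The structural dissimilarity
#' between consecutive trees is recorded as a Schieber D-value series.
#'
#' @param dm a `distance_matrix` (or a plain symmetric matrix with
#'   dimnames)
#' @param n_iter maximum number of spanning trees to extract (default 250)
#' @param d_values compute the D-value series (default `TRUE`; the series
#'   is the stopping diagnostic but costs one D-value per iteration)
#' @return object of class `skeleton_run`: list with `trees` (each a
#'   data.frame `from`, `to`, `weight`), `d_values` (length
#'   `length(trees) - 1`), `node_ids`, and `early_stop`
#' @export
mmst <- function(dm, n_iter = 250L, d_values = TRUE) {
  D <- if (inherits(dm, "distance_matrix")) dm$D else as.matrix(dm)
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  n <- nrow(D)
  stopifnot(n >= 2L, n_iter >= 1L)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ei <- ut[, 1]; ej <- ut[, 2]; w <- D[ut]
  ord <- order(w, ei, ej)
  ei <- ei[ord]; ej <- ej[ord]; w <- w[ord]
  avail <- rep(TRUE, length(w))

  trees <- vector("list", n_iter)
  early <- FALSE
  for (t in seq_len(n_iter)) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    sel <- integer(n - 1L)
    nsel <- 0L
    for (e in which(avail)) {
      ri <- find(ei[e]); rj <- find(ej[e])
      if (ri != rj) {
        parent[ri] <- rj
        nsel <- nsel + 1L
        sel[nsel] <- e
        if (nsel == n - 1L) break
      }
    }
    if (nsel == 0L) { trees <- trees[seq_len(t - 1L)]; early <- TRUE; break }
    sel <- sel[seq_len(nsel)]
    avail[sel] <- FALSE
    trees[[t]] <- data.frame(from = ids[ei[sel]], to = ids[ej[sel]],
                             weight = w[sel], stringsAsFactors = FALSE)
    if (nsel < n - 1L) {
      warning("mmst: working graph disconnected at iteration ", t,
              "; spanning forest taken and run stopped early")
      trees <- trees[seq_len(t)]
      early <- TRUE
      break
    }
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  if (length(trees) < n_iter && !early) early <- TRUE

  dv <- numeric(0)
  if (isTRUE(d_values) && length(trees) >= 2L) {
    gs <- lapply(trees, tree_graph, ids = ids)
    dv <- vapply(seq_len(length(gs) - 1L),
                 function(i) schieber_d(gs[[i]], gs[[i + 1L]]), numeric(1))
  }
  structure(list(trees = trees, d_values = dv, node_ids = ids,
                 n_iter_requested = as.integer(n_iter), early_stop = early),
            class = "skeleton_run")
}

tree_graph <- function(tree, ids) {
  g <- igraph::graph_from_data_frame(tree, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g
}

#' Aggregate the first m spanning trees into a skeleton graph
#'
#' @param run a `skeleton_run`
#' @param m aggregation depth (number of trees to union)
#' @return an undirected `igraph` on the run's node set, edge weights are
#'   the original distances
#' @export
aggregate_skeleton <- function(run, m) {
  stopifnot(inherits(run, "skeleton_run"), m >= 1L)
  if (m > length(run$trees)) {
    stop("aggregate_skeleton: only ", length(run$trees), " trees available, m = ", m)
  }
  edges <- do.call(rbind, run$trees[seq_len(m)])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = run$node_ids))
}

# ---- Schieber structural dissimilarity ---------------------------------

# natural-log Jensen-Shannon divergence of two probability vectors of the
# same length; bounded by log(2)
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  ent(m) - (ent(p) + ent(q)) / 2
}

# per-node hop-distance distributions binned over 1..dmax plus one
# unreachable bin; returns the n x (dmax + 1) matrix
node_distance_profiles <- function(g, dmax) {
  n <- igraph::vcount(g)
  M <- igraph::distances(g, weights = NA)
  P <- matrix(0, n, dmax + 1L)
  for (i in seq_len(n)) {
    d <- M[i, -i]
    fin <- d[is.finite(d)]
    if (length(fin)) P[i, seq_len(dmax)] <- tabulate(fin, nbins = dmax)
    P[i, dmax + 1L] <- sum(!is.finite(d))
  }
  P / (n - 1L)
}

# network node dispersion: generalized JS divergence of the node profiles,
# normalized by log(#bins + 1) where #bins covers the graph's own finite
# diameter plus the unreachable bin when present
node_dispersion <- function(P, g) {
  n <- nrow(P)
  mu <- colMeans(P)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  J <- ent(mu) - mean(apply(P, 1, ent))
  M <- igraph::distances(g, weights = NA)
  fin <- M[upper.tri(M)]
  diam <- suppressWarnings(max(fin[is.finite(fin)], 0))
  bins <- diam + as.integer(any(!is.finite(fin)))
  if (bins < 1) bins <- 1
  list(mu = mu, nnd = max(0, J) / log(bins + 1))
}

# Bonacich-style alpha centrality with attenuation 1/n and exogenous
# contribution deg/(n-1); returned as a sorted probability vector. A graph
# with no edges degenerates to the uniform distribution.
alpha_centrality_profile <- function(g) {
  n <- igraph::vcount(g)
  if (n == 1L) return(1)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  kappa <- rowSums(A) / (n - 1)
  if (all(kappa == 0)) return(rep(1 / n, n))
  x <- solve(diag(n) - A / n, kappa)
  x <- pmax(x, 0)
  sort(x / sum(x), decreasing = TRUE)
}

pad_to <- function(v, len) c(v, rep(0, len - length(v)))

#' Structural dissimilarity (D-value) between two graphs
#'
#' A \[0, 1\] dissimilarity combining three terms: (i) the Jensen-Shannon
#' divergence between the graphs' averaged node-distance distributions,
#' (ii) the difference of the square-rooted network node dispersions, and
#' (iii) a centrality term comparing the alpha-centrality distributions of
#' the graphs and of their complements. Unreachable node pairs occupy a
#' dedicated distance bin, so disconnected graphs are handled without
#' sentinels. `D(G, G) = 0` and `D` is symmetric.
#'
#' @param graph_a,graph_b undirected `igraph` objects (at least 2 nodes
#'   each; node sets may differ in size)
#' @param w the three term weights, default `c(0.45, 0.45, 0.10)`
#' @return a number in \[0, 1\]
#' @export
schieber_d <- function(graph_a, graph_b, w = c(0.45, 0.45, 0.10)) {
  if (igraph::vcount(graph_a) == 0L || igraph::vcount(graph_b) == 0L) {
    stop("schieber_d: empty graph")
  }
  if (igraph::vcount(graph_a) < 2L || igraph::vcount(graph_b) < 2L) {
    stop("schieber_d: graphs need at least 2 nodes")
  }
  stopifnot(length(w) == 3L, all(w >= 0))
  dmax_of <- function(g) {
    M <- igraph::distances(g, weights = NA)
    fin <- M[is.finite(M) & M > 0]
    if (length(fin)) max(fin) else 1
  }
  dmax <- max(dmax_of(graph_a), dmax_of(graph_b))
  Pa <- node_distance_profiles(graph_a, dmax)
  Pb <- node_distance_profiles(graph_b, dmax)
  da <- node_dispersion(Pa, graph_a)
  db <- node_dispersion(Pb, graph_b)

  term1 <- sqrt(js_divergence(da$mu, db$mu) / log(2))
  term2 <- abs(sqrt(da$nnd) - sqrt(db$nnd))

  term3 <- 0
  if (w[3] > 0) {
    ca <- alpha_centrality_profile(graph_a)
    cb <- alpha_centrality_profile(graph_b)
    len <- max(length(ca), length(cb))
    t_g <- sqrt(js_divergence(pad_to(ca, len), pad_to(cb, len)) / log(2))
    cca <- alpha_centrality_profile(igraph::complementer(graph_a))
    ccb <- alpha_centrality_profile(igraph::complementer(graph_b))
    lenc <- max(length(cca), length(ccb))
    t_c <- sqrt(js_divergence(pad_to(cca, lenc), pad_to(ccb, lenc)) / log(2))
    term3 <- (t_g + t_c) / 2
  }
  unname(w[1] * term1 + w[2] * term2 + w[3] * term3)
}

#' Choose the MMST aggregation depth from the D-value series
#'
#' Returns the last index of the first window in which the rolling standard
#' deviation of the D-value series falls below `frac` times the standard
#' deviation of the initial window (further trees add redundant structure).
#' A fixed depth (e.g. 20) can be forced with `fixed`.
#'
#' @param run a `skeleton_run` (or a plain numeric D-value series)
#' @param window rolling window length (default 10)
#' @param frac quiet-window threshold as a fraction of the initial
#'   window's standard deviation (default 0.5)
#' @param fixed if non-`NULL`, return this depth unconditionally
#' @return a positive integer depth
#' @export
choose_depth <- function(run, window = 10L, frac = 0.5, fixed = NULL) {
  if (!is.null(fixed)) return(as.integer(fixed))
  d <- if (inherits(run, "skeleton_run")) run$d_values else as.numeric(run)
  if (length(d) < window) {
    stop("choose_depth: D-value series shorter than the window (", length(d), " < ", window, ")")
  }
  s0 <- stats::sd(d[seq_len(window)])
  for (t in seq_len(length(d) - window + 1L)) {
    s <- stats::sd(d[t:(t + window - 1L)])
    if (s == 0 || s < frac * s0) return(as.integer(t + window - 1L))
  }
  warning("choose_depth: no quiet window found; returning full series length")
  length(d)
}

#' Summary statistics of a network
#'
#' @param graph an `igraph`
#' @return list with node count `n`, edge count `e`, `density`
#'   (`2e / (n (n - 1))`), `avg_degree` (`2e / n`), and the unweighted
#'   hop-count `diameter` of the largest connected component
#' @export
network_stats <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("network_stats: empty graph")
  e <- igraph::ecount(graph)
  comp <- igraph::components(graph)
  big <- igraph::induced_subgraph(graph, which(comp$membership == which.max(comp$csize)))
  list(
    n = n, e = e,
    density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
    avg_degree = 2 * e / n,
    diameter = igraph::diameter(big, weights = NA)
  )
}

#' Guided walk over a skeleton's high-degree neighborhoods
#'
#' Starts at the highest-degree node of a community and repeatedly reports
#' the open neighborhood of the current node (with its community
#' composition), then moves to the highest-degree not-yet-visited node of
#' that neighborhood. Ties are broken lexicographically by node name. The
#' number of steps needed before the walk leaves its starting community
#' measures that community's isolation.
#'
#' @param graph an `igraph`
#' @param partition named community labels covering the graph's nodes
#' @param steps number of neighborhoods to report
#' @param start_community community to start from; default the community
#'   of the graph's highest-degree node
#' @return list of steps, each with `node`, `community`, `neighbors`, and
#'   `composition` (community counts of the neighbors)
#' @export
skeleton_walk <- function(graph, partition, steps, start_community = NULL) {
  stopifnot(steps >= 0)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  miss <- setdiff(nodes, names(partition))
  if (length(miss)) stop("skeleton_walk: partition lacks nodes: ", paste(utils::head(miss, 5), collapse = ", "))
  deg <- stats::setNames(igraph::degree(graph), nodes)
  pick_top <- function(cands) {
    cands <- sort(cands)  # lexicographic tie-break
    cands[which.max(deg[cands])]
  }
  if (is.null(start_community)) {
    start_community <- partition[[pick_top(nodes)]]
  }
  in_comm <- nodes[partition[nodes] == start_community]
  if (!length(in_comm)) stop("skeleton_walk: no nodes in community '", start_community, "'")
  current <- pick_top(in_comm)
  visited <- current
  out <- vector("list", steps)
  for (s in seq_len(steps)) {
    nb <- names(igraph::neighbors(graph, current))
    out[[s]] <- list(
      node = current,
      community = unname(partition[[current]]),
      neighbors = sort(nb),
      composition = table(partition[nb])
    )
    fresh <- setdiff(nb, visited)
    if (s == steps) break
    if (!length(fresh)) {
      warning("skeleton_walk: no unvisited neighbor at step ", s, "; walk truncated")
      out <- out[seq_len(s)]
      break
    }
    current <- pick_top(fresh)
    visited <- c(visited, current)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Write the D-value series of a skeleton run
#'
#' Two-column tab-separated text: iteration index (between trees t and
#' t + 1) and D-value.
#'
#' @param run a `skeleton_run`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_d_values <- function(run, path) {
  stopifnot(inherits(run, "skeleton_run"))
  utils::write.table(
    data.frame(iteration = seq_along(run$d_values), D = run$d_values),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
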
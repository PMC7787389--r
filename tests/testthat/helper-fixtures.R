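# Shared fixture builders. Everything is generated in code; no data files.

options(isonymica.verbose = FALSE)

# person records from parallel surname vectors, with optional coordinates
make_records <- function(pat, mat, x = NULL, y = NULL, block_id = NULL,
                         block_income = NULL, ses = NULL) {
  n <- length(pat)
  df <- data.frame(
    paternal_surname = pat, maternal_surname = mat,
    x = x %||% runif(n), y = y %||% runif(n),
    block_id = block_id %||% rep("B0_0", n),
    block_income = block_income %||% rep(50, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(ses)) df$ses <- ses
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# surname graph with explicit occurrence counts and sample size, for
# filter tests where realising the counts via records would be wasteful
make_surname_graph <- function(edges, n_s, N) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = names(n_s)))
  igraph::V(g)$n_s <- as.integer(n_s[igraph::V(g)$name])
  igraph::set_graph_attr(g, "N", N)
}

# minimal cell_table from a dense count matrix (cells x surnames)
make_cell_table <- function(counts, mean_ses = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  freq <- Matrix::Diagonal(x = 1 / Matrix::rowSums(counts)) %*% counts
  freq <- methods::as(freq, "CsparseMatrix")
  dimnames(freq) <- dimnames(counts)
  ids <- rownames(counts)
  rc <- do.call(rbind, strsplit(ids, "_", fixed = TRUE))
  structure(list(
    cells = data.frame(
      cell_id = ids, row = as.integer(rc[, 1]), col = as.integer(rc[, 2]),
      count = as.integer(Matrix::rowSums(counts) / 2),
      mean_ses = mean_ses %||% rep(NA_real_, length(ids)),
      alpha = isonymica::effective_surname_number(freq),
      stringsAsFactors = FALSE
    ),
    counts = counts, freq = freq,
    grid = list(extent = c(0, 1, 0, 1), nx = 1L, ny = length(ids),
                min_count = 1L, n_candidate_cells = length(ids)),
    n_dropped_cells = 0L
  ), class = "cell_table")
}

# Erdos-Renyi graph with named nodes
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# small library of graphs on <= 6 nodes for the D-value oracle checks
dvalue_test_graphs <- function() {
  named <- list(
    path5 = igraph::make_ring(5, circular = FALSE),
    star5 = igraph::make_star(5, mode = "undirected"),
    cycle5 = igraph::make_ring(5),
    complete5 = igraph::make_full_graph(5),
    complete4 = igraph::make_full_graph(4),
    path6 = igraph::make_ring(6, circular = FALSE),
    disconnected6 = igraph::disjoint_union(igraph::make_full_graph(3),
                                           igraph::make_ring(3))
  )
  named <- lapply(named, function(g) {
    igraph::V(g)$name <- sprintf("v%d", seq_len(igraph::vcount(g)))
    g
  })
  c(named, list(gnp6a = random_named_graph(6, 0.5, 101),
                gnp6b = random_named_graph(6, 0.4, 202),
                gnp5 = random_named_graph(5, 0.6, 303)))
}
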
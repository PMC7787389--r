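#' Build the paternal-maternal surname pair network
#'
#' Nodes are surnames; the weight of edge \{s1, s2\} counts persons bearing
#' that unordered surname pair, irrespective of which slot is paternal. A
#' person whose two surnames coincide contributes no edge (a surname's
#' affinity with itself is not a between-family tie) but still counts
#' towards the surname's occurrence count. Node attribute `n_s` counts
#' person-slots: a person with the same surname in both slots contributes 2.
#' The graph attribute `N` records the number of persons counted, the
#' denominator of the random-pairing expectation used by
#' [affinity_filter()].
#'
#' @param records data.frame with normalized `paternal_surname` and
#'   `maternal_surname` columns
#' @return an undirected `igraph` with edge attribute `weight`, vertex
#'   attribute `n_s`, and graph attribute `N`
#' @export
count_pairs <- function(records) {
  pat <- records$paternal_surname
  mat <- records$maternal_surname
  N <- length(pat)
  if (N == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "N", 0L)
    return(g)
  }
  slots <- c(pat, mat)
  n_s <- table(slots)
  surnames <- sort(names(n_s))

  distinct <- pat != mat
  s1 <- pmin(pat[distinct], mat[distinct])
  s2 <- pmax(pat[distinct], mat[distinct])
  if (length(s1)) {
    dt <- data.table::data.table(s1 = s1, s2 = s2)
    ew <- dt[, .N, by = c("s1", "s2")]
    data.table::setorder(ew, s1, s2)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ew$s1, to = ew$s2, weight = ew$N),
      directed = FALSE, vertices = data.frame(name = surnames)
    )
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE) +
      igraph::vertices(surnames)
  }
  igraph::V(g)$n_s <- as.integer(n_s[igraph::V(g)$name])
  igraph::set_graph_attr(g, "N", N)
}

#' Filter surname pairs down to affinity ties
#'
#' Retains edge \{s1, s2\} only when its observed count `n_ss` is at least
#' `k` times the expected co-occurrence count under random pairing,
#' `k * n_s1 * n_s2 / N`. Isolated nodes are removed afterwards. Larger `k`
#' keeps only strongly over-represented pairs.
#'
#' @param graph a surname graph from [count_pairs()]
#' @param k security multiplier, must be > 1
#' @return the filtered `igraph`
#' @export
affinity_filter <- function(graph, k = 100) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1) {
    stop("affinity_filter: k must be a single finite number > 1")
  }
  N <- igraph::graph_attr(graph, "N")
  if (is.null(N)) stop("affinity_filter: graph lacks attribute N (use count_pairs)")
  if (igraph::ecount(graph) == 0L) return(graph)
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  n_s <- igraph::V(graph)$n_s
  thresh <- k * n_s[ends[, 1]] * n_s[ends[, 2]] / N
  keep <- igraph::E(graph)$weight >= thresh
  g <- igraph::delete_edges(graph, igraph::E(graph)[!keep])
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Reduce a graph to its k-core
#'
#' The maximal subgraph in which every node has degree at least
#' `k_core_min`, obtained by iteratively deleting lower-degree nodes until
#' stable; the fixed point does not depend on deletion order.
#'
#' @param graph an undirected `igraph`
#' @param k_core_min minimum degree retained (default 3)
#' @return the core subgraph (possibly empty)
#' @export
k_core <- function(graph, k_core_min = 3L) {
  stopifnot(k_core_min >= 1)
  core <- igraph::coreness(graph)
  igraph::induced_subgraph(graph, which(core >= k_core_min))
}

#' Mean socioeconomic status per surname
#'
#' Averages person-level SES over all bearers of each surname, counting
#' both surname slots (a person contributes their SES once per slot
#' bearing the surname).
#'
#' @param records data.frame with person-level `ses` (see
#'   [assign_person_ses()])
#' @return named numeric vector: surname -> mean SES
#' @export
surname_ses <- function(records) {
  if (is.null(records$ses)) stop("surname_ses: records lack person-level 'ses'")
  slots <- c(records$paternal_surname, records$maternal_surname)
  ses <- c(records$ses, records$ses)
  out <- tapply(ses, slots, mean)
  stats::setNames(as.numeric(out), names(out))[order(names(out))]
}

#' Write a surname graph
#'
#' `format = "edgelist"` writes a three-column tab-separated file
#' (surname1, surname2, weight); `format = "graphml"` writes GraphML with
#' node attributes (`n_s`, and `ses` when present).
#'
#' @param graph an `igraph`
#' @param path output file
#' @param format `"edgelist"` or `"graphml"`
#' @return `path`, invisibly
#' @export
write_surname_graph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    ends <- igraph::as_data_frame(graph, what = "edges")
    w <- if ("weight" %in% names(ends)) ends$weight else rep(1L, nrow(ends))
    utils::write.table(
      data.frame(surname1 = ends$from, surname2 = ends$to, weight = w),
      path, sep = "\t", row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
    )
  }
  invisible(path)
}

#' Read a surname graph written by [write_surname_graph()]
#'
#' @param path edge-list or GraphML file
#' @param format `"edgelist"` or `"graphml"`
#' @return an undirected weighted `igraph`
#' @export
read_surname_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  igraph::graph_from_data_frame(
    data.frame(from = df$surname1, to = df$surname2, weight = df$weight),
    directed = FALSE
  )
}
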
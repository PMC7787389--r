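# canonical form of a membership vector: communities renumbered by first
# appearance over nodes sorted by name, so label permutations compare equal
canonical_membership <- function(membership) {
  m <- membership[order(names(membership))]
  as.integer(factor(m, levels = unique(m)))
}

#' Consensus modularity community detection
#'
#' Runs Louvain modularity optimization `n_runs` times with distinct
#' sub-seeds, groups the resulting partitions into equivalence classes up
#' to community-label permutation, and returns the most frequent class
#' (ties broken by highest modularity). The run-to-run modularity range and
#' community-count range are reported alongside.
#'
#' @param graph a nonempty undirected `igraph`; edge attribute `weight` is
#'   used when present unless `weighted = FALSE`
#' @param n_runs number of independent runs (default 10)
#' @param seed master seed; run r uses `sub_seed(seed, paste0("louvain", r))`
#' @param weighted use edge weights when present (default `TRUE`)
#' @return object of class `iso_partition`: list with named `membership`,
#'   `modularity`, `n_communities`, `n_runs`, `frequency` of the chosen
#'   class, `modularity_range`, `n_communities_range`, and `method`
#' @export
detect_consensus <- function(graph, n_runs = 10L, seed = 1L, weighted = TRUE) {
  if (igraph::vcount(graph) == 0L) stop("detect_consensus: empty graph")
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  # igraph convention: NA forces the unweighted algorithm even when a
  # weight edge attribute exists
  weights <- if (weighted && "weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight
  } else NA
  if (igraph::ecount(graph) == 0L) {
    membership <- stats::setNames(seq_len(igraph::vcount(graph)), igraph::V(graph)$name)
    return(structure(list(membership = membership, modularity = 0,
                          n_communities = length(membership), n_runs = 0L,
                          frequency = NA_integer_,
                          modularity_range = c(0, 0),
                          n_communities_range = c(length(membership), length(membership)),
                          method = "singletons"),
                     class = "iso_partition"))
  }
  mod_weights <- if (length(weights) == 1L && is.na(weights)) {
    rep(1, igraph::ecount(graph))  # modularity() lacks the NA convention
  } else weights
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(sub_seed(seed, paste0("louvain", r)))
    cl <- igraph::cluster_louvain(graph, weights = weights)
    membership <- stats::setNames(igraph::membership(cl), igraph::V(graph)$name)
    runs[[r]] <- list(
      membership = membership,
      canonical = canonical_membership(membership),
      modularity = igraph::modularity(graph, igraph::membership(cl), weights = mod_weights)
    )
  }
  keys <- vapply(runs, function(r) paste(r$canonical, collapse = ","), character(1))
  tab <- table(keys)
  top_count <- max(tab)
  candidates <- names(tab)[tab == top_count]
  mods <- vapply(candidates, function(k) max(vapply(runs[keys == k], `[[`, numeric(1), "modularity")), numeric(1))
  chosen_key <- candidates[which.max(mods)]
  chosen <- runs[[which(keys == chosen_key)[1]]]
  all_mods <- vapply(runs, `[[`, numeric(1), "modularity")
  all_k <- vapply(runs, function(r) length(unique(r$membership)), integer(1))
  structure(list(
    membership = chosen$membership,
    modularity = chosen$modularity,
    n_communities = length(unique(chosen$membership)),
    n_runs = as.integer(n_runs),
    frequency = as.integer(top_count),
    modularity_range = range(all_mods),
    n_communities_range = range(all_k),
    method = "louvain-consensus"
  ), class = "iso_partition")
}

#' @export
print.iso_partition <- function(x, ...) {
  cat("Consensus partition (", x$method, ")\n", sep = "")
  cat("  nodes:", length(x$membership),
      " communities:", x$n_communities,
      " modularity:", round(x$modularity, 4), "\n")
  if (!is.na(x$frequency)) {
    cat("  chosen by ", x$frequency, "/", x$n_runs, " runs; modularity range [",
        round(x$modularity_range[1], 4), ", ", round(x$modularity_range[2], 4),
        "]; community counts ", x$n_communities_range[1], "-",
        x$n_communities_range[2], "\n", sep = "")
  }
  invisible(x)
}

as_membership_vector <- function(partition) {
  if (inherits(partition, "iso_partition")) partition$membership else partition
}

#' Mean socioeconomic status per community
#'
#' Unweighted mean over the member surnames' per-surname mean SES (each
#' surname counts once regardless of its number of bearers); set
#' `person_weighted = TRUE` and supply `weights` (bearer counts) for a
#' person-weighted variant.
#'
#' @param partition an `iso_partition` or named membership vector
#' @param surname_ses named numeric vector of per-surname mean SES
#' @param person_weighted weight surnames by `weights` (default `FALSE`)
#' @param weights named bearer counts, required when `person_weighted`
#' @return named numeric vector: community -> mean SES; communities with no
#'   SES-bearing surname are excluded with a warning
#' @export
cluster_ses <- function(partition, surname_ses, person_weighted = FALSE, weights = NULL) {
  m <- as_membership_vector(partition)
  ses <- surname_ses[names(m)]
  have <- !is.na(ses)
  if (!all(have)) {
    lost <- unique(m[!have])
    empty <- setdiff(lost, unique(m[have]))
    if (length(empty)) {
      warning("cluster_ses: excluding community(ies) with no SES-bearing surname: ",
              paste(empty, collapse = ", "))
    }
  }
  m <- m[have]; ses <- ses[have]
  if (person_weighted) {
    if (is.null(weights)) stop("cluster_ses: person_weighted needs bearer-count weights")
    wts <- weights[names(ses)]
    out <- tapply(ses * wts, m, sum) / tapply(wts, m, sum)
  } else {
    out <- tapply(ses, m, mean)
  }
  stats::setNames(as.numeric(out), names(out))
}

#' Highest-degree surnames per community
#'
#' @param partition an `iso_partition` or named membership vector over the
#'   graph's nodes
#' @param graph the clustered `igraph`
#' @param top_n list length per community (default 10); communities smaller
#'   than `top_n` return in full
#' @return named list: community -> character vector of surnames, ordered
#'   by decreasing (unweighted) degree, ties lexicographic
#' @export
top_degree_surnames <- function(partition, graph, top_n = 10L) {
  m <- as_membership_vector(partition)
  deg <- stats::setNames(igraph::degree(graph), igraph::V(graph)$name)
  lapply(split(names(m), m), function(members) {
    members <- members[order(-deg[members], members)]
    utils::head(members, top_n)
  })
}

#' Salient surnames per cell community
#'
#' For each community of cells, pools the member cells' surname counts and
#' ranks the community's `top_k` most frequent surnames by the ratio of
#' in-community relative frequency to the maximum out-community relative
#' frequency (out-counts floored at one pooled pseudo-count so exclusive
#' surnames stay finite); the `top_n` highest ratios are returned. This
#' formalises "frequent in the area but infrequent elsewhere".
#'
#' @param cells a `cell_table`
#' @param partition an `iso_partition` or named membership vector over cell
#'   ids
#' @param top_k size of the per-community frequency pool (default 500)
#' @param top_n surnames returned per community (default 10)
#' @return named list: community -> character vector of surnames
#' @export
salient_surnames <- function(cells, partition, top_k = 500L, top_n = 10L) {
  stopifnot(inherits(cells, "cell_table"))
  m <- as_membership_vector(partition)
  ids <- rownames(cells$counts)
  m <- m[names(m) %in% ids]
  comms <- sort(unique(as.character(m)))
  # pooled counts per community x surname
  pooled <- do.call(rbind, lapply(comms, function(cm) {
    Matrix::colSums(cells$counts[names(m)[m == cm], , drop = FALSE])
  }))
  rownames(pooled) <- comms
  totals <- rowSums(pooled)
  out <- stats::setNames(vector("list", length(comms)), comms)
  for (cm in comms) {
    if (totals[cm] == 0) next
    in_freq <- pooled[cm, ] / totals[cm]
    others <- setdiff(comms, cm)
    if (length(others)) {
      out_freq <- apply(pooled[others, , drop = FALSE], 2, function(cnt) {
        max(pmax(cnt, 1) / totals[others])
      })
    } else {
      out_freq <- rep(1 / max(totals[cm], 1), ncol(pooled))
    }
    pool <- names(sort(in_freq, decreasing = TRUE))[seq_len(min(top_k, sum(in_freq > 0)))]
    ratio <- in_freq[pool] / out_freq[pool]
    ord <- pool[order(-ratio, -in_freq[pool], pool)]
    out[[cm]] <- utils::head(ord, top_n)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Representation of surname communities in a historical cohort
#'
#' For every period, the fraction of cohort members bearing at least one
#' surname assigned to each community. A member whose surnames fall in two
#' communities counts toward both, so per-period fractions may sum above 1.
#'
#' @param cohort_records data.frame with `period` and `surname` columns
#'   (one row per member-surname; members with several surnames contribute
#'   several rows sharing a `member_id` column, or one row each if only one
#'   surname is known). When a `member_id` column is absent each row is
#'   treated as one member.
#' @param partition an `iso_partition` or named membership vector over
#'   surnames
#' @return data.frame with columns `period`, `community`, `fraction`
#' @export
cohort_representation <- function(cohort_records, partition) {
  stopifnot(all(c("period", "surname") %in% names(cohort_records)))
  m <- as_membership_vector(partition)
  df <- cohort_records
  df$surname <- normalize_surname(df$surname)
  if (is.null(df$member_id)) df$member_id <- seq_len(nrow(df))
  df$community <- as.character(m[df$surname])
  periods <- sort(unique(df$period))
  comms <- sort(unique(as.character(m)))
  res <- expand.grid(period = periods, community = comms,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res$fraction <- NA_real_
  for (i in seq_len(nrow(res))) {
    sub <- df[df$period == res$period[i], , drop = FALSE]
    n_members <- length(unique(sub$member_id))
    if (n_members == 0L) next  # empty period: fraction stays missing
    hit <- unique(sub$member_id[!is.na(sub$community) & sub$community == res$community[i]])
    res$fraction[i] <- length(hit) / n_members
  }
  res
}

#' Write a partition with a JSON summary
#'
#' Two-column delimited text (`node`, `community`) plus `<path>.json` with
#' modularity, run count, community sizes, and (when supplied) per-community
#' SES.
#'
#' @param partition an `iso_partition`
#' @param path output file
#' @param cluster_ses optional named per-community SES vector for the
#'   summary
#' @return `path`, invisibly
#' @export
write_partition <- function(partition, path, cluster_ses = NULL) {
  stopifnot(inherits(partition, "iso_partition"))
  df <- data.frame(node = names(partition$membership),
                   community = as.integer(partition$membership))
  df <- df[order(df$node), ]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  sizes <- table(partition$membership)
  summary <- list(
    modularity = partition$modularity,
    n_runs = partition$n_runs,
    n_communities = partition$n_communities,
    community_sizes = as.list(stats::setNames(as.integer(sizes), names(sizes))),
    modularity_range = partition$modularity_range
  )
  if (!is.null(cluster_ses)) summary$cluster_ses <- as.list(cluster_ses)
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
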
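two_cliques <- function(size = 10) {
  a <- sprintf("a%02d", seq_len(size)); b <- sprintf("b%02d", seq_len(size))
  edges <- rbind(t(utils::combn(a, 2)), t(utils::combn(b, 2)), c(a[1], b[1]))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

test_that("consensus recovers planted two-clique structure in every run", {
  g <- two_cliques(10)
  p <- detect_consensus(g, n_runs = 10, seed = 3)
  expect_identical(p$n_communities, 2L)
  expect_identical(p$n_communities_range, c(2L, 2L))
  expect_identical(p$frequency, 10L)
  truth <- setNames(rep(c("A", "B"), each = 10), sort(names(p$membership)))
  expect_equal(adjusted_rand_index(p$membership[names(truth)], truth), 1)
})

test_that("a complete graph is one community and empty graphs error", {
  p <- detect_consensus(igraph::make_full_graph(8), n_runs = 5, seed = 1)
  expect_identical(p$n_communities, 1L)
  expect_error(detect_consensus(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
  # edgeless graph: every node its own community, modularity 0
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("x", "y", "z")
  p0 <- detect_consensus(lone)
  expect_identical(p0$n_communities, 3L)
  expect_identical(p0$modularity, 0)
})

test_that("consensus is deterministic and its modularity recomputes exactly", {
  set.seed(77)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("v%02d", 1:40)
  igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), TRUE)
  p1 <- detect_consensus(g, n_runs = 6, seed = 9)
  p2 <- detect_consensus(g, n_runs = 6, seed = 9)
  expect_identical(p1$membership, p2$membership)
  expect_equal(p1$modularity,
               oracle_modularity(g, p1$membership, igraph::E(g)$weight),
               tolerance = 1e-9)
})

test_that("partition equivalence ignores community label permutations", {
  set.seed(5)
  for (i in 1:10) {
    m <- setNames(sample(1:4, 20, TRUE), sprintf("n%02d", 1:20))
    perm <- sample(4)
    relabeled <- setNames(perm[m], names(m))
    expect_identical(isonymica:::canonical_membership(m),
                     isonymica:::canonical_membership(relabeled))
  }
})

test_that("cluster_ses averages member surnames and respects labels", {
  m <- c(A = 1, B = 1, C = 2)
  ses <- c(A = 10, B = 30, C = 77)
  out <- cluster_ses(m, ses)
  expect_equal(out[["1"]], 20)
  expect_equal(out[["2"]], 77)  # singleton community
  # permuting labels permutes outputs identically
  m2 <- c(A = 2, B = 2, C = 1)
  out2 <- cluster_ses(m2, ses)
  expect_equal(out2[["2"]], out[["1"]])
  expect_warning(cluster_ses(c(A = 1, D = 2), c(A = 5)), "no SES")
  # person-weighted variant
  w <- c(A = 3, B = 1)
  expect_equal(cluster_ses(c(A = 1, B = 1), ses, person_weighted = TRUE,
                           weights = w)[["1"]], (10 * 3 + 30) / 4)
})

test_that("top_degree_surnames ranks by degree with lexicographic ties", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "d", "c", "b", "a")
  m <- setNames(rep(1, 5), igraph::V(star)$name)
  top <- top_degree_surnames(m, star, top_n = 3)[["1"]]
  expect_identical(top, c("hub", "a", "b"))
  expect_identical(top_degree_surnames(m, star, top_n = 0)[["1"]], character(0))
  # community smaller than top_n returned in full
  expect_length(top_degree_surnames(m, star, top_n = 99)[["1"]], 5L)
})

test_that("salient_surnames prefers exclusive surnames over uniform ones", {
  counts <- rbind(
    "0_0" = c(EXC = 6, UNI = 10, OTH = 4, RARE = 0),
    "0_1" = c(EXC = 4, UNI = 10, OTH = 6, RARE = 0),
    "1_0" = c(EXC = 0, UNI = 10, OTH = 5, RARE = 5),
    "1_1" = c(EXC = 0, UNI = 10, OTH = 5, RARE = 5)
  )
  ct <- make_cell_table(counts)
  part <- c("0_0" = "X", "0_1" = "X", "1_0" = "Y", "1_1" = "Y")
  out <- salient_surnames(ct, part, top_k = 4, top_n = 2)
  expect_identical(out[["X"]][1], "EXC")  # exclusive: pseudo-counted but first
  expect_identical(out[["Y"]][1], "RARE")
  expect_false("UNI" %in% c(out[["X"]][1], out[["Y"]][1]))
})

test_that("salient surnames of planted spatial groups come from their pools", {
  cfg <- city_config(n_persons = 6000, n_groups = 2, endogamy = 1,
                     group_spread = 0.8, seed = 13)
  rec <- generate_city(cfg)
  ct <- grid_bin(rec, cfg$grid_extent, nx = 8, ny = 8, min_count = 20)
  modal <- vapply(rownames(ct$counts), function(id) {
    sub <- rec[sprintf("%d_%d",
                       pmin(floor(rec$y / 10 * 8), 7),
                       pmin(floor(rec$x / 10 * 8), 7)) == id, ]
    names(which.max(table(sub$group_label)))
  }, character(1))
  out <- salient_surnames(ct, modal, top_k = 100, top_n = 10)
  for (grp in names(out)) {
    expect_true(all(startsWith(out[[grp]], paste0(grp, "_"))))
  }
})

test_that("cohort_representation computes per-period community fractions", {
  m <- c(AAA = 1, BBB = 1, CCC = 2)
  cohort <- data.frame(
    period = c(rep("p1", 10), "p2", "p2"),
    surname = c(rep("AAA", 3), "CCC", rep("ZZZ", 6), "ZZZ", "ZZZ"),
    member_id = c(1:10, 11, 12)
  )
  out <- cohort_representation(cohort, m)
  expect_equal(out$fraction[out$period == "p1" & out$community == "1"], 0.3)
  expect_equal(out$fraction[out$period == "p1" & out$community == "2"], 0.1)
  expect_equal(out$fraction[out$period == "p2" & out$community == "1"], 0)
  # one member bearing surnames of two communities counts toward both
  dual <- data.frame(period = "p1", surname = c("AAA", "CCC"),
                     member_id = c(1, 1))
  out2 <- cohort_representation(dual, m)
  expect_equal(sum(out2$fraction), 2)  # 1.0 for each community
})

test_that("partitions round-trip through the writer with a JSON summary", {
  g <- two_cliques(5)
  p <- detect_consensus(g, n_runs = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition(p, path, cluster_ses = c("1" = 10, "2" = 20))
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 10L)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(js$n_communities, 2L)
  expect_equal(js$modularity, p$modularity)
})
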
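test_that("grid_bin uses half-open cells with the far edges closed", {
  rec <- make_records(pat = c("A", "B", "C"), mat = c("B", "C", "A"),
                      x = c(0.25, 0.5, 1.0), y = c(0.25, 0.5, 1.0))
  ct <- grid_bin(rec, c(0, 1, 0, 1), nx = 2, ny = 2, min_count = 1)
  expect_setequal(ct$cells$cell_id, c("0_0", "1_1"))
  expect_identical(ct$grid$n_candidate_cells, 4L)
  got <- ct$cells[ct$cells$cell_id == "1_1", ]
  expect_identical(got$count, 2L)  # (0.5,0.5) and the closed corner (1,1)
})

test_that("cell frequencies count both slots and sum to one", {
  rec <- make_records(pat = c("A", "A"), mat = c("B", "C"),
                      x = c(0.5, 0.5), y = c(0.5, 0.5))
  ct <- grid_bin(rec, c(0, 1, 0, 1), nx = 1, ny = 1, min_count = 1)
  p <- as.numeric(ct$freq["0_0", c("A", "B", "C")])
  expect_equal(p, c(0.5, 0.25, 0.25))
  expect_equal(Matrix::rowSums(ct$freq)[["0_0"]], 1, tolerance = 1e-9)
})

test_that("min_count discards sparse cells and an empty grid errors", {
  set.seed(3)
  rec <- make_records(pat = sample(LETTERS, 200, TRUE),
                      mat = sample(LETTERS, 200, TRUE),
                      x = runif(200), y = runif(200))
  expect_error(grid_bin(rec, c(0, 1, 0, 1), nx = 2, ny = 2, min_count = 1000),
               "min_count")
  expect_error(grid_bin(rec, c(1, 1, 0, 1), nx = 2, ny = 2, min_count = 1),
               "grid_extent")
  ct <- grid_bin(rec, c(0, 1, 0, 1), nx = 4, ny = 4, min_count = 10)
  expect_true(all(ct$cells$count >= 10))
})

test_that("effective surname number follows the inverse Simpson identities", {
  expect_equal(effective_surname_number(rep(1 / 50, 50)), 50)
  expect_equal(effective_surname_number(1), 1)
  expect_equal(effective_surname_number(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_error(effective_surname_number(numeric(0)), "empty")
})

test_that("isonymy matches its definition and I_ii = 1/alpha", {
  u <- setNames(rep(1 / 50, 50), paste0("S", 1:50))
  expect_equal(isonymy_between(u, u), 0.02)
  expect_equal(isonymy_between(c(A = 0.5, B = 0.5), c(C = 0.5, D = 0.5)), 0)
  expect_equal(isonymy_between(c(A = 0.5, B = 0.5), c(A = 0.5, C = 0.5)), 0.25)
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:40, 1)
    p <- runif(k); p <- setNames(p / sum(p), paste0("S", 1:k))
    expect_equal(isonymy_between(p, p), 1 / effective_surname_number(p),
                 tolerance = 1e-12)
  }
})

test_that("distance formulas reproduce the two-cell worked example", {
  p1 <- c(A = 0.5, B = 0.5); p2 <- c(A = 0.5, C = 0.5)
  I12 <- isonymy_between(p1, p2)
  expect_equal(lasker_distance(I12), -log(0.25), tolerance = 1e-12)  # 1.3863
  expect_equal(nei_distance(I12, 0.5, 0.5), -log(0.5), tolerance = 1e-12)  # 0.6931
  expect_equal(euclid_distance(p1, p2), sqrt(0.5), tolerance = 1e-12)  # 0.7071
  # identical cells and disjoint cells
  expect_equal(nei_distance(0.5, 0.5, 0.5), 0)
  expect_equal(euclid_distance(p1, p1), 0)
  expect_equal(euclid_distance(p1, c(X = 1)), 1)
  expect_identical(lasker_distance(0), Inf)
  # literal (radical-free) variant kept behind the flag
  expect_equal(euclid_distance(p1, p2, literal = TRUE), 0.75)
  expect_error(euclid_distance(c(A = -0.1), p2), "negative")
})

test_that("LD >= ND >= 0 whenever within-area isonymies are at most 1", {
  set.seed(15)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    p1 <- runif(k); p1 <- setNames(p1 / sum(p1), paste0("S", 1:k))
    p2 <- runif(k); p2 <- setNames(p2 / sum(p2), paste0("S", 1:k))
    I12 <- isonymy_between(p1, p2)
    ld <- lasker_distance(I12)
    nd <- nei_distance(I12, isonymy_between(p1, p1), isonymy_between(p2, p2))
    expect_gte(ld, nd - 1e-12)
    expect_gte(nd, -1e-12)
  }
})

test_that("distance_matrix is symmetric with the advertised diagonals", {
  counts <- rbind("0_0" = c(A = 4, B = 4, C = 0, D = 0),
                  "0_1" = c(A = 4, B = 4, C = 0, D = 0),
                  "1_0" = c(A = 0, B = 0, C = 6, D = 2))
  ct <- make_cell_table(counts)
  for (m in c("euclid", "lasker", "nei")) {
    dm <- distance_matrix(ct, m)
    expect_identical(dm$metric, m)
    expect_equal(dm$D, t(dm$D), tolerance = 1e-12)
  }
  ed <- distance_matrix(ct, "euclid")$D
  expect_equal(unname(diag(ed)), c(0, 0, 0))
  expect_equal(ed["0_0", "0_1"], 0)        # identical composition
  expect_equal(ed["0_0", "1_0"], 1)        # disjoint composition
  nei <- distance_matrix(ct, "nei")$D
  expect_equal(unname(diag(nei)), c(0, 0, 0))
  expect_identical(nei["0_0", "1_0"], Inf)
  expect_error(distance_matrix(ct, "cosine"))
})

test_that("merging two identical cells leaves distances to third cells unchanged", {
  # two cells with identical frequency vectors, one different
  rec <- make_records(
    pat = c("A", "B", "A", "B", "C", "D"),
    mat = c("B", "A", "B", "A", "D", "C"),
    x = c(0.2, 0.2, 0.8, 0.8, 0.5, 0.5),
    y = c(0.2, 0.2, 0.2, 0.2, 0.8, 0.8)
  )
  fine <- grid_bin(rec, c(0, 1, 0, 1), nx = 2, ny = 2, min_count = 1)
  coarse <- grid_bin(rec, c(0, 1, 0, 1), nx = 1, ny = 2, min_count = 1)
  for (m in c("euclid", "lasker", "nei")) {
    df <- distance_matrix(fine, m)$D  # cells 0_0, 0_1 identical; 1_1 different
    dc <- distance_matrix(coarse, m)$D  # 0_0 is the merged cell, 1_0 the third
    expect_equal(unname(df["0_0", "1_1"]), unname(dc["0_0", "1_0"]),
                 tolerance = 1e-12)
    expect_equal(unname(df["0_0", "1_1"]), unname(df["0_1", "1_1"]),
                 tolerance = 1e-12)
  }
})

test_that("separability_report recovers the simulated component count", {
  set.seed(42)
  one <- rnorm(500)
  expect_identical(separability_report(one)$n_components, 1L)
  two <- c(rnorm(250, 0, 1), rnorm(250, 10, 1))
  expect_identical(separability_report(two)$n_components, 2L)
  expect_identical(separability_report(rep(0.4, 100))$n_components, 1L)
  expect_error(separability_report(rnorm(10)), "at least 30")
})

test_that("alpha_ses_correlation matches the linear and null cases", {
  m <- diag(10) + 1
  dimnames(m) <- list(paste0("0_", 1:10), paste0("S", 1:10))
  lin <- make_cell_table(m)
  lin$cells$mean_ses <- seq(10, 100, 10)
  lin$cells$alpha <- 2 * lin$cells$mean_ses + 3
  expect_equal(alpha_ses_correlation(lin), 1)
  lin$cells$alpha <- -2 * lin$cells$mean_ses + 300
  expect_equal(alpha_ses_correlation(lin), -1)
  set.seed(6)
  big <- lin
  big$cells <- data.frame(cell_id = paste0("0_", 1:500), alpha = rnorm(500, 50, 5),
                          mean_ses = sample(rnorm(500, 40, 10)))
  expect_lt(abs(alpha_ses_correlation(big)), 0.1)
  flat <- lin
  flat$cells$alpha <- rep(7, 10)
  flat$cells$mean_ses <- seq(10, 100, 10)
  expect_warning(r <- alpha_ses_correlation(flat), "zero variance")
  expect_true(is.na(r))
})

test_that("cell tables and distance matrices round-trip their writers", {
  counts <- rbind("0_0" = c(A = 4, B = 2), "1_0" = c(A = 1, B = 5))
  ct <- make_cell_table(counts)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(ct, f1, f2)
  long <- utils::read.csv(f1)
  expect_setequal(names(long), c("cell_row", "cell_col", "surname", "count", "freq"))
  expect_equal(sum(long$count), sum(counts))
  dmf <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(distance_matrix(ct, "euclid"), dmf)
  side <- jsonlite::read_json(paste0(dmf, ".json"))
  expect_identical(side$metric, "euclid")
})
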
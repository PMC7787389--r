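#' Bin person records into a regular spatial grid of surname frequencies
#'
#' Overlays `nx` by `ny` equal-area axis-aligned cells on `grid_extent` and
#' assigns each person to the half-open cell `[left, right) x [bottom, top)`
#' containing their location (the final row and column are closed, so every
#' point of the extent maps to exactly one cell). Cells with fewer than
#' `min_count` persons are discarded. Surname frequencies count both slots:
#' each person contributes their paternal and maternal surname with weight
#' one each.
#'
#' @param records person records with `x`, `y`, surname columns, and
#'   optionally a person-level `ses` column
#' @param grid_extent numeric `c(xmin, xmax, ymin, ymax)`
#' @param nx,ny number of grid columns and rows (default 64 x 64)
#' @param min_count minimum persons per retained cell (default 50)
#' @return object of class `cell_table`: list with `cells` (data.frame:
#'   `cell_id`, `row`, `col`, `count`, `mean_ses`, `alpha`), sparse `counts`
#'   and `freq` matrices (cells x surnames; `freq` rows sum to 1), and a
#'   `grid` descriptor recording `n_candidate_cells = nx * ny`
#' @export
grid_bin <- function(records, grid_extent, nx = 64L, ny = 64L, min_count = 50L) {
  ext <- as.numeric(grid_extent)
  if (length(ext) != 4L || ext[1] >= ext[2] || ext[3] >= ext[4]) {
    stop("grid_bin: grid_extent must be c(xmin, xmax, ymin, ymax) with positive area")
  }
  stopifnot(nx >= 1L, ny >= 1L)
  col <- pmin(floor((records$x - ext[1]) / (ext[2] - ext[1]) * nx), nx - 1L)
  row <- pmin(floor((records$y - ext[3]) / (ext[4] - ext[3]) * ny), ny - 1L)
  inside <- records$x >= ext[1] & records$x <= ext[2] &
            records$y >= ext[3] & records$y <= ext[4]
  if (!all(inside)) {
    iso_log("grid_bin: dropped %d record(s) outside the grid extent", sum(!inside))
    records <- records[inside, , drop = FALSE]
    col <- col[inside]; row <- row[inside]
  }
  cell_id <- sprintf("%d_%d", row, col)

  per_cell <- table(cell_id)
  keep_ids <- names(per_cell)[per_cell >= min_count]
  if (length(keep_ids) == 0L) {
    stop("grid_bin: no cell reaches min_count = ", min_count, " persons")
  }
  n_dropped <- sum(per_cell < min_count)
  if (n_dropped > 0) {
    iso_log("grid_bin: discarded %d cell(s) below min_count = %d", n_dropped, min_count)
  }
  sel <- cell_id %in% keep_ids
  records <- records[sel, , drop = FALSE]
  cell_id <- cell_id[sel]

  keep_ids <- sort(keep_ids)
  ci <- match(cell_id, keep_ids)
  surnames <- sort(unique(c(records$paternal_surname, records$maternal_surname)))
  si_pat <- match(records$paternal_surname, surnames)
  si_mat <- match(records$maternal_surname, surnames)
  counts <- Matrix::sparseMatrix(
    i = c(ci, ci), j = c(si_pat, si_mat), x = 1,
    dims = c(length(keep_ids), length(surnames)),
    dimnames = list(keep_ids, surnames)
  )
  freq <- Matrix::Diagonal(x = 1 / Matrix::rowSums(counts)) %*% counts
  freq <- methods::as(freq, "CsparseMatrix")
  dimnames(freq) <- dimnames(counts)

  rc <- do.call(rbind, strsplit(keep_ids, "_", fixed = TRUE))
  mean_ses <- if (!is.null(records$ses)) {
    as.numeric(tapply(records$ses, factor(cell_id, levels = keep_ids), mean))
  } else rep(NA_real_, length(keep_ids))
  cells <- data.frame(
    cell_id = keep_ids,
    row = as.integer(rc[, 1]), col = as.integer(rc[, 2]),
    count = as.integer(per_cell[keep_ids]),
    mean_ses = mean_ses,
    alpha = effective_surname_number(freq),
    stringsAsFactors = FALSE
  )
  rownames(cells) <- NULL
  structure(
    list(cells = cells, counts = counts, freq = freq,
         grid = list(extent = ext, nx = as.integer(nx), ny = as.integer(ny),
                     min_count = as.integer(min_count),
                     n_candidate_cells = as.integer(nx) * as.integer(ny)),
         n_dropped_cells = as.integer(n_dropped)),
    class = "cell_table"
  )
}

#' Effective surname number (inverse Simpson index)
#'
#' `alpha = 1 / sum(p_k^2)` for a relative-frequency vector: the number of
#' equally frequent surnames that would give the same concentration. 1 for
#' a single surname, equal to the surname count for a uniform cell.
#'
#' @param p a numeric frequency vector summing to 1, or a matrix /
#'   `cell_table` frequency matrix with one cell per row
#' @return a number, or one number per row
#' @export
effective_surname_number <- function(p) {
  if (inherits(p, "cell_table")) p <- p$freq
  if (is.matrix(p) || inherits(p, "Matrix")) {
    rs <- Matrix::rowSums(p^2)
    if (any(rs == 0)) stop("effective_surname_number: empty cell")
    return(as.numeric(1 / rs))
  }
  if (length(p) == 0L || sum(p) == 0) stop("effective_surname_number: empty cell")
  1 / sum(p^2)
}

#' Isonymy between two areas
#'
#' `I_ij = sum over shared surnames of p_k,i * p_k,j`; 0 when the areas
#' share no surname. The within-area isonymy `I_ii` equals `1/alpha_i`.
#'
#' @param p_i,p_j named relative-frequency vectors
#' @return a number in \[0, 1\]
#' @export
isonymy_between <- function(p_i, p_j) {
  shared <- intersect(names(p_i), names(p_j))
  if (length(shared) == 0L) return(0)
  sum(p_i[shared] * p_j[shared])
}

#' Isonymic distance functions
#'
#' Lasker's distance is `-log(I_ij)`; Nei's distance normalizes by the
#' geometric mean of the within-area isonymies,
#' `-log(I_ij / sqrt(I_ii * I_jj))`; the Euclidean (chord) distance is
#' `sqrt(1 - sum_k sqrt(p_k,i * p_k,j))`, 0 for identical areas and 1 for
#' disjoint ones. Logarithms are natural. `I_ij = 0` maps the log forms to
#' `Inf` and the chord form to 1.
#'
#' @param I_ij,I_ii,I_jj isonymy values in \[0, 1\]
#' @param p_i,p_j named relative-frequency vectors
#' @param literal if `TRUE`, `euclid_distance()` returns the radical-free
#'   form `1 - sum p_k,i * p_k,j` instead of the chord distance
#' @return a non-negative number
#' @name isonymic-distances
NULL

#' @rdname isonymic-distances
#' @export
lasker_distance <- function(I_ij) {
  if (I_ij < 0 || I_ij > 1) stop("lasker_distance: I_ij must lie in [0, 1]")
  if (I_ij == 0) Inf else -log(I_ij)
}

#' @rdname isonymic-distances
#' @export
nei_distance <- function(I_ij, I_ii, I_jj) {
  if (min(I_ij, I_ii, I_jj) < 0) stop("nei_distance: isonymies must be non-negative")
  if (I_ij == 0) return(Inf)
  -log(I_ij / sqrt(I_ii * I_jj))
}

#' @rdname isonymic-distances
#' @export
euclid_distance <- function(p_i, p_j, literal = FALSE) {
  if (any(p_i < 0) || any(p_j < 0)) stop("euclid_distance: negative frequencies")
  shared <- intersect(names(p_i), names(p_j))
  if (literal) {
    s <- if (length(shared)) sum(p_i[shared] * p_j[shared]) else 0
    return(1 - s)
  }
  s <- if (length(shared)) sum(sqrt(p_i[shared] * p_j[shared])) else 0
  sqrt(max(0, 1 - s))
}

#' Pairwise isonymic distance matrix between retained cells
#'
#' @param cells a `cell_table` from [grid_bin()]
#' @param metric one of `"euclid"` (chord, the default), `"lasker"`,
#'   `"nei"`, `"euclid_literal"`
#' @return object of class `distance_matrix`: list with `cell_ids`, the
#'   symmetric matrix `D`, and the `metric` tag. The diagonal is exactly 0
#'   for `nei` and the Euclidean forms; for `lasker` it is `-log(I_ii)`.
#' @export
distance_matrix <- function(cells, metric = c("euclid", "lasker", "nei", "euclid_literal")) {
  metric <- match.arg(metric)
  stopifnot(inherits(cells, "cell_table"))
  P <- cells$freq
  if (nrow(P) < 2L) stop("distance_matrix: need at least 2 retained cells")
  if (any(P@x < 0)) stop("distance_matrix: negative frequencies")
  I <- as.matrix(Matrix::tcrossprod(P))  # I[i, j] = sum_k p_ki * p_kj
  D <- switch(metric,
    euclid = {
      B <- sqrt(P)
      d <- 1 - as.matrix(Matrix::tcrossprod(B))
      d[d < 0] <- 0  # guard float noise before the radical
      d <- sqrt(d)
      diag(d) <- 0
      d
    },
    euclid_literal = {
      d <- 1 - I
      diag(d) <- 1 - diag(I)  # not zero in general; literal form kept as is
      d
    },
    lasker = suppressWarnings(-log(I)),  # I = 0 -> Inf by convention
    nei = {
      self <- diag(I)
      d <- suppressWarnings(-log(I / sqrt(outer(self, self))))
      diag(d) <- 0
      d
    }
  )
  D[is.nan(D)] <- Inf
  D <- (D + t(D)) / 2  # enforce exact symmetry against float noise
  dimnames(D) <- list(cells$cells$cell_id, cells$cells$cell_id)
  structure(list(cell_ids = cells$cells$cell_id, D = D, metric = metric),
            class = "distance_matrix")
}

# ---- 1-D Gaussian mixture with BIC selection ---------------------------

# Deterministic EM: quantile-spread initialisation, variance floor, no RNG.
fit_gmm_1d <- function(x, k, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  s_all <- stats::sd(x)
  floor_sd <- max(s_all, 1e-12) * 1e-4
  mu <- as.numeric(stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k)))
  if (anyDuplicated(mu)) mu <- mu + seq_len(k) * 1e-9 * max(s_all, 1)
  sigma <- rep(max(s_all / k, floor_sd), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(vapply(seq_len(k), function(j) sum(resp[, j] * (x - mu[j])^2), numeric(1)) / nk)
    sigma <- pmax(sigma, floor_sd)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(k = k, weight = w, mean = mu, sd = sigma, loglik = ll,
       bic = (3 * k - 1) * log(n) - 2 * ll)
}

#' Mixture-based separability report for a distance matrix
#'
#' Fits one-dimensional Gaussian mixtures with 1..`k_max` components to the
#' off-diagonal distances and selects the component count by BIC. More
#' components indicate a multi-modal distance distribution, i.e. better
#' separability between groups of areas. Non-finite distances (empty shared
#' surname sets under the log metrics) are excluded with a logged count.
#'
#' @param dm a `distance_matrix`, or a plain numeric vector of distances
#' @param k_max largest component count tried (default 7)
#' @return list with `metric`, `n_components`, `range` of the distances,
#'   `bic` per component count, and the selected `fit`
#' @export
separability_report <- function(dm, k_max = 7L) {
  if (inherits(dm, "distance_matrix")) {
    x <- dm$D[upper.tri(dm$D)]
    metric <- dm$metric
  } else {
    x <- as.numeric(dm)
    metric <- "unknown"
  }
  if (any(!is.finite(x))) {
    iso_log("separability_report: excluding %d non-finite distance(s)", sum(!is.finite(x)))
    x <- x[is.finite(x)]
  }
  if (length(x) < 30L) stop("separability_report: need at least 30 off-diagonal distances")
  if (stats::sd(x) == 0) {
    return(list(metric = metric, n_components = 1L, range = range(x),
                bic = NA_real_, fit = list(k = 1L, mean = x[1], sd = 0, weight = 1)))
  }
  fits <- lapply(seq_len(k_max), function(k) fit_gmm_1d(x, k))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  best <- which.min(bic)
  list(metric = metric, n_components = as.integer(best), range = range(x),
       bic = stats::setNames(bic, paste0("k", seq_len(k_max))), fit = fits[[best]])
}

#' Correlation between surname diversity and socioeconomic status
#'
#' Pearson correlation between each retained cell's effective surname
#' number and its mean SES.
#'
#' @param cells a `cell_table` whose cells carry `mean_ses`
#' @return a number in \[-1, 1\], or `NA` (with a warning) when either
#'   variable has zero variance
#' @export
alpha_ses_correlation <- function(cells) {
  stopifnot(inherits(cells, "cell_table"))
  df <- cells$cells
  ok <- is.finite(df$alpha) & is.finite(df$mean_ses)
  if (sum(ok) < 3L) stop("alpha_ses_correlation: need at least 3 cells with SES and alpha")
  if (stats::sd(df$alpha[ok]) == 0 || stats::sd(df$mean_ses[ok]) == 0) {
    warning("alpha_ses_correlation: zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(df$alpha[ok], df$mean_ses[ok])
}

#' Write a cell frequency table
#'
#' Long-format delimited text (`cell_row`, `cell_col`, `surname`, `count`,
#' `freq`) plus a per-cell summary (`cell_id`, `row`, `col`, `count`,
#' `mean_ses`, `alpha`).
#'
#' @param cells a `cell_table`
#' @param path_long long-format output file
#' @param path_summary per-cell summary output file
#' @return `path_long`, invisibly
#' @export
write_cell_table <- function(cells, path_long, path_summary) {
  stopifnot(inherits(cells, "cell_table"))
  tr <- Matrix::summary(cells$counts)
  ids <- rownames(cells$counts)
  rc <- do.call(rbind, strsplit(ids[tr$i], "_", fixed = TRUE))
  long <- data.frame(
    cell_row = as.integer(rc[, 1]), cell_col = as.integer(rc[, 2]),
    surname = colnames(cells$counts)[tr$j],
    count = as.integer(tr$x),
    freq = tr$x / Matrix::rowSums(cells$counts)[tr$i]
  )
  long <- long[order(long$cell_row, long$cell_col, long$surname), ]
  utils::write.csv(long, path_long, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cells$cells, path_summary, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path_long)
}

#' Write a distance matrix with a metric sidecar
#'
#' Square comma-separated matrix with cell ids as header row and column;
#' the metric tag is written to `<path>.json`.
#'
#' @param dm a `distance_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  utils::write.csv(as.data.frame(dm$D), path, row.names = TRUE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(metric = dm$metric, n_cells = length(dm$cell_ids)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
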
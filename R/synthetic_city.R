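#' Configuration for the synthetic city generator
#'
#' Describes a city whose residents carry two surnames each, with a planted
#' group structure: every person belongs to one of `n_groups` groups, each
#' group owns a disjoint pool of surnames with a heavy-tailed (finite Zipf)
#' frequency law, groups live spatially concentrated around distinct
#' centers, and block-level income tracks group membership. The generator is
#' the stated ground truth against which community recovery is validated.
#'
#' @param n_persons number of residents to generate
#' @param n_groups number of planted groups
#' @param surnames_per_group size of each group's disjoint surname pool
#'   (recycled to one value per group)
#' @param zipf_exponent decay exponent of the within-pool rank-frequency law
#'   (finite normalized power law, p(r) proportional to r^-s)
#' @param endogamy probability in \[0,1\] that a surname slot is drawn from
#'   the person's own group pool before the uniform group fallback; the
#'   realised own-group probability per slot is
#'   `endogamy + (1 - endogamy)/n_groups`
#' @param grid_extent numeric `c(xmin, xmax, ymin, ymax)` planar bounding box
#' @param group_centers matrix with one `(x, y)` row per group; default
#'   places the groups evenly on a circle inside the extent
#' @param group_spread per-group spatial standard deviation (recycled)
#' @param block_size side length of the square census blocks
#' @param ses_group_means per-group mean block income (recycled not allowed;
#'   default evenly spaced 25..85)
#' @param ses_noise_sd standard deviation of block-level income noise
#' @param seed integer RNG seed; generation is a pure function of the config
#' @return an object of class `city_config`
#' @export
city_config <- function(n_persons = 20000L,
                        n_groups = 4L,
                        surnames_per_group = 50L,
                        zipf_exponent = 1.0,
                        endogamy = 0.95,
                        grid_extent = c(0, 10, 0, 10),
                        group_centers = NULL,
                        group_spread = 1.2,
                        block_size = 0.25,
                        ses_group_means = NULL,
                        ses_noise_sd = 5,
                        seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons), n_groups = as.integer(n_groups),
    surnames_per_group = rep_len(as.integer(surnames_per_group), as.integer(n_groups)),
    zipf_exponent = zipf_exponent, endogamy = endogamy,
    grid_extent = as.numeric(grid_extent),
    group_centers = group_centers,
    group_spread = rep_len(group_spread, n_groups),
    block_size = block_size,
    ses_group_means = ses_group_means %||%
      seq(25, 85, length.out = as.integer(n_groups)),
    ses_noise_sd = ses_noise_sd, seed = as.integer(seed)
  )
  if (is.null(cfg$group_centers)) {
    ext <- cfg$grid_extent
    cx <- mean(ext[1:2]); cy <- mean(ext[3:4])
    r <- 0.35 * min(ext[2] - ext[1], ext[4] - ext[3])
    th <- 2 * pi * (seq_len(cfg$n_groups) - 1) / cfg$n_groups
    cfg$group_centers <- cbind(cx + r * cos(th), cy + r * sin(th))
  }
  cfg$group_centers <- matrix(as.numeric(cfg$group_centers), ncol = 2)
  validate_city_config(cfg)
  structure(cfg, class = "city_config")
}

validate_city_config <- function(cfg) {
  scalar_fields <- c("n_persons", "n_groups", "zipf_exponent", "endogamy",
                     "block_size", "ses_noise_sd", "seed")
  for (f in scalar_fields) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v)) {
      stop("city_config: field '", f, "' must be a single finite value")
    }
  }
  for (f in c("grid_extent", "group_spread", "ses_group_means", "surnames_per_group")) {
    if (!all(is.finite(cfg[[f]]))) {
      stop("city_config: field '", f, "' contains non-finite values")
    }
  }
  if (!all(is.finite(cfg$group_centers))) {
    stop("city_config: field 'group_centers' contains non-finite values")
  }
  if (cfg$endogamy < 0 || cfg$endogamy > 1) {
    stop("city_config: field 'endogamy' must lie in [0, 1]")
  }
  if (cfg$n_persons < 1L || cfg$n_groups < 1L || any(cfg$surnames_per_group < 1L)) {
    stop("city_config: counts must be >= 1")
  }
  if (cfg$zipf_exponent <= 0 || cfg$block_size <= 0 || any(cfg$group_spread <= 0)) {
    stop("city_config: 'zipf_exponent', 'block_size' and 'group_spread' must be positive")
  }
  if (cfg$ses_noise_sd < 0) stop("city_config: field 'ses_noise_sd' must be non-negative")
  ext <- cfg$grid_extent
  if (length(ext) != 4L || ext[1] >= ext[2] || ext[3] >= ext[4]) {
    stop("city_config: field 'grid_extent' must be c(xmin, xmax, ymin, ymax) with positive area")
  }
  gc <- cfg$group_centers
  if (nrow(gc) != cfg$n_groups) {
    stop("city_config: field 'group_centers' needs one row per group")
  }
  if (any(gc[, 1] < ext[1] | gc[, 1] > ext[2] | gc[, 2] < ext[3] | gc[, 2] > ext[4])) {
    stop("city_config: field 'group_centers' must lie inside grid_extent")
  }
  if (length(cfg$ses_group_means) != cfg$n_groups) {
    stop("city_config: field 'ses_group_means' needs one value per group")
  }
  invisible(cfg)
}

#' Read a city configuration from a JSON document
#'
#' Field names mirror [city_config()] arguments; absent fields take the
#' defaults.
#'
#' @param path JSON file path
#' @return a `city_config`
#' @export
city_config_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(city_config))
  bad <- setdiff(names(doc), known)
  if (length(bad)) stop("unknown city_config fields: ", paste(bad, collapse = ", "))
  if (!is.null(doc$group_centers)) doc$group_centers <- matrix(unlist(doc$group_centers), ncol = 2, byrow = TRUE)
  do.call(city_config, doc)
}

# finite-pool Zipf probabilities, p(r) ~ r^-s over ranks 1..n
zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

surname_token <- function(group, rank) sprintf("G%d_S%d", group, rank)

#' Generate a synthetic city of person records
#'
#' For each person a group is sampled uniformly. Each surname slot
#' (paternal, maternal) independently comes from the person's own group pool
#' with probability `endogamy`, otherwise from a uniformly chosen group
#' (including the own group, so the realised own-pool probability is
#' `endogamy + (1 - endogamy)/n_groups`). Within a pool, surname identity
#' follows the finite Zipf law. Locations are 2-D Gaussians around the group
#' center truncated to the grid extent; blocks are axis-aligned squares of
#' side `block_size`, and block income is the configured mean of the block's
#' modal group plus Gaussian noise, constant within a block.
#'
#' @param config a [city_config()]
#' @return a `data.frame` with columns `paternal_surname`,
#'   `maternal_surname`, `x`, `y`, `block_id`, `block_income`, `group_label`
#' @export
generate_city <- function(config) {
  validate_city_config(config)
  set.seed(config$seed)
  n <- config$n_persons
  G <- config$n_groups
  pool_size <- config$surnames_per_group
  pool_p <- lapply(seq_len(G), function(g) zipf_probs(pool_size[g], config$zipf_exponent))

  group <- sample.int(G, n, replace = TRUE)

  draw_slot <- function() {
    own <- runif(n) < config$endogamy
    g <- ifelse(own, group, sample.int(G, n, replace = TRUE))
    rank <- integer(n)
    for (gg in seq_len(G)) {  # fixed group order keeps the draw deterministic
      idx <- which(g == gg)
      if (length(idx)) {
        rank[idx] <- sample.int(pool_size[gg], length(idx), replace = TRUE,
                                prob = pool_p[[gg]])
      }
    }
    surname_token(g, rank)
  }
  paternal <- draw_slot()
  maternal <- draw_slot()

  ext <- config$grid_extent
  x <- config$group_centers[group, 1] + rnorm(n, 0, config$group_spread[group])
  y <- config$group_centers[group, 2] + rnorm(n, 0, config$group_spread[group])
  for (i in 1:1000) {
    out <- x < ext[1] | x > ext[2] | y < ext[3] | y > ext[4]
    if (!any(out)) break
    k <- sum(out)
    x[out] <- config$group_centers[group[out], 1] + rnorm(k, 0, config$group_spread[group[out]])
    y[out] <- config$group_centers[group[out], 2] + rnorm(k, 0, config$group_spread[group[out]])
  }
  # pathological spread/extent combinations: clamp the stragglers
  x <- pmin(pmax(x, ext[1]), ext[2])
  y <- pmin(pmax(y, ext[3]), ext[4])

  bi <- floor((x - ext[1]) / config$block_size)
  bj <- floor((y - ext[3]) / config$block_size)
  block_id <- sprintf("B%d_%d", bi, bj)

  # block income: modal resident group decides the mean; noise per block
  blocks <- sort(unique(block_id))
  modal <- vapply(split(group, block_id), function(g) {
    tb <- tabulate(g, nbins = G)
    which.max(tb)  # ties: lowest group index, deterministic
  }, integer(1))[blocks]
  income <- config$ses_group_means[modal] + rnorm(length(blocks), 0, config$ses_noise_sd)
  block_income <- income[match(block_id, blocks)]

  data.frame(
    paternal_surname = paternal, maternal_surname = maternal,
    x = x, y = y, block_id = block_id, block_income = block_income,
    group_label = sprintf("G%d", group),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth partition of surnames into their generating groups
#'
#' Synthetic surname tokens are `G<g>_S<rank>`, so the generating pool is
#' recoverable from the token itself; pools are disjoint by construction.
#'
#' @param records synthetic records from [generate_city()] (must carry
#'   `group_label`, the marker of synthetic provenance)
#' @return named character vector: surname -> group label
#' @export
planted_partition <- function(records) {
  if (is.null(records$group_label)) {
    stop("planted_partition: records lack 'group_label'; only synthetic records carry ground truth")
  }
  surnames <- sort(unique(c(records$paternal_surname, records$maternal_surname)))
  grp <- sub("^(G[0-9]+)_S[0-9]+$", "\\1", surnames)
  if (any(grp == surnames)) {
    stop("planted_partition: surnames do not follow the synthetic G<g>_S<rank> scheme")
  }
  stats::setNames(grp, surnames)
}

#' Write person records as delimited text
#'
#' Comma-separated UTF-8 with the canonical header
#' `paternal_surname, maternal_surname, x, y, block_id, block_income`
#' (plus `group_label` when present).
#'
#' @param records data.frame of person records
#' @param path output file
#' @return `path`, invisibly
#' @export
write_person_records <- function(records, path) {
  cols <- c("paternal_surname", "maternal_surname", "x", "y",
            "block_id", "block_income")
  if (!is.null(records$group_label)) cols <- c(cols, "group_label")
  missing <- setdiff(cols, names(records))
  if (length(missing)) stop("records lack columns: ", paste(missing, collapse = ", "))
  utils::write.csv(records[cols], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
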
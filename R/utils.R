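#' @importFrom stats rnorm runif sd cor quantile dnorm setNames aggregate
#' @importFrom utils read.csv write.csv head
#' @importFrom methods as
NULL

# let data.table's `[` dispatch see this package as data.table-aware
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage sub-seed from a master seed
#'
#' Stages of a pipeline each receive their own RNG seed so that a stage can
#' be re-run in isolation and still reproduce the end-to-end result. The
#' derivation is a small deterministic integer hash of the master seed and a
#' stage label; results stay below 2^31.
#'
#' @param seed master seed (single integer)
#' @param stage character stage label
#' @return a single integer usable with [set.seed()]
#' @export
sub_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage), length(stage) == 1L)
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 1000003 + h) %% 2147483647)
}

# Logging: package-level verbosity, INFO-level counters for dropped records.
iso_log <- function(fmt, ...) {
  if (isTRUE(getOption("isonymica.verbose", TRUE))) {
    message(sprintf(paste0("[isonymica] ", fmt), ...))
  }
  invisible(NULL)
}

# shortest-path hop distance matrix with Inf for unreachable pairs
hop_distances <- function(g) {
  igraph::distances(g, weights = NA)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type)
#' @return a single number in \[-1, 1\]
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
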
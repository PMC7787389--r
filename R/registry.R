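#' Normalize a surname token
#'
#' Trims, uppercases, strips Latin diacritics, and collapses internal
#' whitespace, so that registry spelling variants (accents, case, stray
#' spaces) map to a single node.
#'
#' @param token character vector of raw surnames
#' @return normalized character vector (possibly containing empty strings,
#'   which callers must drop; see [read_person_records()])
#' @export
normalize_surname <- function(token) {
  x <- enc2utf8(as.character(token))
  x <- toupper(x)
  from <- paste0("ÁÉÍÓÚ",  # A E I O U acute
                 "ÀÈÌÒÙ",  # grave
                 "ÂÊÎÔÛ",  # circumflex
                 "ÄËÏÖÜ",  # diaeresis
                 "ÃÕÑÇŸ")  # tilde A O, enye, cedilla, Y
  to <- paste0("AEIOU", "AEIOU", "AEIOU", "AEIOU", "AONCY")
  x <- chartr(from, to, x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Min-max normalize block incomes to a 0-100 socioeconomic index
#'
#' `z_i = 100 * (x_i - min x) / (max x - min x)`. When all incomes are
#' equal the range is degenerate and every block gets 0.
#'
#' @param raw_incomes named numeric vector (names are block ids) or a plain
#'   numeric vector
#' @return object of class `ses_index`: list with `raw` and `z` (both named
#'   like the input)
#' @export
normalize_ses <- function(raw_incomes) {
  x <- raw_incomes
  if (length(x) == 0L) stop("normalize_ses: no incomes supplied")
  bad <- !is.finite(x)
  if (any(bad)) {
    lab <- if (!is.null(names(x))) paste(names(x)[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("normalize_ses: non-finite income for block(s): ", lab)
  }
  rng <- range(x)
  z <- if (rng[1] == rng[2]) rep(0, length(x)) else 100 * (x - rng[1]) / (rng[2] - rng[1])
  names(z) <- names(x)
  structure(list(raw = x, z = z), class = "ses_index")
}

#' Attach block-level SES to person records
#'
#' Each person receives the normalized SES of the block they live in.
#' Records whose `block_id` is absent from the index are dropped (with a
#' logged count) or raise an error, per `unmatched`.
#'
#' @param records data.frame with a `block_id` column
#' @param ses a `ses_index` whose `z` is named by block id
#' @param unmatched `"drop"` (default) or `"error"`
#' @return records with an added numeric `ses` column
#' @export
assign_person_ses <- function(records, ses, unmatched = c("drop", "error")) {
  unmatched <- match.arg(unmatched)
  stopifnot(inherits(ses, "ses_index"), !is.null(names(ses$z)))
  idx <- match(records$block_id, names(ses$z))
  miss <- is.na(idx)
  if (any(miss)) {
    if (unmatched == "error") {
      stop("assign_person_ses: ", sum(miss), " record(s) in blocks absent from the SES index")
    }
    iso_log("assign_person_ses: dropped %d record(s) with unmatched block_id", sum(miss))
    records <- records[!miss, , drop = FALSE]
    idx <- idx[!miss]
  }
  records$ses <- unname(ses$z[idx])
  rownames(records) <- NULL
  records
}

#' Read a person-record table from delimited text
#'
#' Reads the canonical comma-separated format written by
#' [write_person_records()]; `col_map` renames registry-specific columns to
#' the canonical names (`paternal_surname`, `maternal_surname`, `x`, `y`,
#' `block_id`, `block_income`). Surnames are normalized on read; records
#' whose surnames normalize to the empty string are dropped with a logged
#' count.
#'
#' @param path input file
#' @param col_map named character vector mapping canonical name ->
#'   file column name, for non-canonical headers
#' @param sep field separator (default comma)
#' @return data.frame of normalized person records
#' @export
read_person_records <- function(path, col_map = NULL, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        stop("read_person_records: mapped column '", col_map[[canon]], "' not in file")
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  need <- c("paternal_surname", "maternal_surname", "x", "y", "block_id", "block_income")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("read_person_records: missing columns: ", paste(missing, collapse = ", "))
  df$paternal_surname <- normalize_surname(df$paternal_surname)
  df$maternal_surname <- normalize_surname(df$maternal_surname)
  empty <- df$paternal_surname == "" | df$maternal_surname == ""
  if (any(empty)) {
    iso_log("read_person_records: dropped %d record(s) with empty surnames after normalization", sum(empty))
    df <- df[!empty, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Compute the block-level SES index from person records
#'
#' Convenience wrapper: extracts one raw income per block and min-max
#' normalizes it to 0-100.
#'
#' @param records data.frame with `block_id` and `block_income`
#' @return a `ses_index` named by block id
#' @export
block_ses_index <- function(records) {
  inc <- tapply(records$block_income, records$block_id, function(v) v[1])
  normalize_ses(stats::setNames(as.numeric(inc), names(inc)))
}
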
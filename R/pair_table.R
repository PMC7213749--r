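#' Clonotype count-pair table
#'
#' The unit of all likelihoods in the package: one row per clonotype with
#' its molecule (UMI) counts in two samples — either two same-day replicates
#' (for learning the noise model) or two time points (for learning the
#' expansion model). Rows with both counts zero are rejected: unobserved
#' clones are handled analytically, never enumerated.
#'
#' @param x A data frame with columns `clone_id`, `n`, `n_prime` (or columns
#'   named by the `col_*` arguments).
#' @param col_clone,col_n,col_n_prime Column names to map from, for foreign
#'   tables (e.g. aligner/clonotype-pipeline exports).
#' @param n_read,n_read_prime Total molecule counts of the two samples;
#'   default to the column sums (the table's own accounting).
#' @return A tibble of class `pair_table` with columns `clone_id` (character),
#'   `n`, `n_prime` (integers) and attributes `n_read`, `n_read_prime`.
#' @examples
#' pair_table(data.frame(clone_id = c("a", "b"), n = c(3, 0), n_prime = c(1, 2)))
#' @export
pair_table <- function(x, col_clone = "clone_id", col_n = "n",
                       col_n_prime = "n_prime",
                       n_read = NULL, n_read_prime = NULL) {
  miss <- setdiff(c(col_clone, col_n, col_n_prime), names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  tab <- tibble::tibble(
    clone_id = as.character(x[[col_clone]]),
    n = x[[col_n]],
    n_prime = x[[col_n_prime]]
  )
  extra <- setdiff(names(x), c(col_clone, col_n, col_n_prime))
  for (nm in extra) tab[[nm]] <- x[[nm]]   # keep ground-truth/annotation columns
  bad <- which(!is.finite(tab$n) | !is.finite(tab$n_prime) |
                 tab$n != floor(tab$n) | tab$n_prime != floor(tab$n_prime))
  if (length(bad) > 0) {
    rlang::abort(sprintf("Non-integer or missing count in row(s) %s.",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(tab$n < 0) || any(tab$n_prime < 0)) {
    rlang::abort("Counts must be non-negative.")
  }
  zz <- which(tab$n + tab$n_prime == 0)
  if (length(zz) > 0) {
    rlang::abort(sprintf(
      "Row(s) %s have n + n' = 0; a pair table contains observed clones only (n + n' > 0).",
      paste(utils::head(zz, 5), collapse = ", ")
    ))
  }
  if (anyDuplicated(tab$clone_id)) {
    rlang::abort("Duplicate clone_id values; clonotype keys must be unique.")
  }
  tab$n <- as.integer(round(tab$n))
  tab$n_prime <- as.integer(round(tab$n_prime))
  attr(tab, "n_read") <- if (is.null(n_read)) sum(tab$n) else n_read
  attr(tab, "n_read_prime") <- if (is.null(n_read_prime)) sum(tab$n_prime) else n_read_prime
  class(tab) <- c("pair_table", class(tab))
  tab
}

# multiplicity table of unique (n, n') pairs; likelihoods are evaluated once
# per unique pair, never per clone
pt_pairs <- function(tab) {
  key <- paste(tab$n, tab$n_prime)
  u <- !duplicated(key)
  idx <- match(key, key[u])
  tibble::tibble(
    n = tab$n[u], n_prime = tab$n_prime[u],
    weight = tabulate(idx, nbins = sum(u))
  )
}

pt_n_read <- function(tab) {
  c(attr(tab, "n_read") %||% sum(tab$n),
    attr(tab, "n_read_prime") %||% sum(tab$n_prime))
}

#' Read a clonotype count-pair table from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row naming columns
#' `clone_id`, `count_1`, `count_2` (override with the `col_*` arguments for
#' foreign exports), and optional `#`-prefixed metadata lines. Rows with
#' both counts zero are rejected.
#'
#' @param path Path to the TSV file.
#' @inheritParams pair_table
#' @return A [pair_table()].
#' @export
read_pair_table <- function(path, col_clone = "clone_id", col_n = "count_1",
                            col_n_prime = "count_2",
                            n_read = NULL, n_read_prime = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("No such file: ", path))
  # honor '# n_read_*=' metadata written by write_pair_table (the model's
  # read-total constants, which for simulated tables are the nominal values)
  head_lines <- readLines(path, n = 10L, warn = FALSE)
  meta <- head_lines[startsWith(head_lines, "#")]
  get_meta <- function(key) {
    m <- regmatches(meta, regexec(paste0(key, "\\s*=\\s*([0-9.eE+]+)"), meta))
    v <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
    if (length(v) > 0) as.numeric(v[1]) else NULL
  }
  if (is.null(n_read)) n_read <- get_meta("n_read_1")
  if (is.null(n_read_prime)) n_read_prime <- get_meta("n_read_2")
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    rlang::abort(sprintf("Malformed TSV at line %d: %s", prob$row[1] + 1L,
                         prob$expected[1]))
  }
  pair_table(raw, col_clone = col_clone, col_n = col_n,
             col_n_prime = col_n_prime,
             n_read = n_read, n_read_prime = n_read_prime)
}

#' Write a clonotype count-pair table to TSV
#'
#' Writes columns `clone_id`, `count_1`, `count_2` with `#` metadata lines
#' carrying the sample totals, the format [read_pair_table()] reads back.
#'
#' @param tab A [pair_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(tab, path) {
  stopifnot(inherits(tab, "pair_table"))
  nr <- pt_n_read(tab)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_read_1=%d", as.integer(nr[1])), con)
  writeLines(sprintf("# n_read_2=%d", as.integer(nr[2])), con)
  writeLines("clone_id\tcount_1\tcount_2", con)
  writeLines(sprintf("%s\t%d\t%d", tab$clone_id, tab$n, tab$n_prime), con)
  invisible(path)
}
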
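#' @importFrom rlang abort warn %||%
#' @importFrom stats setNames
NULL

# Convert a wide sample (or MAG) table -- id column plus numeric columns --
# into a numeric matrix with ids as rownames. The inverse of matrix_to_tbl().
as_id_matrix <- function(tbl, id_col) {
  if (!is.data.frame(tbl)) {
    abort("expected a data frame")
  }
  if (!id_col %in% names(tbl)) {
    abort(sprintf("column '%s' not found", id_col))
  }
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated %s values: %s", id_col,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (!is.numeric(m)) {
    abort("non-numeric cells in table body")
  }
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_col) {
  tibble::as_tibble(m, rownames = id_col)
}

# Relative-abundance vector check: non-negative, sums to one.
check_simplex <- function(p, tol = 1e-9) {
  if (length(p) == 0 || all(p == 0)) {
    abort("abundance vector is empty or all zero")
  }
  if (any(p < 0)) {
    abort("negative abundances")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("abundances must sum to 1 (got %.12f)", sum(p)))
  }
  invisible(p)
}

# Deterministic child seeds below 2^31, so stages can be rerun in isolation.
child_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, phylogeny = 23L, pathways = 37L, genes = 53L,
               counts = 71L, permanova = 97L, bootstrap = 113L,
               correlation = 131L, study = 151L)
  off <- offsets[[stage]] %||% 173L
  (as.integer(seed) %% 20000000L) * 100L + off
}
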
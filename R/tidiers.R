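#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA fit
#'
#' @param x A `mag_permanova` object.
#' @param ... Unused.
#' @return One row per ANOVA-table term (groups, residual, total) with sums
#'   of squares, degrees of freedom, statistic and p-value.
#' @export
tidy.mag_permanova <- function(x, ...) {
  tibble::tibble(
    term = c(x$term, "residual", "total"),
    df = c(x$df[["among"]], x$df[["within"]], x$n - 1),
    sum_of_squares = unname(c(x$ss[["among"]], x$ss[["within"]], x$ss[["total"]])),
    r_squared = c(x$r_squared, 1 - x$r_squared, 1),
    statistic = c(x$pseudo_f, NA, NA),
    p_value = c(x$p_value, NA, NA)
  )
}

#' One-row summary of a PERMANOVA fit
#'
#' @inheritParams tidy.mag_permanova
#' @return Tibble with `pseudo_f`, `r_squared`, `p_value`, `n_permutations`,
#'   `n_samples`.
#' @export
glance.mag_permanova <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, r_squared = x$r_squared,
                 p_value = x$p_value, n_permutations = x$n_permutations,
                 n_samples = x$n)
}

#' Tidy a CAP ordination (site scores)
#'
#' @param x A `mag_cap` object.
#' @param ... Unused.
#' @return Tibble of sample id, group and canonical-axis scores.
#' @export
tidy.mag_cap <- function(x, ...) {
  x$scores
}

#' One-row summary of a CAP ordination
#'
#' @inheritParams tidy.mag_cap
#' @return Tibble with `m`, `loo_success`, `n_axes`, `n_samples`.
#' @export
glance.mag_cap <- function(x, ...) {
  tibble::tibble(m = x$m, loo_success = x$loo_success,
                 n_axes = sum(grepl("^LD", names(x$scores))),
                 n_samples = nrow(x$scores))
}
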
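#' Rao quadratic entropy
#'
#' Expected functional distance between two individuals drawn at random from
#' the community: `Q = sum_ij p_i p_j d_ij`.
#'
#' @param p Relative-abundance vector.
#' @param d Pairwise functional distance matrix in \[0,1\], aligned with `p`
#'   (by names when both are named).
#' @return Non-negative real.
#' @export
rao_quadratic <- function(p, d) {
  check_simplex(p)
  if (!is.null(names(p)) && !is.null(rownames(d))) {
    miss <- setdiff(names(p), rownames(d))
    if (length(miss) > 0) {
      abort(sprintf("MAG(s) missing from distance matrix: %s",
                    paste(miss, collapse = ", ")))
    }
    d <- d[names(p), names(p), drop = FALSE]
  } else if (length(p) != nrow(d)) {
    abort("abundance vector and distance matrix are misaligned")
  }
  sum(outer(p, p) * d)
}

#' Gini-Simpson index
#'
#' Probability that two randomly drawn individuals belong to different MAGs:
#' `D = 1 - sum(p_i^2)`.
#'
#' @param p Relative-abundance vector.
#' @return Value in \[0, 1).
#' @export
gini_simpson <- function(p) {
  check_simplex(p)
  1 - sum(p^2)
}

#' Functional uniqueness and redundancy of communities
#'
#' Uniqueness `Ustar = Q/D` is the ratio of Rao quadratic entropy to the
#' Gini-Simpson index; redundancy `Rstar = 1 - Ustar`. With distances bounded
#' in \[0,1\] (as Gower guarantees) the ratio is bounded: Rstar = 1 means the
#' community is fully functionally redundant (all members identical),
#' Rstar = 0 means every member is completely functionally unique.
#' Single-MAG communities have `D = 0`; they are returned with
#' `defined = FALSE` and `NA` uniqueness, to be excluded from summaries.
#'
#' @param abund Relative-abundance tibble (`sample_id` + MAG columns).
#' @param d Pairwise functional distance matrix in \[0,1\].
#' @return Tibble with `sample_id`, `rao_q`, `simpson`, `ustar`, `rstar`,
#'   `defined`.
#' @export
functional_redundancy <- function(abund, d) {
  if (any(d < 0 | d > 1)) {
    abort("distances must lie in [0,1] for bounded uniqueness")
  }
  m <- as_id_matrix(abund, "sample_id")
  purrr::map_dfr(rownames(m), function(s) {
    p <- m[s, ]
    p <- p[p > 0]
    p <- p / sum(p)
    if (length(p) < 2) {
      return(tibble::tibble(sample_id = s, rao_q = 0, simpson = 0,
                            ustar = NA_real_, rstar = NA_real_, defined = FALSE))
    }
    dd <- d[names(p), names(p), drop = FALSE]
    Q <- sum(outer(p, p) * dd)
    D <- 1 - sum(p^2)
    u <- Q / D
    if (u > 1 + 1e-8) {
      abort(sprintf("sample '%s': Q/D = %.6f > 1 with in-range distances", s, u))
    }
    u <- pmin(1, pmax(0, u))
    tibble::tibble(sample_id = s, rao_q = Q, simpson = D,
                   ustar = u, rstar = 1 - u, defined = TRUE)
  })
}

#' Relationship between diversity and functional redundancy
#'
#' Pairs the log neutral Hill diversity of each sample with its redundancy
#' (`rstar`) and reports Pearson and Spearman correlations with permutation
#' p-values (seeded). Degenerate variance yields `NA` correlations.
#'
#' @param diversity Alpha-diversity tibble ([alpha_diversity()]); the
#'   `neutral` component is used.
#' @param redundancy Redundancy tibble ([functional_redundancy()]).
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation generator.
#' @return List with `data` (tibble `sample_id`, `log_diversity`, `rstar`)
#'   and `correlations` (tibble `method`, `estimate`, `p_value`).
#' @export
redundancy_diversity_relation <- function(diversity, redundancy, n_perm = 999,
                                          seed = NULL) {
  div <- dplyr::filter(diversity, .data$component == "neutral")
  tbl <- dplyr::inner_join(
    dplyr::transmute(div, sample_id = .data$sample_id,
                     log_diversity = log(.data$diversity)),
    dplyr::filter(redundancy, .data$defined) |>
      dplyr::select("sample_id", "rstar"),
    by = "sample_id"
  )
  if (nrow(tbl) < 3) {
    abort("need at least 3 samples with defined redundancy")
  }
  x <- tbl$log_diversity
  y <- tbl$rstar
  cors <- purrr::map_dfr(c("pearson", "spearman"), function(meth) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(method = meth, estimate = NA_real_,
                            p_value = NA_real_))
    }
    obs <- stats::cor(x, y, method = meth)
    perm <- withr::with_seed(seed %||% 1L, {
      replicate(n_perm, stats::cor(x, sample(y), method = meth))
    })
    tibble::tibble(method = meth, estimate = obs,
                   p_value = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm))
  })
  list(data = tbl, correlations = cors)
}
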
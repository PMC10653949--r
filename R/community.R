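#' Gower-centered inner-product matrix of a dissimilarity
#'
#' Standard double-centering used by distance-based partitioning and
#' principal-coordinates analysis: `G = -0.5 * J A J` with `A` the squared
#' dissimilarities and `J` the centering projector. Rows of `G` sum to zero.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @return Centered symmetric matrix `G`.
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort("dissimilarity matrix must be symmetric")
  }
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  gm <- mean(a)
  sweep(sweep(a, 1, rm_), 2, rm_) + gm
}

# Sum of squares decomposition from squared dissimilarities, the classic
# trace identity: SS_total = sum(d^2)/(2N), SS_within = sum over groups of
# within-group squared dissimilarities / (2 n_g).
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  lev <- unique(groups)
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, among = ss_total - ss_within, within = ss_within)
}

permanova_f <- function(d2, groups, a, n) {
  ss <- permanova_ss(d2, groups)
  (ss[["among"]] / (a - 1)) / (ss[["within"]] / (n - a))
}

#' PERMANOVA with strata-restricted permutations
#'
#' Permutational multivariate analysis of variance of a single grouping
#' factor on a dissimilarity matrix. The observed pseudo-F compares
#' among-group to residual sums of squared dissimilarities; significance
#' comes from permuting group labels, restricted to exchanges within each
#' stratum (e.g. within each individual in a repeated-measures design).
#' The reported R-squared is the unadjusted among-group proportion
#' `SS_among / SS_total`.
#'
#' @param d Symmetric dissimilarity matrix over samples (e.g. from
#'   [beta_dissimilarity()]).
#' @param groups Factor-like vector of group labels, length `nrow(d)`.
#' @param strata Optional vector of block labels; labels are permuted only
#'   within blocks. `NULL` means free permutation. Blocks with a single
#'   sample contribute no permutation.
#' @param n_perm Number of permutations (default 999); the observed
#'   labelling is always part of the reference set. `0` skips the test and
#'   returns `p_value = NA`.
#' @param seed Seed for the permutation generator.
#' @return Object of class `mag_permanova`: list with `term`, `pseudo_f`,
#'   `r_squared`, `p_value`, `n_permutations`, `ss` (total/among/within),
#'   `df`, `n`. Has [tidy()] and [glance()] methods.
#' @export
permanova <- function(d, groups, strata = NULL, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) {
    abort("groups must have one label per sample")
  }
  a <- length(unique(groups))
  if (a < 2) {
    abort("groups must have at least 2 levels")
  }
  d2 <- d^2
  ss <- permanova_ss(d2, groups)
  f_obs <- (ss[["among"]] / (a - 1)) / (ss[["within"]] / (n - a))
  r2 <- ss[["among"]] / ss[["total"]]

  p_value <- NA_real_
  if (n_perm > 0) {
    blocks <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
    singletons <- vapply(blocks, length, integer(1)) == 1
    perm_f <- withr::with_seed(seed %||% 1L, {
      vapply(seq_len(n_perm), function(i) {
        g <- groups
        for (b in blocks[!singletons]) {
          g[b] <- g[b][sample.int(length(b))]
        }
        permanova_f(d2, g, a, n)
      }, numeric(1))
    })
    p_value <- (1 + sum(perm_f >= f_obs - 1e-12)) / (1 + n_perm)
  }

  structure(list(term = "groups", pseudo_f = unname(f_obs),
                 r_squared = unname(r2), p_value = p_value,
                 n_permutations = n_perm,
                 ss = ss, df = c(among = a - 1, within = n - a),
                 n = n, strata = !is.null(strata)),
            class = "mag_permanova")
}

#' @export
print.mag_permanova <- function(x, ...) {
  cat("PERMANOVA (", if (x$strata) "strata-restricted" else "free",
      " permutations)\n", sep = "")
  cat(sprintf("  pseudo-F = %.4f on (%d, %d) df\n", x$pseudo_f,
              x$df[["among"]], x$df[["within"]]))
  cat(sprintf("  unadjusted R2 = %.4f\n", x$r_squared))
  if (!is.na(x$p_value)) {
    cat(sprintf("  p = %.4g (%d permutations)\n", x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Constrained ordination that makes group separation visible: the
#' dissimilarity matrix is decomposed into principal coordinates (axes with
#' negative eigenvalues are excluded with a warning), the first `m`
#' coordinates are retained, and a canonical discriminant analysis of group
#' membership is run on them. When `m` is not given it is chosen to maximize
#' leave-one-out group-allocation success (ties resolved to the smallest
#' `m`).
#'
#' @param d Symmetric dissimilarity matrix over samples.
#' @param groups Group labels, length `nrow(d)`.
#' @param m Number of principal-coordinate axes to retain (optional).
#' @return Object of class `mag_cap`: list with `scores` (tibble of sample
#'   id, group and canonical axis scores), `eigenvalues` (PCoA), `m`,
#'   `loo_success`. Has [tidy()], [glance()] and [ggplot2::autoplot()]
#'   methods.
#' @export
cap <- function(d, groups, m = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    abort("groups must have at least 2 levels")
  }
  G <- gower_center(d)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- which(eig$values > tol)
  if (any(eig$values < -tol)) {
    warn(sprintf("%d axis/axes with negative eigenvalues excluded",
                 sum(eig$values < -tol)))
  }
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]),
                                                      length(pos))
  m_max <- min(length(pos), n - 2)

  quiet_lda <- function(...) {
    withCallingHandlers(MASS::lda(...), warning = function(w) {
      if (grepl("collinear", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  }
  loo_for <- function(mm) {
    fit <- try(quiet_lda(coords[, seq_len(mm), drop = FALSE], grouping = groups,
                         CV = TRUE), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    mean(fit$class == groups, na.rm = TRUE)
  }
  if (is.null(m)) {
    succ <- vapply(seq_len(m_max), loo_for, numeric(1))
    if (all(is.na(succ))) abort("leave-one-out allocation failed for every m")
    m <- which.max(succ)  # which.max returns the first (smallest) maximizer
    loo <- succ[m]
  } else {
    if (m < 1 || m >= n) abort("m must satisfy 1 <= m < N")
    m <- min(m, m_max)
    loo <- loo_for(m)
  }
  retained <- coords[, seq_len(m), drop = FALSE]
  fit <- quiet_lda(retained, grouping = groups)
  scores <- stats::predict(fit, newdata = retained)$x
  ids <- rownames(d) %||% as.character(seq_len(n))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = ids, group = groups),
                              tibble::as_tibble(scores)),
    eigenvalues = eig$values[pos],
    m = m,
    loo_success = loo
  ), class = "mag_cap")
}

#' @export
print.mag_cap <- function(x, ...) {
  cat(sprintf("CAP: %d PCo axes retained, leave-one-out success %.3f\n",
              x$m, x$loo_success))
  cat(sprintf("  %d canonical axes over %d samples\n",
              sum(grepl("^LD", names(x$scores))), nrow(x$scores)))
  invisible(x)
}
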
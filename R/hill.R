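#' Neutral Hill number of a community
#'
#' Effective number of equally-abundant MAGs at diversity order `q`. At
#' `q = 1` (the default) this is the exponential of Shannon entropy,
#' weighting MAGs by their relative abundances; the limit is taken
#' analytically. Zero-abundance entries are ignored.
#'
#' @param p Relative-abundance vector (non-negative, sums to 1).
#' @param q Diversity order (default 1).
#' @return Effective number of MAGs, in \[1, S\] for q >= 0.
#' @export
hill_neutral <- function(p, q = 1) {
  check_simplex(p)
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

# Per-branch descendant abundances for a rooted tree and a named abundance
# vector. Returns list(length = edge lengths, a = summed tip abundance below
# each edge). Tips absent from p (or zero) contribute 0.
branch_abundances <- function(tree, p) {
  pos <- names(p)[p > 0]
  miss <- setdiff(pos, tree$tip.label)
  if (length(miss) > 0) {
    abort(sprintf("abundant MAG(s) missing from tree tips: %s",
                  paste(miss, collapse = ", ")))
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  acc <- numeric(nnode)
  tipp <- setNames(rep(0, ntip), tr$tip.label)
  tipp[names(p)] <- p
  acc[seq_len(ntip)] <- unname(tipp)
  for (e in seq_len(nrow(tr$edge))) {
    acc[tr$edge[e, 1]] <- acc[tr$edge[e, 1]] + acc[tr$edge[e, 2]]
  }
  list(length = tr$edge.length, a = acc[tr$edge[, 2]])
}

#' Phylogenetic Hill number of a community
#'
#' Abundance-weighted effective number of lineages. Each branch carries the
#' summed relative abundance of its descendant tips; with `T` the
#' abundance-weighted mean tree depth (sum of branch length times branch
#' abundance), the order-1 value is
#' `exp(-sum((L_b/T) * a_b * log(a_b)))`. On a star tree with equal branch
#' lengths this reduces exactly to [hill_neutral()].
#'
#' @param p Named relative-abundance vector; names are tree tips.
#' @param tree Rooted `phylo` with branch lengths.
#' @param q Diversity order (default 1).
#' @param normalized If `TRUE` (default) return the effective number of
#'   lineages (mean diversity over the tree depth `T`); if `FALSE`, the
#'   un-normalized effective total branch length (`T` times the former).
#' @return Positive real diversity value.
#' @export
hill_phylo <- function(p, tree, q = 1, normalized = TRUE) {
  check_simplex(p)
  br <- branch_abundances(tree, p)
  keep <- br$a > 0 & br$length > 0
  L <- br$length[keep]
  a <- br$a[keep]
  Tbar <- sum(L * a)
  if (Tbar <= 0) {
    abort("abundance-weighted tree depth is zero")
  }
  d <- if (abs(q - 1) < 1e-12) {
    exp(-sum((L / Tbar) * a * log(a)))
  } else {
    sum((L / Tbar) * a^q)^(1 / (1 - q))
  }
  if (normalized) d else Tbar * d
}

#' Gower distance between MAGs over functional traits
#'
#' Range-normalized mean absolute difference: traits are scaled by their
#' observed range and averaged; constant traits carry no information and are
#' excluded from the mean.
#'
#' @param traits Tibble with `mag_id` and numeric trait columns (e.g. an MCI
#'   table from [distill_mci()]).
#' @return Symmetric matrix of pairwise distances in \[0,1\] with zero
#'   diagonal, dimnames = MAG ids.
#' @export
gower_distance <- function(traits) {
  m <- as_id_matrix(traits, "mag_id")
  if (nrow(m) < 2) {
    abort("need at least 2 MAGs for a distance matrix")
  }
  rng <- apply(m, 2, function(x) diff(range(x)))
  use <- which(rng > 0)
  if (length(use) == 0) {
    abort("all traits are constant; Gower distance undefined")
  }
  d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (j in use) {
    d <- d + abs(outer(m[, j], m[, j], "-")) / rng[j]
  }
  d / length(use)
}

#' Functional Hill number of a community
#'
#' Attribute-diversity of order `q` built on pairwise functional distances:
#' with Rao `Q = sum(d_ij p_i p_j)`, the order-1 value is
#' `exp(-0.5 * sum((d_ij/Q) p_i p_j log(p_i p_j)))`, the effective number of
#' equally-abundant and equally-distinct MAGs.
#'
#' @param p Relative-abundance vector (named if `d` has dimnames to align).
#' @param d Symmetric pairwise functional distance matrix in \[0,1\].
#' @param q Diversity order (default 1).
#' @return Effective number of equally-distinct MAGs.
#' @export
hill_func <- function(p, d, q = 1) {
  check_simplex(p)
  if (!is.null(names(p)) && !is.null(rownames(d))) {
    miss <- setdiff(names(p)[p > 0], rownames(d))
    if (length(miss) > 0) {
      abort(sprintf("MAG(s) missing from distance matrix: %s",
                    paste(miss, collapse = ", ")))
    }
    keep <- names(p)[p > 0]
    d <- d[keep, keep, drop = FALSE]
    p <- p[keep]
  } else {
    d <- d[p > 0, p > 0, drop = FALSE]
    p <- p[p > 0]
  }
  pp <- outer(p, p)
  Q <- sum(d * pp)
  if (Q <= 0) {
    abort("Rao Q is zero: community is functionally uniform, functional Hill number undefined")
  }
  if (abs(q - 1) < 1e-12) {
    exp(-0.5 * sum((d / Q) * pp * log(pp)))
  } else {
    sum((d / Q) * pp^q)^(1 / (2 * (1 - q)))
  }
}

#' Alpha diversities for every sample of an abundance table
#'
#' Computes neutral, phylogenetic and/or functional Hill numbers per sample
#' in tidy long format. All-zero samples are skipped with a warning.
#'
#' @param abund Relative-abundance tibble (`sample_id` + MAG columns).
#' @param tree `phylo` covering the MAGs (for the phylogenetic component).
#' @param dist Functional distance matrix (for the functional component).
#' @param q Diversity order (default 1).
#' @param components Which components to compute.
#' @return Tibble with `sample_id`, `component`, `q`, `diversity`.
#' @export
alpha_diversity <- function(abund, tree = NULL, dist = NULL, q = 1,
                            components = c("neutral", "phylogenetic", "functional")) {
  components <- match.arg(components, several.ok = TRUE)
  if ("phylogenetic" %in% components && is.null(tree)) {
    abort("phylogenetic component requested but no tree given")
  }
  if ("functional" %in% components && is.null(dist)) {
    abort("functional component requested but no distance matrix given")
  }
  m <- as_id_matrix(abund, "sample_id")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warn(sprintf("skipping all-zero sample(s): %s",
                 paste(rownames(m)[zero], collapse = ", ")))
    m <- m[!zero, , drop = FALSE]
  }
  purrr::map_dfr(rownames(m), function(s) {
    p <- m[s, ]
    p <- p / sum(p)
    purrr::map_dfr(components, function(comp) {
      val <- switch(comp,
                    neutral = hill_neutral(p, q),
                    phylogenetic = hill_phylo(p, tree, q),
                    functional = hill_func(p, d = dist, q = q))
      tibble::tibble(sample_id = s, component = comp, q = q, diversity = val)
    })
  })
}

#' Partition diversity of a set of samples into alpha, gamma and beta
#'
#' Equal-weight Hill-number partition at order `q`. Gamma is the diversity
#' of the pooled (mean) community; alpha is the within-sample average in the
#' Hill framework (for `q = 1`, the exponential of the mean Shannon entropy
#' for the neutral and phylogenetic components; the attribute-diversity
#' alpha for the functional component). Beta = gamma/alpha lies in \[1, N\]
#' for neutral and phylogenetic components and \[1, N^2\] for the functional
#' component (which counts effective pairs).
#'
#' @param mat Numeric matrix, samples in rows (each row summing to 1), MAGs
#'   in columns; or a tibble with `sample_id`.
#' @param component One of "neutral", "phylogenetic", "functional".
#' @param tree Tree for the phylogenetic backbone.
#' @param dist Functional distance matrix for the functional backbone.
#' @param q Diversity order (default 1).
#' @return List with `alpha`, `gamma`, `beta`, `n_samples`, `component`.
#' @export
beta_partition <- function(mat, component = c("neutral", "phylogenetic", "functional"),
                           tree = NULL, dist = NULL, q = 1) {
  component <- match.arg(component)
  if (is.data.frame(mat)) {
    mat <- as_id_matrix(mat, "sample_id")
  }
  if (nrow(mat) < 2) {
    abort("need at least 2 samples to partition diversity")
  }
  mat <- mat / rowSums(mat)
  N <- nrow(mat)
  is_q1 <- abs(q - 1) < 1e-12

  if (component == "neutral") {
    pbar <- colMeans(mat)
    gamma <- hill_neutral(pbar, q)
    if (is_q1) {
      hs <- apply(mat, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
      alpha <- exp(mean(hs))
    } else {
      w <- mat / N
      alpha <- sum(w[w > 0]^q)^(1 / (1 - q)) / N
    }
  } else if (component == "phylogenetic") {
    if (is.null(tree)) abort("phylogenetic partition needs a tree")
    A <- t(apply(mat, 1, function(p) branch_abundances(tree, setNames(p, colnames(mat)))$a))
    L <- branch_abundances(tree, setNames(mat[1, ], colnames(mat)))$length
    abar <- colMeans(A)
    Tbar <- sum(L * abar)
    if (Tbar <= 0) abort("abundance-weighted tree depth is zero")
    keep <- abar > 0 & L > 0
    if (is_q1) {
      gamma <- exp(-sum((L[keep] / Tbar) * abar[keep] * log(abar[keep])))
      W <- A / N
      lw <- W * log(W)
      lw[W == 0] <- 0
      alpha <- exp(-sum((L / Tbar) * colSums(lw))) / N
    } else {
      gamma <- sum((L[keep] / Tbar) * abar[keep]^q)^(1 / (1 - q))
      W <- A / N
      alpha <- sum((L / Tbar) * colSums(W^q * (W > 0)))^(1 / (1 - q)) / N
    }
  } else {
    if (is.null(dist)) abort("functional partition needs a distance matrix")
    if (!is.null(colnames(mat)) && !is.null(rownames(dist))) {
      dist <- dist[colnames(mat), colnames(mat), drop = FALSE]
    }
    pbar <- colMeans(mat)
    ppbar <- outer(pbar, pbar)
    Q <- sum(dist * ppbar)
    if (Q <= 0) abort("pooled Rao Q is zero; functional partition undefined")
    # FD (effective-pair) gamma and alpha; beta = gamma/alpha in [1, N^2].
    s <- colSums(mat)           # N * pbar
    if (is_q1) {
      lg <- log(ppbar)
      lg[ppbar == 0] <- 0
      fd_gamma <- exp(-sum((dist / Q) * ppbar * lg))
      lp <- mat * log(mat)
      lp[mat == 0] <- 0
      t_i <- colSums(lp)        # sum_k p_ik log p_ik
      inner <- (outer(t_i, s) + outer(s, t_i) - 2 * log(N) * outer(s, s)) / N^2
      fd_alpha <- exp(-sum((dist / Q) * inner)) / N^2
    } else {
      fd_gamma <- sum((dist / Q) * ppbar^q)^(1 / (1 - q))
      wq <- colSums((mat / N)^q * (mat > 0))
      fd_alpha <- sum((dist / Q) * outer(wq, wq))^(1 / (1 - q)) / N^2
    }
    gamma <- fd_gamma
    alpha <- fd_alpha
  }
  beta <- gamma / alpha
  list(alpha = alpha, gamma = gamma, beta = beta, n_samples = N,
       component = component)
}

#' Sorensen-type turnover from a beta-diversity value
#'
#' Normalizes Hill-framework beta onto \[0,1\]: `(beta - 1)/(N - 1)` for the
#' neutral and phylogenetic components, `(beta - 1)/(N^2 - 1)` for the
#' functional component whose beta counts effective pairs and ranges to
#' `N^2`. 0 means identical communities, 1 complete turnover.
#'
#' @param beta Beta-diversity value (gamma/alpha).
#' @param n_samples Number of samples in the partition.
#' @param component Diversity component the beta came from.
#' @return Turnover in \[0,1\].
#' @export
sorensen_turnover <- function(beta, n_samples,
                              component = c("neutral", "phylogenetic", "functional")) {
  component <- match.arg(component)
  top <- if (component == "functional") n_samples^2 else n_samples
  if (any(beta < 1 - 1e-9) || any(beta > top + 1e-6)) {
    abort(sprintf("beta %.6f outside legal range [1, %d]", beta, top))
  }
  pmin(1, pmax(0, (beta - 1) / (top - 1)))
}

# Turnover between a subset of rows of an abundance matrix.
turnover_of <- function(mat, component, tree = NULL, dist = NULL, q = 1) {
  part <- beta_partition(mat, component, tree = tree, dist = dist, q = q)
  sorensen_turnover(part$beta, part$n_samples, component)
}

#' Within-individual turnover series
#'
#' For each individual, computes the Sorensen-type turnover between
#' consecutive time points, the overall turnover of the N-sample partition
#' over all of the individual's time points, and the mean of all pairwise
#' turnovers. Individuals with fewer than 2 time points are skipped with a
#' warning.
#'
#' @param abund Relative-abundance tibble (`sample_id` + MAG columns).
#' @param metadata Sample metadata ([read_metadata()]).
#' @param component Diversity component.
#' @param tree,dist Backbones for the phylogenetic/functional components.
#' @param q Diversity order (default 1).
#' @return Tibble with `individual_id`, `species`, `component`, `kind`
#'   (`consecutive`, `overall`, `pairwise_mean`), `pair` (e.g. `"t1-t2"`,
#'   `NA` for summaries) and `turnover`.
#' @export
turnover_series <- function(abund, metadata,
                            component = c("neutral", "phylogenetic", "functional"),
                            tree = NULL, dist = NULL, q = 1) {
  component <- match.arg(component)
  m <- as_id_matrix(abund, "sample_id")
  md <- metadata[match(rownames(m), metadata$sample_id), ]
  purrr::map_dfr(unique(md$individual_id), function(ind) {
    rows <- which(md$individual_id == ind)
    rows <- rows[order(md$time_index[rows])]
    if (length(rows) < 2) {
      warn(sprintf("individual '%s' has < 2 time points; skipped", ind))
      return(NULL)
    }
    times <- md$time_index[rows]
    sp <- md$species[rows[1]]
    cons <- purrr::map_dfr(seq_len(length(rows) - 1), function(k) {
      tibble::tibble(
        kind = "consecutive",
        pair = sprintf("t%d-t%d", times[k], times[k + 1]),
        turnover = turnover_of(m[rows[c(k, k + 1)], , drop = FALSE],
                               component, tree, dist, q)
      )
    })
    pw <- utils::combn(seq_along(rows), 2)
    pw_vals <- apply(pw, 2, function(ij) {
      turnover_of(m[rows[ij], , drop = FALSE], component, tree, dist, q)
    })
    out <- dplyr::bind_rows(
      cons,
      tibble::tibble(kind = "overall", pair = NA_character_,
                     turnover = turnover_of(m[rows, , drop = FALSE],
                                            component, tree, dist, q)),
      tibble::tibble(kind = "pairwise_mean", pair = NA_character_,
                     turnover = mean(pw_vals))
    )
    dplyr::mutate(out, individual_id = ind, species = sp,
                  component = component, .before = 1)
  })
}

#' Pairwise turnover dissimilarity matrix over samples
#'
#' Sorensen-type turnover for every pair of samples, the dissimilarity input
#' used for PERMANOVA and CAP.
#'
#' @inheritParams turnover_series
#' @return Symmetric matrix of pairwise turnover values in \[0,1\].
#' @export
beta_dissimilarity <- function(abund,
                               component = c("neutral", "phylogenetic", "functional"),
                               tree = NULL, dist = NULL, q = 1) {
  component <- match.arg(component)
  m <- as_id_matrix(abund, "sample_id")
  m <- m / rowSums(m)
  N <- nrow(m)
  is_q1 <- abs(q - 1) < 1e-12
  out <- matrix(0, N, N, dimnames = list(rownames(m), rownames(m)))
  if (component == "phylogenetic" && is_q1) {
    # precompute branch abundances once per sample, then work on edge vectors
    A <- t(apply(m, 1, function(p) branch_abundances(tree, setNames(p, colnames(m)))$a))
    L <- branch_abundances(tree, setNames(m[1, ], colnames(m)))$length
    for (i in seq_len(N - 1)) {
      for (j in seq(i + 1, N)) {
        ai <- A[i, ]; aj <- A[j, ]
        abar <- (ai + aj) / 2
        Tbar <- sum(L * abar)
        keep <- abar > 0 & L > 0
        gamma <- exp(-sum((L[keep] / Tbar) * abar[keep] * log(abar[keep])))
        w1 <- ai / 2; w2 <- aj / 2
        h <- function(w) { k <- w > 0 & L > 0; sum((L[k] / Tbar) * w[k] * log(w[k])) }
        alpha <- exp(-(h(w1) + h(w2))) / 2
        out[i, j] <- out[j, i] <- sorensen_turnover(gamma / alpha, 2, component)
      }
    }
  } else {
    for (i in seq_len(N - 1)) {
      for (j in seq(i + 1, N)) {
        out[i, j] <- out[j, i] <- turnover_of(m[c(i, j), , drop = FALSE],
                                              component, tree, dist, q)
      }
    }
  }
  out
}
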
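# Small fixtures and independent oracles shared across test files.

# Random point on the simplex.
rand_simplex <- function(s) {
  x <- stats::rexp(s)
  x / sum(x)
}

# Exhaustive GIFT scorer: enumerates every choice of one alternative per
# step (no per-step max shortcut) and takes the best full assignment.
oracle_gift <- function(steps, genes) {
  alt_scores <- lapply(steps, function(step) {
    vapply(step, function(comb) mean(comb %in% genes), numeric(1))
  })
  grid <- expand.grid(lapply(alt_scores, seq_along))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    sc <- mean(mapply(function(scores, k) scores[k], alt_scores, unlist(grid[r, ])))
    best <- max(best, sc)
  }
  best
}

# Direct double-sum functional Hill oracle (q = 1), explicit loops.
oracle_hill_func_q1 <- function(p, d) {
  keep <- p > 0
  p <- p[keep]; d <- d[keep, keep, drop = FALSE]
  Q <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) Q <- Q + d[i, j] * p[i] * p[j]
  acc <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    acc <- acc + (d[i, j] / Q) * p[i] * p[j] * log(p[i] * p[j])
  }
  exp(-0.5 * acc)
}

# Random pathway step list (for property tests).
rand_steps <- function(n_steps, gene_pool) {
  lapply(seq_len(n_steps), function(s) {
    lapply(seq_len(sample(1:3, 1)), function(a) {
      sample(gene_pool, sample(1:2, 1))
    })
  })
}

# Tiny toy database with hand-computable scores.
toy_db <- function() {
  tibble::tibble(
    pathway_id = c("P1", "P2", "P3"),
    function_id = c("F1", "F1", "F2"),
    steps = list(
      list(list(c("K1", "K2"))),                       # one 2-gene step
      list(list("K3"), list("K4", c("K5", "K6"))),     # 2 steps, 2nd has alts
      list(list("K7"), list("K8"), list("K9"), list("K10"))
    )
  )
}

# A small deterministic metadata + relative-abundance pair.
toy_rel <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    A = c(0.5, 0.0, 0.25),
    B = c(0.5, 0.0, 0.25),
    C = c(0.0, 0.5, 0.25),
    D = c(0.0, 0.5, 0.25)
  )
}
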
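test_that("Gower centering reproduces centered inner products", {
  # 2-point configuration: diagonal entries d^2/4
  d <- matrix(c(0, 3, 3, 0), 2)
  G <- gower_center(d)
  expect_equal(diag(G), rep(9 / 4, 2))
  expect_equal(rowSums(G), rep(0, 2), tolerance = 1e-12)

  expect_equal(gower_center(matrix(0, 3, 3)), matrix(0, 3, 3))

  # Euclidean distances from known coordinates -> centered dot products
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(stats::dist(X))
  Xc <- scale(X, scale = FALSE)
  expect_equal(gower_center(d2), Xc %*% t(Xc), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(gower_center(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA pseudo-F equals classical one-way ANOVA F on 1-D data", {
  set.seed(8)
  for (rep in 1:5) {
    g <- rep(c("a", "b", "c"), times = c(5, 7, 6))
    y <- rnorm(length(g), mean = as.integer(factor(g)) * 0.5)
    d <- as.matrix(stats::dist(y))
    fit <- permanova(d, g, n_perm = 0)
    f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(fit$pseudo_f, f_classic, tolerance = 1e-9)
  }
})

test_that("PERMANOVA decomposes SS exactly and matches vegan::adonis2", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  d <- as.matrix(stats::dist(X))
  fit <- permanova(d, g, n_perm = 99, seed = 5)
  expect_equal(fit$ss[["among"]] + fit$ss[["within"]], fit$ss[["total"]],
               tolerance = 1e-9)
  # SS_total equals the trace of the Gower-centered matrix
  expect_equal(fit$ss[["total"]], sum(diag(gower_center(d))), tolerance = 1e-9)

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(stats::dist(X) ~ g, permutations = 999)
  expect_equal(fit$r_squared, ref$R2[1], tolerance = 1e-9)
  expect_equal(fit$pseudo_f, ref$F[1], tolerance = 1e-9)
})

test_that("complete separation gives R2 near 1 and the minimal p-value", {
  # unequal group sizes so no permutation can recreate the exact grouping
  pts <- c(rep(0, 10), rep(10, 8))
  d <- as.matrix(stats::dist(pts))
  g <- rep(c("a", "b"), times = c(10, 8))
  fit <- permanova(d, g, n_perm = 199, seed = 1)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(fit$p_value, 1 / 200)
})

test_that("strata with one block for all samples equals free permutation", {
  set.seed(33)
  y <- matrix(rnorm(36), 12, 3)
  d <- as.matrix(stats::dist(y))
  g <- rep(c("a", "b", "c"), 4)
  free <- permanova(d, g, n_perm = 199, seed = 77)
  one_block <- permanova(d, g, strata = rep("all", 12), n_perm = 199, seed = 77)
  expect_identical(free$p_value, one_block$p_value)
  expect_identical(free$pseudo_f, one_block$pseudo_f)
})

test_that("PERMANOVA output is invariant to sample relabelling", {
  set.seed(44)
  y <- matrix(rnorm(30), 15, 2)
  d <- as.matrix(stats::dist(y))
  g <- rep(c("a", "b", "c"), each = 5)
  fit <- permanova(d, g, n_perm = 0)
  perm <- sample(15)
  fit2 <- permanova(d[perm, perm], g[perm], n_perm = 0)
  expect_equal(fit$pseudo_f, fit2$pseudo_f, tolerance = 1e-9)
  expect_equal(fit$r_squared, fit2$r_squared, tolerance = 1e-9)
})

test_that("PERMANOVA validates inputs and seeds reproducibly", {
  d <- as.matrix(stats::dist(rnorm(8)))
  expect_error(permanova(d, rep("a", 8)), "2 levels")
  g <- rep(c("a", "b"), 4)
  p1 <- permanova(d, g, n_perm = 99, seed = 5)$p_value
  p2 <- permanova(d, g, n_perm = 99, seed = 5)$p_value
  expect_identical(p1, p2)
  td <- tidy(permanova(d, g, n_perm = 49, seed = 1))
  expect_equal(td$term, c("groups", "residual", "total"))
  expect_equal(sum(td$sum_of_squares[1:2]), td$sum_of_squares[3], tolerance = 1e-9)
})

test_that("CAP separates well-separated clusters and matches LDA on coordinates", {
  set.seed(55)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  g <- rep(c("a", "b"), each = 10)
  d <- as.matrix(stats::dist(X))
  fit <- cap(d, g)
  expect_equal(fit$loo_success, 1.0)
  expect_equal(sum(grepl("^LD", names(fit$scores))), 1)  # axes <= groups - 1
  expect_equal(glance(fit)$n_samples, 20)

  # full-rank PCoA of Euclidean distances recovers the raw-coordinate LDA
  fit_m <- cap(d, g, m = 2)
  ref <- MASS::lda(X, grouping = factor(g))
  ref_scores <- stats::predict(ref, newdata = X)$x
  r <- abs(stats::cor(fit_m$scores$LD1, ref_scores[, 1]))
  expect_equal(r, 1, tolerance = 1e-6)
})

test_that("CAP on shuffled labels allocates near chance level", {
  set.seed(66)
  X <- matrix(rnorm(60), 30, 2)
  g <- sample(rep(c("a", "b"), each = 15))
  d <- as.matrix(stats::dist(X))
  fit <- cap(d, g)
  # binomial 99% envelope around 0.5 for n = 30
  expect_lt(fit$loo_success, 0.5 + 2.58 * sqrt(0.25 / 30) + 0.1)
})
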
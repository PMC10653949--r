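test_that("neutral Hill number matches closed forms and exp(Shannon)", {
  expect_equal(hill_neutral(c(0.5, 0.5)), 2.0)
  expect_equal(hill_neutral(rep(0.1, 10)), 10.0, tolerance = 1e-12)
  p <- c(0.7, 0.2, 0.1)
  expect_equal(hill_neutral(p), exp(-sum(p * log(p))), tolerance = 1e-12)
  expect_error(hill_neutral(c(0, 0)), "all zero")
  # general q recovers richness at q = 0 and Simpson diversity at q = 2
  expect_equal(hill_neutral(p, q = 0), 3)
  expect_equal(hill_neutral(p, q = 2), 1 / sum(p^2))
})

test_that("phylogenetic Hill reduces to neutral on star trees", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(11)
  for (i in 1:20) {
    p <- setNames(rand_simplex(5), star$tip.label)
    expect_equal(hill_phylo(p, star), hill_neutral(p), tolerance = 1e-9)
  }
  # single lineage
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(hill_phylo(c(A = 1, B = 0), two), 1.0)
})

test_that("phylogenetic Hill matches a branch-enumeration oracle", {
  # 4-tip balanced tree, unit branches, uniform p: branches are 4 tips with
  # a = 1/4 and 2 internal with a = 1/2; T = 2; value = 2^(3/2)
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  p <- setNames(rep(0.25, 4), c("A", "B", "C", "D"))
  L <- c(rep(1, 4), 1, 1)
  a <- c(rep(0.25, 4), 0.5, 0.5)
  Tb <- sum(L * a)
  expected <- exp(-sum((L / Tb) * a * log(a)))
  expect_equal(hill_phylo(p, tr), expected, tolerance = 1e-12)
  expect_equal(expected, 2^(3 / 2))
  # un-normalized variant is T times the effective-lineage count
  expect_equal(hill_phylo(p, tr, normalized = FALSE), Tb * expected)
  expect_error(hill_phylo(c(A = 0.5, Z = 0.5), tr), "Z")
})

test_that("Gower distance is range-normalized with constant traits dropped", {
  tr <- tibble::tibble(mag_id = c("a", "b", "c"),
                       t1 = c(0, 1, 0.2), t2 = c(0, 1, 0.4), t3 = c(0.5, 0.5, 0.5))
  d <- gower_distance(tr)
  expect_equal(d["a", "b"], 1)            # opposite extremes of every usable trait
  expect_equal(d["a", "c"], mean(c(0.2, 0.4)))
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(d))
  expect_error(gower_distance(tr[, c("mag_id", "t3")]), "constant")

  skip_if_not_installed("cluster")
  set.seed(5)
  x <- tibble::tibble(mag_id = letters[1:6], u = runif(6), v = runif(6), w = runif(6))
  ref <- as.matrix(cluster::daisy(as.data.frame(x[-1]), metric = "gower"))
  expect_equal(unname(gower_distance(x)), unname(ref), tolerance = 1e-9)
})

test_that("functional Hill matches the brute-force double-sum oracle", {
  expect_equal(hill_func(c(0.5, 0.5), matrix(c(0, .3, .3, 0), 2)), 2.0)
  # equal off-diagonal distances, uniform p over S -> S
  S <- 5
  d <- matrix(0.4, S, S); diag(d) <- 0
  expect_equal(hill_func(rep(1 / S, S), d), S, tolerance = 1e-9)
  set.seed(23)
  for (i in 1:30) {
    s <- sample(3:8, 1)
    p <- rand_simplex(s)
    d <- matrix(runif(s * s), s); d <- (d + t(d)) / 2; diag(d) <- 0
    expect_equal(hill_func(p, d), oracle_hill_func_q1(p, d), tolerance = 1e-9)
  }
  dz <- matrix(0, 3, 3)
  expect_error(hill_func(c(.5, .3, .2), dz), "functionally uniform")
})

test_that("beta partition hits the analytic extremes for every component", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- gower_distance(tibble::tibble(mag_id = c("A", "B", "C", "D"),
                                     t1 = c(0, 1, 0.3, 0.7), t2 = c(1, 0, 0.4, 0.9)))
  ident <- rbind(s1 = c(.4, .3, .2, .1), s2 = c(.4, .3, .2, .1))
  colnames(ident) <- c("A", "B", "C", "D")
  disj <- rbind(s1 = c(.5, .5, 0, 0), s2 = c(0, 0, .5, .5))
  colnames(disj) <- colnames(ident)
  for (comp in c("neutral", "phylogenetic", "functional")) {
    bp <- beta_partition(ident, comp, tree = tr, dist = d)
    expect_equal(bp$beta, 1, tolerance = 1e-9)
    expect_equal(sorensen_turnover(bp$beta, 2, comp), 0, tolerance = 1e-9)
  }
  expect_equal(beta_partition(disj, "neutral")$beta, 2, tolerance = 1e-9)
  expect_equal(sorensen_turnover(2, 2, "neutral"), 1)
})

test_that("beta partition matches an independent pooled-vs-mean oracle", {
  m <- rbind(s1 = c(0.6, 0.3, 0.1), s2 = c(0.2, 0.2, 0.6))
  colnames(m) <- c("A", "B", "C")
  pooled <- colMeans(m)
  gamma <- exp(-sum(pooled * log(pooled)))
  alpha <- exp(mean(apply(m, 1, function(p) -sum(p * log(p)))))
  bp <- beta_partition(m, "neutral")
  expect_equal(bp$gamma, gamma, tolerance = 1e-12)
  expect_equal(bp$alpha, alpha, tolerance = 1e-12)
  expect_equal(bp$beta, gamma / alpha, tolerance = 1e-12)
})

test_that("turnover normalization uses N-1 and N^2-1 scales", {
  expect_equal(sorensen_turnover(1, 2, "neutral"), 0)
  expect_equal(sorensen_turnover(2, 2, "neutral"), 1)
  expect_equal(sorensen_turnover(2.5, 2, "functional"), 0.5)
  expect_error(sorensen_turnover(2.5, 2, "neutral"), "legal range")
})

test_that("replication invariance: pooling identical communities keeps alpha, beta = 1", {
  set.seed(3)
  p <- rand_simplex(6)
  m <- rbind(s1 = p, s2 = p)
  colnames(m) <- paste0("m", 1:6)
  bp <- beta_partition(m, "neutral")
  expect_equal(bp$alpha, hill_neutral(p), tolerance = 1e-12)
  expect_equal(bp$beta, 1, tolerance = 1e-12)
})

test_that("turnover is symmetric, in [0,1], and 0 for identical samples", {
  set.seed(9)
  mags <- paste0("m", 1:5)
  tr <- generate_phylogeny(5, seed = 4, tip_prefix = "m")
  tr$tip.label <- mags
  d <- matrix(runif(25, 0.1, 0.9), 5); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(mags, mags)
  for (comp in c("neutral", "phylogenetic", "functional")) {
    for (i in 1:10) {
      x <- rand_simplex(5); y <- rand_simplex(5)
      mxy <- rbind(s1 = x, s2 = y); colnames(mxy) <- mags
      myx <- rbind(s1 = y, s2 = x); colnames(myx) <- mags
      t1 <- magdyn:::turnover_of(mxy, comp, tree = tr, dist = d)
      t2 <- magdyn:::turnover_of(myx, comp, tree = tr, dist = d)
      expect_equal(t1, t2, tolerance = 1e-9)
      expect_true(t1 >= 0 && t1 <= 1)
      mxx <- rbind(s1 = x, s2 = x); colnames(mxx) <- mags
      expect_equal(magdyn:::turnover_of(mxx, comp, tree = tr, dist = d), 0,
                   tolerance = 1e-9)
    }
  }
})

test_that("consistent MAG permutation leaves every result unchanged", {
  set.seed(31)
  mags <- paste0("m", 1:6)
  tr <- generate_phylogeny(6, seed = 8, tip_prefix = "x")
  tr$tip.label <- mags
  d <- matrix(runif(36, .1, .9), 6); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(mags, mags)
  p <- setNames(rand_simplex(6), mags)
  perm <- sample(mags)
  expect_equal(hill_neutral(p[perm]), hill_neutral(p), tolerance = 1e-12)
  expect_equal(hill_phylo(p[perm], tr), hill_phylo(p, tr), tolerance = 1e-12)
  expect_equal(hill_func(p[perm], d[perm, perm]), hill_func(p, d),
               tolerance = 1e-12)
})

test_that("turnover_series reports consecutive, overall and pairwise-mean values", {
  rel <- toy_rel()
  md <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       individual_id = "i1", cage_id = "c1", species = "spA",
                       treatment = c("T1", "T2", "T3"), time_index = 1:3)
  ts <- turnover_series(rel, md, "neutral")
  expect_equal(ts$kind, c("consecutive", "consecutive", "overall", "pairwise_mean"))
  expect_equal(ts$turnover[1], 1)  # s1 -> s2 is a disjoint swap
  m <- as.matrix(rel[-1]); rownames(m) <- rel$sample_id
  expect_equal(ts$turnover[3],
               magdyn:::turnover_of(m, "neutral"), tolerance = 1e-12)
  pw <- mean(c(1,
               magdyn:::turnover_of(m[c(1, 3), ], "neutral"),
               magdyn:::turnover_of(m[c(2, 3), ], "neutral")))
  expect_equal(ts$turnover[4], pw, tolerance = 1e-12)

  # constant series: all zeros
  relc <- rel; relc[2, -1] <- relc[1, -1]; relc[3, -1] <- relc[1, -1]
  tsc <- turnover_series(relc, md, "neutral")
  expect_equal(tsc$turnover, rep(0, 4), tolerance = 1e-9)

  expect_warning(turnover_series(rel[1, ], md[1, ], "neutral"), "skipped")
})
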
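test_that("simulated phylogenies are reproducible, bifurcating and labelled", {
  tr <- generate_phylogeny(60, seed = 5)
  expect_equal(length(tr$tip.label), 60)
  expect_equal(nrow(tr$edge), 2 * 60 - 2)  # rooted, strictly bifurcating
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr), ape::write.tree(generate_phylogeny(60, seed = 5)))
  tr2 <- generate_phylogeny(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_error(generate_phylogeny(1, seed = 1), "at least 2")
})

test_that("simulated pathway databases are valid, deterministic and cover functions", {
  db <- generate_pathway_db(28, 14, seed = 9)
  expect_silent(validate_pathway_db(db))
  expect_equal(length(unique(db$function_id)), 14)
  expect_true(all(table(db$function_id) >= 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_pathway_db(db, path)
  j1 <- readLines(path)
  expect_equal(read_pathway_db(path), db)
  write_pathway_db(generate_pathway_db(28, 14, seed = 9), path)
  expect_identical(readLines(path), j1)  # byte-identical at fixed seed
})

test_that("gene content shows phylogenetic signal and redundancy limits", {
  db <- generate_pathway_db(20, 10, seed = 2)
  tr <- generate_phylogeny(12, seed = 3)

  # near-infinite signal: gene gain/loss rate ~ 0, all tips share the root state
  gc_inf <- generate_gene_content(tr, db, signal = 1e9, redundancy_level = 0,
                                  seed = 4, thin = FALSE)
  sets <- gc_inf$truth$genes
  expect_true(all(vapply(sets, identical, logical(1), y = sets[[1]])))

  # full redundancy: every MAG carries every block, distances collapse to 0
  gc_red <- generate_gene_content(tr, db, signal = 5, redundancy_level = 1,
                                  seed = 4, thin = FALSE)
  expect_true(all(vapply(gc_red$truth$genes, identical, logical(1),
                         y = gc_red$truth$genes[[1]])))
  gifts <- distill_gifts(gc_red$truth, db, adjust = FALSE)
  expect_true(all(vapply(gifts[-1], function(x) diff(range(x)) == 0, logical(1))))
})

test_that("completeness thinning retains the expected gene fraction", {
  truth <- tibble::tibble(mag_id = "m", genes = list(sprintf("K%04d", 1:1000)))
  obs <- thin_gene_sets(truth, completeness = 0.8, seed = 11)
  expect_equal(length(obs$genes[[1]]) / 1000, 0.8, tolerance = 0.02)
})

test_that("simulated counts honour depths, design and responder ranking", {
  sim <- generate_counts(sprintf("m%02d", 1:10), "spB",
                         c("Acclimation", "Heat", "Cold", "Diet", "Acclimation2"),
                         n_individuals = 4, n_cages = 2,
                         responder = list(mag_id = "m03",
                                          effects = c(Acclimation = 1, Heat = 6,
                                                      Cold = 0.05, Diet = 4,
                                                      Acclimation2 = 1)),
                         seed = 21)
  m <- as.matrix(sim$counts[-1])
  expect_true(all(m >= 0))
  expect_equal(nrow(m), 4 * 5)
  expect_silent(validate_metadata(sim$metadata))

  # responder mean relative abundance ranks highest under Heat across seeds
  ranks_ok <- vapply(1:10, function(s) {
    sm <- generate_counts(sprintf("m%02d", 1:10), "spB",
                          c("Acclimation", "Heat", "Cold", "Diet", "Acclimation2"),
                          n_individuals = 4, n_cages = 2,
                          responder = list(mag_id = "m03",
                                           effects = c(Acclimation = 1, Heat = 6,
                                                       Cold = 0.05, Diet = 4,
                                                       Acclimation2 = 1)),
                          seed = 100 + s)
    mm <- as.matrix(sm$counts[-1])
    rel <- mm / rowSums(mm)
    byt <- tapply(rel[, "m03"], sm$metadata$treatment, mean)
    names(which.max(byt)) == "Heat"
  }, logical(1))
  expect_true(all(ranks_ok))
})

test_that("full study bundles are deterministic and internally consistent", {
  cfg <- synthetic_config(seed = 3)
  b1 <- generate_study(cfg)
  b2 <- generate_study(synthetic_config(seed = 3))
  expect_identical(b1$counts, b2$counts)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_identical(b1$ground_truth$responder_id, b2$ground_truth$responder_id)

  # config echo: 60 + 15 MAGs over two species
  expect_equal(ncol(b1$counts) - 1, 75)
  expect_setequal(names(b1$counts)[-1], b1$tree$tip.label)
  expect_setequal(b1$quality$mag_id, b1$annotations$mag_id)
  expect_silent(validate_metadata(b1$metadata))
  expect_silent(validate_pathway_db(b1$pathway_db))
  expect_true(b1$ground_truth$responder_id %in% names(b1$counts))

  # io round-trip through the on-disk formats
  dir <- withr::local_tempdir()
  write_study(b1, dir)
  back <- read_study(dir)
  expect_equal(back$counts, b1$counts)
  expect_equal(back$metadata, b1$metadata)
  expect_setequal(back$tree$tip.label, b1$tree$tip.label)
  expect_equal(back$pathway_db, b1$pathway_db)
})

test_that("archetype contrast is realized: species A is more diverse", {
  ok <- vapply(1:5, function(s) {
    b <- generate_study(synthetic_config(seed = 400 + s))
    rel <- counts_to_relative(b$counts)
    m <- as.matrix(rel[-1]); rownames(m) <- rel$sample_id
    md <- b$metadata[match(rownames(m), b$metadata$sample_id), ]
    div <- apply(m, 1, function(p) hill_neutral(p / sum(p)))
    mean(div[md$species == "spA"]) > mean(div[md$species == "spB"])
  }, logical(1))
  expect_true(all(ok))
})
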
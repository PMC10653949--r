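#' Configuration for a synthetic two-species longitudinal study
#'
#' The defaults emulate a captivity experiment contrasting two host-species
#' archetypes: a high-diversity, high-redundancy community (species A, 60
#' MAGs) and a low-diversity community carrying one directional responder
#' genome (species B, 15 MAGs). Each species contributes individuals nested
#' in cages, sampled once at the end of each of five sequential treatments
#' (Acclimation, Heat, Cold, Diet and a second baseline). The responder's
#' multiplicative effects rise under Heat, collapse under Cold and recover
#' under Diet, driving community-weighted capacity shifts for the injected
#' functions in species B only.
#'
#' @param seed Integer master seed; every stage derives a child seed from it.
#' @param null If `TRUE`, all treatment effects are switched off (responder
#'   effects 1, no incoherent effects) for calibration studies.
#' @param n_mags,n_individuals,n_cages Per-species design sizes (length 2).
#' @param sigma_base Per-species log-abundance dispersion across MAGs.
#' @param redundancy_level Per-species probability that a pathway's gene
#'   block is shared by every MAG (raises functional redundancy).
#' @param signal Phylogenetic-signal strength for gene content; the gene
#'   gain/loss rate along the tree is `1/signal`.
#' @param sigma_cage,sigma_ind,sigma_noise Log-scale standard deviations of
#'   the cage and individual random intercepts and the residual noise.
#' @param sigma_incoherent SD of the per-individual, per-treatment log
#'   effects in species A (directionless plasticity).
#' @param responder_effects Named multiplicative effects of each treatment
#'   on the species-B responder's latent abundance.
#' @param responder_boost Added to the responder's baseline log abundance so
#'   that it is a prominent community member.
#' @param n_injected_functions Number of functions whose pathway genes are
#'   concentrated in the responder (injected directional functions).
#' @param n_pathways,n_functions Pathway-database size.
#' @param depth_range Sequencing-depth range (uniform integer draw).
#' @param completeness_range Genome completeness range (uniform draw).
#' @return A `magdyn_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             null = FALSE,
                             n_mags = c(60L, 15L),
                             n_individuals = c(8L, 8L),
                             n_cages = c(3L, 3L),
                             sigma_base = c(1.0, 1.5),
                             redundancy_level = c(0.7, 0.15),
                             signal = c(5, 5),
                             sigma_cage = 0.3,
                             sigma_ind = 0.5,
                             sigma_noise = 0.3,
                             sigma_incoherent = 0.2,
                             responder_effects = c(Acclimation = 1, Heat = 6,
                                                   Cold = 0.05, Diet = 4,
                                                   Acclimation2 = 1),
                             responder_boost = 1.0,
                             n_injected_functions = 4L,
                             n_pathways = 28L,
                             n_functions = 14L,
                             depth_range = c(20000L, 100000L),
                             completeness_range = c(0.7, 1.0)) {
  if (null) {
    responder_effects[] <- 1
    sigma_incoherent <- 0
  }
  stopifnot(all(n_mags >= 2), all(n_individuals >= 1), all(n_cages >= 1),
            all(is.finite(responder_effects)), n_pathways >= n_functions)
  structure(list(
    seed = as.integer(seed), null = null,
    species = tibble::tibble(
      species = c("spA", "spB"),
      archetype = c("high_diversity", "low_diversity"),
      n_mags = as.integer(n_mags), n_individuals = as.integer(n_individuals),
      n_cages = as.integer(n_cages), sigma_base = sigma_base,
      redundancy_level = redundancy_level, signal = signal
    ),
    treatments = names(responder_effects),
    sigma_cage = sigma_cage, sigma_ind = sigma_ind, sigma_noise = sigma_noise,
    sigma_incoherent = sigma_incoherent,
    responder_effects = responder_effects,
    responder_boost = responder_boost,
    n_injected_functions = as.integer(n_injected_functions),
    n_pathways = as.integer(n_pathways), n_functions = as.integer(n_functions),
    depth_range = as.integer(depth_range),
    completeness_range = completeness_range
  ), class = "magdyn_config")
}

#' Simulate a random MAG phylogeny
#'
#' Pure-birth (Yule) topology with independent exponential branch lengths;
#' rooted, strictly bifurcating (`2n - 2` edges).
#'
#' @param n_mags Number of tips (>= 2).
#' @param seed Integer seed.
#' @param tip_prefix Prefix for tip labels (`<prefix>_0001`, ...).
#' @return An [ape::phylo] tree.
#' @export
generate_phylogeny <- function(n_mags, seed = 1L, tip_prefix = "mag") {
  if (n_mags < 2) {
    abort("need at least 2 MAGs for a tree")
  }
  withr::with_seed(seed, {
    tree <- ape::rphylo(n_mags, birth = 1, death = 0)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 2)
    tree$tip.label <- sprintf("%s_%04d", tip_prefix, seq_len(n_mags))
    tree
  })
}

#' Simulate a pathway-definition database
#'
#' Pathways of 2-6 steps; each step carries 1-3 alternative combinations of
#' 1-2 KO-like identifiers; pathways are assigned round-robin to functions.
#'
#' @param n_pathways Number of pathways.
#' @param n_functions Number of function categories (default 14).
#' @param seed Integer seed.
#' @return Pathway tibble as from [read_pathway_db()].
#' @export
generate_pathway_db <- function(n_pathways = 28L, n_functions = 14L, seed = 1L) {
  withr::with_seed(seed, {
    tibble::tibble(
      pathway_id = sprintf("P%03d", seq_len(n_pathways)),
      function_id = sprintf("F%02d", (seq_len(n_pathways) - 1L) %% n_functions + 1L),
      steps = purrr::map(seq_len(n_pathways), function(i) {
        n_steps <- sample(2:6, 1)
        purrr::map(seq_len(n_steps), function(s) {
          n_alt <- sample(1:3, 1)
          purrr::map(seq_len(n_alt), function(a) {
            sprintf("K%05d", sample.int(3000L, sample(1:2, 1)))
          })
        })
      })
    )
  })
}

pathway_genes <- function(db, pathway_ids = db$pathway_id) {
  unique(unlist(db$steps[db$pathway_id %in% pathway_ids]))
}

#' Simulate phylogenetically autocorrelated gene content
#'
#' Gene presence evolves along the tree under a symmetric two-state Markov
#' process with rate `1/signal` (high signal, low rate, clade-conserved gene
#' blocks). With probability `redundancy_level` a pathway's whole gene block
#' is core, i.e. shared by every MAG regardless of the tree; at
#' `redundancy_level = 1` all MAGs share all blocks and functional distances
#' collapse to zero. Observed gene sets are the true sets thinned by uniform
#' dropout at rate `1 - completeness`.
#'
#' @param tree MAG phylogeny (tips = MAG ids).
#' @param db Pathway database whose gene universe is evolved.
#' @param signal Phylogenetic-signal strength (> 0).
#' @param redundancy_level Probability a pathway block is core, in \[0,1\].
#' @param seed Integer seed.
#' @param completeness_range Uniform range for genome completeness.
#' @param thin Apply completeness dropout to produce observed sets?
#' @return List with `truth` (tibble `mag_id`, `genes` list-column of true
#'   sets), `annotations` (observed sets; equals `truth` when
#'   `thin = FALSE`) and `quality` (mag_id, genome_length, completeness,
#'   contamination).
#' @export
generate_gene_content <- function(tree, db, signal = 5, redundancy_level = 0.3,
                                  seed = 1L, completeness_range = c(0.7, 1),
                                  thin = TRUE) {
  stopifnot(signal > 0, redundancy_level >= 0, redundancy_level <= 1)
  withr::with_seed(seed, {
    core <- db$pathway_id[stats::runif(nrow(db)) < redundancy_level]
    core_genes <- pathway_genes(db, core)
    universe <- setdiff(pathway_genes(db), core_genes)
    ntip <- length(tree$tip.label)
    tr <- ape::reorder.phylo(tree, "postorder")
    rate <- 1 / signal
    ng <- length(universe)
    states <- matrix(NA_integer_, nrow = ntip + tr$Nnode, ncol = ng)
    root <- ntip + 1L
    states[root, ] <- stats::rbinom(ng, 1, 0.5)
    for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder: parent before child
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      pflip <- 0.5 * (1 - exp(-2 * rate * tr$edge.length[e]))
      flip <- stats::runif(ng) < pflip
      states[child, ] <- ifelse(flip, 1L - states[parent, ], states[parent, ])
    }
    truth <- tibble::tibble(
      mag_id = tr$tip.label,
      genes = purrr::map(seq_len(ntip), function(i) {
        sort(unique(c(universe[states[i, ] == 1L], core_genes)))
      })
    )
    quality <- tibble::tibble(
      mag_id = tr$tip.label,
      genome_length = as.integer(round(stats::rlnorm(ntip, log(3e6), 0.2))),
      completeness = stats::runif(ntip, completeness_range[1], completeness_range[2]),
      contamination = stats::runif(ntip, 0, 0.05)
    )
    annotations <- if (thin) {
      thin_gene_sets(truth, quality$completeness, seed = seed + 1L)
    } else {
      truth
    }
    list(truth = truth, annotations = annotations, quality = quality)
  })
}

#' Thin true gene sets by genome completeness
#'
#' Each gene of a genome is retained independently with probability equal to
#' the genome's completeness, emulating assembly loss.
#'
#' @param truth Tibble with `mag_id` and `genes` list-column of true sets.
#' @param completeness Completeness fraction per genome.
#' @param seed Integer seed.
#' @return Tibble of observed gene sets.
#' @export
thin_gene_sets <- function(truth, completeness, seed = 1L) {
  withr::with_seed(seed, {
    tibble::tibble(
      mag_id = truth$mag_id,
      genes = purrr::map2(truth$genes, completeness, function(g, comp) {
        g[stats::runif(length(g)) < comp]
      })
    )
  })
}

#' Simulate longitudinal counts for one host species
#'
#' Latent log abundances combine a per-MAG baseline, cage and individual
#' random intercepts, optional treatment effects and residual noise;
#' observed counts are multinomial draws at a uniformly drawn sequencing
#' depth, so treatment effects are multiplicative on the latent scale and
#' relative-abundance directionality is depth-invariant.
#'
#' @param mag_ids Character vector of MAG identifiers.
#' @param species Species label written into the metadata.
#' @param treatments Ordered character vector of treatments (time 1..T).
#' @param n_individuals,n_cages Design sizes; individuals are assigned to
#'   cages round-robin.
#' @param sigma_base SD of baseline log abundances across MAGs.
#' @param sigma_cage,sigma_ind,sigma_noise Random-effect and noise SDs.
#' @param base_log Optional fixed per-MAG baseline log abundances (named or
#'   in `mag_ids` order). When `NULL` (default) the baseline profile is
#'   drawn as `N(0, sigma_base)`; passing it fixes the community profile so
#'   that repeated simulations share one population truth.
#' @param responder Optional list with `mag_id` and named `effects`
#'   (multiplicative, one per treatment) for a directional responder genome.
#' @param responder_boost Added to the responder's baseline log abundance.
#' @param incoherent_sd SD of per-individual, per-treatment log effects
#'   applied to every MAG (directionless responses).
#' @param depth_range Integer range for sequencing depth.
#' @param seed Integer seed.
#' @return List with `counts` (tibble), `metadata` (tibble) and
#'   `expected_rel` (tibble of expected relative abundances per treatment
#'   from the noise-free latent model, the generator's ground truth).
#' @export
generate_counts <- function(mag_ids, species, treatments, n_individuals,
                            n_cages, sigma_base = 1, sigma_cage = 0.3,
                            sigma_ind = 0.5, sigma_noise = 0.3,
                            base_log = NULL, responder = NULL, responder_boost = 1,
                            incoherent_sd = 0, depth_range = c(20000L, 100000L),
                            seed = 1L) {
  n_mags <- length(mag_ids)
  n_t <- length(treatments)
  cages <- sprintf("%s_cage%d", species, seq_len(n_cages))
  inds <- sprintf("%s_ind%02d", species, seq_len(n_individuals))
  ind_cage <- setNames(cages[(seq_len(n_individuals) - 1L) %% n_cages + 1L], inds)

  withr::with_seed(seed, {
    base <- if (is.null(base_log)) {
      stats::rnorm(n_mags, 0, sigma_base)
    } else if (!is.null(names(base_log))) {
      unname(base_log[mag_ids])
    } else {
      base_log
    }
    names(base) <- mag_ids
    log_eff <- matrix(0, n_t, n_mags, dimnames = list(treatments, mag_ids))
    if (!is.null(responder)) {
      if (!responder$mag_id %in% mag_ids) {
        abort("responder MAG is not in this species' MAG set")
      }
      base[responder$mag_id] <- max(base) + responder_boost
      log_eff[, responder$mag_id] <- log(responder$effects[treatments])
    }
    cage_eff <- matrix(stats::rnorm(n_cages * n_mags, 0, sigma_cage), n_cages,
                       dimnames = list(cages, NULL))
    ind_eff <- matrix(stats::rnorm(n_individuals * n_mags, 0, sigma_ind),
                      n_individuals, dimnames = list(inds, NULL))

    meta <- tidyr::expand_grid(individual_id = inds, time_index = seq_len(n_t)) |>
      dplyr::mutate(sample_id = sprintf("%s_t%d", .data$individual_id, .data$time_index),
                    cage_id = unname(ind_cage[.data$individual_id]),
                    species = species,
                    treatment = treatments[.data$time_index]) |>
      dplyr::select("sample_id", "individual_id", "cage_id", "species",
                    "treatment", "time_index")

    counts <- matrix(0L, nrow(meta), n_mags,
                     dimnames = list(meta$sample_id, mag_ids))
    for (r in seq_len(nrow(meta))) {
      ind <- meta$individual_id[r]
      tr <- meta$treatment[r]
      eta <- base + cage_eff[ind_cage[[ind]], ] + ind_eff[ind, ] +
        log_eff[tr, ] + stats::rnorm(n_mags, 0, sigma_noise)
      if (incoherent_sd > 0) {
        eta <- eta + stats::rnorm(n_mags, 0, incoherent_sd)
      }
      p <- exp(eta - max(eta))
      p <- p / sum(p)
      depth <- sample(seq(depth_range[1], depth_range[2]), 1)
      counts[r, ] <- stats::rmultinom(1, depth, p)
    }

    expected <- t(apply(log_eff, 1, function(le) {
      w <- exp(base + le)
      w / sum(w)
    }))
    list(
      counts = matrix_to_tbl(counts, "sample_id"),
      metadata = meta,
      expected_rel = matrix_to_tbl(expected, "treatment")
    )
  })
}

#' Generate a complete synthetic two-species study
#'
#' Produces every input the analysis pipeline consumes — count table, sample
#' metadata, MAG quality table, gene annotations, a combined phylogeny, the
#' pathway database — plus a ground-truth record (responder identity and
#' effects, injected function directions, archetype labels) for
#' parameter-recovery tests. Fully deterministic given the config.
#'
#' @param config A `magdyn_config` from [synthetic_config()].
#' @return A named list bundle; see Details.
#' @export
generate_study <- function(config = synthetic_config()) {
  seed <- config$seed
  db <- generate_pathway_db(config$n_pathways, config$n_functions,
                            seed = child_seed(seed, "pathways"))
  fun_ids <- sort(unique(db$function_id))
  injected <- fun_ids[seq_len(min(config$n_injected_functions, length(fun_ids)))]
  injected_genes <- pathway_genes(db, db$pathway_id[db$function_id %in% injected])

  per_species <- purrr::map(seq_len(nrow(config$species)), function(si) {
    row <- config$species[si, ]
    tree <- generate_phylogeny(row$n_mags,
                               seed = child_seed(seed, "phylogeny") + si,
                               tip_prefix = sprintf("%s_mag", row$species))
    gc <- generate_gene_content(tree, db, signal = row$signal,
                                redundancy_level = row$redundancy_level,
                                seed = child_seed(seed, "genes") + si,
                                completeness_range = config$completeness_range,
                                thin = FALSE)
    responder <- NULL
    if (row$archetype == "low_diversity") {
      responder_id <- withr::with_seed(child_seed(seed, "genes") + 90L + si,
                                       sample(tree$tip.label, 1))
      gc$truth$genes <- purrr::map2(gc$truth$genes, gc$truth$mag_id, function(g, id) {
        if (id == responder_id) sort(unique(c(g, injected_genes)))
        else setdiff(g, injected_genes)
      })
      gc$quality$completeness[gc$quality$mag_id == responder_id] <-
        config$completeness_range[2]
      responder <- list(mag_id = responder_id, effects = config$responder_effects)
    }
    annotations <- thin_gene_sets(gc$truth, gc$quality$completeness,
                                  seed = child_seed(seed, "genes") + 300L + si)
    sim <- generate_counts(
      mag_ids = tree$tip.label, species = row$species,
      treatments = config$treatments, n_individuals = row$n_individuals,
      n_cages = row$n_cages, sigma_base = row$sigma_base,
      sigma_cage = config$sigma_cage, sigma_ind = config$sigma_ind,
      sigma_noise = config$sigma_noise, responder = responder,
      responder_boost = config$responder_boost,
      incoherent_sd = if (row$archetype == "high_diversity") config$sigma_incoherent else 0,
      depth_range = config$depth_range,
      seed = child_seed(seed, "counts") + si
    )
    list(row = row, tree = tree, truth = gc$truth, quality = gc$quality,
         annotations = annotations, responder = responder, sim = sim)
  })

  # combined count table over the union of MAGs (zeros off-species)
  all_mags <- unlist(purrr::map(per_species, ~ .x$tree$tip.label))
  all_meta <- purrr::map_dfr(per_species, ~ .x$sim$metadata)
  counts <- matrix(0L, nrow(all_meta), length(all_mags),
                   dimnames = list(all_meta$sample_id, all_mags))
  for (ps in per_species) {
    m <- as_id_matrix(ps$sim$counts, "sample_id")
    counts[rownames(m), colnames(m)] <- m
  }

  backbone <- ape::read.tree(text = "(spA_anchor:0.5,spB_anchor:0.5);")
  tree <- ape::bind.tree(backbone, per_species[[1]]$tree,
                         where = which(backbone$tip.label == "spA_anchor"))
  tree <- ape::bind.tree(tree, per_species[[2]]$tree,
                         where = which(tree$tip.label == "spB_anchor"))

  responder <- purrr::detect(per_species, ~ !is.null(.x$responder))$responder
  ground_truth <- list(
    responder_id = responder$mag_id,
    responder_effects = as.list(responder$effects),
    injected_functions = injected,
    injected_directions = tibble::tibble(
      from = config$treatments[-length(config$treatments)],
      to = config$treatments[-1],
      direction = sign(diff(log(config$responder_effects[config$treatments])))
    ),
    archetypes = config$species[, c("species", "archetype", "n_mags")],
    expected_rel = purrr::map(per_species, ~ .x$sim$expected_rel) |>
      setNames(config$species$species)
  )

  list(
    counts = matrix_to_tbl(counts, "sample_id"),
    metadata = all_meta,
    quality = purrr::map_dfr(per_species, "quality"),
    annotations = purrr::map_dfr(per_species, "annotations"),
    truth_annotations = purrr::map_dfr(per_species, "truth"),
    tree = tree,
    pathway_db = db,
    ground_truth = ground_truth,
    config = config
  )
}

#' Write a synthetic study bundle to disk
#'
#' Writes the exact file formats the readers consume: counts, metadata and
#' quality as TSV, annotations as TSV with comma-separated identifiers, the
#' tree as Newick, the pathway database and ground truth as JSON.
#'
#' @param bundle Study bundle from [generate_study()].
#' @param dir Output directory.
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @return Invisibly, the directory.
#' @export
write_study <- function(bundle, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "metadata.tsv", "quality.tsv",
                            "annotations.tsv", "tree.nwk", "pathways.json",
                            "ground_truth.json"))
  if (!overwrite && any(file.exists(paths))) {
    abort("refusing to overwrite existing study files (use overwrite = TRUE)")
  }
  readr::write_tsv(bundle$counts, paths[1])
  readr::write_tsv(bundle$metadata, paths[2])
  readr::write_tsv(bundle$quality, paths[3])
  write_annotations(bundle$annotations, paths[4])
  ape::write.tree(bundle$tree, paths[5])
  write_pathway_db(bundle$pathway_db, paths[6])
  gt <- bundle$ground_truth
  gt$expected_rel <- NULL  # matrices live in the bundle, not the JSON record
  jsonlite::write_json(gt, paths[7], auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic study bundle from disk
#'
#' @param dir Directory written by [write_study()].
#' @return A bundle list (without config/ground-truth matrices).
#' @export
read_study <- function(dir) {
  list(
    counts = read_count_table(file.path(dir, "counts.tsv")),
    metadata = read_metadata(file.path(dir, "metadata.tsv")),
    quality = read_mag_quality(file.path(dir, "quality.tsv")),
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    tree = read_newick(file.path(dir, "tree.nwk")),
    pathway_db = read_pathway_db(file.path(dir, "pathways.json")),
    ground_truth = jsonlite::fromJSON(file.path(dir, "ground_truth.json"),
                                      simplifyVector = TRUE)
  )
}
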
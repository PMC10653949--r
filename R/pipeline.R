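#' Run the full analysis pipeline on a study bundle
#'
#' Orchestrates every stage on one study, analysing each host species
#' separately: genome-quality filtering, count normalization, GIFT/MCI
#' distillation, Gower trait distances, alpha diversity, within-individual
#' turnover, pairwise turnover dissimilarities, strata-restricted PERMANOVA
#' and CAP per diversity component, functional redundancy and its relation
#' to diversity, and community-weighted mean trajectories with bootstrap
#' intervals and shift detection.
#'
#' @param bundle Study bundle: a list with `counts`, `metadata`, `quality`,
#'   `annotations`, `tree`, `pathway_db` ([generate_study()] or
#'   [read_study()]).
#' @param components Diversity components to analyse.
#' @param min_completeness,max_contamination Genome-quality thresholds.
#' @param prevalence Relative-abundance prevalence threshold for the
#'   trajectory analysis (default 0.1%).
#' @param q Diversity order (default 1).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param n_boot Bootstrap replicates for CWM intervals (default 2000).
#' @param level Interval level (default 0.90).
#' @param seed Master seed; child seeds are derived per stage.
#' @param run_cap Compute CAP ordinations? (They are the slowest stage.)
#' @return A list of tidy tibbles (`alpha`, `turnover`, `permanova`,
#'   `redundancy`, `redundancy_relation`, `trajectories`, `shifts`, `mci`)
#'   plus `cap` and `permanova_fits` (per species x component objects) and
#'   `parameters`.
#' @export
run_study <- function(bundle,
                      components = c("neutral", "phylogenetic", "functional"),
                      min_completeness = 0.70, max_contamination = 0.10,
                      prevalence = 0.001, q = 1, n_perm = 999, n_boot = 2000,
                      level = 0.90, seed = 1L, run_cap = TRUE) {
  components <- match.arg(components, several.ok = TRUE)
  quality <- filter_mags_by_quality(bundle$quality, min_completeness,
                                    max_contamination)
  keep_mags <- intersect(names(bundle$counts)[-1], quality$mag_id)
  counts <- bundle$counts[, c("sample_id", keep_mags)]
  gifts <- distill_gifts(bundle$annotations[bundle$annotations$mag_id %in% keep_mags, ],
                         bundle$pathway_db, quality = quality, adjust = TRUE)
  mci <- distill_mci(gifts, bundle$pathway_db)

  meta <- bundle$metadata
  out <- list(alpha = NULL, turnover = NULL, permanova = NULL,
              redundancy = NULL, redundancy_relation = list(),
              trajectories = NULL, shifts = NULL,
              cap = list(), permanova_fits = list(), mci = mci)

  for (sp in unique(meta$species)) {
    sp_meta <- meta[meta$species == sp, ]
    sp_counts <- counts[counts$sample_id %in% sp_meta$sample_id, ]
    m <- as_id_matrix(sp_counts, "sample_id")
    sp_mags <- colnames(m)[colSums(m) > 0]
    m <- m[, sp_mags, drop = FALSE]
    sp_counts <- matrix_to_tbl(m, "sample_id")
    rel <- counts_to_relative(sp_counts)

    sp_tree <- NULL
    if ("phylogenetic" %in% components) {
      reconcile_tree(bundle$tree, sp_mags)
      sp_tree <- ape::keep.tip(bundle$tree, sp_mags)
    }
    sp_dist <- NULL
    if ("functional" %in% components) {
      sp_dist <- gower_distance(mci[mci$mag_id %in% sp_mags, ])
    }

    alpha <- alpha_diversity(rel, tree = sp_tree, dist = sp_dist, q = q,
                             components = components) |>
      dplyr::mutate(species = sp, .before = 1)
    out$alpha <- dplyr::bind_rows(out$alpha, alpha)

    for (comp in components) {
      ts <- turnover_series(rel, sp_meta, comp, tree = sp_tree, dist = sp_dist,
                            q = q)
      out$turnover <- dplyr::bind_rows(out$turnover, ts)

      dmat <- beta_dissimilarity(rel, comp, tree = sp_tree, dist = sp_dist,
                                 q = q)
      ord <- match(rownames(dmat), sp_meta$sample_id)
      fit <- permanova(dmat, groups = sp_meta$treatment[ord],
                       strata = sp_meta$individual_id[ord], n_perm = n_perm,
                       seed = child_seed(seed, "permanova"))
      key <- paste(sp, comp, sep = ".")
      out$permanova_fits[[key]] <- fit
      out$permanova <- dplyr::bind_rows(
        out$permanova,
        dplyr::mutate(glance(fit), species = sp, component = comp, .before = 1)
      )
      if (run_cap) {
        out$cap[[key]] <- cap(dmat, groups = sp_meta$treatment[ord])
      }
      if (comp == "functional") {
        red <- functional_redundancy(rel, sp_dist) |>
          dplyr::mutate(species = sp, .before = 1)
        out$redundancy <- dplyr::bind_rows(out$redundancy, red)
        if ("neutral" %in% components) {
          out$redundancy_relation[[sp]] <-
            redundancy_diversity_relation(alpha, red,
                                          seed = child_seed(seed, "correlation"))
        }
      }
    }

    prev <- filter_prevalent(rel, prevalence)
    cwm <- community_weighted_mean(prev, mci)
    traj <- treatment_intervals(cwm, sp_meta, n_boot = n_boot, level = level,
                                seed = child_seed(seed, "bootstrap")) |>
      dplyr::mutate(species = sp, .before = 1)
    out$trajectories <- dplyr::bind_rows(out$trajectories, traj)
    out$shifts <- dplyr::bind_rows(
      out$shifts,
      dplyr::mutate(detect_shifts(traj), species = sp, .before = 1)
    )
  }

  out$parameters <- list(components = components,
                         min_completeness = min_completeness,
                         max_contamination = max_contamination,
                         prevalence = prevalence, q = q, n_perm = n_perm,
                         n_boot = n_boot, level = level, seed = seed)
  out
}

#' Write pipeline results to a directory
#'
#' Writes each tidy result table as TSV with a run manifest; see
#' [write_results()].
#'
#' @param results Result list from [run_study()].
#' @param dir Output directory.
#' @param overwrite Overwrite existing files?
#' @return Invisibly, the manifest.
#' @export
write_study_results <- function(results, dir, overwrite = FALSE) {
  tables <- list(
    alpha_diversity = results$alpha,
    turnover = results$turnover,
    permanova = results$permanova,
    redundancy = results$redundancy,
    cwm_trajectories = results$trajectories,
    cwm_shifts = results$shifts,
    mci = results$mci
  )
  write_results(tables[!vapply(tables, is.null, logical(1))], dir,
                seed = results$parameters$seed,
                parameters = results$parameters[names(results$parameters) != "seed"],
                overwrite = overwrite)
}
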
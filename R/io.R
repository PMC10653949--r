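#' Read a sample x MAG read-count table
#'
#' Reads a TSV whose header row names the MAGs and whose first column holds
#' sample identifiers. Cells must be non-negative integers (read counts from
#' mapping non-host reads back to the dereplicated MAG catalogue).
#'
#' @param path Path to a tab-separated count table.
#' @return A tibble with a `sample_id` column followed by one integer column
#'   per MAG. Sequencing depth per sample is the row sum; see
#'   [count_depths()].
#' @seealso [count_depths()], [counts_to_rpm()], [counts_to_relative()]
#' @export
read_count_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (nrow(tbl) == 0 || ncol(tbl) < 2) {
    abort(sprintf("count table '%s' has an empty data section", path))
  }
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) {
    dup <- unique(tbl$sample_id[duplicated(tbl$sample_id)])
    abort(sprintf("duplicated sample id(s): %s", paste(dup, collapse = ", ")))
  }
  for (j in seq(2, ncol(tbl))) {
    col <- tbl[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      if (is.na(bad)) bad <- 1L
      abort(sprintf("non-integer cell at row %d, column '%s'", bad, names(tbl)[j]))
    }
    off <- which(col < 0 | col != floor(col) | is.na(col))
    if (length(off) > 0) {
      abort(sprintf("non-integer or negative count at row %d, column '%s'",
                    off[1], names(tbl)[j]))
    }
    tbl[[j]] <- as.integer(col)
  }
  tbl
}

#' Per-sample sequencing depth
#'
#' @param counts A count table as returned by [read_count_table()].
#' @return A tibble with `sample_id` and `depth` (row sum over all MAGs).
#' @export
count_depths <- function(counts) {
  m <- as_id_matrix(counts, "sample_id")
  tibble::tibble(sample_id = rownames(m), depth = as.integer(rowSums(m)))
}

#' Write a count table (or any sample-wide table) as TSV
#'
#' @param tbl Tibble with a `sample_id` first column.
#' @param path Output path.
#' @export
write_count_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read the MAG quality table
#'
#' Expects columns `mag_id`, `genome_length`, `completeness`, `contamination`
#' (and optionally `taxonomy`). Completeness and contamination are stored as
#' fractions in \[0,1\]; columns reported as percentages (any completeness
#' value above 1) are converted automatically.
#'
#' @param path Path to a TSV file.
#' @return Tibble of MAG quality records.
#' @export
read_mag_quality <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("mag_id", "genome_length", "completeness", "contamination")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("quality table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (max(tbl$completeness, na.rm = TRUE) > 1) {
    tbl$completeness <- tbl$completeness / 100
    tbl$contamination <- tbl$contamination / 100
  }
  validate_mag_quality(tbl)
  tbl
}

validate_mag_quality <- function(tbl) {
  if (any(tbl$completeness < 0 | tbl$completeness > 1)) {
    abort("completeness outside [0,1]")
  }
  if (any(tbl$contamination < 0)) {
    abort("negative contamination")
  }
  if (any(tbl$genome_length <= 0)) {
    abort("non-positive genome length")
  }
  invisible(tbl)
}

#' Filter MAGs on genome quality
#'
#' Retains genomes with completeness at or above `min_completeness` and
#' contamination strictly below `max_contamination` (defaults 70% and 10%),
#' the conventional quality gate that limits completeness-driven biases in
#' downstream functional scoring. Input order is preserved and the filter is
#' idempotent.
#'
#' @param quality MAG quality tibble (see [read_mag_quality()]).
#' @param min_completeness Minimum completeness fraction kept (inclusive).
#' @param max_contamination Contamination fraction excluded from (exclusive).
#' @return The filtered quality tibble.
#' @export
filter_mags_by_quality <- function(quality, min_completeness = 0.70,
                                   max_contamination = 0.10) {
  stopifnot(min_completeness >= 0, min_completeness <= 1,
            max_contamination >= 0, max_contamination <= 1)
  dplyr::filter(quality,
                .data$completeness >= min_completeness,
                .data$contamination < max_contamination)
}

#' Normalize counts to reads per million (RPM)
#'
#' Counts are first divided by genome length (longer genomes recruit more
#' reads per cell) and the length-normalized values are rescaled so that each
#' sample sums to one million. All-zero samples are kept as zero rows with a
#' warning.
#'
#' @param counts Count table (`sample_id` + MAG columns).
#' @param quality MAG quality tibble supplying `genome_length` per MAG.
#' @return Tibble of the same shape with RPM values; non-zero rows sum to 1e6.
#' @export
counts_to_rpm <- function(counts, quality) {
  m <- as_id_matrix(counts, "sample_id")
  lens <- setNames(quality$genome_length, quality$mag_id)
  miss <- setdiff(colnames(m), names(lens))
  if (length(miss) > 0) {
    abort(sprintf("no genome length for MAG(s): %s", paste(miss, collapse = ", ")))
  }
  v <- sweep(m, 2, lens[colnames(m)], "/")
  tot <- rowSums(v)
  zero <- tot == 0
  if (any(zero)) {
    warn(sprintf("all-zero sample(s) left as zero rows: %s",
                 paste(rownames(m)[zero], collapse = ", ")))
    tot[zero] <- 1
  }
  matrix_to_tbl(1e6 * v / tot, "sample_id")
}

#' Normalize counts to relative abundances
#'
#' @inheritParams counts_to_rpm
#' @return Tibble of the same shape; non-zero rows sum to 1.
#' @export
counts_to_relative <- function(counts) {
  m <- as_id_matrix(counts, "sample_id")
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warn(sprintf("all-zero sample(s) left as zero rows: %s",
                 paste(rownames(m)[zero], collapse = ", ")))
    tot[zero] <- 1
  }
  matrix_to_tbl(m / tot, "sample_id")
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `individual_id`, `cage_id`, `species`,
#' `treatment`, `time_index`. Validates the nested repeated-measures design:
#' each (individual, time) pair occurs once, individuals nest within cages
#' and cages nest within species.
#'
#' @param path Path to a TSV file.
#' @return Validated metadata tibble.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(time_index = readr::col_integer(),
                                                 .default = readr::col_character()))
  validate_metadata(tbl)
}

#' Validate a sample metadata table
#'
#' @param tbl Metadata tibble (see [read_metadata()] for required columns).
#' @return The tibble, invisibly validated (errors describe the offence).
#' @export
validate_metadata <- function(tbl) {
  need <- c("sample_id", "individual_id", "cage_id", "species", "treatment",
            "time_index")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")))
  }
  key <- paste(tbl$individual_id, tbl$time_index)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (individual_id, time_index) pair(s): %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  bad_ind <- tbl |>
    dplyr::distinct(.data$individual_id, .data$cage_id) |>
    dplyr::count(.data$individual_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_ind) > 0) {
    abort(sprintf("individual(s) assigned to multiple cages: %s",
                  paste(bad_ind$individual_id, collapse = ", ")))
  }
  bad_cage <- tbl |>
    dplyr::distinct(.data$cage_id, .data$species) |>
    dplyr::count(.data$cage_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_cage) > 0) {
    abort(sprintf("cage(s) assigned to multiple species: %s",
                  paste(bad_cage$cage_id, collapse = ", ")))
  }
  tbl
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that insists on branch lengths and
#' non-negative edges, the prerequisites for abundance-weighted phylogenetic
#' Hill numbers.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) {
    abort(sprintf("could not parse Newick file '%s'", path))
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; phylogenetic diversity requires them")
  }
  if (any(tree$edge.length < 0)) {
    abort("negative branch length(s) in tree")
  }
  if (length(tree$tip.label) < 2) {
    abort("tree must have at least 2 tips")
  }
  tree
}

#' Check that abundance-table MAGs are tips of a tree
#'
#' @param tree `phylo` object.
#' @param mag_ids Character vector of MAG identifiers to reconcile.
#' @return Invisibly `TRUE`; errors listing offenders otherwise.
#' @export
reconcile_tree <- function(tree, mag_ids) {
  miss <- setdiff(mag_ids, tree$tip.label)
  if (length(miss) > 0) {
    abort(sprintf("MAG(s) absent from tree tips: %s", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read per-MAG gene annotations
#'
#' TSV with columns `mag_id` and `genes`, the latter a comma-separated list
#' of gene identifiers (KO-like strings). Duplicate identifiers within a
#' genome are collapsed (set semantics).
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with `mag_id` and a `genes` list-column of character vectors.
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("mag_id", "genes") %in% names(tbl))) {
    abort("annotation table needs columns 'mag_id' and 'genes'")
  }
  tibble::tibble(
    mag_id = tbl$mag_id,
    genes = purrr::map(tbl$genes, function(g) {
      if (is.na(g) || g == "") character(0) else unique(strsplit(g, ",", fixed = TRUE)[[1]])
    })
  )
}

#' Write per-MAG gene annotations
#'
#' @param annotations Tibble with `mag_id` and a `genes` list-column.
#' @param path Output TSV path.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(tibble::tibble(
    mag_id = annotations$mag_id,
    genes = purrr::map_chr(annotations$genes, paste, collapse = ",")
  ), path)
  invisible(path)
}

#' Read a pathway-definition database
#'
#' JSON schema: an array of objects `{pathway_id, function_id, steps}` where
#' `steps` is a list of steps, each step a list of alternative identifier
#' combinations, each combination a non-empty array of gene identifiers that
#' are all required.
#'
#' @param path Path to the JSON pathway database.
#' @return Tibble with `pathway_id`, `function_id` and a `steps` list-column.
#' @export
read_pathway_db <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  db <- tibble::tibble(
    pathway_id = purrr::map_chr(raw, "pathway_id"),
    function_id = purrr::map_chr(raw, "function_id"),
    steps = purrr::map(raw, function(p) {
      purrr::map(p$steps, function(step) purrr::map(step, as.character))
    })
  )
  validate_pathway_db(db)
}

#' Validate a pathway database
#'
#' @param db Pathway tibble as from [read_pathway_db()].
#' @return The validated tibble; definition errors name the pathway.
#' @export
validate_pathway_db <- function(db) {
  if (anyDuplicated(db$pathway_id)) {
    abort("duplicated pathway_id in database")
  }
  for (i in seq_len(nrow(db))) {
    steps <- db$steps[[i]]
    if (length(steps) < 1) {
      abort(sprintf("pathway '%s' has no steps", db$pathway_id[i]))
    }
    for (s in steps) {
      if (length(s) < 1) {
        abort(sprintf("pathway '%s' has a step with no alternatives", db$pathway_id[i]))
      }
      for (comb in s) {
        if (length(comb) < 1 || any(!nzchar(comb))) {
          abort(sprintf("pathway '%s' has an empty identifier combination", db$pathway_id[i]))
        }
      }
    }
  }
  db
}

#' Write a pathway database as JSON
#'
#' @param db Pathway tibble.
#' @param path Output JSON path.
#' @export
write_pathway_db <- function(db, path) {
  out <- purrr::pmap(db, function(pathway_id, function_id, steps) {
    list(pathway_id = pathway_id, function_id = function_id, steps = steps)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a set of result tables with a run manifest
#'
#' Each named tibble is written as `<name>.tsv` in `dir`, together with a
#' `manifest.json` recording the seed, parameters, package and R versions and
#' md5 checksums of the written files.
#'
#' @param tables Named list of tibbles.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed used for the run (stored in the manifest).
#' @param parameters Named list of run parameters.
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(tables, dir, seed = NULL, parameters = list(),
                          overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(tables), ".tsv"))
  if (!overwrite && any(file.exists(paths))) {
    abort(sprintf("refusing to overwrite: %s (use overwrite = TRUE)",
                  paste(paths[file.exists(paths)], collapse = ", ")))
  }
  purrr::walk2(tables, paths, readr::write_tsv)
  manifest <- list(
    seed = seed,
    parameters = parameters,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("magdyn")),
    files = as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
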
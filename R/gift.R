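#' Score one pathway step against a genome's gene set
#'
#' A step is satisfied by any of its alternative identifier combinations.
#' Each alternative scores the fraction of its required identifiers present
#' in the genome, and the step takes the best alternative. For a single
#' two-identifier combination this reduces to the classic rule: 1 when both
#' identifiers are present, 0.5 when one is, 0 when none.
#'
#' @param step List of alternative combinations; each combination is a
#'   character vector of identifiers that are all required.
#' @param genes Character vector (set) of gene identifiers in the genome.
#' @return Step score in \[0,1\].
#' @export
score_step <- function(step, genes) {
  if (length(step) < 1) {
    abort("step has no alternative combinations")
  }
  max(vapply(step, function(comb) {
    if (length(comb) < 1) abort("empty identifier combination")
    mean(comb %in% genes)
  }, numeric(1)))
}

#' Score a genome-inferred functional trait (GIFT) for one pathway
#'
#' The GIFT is the arithmetic mean of the pathway's step scores: 0 when no
#' step has any of its genes, 1 when every step is fully satisfied.
#'
#' @param pathway One-row slice of a pathway database, or a list with a
#'   `steps` element (list of steps, see [score_step()]).
#' @param genes Character vector of gene identifiers present in the genome.
#' @return GIFT score in \[0,1\].
#' @export
score_gift <- function(pathway, genes) {
  steps <- if (is.data.frame(pathway)) pathway$steps[[1]] else pathway$steps
  mean(vapply(steps, score_step, numeric(1), genes = genes))
}

#' Adjust a GIFT score for genome completeness
#'
#' An incomplete genome assembly loses genes roughly uniformly at random, so
#' the observed pathway completeness underestimates the true one by a factor
#' close to the genome completeness. The adjustment divides the raw score by
#' completeness and caps at the scale maximum of 1; at completeness 1 it is
#' the identity and it never lowers a score.
#'
#' @param gift Raw GIFT score(s) in \[0,1\].
#' @param completeness Genome completeness fraction(s) in (0,1\].
#' @return Adjusted score(s) in \[0,1\].
#' @export
adjust_for_completeness <- function(gift, completeness) {
  if (any(completeness <= 0)) {
    abort("completeness must be > 0 for adjustment")
  }
  if (any(completeness > 1)) {
    abort("completeness must be <= 1 (a fraction, not a percentage)")
  }
  pmin(1, gift / completeness)
}

#' Distil one genome into its GIFT row
#'
#' @param genes Character vector of gene identifiers in the genome.
#' @param db Pathway database tibble ([read_pathway_db()]).
#' @param completeness Genome completeness in (0,1\]; used when `adjust`.
#' @param adjust Apply completeness adjustment? Default `TRUE`.
#' @return Named numeric vector of GIFT scores, one per pathway.
#' @export
distill_genome <- function(genes, db, completeness = 1, adjust = TRUE) {
  raw <- vapply(db$steps, function(steps) {
    mean(vapply(steps, score_step, numeric(1), genes = genes))
  }, numeric(1))
  if (adjust) {
    raw <- adjust_for_completeness(raw, completeness)
  }
  setNames(raw, db$pathway_id)
}

#' Distil all genomes into a GIFT matrix
#'
#' @param annotations Tibble with `mag_id` and a `genes` list-column
#'   ([read_annotations()]).
#' @param db Pathway database tibble.
#' @param quality Optional MAG quality tibble supplying `completeness`;
#'   required when `adjust = TRUE`.
#' @param adjust Apply per-genome completeness adjustment? Default `TRUE`.
#' @return Tibble with `mag_id` plus one \[0,1\] column per pathway.
#' @export
distill_gifts <- function(annotations, db, quality = NULL, adjust = TRUE) {
  comp <- rep(1, nrow(annotations))
  if (adjust) {
    if (is.null(quality)) {
      abort("completeness adjustment requested but no quality table given")
    }
    cmap <- setNames(quality$completeness, quality$mag_id)
    miss <- setdiff(annotations$mag_id, names(cmap))
    if (length(miss) > 0) {
      abort(sprintf("no completeness for MAG(s): %s", paste(miss, collapse = ", ")))
    }
    comp <- unname(cmap[annotations$mag_id])
  }
  rows <- purrr::map2(annotations$genes, comp, distill_genome,
                      db = db, adjust = adjust)
  m <- do.call(rbind, rows)
  rownames(m) <- annotations$mag_id
  matrix_to_tbl(m, "mag_id")
}

#' Aggregate GIFTs into function-level metabolic capacity indices (MCI)
#'
#' The MCI of a genome for a metabolic function is the mean of its GIFT
#' scores over the pathways mapped to that function.
#'
#' @param gifts GIFT tibble (`mag_id` + pathway columns, [distill_gifts()]).
#' @param db Pathway database providing the pathway-to-function mapping.
#' @return Tibble with `mag_id` plus one \[0,1\] column per function.
#' @export
distill_mci <- function(gifts, db) {
  m <- as_id_matrix(gifts, "mag_id")
  fmap <- setNames(db$function_id, db$pathway_id)
  miss <- setdiff(colnames(m), names(fmap))
  if (length(miss) > 0) {
    abort(sprintf("pathway(s) not mapped to a function: %s",
                  paste(miss, collapse = ", ")))
  }
  funs <- fmap[colnames(m)]
  out <- vapply(sort(unique(funs)), function(f) {
    rowMeans(m[, funs == f, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, sort(unique(funs))))
  rownames(out) <- rownames(m)
  matrix_to_tbl(out, "mag_id")
}
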
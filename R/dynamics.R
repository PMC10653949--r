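#' Prevalence filter on relative abundances
#'
#' Keeps MAGs whose relative abundance reaches `threshold` (default 0.1%) in
#' at least one sample — rare genomes carry too little information for
#' trajectory modelling — and re-closes each row to sum 1. Idempotent at a
#' fixed threshold.
#'
#' @param abund Relative-abundance tibble (`sample_id` + MAG columns).
#' @param threshold Minimum per-sample relative abundance (default 0.001).
#' @return Filtered, re-closed relative-abundance tibble.
#' @export
filter_prevalent <- function(abund, threshold = 0.001) {
  m <- as_id_matrix(abund, "sample_id")
  keep <- apply(m, 2, max) >= threshold
  if (!any(keep)) {
    abort("prevalence filter removed every MAG")
  }
  m <- m[, keep, drop = FALSE]
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  matrix_to_tbl(m / tot, "sample_id")
}

#' Community-weighted mean functional capacity
#'
#' For each sample and metabolic function, the abundance-weighted mean MCI:
#' `CWM_f = sum_i p_i * MCI(i, f)`, bounded by the extreme MCIs among
#' present MAGs.
#'
#' @param abund Relative-abundance tibble (rows on the simplex).
#' @param mci MCI tibble (`mag_id` + function columns, [distill_mci()]).
#' @return Long tibble with `sample_id`, `function_id`, `cwm`.
#' @export
community_weighted_mean <- function(abund, mci) {
  p <- as_id_matrix(abund, "sample_id")
  t_m <- as_id_matrix(mci, "mag_id")
  miss <- setdiff(colnames(p), rownames(t_m))
  if (length(miss) > 0) {
    abort(sprintf("no MCI row for MAG(s): %s", paste(miss, collapse = ", ")))
  }
  cwm <- p %*% t_m[colnames(p), , drop = FALSE]
  matrix_to_tbl(cwm, "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "function_id",
                        values_to = "cwm")
}

#' Per-treatment CWM means with bootstrap intervals
#'
#' For each (function, treatment) cell: the mean CWM over that treatment's
#' samples, with a percentile bootstrap interval obtained by resampling
#' individuals (not samples) with replacement, honouring the
#' repeated-measures structure. Treatments observed in a single individual
#' get a point estimate with an undefined (`NA`) interval.
#'
#' @param cwm Long CWM tibble ([community_weighted_mean()]).
#' @param metadata Sample metadata.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param level Interval level (default 0.90).
#' @param seed Seed for the resampling generator.
#' @return Tibble with `function_id`, `treatment`, `time_index`, `cwm_mean`,
#'   `lower`, `upper`, `n_samples`, `n_individuals`.
#' @export
treatment_intervals <- function(cwm, metadata, n_boot = 2000, level = 0.90,
                                seed = NULL) {
  tbl <- dplyr::inner_join(cwm, metadata, by = "sample_id")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  cells <- tbl |>
    dplyr::distinct(.data$function_id, .data$treatment, .data$time_index) |>
    dplyr::arrange(.data$function_id, .data$time_index)
  withr::with_seed(seed %||% 1L, {
    purrr::pmap_dfr(cells, function(function_id, treatment, time_index) {
      sub <- tbl[tbl$function_id == function_id & tbl$treatment == treatment, ]
      ind_means <- tapply(sub$cwm, sub$individual_id, mean)
      k <- length(ind_means)
      if (k < 2) {
        return(tibble::tibble(function_id = function_id, treatment = treatment,
                              time_index = time_index,
                              cwm_mean = mean(sub$cwm),
                              lower = NA_real_, upper = NA_real_,
                              n_samples = nrow(sub), n_individuals = k))
      }
      idx <- matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = k)
      boots <- colMeans(matrix(ind_means[idx], nrow = k))
      qs <- stats::quantile(boots, probs, names = FALSE, type = 7)
      tibble::tibble(function_id = function_id, treatment = treatment,
                     time_index = time_index, cwm_mean = mean(sub$cwm),
                     lower = qs[1], upper = qs[2],
                     n_samples = nrow(sub), n_individuals = k)
    })
  })
}

#' Detect functional-capacity shifts between consecutive treatments
#'
#' Flags a shift when the bootstrap intervals of consecutive treatments do
#' not overlap — the interval-overlap rule for strong evidence of temporal
#' change — and reports the direction of the mean difference. Pairs with an
#' undefined interval are skipped with a warning.
#'
#' @param trajectories Tibble from [treatment_intervals()].
#' @return Tibble with `function_id`, `from`, `to`, `shift` (logical),
#'   `direction` (-1, 0, 1).
#' @export
detect_shifts <- function(trajectories) {
  purrr::map_dfr(split(trajectories, trajectories$function_id), function(tr) {
    tr <- dplyr::arrange(tr, .data$time_index)
    purrr::map_dfr(seq_len(nrow(tr) - 1), function(k) {
      a <- tr[k, ]; b <- tr[k + 1, ]
      if (any(is.na(c(a$lower, a$upper, b$lower, b$upper)))) {
        warn(sprintf("undefined interval for '%s' (%s or %s); pair skipped",
                     a$function_id, a$treatment, b$treatment))
        return(NULL)
      }
      tibble::tibble(
        function_id = a$function_id, from = a$treatment, to = b$treatment,
        shift = (b$lower > a$upper) || (b$upper < a$lower),
        direction = sign(b$cwm_mean - a$cwm_mean)
      )
    })
  })
}
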
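# Cohort-level validation framework: sample-level specificity and
# sensitivity, Wilson score intervals, two-proportion tests, the
# conflicting-interpretation scenario sweep and compound-het co-occurrence
# classification.
#
# "Specificity" here is sample-level: the fraction of screened samples with
# no prioritized variant. This differs from variant-level specificity and is
# exactly how the screening study's cohort tables compute it.

#' Summarize a cohort's prioritization output
#'
#' @param prioritized Prioritized-call data frame (\code{\link{run_cohort}}).
#' @param n_samples Number of samples screened.
#' @param sources Restrict to calls fired by any of these sources (default:
#'   all).
#' @return List of class \code{"nbs_cohort_result"}: n_samples,
#'   flagged_samples, unique_variants, per_source (data frame with unique
#'   variant and flagged-sample counts), per_gene sample counts.
#' @export
cohort_result <- function(prioritized, n_samples, sources = NULL) {
  p <- prioritized
  if (!is.null(sources) && nrow(p)) {
    hit <- vapply(strsplit(p$sources, ","), function(s)
      any(s %in% sources), logical(1))
    p <- p[hit, , drop = FALSE]
  }
  src_list <- if (nrow(p)) strsplit(p$sources, ",") else list()
  all_sources <- sort(unique(unlist(src_list)))
  per_source <- do.call(rbind, lapply(all_sources, function(s) {
    hit <- vapply(src_list, function(x) s %in% x, logical(1))
    data.frame(source = s,
               unique_variants = length(unique(p$key[hit])),
               flagged_samples = length(unique(p$sample_id[hit])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_source)) {
    per_source <- data.frame(source = character(), unique_variants = integer(),
                             flagged_samples = integer(),
                             stringsAsFactors = FALSE)
  }
  per_gene <- if (nrow(p)) {
    stats::aggregate(sample_id ~ gene, data = p,
                     FUN = function(x) length(unique(x)))
  } else data.frame(gene = character(), sample_id = integer())
  names(per_gene) <- c("gene", "flagged_samples")
  structure(list(
    n_samples = n_samples,
    flagged_samples = length(unique(p$sample_id)),
    unique_variants = length(unique(p$key)),
    per_source = per_source,
    per_gene = per_gene), class = "nbs_cohort_result")
}

#' Sample-level specificity
#'
#' 100 x (1 - flagged samples / screened samples): the percentage of samples
#' with no prioritized variant.
#'
#' @param result An \code{nbs_cohort_result}, or the number of flagged
#'   samples.
#' @param n_samples Cohort size (when \code{result} is a count).
#' @return Percentage in [0, 100].
#' @examples
#' specificity(1289, 34410)  # 96.25...
#' @export
specificity <- function(result, n_samples = NULL) {
  if (inherits(result, "nbs_cohort_result")) {
    flagged <- result$flagged_samples
    n_samples <- result$n_samples
  } else flagged <- result
  if (is.null(n_samples) || n_samples <= 0) stop("n_samples must be > 0")
  100 * (1 - flagged / n_samples)
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form interval obtained by inverting the score test; well behaved
#' for proportions near 1, which is why it is the interval of choice for
#' screening specificity.
#'
#' @param successes Number of successes.
#' @param n Number of trials (> 0).
#' @param z Normal quantile (1.96 for 95%).
#' @return Numeric vector \code{c(low, high)} on the proportion scale.
#' @examples
#' wilson_ci(33121, 34410)  # c(0.9605, 0.9645) to 4 decimals
#' @export
wilson_ci <- function(successes, n, z = 1.96) {
  if (n <= 0) stop("n must be > 0")
  if (successes < 0 || successes > n) stop("successes must be in [0, n]")
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = (centre - half) / denom, high = (centre + half) / denom)
}

#' Two-sided two-proportion test
#'
#' Pooled two-sample test for equality of proportions (the chi-squared test
#' on the 2x2 table, equivalently the squared pooled z statistic), with or
#' without Yates continuity correction. Thin wrapper over
#' \code{stats::prop.test}.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param continuity Apply the continuity correction.
#' @return Two-sided p-value.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, continuity = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop("both group sizes must be > 0")
  if (x1 == 0 && x2 == 0) return(1)
  if (x1 == n1 && x2 == n2) return(1)
  suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = continuity)$p.value)
}

#' Sensitivity of prioritization on a case cohort
#'
#' Percentage of case samples for which at least one designated diagnostic
#' variant appears among the sample's prioritized calls. A prioritization
#' source can be masked (the validation study ignored the CVA-like source
#' because it was the provenance of the diagnostic variants themselves): a
#' call counts only if it fired through at least one unmasked source.
#'
#' @param truth Data frame with columns \code{sample_id} and \code{key}
#'   (diagnostic variant keys; one row per diagnostic variant).
#' @param prioritized Prioritized-call data frame.
#' @param mask_sources Sources to ignore when crediting a call.
#' @return Percentage in [0, 100].
#' @export
sensitivity <- function(truth, prioritized, mask_sources = NULL) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty case cohort")
  p <- prioritized
  if (!is.null(mask_sources) && nrow(p)) {
    keep <- vapply(strsplit(p$sources, ","), function(s)
      length(setdiff(s, mask_sources)) > 0, logical(1))
    p <- p[keep, , drop = FALSE]
  }
  hit_tab <- paste(p$sample_id, p$key)
  samples <- unique(truth$sample_id)
  hits <- vapply(samples, function(s) {
    keys <- truth$key[truth$sample_id == s]
    any(paste(s, keys) %in% hit_tab)
  }, logical(1))
  100 * mean(hits)
}

#' Sweep the conflicting-interpretation scenarios over a cohort
#'
#' Runs the engine once per scenario and summarizes each run. Because each
#' scenario's eligible variant set contains the previous one's, the flagged
#' sample counts are monotone along the chain
#' none, p_and_no_b, p_and_le1_b, le1_b, all.
#'
#' @param cohort,resources,annotations,config As \code{\link{run_cohort}}.
#' @param scenarios Subset of \code{\link{cip_modes}()}.
#' @return Named list of \code{nbs_cohort_result}, one per scenario.
#' @export
cip_sweep <- function(cohort, resources, annotations = NULL,
                      config = nbs_config(), scenarios = cip_modes()) {
  stopifnot(all(scenarios %in% cip_modes()))
  out <- lapply(scenarios, function(mode) {
    pr <- run_cohort(cohort, resources, annotations, config, cip_mode = mode)
    cohort_result(pr, n_samples = length(cohort))
  })
  names(out) <- scenarios
  out
}

#' Classify compound-het pairs by predicted co-occurrence
#'
#' Looks up each prioritized potential compound-het pair in a local
#' co-occurrence table (haplotype predictions, e.g. derived from a
#' population co-occurrence resource) and returns the fractions predicted on
#' the same haplotype, different haplotypes, or uncertain, over the
#' queryable pairs. Pair order is irrelevant.
#'
#' @param pairs Data frame with \code{variant_a}, \code{variant_b} keys.
#' @param table Co-occurrence data frame
#'   (\code{\link{read_cooccurrence_table}}).
#' @return List: \code{fractions} (same_haplotype, different_haplotypes,
#'   uncertain; NA when nothing is queryable), \code{n_queryable},
#'   \code{n_non_queryable}.
#' @export
cooccurrence_classify <- function(pairs, table) {
  norm_pair <- function(a, b) paste(pmin(a, b), pmax(a, b))
  want <- norm_pair(pairs$variant_a, pairs$variant_b)
  have <- norm_pair(table$variant_a, table$variant_b)
  idx <- match(want, have)
  pred <- table$prediction[idx]
  queryable <- !is.na(pred)
  n_q <- sum(queryable)
  fr <- if (n_q == 0L) {
    c(same_haplotype = NA_real_, different_haplotypes = NA_real_,
      uncertain = NA_real_)
  } else {
    c(same_haplotype = mean(pred[queryable] == "same_haplotype"),
      different_haplotypes = mean(pred[queryable] == "different_haplotypes"),
      uncertain = mean(pred[queryable] == "uncertain"))
  }
  list(fractions = fr, n_queryable = n_q,
       n_non_queryable = sum(!queryable))
}

#' Extract prioritized compound-het pairs from engine output
#'
#' @param prioritized Prioritized-call data frame.
#' @return Data frame sample_id, variant_a, variant_b (unique unordered
#'   pairs per sample).
#' @export
comphet_pairs <- function(prioritized) {
  rows <- prioritized[grepl("comphet", prioritized$zygosity_rationale) &
                        !is.na(prioritized$partner_keys), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    for (pk in strsplit(rows$partner_keys[i], ",")[[1]]) {
      a <- min(rows$key[i], pk); b <- max(rows$key[i], pk)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rows$sample_id[i], variant_a = a, variant_b = b,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample_id = character(), variant_a = character(),
                      variant_b = character(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Evaluation report in the cohort-table layout
#'
#' One row per prioritization source plus an "all" row: unique variant
#' count, flagged samples, specificity (%) and its Wilson interval (%).
#'
#' @param result \code{nbs_cohort_result}.
#' @param z Normal quantile for the Wilson interval.
#' @return Data frame.
#' @export
evaluation_report <- function(result, z = 1.96) {
  n <- result$n_samples
  row_for <- function(source, uv, flagged) {
    ci <- wilson_ci(n - flagged, n, z)
    data.frame(source = source, unique_variants = uv,
               flagged_samples = flagged,
               specificity = specificity(flagged, n),
               ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(result$per_source)), function(i) {
    s <- result$per_source[i, ]
    row_for(s$source, s$unique_variants, s$flagged_samples)
  })
  rows[[length(rows) + 1L]] <-
    row_for("all", result$unique_variants, result$flagged_samples)
  do.call(rbind, rows)
}
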
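# Gene-level analytical-validity gating: coverage metrics over exon models
# and CNV callability against homology-excluded regions. The depth track is
# expected to come from a coverage tool run with the pipeline's read filters
# (MQ > 10, BQ > 30, soft-clipped reads removed); those filters are input
# provenance, not recomputed here.

# Expand a run-length depth track to per-base depths over a set of intervals
# (1-based inclusive). Bases not covered by the track have depth 0.
depth_over <- function(depth_track, contig, intervals) {
  track <- depth_track[depth_track$contig == contig, , drop = FALSE]
  unlist(lapply(seq_len(nrow(intervals)), function(i) {
    pos <- seq.int(intervals$start[i], intervals$end[i])
    d <- numeric(length(pos))
    for (j in seq_len(nrow(track))) {
      hit <- pos >= track$start[j] & pos <= track$end[j]
      d[hit] <- track$depth[j]
    }
    d
  }), use.names = FALSE)
}

#' Coverage metrics per exon and per transcript
#'
#' Computes mean depth, median depth and the fraction of bases with depth at
#' or above the QC threshold (default 15x), per exon and pooled over all
#' exon bases of the transcript.
#'
#' @param depth_track Data frame contig, start, end, depth (1-based
#'   inclusive; \code{\link{read_depth_track}}). Bases absent from the track
#'   count as depth 0.
#' @param exons Exon intervals for one transcript: data frame with contig (or
#'   a single \code{contig} argument value), start, end.
#' @param contig Contig of the exons (used when \code{exons} lacks a contig
#'   column).
#' @param min_depth Depth threshold for the fraction metric.
#' @return List of class \code{"nbs_coverage"}: \code{per_exon} data frame
#'   (exon, mean, median, fraction_ge) and \code{transcript} (mean, median,
#'   fraction_ge, n_bases).
#' @examples
#' track <- data.frame(contig = "1", start = 1, end = 4,
#'                     depth = NA)  # see tests for worked examples
#' @export
coverage_metrics <- function(depth_track, exons, contig = NULL,
                             min_depth = 15) {
  if (is.null(exons) || nrow(exons) == 0L) {
    stop("coverage_metrics requires at least one exon interval")
  }
  if (is.null(contig)) contig <- exons$contig[1]
  per_exon <- do.call(rbind, lapply(seq_len(nrow(exons)), function(i) {
    d <- depth_over(depth_track, contig, exons[i, c("start", "end")])
    data.frame(exon = i, mean = mean(d), median = stats::median(d),
               fraction_ge = mean(d >= min_depth))
  }))
  all_d <- depth_over(depth_track, contig, exons[, c("start", "end")])
  structure(list(
    per_exon = per_exon,
    transcript = list(mean = mean(all_d), median = stats::median(all_d),
                      fraction_ge = mean(all_d >= min_depth),
                      n_bases = length(all_d)),
    min_depth = min_depth), class = "nbs_coverage")
}

#' CNV callability of a gene span
#'
#' Fraction of the gene span that falls inside regions of increased sequence
#' homology excluded by the CNV caller.
#'
#' @param gene_start,gene_end Gene span (1-based inclusive).
#' @param excluded_regions Data frame start, end (already on the gene's
#'   contig; convert BED input with \code{\link{read_bed}}).
#' @return List: \code{fraction_excluded} in [0,1], \code{gene_length}.
#' @export
cnv_callability <- function(gene_start, gene_end, excluded_regions) {
  len <- gene_end - gene_start + 1
  if (len <= 0) stop("zero-length gene span")
  if (is.null(excluded_regions) || nrow(excluded_regions) == 0L) {
    return(list(fraction_excluded = 0, gene_length = len))
  }
  # clip, then merge overlapping excluded intervals before summing
  s <- pmax(excluded_regions$start, gene_start)
  e <- pmin(excluded_regions$end, gene_end)
  ok <- s <= e
  s <- s[ok]; e <- e[ok]
  if (length(s) == 0L) return(list(fraction_excluded = 0, gene_length = len))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e + 1) cur_e <- max(cur_e, e[i])
    else { tot <- tot + cur_e - cur_s + 1; cur_s <- s[i]; cur_e <- e[i] }
  }
  tot <- tot + cur_e - cur_s + 1
  list(fraction_excluded = tot / len, gene_length = len)
}

#' Gene keep/exclude decision
#'
#' A gene is excluded only if poor coverage affects the entire gene (median
#' and mean depth both below 30x and at least 95% of assessed bases below
#' 15x), or, for genes in which most known pathogenic variants are CNVs, if
#' CNV callability is compromised (fraction of the gene inside
#' homology-excluded regions at or above the configured cut-off,
#' default 0.5).
#'
#' @param coverage \code{\link{coverage_metrics}} result (or a list with
#'   \code{transcript$mean}, \code{$median}, \code{$fraction_ge}).
#' @param callability \code{\link{cnv_callability}} result (may be NULL when
#'   \code{cnv_predominant} is FALSE).
#' @param cnv_predominant Are most known pathogenic variants in this gene
#'   CNVs?
#' @param config \code{\link{nbs_config}}.
#' @return List: \code{decision} ("keep"/"exclude"), \code{reason}.
#' @export
gene_exclusion_decision <- function(coverage, callability = NULL,
                                    cnv_predominant = FALSE,
                                    config = nbs_config()) {
  tr <- coverage$transcript
  frac_below <- 1 - tr$fraction_ge
  if (tr$median < config$coverage_exclude_mean_median &&
      tr$mean < config$coverage_exclude_mean_median &&
      frac_below >= config$coverage_exclude_fraction) {
    return(list(decision = "exclude", reason = "coverage"))
  }
  if (isTRUE(cnv_predominant) && !is.null(callability) &&
      callability$fraction_excluded >=
        config$callability_compromised_fraction) {
    return(list(decision = "exclude", reason = "cnv_callability"))
  }
  list(decision = "keep", reason = NA_character_)
}
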
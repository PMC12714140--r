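# Copy-number variant rules: caller merging, reciprocal overlap, reference
# frequency filtering and the prioritization rule for losses/gains in genes
# with a loss-of-function disease mechanism.

#' Reciprocal overlap of two intervals
#'
#' min(overlap/len(a), overlap/len(b)) for 1-based inclusive intervals on the
#' same contig; 0 when disjoint.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds (vectors recycle).
#' @return Numeric fraction(s) in [0,1].
#' @examples
#' reciprocal_overlap(100, 199, 150, 249)  # 0.5
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- pmin(a_end, b_end) - pmax(a_start, b_start) + 1
  ov <- pmax(ov, 0)
  len_a <- a_end - a_start + 1
  len_b <- b_end - b_start + 1
  pmin(ov / len_a, ov / len_b)
}

#' Merge CNV-caller and SV-caller calls into quality-annotated CNVs
#'
#' High-quality CNVs larger than 10 kb keep the CNV caller's own filter
#' status. Smaller calls (2-10 kb) are set to PASS only when a same-type
#' SV-caller call supports them with reciprocal overlap of at least 50%;
#' unsupported small calls retain a non-PASS status
#' (\code{"no_sv_support"} when they were PASS from the caller). Calls at or
#' below the 2 kb floor are dropped.
#'
#' @param cnv_calls,sv_calls CNV call data frames
#'   (\code{\link{read_cnv_calls}} layout). Either may be empty.
#' @param config \code{\link{nbs_config}}.
#' @return The CNV calls with updated \code{filter} column.
#' @export
merge_cnv_calls <- function(cnv_calls, sv_calls = NULL, config = nbs_config()) {
  if (nrow(cnv_calls) == 0L) return(cnv_calls)
  keep <- cnv_calls$length > config$cnv_min_length_bp
  cnv_calls <- cnv_calls[keep, , drop = FALSE]
  if (nrow(cnv_calls) == 0L) return(cnv_calls)
  small <- cnv_calls$length <= config$cnv_small_max_bp
  if (any(small)) {
    supported <- vapply(which(small), function(i) {
      if (is.null(sv_calls) || nrow(sv_calls) == 0L) return(FALSE)
      cand <- sv_calls$contig == cnv_calls$contig[i] &
        sv_calls$type == cnv_calls$type[i]
      if (!is.na(cnv_calls$sample_id[i]) && !all(is.na(sv_calls$sample_id))) {
        cand <- cand & sv_calls$sample_id == cnv_calls$sample_id[i]
      }
      any(reciprocal_overlap(cnv_calls$start[i], cnv_calls$end[i],
                             sv_calls$start[cand], sv_calls$end[cand]) >=
            config$cnv_merge_recip_overlap)
    }, logical(1))
    f <- cnv_calls$filter[small]
    f[supported] <- "PASS"
    f[!supported & f == "PASS"] <- "no_sv_support"
    cnv_calls$filter[small] <- f
  }
  cnv_calls
}

#' Frequency of a CNV in a reference set
#'
#' The maximum frequency among reference CNVs of the same type whose
#' reciprocal overlap with the query reaches \code{ro_threshold}
#' (default 80%); 0 when no reference CNV matches.
#'
#' @param cnv One CNV call (one-row data frame or list with contig, start,
#'   end, type).
#' @param reference_set CNV reference data frame
#'   (\code{\link{read_cnv_reference}} layout).
#' @param ro_threshold Reciprocal-overlap threshold.
#' @return Numeric frequency in [0,1].
#' @export
cnv_reference_frequency <- function(cnv, reference_set, ro_threshold = 0.8) {
  if (is.null(reference_set) || nrow(reference_set) == 0L) return(0)
  cand <- reference_set$contig == cnv$contig & reference_set$type == cnv$type
  if (!any(cand)) return(0)
  ro <- reciprocal_overlap(cnv$start, cnv$end,
                           reference_set$start[cand], reference_set$end[cand])
  hit <- ro >= ro_threshold
  if (!any(hit)) return(0)
  max(reference_set$frequency[cand][hit])
}

# Coding region of a panel gene: union of coding exons of the reference
# transcript; for genes without coding exons the transcript span is used.
coding_region <- function(pair, exons) {
  ex <- exons[exons$gene == pair$gene & exons$transcript == pair$transcript &
                exons$coding, , drop = FALSE]
  if (nrow(ex) == 0L) {
    data.frame(start = pair$tx_start, end = pair$tx_end)
  } else ex[, c("start", "end")]
}

#' CNV prioritization rule
#'
#' A PASS CNV in a gene where loss of function is the disease mechanism is
#' prioritized when (i) the CNV padded by 2 kb overlaps the gene's coding
#' region (the transcript span for noncoding genes); (ii) for gains, both
#' breakpoints fall within the reference transcript; (iii) its frequency in
#' the reference set, matched at 80% reciprocal overlap, is below the
#' type-and-inheritance threshold (losses: monoallelic < 0.001, biallelic
#' < 0.005; gains: monoallelic < 0.002, biallelic < 0.01); and (iv) the
#' implied dosage matches the mode of inheritance. A heterozygous loss
#' satisfies a monoallelic condition on its own; in a biallelic gene it
#' needs homozygosity or a partner allele (resolved by
#' \code{\link{moi_gate}}).
#'
#' @param cnv One CNV call (with \code{zygosity}).
#' @param pair Panel row.
#' @param reference_set CNV reference frequency data frame.
#' @param exons Exon model data frame.
#' @param config \code{\link{nbs_config}}.
#' @return List: \code{fires} (dosage question deferred to the MOI gate) and
#'   \code{reason} for non-firing.
#' @export
prioritize_cnv <- function(cnv, pair, reference_set, exons,
                           config = nbs_config()) {
  fail <- function(reason) list(fires = FALSE, reason = reason)
  if (!isTRUE(pair$lof_mechanism)) return(fail("not_lof_gene"))
  if (isTRUE(pair$inclusion_list_only)) return(fail("inclusion_list_only"))
  if (!identical(cnv$contig, pair$contig)) return(fail("different_contig"))
  cr <- coding_region(pair, exons)
  pad <- config$cnv_flank_bp
  if (!any(cnv$start - pad <= cr$end & cnv$end + pad >= cr$start)) {
    return(fail("no_coding_overlap"))
  }
  if (cnv$type == "gain" &&
      !(cnv$start >= pair$tx_start && cnv$end <= pair$tx_end)) {
    return(fail("gain_breakpoints_outside_transcript"))
  }
  freq <- cnv_reference_frequency(cnv, reference_set, config$cnv_recip_overlap)
  moi_tier <- if (pair$moi == "monoallelic") "monoallelic" else "biallelic"
  ceiling_ <- if (cnv$type == "loss") config$cnv_loss_af_max[[moi_tier]]
              else config$cnv_gain_af_max[[moi_tier]]
  if (freq >= ceiling_) return(fail("reference_frequency"))
  list(fires = TRUE, reason = NA_character_)
}
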
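# Knowledge-base eligibility rules.
#
# A variant key is "CIP" (conflicting interpretations of pathogenicity) when
# its classification records span more than one of the categories
# {P/LP, VUS, B/LB}. Non-conflicting keys are eligible only when their records
# are P/LP. The five CIP scenarios then add conflicting keys progressively,
# forming a containment chain none < p_and_no_b < p_and_le1_b < le1_b < all.
# Under the default scenario this reduces to the plain rule ">= 1 P/LP and
# <= 1 B/LB classification".

#' Aggregate classification records for one variant (or protein) key
#'
#' @param classifications Character vector of canonical classifications
#'   (P/LP/VUS/LB/B) for one key, or a data frame with a
#'   \code{classification} column. Empty input is not eligible.
#' @param cip_mode One of \code{"none"} (no conflicting keys prioritized),
#'   \code{"p_and_no_b"} (conflicting keys with >=1 P/LP and 0 B/LB),
#'   \code{"p_and_le1_b"} (default; >=1 P/LP and <=1 B/LB), \code{"le1_b"}
#'   (<=1 B/LB), \code{"all"} (every conflicting key).
#' @return TRUE iff the key is eligible for prioritization under the scenario.
#' @examples
#' aggregate_classifications(c("P", "P", "B"))        # TRUE
#' aggregate_classifications(c("LP", "B", "B"))       # FALSE
#' aggregate_classifications(character(0))            # FALSE
#' @export
aggregate_classifications <- function(classifications,
                                      cip_mode = "p_and_le1_b") {
  cip_mode <- match.arg(cip_mode, cip_modes())
  if (is.data.frame(classifications)) {
    classifications <- classifications$classification
  }
  cl <- classifications[!is.na(classifications)]
  if (length(cl) == 0L) return(FALSE)
  n_plp <- sum(cl %in% c("P", "LP"))
  n_blb <- sum(cl %in% c("B", "LB"))
  n_vus <- sum(cl == "VUS")
  n_categories <- (n_plp > 0) + (n_blb > 0) + (n_vus > 0)
  is_cip <- n_categories >= 2L
  base <- n_plp >= 1L && !is_cip
  if (base) return(TRUE)
  if (!is_cip) return(FALSE)
  switch(cip_mode,
         none = FALSE,
         p_and_no_b = n_plp >= 1L && n_blb == 0L,
         p_and_le1_b = n_plp >= 1L && n_blb <= 1L,
         le1_b = n_blb <= 1L,
         all = TRUE)
}

# Sources for which a match on the predicted protein change is admitted.
PROTEIN_MATCH_SOURCES <- c("clinvar_like", "cva_like")

#' Look up classification records for a variant
#'
#' Exact coordinate-and-allele matches are always returned. When
#' \code{allow_protein_match} is TRUE, records asserting the same predicted
#' protein change in the same gene are additionally returned for sources that
#' support protein matching (ClinVar-like and CVA-like; not the curated
#' commercial source), and never for MNVs.
#'
#' @param v An \code{nbs_variant}, or a variant key string (exact matching
#'   only in the latter case unless annotations are given).
#' @param annotations Annotation data frame rows for this variant (columns
#'   gene, protein_change); required for protein matching.
#' @param source_table Knowledge-base data frame (one source or several; the
#'   \code{source} column decides protein-match support per record).
#' @param allow_protein_match Enable protein-change matching.
#' @return The matching rows of \code{source_table}, with a
#'   \code{match_type} column (\code{"coordinate"} or \code{"protein"}).
#' @export
match_variant <- function(v, source_table, annotations = NULL,
                          allow_protein_match = TRUE) {
  key <- if (inherits(v, "nbs_variant"))
    variant_key(v$contig, v$pos, v$ref, v$alt) else as.character(v)
  exact <- source_table[source_table$key == key, , drop = FALSE]
  if (nrow(exact)) exact$match_type <- "coordinate"
  vclass <- if (inherits(v, "nbs_variant")) v$variant_class else NA_character_
  prot <- source_table[0, , drop = FALSE]
  if (allow_protein_match && !identical(vclass, "mnv") &&
      !is.null(annotations) && nrow(annotations)) {
    pc <- unique(stats::na.omit(annotations$protein_change))
    genes <- unique(annotations$gene)
    if (length(pc)) {
      hit <- source_table$source %in% PROTEIN_MATCH_SOURCES &
        source_table$gene %in% genes &
        !is.na(source_table$protein_change) &
        source_table$protein_change %in% pc &
        source_table$key != key
      prot <- source_table[hit, , drop = FALSE]
      if (nrow(prot)) prot$match_type <- "protein"
    }
  }
  if (nrow(exact) && nrow(prot)) rbind(exact, prot)
  else if (nrow(prot)) prot
  else if (nrow(exact)) exact
  else { out <- source_table[0, , drop = FALSE]
         out$match_type <- character(0); out }
}

#' Test exclusion-list membership
#'
#' Matching is exact on genomic coordinates and alleles: a different
#' alternate allele at a listed position is not excluded. Exclusion always
#' wins over every prioritization source.
#'
#' @param key Variant key string (or \code{nbs_variant}).
#' @param exclusion_list Data frame with \code{key} and \code{reason}.
#' @return List with \code{excluded} (logical) and \code{reason}
#'   (NA when not excluded).
#' @export
is_excluded <- function(key, exclusion_list) {
  if (inherits(key, "nbs_variant")) {
    key <- variant_key(key$contig, key$pos, key$ref, key$alt)
  }
  i <- match(key, exclusion_list$key)
  if (is.na(i)) list(excluded = FALSE, reason = NA_character_)
  else list(excluded = TRUE, reason = exclusion_list$reason[i])
}

#' Is a variant within the matching window around a panel gene?
#'
#' Previously-reported variants are considered only within a fixed window
#' (default 50 bp) of a panel gene: the variant's reference footprint must
#' intersect the gene span padded by \code{window_bp} on both sides.
#'
#' @param v \code{nbs_variant} (its footprint is pos..pos+nchar(ref)-1).
#' @param pair One panel row (gene span in \code{gene_start}/\code{gene_end}).
#' @param window_bp Padding in bp.
#' @return TRUE/FALSE.
#' @export
within_gene_window <- function(v, pair, window_bp = 50) {
  if (!identical(v$contig, pair$contig)) return(FALSE)
  v_end <- v$pos + nchar(v$ref) - 1L
  v$pos <= pair$gene_end + window_bp && v_end >= pair$gene_start - window_bp
}

#' Internal cohort allele frequency from genotype calls
#'
#' Alternate-allele count over total called alleles: a heterozygote
#' contributes 1 allele, a homozygote 2, a hemizygote 1 (with one called
#' allele). Samples without the variant contribute reference alleles only.
#'
#' @param zygosities Character vector of carrier zygosities for one variant
#'   (\code{"het"}, \code{"hom_alt"}, \code{"hemi"}).
#' @param n_samples Number of genotyped samples in the cohort.
#' @param ploidy Called alleles per non-carrier sample (2 for autosomes).
#' @return Fraction in [0,1]; \code{NA} when no alleles were called
#'   (treated downstream as passing frequency filters: absent = rare).
#' @examples
#' internal_af(c("het", "het", "het", "hom_alt"), 100)  # 5/200
#' @export
internal_af <- function(zygosities, n_samples, ploidy = 2L) {
  n_hemi <- sum(zygosities == "hemi")
  total <- (n_samples - n_hemi) * ploidy + n_hemi
  if (n_samples == 0L || total == 0L) return(NA_real_)
  alt <- sum(c(het = 1, hom_alt = 2, hemi = 1)[zygosities])
  alt / total
}

af_lookup <- function(keys, af_table) {
  if (is.null(af_table) || nrow(af_table) == 0L) {
    return(rep(0, length(keys)))
  }
  af <- af_table$af[match(keys, af_table$key)]
  af[is.na(af)] <- 0
  af
}

# Effective AF of a variant for threshold checks: MNVs use the minimum AF of
# their decomposed SNVs; other classes use their own key.
effective_af <- function(v, af_table) {
  if (v$variant_class == "mnv") {
    keys <- vapply(decompose_mnv(v), function(s)
      variant_key(s$contig, s$pos, s$ref, s$alt), character(1))
    min(af_lookup(keys, af_table))
  } else {
    af_lookup(variant_key(v$contig, v$pos, v$ref, v$alt), af_table)
  }
}

#' Candidate exclusions for knowledge-base records in overlapping genes
#'
#' Coordinate-and-allele matching can prioritize a record attached to gene A
#' when the variant physically lies inside (or near) a different panel gene
#' B. This emits every knowledge-base record whose coordinates fall inside
#' the padded span of a panel gene other than its own, as a candidate
#' exclusion table for curation.
#'
#' @param knowledge Knowledge-base data frame.
#' @param panel Panel data frame.
#' @param window_bp Padding applied to each gene span.
#' @return Data frame in exclusion-list layout (reason
#'   \code{"overlapping_gene"}).
#' @export
overlapping_gene_exclusions <- function(knowledge, panel, window_bp = 50) {
  hits <- lapply(seq_len(nrow(knowledge)), function(i) {
    r <- knowledge[i, ]
    inside <- panel$contig == r$contig &
      panel$gene_start - window_bp <= r$pos &
      panel$gene_end + window_bp >= r$pos &
      panel$gene != r$gene
    if (any(inside)) {
      data.frame(contig = r$contig, pos = r$pos, ref = r$ref, alt = r$alt,
                 reason = "overlapping_gene", key = r$key,
                 stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      reason = character(), key = character(),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}
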
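# The prioritization rule engine.
#
# Candidate generation is per gene-condition pair: a small variant becomes a
# candidate when any per-source rule (previously-reported pathogenic, pLoF)
# fires for it, a CNV when the CNV rule fires. Candidates then pass through
# the mode-of-inheritance gate, which resolves zygosity rationale and
# potential compound heterozygosity using read-based phasing.

REPORTED_SOURCES <- c("clinvar_like", "cva_like", "curated_commercial",
                      "internal_inclusion")

#' Universal pre-filter applied to every variant and CNV
#'
#' Fails calls without PASS filter status, calls on unsupported contigs, and
#' small variants on the exclusion list (exclusion wins over every
#' prioritization source). The mode-of-inheritance check is deferred to
#' \code{\link{moi_gate}}.
#'
#' @param x A one-row call data frame (small variant with \code{key}, or CNV).
#' @param exclusion_list Exclusion data frame (ignored for CNVs).
#' @return List: \code{pass}, \code{reason}.
#' @export
universal_filter <- function(x, exclusion_list = NULL) {
  if (is.na(x$contig) || !(x$contig %in% SUPPORTED_CONTIGS)) {
    return(list(pass = FALSE, reason = "unsupported_contig"))
  }
  if (!identical(as.character(x$filter), "PASS")) {
    return(list(pass = FALSE, reason = "filter_status"))
  }
  if (!is.null(exclusion_list) && !is.null(x$key)) {
    ex <- is_excluded(x$key, exclusion_list)
    if (ex$excluded) {
      return(list(pass = FALSE, reason = paste0("excluded:", ex$reason)))
    }
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Per-source rules for previously-reported pathogenic variants
#'
#' Evaluates, for one variant, which knowledge-base sources fire:
#' \itemize{
#'   \item ClinVar-like: the variant, or a variant with the same predicted
#'     protein change (not for MNVs), is eligible under
#'     \code{\link{aggregate_classifications}} with the configured
#'     conflicting-interpretation scenario (default: >=1 P/LP and <=1 B/LB).
#'   \item CVA-like: >=1 P/LP classification, protein matching admitted.
#'   \item Curated commercial: P/LP by exact coordinate match only.
#'   \item Internal inclusion list: exact match to a PubMed-evidenced P/LP
#'     record.
#' }
#' Every source additionally requires internal allele frequency below 0.05
#' (for MNVs, the minimum AF of the decomposed variants). For
#' inclusion-list-only genes all sources except the internal list are
#' disabled.
#'
#' @param v \code{nbs_variant}.
#' @param annotations Annotation rows for this variant in the pair's gene.
#' @param pair Panel row.
#' @param knowledge Knowledge-base data frame (all sources).
#' @param internal_af_table Internal AF reference.
#' @param config \code{\link{nbs_config}}.
#' @param cip_mode Conflicting-interpretation scenario override.
#' @return Character vector of firing source names (possibly empty).
#' @export
prioritize_reported <- function(v, annotations, pair, knowledge,
                                internal_af_table, config = nbs_config(),
                                cip_mode = config$cip_mode) {
  if (effective_af(v, internal_af_table) >= config$internal_af_max) {
    return(character(0))
  }
  fired <- character(0)
  for (src in REPORTED_SOURCES) {
    if (isTRUE(pair$inclusion_list_only) && src != "internal_inclusion") next
    tab <- knowledge[knowledge$source == src &
                       knowledge$gene == pair$gene, , drop = FALSE]
    if (nrow(tab) == 0L) next
    rec <- match_variant(v, tab, annotations = annotations,
                         allow_protein_match = src %in% PROTEIN_MATCH_SOURCES)
    if (nrow(rec) == 0L) next
    ok <- switch(src,
      clinvar_like = aggregate_classifications(rec$classification, cip_mode),
      cva_like = any(rec$classification %in% c("P", "LP")),
      curated_commercial = any(rec$classification %in% c("P", "LP") &
                                 rec$match_type == "coordinate"),
      internal_inclusion = any(rec$classification %in% c("P", "LP") &
                                 rec$match_type == "coordinate"))
    if (isTRUE(ok)) fired <- c(fired, src)
  }
  fired
}

#' Select the reference transcript annotation for pLoF assessment
#'
#' Preference order: MANE Select, then MANE Clinical, then the predefined
#' canonical transcript; ties broken by longest coding sequence, then
#' lexicographic transcript id (deterministic).
#'
#' @param annotations Annotation rows for one gene (with a \code{flags}
#'   column containing \code{mane_select}/\code{mane_clinical}/
#'   \code{predefined_canonical} tokens).
#' @param pair Panel row (unused beyond the gene; kept for interface parity).
#' @return The selected annotation row, or \code{NULL} when no annotation is
#'   on a flagged transcript (the variant is then ineligible for pLoF).
#' @export
select_transcript <- function(annotations, pair = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(NULL)
  rank_of <- function(flags) {
    toks <- strsplit(ifelse(is.na(flags), "", flags), "[&,;]")
    vapply(toks, function(tk) {
      if ("mane_select" %in% tk) 1L
      else if ("mane_clinical" %in% tk) 2L
      else if ("predefined_canonical" %in% tk) 3L
      else NA_integer_
    }, integer(1))
  }
  r <- rank_of(annotations$flags)
  if (all(is.na(r))) return(NULL)
  cds <- annotations$cds_length
  cds[is.na(cds)] <- -1L
  ord <- order(r, -cds, annotations$transcript, na.last = TRUE)
  annotations[ord[1], , drop = FALSE]
}

#' Predicted loss-of-function rule for small variants
#'
#' Fires when the variant is annotated with a high-impact consequence on the
#' selected transcript (MANE Select / MANE Clinical / predefined canonical),
#' the gene's disease mechanism is loss of function, every population AF
#' tier is below the per-inheritance ceiling, and the internal AF is below
#' the configured ceiling (per-MOI pLoF ceiling by default). MNVs use the
#' minimum AF of their decomposed SNVs throughout.
#'
#' @param v \code{nbs_variant}.
#' @param annotations Annotation rows for the pair's gene.
#' @param pair Panel row.
#' @param internal_af_table,population_af_table AF references.
#' @param config \code{\link{nbs_config}}.
#' @return TRUE iff the rule fires.
#' @export
prioritize_plof_small <- function(v, annotations, pair, internal_af_table,
                                  population_af_table,
                                  config = nbs_config()) {
  if (!isTRUE(pair$lof_mechanism) || isTRUE(pair$inclusion_list_only)) {
    return(FALSE)
  }
  sel <- select_transcript(annotations, pair)
  if (is.null(sel)) return(FALSE)
  terms <- strsplit(ifelse(is.na(sel$consequence), "", sel$consequence),
                    "[&,;]")[[1]]
  high <- identical(sel$impact, "high") ||
    any(terms %in% config$high_impact_consequences)
  if (!high) return(FALSE)
  moi_tier <- if (pair$moi == "monoallelic") "monoallelic" else "biallelic"
  ceiling_ <- config$plof_af_max[[moi_tier]]
  if (!is.null(population_af_table) && nrow(population_af_table)) {
    for (tier in unique(population_af_table$tier)) {
      tab <- population_af_table[population_af_table$tier == tier, ,
                                 drop = FALSE]
      if (effective_af(v, tab) >= ceiling_) return(FALSE)
    }
  }
  internal_ceiling <- if (config$plof_internal_af_mode == "plof_threshold")
    ceiling_ else config$internal_af_max
  effective_af(v, internal_af_table) < internal_ceiling
}

#' SMN1 targeted-caller rule
#'
#' @param intact_smn1_copy_number Inferred copy number of intact SMN1.
#' @return TRUE iff the copy number is 0 (the case is prioritized).
#' @export
smn1_rule <- function(intact_smn1_copy_number) {
  cn <- as.integer(intact_smn1_copy_number)
  if (is.na(cn) || cn < 0L) stop("intact SMN1 copy number must be >= 0")
  cn == 0L
}

#' Mode-of-inheritance gate
#'
#' Decides which individually-eligible candidates in one gene, for one
#' sample, match the condition's inheritance mode:
#' \itemize{
#'   \item monoallelic: every het/hom candidate passes alone;
#'   \item biallelic: homozygous (and hemizygous) candidates pass alone; two
#'     or more heterozygous candidates pass as a potential compound
#'     heterozygote unless read-based phasing places them on the same
#'     haplotype (same phase set and haplotype index within the phasing
#'     window, default 150 bp), in which case the cis pair collapses to one
#'     allele; a lone het does not pass;
#'   \item x_linked: hemizygous calls pass alone; heterozygous calls are
#'     gated as biallelic.
#' }
#' A homozygous candidate counts as two alleles, so a co-occurring het
#' passes as its potential compound-het partner. Heterozygous CNV losses
#' participate as unphased alleles when
#' \code{config$cnv_comphet_with_small} is on.
#'
#' @param candidates Data frame with columns \code{key}, \code{pos},
#'   \code{zygosity}, \code{phase_set}, \code{haplotype_index},
#'   \code{is_cnv}.
#' @param moi \code{"monoallelic"}, \code{"biallelic"} or \code{"x_linked"}.
#' @param config \code{\link{nbs_config}}.
#' @return The passing subset with \code{zygosity_rationale} and
#'   \code{partner_keys} columns.
#' @export
moi_gate <- function(candidates, moi, config = nbs_config()) {
  out <- candidates[0, , drop = FALSE]
  out$zygosity_rationale <- character(0)
  out$partner_keys <- character(0)
  n <- nrow(candidates)
  if (n == 0L) return(out)
  zyg <- candidates$zygosity
  if (moi == "monoallelic") {
    out <- candidates
    out$zygosity_rationale <- ifelse(zyg == "hom_alt", "monoallelic_hom",
                                     ifelse(zyg == "hemi", "hemizygous",
                                            "monoallelic_het"))
    out$partner_keys <- NA_character_
    return(out)
  }
  # biallelic / x_linked
  alone <- zyg %in% c("hom_alt", "hemi")
  hets <- which(zyg == "het" &
                  (!candidates$is_cnv | config$cnv_comphet_with_small))
  # group hets phased in cis (same phase set + haplotype, within window)
  grp <- seq_len(n)
  if (length(hets) > 1L) {
    for (a in hets) for (b in hets) {
      if (a < b && in_cis(candidates[a, ], candidates[b, ],
                          config$phasing_window_bp)) {
        grp[grp == grp[b]] <- grp[a]
      }
    }
  }
  units_of <- function(i) {
    if (zyg[i] %in% c("hom_alt", "hemi")) 2L else 1L
  }
  # distinct allele units: one per cis-group of hets, two per hom/hemi
  het_groups <- unique(grp[hets])
  total_units <- sum(vapply(seq_len(n), function(i)
    if (i %in% hets) 0L else if (alone[i]) 2L else 0L, integer(1))) +
    length(het_groups)
  pass <- logical(n)
  rationale <- rep(NA_character_, n)
  partners <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (alone[i]) {
      pass[i] <- TRUE
      rationale[i] <- if (zyg[i] == "hemi") "hemizygous" else "biallelic_hom"
    } else if (i %in% hets) {
      in_group <- hets[grp[hets] == grp[i]]
      # this het's cis group contributes exactly one allele unit
      other_units <- total_units - 1L
      if (other_units >= 1L) {
        pass[i] <- TRUE
        mates <- setdiff(union(hets, which(alone)), in_group)
        trans_ev <- any(vapply(setdiff(hets, in_group), function(j)
          in_trans(candidates[i, ], candidates[j, ],
                   config$phasing_window_bp), logical(1)))
        rationale[i] <- if (trans_ev) "biallelic_comphet_trans"
                        else "biallelic_comphet_unphased"
        partners[i] <- paste(candidates$key[mates], collapse = ",")
      }
    }
  }
  out <- candidates[pass, , drop = FALSE]
  out$zygosity_rationale <- rationale[pass]
  out$partner_keys <- partners[pass]
  out
}

in_cis <- function(a, b, window_bp) {
  !a$is_cnv && !b$is_cnv &&
    !is.na(a$phase_set) && !is.na(b$phase_set) &&
    a$phase_set == b$phase_set &&
    !is.na(a$haplotype_index) && !is.na(b$haplotype_index) &&
    a$haplotype_index == b$haplotype_index &&
    abs(a$pos - b$pos) <= window_bp
}

in_trans <- function(a, b, window_bp) {
  !a$is_cnv && !b$is_cnv &&
    !is.na(a$phase_set) && !is.na(b$phase_set) &&
    a$phase_set == b$phase_set &&
    !is.na(a$haplotype_index) && !is.na(b$haplotype_index) &&
    a$haplotype_index != b$haplotype_index &&
    abs(a$pos - b$pos) <= window_bp
}

#' Companion-variant genotype flags
#'
#' When a prioritized variant triggers a configured companion check (e.g.
#' the other component of a complex allele that is itself on the exclusion
#' list), the sample's genotype for each companion is reported alongside the
#' prioritized call — including \code{"absent"} — so a clinical scientist can
#' check it manually. Flags never change prioritization.
#'
#' @param key Prioritized variant key.
#' @param companion_table \code{\link{read_companion_table}} data frame.
#' @param sample_calls Genotype calls for the sample.
#' @return Data frame: companion_key, label, genotype.
#' @export
companion_flags <- function(key, companion_table, sample_calls) {
  empty <- data.frame(companion_key = character(), label = character(),
                      genotype = character(), stringsAsFactors = FALSE)
  if (is.null(companion_table) || nrow(companion_table) == 0L) return(empty)
  rows <- companion_table[companion_table$trigger_key == key, , drop = FALSE]
  if (nrow(rows) == 0L) return(empty)
  gt <- vapply(rows$companion_key, function(ck) {
    i <- match(ck, sample_calls$key)
    if (is.na(i)) "absent" else sample_calls$zygosity[i]
  }, character(1))
  data.frame(companion_key = rows$companion_key, label = rows$label,
             genotype = unname(gt), stringsAsFactors = FALSE)
}

empty_prioritized <- function() {
  data.frame(sample_id = character(), payload = character(),
             contig = character(), pos = integer(), ref = character(),
             alt = character(), cnv_type = character(), cnv_start = integer(),
             cnv_end = integer(), gene = character(), condition = character(),
             moi = character(), sources = character(),
             zygosity_rationale = character(), partner_keys = character(),
             companion_flags = character(), key = character(),
             stringsAsFactors = FALSE)
}

#' Run the full prioritization pipeline for one sample
#'
#' Applies the universal filter, per-source and pLoF candidate generation,
#' the CNV rule, the mode-of-inheritance gate, companion flags and the SMN1
#' targeted-caller rule, in that order. Output is deterministic and ordered
#' by (contig, pos).
#'
#' @param calls Genotype-call data frame for one sample
#'   (\code{\link{read_small_variant_vcf}} layout).
#' @param annotations Per-transcript annotation data frame.
#' @param resources List with panel, exons, knowledge, exclusion,
#'   internal_af, population_af, cnv_reference and optionally companion
#'   tables (see \code{\link{load_resources}}).
#' @param cnvs Merged CNV calls for the sample (may be NULL).
#' @param smn_copy_number Inferred intact SMN1 copy number (NULL to skip).
#' @param config \code{\link{nbs_config}}.
#' @param cip_mode Conflicting-interpretation scenario override.
#' @return Data frame of prioritized calls with rule provenance
#'   (\code{sources}), zygosity rationale and companion flags.
#' @export
run_sample <- function(calls, annotations, resources, cnvs = NULL,
                       smn_copy_number = NULL, config = nbs_config(),
                       cip_mode = config$cip_mode) {
  panel <- resources$panel
  out <- list()
  sample_id <- if (nrow(calls)) calls$sample_id[1] else NA_character_
  variants <- unique(calls[, setdiff(names(calls), "sample_id"), drop = FALSE])
  for (pi in seq_len(nrow(panel))) {
    pair <- panel[pi, ]
    cand <- list()
    for (vi in seq_len(nrow(variants))) {
      row <- variants[vi, ]
      uf <- universal_filter(row, resources$exclusion)
      if (!uf$pass) next
      v <- structure(list(contig = row$contig, pos = row$pos, ref = row$ref,
                          alt = row$alt, variant_class = row$variant_class),
                     class = "nbs_variant")
      if (!within_gene_window(v, pair, config$gene_window_bp)) next
      ann <- annotations[annotations$key == row$key &
                           annotations$gene == pair$gene, , drop = FALSE]
      sources <- prioritize_reported(v, ann, pair, resources$knowledge,
                                     resources$internal_af, config, cip_mode)
      if (prioritize_plof_small(v, ann, pair, resources$internal_af,
                                resources$population_af, config)) {
        sources <- c(sources, "plof")
      }
      if (length(sources) == 0L) next
      cand[[length(cand) + 1L]] <- data.frame(
        key = row$key, pos = row$pos, zygosity = row$zygosity,
        phase_set = row$phase_set, haplotype_index = row$haplotype_index,
        is_cnv = FALSE, sources = paste(sources, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (!is.null(cnvs) && nrow(cnvs)) {
      for (ci in seq_len(nrow(cnvs))) {
        cnv <- cnvs[ci, ]
        if (!universal_filter(cnv)$pass) next
        pr <- prioritize_cnv(cnv, pair, resources$cnv_reference,
                             resources$exons, config)
        if (!pr$fires) next
        cand[[length(cand) + 1L]] <- data.frame(
          key = paste0("cnv:", cnv$contig, ":", cnv$start, "-", cnv$end, ":",
                       cnv$type),
          pos = cnv$start, zygosity = cnv$zygosity,
          phase_set = NA_character_, haplotype_index = NA_integer_,
          is_cnv = TRUE, sources = "cnv_plof", stringsAsFactors = FALSE)
      }
    }
    if (length(cand) == 0L) next
    cand <- do.call(rbind, cand)
    gated <- moi_gate(cand, pair$moi, config)
    for (gi in seq_len(nrow(gated))) {
      g <- gated[gi, ]
      if (g$is_cnv) {
        parts <- strsplit(sub("^cnv:", "", g$key), "[:-]")[[1]]
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, payload = "cnv", contig = parts[1],
          pos = as.integer(parts[2]), ref = NA_character_,
          alt = NA_character_, cnv_type = parts[4],
          cnv_start = as.integer(parts[2]), cnv_end = as.integer(parts[3]),
          gene = pair$gene, condition = pair$condition, moi = pair$moi,
          sources = g$sources, zygosity_rationale = g$zygosity_rationale,
          partner_keys = g$partner_keys, companion_flags = NA_character_,
          key = g$key, stringsAsFactors = FALSE)
      } else {
        kp <- strsplit(g$key, ":", fixed = TRUE)[[1]]
        cf <- companion_flags(g$key, resources$companion, calls)
        cf_str <- if (nrow(cf))
          paste(paste0(cf$companion_key, "=", cf$genotype), collapse = ";")
          else NA_character_
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, payload = "small", contig = kp[1],
          pos = as.integer(kp[2]), ref = kp[3], alt = kp[4],
          cnv_type = NA_character_, cnv_start = NA_integer_,
          cnv_end = NA_integer_, gene = pair$gene,
          condition = pair$condition, moi = pair$moi, sources = g$sources,
          zygosity_rationale = g$zygosity_rationale,
          partner_keys = g$partner_keys, companion_flags = cf_str,
          key = g$key, stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(smn_copy_number) && "SMN1" %in% panel$gene &&
      smn1_rule(smn_copy_number)) {
    pair <- panel[panel$gene == "SMN1", ][1, ]
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sample_id, payload = "smn1", contig = pair$contig,
      pos = pair$gene_start, ref = NA_character_, alt = NA_character_,
      cnv_type = NA_character_, cnv_start = NA_integer_,
      cnv_end = NA_integer_, gene = "SMN1", condition = pair$condition,
      moi = pair$moi, sources = "smn1", zygosity_rationale = "biallelic_hom",
      partner_keys = NA_character_, companion_flags = NA_character_,
      key = "smn1:cn0", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_prioritized())
  res <- do.call(rbind, out)
  res <- res[order(ord_contig(res$contig), res$pos, res$sample_id, res$key,
                   res$gene), ]
  rownames(res) <- NULL
  res
}

#' Run the pipeline over a cohort of samples
#'
#' @param cohort List of per-sample lists with elements \code{calls},
#'   \code{annotations} (optional; cohort-level annotations may be given in
#'   \code{annotations}), \code{cnvs}, \code{smn_copy_number}.
#' @param resources Shared resource list (\code{\link{load_resources}}).
#' @param annotations Cohort-level annotation data frame used when a sample
#'   carries none.
#' @param config \code{\link{nbs_config}}.
#' @param cip_mode Scenario override forwarded to \code{\link{run_sample}}.
#' @return Combined prioritized-call data frame, ordered by (contig, pos,
#'   sample).
#' @export
run_cohort <- function(cohort, resources, annotations = NULL,
                       config = nbs_config(), cip_mode = config$cip_mode) {
  res <- lapply(cohort, function(s) {
    ann <- if (!is.null(s$annotations) && nrow(s$annotations)) s$annotations
           else if (!is.null(annotations)) annotations
           else empty_annotations()
    if (is.null(s$cnvs) && !is.null(s$cnv_calls)) {
      s$cnvs <- merge_cnv_calls(s$cnv_calls, s$sv_calls, config)
    }
    run_sample(s$calls, ann, resources, cnvs = s$cnvs,
               smn_copy_number = s$smn_copy_number, config = config,
               cip_mode = cip_mode)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(empty_prioritized())
  out <- out[order(ord_contig(out$contig), out$pos, out$sample_id, out$key), ]
  rownames(out) <- NULL
  out
}

#' Load all engine resources from files
#'
#' @param panel,exons,knowledge,exclusion,internal_af,population_af,
#'   cnv_reference,companion File paths (companion, population_af,
#'   cnv_reference and exclusion optional).
#' @return Named list of data frames for \code{\link{run_sample}}.
#' @export
load_resources <- function(panel, exons, knowledge, exclusion = NULL,
                           internal_af = NULL, population_af = NULL,
                           cnv_reference = NULL, companion = NULL) {
  list(
    panel = read_panel(panel),
    exons = read_exons(exons),
    knowledge = read_knowledge(knowledge),
    exclusion = if (is.null(exclusion))
      data.frame(key = character(), reason = character()) else
        read_exclusion(exclusion),
    internal_af = if (is.null(internal_af)) NULL else
      read_internal_af(internal_af),
    population_af = if (is.null(population_af)) NULL else
      read_population_af(population_af),
    cnv_reference = if (is.null(cnv_reference)) NULL else
      read_cnv_reference(cnv_reference),
    companion = if (is.null(companion)) NULL else
      read_companion_table(companion)
  )
}
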
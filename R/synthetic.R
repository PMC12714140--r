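# Synthetic-cohort generator.
#
# Builds a fully controlled miniature screening world: three fabricated
# ~100 kb contigs, a ten-gene panel covering every inheritance mode and rule
# family, knowledge bases with controlled classification mixtures, frequency
# references consistent with the planted carrier rates, and per-sample VCFs
# plus a truth table stating which planted variants must and must not be
# prioritized under the default configuration. Carrier sets are drawn from
# per-category sub-streams keyed by the seed, so the truth table is stable
# when one category's rate changes; carrier counts are exact
# (round(rate * n)), so expectations hold for every seed.

CONTIG_LEN <- 100000L

derive_seed <- function(seed, tag) {
  (as.integer(seed) %% 100000L * 19997L +
     sum(utf8ToInt(tag)) * 131L) %% 2147483646L + 1L
}

#' Simulation specification
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_samples Cohort size.
#' @param rates Named numeric vector of per-category carrier rates; see
#'   \code{sim_categories()} for the category names and defaults.
#' @param background_variants_per_sample Benign intergenic variants added to
#'   each sample's VCF (never eligible; exercise the filters).
#' @return List of class \code{"nbs_sim_spec"}.
#' @export
sim_spec <- function(seed = 1L, n_samples = 200L, rates = NULL,
                     background_variants_per_sample = 2L) {
  r <- sim_default_rates()
  if (!is.null(rates)) r[names(rates)] <- rates
  stopifnot(all(r >= 0 & r <= 1), n_samples >= 1)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 rates = r,
                 background_variants_per_sample =
                   as.integer(background_variants_per_sample)),
            class = "nbs_sim_spec")
}

sim_default_rates <- function() c(
  reported_het = 0.04, protein_match = 0.02, plof = 0.03, nonpass = 0.02,
  cnv_loss = 0.02, cnv_common = 0.02, cnv_small_supported = 0.015,
  cnv_small_unsupported = 0.015, cnv_gain_inside = 0.015,
  cnv_gain_spanning = 0.015,
  comphet_trans = 0.03, comphet_unphased = 0.03, comphet_cis = 0.03,
  single_het = 0.04,
  cip_eligible = 0.03, cip_vus = 0.02, cip_conflict = 0.03,
  plof_nonlof = 0.03,
  inclusion_hit = 0.03, inclusion_bypass = 0.03,
  artefact = 0.08, complex_trigger = 0.02,
  high_af = 0.16,
  mnv_exact = 0.02, mnv_protein_only = 0.02,
  hemi_reported = 0.02, x_het = 0.02,
  hom_ar = 0.03, cnv_hom_loss = 0.02, cnv_het_loss = 0.02,
  cnv_snv_comphet = 0.02,
  smn_zero = 0.01)

#' Deterministic synthetic reference sequences
#' @param spec \code{\link{sim_spec}}.
#' @return Named character vector of contig sequences ("1", "2", "X").
#' @export
sim_reference <- function(spec) {
  set.seed(derive_seed(spec$seed, "reference"))
  out <- vapply(c("1", "2", "X"), function(ctg) {
    paste(sample(c("A", "C", "G", "T"), CONTIG_LEN, replace = TRUE),
          collapse = "")
  }, character(1))
  out
}

ref_base <- function(reference, contig, pos, len = 1L) {
  substr(reference[[contig]], pos, pos + len - 1L)
}

# transversion partner; applied per base it turns an n-mer into an n-mer MNV
flip_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

#' Synthetic panel and exon models
#'
#' Ten gene-condition pairs covering monoallelic, biallelic and X-linked
#' inheritance, LoF and non-LoF mechanisms, and one inclusion-list-only
#' gene; each gene has three coding exons on its reference transcript.
#' @return List with \code{panel} and \code{exons} data frames.
#' @export
sim_gene_models <- function() {
  panel <- data.frame(
    gene = c("GENE_AD1", "GENE_AR1", "GENE_CF", "GENE_MNV", "GENE_AD2",
             "GENE_AR2", "GENE_INC", "GENE_HF", "SMN1", "GENE_XL1"),
    condition = c("COND_AD1", "COND_AR1", "COND_CF", "COND_MNV", "COND_AD2",
                  "COND_AR2", "COND_INC", "COND_HF", "COND_SMA", "COND_XL"),
    moi = c("monoallelic", "biallelic", "monoallelic", "monoallelic",
            "monoallelic", "biallelic", "monoallelic", "monoallelic",
            "biallelic", "x_linked"),
    lof_mechanism = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                      TRUE, TRUE),
    inclusion_list_only = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                            FALSE, FALSE, FALSE),
    contig = c("1", "1", "1", "1", "2", "2", "2", "2", "2", "X"),
    gene_start = c(10000L, 50000L, 70000L, 90000L, 10000L, 30000L, 70000L,
                   90000L, 95000L, 10000L),
    gene_end = c(30000L, 56000L, 76000L, 93000L, 16000L, 50000L, 74000L,
                 92000L, 97000L, 16000L),
    stringsAsFactors = FALSE)
  panel$transcript <- paste0("TX_", panel$gene)
  panel$tx_start <- panel$gene_start
  panel$tx_end <- panel$gene_end
  exons <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    g <- panel[i, ]
    mid <- as.integer((g$gene_start + g$gene_end) / 2)
    data.frame(gene = g$gene, transcript = g$transcript,
               start = c(g$gene_start, mid - 250L, g$gene_end - 500L),
               end = c(g$gene_start + 500L, mid + 250L, g$gene_end),
               coding = TRUE, contig = g$contig, stringsAsFactors = FALSE)
  }))
  list(panel = panel, exons = exons)
}

# Positions of the planted small variants (all constants; alleles are read
# from the synthetic reference so fixtures stay internally consistent).
sim_sites <- function(reference) {
  site <- function(category, contig, pos, len = 1L) {
    rb <- ref_base(reference, contig, pos, len)
    data.frame(category = category, contig = contig, pos = pos, ref = rb,
               alt = flip_base(rb), stringsAsFactors = FALSE)
  }
  rbind(
    site("reported_het", "1", 19100L),
    site("protein_match", "1", 19200L),
    site("protein_match_record", "1", 19250L),  # knowledge only, not planted
    site("plof", "1", 19300L),
    site("nonpass", "1", 19400L),
    site("diag_missense", "1", 19600L),          # case-cohort, no KB record
    site("comphet_trans_a", "1", 52000L),
    site("comphet_trans_b", "1", 52080L),
    site("comphet_unphased_a", "1", 52300L),
    site("comphet_unphased_b", "1", 53500L),
    site("comphet_cis_a", "1", 54000L),
    site("comphet_cis_b", "1", 54080L),
    site("single_het", "1", 55000L),
    site("artefact", "1", 71000L),
    site("complex_trigger", "1", 73000L),
    site("complex_companion", "1", 74500L),
    site("mnv_exact", "1", 91000L, len = 2L),
    site("mnv_protein_only", "1", 92000L, len = 2L),
    site("mnv_protein_record", "1", 92500L),     # knowledge only
    site("cip_eligible", "2", 12000L),
    site("cip_vus", "2", 12500L),
    site("cip_conflict", "2", 13000L),
    site("plof_nonlof", "2", 14000L),
    site("hom_ar", "2", 40100L),
    site("cnv_snv_comphet_snv", "2", 40200L),
    site("inclusion_hit", "2", 71000L),
    site("inclusion_bypass", "2", 72000L),
    site("high_af", "2", 91000L),
    site("hemi_reported", "X", 11000L),
    site("x_het", "X", 12000L))
}

site_key <- function(sites, category) {
  s <- sites[sites$category == category, ]
  variant_key(s$contig, s$pos, s$ref, s$alt)
}

sim_gene_of <- c(
  reported_het = "GENE_AD1", protein_match = "GENE_AD1",
  protein_match_record = "GENE_AD1", plof = "GENE_AD1",
  nonpass = "GENE_AD1", diag_missense = "GENE_AD1",
  comphet_trans_a = "GENE_AR1", comphet_trans_b = "GENE_AR1",
  comphet_unphased_a = "GENE_AR1", comphet_unphased_b = "GENE_AR1",
  comphet_cis_a = "GENE_AR1", comphet_cis_b = "GENE_AR1",
  single_het = "GENE_AR1",
  artefact = "GENE_CF", complex_trigger = "GENE_CF",
  complex_companion = "GENE_CF",
  mnv_exact = "GENE_MNV", mnv_protein_only = "GENE_MNV",
  mnv_protein_record = "GENE_MNV",
  cip_eligible = "GENE_AD2", cip_vus = "GENE_AD2", cip_conflict = "GENE_AD2",
  plof_nonlof = "GENE_AD2",
  hom_ar = "GENE_AR2", cnv_snv_comphet_snv = "GENE_AR2",
  inclusion_hit = "GENE_INC", inclusion_bypass = "GENE_INC",
  high_af = "GENE_HF",
  hemi_reported = "GENE_XL1", x_het = "GENE_XL1")

# CNV plants (constants). GENE_AD1 spans 10k-30k on contig 1; GENE_AR2 spans
# 30k-50k on contig 2. The common loss matches the reference-set entry at
# reciprocal overlap 1; the rare loss overlaps it at only 0.75, below the
# 0.8 matching threshold.
sim_cnvs <- function() {
  data.frame(
    category = c("cnv_loss", "cnv_common", "cnv_small_supported",
                 "cnv_small_unsupported", "cnv_gain_inside",
                 "cnv_gain_spanning", "cnv_hom_loss", "cnv_het_loss",
                 "cnv_snv_comphet"),
    contig = c("1", "1", "1", "1", "1", "1", "2", "2", "2"),
    start = c(5000L, 10000L, 12000L, 21000L, 12000L, 15000L, 28000L, 28000L,
              28000L),
    end = c(25000L, 30000L, 16999L, 25999L, 26000L, 35000L, 48000L, 48000L,
            48000L),
    type = c("loss", "loss", "loss", "loss", "gain", "gain", "loss", "loss",
             "loss"),
    zygosity = c("het", "het", "het", "het", "het", "het", "hom_alt", "het",
                 "het"),
    sv_support = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE),
    gene = c("GENE_AD1", "GENE_AD1", "GENE_AD1", "GENE_AD1", "GENE_AD1",
             "GENE_AD1", "GENE_AR2", "GENE_AR2", "GENE_AR2"),
    stringsAsFactors = FALSE)
}

#' Generate the knowledge side of the synthetic world
#'
#' Emits the panel, exon models, knowledge base (with controlled P/LP/VUS/
#' B/LB mixtures for the conflicting-interpretation scenarios), exclusion
#' list, companion table, internal and population allele-frequency
#' references, and the CNV reference set. The internal AF reference plays
#' the role of a separate control-like cohort: planted pathogenic variants
#' carry small frequencies, the high-frequency plant carries 0.08
#' (failing the 0.05 ceiling), and novel pLoF plants are absent.
#'
#' @param spec \code{\link{sim_spec}}.
#' @param dir Optional directory; when given, every table is written as TSV.
#' @return Named list of data frames (resources layout of
#'   \code{\link{run_sample}} plus \code{files} when written).
#' @export
generate_knowledge <- function(spec, dir = NULL) {
  reference <- sim_reference(spec)
  models <- sim_gene_models()
  sites <- sim_sites(reference)
  s <- function(cat) sites[sites$category == cat, ]
  rec <- function(cat, source, classification, protein = NA_character_,
                  evidence = NA_character_, gene = NULL) {
    x <- s(cat)
    data.frame(source = source, contig = x$contig, pos = x$pos, ref = x$ref,
               alt = x$alt, gene = if (is.null(gene)) sim_gene_of[[cat]]
                                   else gene,
               protein_change = protein, classification = classification,
               evidence_ids = evidence, stringsAsFactors = FALSE)
  }
  knowledge <- rbind(
    rec("reported_het", "clinvar_like", "P"),
    # protein-matched record: a *different* allele with the same predicted
    # protein change as the planted protein_match variant
    rec("protein_match_record", "clinvar_like", "P", protein = "Arg200Cys"),
    rec("comphet_trans_a", "clinvar_like", "P"),
    rec("comphet_trans_b", "clinvar_like", "LP"),
    rec("comphet_unphased_a", "clinvar_like", "P"),
    rec("comphet_unphased_b", "clinvar_like", "P"),
    rec("comphet_cis_a", "clinvar_like", "P"),
    rec("comphet_cis_b", "clinvar_like", "P"),
    rec("single_het", "clinvar_like", "P"),
    rec("artefact", "clinvar_like", "P"),
    rec("complex_trigger", "clinvar_like", "P"),
    rec("complex_companion", "clinvar_like", "P"),
    rec("mnv_exact", "clinvar_like", "P"),
    rec("mnv_protein_record", "clinvar_like", "P", protein = "Gly10Arg"),
    rec("cip_eligible", "clinvar_like", "P"),
    rec("cip_eligible", "clinvar_like", "P"),
    rec("cip_eligible", "clinvar_like", "B"),
    rec("cip_vus", "clinvar_like", "P"),
    rec("cip_vus", "clinvar_like", "VUS"),
    rec("cip_conflict", "clinvar_like", "P"),
    rec("cip_conflict", "clinvar_like", "B"),
    rec("cip_conflict", "clinvar_like", "B"),
    rec("inclusion_bypass", "clinvar_like", "P"),
    rec("high_af", "clinvar_like", "P"),
    rec("x_het", "clinvar_like", "P"),
    rec("cnv_snv_comphet_snv", "clinvar_like", "P"),
    rec("hemi_reported", "cva_like", "P"),
    rec("hom_ar", "curated_commercial", "P"),
    rec("inclusion_hit", "internal_inclusion", "P",
        evidence = "PMID:10000001"))
  exclusion <- rbind(
    data.frame(s("artefact")[, c("contig", "pos", "ref", "alt")],
               reason = "artefact"),
    data.frame(s("complex_companion")[, c("contig", "pos", "ref", "alt")],
               reason = "complex_allele_component"))
  companion <- {
    tg <- s("complex_trigger"); cp <- s("complex_companion")
    data.frame(trigger_contig = tg$contig, trigger_pos = tg$pos,
               trigger_ref = tg$ref, trigger_alt = tg$alt,
               companion_contig = cp$contig, companion_pos = cp$pos,
               companion_ref = cp$ref, companion_alt = cp$alt,
               label = "complex_allele", stringsAsFactors = FALSE)
  }
  af_row <- function(cat, af, first_base_only = FALSE) {
    x <- s(cat)
    if (first_base_only) {
      data.frame(contig = x$contig, pos = x$pos,
                 ref = substr(x$ref, 1, 1), alt = substr(x$alt, 1, 1),
                 af = af, stringsAsFactors = FALSE)
    } else {
      data.frame(contig = x$contig, pos = x$pos, ref = x$ref, alt = x$alt,
                 af = af, stringsAsFactors = FALSE)
    }
  }
  internal_af <- rbind(
    af_row("reported_het", 0.002), af_row("comphet_trans_a", 0.002),
    af_row("comphet_trans_b", 0.002), af_row("comphet_unphased_a", 0.002),
    af_row("comphet_unphased_b", 0.002), af_row("comphet_cis_a", 0.002),
    af_row("comphet_cis_b", 0.002), af_row("single_het", 0.002),
    af_row("hom_ar", 0.003), af_row("cnv_snv_comphet_snv", 0.002),
    af_row("inclusion_hit", 0.002), af_row("inclusion_bypass", 0.002),
    af_row("complex_trigger", 0.002), af_row("complex_companion", 0.01),
    af_row("hemi_reported", 0.002), af_row("x_het", 0.002),
    af_row("cip_eligible", 0.002), af_row("cip_vus", 0.002),
    af_row("cip_conflict", 0.002),
    # the high-AF plant: carrier rate 0.16 -> allele frequency 0.08 >= 0.05
    af_row("high_af", 0.08),
    af_row("artefact", 0.2),
    # one decomposed base of the exact-match MNV is common; the other is
    # absent, so the minimum decomposed AF (0) passes the ceiling
    af_row("mnv_exact", 0.2, first_base_only = TRUE))
  population_af <- data.frame(
    contig = "1", pos = 19600L,
    ref = ref_base(reference, "1", 19600L),
    alt = flip_base(ref_base(reference, "1", 19600L)),
    tier = "popmax", af = 0.01, stringsAsFactors = FALSE)
  cnv_reference <- data.frame(contig = "1", start = 10000L, end = 30000L,
                              type = "loss", frequency = 0.004,
                              stringsAsFactors = FALSE)
  out <- list(panel = models$panel, exons = models$exons,
              knowledge = knowledge, exclusion = exclusion,
              companion = companion, internal_af = internal_af,
              population_af = population_af, cnv_reference = cnv_reference)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (nm in names(out)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(out[[nm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files[[nm]] <- f
    }
    out$files <- files
  }
  # return tables in the parsed layout the engine expects
  out$knowledge$key <- variant_key(out$knowledge$contig, out$knowledge$pos,
                                   out$knowledge$ref, out$knowledge$alt)
  out$knowledge$protein_change <-
    normalize_protein_change(out$knowledge$protein_change)
  out$exclusion$key <- variant_key(out$exclusion$contig, out$exclusion$pos,
                                   out$exclusion$ref, out$exclusion$alt)
  out$internal_af$key <- variant_key(out$internal_af$contig,
                                     out$internal_af$pos,
                                     out$internal_af$ref,
                                     out$internal_af$alt)
  out$population_af$key <- variant_key(out$population_af$contig,
                                       out$population_af$pos,
                                       out$population_af$ref,
                                       out$population_af$alt)
  out$companion$trigger_key <- variant_key(
    out$companion$trigger_contig, out$companion$trigger_pos,
    out$companion$trigger_ref, out$companion$trigger_alt)
  out$companion$companion_key <- variant_key(
    out$companion$companion_contig, out$companion$companion_pos,
    out$companion$companion_ref, out$companion$companion_alt)
  out
}

mk_call <- function(sample_id, contig, pos, ref, alt, filter = "PASS",
                    zygosity = "het", phase_set = NA_character_,
                    haplotype_index = NA_integer_) {
  data.frame(sample_id = sample_id, contig = contig, pos = as.integer(pos),
             ref = ref, alt = alt, variant_class = variant_class(ref, alt),
             filter = filter, zygosity = zygosity, phase_set = phase_set,
             haplotype_index = as.integer(haplotype_index),
             key = variant_key(contig, pos, ref, alt),
             stringsAsFactors = FALSE)
}

mk_ann <- function(key, gene, consequence, impact,
                   protein_change = NA_character_, flags = "mane_select",
                   cds_length = 1500L) {
  data.frame(key = key, gene = gene, transcript = paste0("TX_", gene),
             consequence = consequence, impact = impact,
             protein_change = protein_change, flags = flags,
             cds_length = as.integer(cds_length), stringsAsFactors = FALSE)
}

# Annotations for every plantable site (cohort-level sidecar).
sim_annotations <- function(sites) {
  ann <- function(cat, consequence, impact, protein = NA_character_) {
    x <- sites[sites$category == cat, ]
    mk_ann(variant_key(x$contig, x$pos, x$ref, x$alt), sim_gene_of[[cat]],
           consequence, impact, protein)
  }
  rbind(
    ann("reported_het", "missense_variant", "moderate", "Leu100Pro"),
    ann("protein_match", "missense_variant", "moderate", "Arg200Cys"),
    ann("plof", "stop_gained", "high"),
    ann("nonpass", "missense_variant", "moderate"),
    ann("diag_missense", "missense_variant", "moderate"),
    ann("comphet_trans_a", "missense_variant", "moderate"),
    ann("comphet_trans_b", "missense_variant", "moderate"),
    ann("comphet_unphased_a", "missense_variant", "moderate"),
    ann("comphet_unphased_b", "missense_variant", "moderate"),
    ann("comphet_cis_a", "missense_variant", "moderate"),
    ann("comphet_cis_b", "missense_variant", "moderate"),
    ann("single_het", "missense_variant", "moderate"),
    ann("artefact", "missense_variant", "moderate"),
    ann("complex_trigger", "missense_variant", "moderate", "Ala151Thr"),
    ann("complex_companion", "missense_variant", "moderate", "Asp424His"),
    ann("mnv_exact", "missense_variant", "moderate"),
    ann("mnv_protein_only", "missense_variant", "moderate", "Gly10Arg"),
    ann("cip_eligible", "missense_variant", "moderate"),
    ann("cip_vus", "missense_variant", "moderate"),
    ann("cip_conflict", "missense_variant", "moderate"),
    ann("plof_nonlof", "stop_gained", "high"),
    ann("hom_ar", "missense_variant", "moderate"),
    ann("cnv_snv_comphet_snv", "missense_variant", "moderate"),
    ann("inclusion_hit", "missense_variant", "moderate"),
    ann("inclusion_bypass", "missense_variant", "moderate"),
    ann("high_af", "missense_variant", "moderate"),
    ann("hemi_reported", "missense_variant", "moderate"),
    ann("x_het", "missense_variant", "moderate"))
}

# carrier sets: exact counts, exclusive within a pool, one sub-stream per pool
assign_pools <- function(spec) {
  pools <- list(
    ad1_small = c("reported_het", "protein_match", "plof", "nonpass"),
    ad1_cnv = c("cnv_loss", "cnv_common", "cnv_small_supported",
                "cnv_small_unsupported", "cnv_gain_inside",
                "cnv_gain_spanning"),
    ar1 = c("comphet_trans", "comphet_unphased", "comphet_cis", "single_het"),
    ad2 = c("cip_eligible", "cip_vus", "cip_conflict", "plof_nonlof"),
    inc = c("inclusion_hit", "inclusion_bypass"),
    cf = c("artefact", "complex_trigger"),
    hf = "high_af",
    mnv = c("mnv_exact", "mnv_protein_only"),
    xl = c("hemi_reported", "x_het"),
    ar2 = c("hom_ar", "cnv_hom_loss", "cnv_het_loss", "cnv_snv_comphet"),
    smn = "smn_zero")
  out <- list()
  for (pool in names(pools)) {
    cats <- pools[[pool]]
    ks <- vapply(cats, function(cat) as.integer(round(
      spec$rates[[cat]] * spec$n_samples)), integer(1))
    if (sum(ks) > spec$n_samples) stop("pool ", pool, " oversubscribed")
    set.seed(derive_seed(spec$seed, paste0("pool_", pool)))
    chosen <- sample.int(spec$n_samples, sum(ks))
    at <- 0L
    for (j in seq_along(cats)) {
      out[[cats[j]]] <- sort(chosen[seq_len(ks[j]) + at])
      at <- at + ks[j]
    }
  }
  out
}

#' Generate a synthetic screening cohort with its truth table
#'
#' Produces per-sample genotype calls (optionally written as per-sample
#' VCFs), raw CNV and SV caller calls, SMN1 copy numbers, the cohort-level
#' annotation table and a truth table stating, per sample and planted
#' variant, whether the default configuration must prioritize it.
#'
#' @param spec \code{\link{sim_spec}}.
#' @param dir Optional output directory (VCFs under \code{dir/vcf},
#'   CNV tables under \code{dir/cnv}, truth table as TSV).
#' @return List: \code{cohort} (list per sample: sample_id, calls,
#'   cnv_calls, sv_calls, smn_copy_number), \code{annotations},
#'   \code{truth}, \code{sample_ids}.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  reference <- sim_reference(spec)
  sites <- sim_sites(reference)
  cnvdef <- sim_cnvs()
  annotations <- sim_annotations(sites)
  carriers <- assign_pools(spec)
  n <- spec$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  truth <- list()
  cohort <- vector("list", n)
  # background variants: benign intergenic fill, one shared sub-stream
  set.seed(derive_seed(spec$seed, "background"))
  bg_pos <- lapply(seq_len(n), function(i)
    sort(sample(60000:68000, spec$background_variants_per_sample)))

  add_truth <- function(sample, category, key, gene, expect) {
    truth[[length(truth) + 1L]] <<- data.frame(
      sample_id = sample, category = category, key = key, gene = gene,
      expect_prioritized = expect, stringsAsFactors = FALSE)
  }
  plant_small <- function(sample, cat, zygosity = "het", filter = "PASS",
                          phase_set = NA_character_, hap = NA_integer_) {
    x <- sites[sites$category == cat, ]
    mk_call(sample, x$contig, x$pos, x$ref, x$alt, filter = filter,
            zygosity = zygosity, phase_set = phase_set,
            haplotype_index = hap)
  }
  skey <- function(cat) site_key(sites, cat)

  for (i in seq_len(n)) {
    sid <- ids[i]
    calls <- list()
    cnv_calls <- list(); sv_calls <- list()
    smn_cn <- 2L
    has <- function(cat) i %in% carriers[[cat]]

    # background fill (never eligible: no knowledge-base records)
    for (p in bg_pos[[i]]) {
      rb <- ref_base(reference, "1", p)
      calls[[length(calls) + 1L]] <- mk_call(sid, "1", p, rb, flip_base(rb))
    }
    if (has("reported_het")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "reported_het")
      add_truth(sid, "reported_het", skey("reported_het"), "GENE_AD1", TRUE)
    }
    if (has("protein_match")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "protein_match")
      add_truth(sid, "protein_match", skey("protein_match"), "GENE_AD1", TRUE)
    }
    if (has("plof")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "plof")
      add_truth(sid, "plof", skey("plof"), "GENE_AD1", TRUE)
    }
    if (has("nonpass")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "nonpass",
                                                 filter = "LowQual")
      add_truth(sid, "nonpass", skey("nonpass"), "GENE_AD1", FALSE)
    }
    if (has("comphet_trans")) {
      calls[[length(calls) + 1L]] <-
        plant_small(sid, "comphet_trans_a", phase_set = "ps52000", hap = 0L)
      calls[[length(calls) + 1L]] <-
        plant_small(sid, "comphet_trans_b", phase_set = "ps52000", hap = 1L)
      add_truth(sid, "comphet_trans", skey("comphet_trans_a"), "GENE_AR1",
                TRUE)
      add_truth(sid, "comphet_trans", skey("comphet_trans_b"), "GENE_AR1",
                TRUE)
    }
    if (has("comphet_unphased")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "comphet_unphased_a")
      calls[[length(calls) + 1L]] <- plant_small(sid, "comphet_unphased_b")
      add_truth(sid, "comphet_unphased", skey("comphet_unphased_a"),
                "GENE_AR1", TRUE)
      add_truth(sid, "comphet_unphased", skey("comphet_unphased_b"),
                "GENE_AR1", TRUE)
    }
    if (has("comphet_cis")) {
      calls[[length(calls) + 1L]] <-
        plant_small(sid, "comphet_cis_a", phase_set = "ps54000", hap = 0L)
      calls[[length(calls) + 1L]] <-
        plant_small(sid, "comphet_cis_b", phase_set = "ps54000", hap = 0L)
      add_truth(sid, "comphet_cis", skey("comphet_cis_a"), "GENE_AR1", FALSE)
      add_truth(sid, "comphet_cis", skey("comphet_cis_b"), "GENE_AR1", FALSE)
    }
    if (has("single_het")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "single_het")
      add_truth(sid, "single_het", skey("single_het"), "GENE_AR1", FALSE)
    }
    if (has("cip_eligible")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "cip_eligible")
      add_truth(sid, "cip_eligible", skey("cip_eligible"), "GENE_AD2", TRUE)
    }
    if (has("cip_vus")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "cip_vus")
      add_truth(sid, "cip_vus", skey("cip_vus"), "GENE_AD2", TRUE)
    }
    if (has("cip_conflict")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "cip_conflict")
      add_truth(sid, "cip_conflict", skey("cip_conflict"), "GENE_AD2", FALSE)
    }
    if (has("plof_nonlof")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "plof_nonlof")
      add_truth(sid, "plof_nonlof", skey("plof_nonlof"), "GENE_AD2", FALSE)
    }
    if (has("inclusion_hit")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "inclusion_hit")
      add_truth(sid, "inclusion_hit", skey("inclusion_hit"), "GENE_INC",
                TRUE)
    }
    if (has("inclusion_bypass")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "inclusion_bypass")
      add_truth(sid, "inclusion_bypass", skey("inclusion_bypass"),
                "GENE_INC", FALSE)
    }
    if (has("artefact")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "artefact")
      add_truth(sid, "artefact", skey("artefact"), "GENE_CF", FALSE)
    }
    if (has("complex_trigger")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "complex_trigger")
      calls[[length(calls) + 1L]] <- plant_small(sid, "complex_companion")
      add_truth(sid, "complex_trigger", skey("complex_trigger"), "GENE_CF",
                TRUE)
      add_truth(sid, "complex_companion", skey("complex_companion"),
                "GENE_CF", FALSE)
    }
    if (has("high_af")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "high_af")
      add_truth(sid, "high_af", skey("high_af"), "GENE_HF", FALSE)
    }
    if (has("mnv_exact")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "mnv_exact")
      add_truth(sid, "mnv_exact", skey("mnv_exact"), "GENE_MNV", TRUE)
    }
    if (has("mnv_protein_only")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "mnv_protein_only")
      add_truth(sid, "mnv_protein_only", skey("mnv_protein_only"),
                "GENE_MNV", FALSE)
    }
    if (has("hemi_reported")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "hemi_reported",
                                                 zygosity = "hemi")
      add_truth(sid, "hemi_reported", skey("hemi_reported"), "GENE_XL1",
                TRUE)
    }
    if (has("x_het")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "x_het")
      add_truth(sid, "x_het", skey("x_het"), "GENE_XL1", FALSE)
    }
    if (has("hom_ar")) {
      calls[[length(calls) + 1L]] <- plant_small(sid, "hom_ar",
                                                 zygosity = "hom_alt")
      add_truth(sid, "hom_ar", skey("hom_ar"), "GENE_AR2", TRUE)
    }
    # CNV categories
    for (cat in cnvdef$category) {
      if (!has(cat)) next
      cd <- cnvdef[cnvdef$category == cat, ]
      cnv_calls[[length(cnv_calls) + 1L]] <- data.frame(
        sample_id = sid, contig = cd$contig, start = cd$start, end = cd$end,
        type = cd$type, length = cd$end - cd$start + 1L, filter = "PASS",
        zygosity = cd$zygosity, caller = "cnv_caller",
        stringsAsFactors = FALSE)
      if (cd$sv_support) {
        sv_calls[[length(sv_calls) + 1L]] <- data.frame(
          sample_id = sid, contig = cd$contig, start = cd$start,
          end = cd$end, type = cd$type, length = cd$end - cd$start + 1L,
          filter = "PASS", zygosity = cd$zygosity, caller = "sv_caller",
          stringsAsFactors = FALSE)
      }
      cnv_key <- paste0("cnv:", cd$contig, ":", cd$start, "-", cd$end, ":",
                        cd$type)
      expect <- cat %in% c("cnv_loss", "cnv_small_supported",
                           "cnv_gain_inside", "cnv_hom_loss",
                           "cnv_snv_comphet")
      add_truth(sid, cat, cnv_key, cd$gene, expect)
      if (cat == "cnv_snv_comphet") {
        calls[[length(calls) + 1L]] <- plant_small(sid, "cnv_snv_comphet_snv")
        add_truth(sid, "cnv_snv_comphet", skey("cnv_snv_comphet_snv"),
                  "GENE_AR2", TRUE)
      }
    }
    if (has("smn_zero")) {
      smn_cn <- 0L
      add_truth(sid, "smn_zero", "smn1:cn0", "SMN1", TRUE)
    }
    calls <- do.call(rbind, calls)
    calls <- calls[order(ord_contig(calls$contig), calls$pos, calls$alt), ]
    rownames(calls) <- NULL
    cohort[[i]] <- list(
      sample_id = sid, calls = calls,
      cnv_calls = if (length(cnv_calls)) do.call(rbind, cnv_calls)
                  else empty_cnv(),
      sv_calls = if (length(sv_calls)) do.call(rbind, sv_calls)
                 else empty_cnv("sv_caller"),
      smn_copy_number = smn_cn)
  }
  truth <- do.call(rbind, truth)
  out <- list(cohort = cohort, annotations = annotations, truth = truth,
              sample_ids = ids)
  if (!is.null(dir)) {
    vdir <- file.path(dir, "vcf"); cdir <- file.path(dir, "cnv")
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (s in cohort) {
      write_small_variant_vcf(s$calls, annotations,
                              file.path(vdir, paste0(s$sample_id, ".vcf")),
                              sample_id = s$sample_id)
      utils::write.table(
        rbind(s$cnv_calls, s$sv_calls),
        file.path(cdir, paste0(s$sample_id, ".cnv.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = ids,
                 smn_copy_number = vapply(cohort, `[[`, integer(1),
                                          "smn_copy_number")),
      file.path(dir, "smn.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out$dir <- dir
  }
  out
}

#' Generate a diagnostic case cohort for sensitivity analysis
#'
#' Each case sample carries one designated diagnostic heterozygous variant
#' in a monoallelic gene: a configurable fraction carry a variant present in
#' the knowledge base (prioritizable by construction), the rest a missense
#' variant absent from every source (not prioritizable). Sensitivity on this
#' cohort therefore equals the prioritizable fraction.
#'
#' @param spec \code{\link{sim_spec}}.
#' @param n_cases Number of case samples.
#' @param frac_prioritizable Fraction carrying the knowledge-base variant.
#' @return List: \code{cohort}, \code{annotations}, \code{truth}
#'   (sample_id, key — the designated diagnostic variant per sample).
#' @export
generate_case_cohort <- function(spec, n_cases = 40L,
                                 frac_prioritizable = 0.5) {
  reference <- sim_reference(spec)
  sites <- sim_sites(reference)
  annotations <- sim_annotations(sites)
  k_in <- as.integer(round(frac_prioritizable * n_cases))
  set.seed(derive_seed(spec$seed, "case_cohort"))
  in_kb <- sort(sample.int(n_cases, k_in))
  ids <- sprintf("CASE%04d", seq_len(n_cases))
  mkp <- function(sid, cat) {
    x <- sites[sites$category == cat, ]
    mk_call(sid, x$contig, x$pos, x$ref, x$alt)
  }
  cohort <- lapply(seq_len(n_cases), function(i) {
    cat <- if (i %in% in_kb) "reported_het" else "diag_missense"
    list(sample_id = ids[i], calls = mkp(ids[i], cat),
         cnv_calls = empty_cnv(), sv_calls = empty_cnv("sv_caller"),
         smn_copy_number = 2L)
  })
  truth <- do.call(rbind, lapply(seq_len(n_cases), function(i) {
    cat <- if (i %in% in_kb) "reported_het" else "diag_missense"
    data.frame(sample_id = ids[i], key = site_key(sites, cat),
               prioritizable = i %in% in_kb, stringsAsFactors = FALSE)
  }))
  list(cohort = cohort, annotations = annotations, truth = truth)
}

#' Generate a synthetic exon depth track
#'
#' Emits a bedGraph-style depth table over the exon bases of each gene, with
#' Poisson-distributed depth per 50 bp window around a per-gene mean.
#'
#' @param spec \code{\link{sim_spec}}.
#' @param exons Exon table (with contig).
#' @param mean_depth Named vector of per-gene mean depths (default 35 for
#'   every gene).
#' @return Data frame contig, start, end, depth (1-based inclusive).
#' @export
generate_depth_track <- function(spec, exons,
                                 mean_depth = NULL) {
  set.seed(derive_seed(spec$seed, "depth"))
  rows <- list()
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    mu <- if (!is.null(mean_depth) && e$gene %in% names(mean_depth))
      mean_depth[[e$gene]] else 35
    starts <- seq.int(e$start, e$end, by = 50L)
    for (s0 in starts) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = e$contig, start = s0, end = min(s0 + 49L, e$end),
        depth = stats::rpois(1, mu), gene = e$gene,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare engine output against a truth table
#'
#' @param truth Truth table from \code{\link{generate_cohort}}.
#' @param prioritized Prioritized-call data frame.
#' @return List: \code{agreement} (fraction of truth rows honoured),
#'   \code{mismatches} (the offending truth rows with the observed state).
#' @export
verify_truth <- function(truth, prioritized) {
  seen <- paste(prioritized$sample_id, prioritized$key)
  observed <- paste(truth$sample_id, truth$key) %in% seen
  ok <- observed == truth$expect_prioritized
  mism <- truth[!ok, , drop = FALSE]
  if (nrow(mism)) mism$observed_prioritized <- observed[!ok]
  list(agreement = mean(ok), mismatches = mism)
}
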
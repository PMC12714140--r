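#' Pipeline configuration
#'
#' Builds the full threshold/policy configuration used by the prioritization
#' engine, the CNV rules and the gene-level QC. Every value can be overridden;
#' the complete configuration is echoed into the run manifest so that policy
#' choices are auditable.
#'
#' @param internal_af_max Internal cohort allele-frequency ceiling for
#'   previously-reported pathogenic variants. For MNVs the minimum allele
#'   frequency of the decomposed SNVs is compared against this ceiling.
#' @param plof_af_max Named numeric vector of population/internal AF ceilings
#'   for predicted loss-of-function small variants, per mode of inheritance
#'   (\code{monoallelic}, \code{biallelic}; X-linked uses the biallelic
#'   ceiling). These are policy values, surfaced here rather than hard-coded.
#' @param plof_internal_af_mode Whether the internal-AF filter for pLoF
#'   candidates uses the per-MOI pLoF ceilings (\code{"plof_threshold"},
#'   default) or the 0.05 reported-variant ceiling (\code{"reported"}).
#' @param cnv_loss_af_max,cnv_gain_af_max Named numeric vectors (per MOI) of
#'   reference-frequency ceilings for CNV losses and gains.
#' @param cnv_recip_overlap Reciprocal-overlap fraction used when matching a
#'   CNV against the reference frequency set.
#' @param cnv_merge_recip_overlap Reciprocal overlap required for an SV-caller
#'   call to rescue a small (2-10 kb) CNV to PASS.
#' @param cnv_flank_bp Padding added to a CNV before testing overlap with a
#'   gene's coding region.
#' @param cnv_min_length_bp Minimum CNV length considered by the pipeline.
#' @param cnv_small_max_bp CNVs at or below this length require SV support.
#' @param cnv_comphet_with_small Allow a heterozygous CNV loss to pair with a
#'   heterozygous small variant as a potential compound het in biallelic genes.
#' @param gene_window_bp Window around the gene span within which
#'   previously-reported variants are considered.
#' @param phasing_window_bp Maximum distance over which read-based phasing is
#'   trusted to place two heterozygous variants on the same haplotype.
#' @param cip_mode Default scenario for variants with conflicting
#'   interpretations of pathogenicity; one of \code{"none"},
#'   \code{"p_and_no_b"}, \code{"p_and_le1_b"}, \code{"le1_b"}, \code{"all"}.
#' @param high_impact_consequences Consequence terms treated as predicted
#'   loss of function.
#' @param coverage_min_depth Depth (x-fold) below which a base counts as
#'   poorly covered in gene QC.
#' @param coverage_exclude_mean_median Mean and median depth ceiling in the
#'   gene-exclusion rule.
#' @param coverage_exclude_fraction Fraction of bases below
#'   \code{coverage_min_depth} at or above which coverage is considered to
#'   affect the entire gene.
#' @param callability_compromised_fraction Fraction of a gene inside
#'   homology-excluded regions at or above which CNV callability is
#'   considered compromised.
#' @param wilson_z Normal quantile used for Wilson score intervals.
#' @return A list of class \code{"nbs_config"}.
#' @examples
#' cfg <- nbs_config()
#' cfg$internal_af_max
#' @export
nbs_config <- function(internal_af_max = 0.05,
                       plof_af_max = c(monoallelic = 1e-4, biallelic = 5e-3),
                       plof_internal_af_mode = c("plof_threshold", "reported"),
                       cnv_loss_af_max = c(monoallelic = 0.001, biallelic = 0.005),
                       cnv_gain_af_max = c(monoallelic = 0.002, biallelic = 0.01),
                       cnv_recip_overlap = 0.8,
                       cnv_merge_recip_overlap = 0.5,
                       cnv_flank_bp = 2000,
                       cnv_min_length_bp = 2000,
                       cnv_small_max_bp = 10000,
                       cnv_comphet_with_small = TRUE,
                       gene_window_bp = 50,
                       phasing_window_bp = 150,
                       cip_mode = c("p_and_le1_b", "none", "p_and_no_b", "le1_b", "all"),
                       high_impact_consequences = c(
                         "stop_gained", "frameshift_variant", "frameshift",
                         "splice_acceptor_variant", "splice_donor_variant",
                         "splice_acceptor", "splice_donor",
                         "start_lost", "stop_lost", "transcript_ablation"),
                       coverage_min_depth = 15,
                       coverage_exclude_mean_median = 30,
                       coverage_exclude_fraction = 0.95,
                       callability_compromised_fraction = 0.5,
                       wilson_z = 1.96) {
  plof_internal_af_mode <- match.arg(plof_internal_af_mode)
  cip_mode <- match.arg(cip_mode)
  stopifnot(
    internal_af_max > 0, internal_af_max < 1,
    all(plof_af_max > 0), all(plof_af_max < 1),
    all(cnv_loss_af_max > 0), all(cnv_gain_af_max > 0),
    cnv_recip_overlap > 0, cnv_recip_overlap <= 1,
    gene_window_bp >= 0, phasing_window_bp >= 0, cnv_flank_bp >= 0,
    wilson_z > 0
  )
  cfg <- list(
    internal_af_max = internal_af_max,
    plof_af_max = plof_af_max,
    plof_internal_af_mode = plof_internal_af_mode,
    cnv_loss_af_max = cnv_loss_af_max,
    cnv_gain_af_max = cnv_gain_af_max,
    cnv_recip_overlap = cnv_recip_overlap,
    cnv_merge_recip_overlap = cnv_merge_recip_overlap,
    cnv_flank_bp = cnv_flank_bp,
    cnv_min_length_bp = cnv_min_length_bp,
    cnv_small_max_bp = cnv_small_max_bp,
    cnv_comphet_with_small = cnv_comphet_with_small,
    gene_window_bp = gene_window_bp,
    phasing_window_bp = phasing_window_bp,
    cip_mode = cip_mode,
    high_impact_consequences = high_impact_consequences,
    coverage_min_depth = coverage_min_depth,
    coverage_exclude_mean_median = coverage_exclude_mean_median,
    coverage_exclude_fraction = coverage_exclude_fraction,
    callability_compromised_fraction = callability_compromised_fraction,
    wilson_z = wilson_z
  )
  class(cfg) <- "nbs_config"
  cfg
}

#' @export
print.nbs_config <- function(x, ...) {
  cat("<nbs_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-34s %s\n", nm,
                paste(if (!is.null(names(v)) && any(nzchar(names(v))))
                  paste0(names(v), "=", v) else format(v), collapse = ", ")))
  }
  invisible(x)
}

# The five conflicting-interpretation scenarios, ordered along the
# containment chain (each scenario's eligible set contains the previous).
#' @export
cip_modes <- function() c("none", "p_and_no_b", "p_and_le1_b", "le1_b", "all")
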
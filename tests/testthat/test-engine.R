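mini_resources <- function(panel = mk_pair("G1"), knowledge = NULL,
                           exclusion = NULL, internal_af = NULL,
                           population_af = NULL, cnv_reference = NULL,
                           companion = NULL, exons = NULL) {
  if (is.null(exclusion)) {
    exclusion <- data.frame(key = character(), reason = character())
  }
  if (is.null(exons)) {
    exons <- data.frame(gene = panel$gene, transcript = panel$transcript,
                        start = panel$gene_start, end = panel$gene_end,
                        coding = TRUE)
  }
  list(panel = panel, exons = exons, knowledge = knowledge,
       exclusion = exclusion, internal_af = internal_af,
       population_af = population_af, cnv_reference = cnv_reference,
       companion = companion)
}

test_that("the universal filter gates on PASS status and the exclusion list", {
  ex <- data.frame(key = "1:100:A:T", reason = "artefact")
  ok <- mk_call_io("S1", "1", 200, "G", "C")
  expect_true(universal_filter(ok, ex)$pass)
  bad <- mk_call_io("S1", "1", 300, "G", "C", filter = "LowQual")
  expect_equal(universal_filter(bad, ex)$reason, "filter_status")
  # a P/LP match elsewhere cannot rescue a non-PASS call (checked upstream
  # of any source logic)
  listed <- mk_call_io("S1", "1", 100, "A", "T")
  expect_match(universal_filter(listed, ex)$reason, "^excluded:artefact")
})

test_that("the MOI gate passes monoallelic candidates alone and gates biallelic hets", {
  cfg <- nbs_config()
  # monoallelic: het and hom pass alone
  got <- moi_gate(rbind(mk_cand("k1", 100), mk_cand("k2", 200, "hom_alt")),
                  "monoallelic", cfg)
  expect_equal(got$zygosity_rationale,
               c("monoallelic_het", "monoallelic_hom"))
  # biallelic: a single het does not pass
  expect_equal(nrow(moi_gate(mk_cand("k1", 100), "biallelic", cfg)), 0L)
  # hom passes alone
  got <- moi_gate(mk_cand("k1", 100, "hom_alt"), "biallelic", cfg)
  expect_equal(got$zygosity_rationale, "biallelic_hom")
  # two unphased hets pass as a potential compound het
  got <- moi_gate(rbind(mk_cand("k1", 100), mk_cand("k2", 600)),
                  "biallelic", cfg)
  expect_equal(nrow(got), 2L)
  expect_true(all(got$zygosity_rationale == "biallelic_comphet_unphased"))
  expect_equal(got$partner_keys, c("k2", "k1"))
  # phased in trans within the window
  got <- moi_gate(rbind(mk_cand("k1", 100, phase_set = "ps", hap = 0L),
                        mk_cand("k2", 180, phase_set = "ps", hap = 1L)),
                  "biallelic", cfg)
  expect_true(all(got$zygosity_rationale == "biallelic_comphet_trans"))
  # phased in cis within the window: collapses to one allele, nothing passes
  got <- moi_gate(rbind(mk_cand("k1", 100, phase_set = "ps", hap = 0L),
                        mk_cand("k2", 180, phase_set = "ps", hap = 0L)),
                  "biallelic", cfg)
  expect_equal(nrow(got), 0L)
  # same phase set and haplotype but beyond 150 bp: treated as unphased
  got <- moi_gate(rbind(mk_cand("k1", 100, phase_set = "ps", hap = 0L),
                        mk_cand("k2", 400, phase_set = "ps", hap = 0L)),
                  "biallelic", cfg)
  expect_equal(nrow(got), 2L)
  expect_true(all(got$zygosity_rationale == "biallelic_comphet_unphased"))
  # a cis pair plus a third het: the pair is one allele, all three pass
  got <- moi_gate(rbind(mk_cand("k1", 100, phase_set = "ps", hap = 0L),
                        mk_cand("k2", 180, phase_set = "ps", hap = 0L),
                        mk_cand("k3", 900)),
                  "biallelic", cfg)
  expect_equal(nrow(got), 3L)
  # x-linked: hemizygous passes alone, a het does not
  got <- moi_gate(mk_cand("k1", 100, "hemi"), "x_linked", cfg)
  expect_equal(got$zygosity_rationale, "hemizygous")
  expect_equal(nrow(moi_gate(mk_cand("k1", 100), "x_linked", cfg)), 0L)
  # het CNV loss pairs with a het small variant (configurable)
  cand <- rbind(mk_cand("k1", 100),
                mk_cand("cnv:1:50-5000:loss", 50, is_cnv = TRUE))
  got <- moi_gate(cand, "biallelic", cfg)
  expect_equal(nrow(got), 2L)
  cfg_off <- nbs_config(cnv_comphet_with_small = FALSE)
  expect_equal(nrow(moi_gate(cand, "biallelic", cfg_off)), 0L)
})

test_that("transcript selection prefers MANE Select, then MANE Clinical, then canonical", {
  ann <- function(tx, flags, cds = 1000L) {
    data.frame(key = "k", gene = "G1", transcript = tx, consequence = "x",
               impact = "high", protein_change = NA, flags = flags,
               cds_length = cds, stringsAsFactors = FALSE)
  }
  a <- rbind(ann("TX2", "mane_select"), ann("TX1", "other"))
  expect_equal(select_transcript(a)$transcript, "TX2")
  a <- rbind(ann("TX3", "predefined_canonical"), ann("TX2", "mane_clinical"))
  expect_equal(select_transcript(a)$transcript, "TX2")
  a <- ann("TX9", "predefined_canonical")
  expect_equal(select_transcript(a)$transcript, "TX9")
  expect_null(select_transcript(ann("TX1", "other")))
  # ties: longest coding sequence, then lexicographic id
  a <- rbind(ann("TXB", "mane_select", 900L), ann("TXA", "mane_select", 1200L))
  expect_equal(select_transcript(a)$transcript, "TXA")
  a <- rbind(ann("TXB", "mane_select", 900L), ann("TXA", "mane_select", 900L))
  expect_equal(select_transcript(a)$transcript, "TXA")
})

test_that("the pLoF rule needs high impact, a LoF gene and sub-threshold frequencies", {
  pair <- mk_pair("G1", moi = "monoallelic", lof = TRUE)
  v <- normalize_variant("1", 1500, "G", "T")
  ann <- data.frame(key = "1:1500:G:T", gene = "G1", transcript = "TX_G1",
                    consequence = "stop_gained", impact = "high",
                    protein_change = NA, flags = "mane_select",
                    cds_length = 1500L, stringsAsFactors = FALSE)
  cfg <- nbs_config()
  expect_true(prioritize_plof_small(v, ann, pair, NULL, NULL, cfg))
  # not in a LoF-mechanism gene
  pair_nl <- mk_pair("G1", lof = FALSE)
  expect_false(prioritize_plof_small(v, ann, pair_nl, NULL, NULL, cfg))
  # missense is not high impact
  ann_mis <- transform(ann, consequence = "missense_variant",
                       impact = "moderate")
  expect_false(prioritize_plof_small(v, ann_mis, pair, NULL, NULL, cfg))
  # population AF at or above the monoallelic ceiling blocks the rule
  pop <- data.frame(key = "1:1500:G:T", tier = "popmax", af = 2e-4)
  expect_false(prioritize_plof_small(v, ann, pair, NULL, pop, cfg))
  pop_ok <- transform(pop, af = 5e-5)
  expect_true(prioritize_plof_small(v, ann, pair, NULL, pop_ok, cfg))
  # the biallelic ceiling is looser
  pair_ar <- mk_pair("G1", moi = "biallelic", lof = TRUE)
  pop_mid <- transform(pop, af = 2e-3)
  expect_true(prioritize_plof_small(v, ann, pair_ar, NULL, pop_mid, cfg))
  # internal AF uses the pLoF ceiling by default, the 0.05 ceiling on request
  iaf <- data.frame(key = "1:1500:G:T", af = 0.01)
  expect_false(prioritize_plof_small(v, ann, pair, iaf, NULL, cfg))
  cfg_rep <- nbs_config(plof_internal_af_mode = "reported")
  expect_true(prioritize_plof_small(v, ann, pair, iaf, NULL, cfg_rep))
  # no annotation on a flagged transcript: ineligible
  ann_uf <- transform(ann, flags = "other")
  expect_false(prioritize_plof_small(v, ann_uf, pair, NULL, NULL, cfg))
})

test_that("per-source reported rules fire as specified", {
  pair <- mk_pair("G1")
  v <- normalize_variant("1", 1500, "A", "T")
  iaf_lo <- data.frame(key = "1:1500:A:T", af = 0.001)
  iaf_hi <- data.frame(key = "1:1500:A:T", af = 0.07)
  kb <- mk_kb(list(source = "clinvar_like", pos = 1500L, cls = "P"))
  cfg <- nbs_config()
  expect_equal(prioritize_reported(v, NULL, pair, kb, iaf_lo, cfg),
               "clinvar_like")
  # internal AF at 0.07 blocks every source
  expect_length(prioritize_reported(v, NULL, pair, kb, iaf_hi, cfg), 0)
  # an MNV with decomposed AFs {0.2, 0.01} passes the minimum-AF rule
  vm <- normalize_variant("1", 1500, "AC", "TG")
  kbm <- mk_kb(list(source = "curated_commercial", pos = 1500L, ref = "AC",
                    alt = "TG", cls = "P"))
  iafm <- rbind(data.frame(key = "1:1500:A:T", af = 0.2),
                data.frame(key = "1:1501:C:G", af = 0.01))
  expect_equal(prioritize_reported(vm, NULL, pair, kbm, iafm, cfg),
               "curated_commercial")
  # inclusion-list-only genes disable non-internal sources
  pair_inc <- mk_pair("G1", inc_only = TRUE)
  expect_length(prioritize_reported(v, NULL, pair_inc, kb, iaf_lo, cfg), 0)
  kb_int <- mk_kb(list(source = "internal_inclusion", pos = 1500L,
                       cls = "P", ev = "PMID:7"))
  expect_equal(prioritize_reported(v, NULL, pair_inc, kb_int, iaf_lo, cfg),
               "internal_inclusion")
  # a variant eligible via several sources carries all provenances
  kb2 <- rbind(kb, kb_int)
  expect_setequal(prioritize_reported(v, NULL, pair, kb2, iaf_lo, cfg),
                  c("clinvar_like", "internal_inclusion"))
})

test_that("the SMN1 rule fires only at copy number zero", {
  expect_true(smn1_rule(0))
  expect_false(smn1_rule(1))
  expect_false(smn1_rule(2))
  expect_error(smn1_rule(-1), ">= 0")
})

test_that("companion flags report the sample genotype without changing prioritization", {
  comp <- data.frame(trigger_key = "1:100:G:A", companion_key = "1:900:G:C",
                     label = "complex_allele")
  calls <- mk_call_io("S1", "1", 900, "G", "C", zyg = "het")
  got <- companion_flags("1:100:G:A", comp, calls)
  expect_equal(got$genotype, "het")
  # companion absent in the sample
  got <- companion_flags("1:100:G:A", comp, calls[0, ])
  expect_equal(got$genotype, "absent")
  # trigger with no companions configured
  expect_equal(nrow(companion_flags("1:555:A:T", comp, calls)), 0L)
})

test_that("run_sample composes the rules, with exclusion taking precedence", {
  kb <- mk_kb(list(source = "clinvar_like", pos = 1500L, cls = "P"))
  iaf <- data.frame(key = "1:1500:A:T", af = 0.001)
  calls <- mk_call_io("S1", "1", 1500, "A", "T")
  res <- run_sample(calls, data.frame(), mini_resources(knowledge = kb,
                                                        internal_af = iaf))
  expect_equal(nrow(res), 1L)
  expect_equal(res$sources, "clinvar_like")
  expect_equal(res$zygosity_rationale, "monoallelic_het")
  # same variant in a biallelic-only gene: gated out
  res <- run_sample(calls, data.frame(),
                    mini_resources(panel = mk_pair("G1", moi = "biallelic"),
                                   knowledge = kb, internal_af = iaf))
  expect_equal(nrow(res), 0L)
  # a planted ClinVar P variant on the exclusion list is never emitted
  ex <- data.frame(key = "1:1500:A:T", reason = "low_penetrance")
  res <- run_sample(calls, data.frame(),
                    mini_resources(knowledge = kb, internal_af = iaf,
                                   exclusion = ex))
  expect_equal(nrow(res), 0L)
  # outside the 50 bp gene window: not considered
  far <- mk_call_io("S1", "1", 5000, "A", "T")
  kb_far <- mk_kb(list(source = "clinvar_like", pos = 5000L, cls = "P"))
  iaf_far <- data.frame(key = "1:5000:A:T", af = 0.001)
  res <- run_sample(far, data.frame(),
                    mini_resources(knowledge = kb_far,
                                   internal_af = iaf_far))
  expect_equal(nrow(res), 0L)
})
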
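test_that("fixture generation is deterministic under a fixed seed", {
  spec <- sim_spec(seed = 5, n_samples = 20)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cohort, b$cohort)
  # written fixtures are byte-identical
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
  # a different seed moves the carriers but keeps the planted sites
  c2 <- generate_cohort(sim_spec(seed = 6, n_samples = 20))
  expect_false(identical(a$truth$sample_id, c2$truth$sample_id))
  # planted sites are fixed; alleles depend on the seed-derived reference
  site_of <- function(k) sub("^((cnv:)?[^:]+:[0-9]+).*", "\\1", k)
  expect_setequal(unique(site_of(a$truth$key)),
                  unique(site_of(c2$truth$key)))
})

test_that("truth tables encode the intended rule outcomes by construction", {
  spec <- sim_spec(seed = 9, n_samples = 50)
  cc <- generate_cohort(spec)
  tr <- cc$truth
  # categories that must never be prioritized under the default config
  never <- c("nonpass", "comphet_cis", "single_het", "cip_conflict",
             "plof_nonlof", "inclusion_bypass", "artefact",
             "complex_companion", "high_af", "mnv_protein_only", "x_het",
             "cnv_common", "cnv_small_unsupported", "cnv_gain_spanning",
             "cnv_het_loss")
  expect_true(all(!tr$expect_prioritized[tr$category %in% never]))
  always <- c("reported_het", "protein_match", "plof", "comphet_trans",
              "comphet_unphased", "cip_eligible", "cip_vus",
              "inclusion_hit", "complex_trigger", "mnv_exact",
              "hemi_reported", "hom_ar", "cnv_loss", "cnv_small_supported",
              "cnv_gain_inside", "cnv_hom_loss", "cnv_snv_comphet",
              "smn_zero")
  expect_true(all(tr$expect_prioritized[tr$category %in% always]))
  # exact carrier counts: rates are honoured deterministically
  n_rep <- length(unique(tr$sample_id[tr$category == "reported_het"]))
  expect_equal(n_rep, round(0.04 * 50))
  # carrier exclusivity within a gene pool: a sample never mixes categories
  # that would interact in the same gene
  ar1 <- tr[tr$gene == "GENE_AR1", ]
  per_sample <- split(sub("_[ab]$", "", ar1$category), ar1$sample_id)
  expect_true(all(vapply(per_sample, function(x)
    length(unique(x)) == 1L, logical(1))))
})

test_that("the engine reproduces the truth table and honours exclusion monotonicity", {
  spec <- sim_spec(seed = 13, n_samples = 50)
  kb <- generate_knowledge(spec)
  cc <- generate_cohort(spec)
  res <- run_cohort(cc$cohort, kb, annotations = cc$annotations)
  v <- verify_truth(cc$truth, res)
  expect_equal(v$agreement, 1.0)

  # a planted hom artefact present on the exclusion list in every sample:
  # exclusion wins under every scenario
  for (mode in cip_modes()) {
    res_m <- run_cohort(cc$cohort, kb, annotations = cc$annotations,
                        cip_mode = mode)
    art_key <- unique(cc$truth$key[cc$truth$category == "artefact"])
    expect_false(art_key %in% res_m$key)
  }

  # adding entries to the exclusion list never increases the call count
  kb_more <- kb
  extra <- data.frame(contig = "1", pos = 19100L, ref = "x", alt = "x",
                      reason = "low_penetrance",
                      key = unique(cc$truth$key[
                        cc$truth$category == "reported_het"]))
  kb_more$exclusion <- rbind(kb$exclusion, extra)
  res2 <- run_cohort(cc$cohort, kb_more, annotations = cc$annotations)
  expect_lte(nrow(res2), nrow(res))
  expect_false(extra$key[1] %in% res2$key)
  # and excluding every prioritized small variant empties the small calls
  kb_all <- kb
  kb_all$exclusion <- rbind(kb$exclusion,
                            data.frame(contig = "x", pos = 0L, ref = "x",
                                       alt = "x", reason = "curated",
                                       key = unique(res$key)))
  res3 <- run_cohort(cc$cohort, kb_all, annotations = cc$annotations)
  expect_equal(sum(res3$payload == "small"), 0L)
})

test_that("planted variants moved to AF >= 0.05 in the internal reference are suppressed", {
  spec <- sim_spec(seed = 17, n_samples = 40)
  kb <- generate_knowledge(spec)
  cc <- generate_cohort(spec)
  res <- run_cohort(cc$cohort, kb, annotations = cc$annotations)
  rep_keys <- unique(cc$truth$key[cc$truth$category %in%
                                    c("reported_het", "protein_match")])
  expect_true(all(rep_keys %in% res$key))
  kb_hot <- kb
  kb_hot$internal_af$af[kb_hot$internal_af$key %in% rep_keys] <- 0.10
  extra <- rep_keys[!rep_keys %in% kb_hot$internal_af$key]
  if (length(extra)) {
    kb_hot$internal_af <- rbind(
      kb_hot$internal_af,
      data.frame(contig = "1", pos = 0L, ref = "x", alt = "x", af = 0.10,
                 key = extra))
  }
  res_hot <- run_cohort(cc$cohort, kb_hot, annotations = cc$annotations)
  expect_false(any(rep_keys %in% res_hot$key))
})

test_that("the case cohort yields the designed sensitivity", {
  spec <- sim_spec(seed = 19)
  case <- generate_case_cohort(spec, n_cases = 20, frac_prioritizable = 0.5)
  kb <- generate_knowledge(spec)
  res <- run_cohort(case$cohort, kb, annotations = case$annotations)
  expect_equal(sensitivity(case$truth, res), 50)
  case2 <- generate_case_cohort(spec, n_cases = 20, frac_prioritizable = 1)
  res2 <- run_cohort(case2$cohort, kb, annotations = case2$annotations)
  expect_equal(sensitivity(case2$truth, res2), 100)
  case3 <- generate_case_cohort(spec, n_cases = 20, frac_prioritizable = 0)
  res3 <- run_cohort(case3$cohort, kb, annotations = case3$annotations)
  expect_equal(sensitivity(case3$truth, res3), 0)
})
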
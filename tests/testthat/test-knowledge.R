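test_that("classification aggregation implements the conflicting-interpretation scenarios", {
  # worked cases under the default scenario (>=1 P/LP, <=1 B/LB)
  expect_true(aggregate_classifications(c("P", "P", "B")))
  expect_false(aggregate_classifications(c("LP", "B", "B")))
  expect_false(aggregate_classifications(character(0)))
  expect_true(aggregate_classifications("P"))
  expect_false(aggregate_classifications("VUS"))

  # scenario-specific behaviour on conflicting keys
  expect_false(aggregate_classifications(c("P", "VUS"), "none"))
  expect_true(aggregate_classifications(c("P", "VUS"), "p_and_no_b"))
  expect_false(aggregate_classifications(c("P", "B"), "p_and_no_b"))
  expect_true(aggregate_classifications(c("P", "B"), "p_and_le1_b"))
  expect_true(aggregate_classifications(c("VUS", "B"), "le1_b"))
  expect_true(aggregate_classifications(c("P", "B", "B"), "all"))
  # a non-conflicting pure-P/LP key is eligible under every scenario
  for (m in cip_modes()) expect_true(aggregate_classifications("LP", m))
})

test_that("scenario eligibility is monotone along the containment chain and in P/LP evidence", {
  set.seed(21)
  chain <- cip_modes()
  for (i in 1:300) {
    cl <- sample(c("P", "LP", "VUS", "LB", "B"), sample(1:6, 1),
                 replace = TRUE)
    el <- vapply(chain, function(m) aggregate_classifications(cl, m),
                 logical(1))
    expect_true(all(diff(as.integer(el)) >= 0))
    # adding P/LP never flips eligible -> not, B/LB counts unchanged
    for (m in c("p_and_no_b", "p_and_le1_b")) {
      if (aggregate_classifications(cl, m)) {
        expect_true(aggregate_classifications(c(cl, "P"), m))
      }
    }
  }
})

test_that("variant matching is coordinate-exact, with per-source protein matching", {
  kb <- mk_kb(
    list(source = "clinvar_like", pos = 100L, cls = "P"),
    list(source = "clinvar_like", pos = 150L, ref = "G", alt = "A",
         cls = "P", protein = "Arg100Ter"),
    list(source = "curated_commercial", pos = 160L, ref = "C", alt = "G",
         cls = "P", protein = "Arg100Ter"))
  v_exact <- normalize_variant("1", 100, "A", "T")
  hit <- match_variant(v_exact, kb)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$match_type, "coordinate")

  # absent by coordinates, present by protein change (ClinVar-like only)
  v_prot <- normalize_variant("1", 400, "A", "C")
  ann <- data.frame(gene = "G1", protein_change = "Arg100Ter")
  hit <- match_variant(v_prot, kb, annotations = ann)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$match_type, "protein")
  expect_equal(hit$source, "clinvar_like")  # curated source never matches

  # protein matching is not supported for MNVs
  v_mnv <- normalize_variant("1", 400, "AT", "CG")
  expect_equal(nrow(match_variant(v_mnv, kb, annotations = ann)), 0L)

  # disabled protein matching equals an exact-coordinate linear scan
  set.seed(22)
  for (i in 1:50) {
    pos <- sample(1:500, 1)
    v <- normalize_variant("1", pos, "A", "T")
    got <- match_variant(v, kb, annotations = ann,
                         allow_protein_match = FALSE)
    want <- kb[kb$key == variant_key("1", pos, "A", "T"), , drop = FALSE]
    expect_equal(nrow(got), nrow(want))
  }
})

test_that("exclusion matching is allele-exact and reports the curated reason", {
  ex <- data.frame(contig = "3", pos = 15645186L, ref = "G", alt = "C",
                   reason = "complex_allele_component")
  ex$key <- variant_key(ex$contig, ex$pos, ex$ref, ex$alt)
  hit <- is_excluded("3:15645186:G:C", ex)
  expect_true(hit$excluded)
  expect_equal(hit$reason, "complex_allele_component")
  expect_false(is_excluded("3:15645186:G:A", ex)$excluded)  # other allele
  expect_false(is_excluded("3:15645100:G:C", ex)$excluded)
})

test_that("the gene matching window is a 50 bp inclusive pad", {
  pair <- mk_pair(gstart = 1000L, gend = 2000L)
  at <- function(pos, ref = "A") {
    v <- structure(list(contig = "1", pos = as.integer(pos), ref = ref,
                        alt = "T", variant_class = "snv"),
                   class = "nbs_variant")
    within_gene_window(v, pair, 50)
  }
  expect_true(at(970))    # 30 bp upstream
  expect_true(at(950))    # exactly 50 bp upstream
  expect_false(at(949))   # 51 bp upstream
  expect_true(at(1500))   # inside
  expect_true(at(2050))
  expect_false(at(2051))
  # a deletion whose footprint reaches the window counts
  expect_true(at(940, ref = "AAAAAAAAAAA"))
})

test_that("internal allele frequency equals brute-force allele counting", {
  expect_equal(internal_af(c("het", "het", "het", "hom_alt"), 100), 5 / 200)
  expect_equal(internal_af(character(0), 50), 0)
  expect_equal(internal_af(rep("hom_alt", 10), 10), 1)
  expect_true(is.na(internal_af(character(0), 0)))
  set.seed(23)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    k <- sample(0:min(n, 20), 1)
    z <- sample(c("het", "hom_alt"), k, replace = TRUE)
    want <- sum(ifelse(z == "het", 1, 2)) / (2 * n)
    expect_equal(internal_af(z, n), want)
  }
})

test_that("knowledge records inside other panel genes become exclusion candidates", {
  panel <- rbind(mk_pair("G1", gstart = 1000L, gend = 2000L),
                 mk_pair("G2", gstart = 1900L, gend = 3000L))
  kb <- mk_kb(list(source = "clinvar_like", pos = 1950L, cls = "P",
                   gene = "G1"),
              list(source = "clinvar_like", pos = 1100L, cls = "P",
                   gene = "G1"))
  out <- overlapping_gene_exclusions(kb, panel)
  expect_equal(out$pos, 1950L)  # inside G2's span but attributed to G1
  expect_equal(out$reason, "overlapping_gene")
})
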
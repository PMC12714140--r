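test_that("reciprocal overlap matches a per-base counting oracle", {
  expect_equal(reciprocal_overlap(100, 199, 100, 199), 1.0)
  expect_equal(reciprocal_overlap(100, 199, 300, 399), 0.0)
  expect_equal(reciprocal_overlap(100, 199, 150, 249), 0.5)
  set.seed(31)
  for (i in 1:1000) {
    a1 <- sample(1:500, 1); a2 <- a1 + sample(0:300, 1)
    b1 <- sample(1:500, 1); b2 <- b1 + sample(0:300, 1)
    expect_equal(reciprocal_overlap(a1, a2, b1, b2),
                 oracle_ro(a1, a2, b1, b2))
  }
})

test_that("caller merging rescues small CNVs only with same-type SV support", {
  cfg <- nbs_config()
  cnv <- function(start, end, type = "loss", filter = "PASS",
                  sample = "S1") {
    data.frame(sample_id = sample, contig = "1", start = start, end = end,
               type = type, length = end - start + 1L, filter = filter,
               zygosity = "het", caller = "cnv_caller",
               stringsAsFactors = FALSE)
  }
  sv <- function(start, end, type = "loss") {
    x <- cnv(start, end, type); x$caller <- "sv_caller"; x
  }
  # 5 kb loss backed by an SV loss at RO 0.8 -> PASS
  m <- merge_cnv_calls(cnv(10000, 14999), sv(10000, 13999), cfg)
  expect_equal(m$filter, "PASS")
  # same span, no SV support -> not PASS
  m <- merge_cnv_calls(cnv(10000, 14999), NULL, cfg)
  expect_false(m$filter == "PASS")
  # opposite-type SV support does not count
  m <- merge_cnv_calls(cnv(10000, 14999), sv(10000, 14999, "gain"), cfg)
  expect_false(m$filter == "PASS")
  # RO below 0.5 does not count
  m <- merge_cnv_calls(cnv(10000, 14999), sv(13000, 17999), cfg)
  expect_false(m$filter == "PASS")
  # >10 kb calls keep their own status either way
  m <- merge_cnv_calls(cnv(10000, 60000), NULL, cfg)
  expect_equal(m$filter, "PASS")
  m <- merge_cnv_calls(cnv(10000, 60000, filter = "cnvQual"), NULL, cfg)
  expect_equal(m$filter, "cnvQual")
  # at or below the 2 kb floor the call is dropped entirely
  m <- merge_cnv_calls(cnv(10000, 11999), NULL, cfg)
  expect_equal(nrow(m), 0L)
})

test_that("CNV reference frequency is type-aware and respects the RO threshold", {
  ref <- data.frame(contig = "1",
                    start = c(10000L, 10000L, 50000L),
                    end = c(30000L, 30000L, 60000L),
                    type = c("loss", "gain", "loss"),
                    frequency = c(0.004, 0.02, 0.001))
  q <- list(contig = "1", start = 10000L, end = 30000L, type = "loss")
  expect_equal(cnv_reference_frequency(q, ref), 0.004)
  # same span, opposite type only
  q$type <- "gain"
  expect_equal(cnv_reference_frequency(q, ref), 0.02)
  # scan oracle on a matching entry at RO 0.9
  q <- list(contig = "1", start = 10000L, end = 28000L, type = "loss")
  expect_equal(cnv_reference_frequency(q, ref), 0.004)
  # below the 0.8 reciprocal-overlap threshold: no match
  q <- list(contig = "1", start = 5000L, end = 25000L, type = "loss")
  expect_equal(cnv_reference_frequency(q, ref), 0.0)
  expect_equal(cnv_reference_frequency(q, ref[0, ]), 0.0)
})

test_that("the CNV rule enforces coding overlap, gain breakpoints and frequency ceilings", {
  pair <- mk_pair("G1", moi = "monoallelic", lof = TRUE,
                  gstart = 10000L, gend = 30000L)
  exons <- data.frame(gene = "G1", transcript = "TX_G1",
                      start = c(10000L, 19750L, 29500L),
                      end = c(10500L, 20250L, 30000L), coding = TRUE)
  cfg <- nbs_config()
  ref0 <- data.frame(contig = character(), start = integer(),
                     end = integer(), type = character(),
                     frequency = numeric())
  cnv <- function(start, end, type = "loss", zyg = "het") {
    data.frame(sample_id = "S1", contig = "1", start = start, end = end,
               type = type, length = end - start + 1L, filter = "PASS",
               zygosity = zyg, caller = "cnv_caller",
               stringsAsFactors = FALSE)
  }
  # 20 kb loss over coding exons, reference frequency 0 -> fires
  expect_true(prioritize_cnv(cnv(5000, 25000), pair, ref0, exons, cfg)$fires)
  # gain with one breakpoint beyond the transcript -> rejected
  r <- prioritize_cnv(cnv(15000, 35000, "gain"), pair, ref0, exons, cfg)
  expect_false(r$fires)
  expect_equal(r$reason, "gain_breakpoints_outside_transcript")
  # gain fully inside the transcript -> fires
  expect_true(prioritize_cnv(cnv(12000, 26000, "gain"), pair, ref0, exons,
                             cfg)$fires)
  # loss at reference frequency 0.002 in a monoallelic gene (< 0.001 rule)
  ref <- data.frame(contig = "1", start = 5000L, end = 25000L,
                    type = "loss", frequency = 0.002)
  r <- prioritize_cnv(cnv(5000, 25000), pair, ref, exons, cfg)
  expect_false(r$fires)
  expect_equal(r$reason, "reference_frequency")
  # the same frequency is acceptable for a biallelic gene (< 0.005)
  pair_ar <- mk_pair("G1", moi = "biallelic", lof = TRUE,
                     gstart = 10000L, gend = 30000L)
  expect_true(prioritize_cnv(cnv(5000, 25000), pair_ar, ref, exons,
                             cfg)$fires)
  # a CNV far from the coding region (even padded by 2 kb) is rejected
  r <- prioritize_cnv(cnv(40000, 70000), pair, ref0, exons, cfg)
  expect_false(r$fires)
  expect_equal(r$reason, "no_coding_overlap")
  # non-LoF gene: the rule never applies
  pair_nl <- mk_pair("G1", lof = FALSE, gstart = 10000L, gend = 30000L)
  expect_false(prioritize_cnv(cnv(5000, 25000), pair_nl, ref0, exons,
                              cfg)$fires)
})
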
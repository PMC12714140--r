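# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Leftmost minimal representation of a variant, by enumeration of every
# equivalent (pos, ref, alt) triple against a short reference sequence.
# A representation is admissible when both alleles are nonempty, it
# reconstructs the same alternate sequence, its trailing bases differ, and
# its leading bases differ unless trimming one would empty an allele
# (the VCF anchor-base case). The oracle returns the admissible triple with
# the smallest position, then the shortest ref allele.
oracle_normalize <- function(ref_seq, pos, ref, alt) {
  L <- nchar(ref_seq)
  alt_seq <- paste0(substr(ref_seq, 1, pos - 1), alt,
                    substr(ref_seq, pos + nchar(ref), L))
  La <- nchar(alt_seq)
  best <- NULL
  for (p in seq_len(L)) {
    if (substr(ref_seq, 1, p - 1) != substr(alt_seq, 1, p - 1)) break
    for (rlen in 1:(L - p + 1)) {
      suffix_len <- L - (p + rlen - 1)
      alen <- La - (p - 1) - suffix_len
      if (alen < 1) next
      if (substr(ref_seq, p + rlen, L) !=
          substr(alt_seq, p + alen, La)) next
      r <- substr(ref_seq, p, p + rlen - 1)
      a <- substr(alt_seq, p, p + alen - 1)
      if (r == a) next
      if (substr(r, rlen, rlen) == substr(a, alen, alen) &&
          ((rlen > 1 && alen > 1) || p > 1)) next
      if (rlen >= 2 && alen >= 2 &&
          substr(r, 1, 1) == substr(a, 1, 1)) next
      cand <- list(pos = p, ref = r, alt = a)
      if (is.null(best) || p < best$pos ||
          (p == best$pos && rlen < nchar(best$ref))) best <- cand
    }
  }
  best
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# random VCF-style variant against a reference string (1-based offset 1)
rand_raw_variant <- function(ref_seq) {
  L <- nchar(ref_seq)
  type <- sample(c("snv", "ins", "del"), 1)
  if (type == "snv") {
    pos <- sample(1:L, 1)
    rb <- substr(ref_seq, pos, pos)
    list(pos = pos, ref = rb, alt = sample(setdiff(c("A", "C", "G", "T"),
                                                   rb), 1))
  } else if (type == "ins") {
    pos <- sample(2:(L - 1), 1)
    rb <- substr(ref_seq, pos, pos)
    list(pos = pos, ref = rb,
         alt = paste0(rb, rand_seq(sample(1:3, 1))))
  } else {
    k <- sample(1:3, 1)
    pos <- sample(2:(L - k - 1), 1)
    list(pos = pos, ref = substr(ref_seq, pos, pos + k),
         alt = substr(ref_seq, pos, pos))
  }
}

# per-base reciprocal overlap
oracle_ro <- function(a1, a2, b1, b2) {
  ov <- length(intersect(seq.int(a1, a2), seq.int(b1, b2)))
  min(ov / (a2 - a1 + 1), ov / (b2 - b1 + 1))
}

# expand a run-length depth table into per-base depths over intervals
oracle_depths <- function(track, intervals) {
  unlist(lapply(seq_len(nrow(intervals)), function(i) {
    vapply(seq.int(intervals$start[i], intervals$end[i]), function(p) {
      hit <- track$start <= p & track$end >= p
      if (any(hit)) track$depth[which(hit)[1]] else 0
    }, numeric(1))
  }))
}

# one-row panel entry used by unit tests
mk_pair <- function(gene = "G1", moi = "monoallelic", lof = TRUE,
                    inc_only = FALSE, contig = "1", gstart = 1000L,
                    gend = 2000L) {
  data.frame(gene = gene, condition = paste0("COND_", gene), moi = moi,
             lof_mechanism = lof, inclusion_list_only = inc_only,
             contig = contig, gene_start = gstart, gene_end = gend,
             transcript = paste0("TX_", gene), tx_start = gstart,
             tx_end = gend, stringsAsFactors = FALSE)
}

mk_kb <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r$source, contig = r$contig %||% "1",
               pos = r$pos, ref = r$ref %||% "A", alt = r$alt %||% "T",
               gene = r$gene %||% "G1",
               protein_change = r$protein %||% NA_character_,
               classification = r$cls, evidence_ids = r$ev %||% "PMID:1",
               stringsAsFactors = FALSE)
  }))
  out$key <- variant_key(out$contig, out$pos, out$ref, out$alt)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_call_io <- function(sample, contig, pos, ref, alt, zyg = "het",
                       ps = NA_character_, hap = NA_integer_,
                       filter = "PASS") {
  data.frame(sample_id = sample, contig = contig, pos = as.integer(pos),
             ref = ref, alt = alt, variant_class = variant_class(ref, alt),
             filter = filter, zygosity = zyg, phase_set = ps,
             haplotype_index = as.integer(hap),
             key = variant_key(contig, pos, ref, alt),
             stringsAsFactors = FALSE)
}

mk_cand <- function(key, pos, zygosity = "het", phase_set = NA_character_,
                    hap = NA_integer_, is_cnv = FALSE) {
  data.frame(key = key, pos = as.integer(pos), zygosity = zygosity,
             phase_set = phase_set, haplotype_index = as.integer(hap),
             is_cnv = is_cnv, sources = "clinvar_like",
             stringsAsFactors = FALSE)
}
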
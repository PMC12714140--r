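# nbscreen

Automated variant prioritization for genomic newborn screening, with the
validation framework used to estimate its specificity and sensitivity.

## The problem

A population-scale newborn screening programme sequences genomes and screens
a panel of gene–condition pairs. Reviewing every candidate variant manually
does not scale, and false positives carry real harm, so an automated rule
engine first decides which small variants and copy-number variants (CNVs)
are *prioritized* — flagged for review by a clinical scientist. Prioritization
is not classification or reporting: it is the high-specificity funnel in
front of manual review.

`nbscreen` implements that funnel for users building or evaluating such
pipelines:

* **Universal filters** — caller PASS status, supported contigs (1–22, X),
  and a curated exclusion list (artefacts, low-penetrance alleles,
  out-of-scope conditions) that always wins over every other rule.
* **Previously-reported pathogenic variants** — per-source rules over a
  ClinVar-like knowledge base (≥ 1 P/LP and ≤ 1 B/LB classification, with
  configurable handling of variants with conflicting interpretations of
  pathogenicity), a CVA-like database (≥ 1 P/LP), a curated commercial
  source (exact-coordinate P/LP only), and per-gene internal inclusion lists
  (PubMed-evidenced, and the *only* source for designated genes). Matching
  is by genomic coordinates and alleles, with protein-change matching where
  a source supports it (never for MNVs). Every source requires internal
  cohort allele frequency < 0.05; MNVs use the minimum frequency of their
  decomposed SNVs.
* **Predicted loss of function** — high-impact consequences on the MANE
  Select / MANE Clinical / predefined canonical transcript, in genes where
  LoF is the disease mechanism, below per-inheritance population and
  internal frequency ceilings.
* **CNV rules** — losses/gains padded by 2 kb must hit the gene's coding
  region, gains must have both breakpoints inside the transcript, and the
  call must be rare in a reference set matched at 80% reciprocal overlap
  (losses: < 0.001 dominant / < 0.005 recessive; gains: < 0.002 / < 0.01).
  2–10 kb calls need same-type SV-caller support at ≥ 50% reciprocal
  overlap to count as PASS.
* **Mode-of-inheritance gate** — monoallelic genes accept het/hom calls;
  biallelic genes require homozygosity or ≥ 2 candidate alleles, with
  read-based phasing (window ≈ 150 bp) collapsing cis pairs; unphased
  potential compound heterozygotes are prioritized for manual review.
* **SMN1** — a targeted-caller rule that prioritizes a sample when the
  inferred copy number of intact *SMN1* is 0.
* **Gene-level QC** — coverage metrics (mean, median, fraction ≥ 15×) and
  CNV callability (fraction of the gene in homology-excluded regions) drive
  a keep/exclude decision per gene: exclusion only when poor coverage
  affects the whole gene (median and mean < 30× and ≥ 95% of bases < 15×)
  or when callability is compromised in CNV-predominant genes.
* **Evaluation** — sample-level specificity (fraction of screened samples
  with *no* prioritized variant), Wilson score intervals, two-proportion
  tests, sensitivity on diagnostic-case cohorts, a sweep over the five
  conflicting-interpretation scenarios, and co-occurrence classification of
  compound-het pairs.
* **Synthetic cohorts** — a deterministic generator that plants every rule
  category (reported-pathogenic, pLoF, CNVs, conflicting classifications,
  excluded artefacts, cis/trans/unphased compound hets, hemizygous X, …)
  with exact carrier counts and emits VCFs plus a truth table, so the whole
  engine is testable without controlled-access data.

The core statistic of the evaluation layer is the Wilson score interval for
a binomial proportion p̂ = k/n:

    ( p̂ + z²/2n ± z·√( p̂(1−p̂)/n + z²/4n² ) ) / ( 1 + z²/n )

which is well behaved for the near-1 proportions typical of screening
specificity.

## Worked example

```r
library(nbscreen)

## evaluation statistics from cohort counts: 1,289 of 34,410 screened
## samples carried a prioritized variant
specificity(1289, 34410)
#> [1] 96.254
round(100 * wilson_ci(34410 - 1289, 34410), 2)
#>   low  high
#> 96.05 96.45
two_proportion_test(12, 1362, 117, 34410, continuity = FALSE)
#> [1] 0.001086919

## a synthetic screening cohort with planted variants of every category
spec  <- sim_spec(seed = 42, n_samples = 200)
kb    <- generate_knowledge(spec)
cc    <- generate_cohort(spec)
calls <- run_cohort(cc$cohort, kb, annotations = cc$annotations)
verify_truth(cc$truth, calls)$agreement   # every planted expectation honoured
#> [1] 1

rep <- evaluation_report(cohort_result(calls, n_samples = 200))
rep[, 4:6] <- round(rep[, 4:6], 2)
print(rep, row.names = FALSE)
#>              source unique_variants flagged_samples specificity ci_low ci_high
#>        clinvar_like              11              45        77.5  71.23   82.74
#>            cnv_plof               4              16        92.0  87.40   95.02
#>  curated_commercial               1               6        97.0  93.61   98.62
#>            cva_like               1               4        98.0  94.97   99.22
#>  internal_inclusion               1               6        97.0  93.61   98.62
#>                plof               1               6        97.0  93.61   98.62
#>                smn1               1               2        99.0  96.43   99.73
#>                 all              20              69        65.5  58.68   71.74
```

The synthetic cohort plants carriers at rates of a few percent per category
— far denser than a real screening population — so its specificity is
deliberately low; what matters is that the flagged set matches the
generator's truth table exactly, per source and per zygosity rationale.

The same pipeline runs from a shell:

```sh
exec/nbscreen simulate   --seed 42 --n-samples 200 --out fixtures
exec/nbscreen prioritize --vcf-dir fixtures/vcf --panel fixtures/knowledge/panel.tsv \
    --exons fixtures/knowledge/exons.tsv --knowledge fixtures/knowledge/knowledge.tsv \
    --exclusion fixtures/knowledge/exclusion.tsv \
    --internal-af fixtures/knowledge/internal_af.tsv \
    --cnv-dir fixtures/cnv --smn fixtures/smn.tsv --out prioritized
exec/nbscreen evaluate   --report prioritized.tsv --n-samples 200 --out evaluation
```

Every command writes a `*.manifest.json` embedding the full threshold
configuration and input digests.

## Scope

The package consumes aligner/caller output (VCFs with annotations); it does
not align reads, call variants, or compute annotations, and it does not
classify prioritized variants — in the screening workflow that remains the
job of the clinical scientist the engine feeds.
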
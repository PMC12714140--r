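---
title: "Variant prioritization for newborn screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant prioritization for newborn screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbscreen)
```

## The screening model

`nbscreen` models the decision problem at the front of a genomic newborn
screening programme: given one genome's small-variant and CNV calls and a
panel of gene–condition pairs, which calls should a clinical scientist look
at? The engine is a composition of deterministic rules; there is no fitted
model, so validity rests on (i) the rules being implemented exactly as
specified and (ii) measurable specificity/sensitivity on cohorts. The
package therefore ships its own validation framework and a synthetic-cohort
generator whose truth tables make every rule branch testable.

A call is prioritized when it survives, in order:

1. **Universal filters.** Caller PASS status; contigs restricted to 1–22
   and X (mitochondrial and alternate contigs are never assessed); absence
   from the exclusion list. Exclusion is checked by exact
   coordinate-and-allele match on normalized representations and takes
   precedence over every prioritization source — this invariant is
   property-tested.
2. **Candidate generation.** Per gene–condition pair, a small variant
   becomes a candidate if any per-source rule for previously-reported
   pathogenic variants fires, or the predicted-loss-of-function rule fires;
   a CNV if the CNV rule fires. A candidate records all firing sources, so
   per-source counts can be reported later from a single run.
3. **Mode-of-inheritance gate.** Applied per gene to the candidate set of a
   sample, resolving zygosity rationale and potential compound
   heterozygosity (below).
4. **Companion flags.** Prioritized variants configured as triggers (e.g.
   one component of a complex allele whose partner is itself excluded)
   carry the sample's genotype for each companion, including "absent", so
   the reviewer can check the combination manually. Flags never alter
   prioritization.

### Variant identity

All matching — knowledge bases, exclusion and inclusion lists, frequency
references — is by genomic coordinates and alleles. That is only well
defined on a canonical representation, so every variant is normalized to
its minimal left-aligned form (shared suffix/prefix bases trimmed, indels
shifted left through repeat runs, one shared anchor base kept, VCF style).
Both sides of every lookup are normalized; whether the original pipeline
normalized its list entries is not documented, so normalizing both sides is
this package's choice — it makes matching insensitive to caller dialect.
Normalization is idempotent and is tested against an independent oracle
that enumerates all equivalent representations and picks the leftmost.
Left-shifting needs reference context; it is accepted as an optional
argument, and only indels inside repeat runs require it. At the extreme
edge (a run touching position 1 of a contig) the anchored representation at
position 1 is kept as minimal.

Multi-allelic records are split before any rule runs, because all matching
is per-allele. MNVs (equal-length multi-base substitutions) are kept as
units for matching but decomposed into SNVs for frequency lookups: the
filter compares the *minimum* allele frequency of the decomposed variants,
so one common component does not mask a rare one. Protein-change matching
is disabled for MNVs, as their protein consequence is not compositional.

### Per-source rules and conflicting interpretations

Four knowledge-base sources are modelled, each with its own eligibility
rule (ClinVar-like aggregation; CVA-like ≥ 1 P/LP; curated-commercial
exact-coordinate P/LP; internal inclusion lists, which for designated genes
*replace* all other sources). A key design question is what to do with
variants under **conflicting interpretations of pathogenicity (CIP)**. The
package formalizes the five scenarios as follows: a key is conflicting when
its records span at least two of the categories {P/LP, VUS, B/LB};
non-conflicting pure-P/LP keys are always eligible; the scenarios then
admit conflicting keys under progressively weaker conditions (`none`, then
`p_and_no_b`, `p_and_le1_b` (default), `le1_b`, `all`). Two properties
follow by construction and are tested: the default scenario is exactly
"≥ 1 P/LP and ≤ 1 B/LB", and the scenarios form a containment chain, so
flagged-sample counts are monotone along the sweep.

### Compound heterozygosity and phasing

Biallelic conditions need two hit alleles. Short-read phasing is only
trustworthy locally, so the gate trusts a phase assignment only when two
heterozygous candidates share a phase set *and* lie within the phasing
window (default 150 bp, configurable). Such a pair on the same haplotype
collapses to one allele (and alone is not prioritized); on opposite
haplotypes it is a confirmed trans pair; everything else is "potentially
compound heterozygous" and *is* prioritized — the programme's stance is
that unresolvable phase goes to manual review rather than being dropped.
Variants sharing a phase set but farther apart than the window are treated
as unphased even though the caller nominally phased them. A homozygous
candidate counts as two alleles, so a co-occurring het is emitted as its
potential partner. Heterozygous CNV losses may pair with heterozygous small
variants (config flag, default on; the underlying policy is not documented
in the source material, so it is explicit configuration). X-linked genes
accept hemizygous calls alone; heterozygous calls in X-linked genes are
gated like biallelic candidates. No sex model is applied: hemizygosity is
taken from the genotype calls themselves.

### CNV rules

CNVs below 2 kb are out of scope. Calls of 2–10 kb count as PASS only with
same-type SV-caller support at reciprocal overlap ≥ 0.5; larger calls keep
the CNV caller's own filter status. Reciprocal overlap is
min(overlap/len(A), overlap/len(B)) on 1-based inclusive intervals, tested
against a per-base counting oracle. The prioritization rule requires
overlap of the ±2 kb-padded call with the gene's coding region — taken as
the union of coding exons of the reference transcript, or the transcript
span for noncoding genes, a choice this package fixes since "coding region
of the gene" does not name a transcript — plus, for gains, both breakpoints
inside the transcript, and a reference-set frequency (matched at 80%
reciprocal overlap, maximum over matches) below per-type, per-inheritance
ceilings.

### Transcript selection for pLoF

Among a variant's annotations in the gene, the assessed transcript is
chosen by flag rank (MANE Select, MANE Clinical, predefined canonical),
then longest coding sequence, then lexicographic transcript id — the last
two being deterministic tie-breaks this package fixes. A variant with no
annotation on a flagged transcript is ineligible for the pLoF rule. The
high-impact consequence set defaults to {stop_gained, frameshift, splice
acceptor/donor, start_lost, stop_lost, transcript_ablation} and is
configurable, since "high impact" is a convention rather than a fixed list;
an annotation whose impact field says `high` is honoured either way.

## Tunable parameters

All policy values live in one configuration object (`nbs_config()`) and are
echoed into every run manifest. The load-bearing ones:

| parameter | default | meaning |
|---|---|---|
| `internal_af_max` | 0.05 | internal-cohort AF ceiling for reported variants (guards against submission errors and artefacts) |
| `plof_af_max` | 1e-4 / 5e-3 | pLoF AF ceiling, monoallelic / biallelic (applied to every population tier) |
| `plof_internal_af_mode` | `plof_threshold` | whether pLoF internal AF uses the per-MOI ceiling or the 0.05 ceiling |
| `cnv_loss_af_max` | 0.001 / 0.005 | CNV loss frequency ceiling, monoallelic / biallelic |
| `cnv_gain_af_max` | 0.002 / 0.01 | CNV gain frequency ceiling |
| `cnv_recip_overlap` | 0.8 | reciprocal overlap for reference matching |
| `cnv_merge_recip_overlap` | 0.5 | reciprocal overlap for SV support of 2–10 kb calls |
| `cnv_flank_bp` | 2000 | CNV padding before the coding-overlap test |
| `gene_window_bp` | 50 | matching window around the gene span for reported variants |
| `phasing_window_bp` | 150 | distance over which read-based phasing is trusted |
| `cip_mode` | `p_and_le1_b` | conflicting-interpretation scenario |
| `coverage_*` | 15× / 30× / 0.95 | gene-QC exclusion thresholds |
| `callability_compromised_fraction` | 0.5 | homology-excluded fraction at which CNV callability counts as compromised |
| `wilson_z` | 1.96 | normal quantile for the Wilson interval |

The per-MOI pLoF ceilings are policy, not algorithm: the programme's actual
values live in configuration the package cannot see, so the defaults here
(1e-4 monoallelic, 5e-3 biallelic) are deliberately conservative and must
be surfaced in the manifest of any run. Likewise the internal-AF mode for
pLoF candidates defaults to the per-MOI ceilings (the stricter reading);
the 0.05 alternative is one flag away. The 50 bp matching window applies to
the gene body by default (whether the source programme pads the gene or the
transcript is not documented; both are expressible since the panel carries
both spans). Protein matching is constrained to the same gene but not the
same transcript, the laxer and safer-for-sensitivity reading. The gene-QC
callability cut-off (0.5) is not quantified in the source material at all
and is therefore configurable and logged.

## Gene-level QC

Coverage metrics (mean, median, fraction of bases ≥ 15×) are computed per
exon and pooled per transcript over the exon bases; by default QC runs on
exonic bases, since that is where the metrics' transcript framing points,
with the full-span alternative available by passing a different interval
set. The depth track is consumed as given — its read filters (MQ > 10,
BQ > 30, soft-clips removed) are provenance of the input, not recomputed.
The exclusion rule is conjunctive on purpose: a gene is lost to screening
only when poor coverage affects essentially the whole gene (median *and*
mean < 30× *and* ≥ 95% of bases below 15×), or when a CNV-predominant
gene's span is substantially homology-masked. "95% of the gene with
coverage < 15×" is read as fraction-below-15× ≥ 0.95 — the inequality
direction forced by the poor-coverage context. The decision is monotone in
depth (raising depths can never flip keep to exclude), which is
property-tested.

## Evaluation framework

**Specificity is sample-level**: 100 × (1 − flagged/n), the percentage of
screened samples with no prioritized variant. This differs from
variant-level specificity and is the operationally relevant number (it
bounds the manual-review workload). Wilson score intervals are computed in
closed form — the interval inverts the score test, and the implementation
is tested against a numerical inversion to 1e-10 and against
`stats::prop.test(correct = FALSE)`. The two-proportion test wraps
`stats::prop.test`; the uncorrected variant equals the chi-squared tail of
the squared pooled z statistic, and both continuity settings are exposed
because both appear in published screening comparisons. Sensitivity is the
percentage of case samples with at least one designated diagnostic variant
among their prioritized calls, with source masking (a study that draws its
diagnostic truth from one database must ignore that database as a
prioritization source or inflate itself). Per-gene specificity counts a
sample toward every gene it is flagged in.

## What the synthetic generator does and does not emulate

The generator builds three ~100 kb contigs with seeded random sequence, a
ten-gene panel covering every inheritance mode, rule family and the
inclusion-list-only case, and plants one variant category per gene pool per
sample. Defaults: 200 samples, per-category carrier rates of 1.5–8%
(16% for the deliberately-too-common variant), two benign background
variants per sample. These rates are chosen so that a 200-sample cohort
contains several carriers of every category — they emulate the *roles* of
the study cohorts (a control-like cohort for specificity, a diagnostic-case
cohort for sensitivity), not their scale or allele-frequency spectrum.
Carrier counts are exact (`round(rate × n)`) rather than Bernoulli draws,
so truth-table expectations hold for every seed; carriers are drawn from
per-category sub-streams keyed by the seed, so changing one category's rate
does not reshuffle the others. The internal AF reference is generated as a
*separate* control-like resource (planted pathogenic variants rare, the
high-AF plant at 0.08, novel pLoF absent), mirroring the real design where
frequencies come from a reference cohort, not from the cohort being
screened.

What passing tests on this cohort shows: every rule branch — each source,
each frequency filter, each MOI/phasing outcome, each CNV clause, exclusion
precedence, the scenario chain — fires exactly when it should on inputs in
the standard formats. What it does not show: performance on real genomes
(annotation noise, representation drift between callers, population
structure in allele frequencies, the true classification mixture of public
databases). The published cohort statistics are therefore recomputed from
the printed counts rather than re-measured; the cohorts themselves are
controlled-access.

## Numerical and degenerate-input choices

* Absent from a frequency table means frequency 0 (absent = rare); an AF
  reference with zero called alleles yields an undefined-AF sentinel that
  passes frequency filters for the same reason.
* `internal_af` counts hemizygous carriers as one allele over one called
  allele for that sample.
* Empty candidate sets, empty CNV inputs, empty cohort directories and
  annotation-less variants all produce empty results, not errors; malformed
  alleles, identity "variants", zero-length genes and zero-trial intervals
  are contract errors.
* Output ordering is fixed (contig, position, sample, key), making runs
  byte-reproducible; determinism under fixed seed is asserted down to file
  digests.
* Wilson intervals use z = 1.96 by default, matching the convention of the
  published tables; exact-quantile z is available by argument.

## Known limitations

* Annotation is consumed, never computed: consequence, impact, flags and
  protein notation must come from the upstream annotator (a VEP-style CSQ
  INFO field or a sidecar table).
* No sex-aware handling of X beyond genotype-level hemizygosity; no
  pseudoautosomal special-casing.
* Targeted-caller logic is modelled only as its decision rule (intact SMN1
  copy number 0); the copy-number inference itself is upstream.
* Breakpoint-resolution SV interpretation, repeat expansions and mobile
  element insertions are out of scope — a diagnostic variant of those
  classes will not be prioritized.
* The co-occurrence classifier consumes a local prediction table; it does
  not query any live population resource.
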
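---
title: "Calling imprinted genes from reciprocal crosses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling imprinted genes from reciprocal crosses: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintcall)
library(dplyr)
```

## The statistical model

The endosperm arises from fertilisation of the homodiploid central cell,
so it carries two maternal genomes and one paternal genome. Under
unbiased biallelic expression the expected maternal share of transcripts
is therefore 2/3, and that — not 1/2 — is the null hypothesis throughout
this package.

For a gene with `m` maternal and `p` paternal informative reads in one
cross, `binom_onesided()` computes the exact binomial tail

\[
p_{\mathrm{mat}} = P(X \ge m), \quad X \sim \mathrm{Bin}(m+p,\ 2/3),
\]

and the analogous paternal tail with success probability 1/3. No normal
approximation is used; the counts here are small enough that exactness
matters and costs nothing.

Reciprocal crosses (A×B and B×A, mother named first) are the crux of the
design: a parent-of-origin effect must reproduce in both directions,
whereas an accession (strain) effect flips. The two per-cross p-values
combine through the distribution of the second-order statistic: for
independent uniform p-values, \(P(\max(P_1,P_2) \le x) = x^2\), so

\[
p_{\mathrm{joint}} = \max(p_1, p_2)^2
\]

is itself a valid, conservative p-value that demands consistency in both
crosses. Because binomial p-values are discrete and stochastically larger
than uniform under the null, the combination is conservative; the
acceptance suite measures the realised type-I rate at about 3% for a
nominal 5% under the study's depth (~50 informative reads per gene).

Genes are ranked by joint p-value and selected by false discovery rate,
`q = p·n/i` at rank `i` of `n`. The raw formula is not monotone in `p`,
so `fdr_select()` applies the standard step-up monotonisation (cumulative
minimum from the largest rank, clipped at 1) and reports both `q_raw` and
the monotone `q`; selection uses the monotone value so that a q-threshold
is consistent, and tied p-values share the smaller q. The suite checks
this against `stats::p.adjust(method = "BH")` on a thousand random
vectors. The maternal and the paternal direction are each tested over the
same gene universe — all genes with at least one informative read in both
crosses; no additional depth filter is imposed at this stage, because
expression-level filtering is a separate, later concern.

## The matching contract

Reads are assigned to parental haplotypes through allele-specific SNP
windows: for each biallelic SNP between the accessions, the 71-nt
reference window (SNP ± 35 nt) is the A-allele window, and the same
sequence with the centre base replaced by the alternate allele is the
B-allele window. With 36-nt reads this width has a useful property: a
read fully contained in a window always covers the centre, so any
full-length match is allele-informative unless sequencing errors hit the
discriminating base.

`assign_reads()` evaluates full-length ungapped alignments at every
offset of every window in both orientations, tolerating at most two
mismatches (`N` counts as a mismatch; qualities are ignored). The
exhaustive scan *is* the contract — there is no heuristic index that
could diverge from it — and the test suite holds it against an
independent pure-R implementation on ten thousand read/window pairs.
Ambiguity is resolved conservatively:

* ties between the two alleles of one SNP → `allele_ambiguous` (the read
  does not discriminate);
* ties among SNPs of one gene, same allele → counted once for that gene
  (one molecule, one count, even where SNPs are dense);
* ties among SNPs of one gene but different alleles →
  `allele_ambiguous`;
* ties touching more than one gene, or a gene and an intergenic SNP →
  `locus_ambiguous`.

Windows overlapping two or more genes (gene span taken start-to-end,
ignoring exon structure) are discarded before matching; windows within
35 bp of a chromosome end are discarded as truncated. Coordinates are
0-based half-open internally; GFF3 and the SNP table are 1-based on disk,
BED-like TE tables 0-based.

## Accession-dependent imprinting

Some alleles are imprinted only when inherited from one accession. After
calling, `classify_accession_dependence()` compares, within each
accession X, the expression of the maternal X alleles against the
paternal X allele across the two crosses — for accession A, the maternal
count from A×B versus the paternal count from B×A. A MEG is "imprinted in
X" when that ratio reaches 5; a PEG when the paternal/maternal ratio
reaches 3. Both accessions → `reciprocal`; one → `A_only` / `B_only`.
Counts are first scaled per million gene-assigned reads per cross
library, because the two libraries generally differ in depth; the scaling
is optional (`library_norm = FALSE`) for pre-normalised inputs. Zero
denominators with positive numerators count as infinite ratios; 0/0 is
`not_applicable`.

The simulator's accession-dependent classes follow the same geometry: an
A-only MEG has its paternal A allele silenced, so its biased cross is
B×A; an A-only PEG has its maternal A alleles silenced, so its biased
cross is A×B; the other cross sits at the 2:1 null. One arithmetic
constraint is worth recording: with the unbiased cross at the null, the
within-accession PEG ratio is bounded by \((1/3)/f\) where \(f\) is the
biased cross's maternal fraction, so the 3-fold rule is attainable only
for \(f < 1/9\). The generator therefore defaults to near-complete
silencing for accession-dependent PEGs
(`maternal_fraction_acc_peg = 0.05`) — consistent with the nearly
exclusive parental expression such genes show in validation assays —
while reciprocal PEGs default to a milder 0.20.

## Tissue filters

Whole-seed RNA mixes endosperm, embryo, and the maternal seed coat, and
female gametophytes contribute long-lived maternal RNAs. Four filters,
all driven by a genes-by-tissues signal-log-ratio (SLR) matrix with a
tissue sidecar (compartment and seed stage per tissue), separate genuine
endosperm candidates:

* **Endosperm preferred** (required for MEGs): at some seed stage, the
  best endosperm-domain SLR is at least 5× the same-stage seed-coat SLR
  — relaxed to 3× for weakly covered genes (total assigned reads in
  [10, 30]) — and all vegetative SLRs are below 5 (strict). Comparisons
  are per stage, then the best stage wins; the 5× is applied to the SLR
  values themselves, literally multiplicative, with both folds
  configurable so a log-difference reading can be tested. A seed-coat
  SLR at or below zero makes the ratio ill-defined; the clause then
  passes when the endosperm SLR reaches the vegetative ceiling (5).
* **Endosperm expressed** (required for PEGs): any endosperm-domain SLR
  strictly above 4.5.
* **Embryo predominant** (excludes from PEGs): the embryo inherits
  alleles 1m:1p, so embryo-dominated genes mimic paternal bias; a gene
  is flagged when its embryo maximum strictly exceeds its endosperm
  maximum over the matched seed stages. The exclusion rule is declared
  here as a simple threshold comparison and is configurable via
  `margin`.
* **Maternal carryover** (reported, never excluding): expression lower
  in 4 DAP seeds than in stage-12 flowers suggests stored gametophytic
  RNA rather than endosperm transcription. The flag travels with the
  candidate table, mirroring how such genes are reported rather than
  removed.

All boundaries are strict exactly where stated, and the boundary
behaviour (7.5 vs 7.49, 4.5 vs 4.51, equal maxima) is pinned by tests.

## Genome context and profiles

`enrichment_test()` pairs the upper-tail hypergeometric probability with
a genuine permutation test (samples drawn without replacement,
`(1 + #\{X^* \ge x\})/(n_{perm}+1)`); the two must and do agree within
Monte-Carlo error. The population for TE and homolog enrichment is the
set of *detectable* genes — genes with at least one informative read —
not the whole annotation. "Vicinity" is a 2-kb flank on either side of
the gene span (matching the 2-kb flanks of the metagene profiles),
configurable via `vicinity_bp`; TEs overlapping the gene body count as
in-vicinity with distance 0, and 5′/3′ distances are signed
(transcription direction positive) from the nearest TE edge to the
strand-aware start/stop.

`scan_clusters()` slides 50-gene windows (step one gene, never across a
chromosome boundary, trailing partial windows dropped) and counts flagged
genes. The null distribution pools per-window counts from permutations
that place the same number of flags uniformly over all genes; a window is
significant when the pooled-null upper tail falls below `alpha`, and
overlapping significant windows merge into clusters. Pooling across
windows is a design choice — per-window nulls would be identical anyway
under exchangeability, and pooling stabilises the tail at moderate
permutation counts (default 1,000).

`splicing_chisq()` guards against parent-specific splicing masquerading
as imprinting: if both alleles are processed identically, the m:p ratio
is homogeneous across a gene's SNPs. The Pearson statistic on the 2×k
per-SNP table gets its p-value from tables drawn under fixed margins
(`stats::r2dtable`), with the add-one estimator so p is never zero; the
suite cross-checks it against `chisq.test(simulate.p.value = TRUE)` and
the asymptotic tail on large balanced tables.

Metagene profiles use 60 bins: 20 fixed 100-bp bins across each 2-kb
flank and 20 body bins of 5% gene length. Body bin `i` spans offsets
`[floor((i-1)L/20), floor(iL/20))` — the floor partition is declared
canonical here because it tiles any gene length exactly, which the tests
verify; genes shorter than 20 bp cannot form the partition and are
rejected. Minus-strand genes are mirrored so bin 1 is always 5′.
Positions without data are excluded from bin means rather than imputed as
zero — bisulfite coverage gaps must not deflate methylation levels — and
flank bins beyond a chromosome end simply have no data. Group profiles
average per-bin over the genes that have data in that bin and report the
TSS reference line as the mean first-body-bin signal of a background gene
set.

## The simulator as study design

`simulate_bundle()` generates everything the pipeline consumes under one
seed: random chromosomes; non-overlapping gene models (~1.5 kb, 1–3
exons) with introns in the annotation; exonic biallelic SNPs at a Poisson
mean of 7 per gene (floor 1) — only exonic SNPs can intersect transcript
reads, which is why the placement is restricted; unspliced 36-nt
single-end unstranded reads drawn from maternal or paternal haplotype
transcripts at each gene's true maternal fraction, with independent
per-base substitution errors (default 0.002) and read ids encoding the
ground truth; TEs around genes at a Poisson density; and an SLR matrix in
which truth-imprinted genes satisfy the filters they must pass while
"decoy" unbiased genes each violate exactly one filter clause (value
ranges are kept strictly off the 5×/3×/4.5 boundaries so every intended
outcome is deterministic).

Default conditions are the study conditions: null maternal fraction 2/3,
MEGs at 0.98, PEGs at 0.20, read length 36 ≤ the 71-nt window. The
default library size, 12,000 reads per cross over 40 genes, follows from
informativeness: with ~7 SNPs in a ~1.5-kb transcript, about 17% of reads
overlap a SNP window, so 300 reads/gene/cross yields ≈50 informative
reads per gene and cross — the depth at which the maternal tail
\((2/3)^n\) has real resolving power. Large statistical runs (calibration
and recovery at 2,000 genes, ~50 reads each) use the count-level sampler
`simulate_allele_counts()`, which draws the count table directly from the
truth fractions; the read-level path is exercised end to end on the
40-gene bundle. These problem sizes are the package's own choices and are
what the test suite and `scripts/acceptance.R` run.

What the simulator does *not* emulate: spliced reads and splice-site
polymorphism, indels, paired ends, strandedness, base-quality error
profiles, PCR duplicates, mapping bias from repetitive sequence, or
correlated expression between neighbouring genes. Passing tests therefore
demonstrate the correctness of the statistical machinery and the matching
contract under clean single-base polymorphism — not robustness to
alignment artefacts in real libraries, which would need dedicated
benchmarking.

## Numerical and degenerate-input conventions

* `m + p = 0` genes are untestable and excluded (an error when tested
  directly); genes observed in only one cross are excluded from calling
  with a log message.
* A gene significant in both directions is set to `none` with a warning
  — possible only pathologically.
* Monte-Carlo p-values always use the `(1 + t)/(n + 1)` estimator, so no
  permutation p is ever exactly zero; statistic ties count for the tail
  (with a 1e-9 tolerance in the splicing test).
* All randomness flows from explicit seeds: the generator derives its
  genome/read/SLR streams from `rng_seed`, and every Monte-Carlo
  function takes a `seed` argument that temporarily scopes the RNG
  (leaving the session RNG untouched).
* Reruns of `run_imprinting_pipeline()` with an identical configuration
  reproduce byte-identical outputs; the manifest records configuration
  and MD5 checksums.

## Known limitations

Single library per cross direction: no replicate-aware or overdispersed
(beta-binomial) model is fitted, so biological variance beyond binomial
sampling is unmodelled — the joint-max combination absorbs some of this
conservatively. The matcher is exhaustive and therefore quadratic in
reads × windows; it is sized for the simulated study scale, not for
hundreds of millions of reads. The embryo-exclusion rule is a declared
threshold interpretation of a step that could also be done by expression
clustering. GO terms are used as annotated, without graph propagation.
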
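---
title: "Methods: fusion screening and resistance-mechanism exclusivity"
author: "fusionscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion screening and resistance-mechanism exclusivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionscape)
```

# Background and scope

Temozolomide (TMZ) kills glioma cells through O6-methylguanine lesions,
which the enzyme MGMT repairs directly. Recurrent tumours escape TMZ in at
least three ways: an unmethylated (hence transcriptionally active) MGMT
promoter, a hypermutator phenotype arising from mismatch-repair loss, and
genomic rearrangements that fuse the intact MGMT coding sequence to another
gene's promoter and 5' untranslated region, driving MGMT overexpression
independently of promoter methylation. `fusionscape` implements the
computational analysis around that third mechanism: screening RNA-seq
fusion-caller output for MGMT rearrangements, characterising their
structure, and testing whether the three resistance mechanisms occur in
mutually exclusive patient sets across a multi-cohort landscape.

The package deliberately starts *after* read alignment and fusion calling:
its inputs are candidate tables in the split-read caller dialect, gene
models as Ensembl-style GTF, pre-tallied pileup base counts, per-patient
cohort tables, and upstream copy-number/hypermutation calls. Alignment, the
caller's internal detection, copy-number prediction and hypermutation
classification are out of scope and are consumed as inputs.

# Fusion screening

## Filtering

Candidates are removed, in a fixed precedence, when they are (1) gene pairs
also fused in normal tissue (read-through transcription), (2) fusions
involving mitochondrial genes, (3) fusions involving uncharacterised genes,
or (4) fusions of two paralogs (a frequent alignment artefact). The fixed
order makes the audit deterministic when a row matches several rules, and
the audit records exactly one reason per input row, so row accounting is
exact. Filtering is monotone and idempotent.

Neither the blacklist nor the paralog set has a canonical published source,
so both are pluggable TSV resources; the packaged defaults contain
well-known normal-tissue read-through pairs and paralog families, enough
for realistic screening tests. "Uncharacterised" has no standard
definition either; the default is a configurable set of regular
expressions for clone-derived symbols (`^LOC\d+`, `^C\d+orf\d+`,
`^A[CLP]\d{6}`, antisense `-AS\d$`, `^LINC\d+`).

## Structural annotation

A fusion junction is annotated against one representative transcript per
gene (longest CDS, ties broken lexicographically by transcript id — the
annotation source does not dictate a choice). Both breakpoints must sit on
exon boundaries in transcription order: the donor side on a last exon base,
the acceptor side on a first exon base. Anything else yields the
`unresolved` category with a diagnostic rather than an error, because
off-boundary junctions are usually caller artefacts rather than analysable
transcripts.

For resolvable junctions the annotation computes, in spliced mRNA
coordinates:

* `partnerCdsNt` — coding nucleotides the 5' partner contributes
  (0 when its contribution is entirely 5'UTR);
* `rightOffsetToStartCodon` — signed distance from the acceptor-side
  breakpoint to the acceptor ATG (positive = upstream, e.g. +12 for the
  MGMT exon-2 boundary);
* the category: a **5'UTR swap** (promoter swap) when the partner
  contributes no CDS and the acceptor CDS is intact, otherwise a chimera,
  **in frame** when `partnerCdsNt + rightOffsetToStartCodon` is divisible
  by 3.

The frame rule deserves a note. Because the MGMT-side offset (+12) is
itself divisible by 3, testing `partnerCdsNt %% 3` alone gives the same
answer for every MGMT fusion; we nevertheless implement the general sum
form, which remains correct when an acceptor breakpoint is not a multiple
of three away from the ATG (including breakpoints inside the acceptor CDS,
where the offset is negative). A protein domain of the acceptor is counted
as retained when the fused product is translated in frame and the domain's
full amino-acid range lies downstream of the junction.

# Hotspot calling

IDH1 R132 / IDH2 R172 status is determined from pileup base counts under a
strict availability rule: fewer than 5 reads over the hotspot means the
call is `NA`, regardless of allele content. The source analysis states
only that availability rule; what counts as "mutant" once the site is
callable is left open, so the package makes its thresholds explicit
configuration: at least 2 non-reference reads *and* a variant fraction of
at least 0.10 (defaults chosen as ordinary practice for RNA-seq hotspot
screening; both exposed as arguments everywhere). Calls are monotone in
the variant reads — adding variant reads can never turn a mutant call into
wildtype. Hotspots are defined by a packaged GRCh37 table with one
canonical genomic position per codon (the base at which essentially all
reported hotspot variants fall); supplying a custom table widens this to
any position set.

1p/19q co-deletion and hypermutation are products of dedicated upstream
tools and are only validated (`yes`/`no`/`NA` tokens, known patient ids)
and attached.

# Landscape and cohort statistics

Expression enters as RPKM (`counts * 1e9 / (length * libsize)`), and is
standardised *within each cohort* (sample SD, n−1) before cross-cohort
comparison, because the cohorts were sequenced under different protocols
and a per-cohort Z-score is the simplest defensible batch adjustment.
Cohorts with fewer than two values, or zero SD, give NA rather than a
misleading number.

Frequencies are tallied with assay-specific denominators — a patient never
enters a denominator for an assay they did not receive — and percentages
are rounded half-up to one decimal (base R's banker's rounding would turn
0.25 into 0.2).

The fusion frequency interval is the exact Clopper–Pearson interval in its
Beta-quantile form: lower `qbeta(α/2, x, n−x+1)`, upper
`qbeta(1−α/2, x+1, n−x)`. The method choice is deliberate: for 7 of 252
the exact interval is (1.1%, 5.6%) at one decimal, whereas Wilson gives
(1.4, 5.6) and Wald (0.8, 4.8), so only the exact interval reproduces the
reference bounds. Group comparisons use the Wilcoxon rank-sum test
(exact by enumeration of group assignments for combined n ≤ 20 — which,
unlike the textbook exact distribution, stays exact under midrank ties —
and the tie-corrected normal approximation otherwise) and the two-sided
Fisher exact test for 2×2 enrichment.

# The exclusivity bootstrap

The test statistic is the **coverage**: the number of patients carrying at
least one of the alterations under test. If mechanisms are mutually
exclusive, their observed coverage is high relative to random assignment
with the same marginal counts. Each of `nReps` (default 10,000) replicates
independently redraws, for every alteration, its positive count uniformly
without replacement; the empirical P is the fraction of replicates with
coverage *strictly greater* than observed, so a maximally exclusive
configuration gives P = 0.

Two open choices, and how they are resolved:

* **Partially assayed alterations.** Methylation-style alterations are
  measured in only a subset of patients. By default each alteration is
  permuted within its own assayed set (coverage is still counted over all
  patients); a flag permutes over all patients instead. Both spaces are
  implemented in the bootstrap and in the exact oracle, and neither is
  asserted as "the" original choice.
* **Tie handling.** Coverage is an integer, so null replicates tie with
  the observed value with non-negligible probability, and the
  strictly-greater count is anti-conservative under the null
  (P(C\* > C₀) = P(C\* ≥ C₀) − P(tie)). The result object therefore
  carries two quantities: `pValue`, the strictly-greater fraction exactly
  as defined above, and `pSmoothed = (#{C* ≥ C₀} + 1)/(nReps + 1)`, the
  standard add-one Monte-Carlo P-value, which is stochastically no smaller
  than uniform under the null and is the quantity to use for inference.
  The calibration test in the suite checks super-uniformity of
  `pSmoothed`; no such guarantee exists, or is claimed, for the strict
  fraction.

`enumerateExclusivityExact()` is an independent oracle: it enumerates the
full cartesian product of count-subsets (refusing instances beyond 10^6
joint states) and returns the exact strictly-greater probability. The test
suite checks bootstrap/oracle agreement on random small instances within
Monte-Carlo error, the monotone relationship between overlap and P, and
patient-relabelling invariance.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of (configuration, seed), and ground
truth is returned alongside every output, so pipeline recovery can be
asserted exactly.

* `genCohort()` draws a multi-cohort patient table with *exact* marginal
  counts per alteration and three overlap regimes (`disjoint`,
  `independent`, `nested`), so both the exclusive alternative and the null
  are testable. Non-assayed patients are chosen uniformly at random —
  there is no published structure for the missingness, so none is
  invented. The default conditions mirror the published cohort scale:
  252 patients; 7 fusion-positive, 27 hypermutated, 52 of 136 assayed
  promoter-hypomethylated. The cohort label proportions and the female
  fraction (0.45) are placeholders at realistic magnitudes, not published
  values.
* `genGeneModels()` builds transcript fixtures with known exon/CDS
  arithmetic, including an MGMT-like model whose exon-2 acceptor boundary
  sits a configurable 12 nt upstream of the ATG, a partner whose first
  exon is pure 5'UTR (promoter-swap donor), a partner donating exactly
  300 nt of CDS, and a minus-strand partner. The planted fusion set
  exercises all structural categories, including out-of-frame chimeras,
  so classifier recovery is informative.
* `genPileups()` plants genotypes at configurable depth law and allele
  fraction (binomial variant reads at VAF 0.5 for heterozygous mutants);
  `genExpression()` draws log2 expression as class baseline plus Gaussian
  noise, with positive shifts for fusion/hypomethylated patients and a
  negative shift for hypermutated ones, matching the direction of the
  reported expression pattern.

What passing tests on these data do **not** show: robustness to real
caller artefact spectra (the decoys are one idealised member per removal
class), to non-Gaussian expression noise or outlier libraries, to
misassigned sample swaps, or to fusions whose breakpoints genuinely fall
off exon boundaries for biological (not artefactual) reasons. Results on
real cohorts depend on the curation quality of the blacklist/paralog
resources, which the packaged defaults only sketch.

# Numerical and design notes

* Problem sizes in the suite are chosen to keep the default test run in
  about a minute: the oracle-agreement property uses 50 random instances
  at 50,000 replicates; calibration uses 1,000 null draws at 400
  replicates; the headline synthetic analysis uses the full 252-patient
  scale at 10,000 replicates.
* One master seed drives a run; the simulation writer derives per-stage
  seeds by fixed small offsets so stages stay independently reproducible.
* Chromosome names are normalised to un-prefixed ("10", not "chr10") at
  every boundary.
* GTF I/O delegates to `rtracklayer`; a light structural pre-check exists
  only to report the 1-based line number of a malformed line, which the
  importer does not provide.
* Percent rounding is half-up to one decimal everywhere a percentage is
  printed.
* Degenerate inputs have defined behaviour rather than errors where a
  pipeline should keep going: empty candidate tables filter to empty
  audits; fusion events with unknown sample ids are skipped with a
  warning; all-NA assay columns tally a zero denominator and an NA
  percentage.

# Worked example

```{r example, eval = FALSE}
dir <- tempfile("study")
sim <- simulateStudy(dir, seed = 1)
cfg <- pipelineConfig(sim[c("cohort_csv", "fusion_tsv", "gtf",
                            "pileup_tsv", "upstream_csv")],
                      outdir = file.path(dir, "out"), seed = 1)
report <- runPipeline(cfg)
report$fusions$frequency_percent   # 2.8 (95% CI 1.1-5.6)
report$exclusivity$p_value         # 0 at 10,000 replicates
```

# Limitations

The package annotates against a single representative transcript per gene;
isoform-specific fusions are out of scope. The exclusivity test treats
patients exchangeably — it does not model per-patient alteration rates, so
it answers "more exclusive than label permutation" and nothing finer.
Survival analysis is intentionally excluded; the landscape TSV is written
so standard survival tooling can consume it directly.
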
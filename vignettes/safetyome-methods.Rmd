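---
title: "Methods: evidence-based safety panels from genetics and pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-based safety panels from genetics and pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(safetyome)
library(dplyr)
```

## The problem

Drug candidates are screened against off-targets — proteins they affect
beyond the intended target — to flag hazards before in vivo studies and
to resolve unexpected phenotypes mechanistically. Which off-targets are
worth screening is the hard question: a useful panel contains targets
whose perturbation has phenotypic consequences in humans. Human genetics
(Mendelian and GWAS associations) and indication-based pharmacology both
tie targets to phenotypes directly, so a panel grounded in them should
translate better than one assembled from hit rates and legacy
experience.

This package builds such panels from tabular evidence. The pipeline
stages are:

1. **Harmonize** per-source gene–trait tables under source-specific
   filters into a deduplicated evidence table.
2. **Map** free-text traits onto a two-level phenotype hierarchy —
   system organ class (SOC) at the organ level, preferred term (PT) at
   the symptom level — with a cascaded matcher.
3. **Score** each target by evidence breadth and rescale to 0–10.
4. **Assemble** the organ-level safetyome (SOC panels above a score
   percentile cutoff) and phenotype-level PT panels (two-source rule).
5. **Prioritize** a core panel by tissue specificity and cross-species
   conservation.
6. **Validate** panels against an independent disease–gene table by
   hypergeometric over-representation and label match rates.

## Harmonization filters

Each source table carries a filter policy:

* *GWAS-like* sources keep associations with `p <= 5e-8` (genome-wide
  significance, inclusive — the boundary value is retained) and a valid
  odds ratio or beta coefficient (`effect_ok`).
* *ClinVar-like* sources drop records whose sub-source annotation is
  missing, empty, or the literal `"NA"`: an association without
  provenance cannot be audited. A missing value is treated exactly like
  `"NA"` since both denote absent provenance.
* *DisGeNET-like* sources keep only association types that constitute
  human genetic evidence (causal, germline-causal, somatic-causal,
  susceptibility, modifying mutations and genetic variation) from
  sub-sources that curate human genetics; both whitelists must hold.
* Everything else passes through.

All sources are then restricted to protein-coding genes (symbols matched
case-sensitively after whitespace trimming, as gene symbols are
case-canonical) and deduplicated on (gene, trait, source). Drug
indications from pharmacology sources enter as ordinary trait text with
evidence class `pharmacological`; only structured indications are
supported.

## The mapping cascade

Trait text is normalized (lower case, punctuation to spaces, whitespace
collapsed) and deduplicated before mapping. Stages run in a fixed order
and the first acceptance wins, so stage attribution partitions the
mapped traits:

1. **Exact / partial lexicon match.** A normalized trait equal to a
   lexicon synonym maps immediately. Otherwise substring containment is
   tried in both directions; the longest matching synonym wins and ties
   go to the lexicographically smallest concept, for reproducibility.
   The precise notion of a "partial" lexicon match is not standardised
   anywhere, so this containment rule is our own stand-in and is
   deliberately conservative. Stage-1 matches carry similarity 1.
2. **Fuzzy match** (default: token-sort normalized Levenshtein over the
   synonym lexicon). The top-ranked candidate is accepted when its
   similarity is at least `fuzzy_min_score` (default 0.85 — not forced
   by anything upstream; chosen strict to keep stage-2 precision high,
   and configurable).
3. **Embedding similarity** (default: character-trigram TF-IDF cosine
   over the lexicon). The top candidate is accepted when similarity is
   at least `embedding_threshold` (default 0.7). Whether the 0.7
   boundary itself is accepted is a genuine choice; we accept it
   (inclusive), which errs toward coverage.

Both matchers are injectable contracts — any function returning ranked
`(concept_id, similarity)` candidates can replace them, so heavier
engines (UMLS lookups, MetaMap, transformer embedders) can be plugged in
without touching the cascade. The built-in defaults are deterministic
and self-contained, which is what makes the test suite reproducible.

A concept with several PTs fans out to all of its (PT, SOC) pairs rather
than forcing one arbitrary label; that multiplicity propagates into the
links, panels and enrichment labels downstream.

## Scoring

For a target with per-source deduplicated record counts
\(c_1, \dots, c_n\), of which \(u\) are positive:

\[
\mathrm{raw} = \Big(\sum_i c_i\Big)\cdot \ln(u + 1)
\]

Occurrence across many records raises the score; the unique-source
multiplier keeps a target that recurs inside a single database from
outrunning one supported independently. We count deduplicated
(gene, trait, source) records — rather than rows or distinct phenotypes
— because that is the unit the harmonizer guarantees unique.

The cohort of raw scores is then z-scored with the population standard
deviation (the cohort *is* the population of scored targets, not a
sample), log-damped, and min-max rescaled:

\[
z = \frac{\mathrm{raw} - \mu}{\sigma},\qquad
\ell = \ln(z - \min z + 1),\qquad
\mathrm{scaled} = 10\,\frac{\ell - \min \ell}{\max \ell - \min \ell}.
\]

Every step is strictly monotone, so the scaled ordering equals the raw
ordering; the cohort minimum lands at 0 and the maximum at 10 exactly.
Percentile ranks are computed from the scaled score with the
strictly-below convention (ties share a rank; the minimum is 0).

```{r}
scale_scores(tibble::tibble(gene = c("g1", "g2", "g3"), raw = c(0, 5, 10)))
```

Note the midpoint lands above 5: the log step compresses the upper tail.

**Degenerate cohorts** (one target, or all raw scores equal) get scaled
10 and percentile 0, with a warning. Uniform evidence should not be
silently zeroed; 10 records the fact that every target sits at the
cohort maximum, while percentile 0 is forced by the strictly-below rank
definition.

**Granularity.** The default is one global score per gene. A per-SOC
variant (`score_targets(by = "soc")`) recomputes counts from distinct
(gene, PT, source) links within each SOC and normalizes within the SOC
cohort; the percentile-cutoff sweep uses it so each organ class is
filtered on its own score distribution, which mirrors filtering targets
from each SOC by their percentile. Both modes are available because the
choice is genuinely underdetermined; global is the default elsewhere.

## Panels

The organ-level safetyome drops SOCs that do not name a specific organ
(the exclusion set is vocabulary-specific configuration — we hard-code
no vocabulary strings) and keeps genes whose percentile rank is **at
least** the cutoff (default 50). Inclusive retention keeps the
50th-percentile group in at the default cutoff. PT panels apply the
two-source confidence rule: a gene joins a phenotype panel only when at
least `min_sources = 2` distinct databases support that gene–PT pair,
counted after multi-PT fan-out, per (gene, PT) — fan-out copies of one
record inherit its sources, so counting after fan-out neither
manufactures nor destroys support. Panels serialize to GMT with the
level, source-count range and evidence classes in the description field.

## Prioritization

Tissue specificity uses the Tau index over a gene × tissue expression
matrix, \(\tau = \sum_i (1 - x_i/x_{\max})/(N-1)\): 1 for single-tissue
expression, 0 for uniform, undefined (NA, with a warning) for all-zero
vectors. Conservation takes, per gene, the median across species
(mouse, rat, dog) of sequence identity and of the 0/1
ortholog-confidence call, converts each median to a percentile rank
across genes in [0, 1], and averages the two ranks. Ranking before
averaging — rather than averaging raw values — keeps the two categories
commensurate; the raw-average alternative would let the 0–100 identity
scale dominate the 0/1 confidence calls.

The core panel ranks targets by the unweighted mean of the percentile
ranks of scaled score, Tau and conservation (weights are exposed for
sensitivity analyses; the symmetric default is the simplest defensible
combination rule). Ties break by scaled score and then gene symbol, so
rankings are deterministic and the top-k prefix is independent of the
requested panel size. Genes missing Tau or conservation are ranked on
their available metrics and flagged rather than dropped. The default
panel size is 500.

## Validation

Only disease–gene rows with direct evidence enter testing. Each panel is
the query set; each disease's gene set is a term; the test is the
one-sided hypergeometric over-representation p-value on the annotated
universe (all genes with at least one direct-evidence annotation, the
convention of standard enrichment tools; a union-with-panels universe is
available). SOC-level p-values are BH-adjusted; PT-level p-values use
the more conservative Bonferroni correction because thousands of PT
terms can be tested. Significance is `p_adj <= 0.05` (configurable). PT
panels with fewer than 50 genes are excluded from testing to avoid
instability of small sets.

A result is **matched** when the disease's mapped label equals the
panel's label exactly — near-miss terms count as mismatches, which makes
match rates conservative. Diseases whose term the cascade cannot map
carry no label and are excluded from testing. The per-panel match rate
is the percentage of significant results that are matched; the mean is
over panels with at least one significant result. The cutoff sweep
rebuilds the SOC safetyome at percentiles 10–90 (step 10) and records
target counts and mean match rates per cutoff.

## The synthetic world

`generate_world()` builds everything the pipeline consumes — hierarchy,
nine source tables (seven genetic, two pharmacological; one GWAS-like,
one ClinVar-like, one DisGeNET-like by policy), a disease–gene table, an
expression matrix, an orthology table and a gene universe — from opaque
labels (`SOC_01`, `PT_0042`, `GENE0001`), with the ground truth
recorded. Defaults: 400 genes, 27 SOCs of which 5 non-organ, 6 PTs per
SOC, 3 synonyms per concept, 25 planted core genes, 12 tissues, a 0.6
multi-source rate and a 0.1 multi-PT rate. These mirror the structural
shape of real harmonization inputs (source composition, SOC count,
organ/non-organ split) at a size where the full pipeline runs in
seconds; rate parameters were fixed once at values that give panels a
realistic mixture of single- and multi-source support.

Design points worth knowing before trusting a passing test:

* **Noise is adversarial to the right stage.** Every lexicon synonym
  carries a qualifier word, and trait noise edits the longest token
  (substitution, transposition, or replacement with an out-of-lexicon
  word), so a perturbed trait cannot be rescued by substring
  containment and genuinely exercises the fuzzy and embedding stages.
* **Genes are SOC-coherent.** Each synthetic gene draws its concepts
  within a single SOC, and multi-PT concepts stay inside one SOC. This
  makes disease gene sets SOC-pure, so at zero noise every significant
  enrichment matches its panel and the SOC match rate is exactly 100% —
  which is what makes recovery testable. Real targets are pleiotropic
  across organ systems; the generator does not emulate that, so passing
  recovery tests say nothing about match rates on real, pleiotropic
  data. Cross-SOC biology must be assessed on real inputs.
* **Decoys are always present.** Filter-violating records
  (above-threshold p-values, invalid effects, `"NA"` provenance,
  non-whitelisted types, non-coding genes) are injected
  unconditionally; the zero-noise ground-truth equality therefore
  checks that filters remove exactly what they should.
* **Determinism.** All randomness flows from one seed; the same
  configuration writes byte-identical files. Dropout and noise events
  are logged so every record is derivable from truth plus noise.
* The generator makes no attempt at statistical realism of GWAS effect
  sizes or expression distributions; it emulates pipeline-relevant
  structure only.

```{r}
world <- generate_world(world_config(n_genes = 120, n_socs = 12,
                                     n_nonorgan_socs = 3, pts_per_soc = 4,
                                     n_core_truth = 10, seed = 1))
run <- run_end_to_end(world, safetyome_cfg = safetyome_config(
  excluded_socs = world$truth$nonorgan_socs, cutoff_percentile = 0))
tidy(run)
```

## Numerical choices and edge cases

* Thresholds are inclusive throughout (GWAS p-value, fuzzy and
  embedding similarity, percentile cutoff, two-source rule, adjusted-p
  significance).
* All tie-breaks are lexicographic (concept ids in the cascade, gene
  symbols in the core panel) so outputs are stable across runs and
  platforms.
* Empty inputs degrade with warnings, not errors: total dropout yields
  an empty run report; a cohort with no significant enrichments yields
  an empty match-rate report.
* The test suite exercises worlds of 60–400 genes and a 2,000-gene
  scoring cohort; these sizes were chosen so the whole suite documents
  the method's behavior in under a minute while still covering every
  stage at non-trivial scale.

## Limitations

* The built-in matchers are deliberately lightweight; mapping coverage
  on real trait corpora depends on the engines plugged into the two
  matcher contracts and on the user-supplied hierarchy, which this
  package does not ship.
* Free-text indication extraction (NLP over drug labels) is out of
  scope; only structured indications enter the pharmacology sources.
* Scores count record occurrences, so databases citing a shared
  upstream source can inflate a target's evidence; the unique-source
  multiplier damps but does not remove this.
* The validation resource may share provenance with the evidence
  sources, so match rates are an orthogonal consistency check, not an
  unbiased external validation.
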
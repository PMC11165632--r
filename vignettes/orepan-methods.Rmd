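---
title: "Methods behind orepan: pan-metagenome profiling and biosynthetic novelty in ore-forming soils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind orepan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orepan)
```

# What the package models

Mineral-deposit soils — fluorite mines in particular — combine extreme pH,
high salinity, and nutrient scarcity, and the bacteria that persist there
are prime candidates for novel secondary metabolites. `orepan` implements
the desk-scale analytical chain used to characterize such a system from
three angles:

1. **Soil geochemistry**: how strongly each anion (chloride, sulphate,
   nitrate, fluoride) is enriched over average continental-crust values.
2. **Community function**: a taxon–KO abundance matrix (KEGG orthologues
   per environment × taxon group), CPM normalization, pan-metagenome
   classification of orthologues, KEGG module aggregation, and twofold
   screens between environments.
3. **Secondary-metabolite potential**: a per-strain biosynthetic novelty
   index over predicted gene clusters, and classical molecular networking
   of tandem mass spectra.

Every stage is driven either by small text tables in standard dialects
(Bracken-style taxonomy reports, eggNOG-mapper-style annotation TSVs, BGC
tables, MGF spectra, geochemistry CSVs) or by the package's synthetic
generators, which plant a known ground truth so each stage can be verified
end to end without any download.

# Geochemistry

`fold_enrichment()` computes `observed / reference` and rounds **half-up**
to one decimal — the precision at which such multipliers are conventionally
printed (2440 p.p.m. chloride over the 145 p.p.m. crustal reference is
16.8×). Half-up is a deliberate choice over base R's round-half-to-even:
printed multipliers in the field use the conventional rule, and the choice
only matters at exact midpoints.

Censoring is first-class: a cell `"<50"` means "below a 50 p.p.m. detection
limit". Censored values never enter fold computation (`NA`, "not
computable") and never win a "highest value" flag, but they do tie as joint
*lowest* whenever their limit does not exceed the minimum uncensored value —
mirroring how elemental-analysis tables annotate their extremes. An analyte
whose every cell is censored has no defined highest value and is reported
as such.

# The taxon–KO matrix and CPM

`build_matrix()` counts, per (environment × taxon group) dataset, how many
annotated queries carry each KO. Three policies matter:

* **Multi-KO annotations** (`ko:K00001,ko:K00002`) contribute one full
  count to each KO, not a fractional split. This keeps the conservation
  invariant exact: the total of the matrix equals the total KO multiplicity
  of the kept annotation rows.
* **Excluded organisms**: rows labelled `Other` (neither Actinomycetota nor
  other bacteria) are dropped before counting.
* **Duplicate query ids** within one dataset are an error, since they would
  double-count reads.

`normalize_cpm()` computes `cpm = raw × 1e6 / mapped_total` cell-wise,
always recomputed from raw counts. When no explicit totals are supplied the
per-dataset raw-count sum is used, so each dataset's CPM column sums to
exactly one million; an explicit mapped-read total (e.g. reads mapped
against a gene catalogue) overrides this and CPM then sums to less than 1e6
by exactly the unannotated fraction. Downstream presence of a KO in a
dataset is `raw >= 1`, with no CPM floor.

`twofold_screen()` flags features whose larger/smaller ratio is **at least**
2 (the boundary is inclusive). Features positive on one side and absent (or
zero) on the other are reported as *exclusive* rather than infinitely
enriched — exclusivity is a different biological statement (taxa detected
in only one soil) and is kept separate from fold changes.

# Pan-metagenome classification

With four datasets (two environments × two taxon groups), each orthologue's
presence mask has a population count between 1 and 4:

| popcount | class    |
|---------:|----------|
| 4        | core     |
| 3        | softcore |
| 2        | shell    |
| 1        | cloud    |

A literal reading of "softcore = present in at least three" would overlap
core; the classes here are made disjoint by exact popcount, which is the
only reading under which the four published percentage shares can sum to
100. Fractions are computed over the union of the four KO sets — the
natural universe when the four sets are all that is observed.
`unique_kos()` returns the cloud orthologues of one dataset, and
`venn_partition()` tabulates all 15 disjoint regions of the four-set Venn
diagram; both are cross-checked in the tests against independent
per-element tabulation.

# KEGG module aggregation

`aggregate_by_module()` turns the matrix into percentage relative
abundances per (dataset, pathway module). The default weight is CPM
(abundance-weighted); a presence-count mode is available because
"relative abundance of orthologues" is ambiguous between the two readings.
KOs mapping to several modules are fully counted in each (the KEGG-mapper
convention) and flagged so a user can switch to fractional splitting;
unmapped KOs are pooled into an explicit `unmapped` bucket so the
percentages remain interpretable. "Exclusive" pathways of an environment
(`exclusive_pathway_proportions()`) are computed over the cloud KOs unique
to that environment's Actinomycetota dataset — the strictest reading of
environment-exclusivity; looser readings (environment-restricted shell
patterns) are computable from the partition but are not the default.

# Biosynthetic novelty (BiNI)

For a strain with `n` predicted gene clusters and per-cluster distances `d`
to the nearest gene cluster family in a reference catalogue,

$$\mathrm{BiNI} = \frac{\sum d}{n}.$$

Two interpretation choices are built in:

* The published **> 900** threshold is a per-cluster novelty *flag*, strict
  at the boundary (901 novel, 900 not), and **not** a filter on which
  distances enter the sum — strain scores below 900 are only arithmetically
  possible when sub-threshold distances are summed.
* Clusters with no available distance still count in `n` but contribute 0
  to the sum; the reported `coverage` (fraction of clusters with a
  distance) makes the effect visible instead of silently shrinking `n`.

The score is linear in the distances, and adding a cluster whose distance
equals the current score leaves the score unchanged — both are tested
properties. One distance per cluster is summed (not one per family hit).

# Molecular networking

`modified_cosine()` matches fragment peaks within a mass tolerance either
directly or after shifting by the precursor mass difference, square-root
transforms intensities, normalizes each spectrum's weight vector to unit
length, and then finds the one-to-one peak matching that **maximizes** the
score. For spectra of up to 12 peaks the matching is an exact
maximum-weight assignment (branch-and-bound over candidate pairs with a
suffix-sum bound); above that size a greedy intensity-product matching is
used. The tests assert exact agreement with an exhaustive enumeration over
all one-to-one matchings on random pairs of up to 8 peaks.

`cluster_spectra()` is a greedy consensus clustering: seed with the most
intense unassigned spectrum, absorb unassigned spectra within the precursor
tolerance whose cosine against the seed passes the threshold, merge peaks
intensity-weighted, repeat. Clusters below the minimum size (default 3
spectra, the consensus-filter reading of "minimum cluster size") are
discarded. `build_network()` then keeps edges with cosine ≥ 0.65 **and** at
least 4 matched fragment ions (the published network parameters, defaults
throughout: 0.03 Da tolerance, 0.65 cosine, 4 ions, minimum cluster size 3;
library search at 0.5 cosine / 4 peaks). No top-K edge pruning is applied
because none is stated for the original analysis.

# The synthetic generators, and what they do not emulate

The generators define the study conditions for testing:

* **KO datasets** (default 400 KOs, even 25 % class split): classes are
  assigned by largest-remainder rounding (realized fractions within
  `1/n_kos` of targets), masks drawn uniformly among the popcount-matching
  patterns, counts `1 + NB(mu = 19, size = 2)` — strictly positive and
  over-dispersed; since downstream presence is binary, any positive count
  model gives identical pan results.
* **Spectra** (default 3 families × 3 compounds × 4 replicates): fragment
  m/z live on a 0.1 Da grid (so the 0.03 Da tolerance cannot cross-match
  distinct planted fragments) inside per-family windows separated by more
  than the largest possible precursor delta — cross-family matches are
  impossible both directly and under the precursor shift, making
  planted-family recovery exact by construction at zero noise. Family-core
  fragments are high-intensity (80–100) and compound-specific peaks
  low-intensity (1–5), which keeps within-family cosines above 0.75 for
  any draw.
* **BGC tables**: cluster counts uniform in 6–42 (the span observed across
  real isolates), distances uniform in 600–1400 so both novel and known
  clusters occur; the planted per-strain score is the literal `sum(d)/n` of
  the emitted table.
* **Geochemistry**: the enriched site carries the 16.8 / 15.1 / 4.5 / 0.1
  multipliers exactly; a background site falls below detection limits so
  censored cells always occur.

What passing these tests shows is that the *chain of computations* is
correct under controlled conditions. The generators do **not** emulate real
sequencing noise, chimeric annotations, fragmentation chemistry, isotope
patterns, retention-time drift, or database incompleteness — so recovery
rates on the planted data say nothing about recall on real mine soils. The
published site-level headline numbers (e.g. a total orthologue count of
8280, the 34.4/9.4/40.4/16 pan split, or the 66 % unclassified-metabolite
rate) depend on deposited raw reads, deposited spectra, and external
database versions, and are deliberately not targets of the synthetic
conditions.

# Numerical choices and degenerate inputs

* Fold rounding: half-up, 1 decimal. Pan fractions: exact rationals over
  the union; summaries must sum to 1 within 1e-9.
* CPM conservation asserted within 1e-3 of 1e6 per dataset.
* Cosine oracle equality asserted at 1e-9; identity spectra score 1 within
  floating tolerance and match all peaks.
* Tie-breaks: strain ranking breaks score ties by ascending strain label;
  greedy clustering seeds by total ion current, a deterministic criterion.
* Degenerate inputs are loud: empty taxonomy reports warn and return empty
  profiles; all-excluded annotation tables warn and return an empty matrix;
  a KO absent from all four datasets is an error if classified; a strain
  with no distance data scores 0 with a warning and zero coverage; an
  all-censored analyte has no highest value.
* Pipeline problem sizes used by the tests and the acceptance script (400
  KOs, 36 spectra, 6 strains, 200 random pan instances, 100 random cosine
  pairs) were chosen as the smallest sizes at which every planted structure
  is non-trivially exercised.

# Reproducibility

Every generator seeds the RNG from the config seed plus a fixed
per-generator offset, so a stage re-run standalone reproduces its in-
pipeline output. `run_pipeline()` writes a JSON report whose stage
summaries are pure functions of (config, seed); identical runs produce
byte-identical input files and identical reports.
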
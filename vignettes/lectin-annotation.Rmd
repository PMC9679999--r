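---
title: "Annotating lectin specificity from glycan-microarray data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating lectin specificity from glycan-microarray data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lectinrules)
library(dplyr)
```

Lectins — non-catalytic glycan-binding proteins — are the workhorse
reagents of glycobiology, yet their specificities are usually described
only at the level of a nominal monosaccharide ("mannose-binding",
"galactose-binding"). Glycan microarrays measure a lectin's binding to
hundreds of immobilized glycans at once and make much finer annotation
possible: a predominant motif, features that are tolerated, and features
that abolish binding. `lectinrules` implements that annotation workflow
end to end: raw replicate spot fluorescence in, combined Z-scores, mined
binding rules, profile clustering, and per-lectin annotation reports out.

This vignette explains the model behind each stage, the parameters that
matter, and the choices made where the method leaves room.

## Glycan structures as rooted labelled trees

Array glycans are printed as condensed-dialect strings such as
`Galb1-4GlcNAcb1-2Mana1-3(Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAcb1-4GlcNAc-Sp12`.
`parse_condensed()` turns such a string into a rooted tree: one node per
monosaccharide (with substituents such as 3-O-sulfation stored on the
node), one edge per linkage carrying the anomer and the child/parent
carbons, rooted at the reducing end, with the printing spacer (`Sp12`)
kept as metadata rather than as a residue.

```{r}
g <- parse_condensed("Galb1-4(Fuca1-3)GlcNAc-Sp8")
g
enumerate_kmers(g, k = 2)
```

Design choices worth knowing:

* **Dialect.** Both ASCII (`b1-4`) and greek (`β1,4`) spellings are
  accepted and normalized; `Neu5,9Ac2`-style symbols are protected from
  the comma rewrite by requiring an anomer letter before a linkage comma.
* **Canonical form.** `to_canonical()` orders sibling branches by parent
  carbon and then by the serialized subtree, so the output is a pure
  function of structure; any permutation of the branches of the input
  string canonicalizes identically. This is what makes deduplication and
  byte-identical feature matrices possible.
* **Unknown linkages.** A `?` carbon in an array structure is matched
  only by a wildcard in a motif template, never by a specified carbon:
  an ambiguous structure should not silently support a specific motif.
* **Unknown decorations** are an error, not a guess: condensed-dialect
  exports vary, and a silently misread sulfate would corrupt every
  downstream feature.

## Featurization: curated motifs plus systematic k-mers

`build_feature_matrix()` combines three blocks:

1. a curated catalog of named epitopes (Lewis and blood-group antigens,
   LacNAc types, polyLacNAc runs, LacdiNAc, O-glycan cores, high-mannose
   frameworks, terminal residues, sialylation/sulfation, core fucose,
   bisecting GlcNAc, ...), scored as presence/absence;
2. every mono- and disaccharide motif (with linkage) observed in the
   library, scored as counts;
3. one-hot linker indicators — linker dependence is a real phenomenon on
   arrays, and the linker is a feature of the printed probe, not of the
   glycan.

Curated motifs are subtree templates matched by `match_motif()`, an
injective embedding counter with anchors (`terminal`, `root`,
`internal`, `anywhere`), wildcard residues/linkages, and forbidden
context (e.g. alpha-Gal is `Gala1-3Gal` terminal *without* a 2-fucose on
the inner galactose, which distinguishes it from blood group B).
Embeddings that use the same set of residues are counted once, so
template automorphisms do not double-count. The catalog ships as a CSV
config (`inst/extdata/motif_catalog.csv`) and can be replaced wholesale
with `read_motif_catalog()`; the published hand-curated feature lists of
specific studies are typically supplementary-only, so the default
catalog implements the motifs that recur in the lectin-annotation
literature and is deliberately user-replaceable. Whether systematic
disaccharide tokens should carry substituents is an open convention;
here they do (`(3S)Galb1-4GlcNAc` is distinct from `Galb1-4GlcNAc`).

## From spot fluorescence to binder calls

`process_scans()` runs a fixed stage order; each stage is exported on
its own as well.

1. **Trimmed spot average** (`robust_spot_average()`): the mean of the
   replicate spots after dropping exactly one maximum and one minimum
   (6 spots in, 4 averaged). Ties drop one instance each.
2. **Per-array Z-score** (`zscore_array()`): `(RFU − mean)/sd` across
   glycans, sample (n−1) SD, computed on raw RFU. This assumes most
   glycans on the array are not bound, so the array mean estimates the
   no-binding level. Libraries where a probe binds the majority of
   glycans violate this assumption, and the synthetic benchmark panels
   are sized so planted binders stay a minority.
3. **Exclusions** (`exclude_low_signal()`): arrays whose best glycan is
   below 1000 RFU are dropped; lectins that never reach 4000 RFU for any
   glycan at any concentration, or keep fewer than two arrays, are
   excluded. The 4000-RFU rule is applied to the trimmed averages.
4. **Stouffer combination** (`stouffer_combine()`): per-glycan Z-scores
   across the concentration series are summed and divided by the square
   root of the number of concentrations, giving the combined score Zs.
5. **Nonvarying/nonspecific flags** (`flag_nonvarying()`): a glycan above
   threshold whose fluorescence barely changes across the concentration
   series is suspect — a genuine binder follows a saturation curve,
   nonspecific sticking gives the same signal at every probe
   concentration. Glycans whose across-concentration RFU variance is
   below 10% of the maximum such variance for that lectin have their
   combined score set to the plain across-concentration average Z and
   are flagged; if the signal at the top concentration is additionally
   below 10% of that array's maximum the glycan is a nonspecific binder
   and can never be called bound. The variance is computed on signals
   (not on Z-scores, which are standardized per array and therefore
   nearly flat for every binder); "maximum variance across arrays" is
   read per lectin (the maximum over glycans); both fractions use
   strict `<`.
6. **Background subtraction** (`subtract_background()`): each glycan's
   mean combined Z across lectins is subtracted, cancelling probes that
   light up for everything. The processed matrix feeds both clustering
   and rule-mining labels.
7. **Binder call** (`call_binders()`): processed Zs at or above 1.645 —
   the one-tailed normal quantile at p = 0.05, `binding_threshold()` —
   and not flagged nonspecific. The comparison is inclusive: reaching
   the threshold counts as binding.
8. **Never-bound drop**: glycans bound by no lectin leave the analysis.

## Mining interpretable binding rules

`mine_ruleset()` extracts conjunctive rules in the style of
ensemble-rule learners: 50 bootstrap decision trees of depth one (Gini
impurity, thresholds placed half a unit above observed count values so
rules read `feature >= 0.5`), each bound-predicting root-to-leaf path
becomes a candidate rule, and candidates are kept when precision ≥ 0.3,
recall ≥ 0.1, and at least 15% of the estimators propose them (all
inclusive). Precision is the fraction of rule-satisfying glycans that
bind; recall the fraction of binders the rule covers, evaluated on a
held-out stratified 20% split (below 25 glycans the full subset is used
and recorded). If depth one yields nothing valid, depth two is tried.

Levels iterate: the glycans satisfying the level-1 rule are re-mined for
a rule that strictly improves precision, and so on until no valid rule
remains, precision reaches 1.0, or five levels are reached. When several
rules pass the filters at one level they are recorded as alternatives
(`1a`, `1b`, ...) and the top-ranked one (precision, then recall, then
support, then canonical name — the ranking is a package choice, as is
reading "improves the prediction" as strictly higher precision) defines
the next subset. The trees are authored in-package rather than wrapped
around a generic CART fitter because the extraction needs per-tree
conjunction bookkeeping and half-integer threshold placement.

```{r, eval = FALSE}
rs <- mine_ruleset(features, labels, mining_config(seed = 1),
                   lectin_id = "ECL-like")
tidy(rs)
glance(rs)
```

## Clustering and annotation reports

`cluster_profiles()` clusters lectins by `1 − Pearson r` of their
processed profiles under average linkage (UPGMA), with lexicographic tie
handling, Newick export (`export_newick()`), and a heatmap-ready
reordered matrix plus a binary bound/unbound layer
(`heatmap_export()`). Glycan-axis clustering with identical settings is
available via `margin = "glycans"`.

`lectin_report()` automates the annotation table: the mined rules are
the predominant specificity ("Prefers"); within the level-1
rule-satisfying subset every varying feature is tested for association
with binding in a two-sided Fisher exact test with Benjamini–Hochberg
adjustment — significantly enriched in binders means enhancer candidate,
in non-binders inhibitor candidate ("Inhibited by"); features present in
at least 20% of binders without a significant association are listed as
"Tolerates". Binders that satisfy no level-1 rule are grouped by their
shared curated features as candidate additional motifs. The exact-test
automation replaces a manual expert step and every rendered report says
so; matched-pair reasoning (single glycan pairs differing in one
feature) is not implemented.

## The synthetic-data generator

Because real raw array campaigns are large, proprietary in format, and
finished by expert judgment, the package validates itself on simulations
with planted ground truth:

* `generate_library()` draws unique structures from parametric templates
  — bi/tri/tetra-antennary N-glycans with optional bisecting GlcNAc,
  core fucose, sialylation and polyLacNAc; high-mannose Man3–Man9;
  O-glycan cores 1–4 on Ser/Thr; terminal-epitope probes — with a
  deterministic largest-remainder class allocation. The default mix
  (22.3% N-linked, 18.5% O-linked, remainder epitope probes) mirrors the
  composition of the standard 611-glycan mammalian array.
* `synthetic_lectin()` defines binding generatively: affinity 1 when the
  predominant motif is present, multiplied by enhancer (>1) and
  inhibitor (<1, 0 = knockout) folds; mean signal
  `baseline + max_rfu · affinity · c/(c + kd)` over a 0.1–100 µg/mL
  series (Hill coefficient 1 — the simplest saturating response);
  replicate spots get multiplicative lognormal noise (CV 0.15 by
  default, a scanner-like positive noise model; baseline 100 RFU). The
  half-saturation constant defaults to 5 µg/mL so the series brackets
  it, and each glycan draws its own constant (lognormal, `kd_sdlog` =
  0.3) because real glycans bind one lectin with a range of affinities —
  this heterogeneity is what makes signals vary across the series.
* `ground_truth()` gives the noise-free labels and the feature names a
  correct miner should recover; `two_stage_panel()` is a factorial
  benchmark (type-2 LacNAc × α2,3-sialyl cap) built so that no single
  feature coincides with the conjunction "LacNAc present and cap
  absent" — recovering the truth requires a genuine two-level rule set.

What the simulations do **not** emulate: spatial slide artifacts,
avidity/multivalency, inter-slide batch effects, concentration-dependent
aggregation, and the long-tailed signal distributions of real scanners.
A pipeline that recovers planted truth here is necessary, not
sufficient, for real-array validity.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run on 200-glycan
libraries, 3–10 lectins, 4-point concentration series and 10 replicate
seeds — sizes chosen so each property is exercised on the same order of
magnitude as one real array campaign while keeping a full run in
minutes on a laptop. Tolerances: the Stouffer implementation must match
a scalar oracle to 1e-12; rule metrics must match exhaustive counting
exactly; boundary comparisons (1.645 threshold, 0.3/0.1/0.15 validity
floors) are inclusive, while the two 10% QC fractions are strict, each
following the wording of its source convention. Planted-rule recovery is
judged against the noise-free ground truth: the miner's own held-out
estimates carry sampling noise of about ±0.04 on a 40-glycan fold,
which would otherwise dominate the check.

## Known limitations

* The condensed-dialect parser covers the CFG-style vocabulary and
  decorations (S, P, Ac); exotic decorations are rejected rather than
  guessed, by design.
* Systematic featurization stops at disaccharides; larger motifs enter
  only through the curated catalog.
* Rule p-values are not computed (the method for published rule p-values
  is unstated); rules carry precision, recall and estimator support.
* The residual step restricts each level to rule-satisfying glycans; the
  alternative reading (remove covered binders and re-mine the remainder)
  is not implemented.
* `lectin_accounting()` trusts the metadata's duplicate/exclusion
  annotations; it does not itself detect duplicated preparations from
  binding profiles (profile clustering is the tool for that).
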
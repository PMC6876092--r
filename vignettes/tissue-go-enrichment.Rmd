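---
title: "Tissue-restricted GO enrichment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-restricted GO enrichment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gotissue)
```

## The problem and the model

Over-representation analysis asks whether a gene list hits a GO term more
often than a random draw of the same size would. The answer depends
entirely on what "random draw" means — the universe. `gotissue`'s premise
is that for tissue-resolved experiments the correct universe is the set of
genes *expressed in that tissue*, not the genome: a term whose genes are
simply expressed in the tissue should not register as enrichment.

The test itself is classical. With a universe of $N$ tissue-expressed
genes, a term annotated to $M$ of them, an effective input list of $n$
background genes, and $k$ hits, the p-value is the hypergeometric upper
tail

$$P(X \ge k) \;=\; \sum_{x=k}^{\min(n,M)}
  \frac{\binom{M}{x}\binom{N-M}{n-x}}{\binom{N}{n}},$$

followed by Benjamini–Hochberg step-up adjustment across the tested terms.
The sum's upper limit is written $\min(n, M)$ rather than $M$: the omitted
terms have a zero binomial factor, so the two forms are identical, but the
truncated sum avoids evaluating degenerate coefficients. Each term in the
sum is computed as $\exp$ of a `lchoose` expression via log-sum-exp, so
p-values remain accurate down to the smallest normal double; anything
smaller is clamped to it and counted in the run's metadata.

Only the upper tail is offered — the method asks about over-representation;
depletion testing is out of scope.

## The universe: dual-threshold expressed-gene selection

A gene is *expressed in tissue T* iff, over T's $S$ samples, **both**
criteria hold:

* TPM $\ge$ `tpm_min` in at least `sample_fraction` of the samples, and
* unnormalized read count $\ge$ `count_min` in at least `sample_fraction`
  of the samples.

Defaults are `tpm_min = 0.1`, `count_min = 6`, `sample_fraction = 0.2`,
the GTEx expressed-gene convention. The TPM criterion guards against
length/depth artifacts; the raw-count criterion guards against TPM noise in
shallow libraries. The two are combined with AND — the stricter reading,
matching the GTEx eQTL gene-selection practice; an OR reading would admit
genes attested by only one measurement type. The prevalence comparison is
a real-number `fraction >= sample_fraction`, never a rounded sample count,
so with 5 samples "at least 20%" means exactly "at least 1 sample".

Raising any of the three thresholds can only shrink the background
(monotonicity), and with both value thresholds at zero the background is
the whole matrix — both properties are exercised in the test suite.

## Counting rules

* **Propagation.** A gene annotated to a term also counts for every
  ancestor along `is_a`/`part_of` edges (the true-path rule), so $M$ is
  consistent with the lineage graphs the tool draws. The field is split on
  whether $M$ should count direct or propagated annotations; propagation is
  the default here and a flag (`propagate = FALSE`) disables it.
* **Relations.** Traversal uses `is_a` and `part_of` only, the standard
  convention for enrichment tools; regulates-family edges change the
  semantics of "is annotated to" and are ignored. Obsolete terms resolve
  but never traverse; `alt_id` accessions canonicalize silently (logged).
  Cross-namespace edges are dropped so the three ontologies stay
  independent.
* **NOT qualifiers.** GAF rows whose qualifier contains `NOT` assert
  absence of function and are excluded; counting them would invert the
  test's meaning. Duplicate (gene, term) rows collapse — all counts are
  distinct-gene counts. Evidence codes are all retained by default, with
  an opt-in exclusion list (e.g. `"IEA"`).
* **The effective list.** $n$ counts input genes *after* intersection with
  the background. Eq.-consistency forces this: $k \le n \le N$ must hold,
  and a gene outside the universe cannot be a draw from it. Dropped genes
  are always reported (`dropped_genes`) so the effect is visible.
* **The FDR family.** Only terms with $M \ge 1$ and $k \ge$ `min_overlap`
  (default 1) are tested, and BH runs across exactly those terms, within
  one run (one tissue, one namespace). Terms with $k = 0$ carry $p = 1$
  and would only dilute the family. The family definition is stamped into
  the output provenance.

## Identifier spaces

Expression matrices usually carry Ensembl-style gene ids (version suffixes
are stripped on read); annotations carry UniProtKB accessions. When the two
differ, a two-column mapping table translates the background into
annotation space; background genes without a mapping are dropped from $N$
with a logged count, since they could never be hit by an annotation and
would otherwise inflate the universe.

## Determinism and serialization

Identical inputs and configuration give byte-identical outputs: rows sort
by ascending p with GO-accession tie-break, DOT nodes and edges sort by
accession, p/q print with 6 significant digits (scientific below $10^{-4}$),
and no timestamp enters any serialized file (run time is kept only in the
in-memory metadata). The TSV is exactly re-readable: integer and string
fields round-trip identically, p/q at the printed precision, and
write–read–write is a fixed point.

## What the synthetic fixtures emulate — and what they do not

The generators produce a single-namespace random DAG (a rooted tree plus
extra parents, acyclic by construction), GAF 2.2 annotations (1–5 random
direct terms per gene), and a GCT expression pair in which each tissue's
designated expressed genes sit at ×10 the thresholds in every sample of
that tissue and all other cells sit at ×0.1 — margins wide enough that the
filter test cannot hinge on float formatting. Input lists mix a chosen
fraction (`enrichment_strength`, default 0.8) of a planted term's genes
with random background genes. Default sizes — 40 terms, 200 genes, 2
tissues × 8 samples, 25-gene lists — keep a full study under a second while
leaving ~35 testable terms per run.

Two-tissue designs come in two flavours: the default bundle gives tissues
different expressed fractions (45% / 60% of the genome), so the universe
$N$ provably differs between tissues; `make_contrast_bundle()` makes the
backgrounds fully *disjoint* and spans the input list across both, which is
the cleanest demonstration that the tissue choice changes the calls — the
planted term tops the list against its home tissue and cannot even be
tested against the other, where its genes are background outsiders.

Deliberately **not** emulated: realistic expression distributions (no
negative-binomial noise, no borderline genes near the thresholds),
annotation bias (real GO is heavily skewed toward studied genes),
multi-namespace ontologies, and release-to-release annotation drift.
Passing tests therefore certify the algorithmic contracts — counting,
propagation, tail probabilities, FDR, determinism — not robustness to
noisy real-world data near the filter boundaries.

Null calibration is checked rather than assumed: with
`enrichment_strength = 0`, across 200 seeded runs, the minimum raw p falls
below 0.05 in well over the single-test rate (multiplicity across ~35
dependent tests) while runs with any BH discovery at $q \le 0.05$ stay
rare — wide sanity bands derived from the one-test lower bound and BH's
control level, not sharp quantiles, because the hypergeometric null is
discrete and the tests are dependent.

## Numerical and degenerate-input choices

* $k = 0$ returns exactly 1 — no log-space round trip.
* Empty effective input (no gene in the background) is a usage error that
  points at id mapping, the most common cause in practice; an input that
  overlaps the background but reaches no term is a valid empty result with
  a warning.
* Graph queries are iterative (explicit frontier sets), so ontology depth
  is bounded by memory, not the recursion stack.
* Cycle detection runs at parse time (topological elimination); a cycle is
  reported with an explicit witness path.
* Ties in p order deterministically by accession; BH handles ties through
  the step-up minimum, so tied raw p share an adjusted value.

## Problem sizes used in validation

The shipped validation suite enumerates all hypergeometric cases with
$N \le 12$ (3,165 cases) against brute-force subset enumeration, checks BH
against its literal definition on 1,000 random vectors, verifies the
true-path rule exhaustively on 100 random DAGs of up to 30 terms,
re-derives planted expressed-gene sets on 20 seeds, and runs the full
pipeline end-to-end on 20 independent bundles (planted-term recovery) plus
the disjoint-background contrast design. `scripts/acceptance.R` repeats
the same derivations from scratch at a user-supplied seed and writes the
resulting numbers as JSON.
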
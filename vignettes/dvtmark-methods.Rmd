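---
title: "Methods: GWAS-driven blood biomarker prioritization for DVT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GWAS-driven blood biomarker prioritization for DVT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure and its assumptions

`dvtmark` formalizes a post-GWAS gene prioritization argument as a chain of
set reductions, each implemented as a pure function over tabular inputs:

SNPs → genome-wide-significant SNPs → LD-expanded SNPs → mapped genes →
risk genes (annotation score ≥ 3) → coagulation/wound-term genes →
disease-network genes → blood biomarkers.

The underlying assumptions are the usual ones for this style of analysis:

* A catalog association row is taken at face value; no re-analysis of
  effect sizes, no conditioning, no fine-mapping. Duplicate rsIDs across
  studies are retained while counting SNPs and deduplicated only when gene
  sets are formed, so row-level counts track the catalog.
* A strong-LD proxy (r² above threshold, population-matched) carries the
  seed's association signal. LD is looked up in a packaged panel table, not
  computed from genotypes.
* A gene supported by several *independent* annotation sources (GWAS top
  hit, coding consequence, blood eQTL, enriched GO processes, immune-gene
  catalog) is more likely to matter than one supported by a single source.
  The binary scorecard treats sources as exchangeable and unweighted; this
  is deliberately simple and transparent rather than optimal.
* A practical blood biomarker must be both detectable in whole blood and
  have genetic variation acting on its blood expression (eQTL); liver-only
  factors are informative but impractical for blood-based testing.

## Tunable parameters

All thresholds live in `pipeline_config()` and are never hard-coded
downstream:

| parameter | default | units | comparison | rationale |
|---|---|---|---|---|
| `alpha` | 5e-8 | p-value | strict `<` | conventional genome-wide significance; boundary excluded |
| `top_n` | 40 | SNPs | smallest p | the top-SNP cut feeding scorecard criterion 1; its p-value line is computed, not a constant |
| `r2_min` | 0.8 | r² | strict `>` | strong-LD convention; a proxy at exactly 0.8 is excluded |
| `population` | `"ASN"` | panel label | exact match | population-specific LD structure |
| `min_score` | 3 | criteria | `>=` | a gene must carry at least three independent evidence types |
| `fdr` | 0.05 | adjusted p | `<=` | Benjamini–Hochberg control for enrichment and GO criteria |
| `min_overlap` | 2 | genes | `>=` | singleton overlaps are untested and excluded from the BH family |
| `tpm_min` | 1.0 | TPM | `>=` | the usual "expressed" floor for bulk RNA quantification |

Deterministic tie-breaking: `select_top_snps()` orders by
(p-value, chromosome order, position, rsID), so the top-N set is
reproducible even with tied p-values.

## Statistics

Over-representation uses the hypergeometric upper tail
P(X ≥ k) for X ~ Hypergeom(N, K, n), evaluated through `stats::phyper` in
log space (`log.p = TRUE`, exponentiated once) so that very small tails at
large N do not underflow; k = 0 returns exactly 1. The enrichment ratio is
(k/n)/(K/N), reported as `NA` when the expected overlap is zero.
Multiple-testing adjustment is `stats::p.adjust(method = "BH")`; the test
suite checks both primitives against independent brute-force
implementations (pmf summation with `choose()` over an exhaustive grid of
all universes N ≤ 30; a hand-written step-up rule on a thousand random
vectors), so the library calls are cross-validated rather than trusted.

The enrichment universe defaults to all genes appearing in the loaded GMT
collection — the "annotated genome" reference common to web enrichment
tools — and is configurable (e.g. to the mapped-gene background) because
the appropriate background is analysis-specific. Query genes outside the
universe are reported and dropped rather than silently inflating n.

## Design choices where the design was open

* **Criterion 1 (top GWAS genes)** is membership in the union of mapped
  genes of the top-40 SNPs. The alternative — a p-value cutoff line — is
  equivalent up to ties and less explicit.
* **Criteria 4–6 (GO)** are flagged when a gene belongs to at least one
  term of that namespace that is *significantly enriched* in the mapped
  gene set at the configured FDR. Raw term membership would flag nearly
  every gene (almost everything is annotated to something) and make the
  criteria uninformative.
* **Criterion 2 (missense in LD)** requires a `missense` consequence on
  the seed SNP or any proxy above the LD threshold mapped to the gene.
* **Network "significant link"** is direct-edge adjacency to a target
  concept, with disease and phenotype ontologies pooled ("either"
  semantics, restrictable via `sources=`): the graph carries no edge
  weights, so any scoring beyond adjacency would be invented structure.
* **Biomarker rule**: the qualitative argument "substantial blood
  expression plus blood eQTL" is formalized as the conjunction
  (blood median TPM ≥ `tpm_min`) ∧ (whole-blood eQTL present). The median
  (not the mean) is the tissue summary: it matches violin-plot central
  tendency and is robust to the long upper tails of blood expression.
* **Report design**: every stage writes its intermediate as TSV when an
  output directory is set, because the scientific argument *is* the chain
  of reductions and each link should be inspectable after the fact.
* The exported functions, `run_pipeline()` and this vignette are the
  user interface; no shell entry point is shipped, as the package's users
  drive it from R.

## The synthetic generator

`generate_bundle()` emulates all seven external resources with planted
ground truth. Gene classes receive nested evidence subsets:

* *biomarker* — top-ranked SNP, missense proxy at r² > 0.8, significant
  whole-blood eQTL, membership in enriched BP/CC/MF terms (including the
  coagulation-named terms), optional PID membership, a direct DVT edge,
  and blood-shifted expression. These are the genes the pipeline must
  recover, and only these.
* *network* decoys — enriched-term membership and a direct disease edge,
  but liver-shifted expression and no blood eQTL (the F2/F9/PROC pattern).
* *coag* decoys — in the coagulation-named terms but no disease edge.
* *risk* decoys — score ≥ 3 via enriched terms whose names do not match
  the coagulation filter.
* remaining mapped genes — at most two evidence types, below any risk
  score.

P-values are drawn log-uniform within the significant
(10⁻³⁰ … α) and non-significant (α … 1) bands: the pipeline consumes only
ranks and threshold crossings, so band membership is the only
distributional property that matters, and a genetic effect-size model
would add realism the consumers never see. Expression is log-normal per
(class, tissue) with medians of 20 TPM (biomarker blood), 0.2 TPM
(liver-class blood) and 80 TPM (liver-class liver), sdlog 0.35 — wide
margins around the 1-TPM detectability floor so that sampling noise cannot
flip a call at the test sample sizes. A single master seed derives
per-file sub-seeds deterministically; identical configuration yields
byte-identical bundles.

Two presets are provided. `"mini"` (60 SNPs, 30 genes, 8 samples/tissue)
generates and runs in well under a second and is the unit of the
multi-seed recovery tests (20 seeds) and ablation tests. `"study-scale"`
reproduces the magnitudes of the motivating study *exactly by
construction* — 689 associations, 458 significant, 4430 expanded SNPs, 334
genes, 28 risk genes, 15 coagulation-term genes, 5 network genes, 2
selected biomarkers — by allocating proxies and gene assignments
deterministically while drawing the within-band values at random. The
enrichment significance of the planted terms is a deterministic function
of the class sizes, so recovery does not depend on the seed.

What the generator does **not** emulate: real LD block structure (proxies
are independent fan-outs), catalog quirks (multi-gene cells appear only in
their clean forms), GO term overlap/DAG structure (terms are flat sets),
and correlated expression between genes. Passing the synthetic recovery
tests therefore demonstrates that the pipeline's logic, thresholds and
bookkeeping are correct — not that the biological conclusions would
survive on noisy real annotations.

## Packaged fixtures

The files under `inst/extdata/` carrying a `_synthetic` suffix are
synthetic reconstructions, not published data. The published text pins
down: the scores of 18 named genes (one at 6, two at 5, eleven at 4, and
four more placed at 3 by their presence in the 15-gene coagulation list),
the total of 28 risk genes, the three enriched process names, the exact
15-gene list, the five network genes, the blood-eQTL status of all five
(present for THBD and F5 only), the liver-dominance of F2/F9/PROC, and the
final {THBD, F5} call. Everything else — the ten remaining score-3 genes,
the per-criterion flag patterns, term memberships beyond the pinned genes,
expression values — is synthesized to be consistent with those facts, and
the acceptance checks assert only the pinned quantities.

## Limitations

* Gene symbols are matched by upper-cased string equality; alias
  resolution is out of scope, so all sources must use consistent symbols.
* No genome-build liftover; positions are treated as opaque integers.
* The LD panel is a static table; no computation of r² from genotypes.
* The scorecard weights all criteria equally; no calibration against an
  outcome is attempted.
* Counts tied to a specific catalog snapshot and LD panel release are
  reproducible only against packaged tables, not against the live,
  continuously updated services.
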
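# dvtmark

GWAS-driven prioritization of blood-based biomarkers for deep vein
thrombosis (DVT), as an offline, fully reproducible R pipeline.

## The problem

DVT — clot formation in the deep veins — has a polygenic basis, and dozens
of loci reach genome-wide significance in association studies. The question
this package addresses is the post-GWAS one: of the hundreds of associated
variants and genes, which few are *practical blood biomarkers* — genes that
are mechanistically tied to thrombosis, measurable in an easily collected
sample (whole blood), and whose genetic variation demonstrably acts on
expression there?

`dvtmark` implements the full prioritization chain as a sequence of
auditable set reductions:

1. **Significance filtering** — keep catalog associations with
   p < 5×10⁻⁸ (strict inequality).
2. **LD proxy expansion** — add variants in strong linkage disequilibrium
   (r² > 0.8, population-matched panel) with the significant SNPs, and map
   the expanded set to genes.
3. **Seven-criterion functional scorecard** — per gene, binary flags for:
   (1) membership among the genes mapped by the top-40 SNPs; (2) a missense
   variant on the seed SNP or a strong-LD proxy; (3) a whole-blood eQTL;
   (4–6) membership in a Gene Ontology BP/CC/MF term significantly enriched
   in the mapped gene set; (7) membership in the IUIS primary
   immunodeficiency list. Genes scoring ≥ 3 are *risk genes*.
4. **Over-representation analysis** — hypergeometric upper-tail test of the
   risk set against GMT collections with Benjamini–Hochberg FDR control;
   the enrichment ratio is (k/n)/(K/N) and the p-value is
   P(X ≥ k), X ~ Hypergeom(N, K, n). Genes driving the significant
   coagulation / wound-response terms are carried forward.
5. **Disease-network filtering** — keep genes with a direct edge to DVT or
   thrombophilia concepts in a gene–disease/phenotype bipartite graph.
6. **Biomarker call** — select genes with (blood median TPM ≥ 1) ∧
   (whole-blood eQTL present); liver-dominant factors drop out here.

Because the original analysis relied on live web services (association
catalog, LD annotation, enrichment, knowledge-graph, and tissue-expression
portals), every external resource is represented by a plain-text file
contract, and a first-class synthetic generator (`generate_bundle()`)
produces coherent bundles with planted ground truth so the entire pipeline
is testable with no downloads.

## Worked example

Bundled under `inst/extdata/` are small synthetic reconstructions of the
published evidence tables (see the file names' `_synthetic` suffix and the
methods vignette for exactly what is and is not transcribed). Chaining the
four downstream stages:

```r
library(dvtmark)
x <- function(f) system.file("extdata", f, package = "dvtmark")

sc   <- read_scorecard(x("scorecard_table2_synthetic.tsv"))
risk <- risk_genes(sc, min_score = 3)
length(risk)
#> [1] 28

bp  <- read_gmt(x("go_bp_fig3_synthetic.gmt"), "BP")
res <- enrich(risk, bp)
head(tibble::as_tibble(res)[, c("name", "k", "K", "ratio", "q")], 3)
#> # A tibble: 3 × 5
#>   name                                   k     K ratio          q
#>   <chr>                              <int> <int> <dbl>      <dbl>
#> 1 coagulation                           12    20  6.39 0.0000000275
#> 2 wound healing                          8    14  6.08 0.0000204
#> 3 regulation of response to wounding     7    11  6.77 0.0000234

coag <- genes_in_terms(res, bp, risk,
                       c("coagulation", "regulation of response to wounding",
                         "wound healing"))
length(coag)   # the 15 coagulation/wound genes
#> [1] 15

edges <- read_disease_edges(x("disease_edges_fig4_synthetic.tsv"))
five  <- direct_disease_genes(edges, coag)
five
#> [1] "F2"   "F5"   "F9"   "PROC" "THBD"

expr  <- read_expression(x("expression_fig5_synthetic.tsv"),
                         x("tissue_map_fig5_synthetic.tsv"))
summ  <- tissue_summary(expr, five)
eq    <- read_eqtl(x("eqtl_fig5_synthetic.tsv"))
flags <- tibble::tibble(gene = unique(eq$gene),
                        has_blood_eqtl = unique(eq$gene) %in%
                          eq$gene[eq$significant])
calls <- call_biomarkers(summ, flags, genes = five, tpm_min = 1)
calls$gene[calls$selected]
#> [1] "THBD" "F5"
```

Reading the output: 28 genes carry at least three independent lines of
functional evidence; 15 of them drive the significantly enriched
coagulation and wound-response processes; 5 of those have direct
disease-graph links to DVT/thrombophilia; and of these, only thrombomodulin
(THBD) and coagulation factor V (F5) are both detectable in whole blood
(median TPM ≥ 1) and carry a whole-blood eQTL — the other three (F2, F9,
PROC) are liver-dominant and drop out at the final call.

The same chain runs end-to-end from raw association tables via
`run_pipeline()`:

```r
dir <- tempfile()
gt  <- generate_bundle(sim_preset("mini", seed = 42), dir)
rep <- run_pipeline(pipeline_config(dir))
glance(rep)     # one-row stage summary
tidy(rep)       # per-stage counts
verify_recovery(gt, rep)   # planted truth vs pipeline output, per stage
```

`autoplot()` methods are provided for Manhattan coordinates
(`manhattan_coordinates()`) and enrichment results, and
`plot_tissue_expression()` summarizes per-tissue TPM.

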
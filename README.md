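# synletScreen

Synthetic lethality (SL) is the relationship between two genes in which the
loss of either gene alone is tolerated but the simultaneous loss of both
kills the cell. A drug pair in which each compound inhibits one partner of
an SL gene pair is therefore a rational combination therapy: the joint
inhibition mimics the double loss. `synletScreen` implements, as a tested
and reusable R pipeline, the workflow that turns this idea into concrete
drug-combination candidates for a disease area (the worked examples use
ovarian cancer):

1. **Yeast screen → human SL pairs.** Double-knockout genetic-interaction
   screens report an epistasis score ε and a p-value per gene pair. Pairs
   with ε < −0.08 and p < 0.05 (both strict, configurable) are retained as
   synthetic-lethal-like and transferred to human gene symbols through the
   union of several orthology resources, expanding one-to-many orthology to
   the full cross-product of human pairs.
2. **Network-feature classification.** Each human gene pair is described by
   a 10-component feature vector: Dice coefficients
   2|A∩B| / (|A| + |B|) of the two genes' annotation-term sets in five
   namespaces (KEGG and PANTHER pathways, a GO slim, MeSH disease terms,
   drug associations), the endpoint means of four node statistics on a
   human gene-interaction network (degree, betweenness, closeness, local
   clustering), and the shortest-path hop count. A random forest — ensemble
   size chosen by 10-fold cross-validation from a grid including 93 trees —
   is trained on known SL pairs against an equal number of negatives
   sampled between well-annotated genes outside the SL set, and predicts
   additional ("predicted") SL pairs that are merged with the
   yeast-derived set.
3. **Combination screening.** Clinical-trial records are filtered to
   late-stage (phase III/IV) interventional trials on the disease with a
   multi-drug arm; regimens are expanded to pairwise drug combinations; a
   combination *addresses* an SL pair when one drug targets one partner and
   the other drug the second partner, and no single drug in the corpus
   targets both. The same matching over all untested pairs of the same
   drugs proposes novel combinations, ranked by *annotation degree* — the
   sum of the two partner genes' disease-specific publication counts.

A seeded synthetic-data generator (`generateWorld()`, `writeWorld()`)
produces every pipeline input with planted ground truth — SL pairs that
share extra annotation and sit closer in the network, a yeast screen in
which they pass the filter, and trials that study SL-addressing
combinations — so each stage can be tested against an oracle.

## Worked example

The package ships the published worked example as fixtures: 14 drugs with
their protein targets, the twelve tested late-stage combinations, and the
twelve SL pairs they address (`fixtureFig3()`), plus the per-gene
publication counts of the ranking table (`fixtureTable1()`).

```r
library(synletScreen)

fig3 <- fixtureFig3()
combos <- data.frame(combo_id = vapply(fig3$combinations, paste,
                                       character(1), collapse = "|"),
                     n_trials = 1L)
combos$drugs <- fig3$combinations
res <- screenTestedCombinations(combos, fig3$drugs, fig3$sl)
head(res$matches, 5)
#>        drug_a      drug_b gene_a gene_b status
#> 1  paclitaxel   veliparib   BCL2  PARP1 tested
#> 2  paclitaxel   veliparib   BCL2  PARP2 tested
#> 3  paclitaxel  pertuzumab   BCL2  ERBB2 tested
#> 4  paclitaxel trastuzumab   BCL2  ERBB2 tested
#> 5 bevacizumab  paclitaxel  VEGFA   BCL2 tested
length(unique(paste(res$matches$drug_a, res$matches$drug_b)))
#> [1] 12
```

Twelve tested combinations address an SL pair — nine of them involve
paclitaxel, e.g. bevacizumab + paclitaxel through the VEGFA–BCL2 pair, and
olaparib + cediranib through PARP1–KDR and PARP2–KDR. Ranking the proposed
novel combinations by annotation degree:

```r
ranked <- rankByAnnotationDegree(fixtureTable1Pairs(), fixtureTable1())
head(ranked[c("drug_a", "drug_b", "gene_a", "gene_b",
              "annotation_degree")], 3)
#>       drug_a      drug_b gene_a gene_b annotation_degree
#> 1 pertuzumab bevacizumab  ERBB2  VEGFA              1262
#> 2 pertuzumab saracatinib  ERBB2    SRC               808
#> 3 pertuzumab   docetaxel  ERBB2   BCL2               761
```

The top proposal pairs the ERBB2 antibody pertuzumab with the VEGFA
antibody bevacizumab (annotation degree 695 + 567 = 1262).

## Documentation

The methods vignette (`vignettes/synthetic-lethality-screening.Rmd`)
documents the model, the fixed statistical conventions (centrality
definitions, the disconnected-path sentinel, Dice on empty sets, strict
cutoff inequalities), the synthetic-world design and what it does and does
not emulate, and known limitations.
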
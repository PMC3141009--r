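# karyevol

Chromosome-number evolution in budding yeasts with point centromeres.

Saccharomycetaceae chromosomes are held together by *point
centromeres* — an 8 bp CDEI motif (consensus `NNCAVBTG`), an AT-rich
CDEII spacer whose length is species-characteristic, and a 26 bp
CDEIII motif with an invariant `CCGAA` core. Chromosome numbers in
this family range from 6 to 16 around an 8-chromosome pre-duplication
ancestor, and every change had to create or destroy a centromere.
karyevol is a toolkit for reconstructing those changes from
comparative gene order and sequence:

* **Centromere detection** — position-frequency consensus models
  built from annotated centromeres (`buildConsensus`,
  `consensusIupac`), log-odds scanning of both strands for the full
  CDEI–CDEII–CDEIII structure (`scanCentromeres`), and a two-pass
  species-level scanner that exploits within-species CDEII length
  uniformity (`scanCentromereSet`).
* **Ancestral mapping** — extant centromeres and telomere locations
  assigned to ancestral loci by syntenic flank evidence
  (`mapCentromeres`, `mapTelomereEnds`), ancestral presence by
  parsimony across non-WGD and post-WGD lineages
  (`inferAncestralPresence`), and Dollo-style branch assignment of
  shared events (`assignEventsToBranches`).
* **Breakpoint analysis** — synteny blocks against the ancestor
  (`findSyntenyBlocks`), breakpoint edges and reciprocal-edge cycle
  walking that resolves breakpoint reuse (`extractEdges`,
  `traceCycle`), and rearrangement counting (`countRearrangements`).
* **Mechanism classification** — telomere-to-telomere fusion with
  centromere death, centromere fission with arm capture, and WGD
  calls from double conserved synteny (`classifyMechanisms`), with
  karyotype prediction (`predictChromosomeNumber`), internalized
  subtelomeric genes (`findInternalizedGenes`) and absent-pillar
  scans (`absentPillars`).
* **A karyotype-evolution simulator** — seeded generation of
  ancestors, rearrangement histories along a species tree, and extant
  genomes with ground-truth event logs (`makeAncestor`, `applyEvent`,
  `evolve`, `makeReuseFixture`); every inference stage is validated
  against it.
* **Packaged fate tables** — machine-readable transcriptions of the
  published ancestral-centromere and ancestral-telomere fate tables
  (`table1Fates`, `table2Fates`, `countFates`).

## A worked example

Simulate a four-species history — a WGD clade in which one lineage
fuses two chromosomes, and a non-WGD clade sharing an older fusion —
then reconstruct it:

```r
library(karyevol)

cfg  <- simConfig(seed = 44)
anc  <- makeAncestor(cfg, with_sequences = FALSE)$genome
tr   <- ape::read.tree(text = "((postA,postB)W,(nonC,nonD)N)R;")
tr$node.label <- c("R", "WGD", "N")
tree <- SpeciesTree(tr, "WGD")

ev <- evolve(anc, tree,
             list(WGD   = "WGD",
                  postA = "telomere_fusion_cen_loss",
                  N     = "telomere_fusion_cen_loss",
                  nonC  = c("reciprocal_translocation", "inversion")),
             cfg)
res <- runPipeline(ev$genomes, anc, tree, out_dir = NULL, seed = 44)

res$observed_chromosomes
#> postA postB  nonC  nonD
#>    15    16     7     7
res$predicted_chromosomes
#> postA postB  nonC  nonD
#>    15    16     7     7
res$branch_assignments
#>                                              event branch conflict
#> 1 telomere_fusion_cen_loss::Anc1-L|Anc3-L|Anc_CEN3  postA    FALSE
#> 2 telomere_fusion_cen_loss::Anc2-R|Anc3-R|Anc_CEN2      N    FALSE
#> 3                                            WGD::    WGD    FALSE
```

The pipeline maps every centromere and telomere location of each leaf
back to the ancestor, classifies the two fusions (naming the dead
centromere and the two ancestral telomeres that met, with the
fusion-versus-loss order flagged as unknowable), places the shared
fusion on the non-WGD stem branch `N`, and predicts each karyotype
from the recovered calls — matching the simulated truth.

Fate counting on the packaged fate-table transcriptions:

```r
countFates(cen_fates = table1Fates())$cen_losses_total
#> [1] 9
countFates(tel_fates = table2Fates())$tel_lost_fusion
#> [1] 14
```

Nine centromere losses across the family; fourteen of the 112
telomere locations examined were lost to chromosome fusions.

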
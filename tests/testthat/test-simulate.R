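# karyotype-evolution simulator: ancestor generation and event engine

test_that("default ancestor has 8 chromosomes, 8 centromeres, 16 telomere ends", {
  g <- fix_ancestor()
  expect_equal(chromosomeCount(g), 8L)
  expect_equal(centromereCount(g), 8L)
  expect_equal(nrow(telomereEnds(g)), 16L)
  expect_true(isTRUE(validKaryotype(g)))
  # subtelomeric zones are pillar-less
  gt <- geneTable(g)
  expect_true(all(is.na(gt$pillar_id[gt$subtelomeric])))
  expect_true(all(!is.na(gt$pillar_id[!gt$subtelomeric])))
})

test_that("sampled CDEI sequences honour the NNCAVBTG invariants", {
  cen <- sampleCentromeres(200, fix_config(), seed = 9)
  m <- do.call(rbind, strsplit(cen$cde1_seq, ""))
  expect_true(all(m[, 3] == "C"))
  expect_true(all(m[, 4] == "A"))
  expect_true(all(m[, 5] %in% c("A", "C", "G")))
  expect_true(all(m[, 6] %in% c("C", "G", "T")))
  expect_true(all(m[, 7] == "T"))
  expect_true(all(m[, 8] == "G"))
  # CDEIII carries the invariant CCGAA core
  expect_true(all(substr(cen$cde3_seq, 13, 17) == "CCGAA"))
  # CDEII stays AT-rich within the configured band
  expect_true(all(cen$cde2_at >= 0.76 & cen$cde2_at <= 1))
})

test_that("generation is deterministic per seed and differs across seeds", {
  a <- makeAncestor(fix_config(7))
  b <- makeAncestor(fix_config(7))
  d <- makeAncestor(fix_config(8))
  expect_identical(a$genome@genes, b$genome@genes)
  expect_identical(as.character(a$genome@sequences),
                   as.character(b$genome@sequences))
  expect_false(identical(as.character(a$genome@sequences),
                         as.character(d$genome@sequences)))
})

test_that("config validation rejects impossible layouts and missing seeds", {
  expect_error(simConfig(seed = 1, genes_per_chromosome = 10,
                         subtelomeric_zone = 4), "subtelomeric_zone")
  expect_error(simConfig(), "seed")
})

test_that("WGD doubles chromosomes and centromeres; fusion conserves genes", {
  g <- fix_ancestor()
  gw <- applyEvent(g, wgdEvent())
  expect_equal(chromosomeCount(gw), 16L)
  expect_equal(centromereCount(gw), 16L)
  expect_equal(wgdStatus(gw), "post-WGD")
  gf <- applyEvent(g, telomereFusion("Anc1", "R", "Anc2", "L",
                                     lost_cen = "Anc_CEN2"))
  expect_equal(chromosomeCount(gf), chromosomeCount(g) - 1L)
  expect_equal(centromereCount(gf), centromereCount(g) - 1L)
  expect_setequal(geneTable(gf)$gene_id, geneTable(g)$gene_id)
  expect_error(applyEvent(g, telomereFusion("Anc1", "R", "Anc2", "L",
                                            lost_cen = "Anc_CEN5")),
               "neither participant")
})

test_that("inversion applied twice restores the genome", {
  g <- fix_ancestor()
  gi <- applyEvent(applyEvent(g, inversionEvent("Anc3", 10, 25)),
                   inversionEvent("Anc3", 10, 25))
  expect_identical(geneTable(gi), geneTable(g))
  expect_identical(centromeres(gi), centromeres(g))
})

test_that("translocations yielding 0- or 2-centromere products are rejected", {
  g <- fix_ancestor()
  expect_error(
    applyEvent(g, reciprocalTranslocation("Anc1", 10, "Anc2", 40)),
    class = "karyevol_rejected_event")
  # and the caller-facing resampler works around rejections
  pe <- randomEvent(g, g, "reciprocal_translocation")
  expect_true(isTRUE(validKaryotype(pe$genome)))
})

test_that("fission conserves genes and reduces both counts by one", {
  g <- fix_ancestor()
  gf <- applyEvent(g, centromereFission("Anc5", "Anc6", "R", "Anc7", "L"))
  expect_equal(chromosomeCount(gf), 7L)
  expect_equal(centromereCount(gf), 7L)
  expect_setequal(geneTable(gf)$gene_id, geneTable(g)$gene_id)
  expect_true(isTRUE(validKaryotype(gf)))
})

test_that("events never mutate their input genome", {
  g <- fix_ancestor()
  snapshot <- geneTable(g)
  invisible(applyEvent(g, wgdEvent()))
  invisible(applyEvent(g, inversionEvent("Anc1", 8, 12)))
  expect_identical(geneTable(g), snapshot)
})

test_that("pillar multisets are conserved by all non-loss events", {
  g <- fix_ancestor()
  pills <- sort(geneTable(g)$pillar_id)
  evs <- list(
    reciprocalTranslocation("Anc1", 10, "Anc2", 12),
    inversionEvent("Anc4", 7, 30),
    telomericTranslocation("Anc3", 35, "Anc4"),
    telomereFusion("Anc5", "R", "Anc6", "L", lost_cen = "Anc_CEN6"),
    centromereFission("Anc7", "Anc1", "L", "Anc2", "R"))
  for (e in evs) {
    g2 <- applyEvent(g, e)
    expect_identical(sort(geneTable(g2)$pillar_id), pills,
                     label = e$kind)
  }
})

test_that("evolve applies schedules along the tree; empty schedule is identity", {
  g <- fix_ancestor()
  tree <- fix_pair_tree()
  ev0 <- evolve(g, tree, list(), fix_config())
  expect_identical(geneTable(ev0$genomes$sp1), geneTable(g))
  expect_identical(geneTable(ev0$genomes$sp2), geneTable(g))
  expect_length(ev0$log, 0L)
})

test_that("post-WGD lineage with WGD + 3 fusions ends at 13 chromosomes", {
  cfg <- fix_config(21)
  anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
  ev <- evolve(anc, fix_pair_tree(),
               list(sp1 = c("WGD", rep("telomere_fusion_cen_loss", 3))),
               cfg)
  expect_equal(chromosomeCount(ev$genomes$sp1), 13L)
  expect_equal(wgdStatus(ev$genomes$sp1), "post-WGD")
  expect_true(isTRUE(validKaryotype(ev$genomes$sp1)))
})

test_that("non-WGD lineage with 2 fusions ends at 6 chromosomes", {
  cfg <- fix_config(22)
  anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
  ev <- evolve(anc, fix_pair_tree(),
               list(sp1 = rep("telomere_fusion_cen_loss", 2)), cfg)
  expect_equal(chromosomeCount(ev$genomes$sp1), 6L)
})

test_that("unsatisfiable schedules fail before any application", {
  g <- fix_ancestor()
  expect_error(
    evolve(g, fix_pair_tree(),
           list(sp1 = rep("telomere_fusion_cen_loss", 8)), fix_config()),
    "unsatisfiable")
})

test_that("post-WGD gene loss reaches the single-copy target, keeping every pillar", {
  cfg <- fix_config(23)
  anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
  ev <- evolve(anc, fix_pair_tree(), list(sp1 = "WGD"), cfg)
  g <- ev$genomes$sp1
  tab <- table(geneTable(g)$pillar_id[!is.na(geneTable(g)$pillar_id)])
  expect_gte(mean(tab == 1L), cfg$post_wgd_single_copy_fraction)
  expect_setequal(names(tab), unique(na.omit(geneTable(anc)$pillar_id)))
})

test_that("reuse fixtures are valid and match their construction contracts", {
  cfg <- fix_config(5)
  fx <- makeReuseFixture("cen9_pathway", cfg)
  expect_length(fx$events, 9L)
  expect_true(all(vapply(fx$events, function(e)
    e$kind == "reciprocal_translocation", logical(1))))
  expect_true(isTRUE(validKaryotype(fx$genome)))
  fy <- makeReuseFixture("klactis_cycle", cfg)
  expect_length(fy$events, 4L)
  expect_true(isTRUE(validKaryotype(fy$genome)))
  # three of the four events break a fresh ancestral centromeric
  # intergenic (the chained re-breaks of the evolving product reuse a
  # novel junction and do not count)
  cenPos <- centromeres(fy$ancestor)
  cenOf <- function(ch) cenPos$pos[cenPos$chrom_id == ch]
  freshCen <- sum(vapply(fy$events, function(e)
    isTRUE(e$pos2 == cenOf(e$chr2)), logical(1))) +
    isTRUE(fy$events[[1]]$pos1 == cenOf(fy$events[[1]]$chr1))
  expect_equal(freshCen, 3L)
})
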
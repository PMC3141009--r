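# mechanism classification, fate counting, karyotype prediction

test_that("an unrearranged genome yields zero mechanism calls", {
  g <- fix_ancestor()
  cls <- classifyMechanisms(g, g)
  expect_length(cls$calls, 0L)
})

test_that("simulated fusions are called with the ground-truth centromere and ends", {
  for (seed in 1:10) {
    cfg <- simConfig(seed = 900 + seed)
    anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
    ev <- evolve(anc, fix_pair_tree(),
                 list(sp1 = "telomere_fusion_cen_loss"), cfg)
    cls <- classifyMechanisms(ev$genomes$sp1, anc)
    kinds <- vapply(cls$calls, `[[`, character(1), "kind")
    expect_equal(kinds, "telomere_fusion_cen_loss",
                 label = paste("seed", 900 + seed))
    call <- cls$calls[[1]]
    truth <- ev$log[[1]]
    expect_equal(call$lost_cen, truth$lost_cen)
    expect_true(call$order_unknown)
    sideLab <- function(ch, side) paste0(ch, "-", side)
    expect_setequal(call$ends, c(sideLab(truth$chr1, truth$side1),
                                 sideLab(truth$chr2, truth$side2)))
  }
})

test_that("a centromere fission is called with the split chromosome and acceptor ends", {
  g <- fix_ancestor()
  gf <- applyEvent(g, centromereFission("Anc5", "Anc6", "R", "Anc7", "L"))
  cls <- classifyMechanisms(gf, g)
  kinds <- vapply(cls$calls, `[[`, character(1), "kind")
  expect_equal(kinds, "centromere_fission")
  call <- cls$calls[[1]]
  expect_equal(call$split_chrom, "Anc5")
  expect_equal(call$lost_cen, "Anc_CEN5")
  expect_setequal(call$acceptor_ends, c("Anc6-R", "Anc7-L"))
  expect_equal(predictChromosomeNumber(8, kinds), chromosomeCount(gf))
})

test_that("a bare centromere loss surfaces as an unexplained-loss call", {
  g <- fix_ancestor()
  gl <- applyEvent(g, centromereLoss("Anc_CEN4"))
  cls <- classifyMechanisms(gl, g)
  kinds <- vapply(cls$calls, `[[`, character(1), "kind")
  expect_true("unexplained_loss" %in% kinds)
  call <- cls$calls[[which(kinds == "unexplained_loss")]]
  expect_equal(call$lost_cen, "Anc_CEN4")
})

test_that("a WGD is called from two-track centromere evidence despite gene loss", {
  cfg <- fix_config(33)
  anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
  ev <- evolve(anc, fix_pair_tree(), list(sp1 = "WGD"), cfg)
  cls <- classifyMechanisms(ev$genomes$sp1, anc)
  expect_equal(vapply(cls$calls, `[[`, character(1), "kind"), "WGD")
  expect_equal(predictChromosomeNumber(8, "WGD"), 16L)
})

test_that("karyotype prediction follows doubling and per-event decrements", {
  expect_equal(predictChromosomeNumber(8, "WGD"), 16L)
  expect_equal(predictChromosomeNumber(
    8, c("WGD", rep("telomere_fusion_cen_loss", 3))), 13L)
  expect_equal(predictChromosomeNumber(
    8, rep("telomere_fusion_cen_loss", 2)), 6L)
  expect_equal(predictChromosomeNumber(
    8, c("telomere_fusion_cen_loss", "centromere_fission")), 6L)
  expect_error(predictChromosomeNumber(
    1, "telomere_fusion_cen_loss"), "below 1")
})

test_that("mechanism recovery matches the ground-truth log across seeds", {
  for (seed in 1:10) {
    cfg <- simConfig(seed = 1000 + seed)
    anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
    nF <- 1 + seed %% 2
    sch <- list(sp1 = c(rep("telomere_fusion_cen_loss", nF),
                        "reciprocal_translocation", "inversion"))
    ev <- evolve(anc, fix_pair_tree(), sch, cfg)
    cls <- classifyMechanisms(ev$genomes$sp1, anc)
    kinds <- vapply(cls$calls, `[[`, character(1), "kind")
    expect_equal(sum(kinds == "telomere_fusion_cen_loss"), nF,
                 label = paste("seed", 1000 + seed))
    truthLost <- sort(vapply(
      Filter(function(e) e$kind == "telomere_fusion_cen_loss", ev$log),
      `[[`, character(1), "lost_cen"))
    gotLost <- sort(vapply(
      cls$calls[kinds == "telomere_fusion_cen_loss"],
      `[[`, character(1), "lost_cen"))
    expect_equal(gotLost, truthLost)
    expect_equal(predictChromosomeNumber(8, kinds),
                 chromosomeCount(ev$genomes$sp1))
  }
})

test_that("fate counting on the packaged centromere transcription gives 9 losses", {
  t1 <- table1Fates()
  counts <- countFates(cen_fates = t1)
  expect_equal(counts$cen_losses_total, 9L)
  by <- counts$cen_losses_by_species
  expect_equal(unname(by[by > 0]), c(3L, 2L, 2L, 1L, 1L))
  expect_equal(by[["C.glabrata"]], 3L)
  expect_equal(by[["Z.rouxii"]], 1L)
})

test_that("fate counting on the packaged telomere transcription matches the study", {
  t2 <- table2Fates()
  counts <- countFates(tel_fates = t2)
  expect_equal(counts$tel_locations, 112L)
  expect_gte(counts$tel_lost_fusion, 14L)
  expect_equal(counts$tel_turnover, 33L)
})

test_that("count invariance under column order and L/R relabeling", {
  t2 <- table2Fates()
  shuf <- t2[withr::with_seed(2, sample(nrow(t2))), ]
  expect_equal(countFates(tel_fates = shuf), countFates(tel_fates = t2))
  swap <- t2
  swap$ancestral_label <- sub("-L$", "-tmp", swap$ancestral_label)
  swap$ancestral_label <- sub("-R$", "-L", swap$ancestral_label)
  swap$ancestral_label <- sub("-tmp$", "-R", swap$ancestral_label)
  expect_equal(countFates(tel_fates = swap), countFates(tel_fates = t2))
})

test_that("fate tables with uncovered loci are rejected, empty tables give zeros", {
  t1 <- table1Fates()
  broken <- t1[!(t1$ancestral_label == "Anc_CEN1" &
                   t1$species == "S.cerevisiae"), ]
  expect_error(countFates(cen_fates = broken), "uncovered")
  z <- countFates()
  expect_equal(z$cen_losses_total, 0L)
  expect_equal(z$tel_locations, 0L)
})

test_that("fusion internalizes both junction subtelomeric zones at one location", {
  g <- fix_ancestor()
  gf <- applyEvent(g, telomereFusion("Anc3", "R", "Anc4", "L",
                                     lost_cen = "Anc_CEN4"))
  gi <- findInternalizedGenes(gf)
  expect_equal(gi$count, 8L)  # two 4-gene zones
  expect_equal(gi$n_locations, 1L)
  expect_equal(findInternalizedGenes(g)$count, 0L)
})

test_that("telomeric translocations internalize the acceptor-side subtelomeric zone", {
  g <- fix_ancestor()
  gtt <- applyEvent(g, telomericTranslocation("Anc3", 35, "Anc4",
                                              acceptor_side = "R"))
  gi <- findInternalizedGenes(gtt)
  expect_equal(gi$n_locations, 1L)
  expect_equal(gi$count, 4L)
  expect_equal(gi$locations$chrom, "Anc4")
})

test_that("absent-pillar scan returns exactly the deleted pillars, in ancestral order", {
  g <- fix_ancestor()
  expect_length(absentPillars(g, g), 0L)
  gt <- geneTable(g)
  core <- gt$gene_id[!is.na(gt$pillar_id)]
  del <- core[c(3, 50, 120, 200)]
  g2 <- applyEvents(g, lapply(del, geneLoss))
  expect_equal(absentPillars(g2, g),
               gt$pillar_id[match(del, gt$gene_id)])
  # post-WGD single-copy survivors still count as present
  gw <- applyEvent(g, wgdEvent())
  gw2 <- applyEvent(gw, geneLoss(paste0(core[10], "_1")))
  expect_length(absentPillars(gw2, g), 0L)
})
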
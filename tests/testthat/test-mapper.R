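# mapping extant centromeres/telomeres to ancestral loci and parsimony

test_that("an unrearranged genome maps every locus with full flanks and no flags", {
  g <- fix_ancestor()
  mc <- mapCentromeres(g, g)
  expect_equal(nrow(mc), 8L)
  expect_true(all(mc$status == "mapped"))
  expect_true(all(mc$evidence == 10L))
  expect_false(any(mc$orientation_change | mc$translocation_at_locus |
                     mc$inversion_at_locus))
  tm <- mapTelomereEnds(g, g)
  expect_equal(nrow(tm$fates), 16L)
  expect_true(all(tm$fates$status == "conserved"))
  expect_equal(nrow(tm$novel_sites), 0L)
})

test_that("fusion lineages lose exactly the ground-truth centromere locus", {
  for (seed in 1:10) {
    cfg <- simConfig(seed = 700 + seed)
    anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
    ev <- evolve(anc, fix_pair_tree(),
                 list(sp1 = "telomere_fusion_cen_loss"), cfg)
    truth <- ev$log[[1]]$lost_cen
    mc <- mapCentromeres(ev$genomes$sp1, anc)
    lost <- mc$ancestral_label[mc$status == "lost"]
    expect_equal(lost, truth, label = paste("seed", 700 + seed))
  }
})

test_that("whole-chromosome orientation flips change flags, not assignments", {
  g <- fix_ancestor()
  # store Anc4 in flipped orientation
  chr <- chromosomeGenes(g, "Anc4")
  n <- nrow(chr)
  flipped <- chr[rev(seq_len(n)), ]
  flipped$idx <- seq_len(n)
  flipped$orientation <- ifelse(flipped$orientation == "+", "-", "+")
  genes <- rbind(g@genes[g@genes$chrom_id != "Anc4", ], flipped)
  cen <- centromeres(g)
  i <- cen$chrom_id == "Anc4"
  cen$pos[i] <- n - cen$pos[i]
  cen$strand[i] <- ifelse(cen$strand[i] == "+", "-", "+")
  g2 <- Genome(species(g), genes, cen, chromOrder = chromosomeIds(g))
  mc <- mapCentromeres(g2, g)
  row <- mc[mc$ancestral_label == "Anc_CEN4", ]
  expect_equal(row$status, "mapped")
  expect_equal(row$chrom, "Anc4")
  expect_true(row$orientation_change)
  tm <- mapTelomereEnds(g2, g)
  expect_true(all(tm$fates$status == "conserved"))
})

test_that("a reciprocal translocation at two centromeric intergenics flags both loci", {
  g <- fix_ancestor()
  g2 <- applyEvent(g, reciprocalTranslocation("Anc1", 25, "Anc2", 25,
                                              cen_side1 = "L",
                                              cen_side2 = "L"))
  mc <- mapCentromeres(g2, g)
  flagged <- mc$ancestral_label[mc$translocation_at_locus]
  expect_setequal(flagged, c("Anc_CEN1", "Anc_CEN2"))
  expect_true(all(mc$status == "mapped"))
})

test_that("an inversion spanning one centromere flank sets the inversion flag", {
  g <- fix_ancestor()
  gi <- applyEvent(g, inversionEvent("Anc3", 20, 25))
  mc <- mapCentromeres(gi, g)
  row <- mc[mc$ancestral_label == "Anc_CEN3", ]
  expect_equal(row$status, "mapped")
  expect_true(row$inversion_at_locus)
})

test_that("fused telomere ends report each other; translocated ends report loss + novel site", {
  g <- fix_ancestor()
  gf <- applyEvent(g, telomereFusion("Anc1", "R", "Anc2", "L",
                                     lost_cen = "Anc_CEN2"))
  tm <- mapTelomereEnds(gf, g)
  f <- tm$fates
  expect_equal(f$status[f$ancestral_label == "Anc1-R"], "fused")
  expect_equal(f$partner[f$ancestral_label == "Anc1-R"], "Anc2-L")
  expect_equal(f$partner[f$ancestral_label == "Anc2-L"], "Anc1-R")
  gtt <- applyEvent(g, telomericTranslocation("Anc3", 35, "Anc4",
                                              acceptor_side = "R"))
  t2 <- mapTelomereEnds(gtt, g)
  expect_equal(t2$fates$status[t2$fates$ancestral_label == "Anc4-R"],
               "lost_translocation")
  expect_equal(nrow(t2$novel_sites), 1L)
  expect_equal(t2$novel_sites$chrom, "Anc3")
})

test_that("post-WGD genomes map two tracks per locus; a fused track is reported lost", {
  cfg <- fix_config(31)
  anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
  gw <- applyEvent(anc, wgdEvent())
  mc <- mapCentromeres(gw, anc)
  expect_equal(nrow(mc), 16L)
  expect_true(all(mc$status == "mapped"))
  gwf <- applyEvent(gw, telomereFusion("Anc1_1", "R", "Anc2_1", "L",
                                       lost_cen = "Anc_CEN1"))
  mc2 <- mapCentromeres(gwf, anc)
  lost <- mc2[mc2$status == "lost", ]
  expect_equal(nrow(lost), 1L)
  expect_equal(lost$ancestral_label, "Anc_CEN1")
  tm <- mapTelomereEnds(gwf, anc)
  fused <- tm$fates[tm$fates$status == "fused", ]
  expect_setequal(fused$ancestral_label, c("Anc1-R", "Anc2-L"))
})

test_that("ancestral presence follows the one-non-WGD-plus-one-post-WGD rule", {
  wgd <- c(a = "non-WGD", b = "non-WGD", c = "post-WGD", d = "post-WGD")
  pres <- function(...) {
    v <- c(...)
    data.frame(locus = "L1", species = names(v), n_mapped = unname(v),
               stringsAsFactors = FALSE)
  }
  # present everywhere
  r <- inferAncestralPresence(pres(a = 1, b = 1, c = 1, d = 1), wgd)
  expect_true(r$present_wgd); expect_true(r$present_nodeB)
  # lost in one post-WGD leaf only
  r <- inferAncestralPresence(pres(a = 1, b = 1, c = 0, d = 1), wgd)
  expect_true(r$present_wgd)
  # only both sister tracks of one post-WGD species
  r <- inferAncestralPresence(pres(a = 0, b = 0, c = 2, d = 0), wgd)
  expect_true(r$present_wgd)
  expect_false(r$present_nodeB)
  # one post-WGD single track, nothing else: not ancestral
  r <- inferAncestralPresence(pres(a = 0, b = 0, c = 1, d = 0), wgd)
  expect_false(r$present_wgd)
  # absent everywhere is never inferred present
  r <- inferAncestralPresence(pres(a = 0, b = 0, c = 0, d = 0), wgd)
  expect_false(r$present_wgd); expect_false(r$present_nodeB)
  # post-WGD-only datasets degenerate to the sister clause, with warning
  expect_warning(
    inferAncestralPresence(pres(c = 2, d = 0), wgd[c("c", "d")]),
    "non-WGD")
})

test_that("events land on the branch above the smallest clade of their carriers", {
  tree <- fix_wgd_tree()
  res <- assignEventsToBranches(
    list(e_leaf = "nonC",
         e_clade = c("postA", "postB"),
         e_all = c("postA", "postB", "nonC", "nonD"),
         e_conflict = c("postA", "nonC")),
    tree)
  expect_equal(res$branch[res$event == "e_leaf"], "nonC")
  expect_equal(res$branch[res$event == "e_clade"], "WGD")
  expect_equal(res$branch[res$event == "e_all"], "R")
  expect_true(res$conflict[res$event == "e_conflict"])
})

test_that("scheduled branches are recovered from simulated carrier patterns", {
  for (seed in 1:5) {
    cfg <- simConfig(seed = 800 + seed)
    anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
    tree <- fix_wgd_tree()
    sch <- list(N = "telomere_fusion_cen_loss",
                postA = "telomere_fusion_cen_loss")
    ev <- evolve(anc, tree, sch, cfg)
    # carriers derived by classifying each leaf independently
    sigs <- list()
    for (sp in names(ev$genomes)) {
      cls <- classifyMechanisms(ev$genomes[[sp]], anc)
      for (cl in cls$calls) {
        if (cl$kind != "telomere_fusion_cen_loss") next
        key <- paste(sort(cl$ends), cl$lost_cen, collapse = "|")
        sigs[[key]] <- c(sigs[[key]], sp)
      }
    }
    res <- assignEventsToBranches(sigs, tree)
    expect_setequal(res$branch, c("N", "postA"))
    expect_false(any(res$conflict))
  }
})
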
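# synteny blocks, breakpoint edges and reuse-cycle tracing

test_that("unrearranged chromosomes give one same-orientation block and no edges", {
  g <- fix_ancestor()
  b <- findSyntenyBlocks(g, g)
  expect_equal(nrow(b), 8L)
  expect_true(all(b$orientation == "same"))
  e <- extractEdges(g, g)
  expect_equal(nrow(e), 0L)
  expect_equal(countRearrangements(g, g)$total, 0L)
})

test_that("one inversion fragments its chromosome into three blocks, middle inverted", {
  g <- fix_ancestor()
  gi <- applyEvent(g, inversionEvent("Anc3", 10, 25))
  b <- findSyntenyBlocks(gi, g)
  b3 <- b[b$chrom == "Anc3", ]
  expect_equal(nrow(b3), 3L)
  expect_equal(b3$orientation, c("same", "inverted", "same"))
  expect_equal(countRearrangements(gi, g)$total, 1L)
})

test_that("blocks equal the independent quadratic-time oracle on random genomes", {
  for (seed in 1:10) {
    cfg <- simConfig(seed = seed, n_ancestral_chromosomes = 4L,
                     genes_per_chromosome = 24L, subtelomeric_zone = 2L)
    anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
    ev <- evolve(anc, fix_pair_tree(),
                 list(sp1 = c("reciprocal_translocation", "inversion",
                              "reciprocal_translocation")), cfg)
    g <- ev$genomes$sp1
    b <- findSyntenyBlocks(g, anc, min_block_len = 1L)
    got <- sort(paste(b$anc_chrom, b$anc_start, b$anc_end, sep = ":"))
    expect_equal(got, oracle_blocks(g, anc), label = paste("seed", seed))
  }
})

test_that("single-gene strand flips stay inside blocks and out of event counts", {
  g <- fix_ancestor()
  gi <- applyEvent(g, inversionEvent("Anc2", 15, 15))
  b <- findSyntenyBlocks(gi, g)
  expect_equal(nrow(b[b$chrom == "Anc2", ]), 1L)
  expect_equal(sum(b$n_within_inversions), 1L)
  expect_equal(countRearrangements(gi, g)$total, 0L)
})

test_that("a reciprocal translocation yields two mutually reciprocal edges, one event", {
  g <- fix_ancestor()
  gt <- applyEvent(g, reciprocalTranslocation("Anc1", 10, "Anc2", 12))
  e <- extractEdges(gt, g)
  expect_equal(nrow(e), 2L)
  expect_true(all(e$kind == "internal"))
  cyc <- traceCycle(e$edge_id[1], e)
  expect_true(cyc$closed)
  expect_equal(length(cyc$edge_ids), 2L)
  expect_equal(cyc$events, 1L)
  expect_equal(cyc$reused, 0L)
})

test_that("a telomere fusion yields one internal edge joining two ancestral end flanks", {
  g <- fix_ancestor()
  gf <- applyEvent(g, telomereFusion("Anc1", "R", "Anc2", "L",
                                     lost_cen = "Anc_CEN2"))
  e <- extractEdges(gf, g)
  expect_equal(nrow(e), 1L)
  expect_equal(e$kind, "internal")
  cyc <- traceCycle(e$edge_id[1], e)
  expect_true(cyc$telomeric)
  expect_equal(cyc$events, 1L)
})

test_that("gene losses at a junction are bridged by the gap-tolerant walk", {
  g <- fix_ancestor()
  gt <- applyEvent(g, reciprocalTranslocation("Anc1", 10, "Anc2", 12))
  # delete one gene right at a junction
  gj <- applyEvent(gt, geneLoss("G0063"))
  cr <- countRearrangements(gj, g)
  expect_equal(cr$total, 1L)
  expect_false(any(cr$breakdown$open))
})

test_that("cycle tracing is start-point invariant", {
  cfg <- fix_config(5)
  fx <- makeReuseFixture("cen9_pathway", cfg)
  e <- extractEdges(fx$genome, fx$ancestor)
  ref <- traceCycle(e$edge_id[1], e)
  for (id in e$edge_id[-1]) {
    cyc <- traceCycle(id, e)
    expect_setequal(cyc$edge_ids, ref$edge_ids)
    expect_equal(cyc$events, ref$events)
  }
})

test_that("the nine-translocation pathway resolves to 9 events with 8 reused breakpoints", {
  fx <- makeReuseFixture("cen9_pathway", fix_config(5))
  cr <- countRearrangements(fx$genome, fx$ancestor)
  expect_equal(nrow(cr$breakdown), 1L)
  expect_equal(cr$total, 9L)
  expect_equal(cr$cycles[[1]]$reused, 8L)
  expect_true(cr$cycles[[1]]$closed)
})

test_that("the four-translocation cycle resolves as one cycle with 3 centromeric breakpoints", {
  fx <- makeReuseFixture("klactis_cycle", fix_config(5))
  cr <- countRearrangements(fx$genome, fx$ancestor)
  expect_equal(nrow(cr$breakdown), 1L)
  expect_equal(cr$total, 4L)
  expect_equal(cr$cycles[[1]]$n_centromeric, 3L)
})

test_that("every edge belongs to exactly one traced cycle", {
  for (seed in c(3, 9, 14)) {
    cfg <- simConfig(seed = seed)
    anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
    ev <- evolve(anc, fix_pair_tree(),
                 list(sp1 = c(rep("reciprocal_translocation", 4),
                              rep("inversion", 3),
                              "telomeric_translocation")), cfg)
    e <- extractEdges(ev$genomes$sp1, anc)
    cr <- countRearrangements(ev$genomes$sp1, anc)
    all_ids <- unlist(lapply(cr$cycles, `[[`, "edge_ids"))
    expect_equal(sort(all_ids), sort(e$edge_id))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("one added no-reuse translocation raises the count by exactly one", {
  cfg <- fix_config(6)
  anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
  g <- anc
  expected <- 0L
  withr::with_seed(61, {
    for (k in 1:6) {
      pe <- randomEvent(g, anc, "reciprocal_translocation")
      g <- pe$genome
      expected <- expected + 1L
      expect_equal(countRearrangements(g, anc)$total, expected)
    }
  })
})

test_that("scheduled no-reuse event counts are recovered exactly across seeds", {
  for (seed in 1:20) {
    cfg <- simConfig(seed = 500 + seed)
    anc <- makeAncestor(cfg, with_sequences = FALSE)$genome
    nT <- 1 + seed %% 4; nI <- 1 + seed %% 3
    ev <- evolve(anc, fix_pair_tree(),
                 list(sp1 = c(rep("reciprocal_translocation", nT),
                              rep("inversion", nI))), cfg)
    expect_equal(countRearrangements(ev$genomes$sp1, anc)$total, nT + nI,
                 label = paste("seed", 500 + seed))
  }
})
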
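# domain types and readers/writers

toy_genes <- function() {
  data.frame(
    gene_id = c("g1", "g2", "g3"),
    pillar_id = c("P1", "P2", "P3"),
    chrom_id = "c1", idx = 1:3,
    orientation = c("+", "+", "-"),
    subtelomeric = FALSE, stringsAsFactors = FALSE)
}

test_that("Genome validity enforces contiguous indices and known orientations", {
  g <- Genome("sp", toy_genes())
  expect_s4_class(g, "Genome")
  bad <- toy_genes(); bad$idx <- c(1L, 1L, 2L)
  expect_error(Genome("sp", bad), "1..n")
  bad2 <- toy_genes(); bad2$orientation[2] <- "x"
  expect_error(Genome("sp", bad2), "orientation")
})

test_that("smallest valid gene-order file reads with correct telomere boundaries", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom_id\tidx\torientation\tpillar_id\tsubtelomeric",
               "g2\tc1\t2\t+\tP2\t0",
               "g1\tc1\t1\t+\tP1\t0",
               "g3\tc1\t3\t-\tP3\t0"), f)
  g <- readGeneOrder(f, species = "toy")
  expect_equal(chromosomeCount(g), 1L)
  te <- telomereEnds(g)
  expect_equal(te$boundary_pillar[te$side == "L"], "P1")
  expect_equal(te$boundary_pillar[te$side == "R"], "P3")
})

test_that("malformed gene-order input is rejected with the offending row named", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom_id\tidx\torientation\tpillar_id\tsubtelomeric",
               "g1\tc1\t1\t+\tP1\t0",
               "g2\tc1\t1\t+\tP2\t0"), f)
  expect_error(readGeneOrder(f), "duplicate index")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom_id\tidx\torientation\tpillar_id\tsubtelomeric",
               "g1\tc1\t1\t?\tP1\t0"), f2)
  expect_error(readGeneOrder(f2), "orientation")
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom_id\tidx\torientation\tpillar_id\tsubtelomeric",
               "g1\tc1\t1\t+\t\t0"), f3)
  expect_error(readGeneOrder(f3), "sentinel")
})

test_that("gene-order writer/reader round-trips simulated genomes exactly", {
  for (seed in seq(1, 99, by = 2)) {  # 50 seeds
    cfg <- simConfig(seed = seed, genes_per_chromosome = 15L,
                     n_ancestral_chromosomes = 3L,
                     subtelomeric_zone = 2L)
    g <- makeAncestor(cfg, with_sequences = FALSE)$genome
    if (seed %% 3 == 0)
      g <- applyEvent(g, reciprocalTranslocation("Anc1", 5, "Anc2", 6))
    f <- tempfile(fileext = ".tsv")
    writeGeneOrder(g, f)
    g2 <- readGeneOrder(f, species = species(g))
    expect_identical(g2@genes, g@genes)
    expect_identical(telomereEnds(g2), telomereEnds(g))
  }
})

test_that("telomere boundaries are independent of input row order and idempotent", {
  g <- fix_ancestor()
  te1 <- telomereEnds(g)
  shuf <- g@genes[withr::with_seed(1, sample(nrow(g@genes))), ]
  g2 <- Genome(species(g), shuf, centromeres(g),
               chromOrder = chromosomeIds(g))
  expect_identical(telomereEnds(g2), te1)
  expect_identical(telomereEnds(g2), telomereEnds(g2))
})

test_that("centromere table and FASTA round-trip, FASTA reads uppercased", {
  anc <- makeAncestor(simConfig(seed = 77, genes_per_chromosome = 15L,
                                n_ancestral_chromosomes = 2L,
                                subtelomeric_zone = 2L))$genome
  cf <- tempfile(fileext = ".tsv")
  writeCentromereTable(centromeres(anc), cf)
  expect_identical(readCentromereTable(cf), centromeres(anc))
  ff <- tempfile(fileext = ".fa")
  writeFastaSequences(genomeSequences(anc), ff)
  s2 <- readFastaSequences(ff)
  expect_identical(as.character(s2), as.character(genomeSequences(anc)))
  lf <- tempfile(fileext = ".fa")
  writeLines(c(">lc desc", "acgtn"), lf)
  r <- readFastaSequences(lf)
  expect_identical(names(r), "lc")
  expect_identical(as.character(r[[1]]), "ACGTN")
})

test_that("event log round-trips kinds and branches", {
  evs <- list(wgdEvent("b1"),
              telomereFusion("c1", "R", "c2", "L", "Anc_CEN2",
                             branch = "b2"),
              inversionEvent("c3", 4, 9, branch = "b3"))
  f <- tempfile(fileext = ".yaml")
  writeEventLog(evs, f)
  e2 <- readEventLog(f)
  expect_identical(lapply(e2, unclass), lapply(evs, unclass))
})

test_that("species tree reads the WGD annotation; its absence errors when required", {
  f <- tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "((a,b)WGD,(c,d)N2)R;")
  writeSpeciesTree(SpeciesTree(tr, "WGD"), f)
  st <- readSpeciesTree(f)
  expect_equal(st@wgdNode, "WGD")
  expect_setequal(postWgdLeaves(st), c("a", "b"))
  f2 <- tempfile(fileext = ".nwk")
  ape::write.tree(ape::read.tree(text = "((a,b)X,(c,d)Y)R;"), file = f2)
  expect_error(readSpeciesTree(f2, requireWgd = TRUE), "WGD")
})

test_that("a ten-leaf tree with a WGD node parses with its full leaf set", {
  leaves <- c("S.cerevisiae", "S.bayanus", "C.glabrata", "V.polyspora",
              "N.castellii", "Z.rouxii", "K.lactis", "A.gossypii",
              "L.kluyveri", "L.thermotolerans")
  txt <- paste0("(((((S.cerevisiae,S.bayanus)n1,C.glabrata)n2,",
                "(V.polyspora,N.castellii)n3)WGD,",
                "(Z.rouxii,((K.lactis,A.gossypii)n4,",
                "(L.kluyveri,L.thermotolerans)n5)n6)n7)B);")
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  st <- readSpeciesTree(f)
  expect_setequal(treeLeaves(st), leaves)
  expect_equal(length(postWgdLeaves(st)), 5L)
})
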
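#' @include accessors.R
NULL

# Generator profiles for the centromere DNA elements. Each position is
# an IUPAC base class sampled uniformly within its allowed set. CDEI is
# the 8 bp NNCAVBTG consensus (invariant C,A,T,G at positions 3,4,7,8);
# CDEIII is 26 bp with the invariant CCGAA core planted at positions
# 13-17 and a T-rich / A-rich degenerate context around it.
CDE1_CONSENSUS <- c("N", "N", "C", "A", "V", "B", "T", "G")
CDE3_CONSENSUS <- c("N", "T", "K", "Y", "T", "W", "T", "T", "W", "S",
                    "N", "W", "C", "C", "G", "A", "A", "N", "T", "W",
                    "A", "A", "R", "T", "W", "N")
CDE3_CCGAA_OFFSET <- 13L  # 1-based start of the invariant CCGAA run

.BASES <- c("A", "C", "G", "T")

.iupacSet <- function(code) strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]

# probability matrix (4 x width, rows ACGT) of an IUPAC profile
.profileMatrix <- function(consensus) {
  m <- vapply(consensus, function(code) {
    s <- .iupacSet(code)
    p <- setNames(numeric(4), .BASES)
    p[s] <- 1 / length(s)
    p
  }, numeric(4))
  rownames(m) <- .BASES
  m
}

#' Simulator configuration
#'
#' Defaults emulate the pre-WGD ancestor of the Saccharomycetaceae: 8
#' chromosomes of ~50 genes, subtelomeric zones of pillar-less genes at
#' each end, point centromeres with an 8 bp CDEI, an AT-rich CDEII
#' spacer of species-characteristic length (species means spanning a
#' twofold range, small within-species spread) and a 26 bp CDEIII.
#'
#' @param n_ancestral_chromosomes number of ancestral chromosomes.
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @param subtelomeric_zone pillar-less subtelomeric genes per end.
#' @param intergenic_length length-2 bp range for intergenic spacers.
#' @param gene_length placeholder gene-block length (bp).
#' @param genome_at_fraction background AT fraction of non-CDE DNA.
#' @param cde2_species_mean_range bp range the per-species CDEII mean is
#'   drawn from.
#' @param cde2_within_species_sd within-species CDEII length sd (bp).
#' @param cde2_at_fraction_range CDEII AT fraction range.
#' @param post_wgd_single_copy_fraction target fraction of pillars
#'   returned to single copy by gene loss after a WGD.
#' @param seed integer seed (required; every simulator draw is seeded).
#' @return a `karyo_sim_config` list.
#' @export
simConfig <- function(n_ancestral_chromosomes = 8L,
                      genes_per_chromosome = 50L,
                      subtelomeric_zone = 4L,
                      intergenic_length = c(200L, 600L),
                      gene_length = 100L,
                      genome_at_fraction = 0.60,
                      cde2_species_mean_range = c(40L, 90L),
                      cde2_within_species_sd = 2,
                      cde2_at_fraction_range = c(0.76, 0.98),
                      post_wgd_single_copy_fraction = 0.85,
                      seed) {
  if (missing(seed) || is.null(seed))
    stop("simConfig: a seed is required")
  if (genes_per_chromosome < 2L * subtelomeric_zone + 3L)
    stop("simConfig: genes_per_chromosome must be >= 2*subtelomeric_zone + 3")
  stopifnot(intergenic_length[1] <= intergenic_length[2],
            cde2_species_mean_range[1] <= cde2_species_mean_range[2],
            all(cde2_at_fraction_range >= 0 & cde2_at_fraction_range <= 1),
            genome_at_fraction >= 0 && genome_at_fraction <= 1)
  structure(list(
    n_ancestral_chromosomes = as.integer(n_ancestral_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    subtelomeric_zone = as.integer(subtelomeric_zone),
    intergenic_length = as.integer(intergenic_length),
    gene_length = as.integer(gene_length),
    genome_at_fraction = genome_at_fraction,
    cde2_species_mean_range = as.integer(cde2_species_mean_range),
    cde2_within_species_sd = cde2_within_species_sd,
    cde2_at_fraction_range = cde2_at_fraction_range,
    post_wgd_single_copy_fraction = post_wgd_single_copy_fraction,
    seed = as.integer(seed)
  ), class = "karyo_sim_config")
}

# random DNA with a given AT fraction
.randomDna <- function(n, at = 0.60) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

.sampleFromProfile <- function(consensus, n) {
  vapply(seq_len(n), function(i) {
    paste(vapply(consensus, function(code) {
      s <- .iupacSet(code)
      s[sample.int(length(s), 1)]
    }, character(1)), collapse = "")
  }, character(1))
}

#' Sample centromere element sequences from the generator profile
#'
#' Draws `n` (CDEI, CDEII, CDEIII) triples. CDEII lengths are normal
#' around a species mean (drawn once per call from the configured
#' species-mean range, emulating one species), with AT fraction drawn
#' per centromere from the configured range.
#'
#' @param n number of centromeres.
#' @param config a [simConfig()].
#' @param seed seed; defaults to `config$seed`.
#' @param cde2_mean optional fixed CDEII species mean (bp).
#' @return data.frame with columns `cde1_seq`, `cde2_seq`, `cde3_seq`,
#'   `cde2_len`, `cde2_at`.
#' @export
sampleCentromeres <- function(n, config, seed = config$seed,
                              cde2_mean = NULL) {
  withr::with_seed(seed, {
    if (is.null(cde2_mean))
      cde2_mean <- runif(1, config$cde2_species_mean_range[1],
                         config$cde2_species_mean_range[2])
    sdv <- config$cde2_within_species_sd
    len <- as.integer(round(rnorm(n, cde2_mean, sdv)))
    # truncate at +/- 3 sd so lengths stay inside the model window
    len <- pmax(10L, pmin(pmax(len, as.integer(floor(cde2_mean - 3 * sdv))),
                          as.integer(ceiling(cde2_mean + 3 * sdv))))
    atr <- config$cde2_at_fraction_range
    at <- runif(n, atr[1], atr[2])
    cde2 <- vapply(seq_len(n), function(i) {
      # keep the realized AT fraction inside the configured band after
      # rounding to an integer base count
      nAT <- min(max(round(len[i] * at[i]), ceiling(len[i] * atr[1])),
                 floor(len[i] * atr[2]))
      b <- c(sample(c("A", "T"), nAT, replace = TRUE),
             sample(c("C", "G"), len[i] - nAT, replace = TRUE))
      paste(sample(b), collapse = "")
    }, character(1))
    data.frame(
      cde1_seq = .sampleFromProfile(CDE1_CONSENSUS, n),
      cde2_seq = cde2,
      cde3_seq = .sampleFromProfile(CDE3_CONSENSUS, n),
      cde2_len = len,
      cde2_at = vapply(cde2, function(s) {
        b <- strsplit(s, "")[[1]]; mean(b %in% c("A", "T"))
      }, numeric(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  })
}

#' The generating consensus model of the simulator
#'
#' Returns the exact position frequencies the simulator samples from, as
#' a [ConsensusModel-class] (counts scaled to 100 observations). The
#' CDEII window spans the configured species-mean range widened by three
#' within-species standard deviations.
#'
#' @param config a [simConfig()].
#' @export
generatorModel <- function(config) {
  w <- ceiling(3 * config$cde2_within_species_sd)
  ConsensusModel(
    pfmCde1 = .profileMatrix(CDE1_CONSENSUS) * 100,
    pfmCde3 = .profileMatrix(CDE3_CONSENSUS) * 100,
    cde2Window = c(config$cde2_species_mean_range[1] - w,
                   config$cde2_species_mean_range[2] + w),
    cde2MinAT = config$cde2_at_fraction_range[1],
    background = rep(0.25, 4),
    pseudocount = 1)
}

#' Generate the ancestral genome
#'
#' Builds a genome with `n_ancestral_chromosomes` chromosomes, each
#' carrying `genes_per_chromosome` genes (random orientation), unique
#' pillar ids on all non-subtelomeric genes, pillar-less subtelomeric
#' zones at both ends, and one point centromere at a mid-chromosome
#' intergenic with CDE sequences sampled from the generator profile.
#' When `with_sequences` is set, chromosome DNA is synthesized
#' (placeholder gene blocks and intergenic spacers at the configured
#' background AT fraction) with the centromere elements planted in the
#' centromeric intergenic, and their DNA spans recorded.
#'
#' @param config a [simConfig()].
#' @param with_sequences synthesize chromosome DNA (default TRUE).
#' @param species species name for the genome.
#' @return list with elements `genome` ([Genome-class]) and `model`
#'   ([ConsensusModel-class], the generating frequencies).
#' @export
makeAncestor <- function(config, with_sequences = TRUE,
                         species = "Ancestor") {
  nchr <- config$n_ancestral_chromosomes
  npc <- config$genes_per_chromosome
  stz <- config$subtelomeric_zone
  cenTab <- sampleCentromeres(nchr, config, seed = config$seed + 1L)
  genome <- withr::with_seed(config$seed, {
    genes <- list(); cens <- list()
    gctr <- 0L; pctr <- 0L
    for (k in seq_len(nchr)) {
      ch <- paste0("Anc", k)
      ids <- sprintf("G%04d", gctr + seq_len(npc)); gctr <- gctr + npc
      core <- seq(stz + 1L, npc - stz)
      pil <- rep(NA_character_, npc)
      pil[core] <- sprintf("P%04d", pctr + seq_along(core))
      pctr <- pctr + length(core)
      genes[[k]] <- data.frame(
        gene_id = ids, pillar_id = pil, chrom_id = ch, idx = seq_len(npc),
        orientation = sample(c("+", "-"), npc, replace = TRUE),
        subtelomeric = seq_len(npc) %in% c(seq_len(stz),
                                           seq(npc - stz + 1L, npc)),
        stringsAsFactors = FALSE)
      cens[[k]] <- data.frame(
        chrom_id = ch, pos = as.integer(floor(npc / 2)),
        strand = sample(c("+", "-"), 1),
        ancestral_label = paste0("Anc_CEN", k),
        cde1_seq = cenTab$cde1_seq[k], cde2_seq = cenTab$cde2_seq[k],
        cde3_seq = cenTab$cde3_seq[k], stringsAsFactors = FALSE)
    }
    genome <- Genome(species = species, genes = do.call(rbind, genes),
                     centromeres = do.call(rbind, cens),
                     wgdStatus = "non-WGD",
                     chromOrder = paste0("Anc", seq_len(nchr)))
    if (with_sequences) genome <- .synthesizeSequences(genome, config)
    genome
  })
  list(genome = genome, model = generatorModel(config))
}

# build chromosome DNA for a genome whose centromeres carry CDE
# sequences; records element spans in cenSpans
.synthesizeSequences <- function(genome, config) {
  at <- config$genome_at_fraction
  seqs <- character(0)
  spans <- list()
  for (ch in genome@chromOrder) {
    g <- chromosomeGenes(genome, ch)
    n <- nrow(g)
    cen <- genome@centromeres[genome@centromeres$chrom_id == ch, ,
                              drop = FALSE]
    cenPos <- if (nrow(cen)) cen$pos[1] else -1L
    parts <- character(0)
    cur <- 0L
    for (i in 0:n) {
      # intergenic before gene i+1 (i = intergenic index)
      ilen <- sample(seq(config$intergenic_length[1],
                         config$intergenic_length[2]), 1)
      if (i == cenPos && nrow(cen)) {
        cassette <- paste0(cen$cde1_seq[1], cen$cde2_seq[1],
                           cen$cde3_seq[1])
        if (cen$strand[1] == "-")
          cassette <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(cassette)))
        lpad <- .randomDna(ceiling(ilen / 2), at)
        rpad <- .randomDna(ceiling(ilen / 2), at)
        w1 <- nchar(cen$cde1_seq[1]); w2 <- nchar(cen$cde2_seq[1])
        w3 <- nchar(cen$cde3_seq[1])
        cstart <- cur + nchar(lpad) + 1L
        cend <- cstart + w1 + w2 + w3 - 1L
        if (cen$strand[1] == "+") {
          s1 <- c(cstart, cstart + w1 - 1L)
          s2 <- c(s1[2] + 1L, s1[2] + w2)
          s3 <- c(s2[2] + 1L, cend)
        } else {  # element order reversed on the forward strand
          s3 <- c(cstart, cstart + w3 - 1L)
          s2 <- c(s3[2] + 1L, s3[2] + w2)
          s1 <- c(s2[2] + 1L, cend)
        }
        spans[[length(spans) + 1L]] <- data.frame(
          chrom_id = ch, strand = cen$strand[1],
          cen_start = cstart, cen_end = cend,
          cde1_start = s1[1], cde1_end = s1[2],
          cde2_start = s2[1], cde2_end = s2[2],
          cde3_start = s3[1], cde3_end = s3[2],
          stringsAsFactors = FALSE)
        seg <- paste0(lpad, cassette, rpad)
      } else {
        seg <- .randomDna(ilen, at)
      }
      parts <- c(parts, seg)
      cur <- cur + nchar(seg)
      if (i < n) {
        gene <- .randomDna(config$gene_length, at)
        parts <- c(parts, gene)
        cur <- cur + nchar(gene)
      }
    }
    seqs[ch] <- paste(parts, collapse = "")
  }
  genome@sequences <- Biostrings::DNAStringSet(seqs)
  genome@cenSpans <- do.call(rbind, spans)
  genome
}

#' Generate standalone intergenic sequences with planted centromeres
#'
#' Produces `n` intergenic windows of background DNA, each with one
#' centromere cassette (CDEI + CDEII + CDEIII, random strand) planted at
#' a random offset, plus the ground truth needed for recall and
#' false-positive calibration of the scanner. With `plant = FALSE` the
#' windows contain background DNA only.
#'
#' @param n number of windows.
#' @param config a [simConfig()].
#' @param seed seed; defaults to `config$seed`.
#' @param window_length bp length of each window (default 600).
#' @param plant plant a centromere in each window (default TRUE).
#' @param mutations number of point mutations applied to the planted
#'   CDEI+CDEIII bases (default 0).
#' @param cde2_mean optional fixed CDEII species mean.
#' @return list with `sequences` ([Biostrings::DNAStringSet]) and
#'   `truth` (data.frame of planted spans/strands, zero rows when
#'   `plant = FALSE`).
#' @export
sampleIntergenics <- function(n, config, seed = config$seed,
                              window_length = 600L, plant = TRUE,
                              mutations = 0L, cde2_mean = NULL) {
  cens <- if (plant) sampleCentromeres(n, config, seed = seed + 7L,
                                       cde2_mean = cde2_mean) else NULL
  withr::with_seed(seed, {
    at <- config$genome_at_fraction
    seqs <- character(n)
    truth <- list()
    for (i in seq_len(n)) {
      if (!plant) {
        seqs[i] <- .randomDna(window_length, at)
        next
      }
      cas1 <- cens$cde1_seq[i]; cas2 <- cens$cde2_seq[i]
      cas3 <- cens$cde3_seq[i]
      if (mutations > 0L) {
        mut <- .mutateElements(cas1, cas3, mutations)
        cas1 <- mut[1]; cas3 <- mut[2]
      }
      cassette <- paste0(cas1, cas2, cas3)
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "-") as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(cassette)))
        else cassette
      pad <- window_length - nchar(ins)
      lpad <- sample.int(pad - 1L, 1)
      seqs[i] <- paste0(.randomDna(lpad, at), ins,
                        .randomDna(pad - lpad, at))
      w1 <- nchar(cas1); w2 <- nchar(cas2); w3 <- nchar(cas3)
      cstart <- lpad + 1L; cend <- lpad + w1 + w2 + w3
      truth[[i]] <- data.frame(
        window = i, strand = strand, cen_start = cstart, cen_end = cend,
        cde1_seq = cas1, cde2_seq = cas2, cde3_seq = cas3,
        stringsAsFactors = FALSE)
    }
    list(sequences = Biostrings::DNAStringSet(
           setNames(seqs, paste0("win", seq_len(n)))),
         truth = if (plant) do.call(rbind, truth) else
           data.frame())
  })
}

# apply k point mutations at distinct positions of the concatenated
# CDEI + CDEIII bases (always changing the base)
.mutateElements <- function(cde1, cde3, k) {
  b1 <- strsplit(cde1, "")[[1]]; b3 <- strsplit(cde3, "")[[1]]
  all <- c(b1, b3)
  pos <- sample.int(length(all), k)
  for (p in pos) all[p] <- sample(setdiff(.BASES, all[p]), 1)
  c(paste(all[seq_along(b1)], collapse = ""),
    paste(all[-seq_along(b1)], collapse = ""))
}
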
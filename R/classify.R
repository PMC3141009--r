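#' @include mapper.R
NULL

#' Classify chromosome-number-changing mechanisms in one species
#'
#' Runs the centromere and telomere mappers against the ancestor and
#' derives mechanism calls:
#'
#' * telomere-to-telomere fusion with centromere loss: two ancestral
#'   chromosomes end-joined at former telomeric flanks on one extant
#'   chromosome, with exactly one of their centromeres lost. The order
#'   of fusion and centromere loss is not inferable from synteny, so
#'   every fusion call carries `order_unknown = TRUE`.
#' * centromere fission: one ancestral chromosome's two
#'   centromere-flanking arms found on two extant chromosomes, each
#'   joined at a former telomere end of a different ancestral
#'   chromosome, the centromere lost.
#' * WGD: at least `wgd_fraction` of pillars present in two copies.
#'
#' Centromere losses matching neither pattern are reported as
#' `unexplained_loss` calls, never dropped.
#'
#' @param extant extant [Genome-class] (annotated centromeres).
#' @param ancestral ancestral [Genome-class].
#' @param w mapper flank window (default 5).
#' @param wgd_fraction duplicate-pillar fraction that calls a WGD
#'   (default 0.5).
#' @return list with `calls` (list of mechanism calls), `cen_fates`
#'   (data.frame from [mapCentromeres()]), `tel_fates` and
#'   `novel_sites` (from [mapTelomereEnds()]).
#' @export
classifyMechanisms <- function(extant, ancestral, w = 5L,
                               wgd_fraction = 0.5) {
  cenF <- mapCentromeres(extant, ancestral, w)
  telM <- mapTelomereEnds(extant, ancestral, w)
  telF <- telM$fates
  sp <- extant@species
  calls <- list()
  addCall <- function(kind, ...) {
    calls[[length(calls) + 1L]] <<- c(
      list(kind = kind, species = sp), list(...))
  }
  # WGD: a whole-genome duplication leaves two extant tracks per
  # ancestral centromere locus (double conserved synteny), robust to
  # the near-complete return to single-copy gene content that follows
  cenF2 <- if (extant@wgdStatus == "post-WGD") cenF else {
    tmp <- extant; tmp@wgdStatus <- "post-WGD"
    mapCentromeres(tmp, ancestral, w)
  }
  labs <- unique(cenF2$ancestral_label)
  frac2 <- mean(vapply(labs, function(l)
    sum(cenF2$status == "mapped" & cenF2$ancestral_label == l) >= 2L,
    logical(1)))
  if (frac2 >= wgd_fraction) addCall("WGD")
  lostCen <- cenF$ancestral_label[cenF$status == "lost"]
  # extant home of each lost centromere locus (where its ancestral
  # flank content now lives); a fusion's dead centromere need not
  # belong to the chromosomes whose ends met at the junction, since
  # earlier translocations may have exchanged the distal segments
  lostHome <- vapply(lostCen, function(lab)
    .locusHomeChrom(extant, ancestral, lab, w), character(1))
  # fusions: mutual fused-to pairs of ancestral ends. Each junction is
  # matched to a dead centromere: one from the ancestral chromosomes
  # whose ends met, or one whose flank content now lives on the fused
  # extant chromosome (earlier translocations may have exchanged the
  # distal segments). Lost centromeres form a multiset (post-WGD loci
  # can die on both tracks); junctions with the fewest candidates are
  # matched first.
  fused <- telF[telF$status == "fused", , drop = FALSE]
  junctions <- list()
  donePairs <- character(0)
  for (r in seq_len(nrow(fused))) {
    a <- fused$ancestral_label[r]; b <- fused$partner[r]
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% donePairs) next
    donePairs <- c(donePairs, key)
    chrA <- sub("-[LR]$", "", a); chrB <- sub("-[LR]$", "", b)
    byEnd <- intersect(vapply(c(chrA, chrB), .cenLabelOf,
                              character(1), ancestral = ancestral),
                       lostCen)
    byHome <- unique(lostCen[lostHome == fused$extant_chrom[r] |
                               is.na(lostHome)])
    junctions[[length(junctions) + 1L]] <- list(
      ends = c(a, b), chrom = fused$extant_chrom[r],
      cand = unique(c(byEnd, byHome)))
  }
  remaining <- lostCen
  explained <- character(0)
  while (length(junctions)) {
    ncand <- vapply(junctions, function(j)
      sum(j$cand %in% remaining), integer(1))
    k <- order(ncand)[1]
    j <- junctions[[k]]
    junctions[[k]] <- NULL
    avail <- j$cand[j$cand %in% remaining]
    if (length(avail)) {
      pick <- avail[1]
      remaining <- remaining[-match(pick, remaining)]
      explained <- c(explained, pick)
      addCall("telomere_fusion_cen_loss", ends = j$ends,
              lost_cen = pick, order_unknown = TRUE,
              extant_chrom = j$chrom)
    } else {
      addCall("fusion_without_cen_loss", ends = j$ends,
              extant_chrom = j$chrom)
    }
  }
  # fissions: two fission_fusion ends naming the same lost centromere
  ff <- telF[telF$status == "fission_fusion", , drop = FALSE]
  if (nrow(ff)) {
    for (lab in unique(ff$partner)) {
      rows <- ff[ff$partner == lab, , drop = FALSE]
      if (nrow(rows) >= 2L && lab %in% remaining) {
        remaining <- remaining[-match(lab, remaining)]
        split_chrom <- .chromOfCen(ancestral, lab)
        addCall("centromere_fission", split_chrom = split_chrom,
                lost_cen = lab,
                acceptor_ends = rows$ancestral_label[1:2])
      }
    }
  }
  for (lab in remaining)
    addCall("unexplained_loss", lost_cen = lab)
  list(calls = calls, cen_fates = cenF, tel_fates = telF,
       novel_sites = telM$novel_sites)
}

# majority extant chromosome carrying the flank pillars of an
# ancestral centromere locus
.locusHomeChrom <- function(extant, ancestral, label, w) {
  loci <- ancestralLoci(ancestral, w)$centromeres
  lc <- Filter(function(x) x$label == label, loci)
  if (!length(lc)) return(NA_character_)
  fl <- c(lc[[1]]$left_flank, lc[[1]]$right_flank)
  g <- extant@genes
  homes <- g$chrom_id[!is.na(g$pillar_id) & g$pillar_id %in% fl]
  if (!length(homes)) return(NA_character_)
  names(sort(table(homes), decreasing = TRUE))[1]
}

.cenLabelOf <- function(ancestral, chrom) {
  lab <- ancestral@centromeres$ancestral_label[
    ancestral@centromeres$chrom_id == chrom]
  if (length(lab)) lab[1] else NA_character_
}

.chromOfCen <- function(ancestral, label) {
  ch <- ancestral@centromeres$chrom_id[
    ancestral@centromeres$ancestral_label == label]
  if (length(ch)) ch[1] else NA_character_
}

#' Summarize centromere and telomere fate tables
#'
#' Computes exact integer counts from fate tables, either produced by
#' the pipeline ([classifyMechanisms()]) or loaded from the packaged
#' literature transcriptions ([table1Fates()], [table2Fates()]).
#'
#' @param cen_fates data.frame with columns `ancestral_label`,
#'   `species`, `status` (`mapped`/`lost`); may be `NULL`.
#' @param tel_fates data.frame with columns `ancestral_label`,
#'   `species`, `status` (`conserved`, `fused`, `lost_translocation`,
#'   `lost_inversion`, `fission_fusion`, `lost_unknown`); may be `NULL`.
#' @return list of counts: `cen_losses_total`, `cen_losses_by_species`,
#'   `tel_locations` (ancestral ends x species), `tel_lost_fusion`,
#'   `tel_lost_translocation_inversion`, `tel_fission_fusion`,
#'   `tel_turnover` (translocation/inversion + fission-fusion losses),
#'   `tel_conserved`.
#' @export
countFates <- function(cen_fates = NULL, tel_fates = NULL) {
  out <- list()
  if (!is.null(cen_fates) && nrow(cen_fates)) {
    .checkCoverage(cen_fates, "centromere")
    lost <- cen_fates[cen_fates$status == "lost", , drop = FALSE]
    by <- table(factor(lost$species,
                       levels = unique(cen_fates$species)))
    out$cen_losses_total <- nrow(lost)
    out$cen_losses_by_species <- sort(
      setNames(as.integer(by), names(by)), decreasing = TRUE)
  } else {
    out$cen_losses_total <- 0L
    out$cen_losses_by_species <- integer(0)
  }
  if (!is.null(tel_fates) && nrow(tel_fates)) {
    .checkCoverage(tel_fates, "telomere")
    nloc <- length(unique(tel_fates$ancestral_label)) *
      length(unique(tel_fates$species))
    st <- tel_fates$status
    out$tel_locations <- nloc
    out$tel_lost_fusion <- sum(st == "fused")
    out$tel_lost_translocation_inversion <-
      sum(st %in% c("lost_translocation", "lost_inversion"))
    out$tel_fission_fusion <- sum(st == "fission_fusion")
    out$tel_lost_unknown <- sum(st == "lost_unknown")
    out$tel_turnover <- out$tel_lost_translocation_inversion +
      out$tel_fission_fusion + out$tel_lost_unknown
    out$tel_conserved <- sum(st == "conserved")
  } else {
    out$tel_locations <- 0L
    out$tel_lost_fusion <- 0L
    out$tel_lost_translocation_inversion <- 0L
    out$tel_fission_fusion <- 0L
    out$tel_lost_unknown <- 0L
    out$tel_turnover <- 0L
    out$tel_conserved <- 0L
  }
  out
}

.checkCoverage <- function(fates, what) {
  labs <- unique(fates$ancestral_label)
  bad <- character(0)
  for (sp in unique(fates$species)) {
    miss <- setdiff(labs, fates$ancestral_label[fates$species == sp])
    if (length(miss))
      bad <- c(bad, paste0(sp, ": ", paste(miss, collapse = ",")))
  }
  if (length(bad))
    stop("uncovered ", what, " loci in fate table: ",
         paste(bad, collapse = "; "))
}

#' Predict a lineage's chromosome number from mechanism calls
#'
#' Starting from the ancestral count, a WGD doubles the number; every
#' telomere-to-telomere fusion (with centromere loss) and every
#' centromere fission subtracts one.
#'
#' @param ancestral_n ancestral chromosome number.
#' @param calls character vector of call kinds, or a list of calls as
#'   produced by [classifyMechanisms()], ordered along the lineage.
#' @return predicted chromosome count (integer).
#' @export
predictChromosomeNumber <- function(ancestral_n, calls) {
  kinds <- if (is.character(calls)) calls
           else vapply(calls, function(x) x$kind, character(1))
  n <- as.integer(ancestral_n)
  for (k in kinds) {
    n <- switch(k,
      WGD = n * 2L,
      telomere_fusion_cen_loss = n - 1L,
      centromere_fission = n - 1L,
      n)
    if (n < 1L) stop("predicted chromosome number fell below 1")
  }
  n
}

#' Find ancestrally subtelomeric genes internalized by rearrangement
#'
#' Genes flagged subtelomeric in the ancestor whose extant position is
#' internal: strictly between the chromosome's two boundary genes (the
#' outermost pillar-bearing genes), i.e. no longer part of any extant
#' subtelomeric zone. Consecutive internalized genes are grouped into
#' one junction location, mirroring per-species "n genes at m
#' locations" tallies.
#'
#' @param extant extant [Genome-class] whose genes carry the ancestral
#'   subtelomeric flags.
#' @return list with `count` (genes), `n_locations`, and `locations`
#'   (data.frame: chrom, gene index range, gene ids).
#' @export
findInternalizedGenes <- function(extant) {
  locs <- list()
  for (ch in extant@chromOrder) {
    g <- chromosomeGenes(extant, ch)
    hasP <- !is.na(g$pillar_id)
    if (!any(hasP)) next
    bL <- which(hasP)[1]; bR <- tail(which(hasP), 1)
    internal <- which(g$subtelomeric & seq_len(nrow(g)) > bL &
                        seq_len(nrow(g)) < bR)
    if (!length(internal)) next
    runs <- split(internal, cumsum(c(1L, diff(internal) != 1L)))
    for (rr in runs) {
      locs[[length(locs) + 1L]] <- data.frame(
        chrom = ch, start_idx = g$idx[rr[1]],
        end_idx = g$idx[tail(rr, 1)], n_genes = length(rr),
        gene_ids = paste(g$gene_id[rr], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  locations <- if (length(locs)) do.call(rbind, locs) else
    data.frame(chrom = character(0), start_idx = integer(0),
               end_idx = integer(0), n_genes = integer(0),
               gene_ids = character(0))
  list(count = sum(locations$n_genes),
       n_locations = nrow(locations), locations = locations)
}

#' Ancestral pillars absent from a genome
#'
#' Set difference between the ancestral pillar complement and the
#' pillars present (in at least one copy) in the genome, ordered by
#' ancestral position. This is the scan that surfaces lineage-specific
#' gene losses (for example the loss of an entire DNA-repair pathway).
#'
#' @param genome extant [Genome-class].
#' @param ancestral ancestral [Genome-class].
#' @return character vector of absent pillar ids.
#' @export
absentPillars <- function(genome, ancestral) {
  pidx <- .pillarIndex(ancestral)
  present <- unique(genome@genes$pillar_id[!is.na(genome@genes$pillar_id)])
  absent <- setdiff(rownames(pidx), present)
  ord <- order(match(pidx[absent, "achr"], ancestral@chromOrder),
               pidx[absent, "apos"])
  absent[ord]
}

## ---- packaged literature fate-table transcriptions -----------------

#' Packaged centromere/telomere fate transcriptions
#'
#' Machine-readable transcriptions of the published mapping between the
#' eight ancestral centromeres (and sixteen ancestral telomere
#' locations) and their counterparts in extant Saccharomycetaceae
#' species, including the loss/fusion/translocation/inversion flags.
#' Post-WGD species carry up to two tracks per ancestral locus.
#'
#' @return data.frame in the schema expected by [countFates()], with
#'   the original table glyphs preserved in the `token` column.
#' @export
table1Fates <- function() {
  path <- system.file("extdata", "table1_centromere_fates.tsv",
                      package = "karyevol", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname table1Fates
#' @export
table2Fates <- function() {
  path <- system.file("extdata", "table2_telomere_fates.tsv",
                      package = "karyevol", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
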
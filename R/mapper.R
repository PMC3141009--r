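#' @include synteny.R
NULL

#' Ancestral centromere and telomere loci with their synteny flanks
#'
#' Builds the locus table used for mapping: one row per ancestral
#' centromere (label, chromosome, `w` flanking pillars on each side)
#' and per ancestral chromosome end (label like `Anc3-L`, the `w`
#' outermost pillars ordered outermost first).
#'
#' @param ancestral ancestral [Genome-class].
#' @param w flank window in pillars (default 5).
#' @return list with data.frame-like lists `centromeres` and
#'   `telomeres`; flanks are character vectors ordered nearest-locus
#'   first (centromeres) or outermost first (telomere ends).
#' @export
ancestralLoci <- function(ancestral, w = 5L) {
  cens <- list(); tels <- list()
  for (ch in ancestral@chromOrder) {
    g <- chromosomeGenes(ancestral, ch)
    gp <- g[!is.na(g$pillar_id), , drop = FALSE]
    if (!nrow(gp)) next
    cc <- ancestral@centromeres[ancestral@centromeres$chrom_id == ch, ,
                                drop = FALSE]
    for (k in seq_len(nrow(cc))) {
      p <- cc$pos[k]
      left <- rev(gp$pillar_id[gp$idx <= p])
      right <- gp$pillar_id[gp$idx > p]
      cens[[length(cens) + 1L]] <- list(
        label = cc$ancestral_label[k], ancestral_chrom = ch,
        left_flank = head(left, w), right_flank = head(right, w))
    }
    tels[[length(tels) + 1L]] <- list(
      label = paste0(ch, "-L"), ancestral_chrom = ch, side = "L",
      flank = head(gp$pillar_id, w))
    tels[[length(tels) + 1L]] <- list(
      label = paste0(ch, "-R"), ancestral_chrom = ch, side = "R",
      flank = head(rev(gp$pillar_id), w))
  }
  list(centromeres = cens, telomeres = tels)
}

# pillars adjacent to an extant centromere, nearest first
.cenFlanks <- function(genome, chrom, pos, w) {
  g <- chromosomeGenes(genome, chrom)
  gp <- g[!is.na(g$pillar_id), , drop = FALSE]
  list(left = head(rev(gp$pillar_id[gp$idx <= pos]), w),
       right = head(gp$pillar_id[gp$idx > pos], w))
}

#' Map extant centromeres to ancestral centromere loci
#'
#' An extant centromere is assigned to an ancestral locus when at least
#' one pillar from each ancestral flank (within the window `w`) lies
#' adjacent to it on the extant chromosome in a consistent layout.
#' Reversed flank layout sets `orientation_change`; flanks of two
#' different ancestral loci abutting one extant centromere set
#' `translocation_at_locus`; a locally reversed run of matched pillars
#' on one side sets `inversion_at_locus`. Ancestral loci matched by no
#' extant centromere are reported `LOST`. Post-WGD genomes may map up
#' to two extant centromeres (tracks) per ancestral locus.
#'
#' @param extant extant [Genome-class] with annotated centromeres.
#' @param ancestral ancestral [Genome-class].
#' @param w flank window in pillars per side (default 5).
#' @return data.frame with one row per (ancestral locus, track):
#'   `ancestral_label`, `species`, `status` (`mapped`/`lost`), extant
#'   `chrom`/`pos`/`strand`, evidence counts and the three flags.
#' @export
mapCentromeres <- function(extant, ancestral, w = 5L) {
  if (!nrow(extant@centromeres)) {
    if (!is.null(extant@sequences))
      stop("genome of ", extant@species, " has no centromere ",
           "annotations; scan its sequences first (scanGenome) and ",
           "attach the annotations")
    stop("genome of ", extant@species,
         " has neither centromere annotations nor sequences")
  }
  loci <- ancestralLoci(ancestral, w)$centromeres
  cens <- extant@centromeres
  pidx <- .pillarIndex(ancestral)
  maxTracks <- if (extant@wgdStatus == "post-WGD") 2L else 1L
  # score each (extant cen, locus) pair; a full match has evidence on
  # both sides in one layout, a half match on one side only (the other
  # side's synteny was carried away by a rearrangement at the locus)
  pair <- list()
  for (i in seq_len(nrow(cens))) {
    fl <- .cenFlanks(extant, cens$chrom_id[i], cens$pos[i], w)
    for (k in seq_along(loci)) {
      lc <- loci[[k]]
      nLN <- sum(fl$left %in% lc$left_flank)
      nRN <- sum(fl$right %in% lc$right_flank)
      nLR <- sum(fl$left %in% lc$right_flank)
      nRL <- sum(fl$right %in% lc$left_flank)
      normal <- nLN >= 1L && nRN >= 1L
      reversed <- nLR >= 1L && nRL >= 1L
      shared <- max(nLN + nRN, nLR + nRL)
      if (shared == 0L) next
      full <- normal || reversed
      pair[[length(pair) + 1L]] <- data.frame(
        cen = i, locus = k, score = shared + if (full) 100L else 0L,
        full = full, reversed = reversed && !normal,
        # which side carries the evidence of a half match
        half_side = if (full) NA_character_ else
          if (nLN + nRL >= nRN + nLR) "left" else "right",
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair)) do.call(rbind, pair) else
    data.frame(cen = integer(0), locus = integer(0), score = numeric(0),
               full = logical(0), reversed = logical(0),
               half_side = character(0))
  # greedy assignment, best score first
  pairs <- pairs[order(-pairs$score, pairs$locus, pairs$cen), ,
                 drop = FALSE]
  usedCen <- integer(0)
  nAssigned <- integer(length(loci))
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$cen[r]; k <- pairs$locus[r]
    if (i %in% usedCen || nAssigned[k] >= maxTracks) next
    usedCen <- c(usedCen, i)
    nAssigned[k] <- nAssigned[k] + 1L
    fl <- .cenFlanks(extant, cens$chrom_id[i], cens$pos[i], w)
    lc <- loci[[k]]
    multiLocus <- length(unique(pairs$locus[pairs$cen == i])) > 1L
    invFlag <- .sideInverted(fl$left, lc$left_flank) ||
      .sideInverted(fl$right, lc$right_flank)
    transFlag <- multiLocus
    if (!pairs$full[r]) {
      # classify the disrupted side by where its genes now come from
      other <- if (pairs$half_side[r] == "left") fl$right else fl$left
      other <- other[other %in% rownames(pidx)]
      if (length(other) &&
          pidx[other[1], "achr"] == lc$ancestral_chrom &&
          !multiLocus)
        invFlag <- TRUE
      else
        transFlag <- TRUE
    }
    rows[[length(rows) + 1L]] <- data.frame(
      ancestral_label = lc$label, species = extant@species,
      track = nAssigned[k], status = "mapped",
      chrom = cens$chrom_id[i], pos = cens$pos[i],
      strand = cens$strand[i],
      evidence = pairs$score[r] %% 100L,
      orientation_change = pairs$reversed[r],
      translocation_at_locus = transFlag,
      inversion_at_locus = invFlag, stringsAsFactors = FALSE)
  }
  # post-WGD genomes owe two tracks per ancestral locus: every
  # unassigned track is a centromere loss
  for (k in seq_along(loci)) {
    for (t in seq_len(maxTracks - nAssigned[k]))
      rows[[length(rows) + 1L]] <- data.frame(
        ancestral_label = loci[[k]]$label, species = extant@species,
        track = nAssigned[k] + t, status = "lost", chrom = NA_character_,
        pos = NA_integer_, strand = NA_character_, evidence = 0L,
        orientation_change = FALSE, translocation_at_locus = FALSE,
        inversion_at_locus = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ancestral_label, out$track), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE when >= 2 matched pillars appear in reversed relative order
.sideInverted <- function(extFlank, ancFlank) {
  shared <- extFlank[extFlank %in% ancFlank]
  if (length(shared) < 2L) return(FALSE)
  ord <- match(shared, ancFlank)
  all(diff(ord) < 0L)
}

#' Map ancestral telomere ends to extant chromosome ends
#'
#' The telomere location of a chromosome is the location beside its
#' outermost pillar-bearing gene. An ancestral end is `conserved` when
#' an extant chromosome end's boundary flank shares at least two of its
#' `w` outermost pillars. Otherwise the ancestral flank is located
#' inside a chromosome and the junction beyond it is classified:
#' `fused` when it abuts another ancestral end's flank (telomere-to-
#' telomere fusion), `fission_fusion` when it abuts an ancestral
#' centromere flank (arm capture after centromere fission),
#' `lost_inversion` when the partner region derives from the same
#' ancestral chromosome, `lost_translocation` otherwise. Extant ends
#' matching no ancestral end are reported as novel telomere sites.
#'
#' @inheritParams mapCentromeres
#' @param min_shared pillars required to call an end conserved
#'   (default 2).
#' @return list with `fates` (data.frame, one row per ancestral end and
#'   track) and `novel_sites` (data.frame of unmatched extant ends).
#' @export
mapTelomereEnds <- function(extant, ancestral, w = 5L, min_shared = 2L) {
  loci <- ancestralLoci(ancestral, w)$telomeres
  maxTracks <- if (extant@wgdStatus == "post-WGD") 2L else 1L
  # extant end flanks, outermost first
  extEnds <- list()
  for (ch in extant@chromOrder) {
    g <- chromosomeGenes(extant, ch)
    gp <- g[!is.na(g$pillar_id), , drop = FALSE]
    if (!nrow(gp)) next
    extEnds[[paste0(ch, ":L")]] <- head(gp$pillar_id, w)
    extEnds[[paste0(ch, ":R")]] <- head(rev(gp$pillar_id), w)
  }
  pidx <- .pillarIndex(ancestral)
  # junction classification uses wider flanks than conserved-end
  # matching: post-WGD gene loss can erase a whole w-pillar flank on
  # one track, and the surviving junction context must still be
  # recognizable
  wWide <- 2L * w + 2L
  lociWide <- ancestralLoci(ancestral, wWide)$telomeres
  endOfPillar <- new.env(parent = emptyenv())
  cenNearPillar <- new.env(parent = emptyenv())
  for (lc in lociWide)
    for (p in lc$flank) assign(p, lc$label, endOfPillar)
  for (lc in ancestralLoci(ancestral, w)$centromeres)
    for (p in c(lc$left_flank, lc$right_flank))
      assign(p, lc$label, cenNearPillar)
  matched <- list()
  rows <- list()
  usedEnds <- character(0)
  geneRows <- extant@genes
  for (k in seq_along(loci)) {
    lc <- loci[[k]]
    lcW <- lociWide[[k]]
    shared <- vapply(extEnds, function(f) sum(f %in% lc$flank),
                     integer(1))
    hits <- names(shared)[shared >= min_shared]
    hits <- hits[order(-shared[hits])]
    hits <- head(hits, maxTracks)
    for (t in seq_along(hits)) {
      he <- strsplit(hits[t], ":")[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        ancestral_label = lc$label, species = extant@species,
        track = t, status = "conserved", extant_chrom = he[1],
        extant_end = he[2], partner = NA_character_,
        stringsAsFactors = FALSE)
      usedEnds <- c(usedEnds, hits[t])
    }
    # tracks with the flank internal: classify the junction beyond the
    # outermost surviving flank pillar (outward in ancestral terms);
    # each track consumes a distinct flank copy
    usedPos <- character(0)
    for (t in seq_len(maxTracks - length(hits))) {
      fate <- .classifyLostEnd(lcW, extant, geneRows, pidx, endOfPillar,
                               cenNearPillar, w, conservedEnds = hits,
                               usedPos = usedPos)
      usedPos <- c(usedPos, fate$used)
      rows[[length(rows) + 1L]] <- data.frame(
        ancestral_label = lc$label, species = extant@species,
        track = length(hits) + t, status = fate$status,
        extant_chrom = fate$chrom, extant_end = NA_character_,
        partner = fate$partner, stringsAsFactors = FALSE)
    }
  }
  fates <- do.call(rbind, rows)
  novel <- setdiff(names(extEnds), usedEnds)
  novel_sites <- if (length(novel)) {
    parts <- strsplit(novel, ":")
    data.frame(species = extant@species,
               chrom = vapply(parts, `[`, character(1), 1),
               end = vapply(parts, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  } else data.frame(species = character(0), chrom = character(0),
                    end = character(0))
  list(fates = fates, novel_sites = novel_sites)
}

.classifyLostEnd <- function(lc, extant, geneRows, pidx, endOfPillar,
                             cenNearPillar, w, conservedEnds = character(0),
                             usedPos = character(0)) {
  res <- list(status = "lost_translocation", chrom = NA_character_,
              partner = NA_character_, used = character(0))
  for (p in lc$flank) {  # outermost first
    hits <- geneRows[!is.na(geneRows$pillar_id) &
                       geneRows$pillar_id == p, , drop = FALSE]
    for (hrow in seq_len(nrow(hits))) {
    hit <- hits[hrow, ]
    if (paste0(hit$chrom_id, "@", hit$idx) %in% usedPos) next
    g <- chromosomeGenes(extant, hit$chrom_id)
    # the side of this gene that ancestrally faced the telomere
    d <- .relSign(hit$orientation, pidx[p, "aorient"])
    outward <- if (lc$side == "L") -d else d  # +1 = extant rightward
    # walk outward to the nearest pillar-bearing gene
    i <- hit$idx + outward
    offEnd <- FALSE
    repeat {
      if (i < 1L || i > nrow(g)) { offEnd <- TRUE; break }
      if (!is.na(g$pillar_id[g$idx == i])) break
      i <- i + outward
    }
    if (offEnd) {
      # this copy still sits at an extant end; if it is the conserved
      # sister track, look at the other copy instead
      endKey <- paste0(hit$chrom_id, ":", if (outward > 0L) "R" else "L")
      if (endKey %in% conservedEnds) next
      res$chrom <- hit$chrom_id
      res$used <- paste0(hit$chrom_id, "@", hit$idx)
      return(res)
    }
    res$chrom <- hit$chrom_id
    res$used <- paste0(hit$chrom_id, "@", hit$idx)
    q <- g$pillar_id[g$idx == i]
    qchr <- pidx[q, "achr"]
    sameChrom <- qchr == lc$ancestral_chrom
    qend <- if (exists(q, endOfPillar)) get(q, endOfPillar) else NA
    if (!is.na(qend)) {
      # another ancestral end flank lies beyond the junction. A fusion
      # joins two former telomeres face to face, so the partner flank
      # must face the junction with its ancestral-telomere side; this
      # separates fusion junctions from inversions beside the locus,
      # from translocated segments that merely carry end-proximal
      # content, and (for the locus's own label) a post-WGD sister
      # track fused to this one from this track's own flank further
      # out.
      qside <- sub("^.*-", "", qend)
      dq <- .relSign(g$orientation[g$idx == i], pidx[q, "aorient"])
      qout <- if (qside == "L") -dq else dq
      if (qout == -outward) {
        res$status <- "fused"; res$partner <- qend
        return(res)
      }
      if (qend == lc$label) next  # own flank, not the outermost survivor
    }
    if (exists(q, cenNearPillar) && !sameChrom) {
      res$status <- "fission_fusion"
      res$partner <- get(q, cenNearPillar)
      return(res)
    }
    res$status <- if (sameChrom) "lost_inversion"
                  else "lost_translocation"
    return(res)
    }
  }
  res
}

#' Infer ancestral presence of loci by parsimony
#'
#' A locus is inferred present in the ancestor at the WGD node if it is
#' present in an orthologous region of at least one non-WGD and one
#' post-WGD species, or in both paralogous sister regions of one
#' post-WGD species. Presence at the older node B (common ancestor of
#' all non-WGD and post-WGD lineages) additionally requires support
#' from the non-WGD side: at least one non-WGD carrier, plus either
#' WGD-node presence or a second independent non-WGD genus.
#'
#' @param presence data.frame with columns `locus`, `species`,
#'   `n_mapped` (0, 1, or 2 mapped tracks in that species).
#' @param wgd named character vector: species -> `"non-WGD"`/`"post-WGD"`.
#' @param genus optional named vector species -> genus (defaults to the
#'   species name, i.e. every species its own genus).
#' @return data.frame per locus: `present_wgd`, `present_nodeB`,
#'   `evidence` (number of carrier species).
#' @export
inferAncestralPresence <- function(presence, wgd, genus = NULL) {
  if (is.null(genus))
    genus <- setNames(names(wgd), names(wgd))
  if (!any(wgd == "non-WGD"))
    warning("no non-WGD species in dataset; WGD-node inference ",
            "degenerates to the sister-region clause")
  out <- lapply(split(presence, presence$locus), function(d) {
    carriers <- d$species[d$n_mapped >= 1L]
    nonw <- carriers[wgd[carriers] == "non-WGD"]
    postw <- carriers[wgd[carriers] == "post-WGD"]
    sister <- any(d$n_mapped[wgd[d$species] == "post-WGD"] == 2L)
    presentWgd <- (length(nonw) >= 1L && length(postw) >= 1L) || sister
    presentB <- length(nonw) >= 1L &&
      (presentWgd || length(unique(genus[nonw])) >= 2L)
    data.frame(locus = d$locus[1], present_wgd = presentWgd,
               present_nodeB = presentB,
               evidence = length(carriers), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign derived events to tree branches (Dollo parsimony)
#'
#' Each event is placed on the branch above the smallest clade
#' containing exactly its carrier species (single origin, no reversal).
#' Carrier sets that are not monophyletic are flagged as conflicting,
#' not forced.
#'
#' @param carriers named list: event id -> character vector of carrier
#'   species.
#' @param tree a [SpeciesTree-class].
#' @return data.frame with `event`, `branch` (child-node label of the
#'   assigned edge, `NA` on conflict) and `conflict`.
#' @export
assignEventsToBranches <- function(carriers, tree) {
  tr <- tree@tree
  ntip <- length(tr$tip.label)
  labelOf <- function(node)
    if (node <= ntip) tr$tip.label[node] else tr$node.label[node - ntip]
  rows <- lapply(names(carriers), function(ev) {
    cs <- unique(carriers[[ev]])
    if (!length(cs))
      return(data.frame(event = ev, branch = NA_character_,
                        conflict = TRUE, stringsAsFactors = FALSE))
    if (length(cs) == 1L)
      return(data.frame(event = ev, branch = cs, conflict = FALSE,
                        stringsAsFactors = FALSE))
    node <- ape::getMRCA(tr, cs)
    clade <- tr$tip.label[.cladeTips(tr, node)]
    ok <- setequal(clade, cs)
    data.frame(event = ev,
               branch = if (ok) labelOf(node) else NA_character_,
               conflict = !ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
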
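#' @include evolve.R
NULL

## Extremity bookkeeping
##
## Breakpoint analysis works on signed gene extremities. Every pillar
## gene has a tail (t, its 5' end on its own + strand) and a head (h);
## a gene placed with orientation "+" presents its tail leftward, with
## "-" its head. Two genomes share an adjacency exactly when the same
## extremity pair is joined in both, which absorbs all orientation
## arithmetic. Chromosome ends are capped with ATEL/ETEL pseudo
## extremities (ancestral/extant).

.ext <- function(pillar, orient, side) {
  lab <- ifelse((orient == "+") == (side == "L"), "t", "h")
  paste0(pillar, ":", lab)
}

.flipExt <- function(x) {
  ifelse(endsWith(x, ":t"), sub(":t$", ":h", x), sub(":h$", ":t", x))
}

.isCap <- function(x) startsWith(x, "ATEL:") | startsWith(x, "ETEL:")

.extPillar <- function(x) sub(":[th]$", "", x)

.edgeKey <- function(x, y) paste(sort(c(x, y)), collapse = "|")

# ancestral adjacency structures: extremity partner map, centromeric
# ancestral-edge labels, pillar index, per-chromosome apos -> pillar map
.ancStructures <- function(ancestral) {
  pidx <- .pillarIndex(ancestral)
  adj <- new.env(parent = emptyenv())
  cen <- new.env(parent = emptyenv())
  aposMap <- list()
  for (ch in ancestral@chromOrder) {
    g <- chromosomeGenes(ancestral, ch)
    g <- g[!is.na(g$pillar_id), , drop = FALSE]
    if (!nrow(g)) next
    aposMap[[ch]] <- g$pillar_id
    exts <- cbind(L = .ext(g$pillar_id, g$orientation, "L"),
                  R = .ext(g$pillar_id, g$orientation, "R"))
    link <- function(x, y) { assign(x, y, adj); assign(y, x, adj) }
    link(paste0("ATEL:", ch, ":L"), exts[1, "L"])
    n <- nrow(g)
    if (n > 1L)
      for (i in seq_len(n - 1L))
        link(exts[i, "R"], exts[i + 1L, "L"])
    link(exts[n, "R"], paste0("ATEL:", ch, ":R"))
    cens <- ancestral@centromeres[ancestral@centromeres$chrom_id == ch, ,
                                  drop = FALSE]
    for (k in seq_len(nrow(cens))) {
      p <- cens$pos[k]
      li <- which(g$idx <= p); ri <- which(g$idx > p)
      if (length(li) && length(ri)) {
        i <- max(li); j <- min(ri)
        key <- .edgeKey(exts[i, "R"], exts[j, "L"])
        lab <- cens$ancestral_label[k]
        if (is.na(lab)) lab <- paste0("cen:", ch)
        assign(key, lab, cen)
      }
    }
  }
  list(adj = adj, cen = cen, pidx = pidx, aposMap = aposMap)
}

# gap-tolerant adjacency conservation using ancestral positions.
# Intermediate pillars may be skipped when they are absent from the
# extant genome (gene losses) or when the genome is post-WGD (the
# surviving copy may live on the sister track).
.consGap <- function(a, b, pidx, present, max_gap, postwgd, aposMap) {
  if (!(a$pillar_id %in% rownames(pidx)) ||
      !(b$pillar_id %in% rownames(pidx))) return(FALSE)
  pa <- pidx[a$pillar_id, ]; pb <- pidx[b$pillar_id, ]
  if (pa$achr != pb$achr) return(FALSE)
  da <- .relSign(a$orientation, pa$aorient)
  db <- .relSign(b$orientation, pb$aorient)
  if (da != db) return(FALSE)
  delta <- (pb$apos - pa$apos) * da
  if (delta < 1L || delta > max_gap + 1L) return(FALSE)
  if (delta > 1L) {
    mids <- aposMap[[pa$achr]][pa$apos + da * seq_len(delta - 1L)]
    if (!postwgd && any(mids %in% present)) return(FALSE)
  }
  TRUE
}

# per-chromosome ordered pillar-gene tables with single flipped genes
# repaired (recorded as within-block inversions, excluded from event
# counting)
.pillarSeqs <- function(genome, ancStruct, max_gap = 1L) {
  pidx <- ancStruct$pidx
  present <- genome@genes$pillar_id[!is.na(genome@genes$pillar_id)]
  postwgd <- genome@wgdStatus == "post-WGD"
  inv <- character(0)
  seqs <- list()
  for (ch in genome@chromOrder) {
    g <- chromosomeGenes(genome, ch)
    g <- g[!is.na(g$pillar_id), , drop = FALSE]
    n <- nrow(g)
    if (n >= 3L) {
      for (i in 2:(n - 1L)) {
        a <- g[i - 1L, ]; x <- g[i, ]; b <- g[i + 1L, ]
        okL <- .consGap(a, x, pidx, present, max_gap, postwgd,
                        ancStruct$aposMap)
        okR <- .consGap(x, b, pidx, present, max_gap, postwgd,
                        ancStruct$aposMap)
        if (!okL && !okR) {
          x2 <- x; x2$orientation <- ifelse(x$orientation == "+", "-", "+")
          if (.consGap(a, x2, pidx, present, max_gap, postwgd,
                       ancStruct$aposMap) &&
              .consGap(x2, b, pidx, present, max_gap, postwgd,
                       ancStruct$aposMap)) {
            g$orientation[i] <- x2$orientation
            inv <- c(inv, x$gene_id)
          }
        }
      }
    }
    seqs[[ch]] <- g
  }
  list(seqs = seqs, inversions = inv, present = present,
       postwgd = postwgd)
}

#' Decompose a genome into synteny blocks against the ancestor
#'
#' A synteny block is a maximal run of extant genes whose pillars are
#' consecutive in the ancestral gene order (up to orientation),
#' tolerating up to `max_gap` missing pillars (gene losses) between
#' neighbours. A single gene with flipped orientation inside an
#' otherwise conserved run is kept in the block and recorded as a
#' within-block inversion; these are excluded from rearrangement
#' counting.
#'
#' @param extant extant [Genome-class] (genes carry pillar ids).
#' @param ancestral ancestral [Genome-class].
#' @param min_block_len minimum pillars per reported block (default 2).
#' @param max_gap missing-pillar tolerance within a block (default 1).
#' @return data.frame with one row per block: extant chromosome and
#'   gene-index interval, ancestral chromosome and pillar-position
#'   interval, `orientation` (`"same"`/`"inverted"`), `n_pillars`, and
#'   `n_within_inversions`. Attribute `within_block_inversions` lists
#'   the flipped gene ids.
#' @export
findSyntenyBlocks <- function(extant, ancestral, min_block_len = 2L,
                              max_gap = 1L) {
  if (!any(!is.na(extant@genes$pillar_id))) {
    warning("genome has no pillar-bearing genes; no blocks")
    return(data.frame())
  }
  as_ <- .ancStructures(ancestral)
  ps <- .pillarSeqs(extant, as_, max_gap)
  rows <- list()
  for (ch in names(ps$seqs)) {
    g <- ps$seqs[[ch]]
    n <- nrow(g)
    if (!n) next
    starts <- 1L
    if (n > 1L)
      for (i in seq_len(n - 1L))
        if (!.consGap(g[i, ], g[i + 1L, ], as_$pidx, ps$present, max_gap,
                      ps$postwgd, as_$aposMap))
          starts <- c(starts, i + 1L)
    bounds <- cbind(starts, c(starts[-1] - 1L, n))
    for (k in seq_len(nrow(bounds))) {
      i <- bounds[k, 1]; j <- bounds[k, 2]
      pa <- as_$pidx[g$pillar_id[i], ]
      pb <- as_$pidx[g$pillar_id[j], ]
      d <- .relSign(g$orientation[i], pa$aorient)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_idx = g$idx[i], end_idx = g$idx[j],
        anc_chrom = pa$achr, anc_start = min(pa$apos, pb$apos),
        anc_end = max(pa$apos, pb$apos),
        orientation = ifelse(d == 1L, "same", "inverted"),
        n_pillars = j - i + 1L,
        n_within_inversions = sum(g$gene_id[i:j] %in% ps$inversions),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, rows)
  blocks <- blocks[blocks$n_pillars >= min_block_len, , drop = FALSE]
  rownames(blocks) <- NULL
  attr(blocks, "within_block_inversions") <- ps$inversions
  blocks
}

## ---- breakpoint edges ----------------------------------------------

# follow ancestral adjacencies from extremity x, skipping up to max_gap
# pillars that are skippable (absent / post-WGD); returns the reached
# extremity or cap (or NA if the gap budget is exhausted), plus the
# ancestral edge keys traversed
.walkAnc <- function(x, as_, present, max_gap, postwgd) {
  keys <- character(0)
  cur <- x
  skips <- 0L
  repeat {
    y <- if (exists(cur, as_$adj)) get(cur, as_$adj) else NA_character_
    if (is.na(y)) return(list(to = NA_character_, keys = keys))
    keys <- c(keys, .edgeKey(cur, y))
    if (.isCap(y)) return(list(to = y, keys = keys))
    p <- .extPillar(y)
    skippable <- !(p %in% present) || postwgd
    if (p %in% present || !skippable)
      return(list(to = y, keys = keys))
    if (skips >= max_gap) return(list(to = NA_character_, keys = keys))
    skips <- skips + 1L
    cur <- .flipExt(y)
  }
}

#' Extract breakpoint edges of an extant genome against the ancestor
#'
#' A breakpoint edge is a novel extant adjacency absent from the
#' ancestral gene order (after orientation handling and gap tolerance):
#' one edge per junction between synteny blocks, plus one edge per
#' chromosome end whose terminal block does not reach an ancestral
#' chromosome end (capped with an extant-telomere pseudo extremity).
#'
#' @inheritParams findSyntenyBlocks
#' @return data.frame of edges with the junction location, flanking
#'   genes/pillars, and the gene-extremity labels used by
#'   [traceCycle()]. Attribute `anc` carries the ancestral adjacency
#'   structures for reuse.
#' @export
extractEdges <- function(extant, ancestral, max_gap = 1L) {
  as_ <- .ancStructures(ancestral)
  ps <- .pillarSeqs(extant, as_, max_gap)
  rows <- list()
  add <- function(chrom, pos, kind, lg, rg, lext, rext) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, kind = kind,
      left_gene = lg, right_gene = rg,
      left_ext = lext, right_ext = rext, stringsAsFactors = FALSE)
  }
  for (ch in names(ps$seqs)) {
    g <- ps$seqs[[ch]]
    n <- nrow(g)
    if (!n) next
    nAll <- nrow(chromosomeGenes(extant, ch))
    # left chromosome end
    xl <- .ext(g$pillar_id[1], g$orientation[1], "L")
    w <- .walkAnc(xl, as_, ps$present, max_gap, ps$postwgd)
    if (is.na(w$to) || !startsWith(w$to, "ATEL:"))
      add(ch, 0L, "end", NA_character_, g$gene_id[1],
          paste0("ETEL:", ch, ":L"), xl)
    # internal junctions
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        a <- g[i, ]; b <- g[i + 1L, ]
        if (.consGap(a, b, as_$pidx, ps$present, max_gap, ps$postwgd,
                     as_$aposMap)) next
        add(ch, a$idx, "internal", a$gene_id, b$gene_id,
            .ext(a$pillar_id, a$orientation, "R"),
            .ext(b$pillar_id, b$orientation, "L"))
      }
    }
    # right chromosome end
    xr <- .ext(g$pillar_id[n], g$orientation[n], "R")
    w <- .walkAnc(xr, as_, ps$present, max_gap, ps$postwgd)
    if (is.na(w$to) || !startsWith(w$to, "ATEL:"))
      add(ch, nAll, "end", g$gene_id[n], NA_character_,
          xr, paste0("ETEL:", ch, ":R"))
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0),
               kind = character(0), left_gene = character(0),
               right_gene = character(0), left_ext = character(0),
               right_ext = character(0), stringsAsFactors = FALSE)
  if (nrow(edges)) edges$edge_id <- seq_len(nrow(edges))
  else edges$edge_id <- integer(0)
  attr(edges, "anc") <- as_
  attr(edges, "present") <- ps$present
  attr(edges, "postwgd") <- ps$postwgd
  edges
}

## ---- cycle tracing -------------------------------------------------

# map: extremity label -> edge ids carrying it
.edgeIndex <- function(edges) {
  idx <- list()
  for (k in seq_len(nrow(edges))) {
    for (x in c(edges$left_ext[k], edges$right_ext[k])) {
      idx[[x]] <- c(idx[[x]], edges$edge_id[k])
    }
  }
  idx
}

#' Trace the breakpoint-reuse cycle containing an edge
#'
#' Starting from one edge of a breakpoint, the reciprocal edge is
#' located by following the broken ancestral adjacency of one flanking
#' gene to the site where its ancestral neighbour now lies; the walk is
#' iterated until it returns to the starting breakpoint's other edge,
#' identifying a closed cycle of breakpoint edges. A walk reaching a
#' chromosome end closes through a telomere pseudo edge and is flagged
#' telomeric; a dangling neighbour missing entirely (deleted beyond the
#' gap budget) leaves an open chain, flagged.
#'
#' The inferred event count is `n_edges - 1` for closed cycles of
#' chained reciprocal events (a plain reciprocal translocation gives a
#' 2-edge cycle and 1 event) and the number of internal (non-end) edges
#' for telomeric paths, minimum 1. This count is a documented heuristic:
#' exact on chained-reciprocal and simple telomeric histories, a lower
#' bound otherwise.
#'
#' @param start edge id to start from.
#' @param edges edge table from [extractEdges()].
#' @return list describing the cycle: `edge_ids` (in walk order),
#'   `closed`, `telomeric`, `open`, `events`, `n_centromeric` (distinct
#'   broken centromeric ancestral adjacencies), `cen_labels`, `reused`
#'   (closed cycles: `n_edges - 2`), `ambiguities`.
#' @export
traceCycle <- function(start, edges) {
  as_ <- attr(edges, "anc")
  present <- attr(edges, "present")
  postwgd <- attr(edges, "postwgd")
  idx <- .edgeIndex(edges)
  erow <- function(id) edges[edges$edge_id == id, , drop = FALSE]
  e0 <- erow(start)
  ambig <- character(0)
  ancKeys <- character(0)
  # walk from an extremity of an edge outward; returns edge ids visited
  # (excluding the starting edge) and the terminal state
  walkDir <- function(fromExt, startEntry) {
    chain <- integer(0)
    seen <- start
    x <- fromExt
    repeat {
      if (startsWith(x, "ETEL:")) return(list(chain = chain, end = "etel"))
      w <- .walkAnc(x, as_, present, max_gap = 1L, postwgd)
      ancKeys <<- c(ancKeys, w$keys)
      if (is.na(w$to)) return(list(chain = chain, end = "open"))
      if (startsWith(w$to, "ATEL:"))
        return(list(chain = chain, end = "atel"))
      y <- w$to
      cands <- idx[[y]] %||% integer(0)
      if (!length(cands)) return(list(chain = chain, end = "open"))
      if (start %in% cands && y == startEntry)
        return(list(chain = chain, end = "closed"))
      fresh <- setdiff(cands, seen)
      pick <- if (length(fresh)) fresh else cands
      if (length(pick) > 1L) {
        # tie: lexicographic by (chrom, pos)
        sub <- edges[edges$edge_id %in% pick, , drop = FALSE]
        sub <- sub[order(sub$chrom, sub$pos), , drop = FALSE]
        ambig <<- c(ambig, sprintf("extremity %s matches %d edges", y,
                                   nrow(sub)))
        pick <- sub$edge_id[1]
      }
      if (pick == start) return(list(chain = chain, end = "closed"))
      er <- erow(pick)
      chain <- c(chain, pick)
      seen <- c(seen, pick)
      x <- if (er$left_ext == y) er$right_ext else er$left_ext
      if (length(chain) > nrow(edges) + 1L)
        return(list(chain = chain, end = "open"))  # safety
    }
  }
  fwd <- walkDir(e0$right_ext, startEntry = e0$left_ext)
  if (fwd$end == "closed") {
    ids <- c(start, fwd$chain)
    closed <- TRUE; telomeric <- FALSE; open <- FALSE
  } else {
    bwd <- walkDir(e0$left_ext, startEntry = e0$right_ext)
    ids <- c(rev(bwd$chain), start, fwd$chain)
    closed <- FALSE
    telomeric <- fwd$end %in% c("atel", "etel") &&
      bwd$end %in% c("atel", "etel")
    open <- !telomeric
  }
  sub <- edges[match(ids, edges$edge_id), , drop = FALSE]
  nInternal <- sum(sub$kind == "internal")
  events <- if (closed) length(ids) - 1L
            else if (telomeric) max(1L, nInternal)
            else length(ids)  # open chain: lower bound
  cenLabels <- unique(unlist(lapply(unique(ancKeys), function(k)
    if (exists(k, as_$cen)) get(k, as_$cen) else NULL)))
  list(edge_ids = ids, closed = closed, telomeric = telomeric,
       open = open, events = events,
       n_centromeric = length(cenLabels), cen_labels = cenLabels,
       reused = if (closed) length(ids) - 2L else NA_integer_,
       ambiguities = ambig)
}

#' Count rearrangements between an extant genome and the ancestor
#'
#' Extracts all breakpoint edges, decomposes them into cycles/chains
#' with [traceCycle()], and sums the per-cycle event counts.
#' Within-block single-gene inversions are excluded. Open chains
#' contribute their edge count as a lower bound and are flagged.
#'
#' @inheritParams findSyntenyBlocks
#' @return list with `total` (integer event count), `cycles` (list of
#'   cycle descriptors) and `breakdown` (one data.frame row per cycle).
#' @export
countRearrangements <- function(extant, ancestral, min_block_len = 2L,
                                max_gap = 1L) {
  edges <- extractEdges(extant, ancestral, max_gap = max_gap)
  if (!nrow(edges))
    return(list(total = 0L, cycles = list(),
                breakdown = data.frame()))
  visited <- integer(0)
  cycles <- list()
  for (id in edges$edge_id) {
    if (id %in% visited) next
    cyc <- traceCycle(id, edges)
    visited <- c(visited, cyc$edge_ids)
    cycles[[length(cycles) + 1L]] <- cyc
  }
  breakdown <- do.call(rbind, lapply(seq_along(cycles), function(i) {
    cyc <- cycles[[i]]
    data.frame(cycle = i, n_edges = length(cyc$edge_ids),
               events = cyc$events, closed = cyc$closed,
               telomeric = cyc$telomeric, open = cyc$open,
               n_centromeric = cyc$n_centromeric,
               stringsAsFactors = FALSE)
  }))
  list(total = sum(breakdown$events), cycles = cycles,
       breakdown = breakdown)
}
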
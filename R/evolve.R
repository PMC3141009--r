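#' @include events.R simulate.R
NULL

## ---- ancestral indexing -------------------------------------------

# pillar lookup table for an ancestral genome: ancestral chromosome,
# position among the pillar-bearing genes of that chromosome (apos),
# ancestral orientation, and gene index
.pillarIndex <- function(ancestral) {
  g <- ancestral@genes
  g <- g[!is.na(g$pillar_id), , drop = FALSE]
  res <- list()
  for (ch in ancestral@chromOrder) {
    gg <- g[g$chrom_id == ch, , drop = FALSE]
    gg <- gg[order(gg$idx), , drop = FALSE]
    if (!nrow(gg)) next
    res[[ch]] <- data.frame(pillar_id = gg$pillar_id, achr = ch,
                            apos = seq_len(nrow(gg)),
                            aorient = gg$orientation, gidx = gg$idx,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- tab$pillar_id
  tab
}

# relative sign of an extant gene vs its ancestral orientation
.relSign <- function(orient, aorient) ifelse(orient == aorient, 1L, -1L)

# exact adjacency conservation between extant-adjacent pillar genes a, b
# (a immediately left of b, pillar-less genes skipped beforehand)
.conservedAdjExact <- function(a, b, pidx) {
  pa <- pidx[a$pillar_id, ]; pb <- pidx[b$pillar_id, ]
  if (is.na(pa$achr) || is.na(pb$achr) || pa$achr != pb$achr) return(FALSE)
  da <- .relSign(a$orientation, pa$aorient)
  db <- .relSign(b$orientation, pb$aorient)
  if (da != db) return(FALSE)
  (pb$apos - pa$apos) == da
}

## ---- random event placement (no-reuse mode) ------------------------

# candidate internal breakpoints: intergenic p such that genes at
# p-1..p+2 all carry pillars forming an ancestrally intact run, and p is
# not a centromeric intergenic. Breaking only intact ancestral
# adjacencies guarantees that scheduled event counts are recoverable
# (no breakpoint reuse).
.breakpointCandidates <- function(genome, pidx, chrom = NULL) {
  chroms <- if (is.null(chrom)) genome@chromOrder else chrom
  out <- list()
  for (ch in chroms) {
    g <- chromosomeGenes(genome, ch)
    n <- nrow(g)
    if (n < 4L) next
    cenPos <- genome@centromeres$pos[genome@centromeres$chrom_id == ch]
    for (p in 2:(n - 2L)) {
      if (p %in% cenPos) next
      quad <- g[(p - 1L):(p + 2L), ]
      if (any(is.na(quad$pillar_id))) next
      ok <- TRUE
      for (i in 1:3)
        if (!.conservedAdjExact(quad[i, ], quad[i + 1L, ], pidx)) {
          ok <- FALSE; break
        }
      if (ok) out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0), pos = integer(0)))
  do.call(rbind, out)
}

.sampleRow <- function(df) df[sample.int(nrow(df), 1L), , drop = FALSE]

#' Place one random rearrangement event
#'
#' Samples concrete participants for an event of the given kind under
#' the simulator's no-reuse policy: breakpoints fall only on ancestrally
#' intact adjacencies flanked by two further intact adjacencies on each
#' side, never on a centromeric intergenic (reuse fixtures are built
#' deliberately with [makeReuseFixture()]). Draws that would produce an
#' invalid karyotype are rejected and resampled.
#'
#' @param genome current [Genome-class].
#' @param ancestral the ancestral [Genome-class] (pillar coordinates).
#' @param kind event kind (see [rearrangementEvent()]).
#' @param branch branch label recorded on the event.
#' @param maxTries resampling attempts before giving up.
#' @return list with `event` (concrete `RearrangementEvent`) and
#'   `genome` (the genome after applying it).
#' @export
randomEvent <- function(genome, ancestral, kind, branch = NA_character_,
                        maxTries = 100L) {
  pidx <- .pillarIndex(ancestral)
  for (try in seq_len(maxTries)) {
    ev <- tryCatch(.proposeEvent(genome, pidx, kind, branch),
                   karyevol_no_candidate = function(e) NULL)
    if (is.null(ev)) next
    g2 <- tryCatch(applyEvent(genome, ev),
                   karyevol_rejected_event = function(e) NULL)
    if (!is.null(g2)) return(list(event = ev, genome = g2))
  }
  stop("randomEvent: could not place a valid '", kind, "' event in ",
       maxTries, " attempts")
}

.noCandidate <- function(msg)
  stop(structure(class = c("karyevol_no_candidate", "error", "condition"),
                 list(message = msg, call = NULL)))

.proposeEvent <- function(genome, pidx, kind, branch) {
  cand <- function(chrom = NULL) {
    bc <- .breakpointCandidates(genome, pidx, chrom)
    if (!nrow(bc)) .noCandidate("no intact breakpoints available")
    bc
  }
  cens <- genome@centromeres
  switch(kind,
    WGD = wgdEvent(branch),
    reciprocal_translocation = {
      bc <- cand()
      if (length(unique(bc$chrom)) < 2L)
        .noCandidate("need breakpoints on two chromosomes")
      b1 <- .sampleRow(bc)
      b2 <- .sampleRow(bc[bc$chrom != b1$chrom, , drop = FALSE])
      reciprocalTranslocation(b1$chrom, b1$pos, b2$chrom, b2$pos,
                              branch = branch)
    },
    inversion = {
      bc <- cand()
      byc <- split(bc, bc$chrom)
      byc <- byc[vapply(byc, function(d)
        max(d$pos) - min(d$pos) >= 2L, logical(1))]
      if (!length(byc)) .noCandidate("no chromosome with a long interval")
      d <- byc[[sample.int(length(byc), 1L)]]
      repeat {
        ps <- sort(sample(d$pos, 2L))
        if (ps[2] - ps[1] >= 2L) break
      }
      inversionEvent(d$chrom[1], ps[1] + 1L, ps[2], branch = branch)
    },
    telomeric_translocation = {
      bc <- cand()
      b <- .sampleRow(bc)
      cenPos <- cens$pos[cens$chrom_id == b$chrom][1]
      side <- if (!is.na(cenPos) && cenPos <= b$pos) "R" else "L"
      others <- setdiff(genome@chromOrder, b$chrom)
      if (!length(others)) .noCandidate("no acceptor chromosome")
      telomericTranslocation(b$chrom, b$pos, sample(others, 1L),
                             segment_side = side,
                             acceptor_side = sample(c("L", "R"), 1L),
                             branch = branch)
    },
    telomere_fusion_cen_loss = {
      if (chromosomeCount(genome) < 2L)
        .noCandidate("need two chromosomes to fuse")
      pair <- sample(genome@chromOrder, 2L)
      lost <- cens[cens$chrom_id == sample(pair, 1L), , drop = FALSE]
      if (!nrow(lost)) .noCandidate("participant lacks a centromere")
      lab <- if (!is.na(lost$ancestral_label[1])) lost$ancestral_label[1]
             else lost$chrom_id[1]
      telomereFusion(pair[1], sample(c("L", "R"), 1L),
                     pair[2], sample(c("L", "R"), 1L),
                     lost_cen = lab, branch = branch)
    },
    centromere_fission = {
      if (chromosomeCount(genome) < 3L)
        .noCandidate("need three chromosomes for a fission")
      trio <- sample(genome@chromOrder, 3L)
      centromereFission(trio[1], trio[2], sample(c("L", "R"), 1L),
                        trio[3], sample(c("L", "R"), 1L), branch = branch)
    },
    gene_loss = {
      g <- genome@genes
      tab <- table(g$pillar_id[!is.na(g$pillar_id)])
      dup <- names(tab)[tab >= 2L]
      if (!length(dup)) .noCandidate("no duplicated pillar to lose")
      pick <- sample(dup, 1L)
      ids <- g$gene_id[!is.na(g$pillar_id) & g$pillar_id == pick]
      geneLoss(sample(ids, 1L), branch = branch)
    },
    stop("cannot place random event of kind ", kind))
}

## ---- evolution along a species tree --------------------------------

#' Evolve an ancestor along a species tree
#'
#' Applies each branch's scheduled events along root-to-leaf paths and
#' returns the leaf genomes plus the ground-truth log of every applied
#' event (with concrete participants and branch). Schedule entries are
#' named by branch (= child node or tip label) and contain either
#' concrete `RearrangementEvent`s or event-kind strings, which are
#' placed randomly under the no-reuse policy. After a WGD, leaves
#' additionally receive random `gene_loss` events until the configured
#' fraction of pillars is back to single copy.
#'
#' @param ancestor the ancestral [Genome-class] (root genome).
#' @param tree a [SpeciesTree-class].
#' @param schedule named list of per-branch event lists (see Details);
#'   branches without an entry are event-free.
#' @param config a [simConfig()]; supplies the seed and the post-WGD
#'   single-copy fraction.
#' @return list with `genomes` (named list of leaf [Genome-class]s) and
#'   `log` (list of applied events in application order).
#' @export
evolve <- function(ancestor, tree, schedule = list(), config) {
  tr <- tree@tree
  ntip <- length(tr$tip.label)
  labelOf <- function(node) {
    if (node <= ntip) tr$tip.label[node]
    else tr$node.label[node - ntip]
  }
  allLabels <- c(tr$tip.label, tr$node.label)
  bad <- setdiff(names(schedule), allLabels)
  if (length(bad))
    stop("schedule names unknown branches: ", paste(bad, collapse = ", "))
  .checkSchedule(ancestor, tr, schedule, labelOf)
  rootNode <- ntip + 1L
  log <- list()
  genomes <- list()
  withr::with_seed(config$seed + 101L, {
    walk <- function(node, genome) {
      if (node <= ntip) {
        lab <- labelOf(node)
        genome@species <- lab
        if (genome@wgdStatus == "post-WGD")
          genome <- .resolvePostWgd(genome, config, lab)
        genomes[[lab]] <<- genome
        return(invisible(NULL))
      }
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      for (kid in kids) {
        lab <- labelOf(kid)
        g <- genome
        for (item in schedule[[lab]] %||% list()) {
          if (inherits(item, "RearrangementEvent")) {
            item$branch <- lab
            g <- applyEvent(g, item)
            log[[length(log) + 1L]] <<- item
          } else {
            pe <- randomEvent(g, ancestor, as.character(item), branch = lab)
            g <- pe$genome
            log[[length(log) + 1L]] <<- pe$event
          }
        }
        walk(kid, g)
      }
    }
    walk(rootNode, ancestor)
    # post-WGD leaf gene losses are logged inside .resolvePostWgd via
    # attribute; collect them
    for (lab in names(genomes)) {
      ev <- attr(genomes[[lab]], "loss_log")
      if (!is.null(ev)) {
        log <- c(log, ev)
        attr(genomes[[lab]], "loss_log") <- NULL
      }
    }
  })
  list(genomes = genomes, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random duplicate-copy losses until the single-copy pillar fraction is
# reached; always keeps >= 1 copy per pillar
.resolvePostWgd <- function(genome, config, branch) {
  losses <- list()
  repeat {
    g <- genome@genes
    tab <- table(g$pillar_id[!is.na(g$pillar_id)])
    frac <- mean(tab == 1L)
    if (frac >= config$post_wgd_single_copy_fraction) break
    dup <- names(tab)[tab >= 2L]
    pick <- sample(dup, 1L)
    ids <- g$gene_id[!is.na(g$pillar_id) & g$pillar_id == pick]
    ev <- geneLoss(sample(ids, 1L), branch = branch)
    genome <- applyEvent(genome, ev)
    losses[[length(losses) + 1L]] <- ev
  }
  attr(genome, "loss_log") <- losses
  genome
}

# arithmetic satisfiability check before any application
.checkSchedule <- function(ancestor, tr, schedule, labelOf) {
  ntip <- length(tr$tip.label)
  kindOf <- function(item)
    if (inherits(item, "RearrangementEvent")) item$kind
    else as.character(item)
  walk <- function(node, nchr) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    for (kid in kids) {
      n <- nchr
      for (item in schedule[[labelOf(kid)]] %||% list()) {
        k <- kindOf(item)
        if (k == "WGD") n <- n * 2L
        else if (k == "telomere_fusion_cen_loss") {
          if (n < 2L) stop("unsatisfiable schedule: fusion on branch '",
                           labelOf(kid), "' with ", n, " chromosome(s)")
          n <- n - 1L
        } else if (k == "centromere_fission") {
          if (n < 3L) stop("unsatisfiable schedule: fission on branch '",
                           labelOf(kid), "' with ", n, " chromosome(s)")
          n <- n - 1L
        }
      }
      if (kid > ntip) walk(kid, n)
    }
  }
  walk(ntip + 1L, chromosomeCount(ancestor))
  invisible(TRUE)
}

## ---- deliberate breakpoint-reuse fixtures --------------------------

#' Construct breakpoint-reuse fixtures
#'
#' Two deliberately chained rearrangement histories used to validate
#' cycle tracing on breakpoint reuse:
#'
#' * `cen9_pathway`: nine reciprocal translocations chained around one
#'   centromere; each event re-breaks the novel junction created by the
#'   previous event at the centromeric intergenic, so eight breakpoints
#'   are reused and all synteny on that side of the centromere is
#'   progressively erased.
#' * `klactis_cycle`: four chained reciprocal translocations forming a
#'   single closed cycle, three of them with a breakpoint at an
#'   ancestral centromeric intergenic.
#'
#' @param style `"cen9_pathway"` or `"klactis_cycle"`.
#' @param config a [simConfig()]; its seed drives the deterministic
#'   construction.
#' @return list with `ancestor` ([Genome-class]), `genome` (rearranged
#'   [Genome-class]) and `events` (ground-truth list).
#' @export
makeReuseFixture <- function(style = c("cen9_pathway", "klactis_cycle"),
                             config) {
  style <- match.arg(style)
  anc <- makeAncestor(config, with_sequences = FALSE)$genome
  cen <- anc@centromeres
  cenPosOf <- function(ch) cen$pos[cen$chrom_id == ch][1]
  g <- anc
  events <- list()
  doEvent <- function(ev) {
    g <<- applyEvent(g, ev)
    events[[length(events) + 1L]] <<- ev
  }
  tc <- anc@chromOrder[1]
  p <- cenPosOf(tc)
  if (style == "cen9_pathway") {
    partners <- c(anc@chromOrder[-1], anc@chromOrder[2:3])[1:9]
    used <- integer(0)
    for (k in 1:9) {
      pt <- partners[k]
      nth <- sum(names(used) == pt) + 1L
      q <- cenPosOf(pt) + c(8L, 4L)[nth]
      used <- c(used, setNames(q, pt))
      doEvent(reciprocalTranslocation(tc, p, pt, q, cen_side1 = "L",
                                      branch = "fixture"))
    }
  } else {
    cenChroms <- anc@chromOrder[2:4]
    ordinary <- anc@chromOrder[5:6]
    # e1: centromeric break x ordinary; e2, e3: reuse x centromeric;
    # e4: reuse x ordinary (closes the cycle)
    doEvent(reciprocalTranslocation(tc, p, ordinary[1],
                                    cenPosOf(ordinary[1]) + 8L,
                                    cen_side1 = "L", branch = "fixture"))
    doEvent(reciprocalTranslocation(tc, p, cenChroms[1],
                                    cenPosOf(cenChroms[1]),
                                    cen_side1 = "L", cen_side2 = "L",
                                    branch = "fixture"))
    doEvent(reciprocalTranslocation(tc, p, cenChroms[2],
                                    cenPosOf(cenChroms[2]),
                                    cen_side1 = "L", cen_side2 = "L",
                                    branch = "fixture"))
    doEvent(reciprocalTranslocation(tc, p, ordinary[2],
                                    cenPosOf(ordinary[2]) + 8L,
                                    cen_side1 = "L", branch = "fixture"))
  }
  list(ancestor = anc, genome = g, events = events)
}
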
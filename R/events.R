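#' @include accessors.R
NULL

EVENT_KINDS <- c("WGD", "reciprocal_translocation", "inversion",
                 "telomeric_translocation", "telomere_fusion_cen_loss",
                 "centromere_fission", "gene_loss", "centromere_loss")

#' Construct a rearrangement event
#'
#' Events are plain records (kind, branch, kind-specific participants)
#' applied to genomes with [applyEvent()]. Convenience constructors for
#' each kind are provided below.
#'
#' @param kind one of `r paste(EVENT_KINDS, collapse = ", ")`.
#' @param branch tree-branch identifier (child-node label) or `NA`.
#' @param ... kind-specific fields.
#' @return an object of class `RearrangementEvent`.
#' @export
rearrangementEvent <- function(kind, branch = NA_character_, ...) {
  kind <- match.arg(kind, EVENT_KINDS)
  structure(c(list(kind = kind, branch = branch), list(...)),
            class = "RearrangementEvent")
}

#' @rdname rearrangementEvent
#' @export
wgdEvent <- function(branch = NA_character_)
  rearrangementEvent("WGD", branch)

#' @rdname rearrangementEvent
#' @param chr1,chr2,chrom,donor,acceptor,acceptor1,acceptor2 chromosome ids.
#' @param pos1,pos2,pos intergenic positions (0..n, 0 = before first gene).
#' @param cen_side1,cen_side2 when a breakpoint coincides with a
#'   centromeric intergenic, which product keeps the centromere
#'   (`"L"` = the segment left of the breakpoint).
#' @export
reciprocalTranslocation <- function(chr1, pos1, chr2, pos2,
                                    cen_side1 = "L", cen_side2 = "L",
                                    branch = NA_character_)
  rearrangementEvent("reciprocal_translocation", branch, chr1 = chr1,
                     pos1 = as.integer(pos1), chr2 = chr2,
                     pos2 = as.integer(pos2), cen_side1 = cen_side1,
                     cen_side2 = cen_side2)

#' @rdname rearrangementEvent
#' @param start,end 1-based gene index interval to invert (inclusive).
#' @export
inversionEvent <- function(chrom, start, end, branch = NA_character_)
  rearrangementEvent("inversion", branch, chrom = chrom,
                     start = as.integer(start), end = as.integer(end))

#' @rdname rearrangementEvent
#' @param segment_side which side of `pos` moves (`"R"`: genes
#'   `pos+1..n`; `"L"`: genes `1..pos`).
#' @param acceptor_side chromosome end of the acceptor that receives the
#'   segment.
#' @export
telomericTranslocation <- function(donor, pos, acceptor,
                                   segment_side = "R",
                                   acceptor_side = "R",
                                   branch = NA_character_)
  rearrangementEvent("telomeric_translocation", branch, donor = donor,
                     pos = as.integer(pos), segment_side = segment_side,
                     acceptor = acceptor, acceptor_side = acceptor_side)

#' @rdname rearrangementEvent
#' @param side1,side2 fused telomere ends of `chr1` and `chr2`.
#' @param lost_cen ancestral label (or chromosome id) of the centromere
#'   that dies in the fusion.
#' @export
telomereFusion <- function(chr1, side1, chr2, side2, lost_cen,
                           branch = NA_character_)
  rearrangementEvent("telomere_fusion_cen_loss", branch, chr1 = chr1,
                     side1 = side1, chr2 = chr2, side2 = side2,
                     lost_cen = lost_cen)

#' @rdname rearrangementEvent
#' @export
centromereFission <- function(chrom, acceptor1, side1, acceptor2, side2,
                              branch = NA_character_)
  rearrangementEvent("centromere_fission", branch, chrom = chrom,
                     acceptor1 = acceptor1, side1 = side1,
                     acceptor2 = acceptor2, side2 = side2)

#' @rdname rearrangementEvent
#' @param gene_id gene copy to delete.
#' @export
geneLoss <- function(gene_id, branch = NA_character_)
  rearrangementEvent("gene_loss", branch, gene_id = gene_id)

#' @rdname rearrangementEvent
#' @param label ancestral label or chromosome id of the centromere.
#' @export
centromereLoss <- function(label, branch = NA_character_)
  rearrangementEvent("centromere_loss", branch, label = label)

#' @export
print.RearrangementEvent <- function(x, ...) {
  fields <- setdiff(names(x), c("kind", "branch"))
  cat(sprintf("<%s on %s: %s>\n", x$kind,
              ifelse(is.na(x$branch), "?", x$branch),
              paste(vapply(fields, function(f)
                paste0(f, "=", paste(x[[f]], collapse = ",")),
                character(1)), collapse = " ")))
  invisible(x)
}

## ---- internal chromosome manipulation ------------------------------

# a chromosome as list(genes = ordered data.frame, cens = data.frame)
.toChrList <- function(genome) {
  setNames(lapply(genome@chromOrder, function(ch) {
    list(genes = chromosomeGenes(genome, ch),
         cens = genome@centromeres[genome@centromeres$chrom_id == ch, ,
                                   drop = FALSE])
  }), genome@chromOrder)
}

.fromChrList <- function(genome, chrs) {
  glist <- list(); clist <- list()
  for (ch in names(chrs)) {
    g <- chrs[[ch]]$genes
    if (nrow(g)) {
      g$chrom_id <- ch
      g$idx <- seq_len(nrow(g))
    }
    glist[[ch]] <- g
    cen <- chrs[[ch]]$cens
    if (nrow(cen)) cen$chrom_id <- ch
    clist[[ch]] <- cen
  }
  Genome(species = genome@species,
         genes = do.call(rbind, glist),
         centromeres = do.call(rbind, clist),
         wgdStatus = genome@wgdStatus,
         chromOrder = names(chrs))
}

.flipChr <- function(chr) {
  n <- nrow(chr$genes)
  g <- chr$genes[rev(seq_len(n)), , drop = FALSE]
  g$orientation <- ifelse(g$orientation == "+", "-", "+")
  cen <- chr$cens
  if (nrow(cen)) {
    cen$pos <- n - cen$pos
    cen$strand <- ifelse(cen$strand == "+", "-", "+")
  }
  list(genes = g, cens = cen)
}

# split at intergenic p; a centromere sitting exactly at p follows
# cen_side ("L": stays with the left segment)
.splitChr <- function(chr, p, cen_side = "L") {
  n <- nrow(chr$genes)
  stopifnot(p >= 0, p <= n)
  gL <- chr$genes[seq_len(p), , drop = FALSE]
  gR <- chr$genes[setdiff(seq_len(n), seq_len(p)), , drop = FALSE]
  cen <- chr$cens
  goesLeft <- cen$pos < p | (cen$pos == p & cen_side == "L")
  cL <- cen[goesLeft, , drop = FALSE]
  cR <- cen[!goesLeft, , drop = FALSE]
  if (nrow(cR)) cR$pos <- cR$pos - p
  list(left = list(genes = gL, cens = cL),
       right = list(genes = gR, cens = cR))
}

.concatChr <- function(a, b) {
  cb <- b$cens
  if (nrow(cb)) cb$pos <- cb$pos + nrow(a$genes)
  list(genes = rbind(a$genes, b$genes), cens = rbind(a$cens, cb))
}

.invertChr <- function(chr, i, j) {
  n <- nrow(chr$genes)
  stopifnot(i >= 1, j <= n, i <= j)
  g <- chr$genes
  seg <- g[i:j, , drop = FALSE]
  seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$orientation <- ifelse(seg$orientation == "+", "-", "+")
  g[i:j, ] <- seg
  cen <- chr$cens
  inside <- cen$pos >= i & cen$pos <= j - 1L
  if (any(inside)) {
    cen$pos[inside] <- i - 1L + (j - cen$pos[inside])
    cen$strand[inside] <- ifelse(cen$strand[inside] == "+", "-", "+")
  }
  list(genes = g, cens = cen)
}

.nCen <- function(chr) nrow(chr$cens)

.rejectEvent <- function(msg) {
  stop(structure(class = c("karyevol_rejected_event", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## ---- applyEvent ----------------------------------------------------

#' Apply a rearrangement event to a genome
#'
#' Pure: the input genome is untouched; a new genome is returned.
#' Chromosome DNA sequences, if present, are dropped (events operate on
#' gene order and centromere annotations).
#'
#' A reciprocal translocation whose products would carry zero or two
#' centromeres raises a rejected-event error (condition class
#' `karyevol_rejected_event`); callers placing random events may catch
#' it and resample. A fusion naming a centromere found on neither
#' participant is an error.
#'
#' @param genome a [Genome-class].
#' @param event a `RearrangementEvent`.
#' @return the rearranged [Genome-class].
#' @export
applyEvent <- function(genome, event) {
  stopifnot(inherits(event, "RearrangementEvent"))
  genome@sequences <- NULL
  genome@cenSpans <- data.frame()
  switch(event$kind,
    WGD = .applyWgd(genome),
    reciprocal_translocation = .applyRecip(genome, event),
    inversion = .applyInversion(genome, event),
    telomeric_translocation = .applyTelTrans(genome, event),
    telomere_fusion_cen_loss = .applyFusion(genome, event),
    centromere_fission = .applyFission(genome, event),
    gene_loss = .applyGeneLoss(genome, event),
    centromere_loss = .applyCenLoss(genome, event),
    stop("unknown event kind: ", event$kind))
}

.applyWgd <- function(genome) {
  chrs <- .toChrList(genome)
  out <- list()
  for (ch in names(chrs)) {
    for (copy in c("1", "2")) {
      nc <- chrs[[ch]]
      nc$genes$gene_id <- paste0(nc$genes$gene_id, "_", copy)
      out[[paste0(ch, "_", copy)]] <- nc
    }
  }
  g <- .fromChrList(genome, out)
  g@wgdStatus <- "post-WGD"
  g
}

.chk <- function(genome, ch) {
  if (!ch %in% genome@chromOrder)
    stop("unknown chromosome: ", ch)
}

.applyRecip <- function(genome, e) {
  .chk(genome, e$chr1); .chk(genome, e$chr2)
  if (e$chr1 == e$chr2)
    stop("reciprocal translocation needs two distinct chromosomes")
  chrs <- .toChrList(genome)
  s1 <- .splitChr(chrs[[e$chr1]], e$pos1, e$cen_side1)
  s2 <- .splitChr(chrs[[e$chr2]], e$pos2, e$cen_side2)
  p1 <- .concatChr(s1$left, s2$right)
  p2 <- .concatChr(s2$left, s1$right)
  if (.nCen(p1) != 1L || .nCen(p2) != 1L)
    .rejectEvent(sprintf(
      "translocation %s:%d x %s:%d yields products with %d and %d centromeres",
      e$chr1, e$pos1, e$chr2, e$pos2, .nCen(p1), .nCen(p2)))
  chrs[[e$chr1]] <- p1
  chrs[[e$chr2]] <- p2
  .fromChrList(genome, chrs)
}

.applyInversion <- function(genome, e) {
  .chk(genome, e$chrom)
  chrs <- .toChrList(genome)
  chrs[[e$chrom]] <- .invertChr(chrs[[e$chrom]], e$start, e$end)
  .fromChrList(genome, chrs)
}

.applyTelTrans <- function(genome, e) {
  .chk(genome, e$donor); .chk(genome, e$acceptor)
  if (e$donor == e$acceptor)
    stop("telomeric translocation needs distinct donor and acceptor")
  chrs <- .toChrList(genome)
  sp <- .splitChr(chrs[[e$donor]], e$pos,
                  cen_side = if (e$segment_side == "R") "L" else "R")
  if (e$segment_side == "R") { seg <- sp$right; rest <- sp$left }
  else { seg <- sp$left; rest <- sp$right }
  if (.nCen(seg) != 0L || .nCen(rest) != 1L)
    .rejectEvent("telomeric translocation would move or strand a centromere")
  acc <- chrs[[e$acceptor]]
  # keep the segment's telomeric end outermost at its new home
  if (e$acceptor_side == "R") {
    segR <- if (e$segment_side == "R") seg else .flipChr(seg)
    acc <- .concatChr(acc, segR)
  } else {
    segL <- if (e$segment_side == "L") seg else .flipChr(seg)
    acc <- .concatChr(segL, acc)
  }
  chrs[[e$donor]] <- rest
  chrs[[e$acceptor]] <- acc
  .fromChrList(genome, chrs)
}

.findCen <- function(cens, label) {
  hit <- which(cens$ancestral_label == label | cens$chrom_id == label)
  hit
}

.applyFusion <- function(genome, e) {
  .chk(genome, e$chr1); .chk(genome, e$chr2)
  if (e$chr1 == e$chr2) stop("fusion needs two distinct chromosomes")
  chrs <- .toChrList(genome)
  a <- chrs[[e$chr1]]; b <- chrs[[e$chr2]]
  if (e$side1 == "L") a <- .flipChr(a)
  if (e$side2 == "R") b <- .flipChr(b)
  fused <- .concatChr(a, b)
  hit <- .findCen(fused$cens, e$lost_cen)
  if (!length(hit))
    stop("fusion names centromere '", e$lost_cen,
         "' which is on neither participant")
  fused$cens <- fused$cens[-hit[1], , drop = FALSE]
  newId <- paste0(e$chr1, "+", e$chr2)
  keep <- setdiff(names(chrs), c(e$chr1, e$chr2))
  chrs <- chrs[keep]
  chrs[[newId]] <- fused
  .fromChrList(genome, chrs)
}

.applyFission <- function(genome, e) {
  .chk(genome, e$chrom); .chk(genome, e$acceptor1); .chk(genome, e$acceptor2)
  if (length(unique(c(e$chrom, e$acceptor1, e$acceptor2))) != 3L)
    stop("fission needs three distinct chromosomes")
  chrs <- .toChrList(genome)
  src <- chrs[[e$chrom]]
  if (.nCen(src) != 1L)
    stop("fission source must carry exactly one centromere")
  p <- src$cens$pos[1]
  sp <- .splitChr(src, p, cen_side = "L")
  armL <- sp$left; armR <- sp$right
  armL$cens <- armL$cens[0, , drop = FALSE]  # the centromere dies
  # broken edge of the left arm is its right end; of the right arm its left
  a1 <- chrs[[e$acceptor1]]
  a2 <- chrs[[e$acceptor2]]
  chrs[[e$acceptor1]] <- if (e$side1 == "R") .concatChr(a1, .flipChr(armL))
                         else .concatChr(armL, a1)
  chrs[[e$acceptor2]] <- if (e$side2 == "R") .concatChr(a2, armR)
                         else .concatChr(.flipChr(armR), a2)
  chrs[[e$chrom]] <- NULL
  .fromChrList(genome, chrs)
}

.applyGeneLoss <- function(genome, e) {
  g <- genome@genes
  row <- which(g$gene_id == e$gene_id)
  if (!length(row)) stop("unknown gene: ", e$gene_id)
  ch <- g$chrom_id[row]; i <- g$idx[row]
  chrs <- .toChrList(genome)
  chr <- chrs[[ch]]
  chr$genes <- chr$genes[chr$genes$gene_id != e$gene_id, , drop = FALSE]
  if (nrow(chr$cens)) {
    adj <- chr$cens$pos >= i
    chr$cens$pos[adj] <- chr$cens$pos[adj] - 1L
  }
  chrs[[ch]] <- chr
  .fromChrList(genome, chrs)
}

.applyCenLoss <- function(genome, e) {
  cen <- genome@centromeres
  hit <- .findCen(cen, e$label)
  if (!length(hit)) stop("no centromere matching '", e$label, "'")
  genome@centromeres <- cen[-hit[1], , drop = FALSE]
  genome
}

#' Apply a sequence of events
#'
#' @param genome a [Genome-class].
#' @param events list of `RearrangementEvent`s, applied in order.
#' @export
applyEvents <- function(genome, events) {
  for (e in events) genome <- applyEvent(genome, e)
  genome
}
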
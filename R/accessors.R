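#' @include AllClasses.R
NULL

#' Construct a Genome object
#'
#' @param species species name.
#' @param genes data.frame with columns `gene_id`, `pillar_id`,
#'   `chrom_id`, `idx`, `orientation`, `subtelomeric`. `pillar_id` uses
#'   `NA` for genes without an ancestral counterpart.
#' @param centromeres data.frame with columns `chrom_id`, `pos`,
#'   `strand`, `ancestral_label`, `cde1_seq`, `cde2_seq`, `cde3_seq`;
#'   missing columns are filled with `NA`.
#' @param wgdStatus `"non-WGD"` (default) or `"post-WGD"`.
#' @param chromOrder ordered chromosome ids; defaults to order of first
#'   appearance in `genes`.
#' @param sequences optional named [Biostrings::DNAStringSet].
#' @param cenSpans optional data.frame of centromere DNA spans.
#' @return a validated [Genome-class] object.
#' @export
Genome <- function(species, genes, centromeres = NULL,
                   wgdStatus = "non-WGD", chromOrder = NULL,
                   sequences = NULL, cenSpans = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(chromOrder)) chromOrder <- unique(genes$chrom_id)
  if (is.null(centromeres) || nrow(centromeres) == 0L) {
    centromeres <- emptyCentromeres()
  } else {
    centromeres <- as.data.frame(centromeres, stringsAsFactors = FALSE)
    for (cc in .CEN_COLS)
      if (!cc %in% names(centromeres)) centromeres[[cc]] <- NA_character_
    centromeres <- centromeres[.CEN_COLS]
    centromeres$pos <- as.integer(centromeres$pos)
  }
  genes$idx <- as.integer(genes$idx)
  genes$subtelomeric <- as.logical(genes$subtelomeric)
  ord <- order(match(genes$chrom_id, chromOrder), genes$idx)
  genes <- genes[ord, .GENE_COLS, drop = FALSE]
  rownames(genes) <- NULL
  cen <- centromeres[order(match(centromeres$chrom_id, chromOrder)), ,
                     drop = FALSE]
  rownames(cen) <- NULL
  if (is.null(cenSpans)) cenSpans <- data.frame()
  new("Genome", species = species, wgdStatus = wgdStatus, genes = genes,
      centromeres = cen, chromOrder = chromOrder, sequences = sequences,
      cenSpans = cenSpans)
}

emptyCentromeres <- function() {
  data.frame(chrom_id = character(0), pos = integer(0),
             strand = character(0), ancestral_label = character(0),
             cde1_seq = character(0), cde2_seq = character(0),
             cde3_seq = character(0), stringsAsFactors = FALSE)
}

#' @rdname Genome
#' @param object,x a `Genome`.
#' @export
setGeneric("species", function(x) standardGeneric("species"))
#' @rdname Genome
#' @export
setMethod("species", "Genome", function(x) x@species)

#' @rdname Genome
#' @export
setGeneric("wgdStatus", function(x) standardGeneric("wgdStatus"))
#' @rdname Genome
#' @export
setMethod("wgdStatus", "Genome", function(x) x@wgdStatus)

#' @rdname Genome
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname Genome
#' @export
setMethod("geneTable", "Genome", function(x) x@genes)

#' @rdname Genome
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))
#' @rdname Genome
#' @export
setMethod("centromeres", "Genome", function(x) x@centromeres)

#' @rdname Genome
#' @export
setGeneric("chromosomeIds", function(x) standardGeneric("chromosomeIds"))
#' @rdname Genome
#' @export
setMethod("chromosomeIds", "Genome", function(x) x@chromOrder)

#' @rdname Genome
#' @export
setGeneric("chromosomeCount", function(x) standardGeneric("chromosomeCount"))
#' @rdname Genome
#' @export
setMethod("chromosomeCount", "Genome", function(x) length(x@chromOrder))

#' @rdname Genome
#' @export
setGeneric("centromereCount", function(x) standardGeneric("centromereCount"))
#' @rdname Genome
#' @export
setMethod("centromereCount", "Genome", function(x) nrow(x@centromeres))

#' @rdname Genome
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @rdname Genome
#' @export
setMethod("genomeSequences", "Genome", function(x) x@sequences)

#' Gene list of one chromosome, in order
#'
#' @param x a [Genome-class].
#' @param chrom chromosome id.
#' @return data.frame of the chromosome's genes ordered by `idx`.
#' @export
chromosomeGenes <- function(x, chrom) {
  g <- x@genes[x@genes$chrom_id == chrom, , drop = FALSE]
  g[order(g$idx), , drop = FALSE]
}

#' Telomere ends of every chromosome
#'
#' The telomere location of a chromosome end is defined as the location
#' beside the outermost gene that carries a pillar id (an ancestral
#' ortholog); genes beyond that boundary are the subtelomeric zone of
#' that end. Chromosomes whose genes carry no pillar at all report `NA`
#' boundaries.
#'
#' @param x a [Genome-class].
#' @return data.frame with columns `chrom_id`, `side` (`"L"`/`"R"`),
#'   `boundary_gene`, `boundary_pillar`, `n_subtelomeric`.
#' @export
telomereEnds <- function(x) {
  res <- lapply(x@chromOrder, function(ch) {
    g <- chromosomeGenes(x, ch)
    hasP <- !is.na(g$pillar_id)
    if (!any(hasP)) {
      return(data.frame(chrom_id = ch, side = c("L", "R"),
                        boundary_gene = NA_character_,
                        boundary_pillar = NA_character_,
                        n_subtelomeric = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    iL <- which(hasP)[1]
    iR <- tail(which(hasP), 1)
    data.frame(
      chrom_id = ch, side = c("L", "R"),
      boundary_gene = c(g$gene_id[iL], g$gene_id[iR]),
      boundary_pillar = c(g$pillar_id[iL], g$pillar_id[iR]),
      n_subtelomeric = c(iL - 1L, nrow(g) - iR),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Check that a genome is a valid resolved karyotype
#'
#' A resolved karyotype has exactly one centromere per chromosome (and
#' hence two telomere ends per chromosome). Intermediate states during
#' event application may violate this; this check is therefore separate
#' from the structural class validity.
#'
#' @param x a [Genome-class].
#' @return `TRUE`, or a character vector of problems.
#' @export
validKaryotype <- function(x) {
  cnt <- table(factor(x@centromeres$chrom_id, levels = x@chromOrder))
  bad <- names(cnt)[cnt != 1L]
  if (!length(bad)) TRUE
  else sprintf("chromosome %s has %d centromeres", bad,
               as.integer(cnt[bad]))
}

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome of %s (%s)\n", object@species, object@wgdStatus))
  cat(sprintf("  %d chromosomes, %d genes (%d with pillar), %d centromeres\n",
              length(object@chromOrder), nrow(object@genes),
              sum(!is.na(object@genes$pillar_id)),
              nrow(object@centromeres)))
  if (!is.null(object@sequences))
    cat(sprintf("  sequences: %d chromosomes, %.1f kb total\n",
                length(object@sequences),
                sum(Biostrings::width(object@sequences)) / 1000))
})

#' @rdname ConsensusModel-class
#' @param pfmCde1,pfmCde3 count matrices (4 rows A,C,G,T).
#' @param cde2Window integer length-2 CDEII length window (bp).
#' @param cde2MinAT minimum CDEII AT fraction.
#' @param background base composition (A,C,G,T), defaults to uniform.
#' @param pseudocount pseudocount per base per position (default 1).
#' @export
ConsensusModel <- function(pfmCde1, pfmCde3, cde2Window, cde2MinAT = 0.76,
                           background = rep(0.25, 4), pseudocount = 1) {
  rn <- c("A", "C", "G", "T")
  pfmCde1 <- as.matrix(pfmCde1); rownames(pfmCde1) <- rn
  pfmCde3 <- as.matrix(pfmCde3); rownames(pfmCde3) <- rn
  new("ConsensusModel", pfmCde1 = pfmCde1, pfmCde3 = pfmCde3,
      cde2Window = as.integer(cde2Window), cde2MinAT = cde2MinAT,
      background = setNames(background, rn), pseudocount = pseudocount)
}

setMethod("show", "ConsensusModel", function(object) {
  cs <- consensusIupac(object)
  cat("Point-centromere consensus model\n")
  cat(sprintf("  CDEI  (8 bp):  %s  [%d invariant]\n", cs$cde1_iupac,
              length(cs$invariant_cde1)))
  cat(sprintf("  CDEIII (26 bp): %s  [%d invariant]\n", cs$cde3_iupac,
              length(cs$invariant_cde3)))
  cat(sprintf("  CDEII: length %d-%d bp, AT >= %.2f\n",
              object@cde2Window[1], object@cde2Window[2],
              object@cde2MinAT))
})

#' @rdname SpeciesTree-class
#' @param tree an `ape` phylo object.
#' @param wgdNode label of the WGD internal node (`NA` allowed).
#' @export
SpeciesTree <- function(tree, wgdNode = NA_character_) {
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    lab <- tree$node.label
    if (is.null(lab)) lab <- rep("", tree$Nnode)
    empty <- lab == ""
    lab[empty] <- paste0("N", which(empty))
    tree$node.label <- lab
  }
  new("SpeciesTree", tree = tree, wgdNode = as.character(wgdNode))
}

#' Leaf names of a species tree
#' @param x a [SpeciesTree-class].
#' @export
treeLeaves <- function(x) x@tree$tip.label

#' Post-WGD leaves of a species tree
#'
#' Leaves descending from the marked WGD node.
#' @param x a [SpeciesTree-class].
#' @export
postWgdLeaves <- function(x) {
  if (is.na(x@wgdNode)) return(character(0))
  tr <- x@tree
  node <- length(tr$tip.label) + match(x@wgdNode, tr$node.label)
  tips <- .cladeTips(tr, node)
  tr$tip.label[tips]
}

# tip indices under an (internal or tip) node
.cladeTips <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, .cladeTips, tr = tr))
}

setMethod("show", "SpeciesTree", function(object) {
  cat(sprintf("SpeciesTree: %d leaves, WGD node: %s\n",
              length(object@tree$tip.label),
              ifelse(is.na(object@wgdNode), "none", object@wgdNode)))
  post <- postWgdLeaves(object)
  if (length(post))
    cat("  post-WGD:", paste(post, collapse = ", "), "\n")
})
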
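#' @import methods
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils head tail read.delim write.table
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' Genome: species gene order, centromeres and optional sequences
#'
#' Central container of the package. A `Genome` holds the ordered gene
#' content of every chromosome of one species, its point-centromere
#' annotations, and (optionally) the chromosome DNA sequences.
#'
#' Gene order is stored as one data frame with columns `gene_id`
#' (unique), `pillar_id` (ancestral ortholog-column identifier, `NA` when
#' the gene has no ancestral counterpart, e.g. subtelomeric repeat-family
#' genes), `chrom_id`, `idx` (1-based position in the chromosome's gene
#' order), `orientation` (`"+"`/`"-"`) and `subtelomeric` (logical).
#'
#' Centromeres are point centromeres living in intergenic space:
#' `pos` is an integer in `0..n` meaning "between gene `pos` and gene
#' `pos + 1`" (0 = before the first gene). Each row may carry the CDEI
#' (8 bp), CDEII (AT-rich spacer) and CDEIII (26 bp) sequences, a strand,
#' and the label of the ancestral centromere it derives from.
#'
#' @slot species single species name.
#' @slot wgdStatus `"non-WGD"` or `"post-WGD"`.
#' @slot genes data.frame of gene records (see Details).
#' @slot centromeres data.frame with columns `chrom_id`, `pos`, `strand`,
#'   `ancestral_label`, `cde1_seq`, `cde2_seq`, `cde3_seq` (sequence
#'   columns may be `NA`).
#' @slot chromOrder character vector giving the display/storage order of
#'   chromosomes.
#' @slot sequences optional [Biostrings::DNAStringSet] named by
#'   chromosome, or `NULL`.
#' @slot cenSpans data.frame of DNA coordinates (1-based, closed) of
#'   annotated centromere elements when sequences are present; zero rows
#'   otherwise.
#'
#' @export
setClass("Genome",
  slots = c(
    species = "character",
    wgdStatus = "character",
    genes = "data.frame",
    centromeres = "data.frame",
    chromOrder = "character",
    sequences = "DNAStringSetOrNULL",
    cenSpans = "data.frame"
  ),
  prototype = list(
    species = "unnamed",
    wgdStatus = "non-WGD",
    genes = data.frame(),
    centromeres = data.frame(),
    chromOrder = character(0),
    sequences = NULL,
    cenSpans = data.frame()
  )
)

.GENE_COLS <- c("gene_id", "pillar_id", "chrom_id", "idx", "orientation",
                "subtelomeric")
.CEN_COLS <- c("chrom_id", "pos", "strand", "ancestral_label",
               "cde1_seq", "cde2_seq", "cde3_seq")

.validGenome <- function(object) {
  msg <- character(0)
  g <- object@genes
  if (length(object@species) != 1L)
    msg <- c(msg, "species must be a single string")
  if (!object@wgdStatus %in% c("non-WGD", "post-WGD"))
    msg <- c(msg, "wgdStatus must be 'non-WGD' or 'post-WGD'")
  if (nrow(g)) {
    if (!all(.GENE_COLS %in% names(g)))
      msg <- c(msg, paste("genes must have columns:",
                          paste(.GENE_COLS, collapse = ", ")))
    else {
      if (anyDuplicated(g$gene_id))
        msg <- c(msg, "duplicate gene_id")
      if (!all(g$orientation %in% c("+", "-")))
        msg <- c(msg, "orientation must be '+' or '-'")
      for (ch in unique(g$chrom_id)) {
        idx <- sort(g$idx[g$chrom_id == ch])
        if (!identical(idx, seq_along(idx)))
          msg <- c(msg, sprintf(
            "chromosome %s: gene indices must be 1..n with no gaps or duplicates",
            ch))
      }
      if (!all(unique(g$chrom_id) %in% object@chromOrder))
        msg <- c(msg, "chromOrder must cover all chromosomes in genes")
    }
  }
  cen <- object@centromeres
  if (nrow(cen)) {
    if (!all(.CEN_COLS %in% names(cen)))
      msg <- c(msg, paste("centromeres must have columns:",
                          paste(.CEN_COLS, collapse = ", ")))
    else {
      if (!all(cen$chrom_id %in% object@chromOrder))
        msg <- c(msg, "centromere on unknown chromosome")
      nper <- table(factor(g$chrom_id, levels = object@chromOrder))
      bad <- cen$pos < 0 | cen$pos > nper[cen$chrom_id]
      if (any(bad))
        msg <- c(msg, "centromere intergenic position outside 0..n")
      ok1 <- is.na(cen$cde1_seq) | nchar(cen$cde1_seq) == 8L
      ok3 <- is.na(cen$cde3_seq) | nchar(cen$cde3_seq) == 26L
      if (!all(ok1)) msg <- c(msg, "cde1_seq must be 8 bp when present")
      if (!all(ok3)) msg <- c(msg, "cde3_seq must be 26 bp when present")
    }
  }
  if (!is.null(object@sequences)) {
    if (is.null(names(object@sequences)) ||
        !all(object@chromOrder %in% names(object@sequences)))
      msg <- c(msg, "sequences must be named by chromosome id")
  }
  if (length(msg)) msg else TRUE
}

setValidity("Genome", .validGenome)

#' Consensus model for point-centromere elements
#'
#' Position frequency matrices (counts) for the 8 bp CDEI and 26 bp
#' CDEIII elements, together with the CDEII spacer constraints (length
#' window and minimum AT fraction), a background base composition and a
#' pseudocount used for log-odds scoring.
#'
#' @slot pfmCde1 4 x 8 count matrix, rows `A,C,G,T`.
#' @slot pfmCde3 4 x 26 count matrix, rows `A,C,G,T`.
#' @slot cde2Window integer length-2 vector, allowed CDEII lengths (bp).
#' @slot cde2MinAT minimum CDEII AT fraction in `[0,1]`.
#' @slot background length-4 base composition summing to 1 (A,C,G,T).
#' @slot pseudocount nonnegative number added per base per position.
#'
#' @export
setClass("ConsensusModel",
  slots = c(
    pfmCde1 = "matrix",
    pfmCde3 = "matrix",
    cde2Window = "integer",
    cde2MinAT = "numeric",
    background = "numeric",
    pseudocount = "numeric"
  )
)

.validConsensusModel <- function(object) {
  msg <- character(0)
  if (!identical(dim(object@pfmCde1), c(4L, 8L)))
    msg <- c(msg, "pfmCde1 must be 4 x 8")
  if (!identical(dim(object@pfmCde3), c(4L, 26L)))
    msg <- c(msg, "pfmCde3 must be 4 x 26")
  if (any(object@pfmCde1 < 0) || any(object@pfmCde3 < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (length(object@cde2Window) != 2L ||
      object@cde2Window[1] > object@cde2Window[2])
    msg <- c(msg, "cde2Window must be a nonempty integer range")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 values summing to 1")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (object@cde2MinAT < 0 || object@cde2MinAT > 1)
    msg <- c(msg, "cde2MinAT must be in [0,1]")
  if (length(msg)) msg else TRUE
}

setValidity("ConsensusModel", .validConsensusModel)

#' Rooted species tree with a marked whole-genome duplication node
#'
#' Wraps an [ape::read.tree] `phylo` object. The WGD node is identified
#' by its internal node label; leaves descending from it are post-WGD,
#' all others non-WGD. Internal nodes carry labels so that rearrangement
#' events can be assigned to named branches (a branch is named after its
#' child node).
#'
#' @slot tree an `ape` phylo object (rooted, node labels present).
#' @slot wgdNode label of the internal node marking the WGD, or `NA` if
#'   the tree contains no post-WGD lineage.
#'
#' @export
setClass("SpeciesTree",
  slots = c(tree = "ANY", wgdNode = "character")
)

.validSpeciesTree <- function(object) {
  msg <- character(0)
  tr <- object@tree
  if (!inherits(tr, "phylo")) msg <- c(msg, "tree must be a phylo object")
  else {
    if (is.null(tr$node.label) || any(tr$node.label == ""))
      msg <- c(msg, "all internal nodes must be labelled")
    if (!is.na(object@wgdNode) && !object@wgdNode %in% tr$node.label)
      msg <- c(msg, sprintf("wgdNode '%s' not among node labels",
                            object@wgdNode))
  }
  if (length(msg)) msg else TRUE
}

setValidity("SpeciesTree", .validSpeciesTree)
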
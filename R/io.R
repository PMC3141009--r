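#' @include accessors.R
NULL

# Sentinel used in files for "no ancestral pillar". An explicit token
# (never an empty field) so that absence of an ortholog is
# distinguishable from a parse failure.
PILLAR_ABSENT <- "NONE"

#' Read a gene-order table
#'
#' Tab-separated file with header columns `gene_id`, `chrom_id`, `idx`,
#' `orientation`, `pillar_id`, `subtelomeric`. Gene indices are 1-based
#' within each chromosome; `pillar_id` uses the sentinel `NONE` for
#' genes without an ancestral ortholog. Rows may appear in any order.
#'
#' @param path file path.
#' @param species species name; default taken from the file name.
#' @param wgdStatus `"non-WGD"` or `"post-WGD"`.
#' @return a [Genome-class].
#' @export
readGeneOrder <- function(path, species = NULL, wgdStatus = "non-WGD") {
  if (is.null(species))
    species <- sub("\\.[^.]*$", "", basename(path))
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom_id", "idx", "orientation", "pillar_id",
            "subtelomeric")
  if (!all(need %in% names(d)))
    stop("malformed gene-order file ", path, ": missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  bad <- !d$orientation %in% c("+", "-")
  if (any(bad))
    stop("malformed gene-order file ", path, ": unknown orientation '",
         d$orientation[which(bad)[1]], "' in row ", which(bad)[1])
  for (ch in unique(d$chrom_id)) {
    idx <- d$idx[d$chrom_id == ch]
    if (anyDuplicated(idx)) {
      dup <- idx[duplicated(idx)][1]
      row <- which(d$chrom_id == ch & d$idx == dup)[1]
      stop("malformed gene-order file ", path, ": duplicate index ", dup,
           " on chromosome ", ch, " (row ", row, ")")
    }
    if (!setequal(idx, seq_along(idx)))
      stop("malformed gene-order file ", path, ": indices on chromosome ",
           ch, " are not 1..n")
  }
  if (any(is.na(d$pillar_id) | d$pillar_id == ""))
    stop("malformed gene-order file ", path,
         ": empty pillar_id (use sentinel '", PILLAR_ABSENT, "')")
  d$pillar_id[d$pillar_id == PILLAR_ABSENT] <- NA_character_
  d$subtelomeric <- as.logical(d$subtelomeric)
  Genome(species = species,
         genes = d[, c("gene_id", "pillar_id", "chrom_id", "idx",
                       "orientation", "subtelomeric")],
         wgdStatus = wgdStatus)
}

#' Write a gene-order table
#'
#' @param genome a [Genome-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneOrder <- function(genome, path) {
  g <- genome@genes
  out <- data.frame(gene_id = g$gene_id, chrom_id = g$chrom_id,
                    idx = g$idx, orientation = g$orientation,
                    pillar_id = ifelse(is.na(g$pillar_id), PILLAR_ABSENT,
                                       g$pillar_id),
                    subtelomeric = as.integer(g$subtelomeric),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write chromosome sequences as FASTA
#'
#' Reading uppercases all bases; names are taken up to the first
#' whitespace of the FASTA header.
#'
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet] for `readFastaSequences`.
#' @export
readFastaSequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  # DNAStringSet stores bases uppercased already for lowercase input
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' @rdname readFastaSequences
#' @param seqs named [Biostrings::DNAStringSet] (or named character).
#' @export
writeFastaSequences <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a species tree with WGD annotation
#'
#' Newick file whose internal node labels name the tree nodes; the node
#' labelled `WGD` (or matching `wgdLabel`) marks the whole-genome
#' duplication. All leaves below it are post-WGD.
#'
#' @param path Newick file.
#' @param wgdLabel label identifying the WGD node (default `"WGD"`).
#' @param requireWgd error when no WGD node is present (set when the
#'   dataset contains post-WGD species).
#' @return a [SpeciesTree-class].
#' @export
readSpeciesTree <- function(path, wgdLabel = "WGD", requireWgd = FALSE) {
  tr <- ape::read.tree(path)
  hit <- if (!is.null(tr$node.label)) grep(wgdLabel, tr$node.label,
                                           fixed = TRUE) else integer(0)
  if (!length(hit)) {
    if (requireWgd)
      stop("tree at ", path, " has no node labelled '", wgdLabel,
           "' but post-WGD species are present")
    return(SpeciesTree(tr, NA_character_))
  }
  SpeciesTree(tr, tr$node.label[hit[1]])
}

#' @rdname readSpeciesTree
#' @param x a [SpeciesTree-class].
#' @export
writeSpeciesTree <- function(x, path) {
  ape::write.tree(x@tree, file = path)
  invisible(path)
}

#' Read/write centromere annotations (BED-like TSV)
#'
#' Columns: `chrom_id`, `pos` (intergenic index), `strand`,
#' `ancestral_label`, `cde1_seq`, `cde2_seq`, `cde3_seq`. Missing
#' sequences use the `NONE` sentinel.
#'
#' @param path file path.
#' @export
readCentromereTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  for (cc in c("ancestral_label", "cde1_seq", "cde2_seq", "cde3_seq"))
    d[[cc]][d[[cc]] == PILLAR_ABSENT] <- NA_character_
  d$pos <- as.integer(d$pos)
  d[.CEN_COLS]
}

#' @rdname readCentromereTable
#' @param cen centromere data.frame (as in [centromeres()]).
#' @export
writeCentromereTable <- function(cen, path) {
  out <- cen[.CEN_COLS]
  for (cc in c("ancestral_label", "cde1_seq", "cde2_seq", "cde3_seq"))
    out[[cc]][is.na(out[[cc]])] <- PILLAR_ABSENT
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a rearrangement event log
#'
#' Events are serialized as a structured-text (YAML) list; each entry
#' records the event `kind`, the tree `branch` it happened on, and the
#' kind-specific participants. Round-trips losslessly.
#'
#' @param events list of events (see [rearrangementEvent()]).
#' @param path file path.
#' @export
writeEventLog <- function(events, path) {
  ser <- lapply(events, function(e) {
    e <- unclass(e)
    e[!vapply(e, is.null, logical(1))]
  })
  yaml::write_yaml(list(events = ser), path)
  invisible(path)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw$events, function(e) {
    if (!is.null(e$participants)) {
      e$participants <- lapply(e$participants, function(p) {
        if (is.list(p)) p else p
      })
    }
    structure(e, class = "RearrangementEvent")
  })
}
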
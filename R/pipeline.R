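#' @include classify.R consensus.R
NULL

#' Run the full karyotype-evolution analysis pipeline
#'
#' Orchestrates the analysis end to end for a set of extant genomes
#' against an ancestral genome: map centromeres and telomere locations,
#' trace breakpoint cycles and count rearrangements, classify
#' chromosome-number-changing mechanisms, assign shared events to tree
#' branches, and summarize centromere structure (consensus strings and
#' CDEII statistics). Writes a report bundle to `out_dir` and returns
#' it invisibly.
#'
#' @param genomes named list of extant [Genome-class] objects, or a
#'   directory of `<species>.tsv` gene-order files with matching
#'   `<species>.cen.tsv` centromere tables.
#' @param ancestral the ancestral [Genome-class], or a directory with
#'   `ancestor.tsv` + `ancestor.cen.tsv`.
#' @param tree a [SpeciesTree-class] or a Newick file path.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param w mapper flank window (default 5).
#' @param min_block_len,max_gap synteny-block parameters.
#' @param seed echoed in the run log (the pipeline itself is
#'   deterministic).
#' @return list with per-species results (`fates`, `calls`,
#'   `rearrangements`), the branch assignment table, the fate count
#'   summary, the consensus report, and predicted chromosome numbers.
#' @export
runPipeline <- function(genomes, ancestral, tree = NULL, out_dir = NULL,
                        w = 5L, min_block_len = 2L, max_gap = 1L,
                        seed = NA_integer_) {
  if (is.character(genomes)) genomes <- .readGenomeDir(genomes)
  if (is.character(ancestral)) {
    anc <- .readGenomeDir(ancestral)
    ancestral <- anc[[1]]
  }
  if (is.character(tree)) tree <- readSpeciesTree(tree)
  stopifnot(length(genomes) >= 1L,
            all(vapply(genomes, is, logical(1), "Genome")))
  stage <- "setup"
  res <- tryCatch({
    perSpecies <- list()
    allCalls <- list()
    for (sp in names(genomes)) {
      stage <- paste0("classify:", sp)
      cls <- classifyMechanisms(genomes[[sp]], ancestral, w = w)
      stage <- paste0("trace:", sp)
      rr <- countRearrangements(genomes[[sp]], ancestral,
                                min_block_len = min_block_len,
                                max_gap = max_gap)
      perSpecies[[sp]] <- list(classification = cls,
                               rearrangements = rr)
      allCalls <- c(allCalls, cls$calls)
    }
    stage <- "branches"
    branchTab <- NULL
    if (!is.null(tree) && length(allCalls)) {
      sig <- vapply(allCalls, .callSignature, character(1))
      carriers <- lapply(split(seq_along(allCalls), sig), function(ix)
        unique(vapply(allCalls[ix], function(x) x$species, character(1))))
      branchTab <- assignEventsToBranches(carriers, tree)
    }
    stage <- "summary"
    cenF <- do.call(rbind, lapply(perSpecies, function(x)
      x$classification$cen_fates))
    telF <- do.call(rbind, lapply(perSpecies, function(x)
      x$classification$tel_fates))
    counts <- countFates(cenF, telF)
    predicted <- vapply(names(genomes), function(sp) {
      kinds <- vapply(perSpecies[[sp]]$classification$calls,
                      function(x) x$kind, character(1))
      predictChromosomeNumber(chromosomeCount(ancestral), kinds)
    }, integer(1))
    stage <- "consensus"
    consensus <- .consensusReport(c(genomes, list(Ancestor = ancestral)))
    list(per_species = perSpecies, branch_assignments = branchTab,
         counts = counts, consensus = consensus,
         predicted_chromosomes = predicted,
         observed_chromosomes = vapply(genomes, chromosomeCount,
                                       integer(1)),
         cen_fates = cenF, tel_fates = telF,
         params = list(w = w, min_block_len = min_block_len,
                       max_gap = max_gap, seed = seed))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(out_dir)) .writeReportBundle(res, out_dir)
  invisible(res)
}

.callSignature <- function(call) {
  extra <- switch(call$kind,
    telomere_fusion_cen_loss = paste(c(sort(call$ends), call$lost_cen),
                                     collapse = "|"),
    centromere_fission = paste(call$split_chrom, call$lost_cen,
                               sep = "|"),
    unexplained_loss = call$lost_cen,
    fusion_without_cen_loss = paste(sort(call$ends), collapse = "|"),
    "")
  paste(call$kind, extra, sep = "::")
}

.consensusReport <- function(genomes) {
  ann <- do.call(rbind, lapply(genomes, function(g) {
    cen <- g@centromeres
    cen <- cen[!is.na(cen$cde1_seq) & !is.na(cen$cde3_seq), ,
               drop = FALSE]
    if (!nrow(cen)) return(NULL)
    data.frame(species = g@species, cde1_seq = cen$cde1_seq,
               cde2_seq = cen$cde2_seq, cde3_seq = cen$cde3_seq,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann) || nrow(ann) < 2L) return(NULL)
  model <- buildConsensus(ann)
  iup <- consensusIupac(model)
  stats <- if (all(!is.na(ann$cde2_seq))) cde2Stats(ann) else NULL
  list(model = model, iupac = iup, cde2 = stats, n_centromeres = nrow(ann))
}

.readGenomeDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[!grepl("\\.cen\\.tsv$", files)]
  if (!length(files)) stop("no gene-order files in ", dir)
  gs <- list()
  for (f in files) {
    sp <- sub("\\.tsv$", "", basename(f))
    g <- readGeneOrder(f, species = sp)
    cf <- file.path(dir, paste0(sp, ".cen.tsv"))
    if (file.exists(cf)) {
      g@centromeres <- readCentromereTable(cf)
      validObject(g)
    }
    gs[[sp]] <- g
  }
  gs
}

.writeReportBundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(res$cen_fates, file.path(out_dir, "cen_fates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$tel_fates, file.path(out_dir, "tel_fates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- unlist(lapply(res$per_species, function(x)
    x$classification$calls), recursive = FALSE)
  yaml::write_yaml(list(calls = calls),
                   file.path(out_dir, "mechanism_calls.yaml"))
  if (!is.null(res$branch_assignments))
    write.table(res$branch_assignments,
                file.path(out_dir, "branch_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(
    species = names(res$predicted_chromosomes),
    observed_chromosomes = res$observed_chromosomes,
    predicted_chromosomes = res$predicted_chromosomes,
    rearrangements = vapply(res$per_species, function(x)
      x$rearrangements$total, integer(1)),
    stringsAsFactors = FALSE)
  write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lines <- c(sprintf("karyevol %s",
                     as.character(utils::packageVersion("karyevol"))),
             sprintf("seed: %s", res$params$seed),
             sprintf("params: w=%d min_block_len=%d max_gap=%d",
                     res$params$w, res$params$min_block_len,
                     res$params$max_gap),
             sprintf("centromere losses: %d",
                     res$counts$cen_losses_total))
  if (!is.null(res$consensus)) {
    iup <- res$consensus$iupac
    lines <- c(lines,
               sprintf("CDEI consensus:   %s (invariant: %s)",
                       iup$cde1_iupac,
                       paste(iup$invariant_cde1, collapse = ",")),
               sprintf("CDEIII consensus: %s (invariant: %s)",
                       iup$cde3_iupac,
                       paste(iup$invariant_cde3, collapse = ",")))
  }
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
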
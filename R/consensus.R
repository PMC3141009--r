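#' @include accessors.R
NULL

#' Build a point-centromere consensus model from annotations
#'
#' Tallies per-position base counts of the fixed-width CDEI (8 bp) and
#' CDEIII (26 bp) elements. The CDEII spacer window and minimum AT
#' fraction are taken from the annotation set's observed range, widened
#' by a configurable slack.
#'
#' @param annotations data.frame with columns `cde1_seq` and `cde3_seq`
#'   (and optionally `cde2_seq`).
#' @param pseudocount pseudocount per base per position (default 1).
#' @param background base composition (A,C,G,T); uniform by default.
#' @param cde2_slack bp added on both sides of the observed CDEII
#'   length range (default 3).
#' @param cde2_at_slack subtracted from the observed minimum CDEII AT
#'   fraction (default 0.02).
#' @return a [ConsensusModel-class].
#' @export
buildConsensus <- function(annotations, pseudocount = 1,
                           background = rep(0.25, 4), cde2_slack = 3L,
                           cde2_at_slack = 0.02) {
  if (nrow(annotations) < 2L)
    stop("buildConsensus needs at least 2 annotated centromeres")
  bad1 <- which(nchar(annotations$cde1_seq) != 8L)
  if (length(bad1))
    stop("cde1_seq of record ", bad1[1], " has length ",
         nchar(annotations$cde1_seq[bad1[1]]), ", expected 8")
  bad3 <- which(nchar(annotations$cde3_seq) != 26L)
  if (length(bad3))
    stop("cde3_seq of record ", bad3[1], " has length ",
         nchar(annotations$cde3_seq[bad3[1]]), ", expected 26")
  pfm1 <- .countMatrix(annotations$cde1_seq, 8L)
  pfm3 <- .countMatrix(annotations$cde3_seq, 26L)
  if (!is.null(annotations$cde2_seq) &&
      all(!is.na(annotations$cde2_seq))) {
    len <- nchar(annotations$cde2_seq)
    at <- vapply(strsplit(annotations$cde2_seq, ""), function(b)
      mean(b %in% c("A", "T")), numeric(1))
    win <- c(max(1L, min(len) - cde2_slack), max(len) + cde2_slack)
    minAT <- max(0, min(at) - cde2_at_slack)
  } else {
    win <- c(30L, 100L)
    minAT <- 0.76
  }
  ConsensusModel(pfm1, pfm3, cde2Window = win, cde2MinAT = minAT,
                 background = background, pseudocount = pseudocount)
}

.countMatrix <- function(seqs, width) {
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  out <- matrix(0, 4, width, dimnames = list(.BASES, NULL))
  common <- intersect(rownames(m), .BASES)
  out[common, ] <- m[common, seq_len(width)]
  out
}

# the IUPAC letter of a base set
.iupacOf <- function(bases) {
  key <- paste(sort(bases), collapse = "")
  hits <- names(Biostrings::IUPAC_CODE_MAP)[
    vapply(Biostrings::IUPAC_CODE_MAP, function(v)
      paste(sort(strsplit(v, "")[[1]]), collapse = "") == key,
      logical(1))]
  hits[1]
}

#' IUPAC consensus strings and invariant positions of a model
#'
#' A position is invariant iff a single base carries 100% of the
#' pre-pseudocount counts. The IUPAC letter of each position is chosen
#' as the smallest base set covering at least `threshold` of the count
#' mass (bases admitted in decreasing count order, ties alphabetical).
#'
#' @param model a [ConsensusModel-class].
#' @param threshold mass coverage for the IUPAC call (default 0.95).
#' @return list with `cde1_iupac`, `cde3_iupac` (strings) and
#'   `invariant_cde1`, `invariant_cde3` (integer position sets).
#' @export
consensusIupac <- function(model, threshold = 0.95) {
  call1 <- .iupacCalls(model@pfmCde1, threshold)
  call3 <- .iupacCalls(model@pfmCde3, threshold)
  list(cde1_iupac = call1$iupac, cde3_iupac = call3$iupac,
       invariant_cde1 = call1$invariant,
       invariant_cde3 = call3$invariant)
}

.iupacCalls <- function(pfm, threshold) {
  w <- ncol(pfm)
  letters <- character(w)
  invariant <- integer(0)
  for (j in seq_len(w)) {
    cnt <- pfm[, j]
    tot <- sum(cnt)
    if (tot > 0 && sum(cnt > 0) == 1L)
      invariant <- c(invariant, j)
    ord <- order(-cnt, .BASES)
    cum <- cumsum(cnt[ord]) / max(tot, 1)
    k <- which(cum >= threshold)[1]
    if (is.na(k)) k <- 4L
    letters[j] <- .iupacOf(.BASES[ord][seq_len(k)])
  }
  list(iupac = paste(letters, collapse = ""), invariant = invariant)
}

# per-position log2 odds matrix of one element
.logOdds <- function(model, which = c("cde1", "cde3")) {
  which <- match.arg(which)
  pfm <- if (which == "cde1") model@pfmCde1 else model@pfmCde3
  p <- model@pseudocount
  tot <- colSums(pfm)
  freq <- sweep(pfm + p, 2, tot + 4 * p, "/")
  log2(freq / model@background)
}

#' Log-odds score of a DNA window against one element matrix
#'
#' Sum over positions of
#' `log2(((count + pseudocount) / (total + 4 pseudocount)) / background)`.
#' Non-ACGT bases contribute 0 (scored as background).
#'
#' @param model a [ConsensusModel-class].
#' @param seq DNA string whose length matches the matrix width.
#' @param which `"cde1"` or `"cde3"`.
#' @return score in bits.
#' @export
scoreWindow <- function(model, seq, which = c("cde1", "cde3")) {
  which <- match.arg(which)
  lo <- .logOdds(model, which)
  b <- strsplit(toupper(seq), "")[[1]]
  if (length(b) != ncol(lo))
    stop("window length ", length(b), " does not match matrix width ",
         ncol(lo))
  s <- 0
  for (j in seq_along(b)) {
    if (b[j] %in% .BASES) s <- s + lo[b[j], j]
  }
  unname(s)
}

#' Maximum achievable score of one element matrix
#'
#' @inheritParams scoreWindow
#' @export
maxScore <- function(model, which = c("cde1", "cde3")) {
  sum(apply(.logOdds(model, match.arg(which)), 2, max))
}

# scores of all windows of width ncol(lo) along an integer-coded
# sequence; non-ACGT codes contribute 0
.slideScores <- function(codes, lo) {
  w <- ncol(lo)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) {
    v <- lo[, j][codes[j:(j + n - 1L)]]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s
}

.encode <- function(seq) match(strsplit(toupper(seq), "")[[1]], .BASES)

#' Scan DNA for point-centromere candidates
#'
#' Searches both strands for the collinear CDEI - CDEII - CDEIII
#' structure: a CDEI window and a CDEIII window each scoring at least
#' `min_score_fraction` of that matrix's maximum achievable score,
#' separated by a spacer whose length lies in the model's CDEII window
#' and whose AT fraction meets the model's minimum, all on a common
#' strand. The reported score is the sum of the CDEI and CDEIII
#' log-odds plus a spacer term scoring each CDEII base under an AT-rich
#' composition model (AT fraction midway between the model's minimum
#' and 1) against the background; the spacer term ranks the compact
#' true structure above candidates extended into non-CDEII context by
#' a chance motif match. Overlapping candidates are resolved to the
#' single best scoring one (ties: leftmost, then most compact).
#'
#' @param seq DNA string (or [Biostrings::DNAString]).
#' @param model a [ConsensusModel-class].
#' @param min_score_fraction per-element score threshold as a fraction
#'   of the maximum achievable bits (default 0.6).
#' @param resolve resolve overlapping candidates to the best one
#'   (default); `FALSE` returns every structural candidate, which
#'   [scanCentromereSet()] uses for its second pass.
#' @return data.frame of candidates (possibly empty): 1-based closed
#'   spans `cen_start`, `cen_end`, `cde1_start/end`, `cde2_start/end`,
#'   `cde3_start/end` on the forward strand, `strand`, `score` (bits)
#'   and element sequences as read on the candidate strand.
#' @export
scanCentromeres <- function(seq, model, min_score_fraction = 0.6,
                            resolve = TRUE) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  empty <- data.frame(cen_start = integer(0), cen_end = integer(0),
                      cde1_start = integer(0), cde1_end = integer(0),
                      cde2_start = integer(0), cde2_end = integer(0),
                      cde3_start = integer(0), cde3_end = integer(0),
                      strand = character(0), score = numeric(0),
                      cde1_seq = character(0), cde2_seq = character(0),
                      cde3_seq = character(0), stringsAsFactors = FALSE)
  minLen <- 8L + model@cde2Window[1] + 26L
  if (L < minLen) return(empty)
  lo1 <- .logOdds(model, "cde1"); lo3 <- .logOdds(model, "cde3")
  thr1 <- min_score_fraction * sum(apply(lo1, 2, max))
  thr3 <- min_score_fraction * sum(apply(lo3, 2, max))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rows <- list()
  # per-base CDEII composition log-odds (AT-rich spacer vs background)
  atModel <- (model@cde2MinAT + 1) / 2
  lo2 <- log2(c(A = atModel / 2, C = (1 - atModel) / 2,
                G = (1 - atModel) / 2, T = atModel / 2) /
                model@background)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    codes <- .encode(s)
    s1 <- .slideScores(codes, lo1)
    s3 <- .slideScores(codes, lo3)
    h1 <- which(s1 >= thr1)
    h3 <- which(s3 >= thr3)
    if (!length(h1) || !length(h3)) next
    isAT <- !is.na(codes) & (codes == 1L | codes == 4L)
    cumAT <- c(0L, cumsum(isAT))
    b2 <- lo2[codes]
    b2[is.na(b2)] <- 0
    cumB2 <- c(0, cumsum(b2))
    for (i in h1) {
      jmin <- i + 8L + model@cde2Window[1]
      jmax <- i + 8L + model@cde2Window[2]
      for (j in h3[h3 >= jmin & h3 <= jmax]) {
        glen <- j - (i + 8L)
        at <- (cumAT[j] - cumAT[i + 8L]) / glen
        if (at < model@cde2MinAT) next
        score <- s1[i] + s3[j] + (cumB2[j] - cumB2[i + 8L])
        # spans on the scanning strand
        sp <- c(cde1 = i, cde1e = i + 7L, cde2 = i + 8L, cde2e = j - 1L,
                cde3 = j, cde3e = j + 25L)
        if (strand == "-") {
          # map back to forward-strand coordinates
          mp <- function(a, b) c(L - b + 1L, L - a + 1L)
          c1 <- mp(sp["cde1"], sp["cde1e"])
          c2 <- mp(sp["cde2"], sp["cde2e"])
          c3 <- mp(sp["cde3"], sp["cde3e"])
        } else {
          c1 <- c(sp[["cde1"]], sp[["cde1e"]])
          c2 <- c(sp[["cde2"]], sp[["cde2e"]])
          c3 <- c(sp[["cde3"]], sp[["cde3e"]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cen_start = min(c1[1], c3[1]), cen_end = max(c1[2], c3[2]),
          cde1_start = c1[1], cde1_end = c1[2],
          cde2_start = c2[1], cde2_end = c2[2],
          cde3_start = c3[1], cde3_end = c3[2],
          strand = strand, score = score,
          cde1_seq = substr(s, sp[["cde1"]], sp[["cde1e"]]),
          cde2_seq = substr(s, sp[["cde2"]], sp[["cde2e"]]),
          cde3_seq = substr(s, sp[["cde3"]], sp[["cde3e"]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  if (!resolve) {
    rownames(cand) <- NULL
    return(cand)
  }
  .resolveOverlaps(cand)
}

# overlap resolution: best (possibly adjusted) score first, leftmost
# then most compact span on ties
.resolveOverlaps <- function(cand, score = cand$score) {
  cand <- cand[order(-score, cand$cen_start,
                     cand$cen_end - cand$cen_start), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ov <- keep & !(cand$cen_end < cand$cen_start[k] |
                   cand$cen_start > cand$cen_end[k])
    keep[k] <- !any(ov)
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$cen_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of same-species sequences with CDEII length re-ranking
#'
#' Point-centromere CDEII lengths vary little within a species. This
#' two-pass scanner exploits that: each sequence is scanned for all
#' structural candidates, a provisional best candidate per sequence
#' fixes the species' median CDEII length, and candidates are then
#' re-ranked with a penalty of `length_penalty` bits per bp of
#' deviation from that median before overlap resolution. This resolves
#' parses that are ambiguous within a single sequence, e.g. a chance
#' CDEI match inside or beside the true element.
#'
#' @param seqs [Biostrings::DNAStringSet] (or list/character) of
#'   sequences from one species.
#' @inheritParams scanCentromeres
#' @param length_penalty bits per bp of CDEII-length deviation
#'   (default 1).
#' @return data.frame of candidates with a `seq_name` column.
#' @export
scanCentromereSet <- function(seqs, model, min_score_fraction = 0.6,
                              length_penalty = 1) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- as.character(seq_along(seqs))
  all <- lapply(seq_along(seqs), function(i)
    scanCentromeres(seqs[[i]], model, min_score_fraction,
                    resolve = FALSE))
  pass1 <- lapply(all, function(cand)
    if (nrow(cand)) .resolveOverlaps(cand) else cand)
  lens <- unlist(lapply(pass1, function(d)
    if (nrow(d)) d$cde2_end - d$cde2_start + 1L else integer(0)))
  if (!length(lens)) {
    out <- do.call(rbind, pass1)
    out$seq_name <- character(0)
    return(out)
  }
  med <- stats::median(lens)
  res <- lapply(seq_along(all), function(i) {
    cand <- all[[i]]
    if (!nrow(cand)) return(NULL)
    l2 <- cand$cde2_end - cand$cde2_start + 1L
    adj <- cand$score - length_penalty * abs(l2 - med)
    d <- .resolveOverlaps(cand, score = adj)
    cbind(seq_name = nm[i], d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Scan every chromosome of a genome
#'
#' @param genome a [Genome-class] with sequences.
#' @inheritParams scanCentromeres
#' @return data.frame of candidates with a `chrom_id` column.
#' @export
scanGenome <- function(genome, model, min_score_fraction = 0.6) {
  if (is.null(genome@sequences))
    stop("genome of ", genome@species, " carries no sequences")
  out <- scanCentromereSet(genome@sequences[genome@chromOrder], model,
                           min_score_fraction)
  if (is.null(out) || !nrow(out))
    return(data.frame(chrom_id = character(0)))
  names(out)[names(out) == "seq_name"] <- "chrom_id"
  out
}

#' Per-species CDEII statistics
#'
#' @param annotations data.frame with columns `species` and `cde2_seq`.
#' @return list with `per_species` (length n, mean, sd, AT range per
#'   species) and `length_ratio` (max species mean / min species mean).
#' @export
cde2Stats <- function(annotations) {
  stopifnot(all(c("species", "cde2_seq") %in% names(annotations)))
  sp <- split(annotations$cde2_seq, annotations$species)
  per <- do.call(rbind, lapply(names(sp), function(s) {
    len <- nchar(sp[[s]])
    at <- vapply(strsplit(sp[[s]], ""), function(b)
      mean(b %in% c("A", "T")), numeric(1))
    data.frame(species = s, n = length(len), mean_len = mean(len),
               sd_len = if (length(len) > 1L) sd(len) else 0,
               min_at = min(at), max_at = max(at),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_species = per,
       length_ratio = max(per$mean_len) / min(per$mean_len))
}
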
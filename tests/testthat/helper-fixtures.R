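# shared fixtures, built once per test run

.fixenv <- new.env()

fix_config <- function(seed = 42) simConfig(seed = seed)

# memoized default ancestor (no sequences) for the many tests that only
# need gene order
fix_ancestor <- function(seed = 42) {
  key <- paste0("anc", seed)
  if (is.null(.fixenv[[key]]))
    .fixenv[[key]] <- makeAncestor(fix_config(seed),
                                   with_sequences = FALSE)$genome
  .fixenv[[key]]
}

fix_model <- function(seed = 42) generatorModel(fix_config(seed))

# a two-leaf tree for single-lineage evolution
fix_pair_tree <- function() {
  SpeciesTree(ape::read.tree(text = "(sp1,sp2)R;"))
}

# four-leaf tree with a WGD clade
fix_wgd_tree <- function() {
  tr <- ape::read.tree(text = "((postA,postB)W,(nonC,nonD)N)R;")
  tr$node.label <- c("R", "WGD", "N")
  SpeciesTree(tr, "WGD")
}

# independent quadratic-time synteny-block oracle: returns the sorted
# multiset of (anc_chrom, anc_start, anc_end) block intervals per
# extant chromosome, computed directly from the two gene tables without
# any package internals
oracle_blocks <- function(extant, ancestral, max_gap = 1) {
  ag <- geneTable(ancestral)
  ag <- ag[!is.na(ag$pillar_id), ]
  apos <- list(); aorient <- list(); achr <- list()
  for (ch in unique(ag$chrom_id)) {
    gg <- ag[ag$chrom_id == ch, ]
    gg <- gg[order(gg$idx), ]
    for (i in seq_len(nrow(gg))) {
      apos[[gg$pillar_id[i]]] <- i
      aorient[[gg$pillar_id[i]]] <- gg$orientation[i]
      achr[[gg$pillar_id[i]]] <- ch
    }
  }
  present <- geneTable(extant)$pillar_id
  present <- present[!is.na(present)]
  out <- list()
  eg <- geneTable(extant)
  for (ch in unique(eg$chrom_id)) {
    gg <- eg[eg$chrom_id == ch & !is.na(eg$pillar_id), ]
    gg <- gg[order(gg$idx), ]
    if (!nrow(gg)) next
    # repair isolated flipped genes (positionally in place, orientation
    # reversed relative to both neighbours' run)
    n <- nrow(gg)
    cons <- function(i, j, oi = gg$orientation[i], oj = gg$orientation[j]) {
      pi <- gg$pillar_id[i]; pj <- gg$pillar_id[j]
      if (achr[[pi]] != achr[[pj]]) return(FALSE)
      di <- if (oi == aorient[[pi]]) 1 else -1
      dj <- if (oj == aorient[[pj]]) 1 else -1
      if (di != dj) return(FALSE)
      delta <- (apos[[pj]] - apos[[pi]]) * di
      if (delta < 1 || delta > max_gap + 1) return(FALSE)
      if (delta > 1) {
        ac <- achr[[pi]]
        mids <- names(apos)[vapply(names(apos), function(p)
          achr[[p]] == ac &&
            (apos[[p]] - apos[[pi]]) * di > 0 &&
            (apos[[p]] - apos[[pj]]) * di < 0, logical(1))]
        if (any(mids %in% present)) return(FALSE)
      }
      TRUE
    }
    flip <- function(o) if (o == "+") "-" else "+"
    if (n >= 3) for (i in 2:(n - 1)) {
      if (!cons(i - 1, i) && !cons(i, i + 1) &&
          cons(i - 1, i, oj = flip(gg$orientation[i])) &&
          cons(i, i + 1, oi = flip(gg$orientation[i])))
        gg$orientation[i] <- flip(gg$orientation[i])
    }
    breaks <- 1
    if (n > 1) for (i in 1:(n - 1))
      if (!cons(i, i + 1)) breaks <- c(breaks, i + 1)
    bounds <- cbind(breaks, c(breaks[-1] - 1, n))
    for (k in seq_len(nrow(bounds))) {
      i <- bounds[k, 1]; j <- bounds[k, 2]
      pi <- gg$pillar_id[i]; pj <- gg$pillar_id[j]
      out[[length(out) + 1]] <- c(
        achr[[pi]], min(apos[[pi]], apos[[pj]]),
        max(apos[[pi]], apos[[pj]]))
    }
  }
  srt <- sort(vapply(out, paste, character(1), collapse = ":"))
  srt
}
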
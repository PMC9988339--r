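# Independent brute-force oracles. These re-derive expected values directly
# from the region definitions with plain scalar/vector arithmetic, without
# touching the package's interval engine, so agreement is a real check.

# Gene-region label of positions on one chromosome, per transcript, by
# direct membership tests on explicit intervals.
oracle_gene_region <- function(pos, transcripts) {
  priority <- c("TSS1500", "TSS200", "UTR5", "Exon1", "Body", "UTR3")
  labels <- rep("Intergenic", length(pos))
  best <- rep(Inf, length(pos))
  for (r in seq_len(nrow(transcripts))) {
    tx <- transcripts[r, ]
    ex <- tx$exons[[1]]
    el <- min(ex$start); er <- max(ex$end)
    if (tx$strand == "+") {
      tss <- tx$tx_start
      e1s <- el; e1e <- ex$end[which.min(ex$start)]
      in_utr5 <- pos >= tx$tx_start & pos <= e1s - 1
      in_body <- pos >= e1e + 1 & pos <= er
      in_utr3 <- pos >= er + 1 & pos <= tx$tx_end
    } else {
      tss <- tx$tx_end
      e1s <- ex$start[which.max(ex$end)]; e1e <- max(ex$end)
      in_utr5 <- pos >= e1e + 1 & pos <= tx$tx_end
      in_body <- pos >= el & pos <= e1s - 1
      in_utr3 <- pos >= tx$tx_start & pos <= el - 1
    }
    d <- abs(pos - tss)
    in_exon1 <- pos >= e1s & pos <= e1e
    lab <- rep(NA_character_, length(pos))
    lab[in_utr3] <- "UTR3"
    lab[in_body] <- "Body"
    lab[in_exon1] <- "Exon1"
    lab[in_utr5] <- "UTR5"
    lab[d <= 1500 & d > 200] <- "TSS1500"
    lab[d <= 200] <- "TSS200"
    pr <- match(lab, priority)
    improved <- !is.na(pr) & pr < best
    best[improved] <- pr[improved]
    labels[improved] <- lab[improved]
  }
  labels
}

# Island context by explicit min distance over every island.
oracle_island_context <- function(pos, islands) {
  vapply(pos, function(p) {
    if (nrow(islands) == 0) return("OpenSea")
    d <- min(pmax(0, islands$start - p, p - islands$end))
    if (d == 0) "Island"
    else if (d <= 2000) "Shore"
    else if (d <= 4000) "Shelf"
    else "OpenSea"
  }, character(1))
}

# Naive O(n*m) containment scan; first-by-coordinate tie rule.
oracle_track_label <- function(probes, track) {
  vapply(seq_len(nrow(probes)), function(i) {
    hit <- which(track$chrom == probes$chrom[i] &
                   track$start <= probes$pos[i] &
                   probes$pos[i] <= track$end)
    if (length(hit) == 0) return(NA_character_)
    hit <- hit[order(track$start[hit], track$end[hit])]
    track$label[hit[1]]
  }, character(1))
}

# Agglomerative Ward.D by the Lance-Williams recurrence on unsquared input
# distances, run by explicit pairwise search.
oracle_ward_d <- function(d) {
  m <- as.matrix(d)
  labs <- rownames(m)
  n <- nrow(m)
  sizes <- rep(1, n)
  clusters <- lapply(seq_len(n), function(i) labs[i])
  heights <- numeric(0)
  sets <- list()
  while (length(clusters) > 1) {
    nm <- length(clusters)
    bd <- Inf; bi <- 1; bj <- 2
    for (i in seq_len(nm - 1)) {
      for (j in seq(i + 1, nm)) {
        if (m[i, j] < bd) { bd <- m[i, j]; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, bd)
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    sets[[length(sets) + 1]] <- merged
    ni <- sizes[bi]; nj <- sizes[bj]
    newd <- vapply(seq_len(nm), function(l) {
      if (l == bi || l == bj) return(NA_real_)
      nl <- sizes[l]
      ((ni + nl) * m[bi, l] + (nj + nl) * m[bj, l] - nl * m[bi, bj]) /
        (ni + nj + nl)
    }, numeric(1))
    keep <- setdiff(seq_len(nm), c(bi, bj))
    m <- rbind(cbind(m[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    clusters <- c(clusters[keep], list(merged))
  }
  list(heights = heights, sets = sets)
}

# Exhaustive hypergeometric upper tail via binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- seq(k, min(K, n))
  if (length(kk) == 0 || k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  if (m >= 2) {
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Mirror a genome of length L: positions p -> L + 1 - p, strands flipped.
mirror_transcripts <- function(transcripts, L) {
  out <- transcripts
  out$strand <- ifelse(transcripts$strand == "+", "-", "+")
  out$tx_start <- L + 1L - transcripts$tx_end
  out$tx_end <- L + 1L - transcripts$tx_start
  out$exons <- lapply(transcripts$exons, function(ex) {
    tibble::tibble(start = L + 1L - ex$end, end = L + 1L - ex$start)
  })
  out
}

mirror_track <- function(track, L) {
  out <- track
  out$start <- L + 1L - track$end
  out$end <- L + 1L - track$start
  out[order(out$chrom, out$start), ]
}

# Tiny deterministic manifest for hand fixtures.
tiny_manifest <- function(probe_id, chrom = "chr1", pos = NULL,
                          strand = "+", design = "InfiniumII",
                          masked = FALSE) {
  n <- length(probe_id)
  tibble::tibble(
    probe_id = probe_id,
    chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) seq_len(n) * 100L else as.integer(pos),
    strand = rep_len(strand, n),
    design = rep_len(design, n),
    probe_class = probe_class_from_id(probe_id),
    masked = rep_len(masked, n),
    chrom_canonical = is_canonical_chrom(rep_len(chrom, n))
  )
}

# hclust-backed dendrogram from a hand-written ultrametric newick string.
dend_from_newick <- function(nwk) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(nwk, tf)
  read_dendrogram_newick(tf)
}
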
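gene_region_rank <- function(label) match(label, GENE_REGION_LEVELS)

#' Genomic intervals of every gene-relative region of a transcript
#'
#' Expands transcript models into 1-based inclusive genomic intervals, one
#' per gene-relative region, strand-aware:
#'
#' * `TSS200`: TSS +/- 200 bp (TSS = transcript 5' end).
#' * `TSS1500`: TSS +/- 1500 bp, excluding the TSS200 band (two flanking
#'   intervals), so the two TSS categories are disjoint within a transcript.
#' * `Exon1`: the first exon in transcript orientation.
#' * `UTR5`: the region between the transcript start and the first-exon
#'   start (empty for most transcripts, where the two coincide). With
#'   `utr_mode = "cds_based"` and a CDS-bearing model, the transcript start
#'   to the CDS start instead.
#' * `Body`: between the first-exon end and the last-exon end (exclusive of
#'   the first-exon end base, inclusive of the last-exon end base).
#' * `UTR3`: between the last-exon end and the transcript end (empty when
#'   they coincide; CDS end to transcript end under `cds_based`).
#'
#' Degenerate (empty) intervals are dropped. Unknown strand is treated as
#' `+`.
#'
#' @param transcripts Transcript tibble from [read_gene_models()] (columns
#'   `transcript_id`, `transcript_type`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `exons`; optional `cds_start`, `cds_end`).
#' @param utr_mode `"literal"` (default) or `"cds_based"`.
#' @return Tibble with `transcript_id`, `transcript_type`, `chrom`,
#'   `region`, `start`, `end`.
#' @export
transcript_region_table <- function(transcripts, utr_mode = c("literal", "cds_based")) {
  utr_mode <- match.arg(utr_mode)
  if (nrow(transcripts) == 0) {
    return(tibble(transcript_id = character(), transcript_type = character(),
                  chrom = character(), region = character(),
                  start = integer(), end = integer()))
  }
  has_cds <- all(c("cds_start", "cds_end") %in% names(transcripts))
  rows <- pmap(transcripts, function(transcript_id, transcript_type = "other",
                                     chrom, strand, tx_start, tx_end, exons,
                                     cds_start = NA_integer_,
                                     cds_end = NA_integer_, ...) {
    s <- if (identical(strand, "-")) "-" else "+"
    ex <- exons
    if (nrow(ex) == 0) ex <- tibble(start = tx_start, end = tx_end)
    gl <- min(ex$start); gr <- max(ex$end)
    if (s == "+") {
      tss <- tx_start
      e1 <- ex[which.min(ex$start), ]
      utr5 <- c(tx_start, e1$start - 1L)
      body <- c(e1$end + 1L, gr)
      utr3 <- c(gr + 1L, tx_end)
      if (utr_mode == "cds_based" && has_cds && !is.na(cds_start)) {
        utr5 <- c(tx_start, cds_start - 1L)
        utr3 <- c(cds_end + 1L, tx_end)
      }
    } else {
      tss <- tx_end
      e1 <- ex[which.max(ex$start), ]
      utr5 <- c(e1$end + 1L, tx_end)
      body <- c(gl, e1$start - 1L)
      utr3 <- c(tx_start, gl - 1L)
      if (utr_mode == "cds_based" && has_cds && !is.na(cds_start)) {
        utr5 <- c(cds_end + 1L, tx_end)
        utr3 <- c(tx_start, cds_start - 1L)
      }
    }
    reg <- tibble(
      region = c("TSS200", "TSS1500", "TSS1500", "UTR5", "Exon1", "Body", "UTR3"),
      start = as.integer(c(tss - 200L, tss - 1500L, tss + 201L,
                           utr5[1], e1$start, body[1], utr3[1])),
      end = as.integer(c(tss + 200L, tss - 201L, tss + 1500L,
                         utr5[2], e1$end, body[2], utr3[2]))
    )
    reg$start <- pmax(reg$start, 1L)
    reg <- reg[reg$start <= reg$end, , drop = FALSE]
    reg$transcript_id <- transcript_id
    reg$transcript_type <- transcript_type
    reg$chrom <- chrom
    reg
  })
  bind_rows(rows)[, c("transcript_id", "transcript_type", "chrom", "region",
                      "start", "end")]
}

#' Classify one probe against one transcript
#'
#' Returns the most 5' gene-relative region of `tx` containing the probe's
#' cytosine position, or `NA` if the probe touches none (or lies on a
#' different chromosome). The two TSS bands are disjoint within a transcript
#' (TSS200 wins inside +/- 200 bp; TSS1500 covers 200 < |d| <= 1500), so the
#' 5'-to-3' priority TSS1500 > TSS200 > UTR5 > Exon1 > Body > UTR3 is
#' well defined.
#'
#' @param probe One-row probe tibble (needs `chrom`, `pos`).
#' @param tx One-row transcript tibble.
#' @param utr_mode See [transcript_region_table()].
#' @return A single region label or `NA_character_`.
#' @export
classify_probe_vs_transcript <- function(probe, tx, utr_mode = "literal") {
  if (probe$chrom[[1]] != tx$chrom[[1]]) return(NA_character_)
  reg <- transcript_region_table(tx, utr_mode = utr_mode)
  hit <- reg$region[reg$start <= probe$pos[[1]] & probe$pos[[1]] <= reg$end]
  if (length(hit) == 0) return(NA_character_)
  GENE_REGION_LEVELS[min(gene_region_rank(hit))]
}

#' Flatten per-transcript labels to a single gene-region label
#'
#' Applies the 5'-to-3' priority
#' TSS1500 > TSS200 > 5'UTR > first exon > body > 3'UTR across all
#' per-transcript labels of a probe; an empty label set means the probe is
#' intergenic.
#'
#' @param labels Character vector of per-transcript region labels (possibly
#'   empty; `NA`s ignored).
#' @return One label from `TSS1500, TSS200, UTR5, Exon1, Body, UTR3,
#'   Intergenic`.
#' @export
flatten_gene_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return("Intergenic")
  GENE_REGION_LEVELS[min(gene_region_rank(labels))]
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  s <- start[o]; ce <- cummax(end[o])
  new_grp <- c(TRUE, s[-1] > ce[-length(ce)])
  idx_start <- which(new_grp)
  idx_end <- c(idx_start[-1] - 1L, length(s))
  tibble(start = s[idx_start], end = ce[idx_end])
}

#' Classify probes by CpG-island context
#'
#' Distance banding from the nearest island: inside an island (`Island`),
#' within 2 kb of an island edge (`Shore`), within the next 2 kb (`Shelf`),
#' beyond 4 kb (`OpenSea`). Where the flanks of two islands overlap, the
#' higher-priority context wins (Island > Shore > Shelf > OpenSea), which
#' the minimum-distance rule enforces automatically.
#'
#' @param probes Probe tibble (columns `chrom`, `pos`).
#' @param islands Island region track (tibble with `chrom`, `start`, `end`).
#' @return Character vector of contexts, one per probe row.
#' @export
classify_island_context <- function(probes, islands) {
  out <- rep("OpenSea", nrow(probes))
  if (nrow(islands) == 0 || nrow(probes) == 0) return(out)
  isl_by_chrom <- split(islands[, c("start", "end")], islands$chrom)
  for (ch in intersect(unique(probes$chrom), names(isl_by_chrom))) {
    idx <- which(probes$chrom == ch)
    iv <- isl_by_chrom[[ch]]
    m <- merge_intervals(iv$start, iv$end)
    p <- probes$pos[idx]
    # nearest merged island left of / containing p, and the next one right
    j <- findInterval(p, m$start)
    d_left <- ifelse(j >= 1, pmax(0L, p - m$end[pmax(j, 1L)]), Inf)
    d_right <- ifelse(j < nrow(m), m$start[pmin(j + 1L, nrow(m))] - p, Inf)
    d <- pmin(d_left, d_right)
    out[idx] <- dplyr::case_when(
      d == 0 ~ "Island",
      d <= 2000 ~ "Shore",
      d <= 4000 ~ "Shelf",
      TRUE ~ "OpenSea"
    )
  }
  out
}

#' Assign the label of the region-track interval containing each probe
#'
#' Overlapping track intervals are resolved first-by-coordinate (smallest
#' start, then smallest end, then input order).
#'
#' @param probes Probe tibble (columns `chrom`, `pos`).
#' @param track Region track tibble (`chrom`, `start`, `end`, `label`).
#' @param tie_rule Only `"first"` (first-by-coordinate) is implemented.
#' @return Character vector of labels, `NA` where a probe is uncovered.
#' @export
assign_track_label <- function(probes, track, tie_rule = "first") {
  stopifnot(identical(tie_rule, "first"))
  out <- rep(NA_character_, nrow(probes))
  if (nrow(track) == 0 || nrow(probes) == 0) return(out)
  for (ch in intersect(unique(probes$chrom), unique(track$chrom))) {
    idx <- which(probes$chrom == ch)
    tr <- track[track$chrom == ch, ]
    tr <- tr[order(tr$start, tr$end), ]
    q <- IRanges::IRanges(probes$pos[idx], width = 1L)
    s <- IRanges::IRanges(tr$start, tr$end)
    ov <- IRanges::findOverlaps(q, s, select = "first")
    hit <- !is.na(ov)
    out[idx[hit]] <- tr$label[ov[hit]]
  }
  out
}

#' Annotate every probe of a manifest along all four functional dimensions
#'
#' Combines gene-relative classification (per transcript, then flattened by
#' the 5'-to-3' priority), CpG-island context, chromatin-state label and
#' CTCF-binding flag into a single annotated manifest — the flat annotation
#' layer that array manifests do not ship.
#'
#' @param probes Probe tibble from [read_manifest()].
#' @param transcripts Transcript tibble from [read_gene_models()] (may be
#'   empty: every probe is then intergenic).
#' @param islands,states,ctcf Region tracks from [read_region_track()]
#'   (each may be `NULL` or empty).
#' @param utr_mode See [transcript_region_table()].
#' @return The probe tibble plus columns `flat_gene_label`,
#'   `per_transcript` (list-column of tibbles `transcript_id`, `label`),
#'   `representative_transcript` (lexicographically smallest transcript
#'   achieving the flat label), `transcript_types` (list-column, union of
#'   contributing types), `transcript_type_top` (single type under
#'   mRNA > lncRNA > other), `island_context`, `chromatin_state`,
#'   `ctcf_bound`.
#' @export
build_annotated_manifest <- function(probes, transcripts = NULL,
                                     islands = NULL, states = NULL,
                                     ctcf = NULL, utr_mode = "literal") {
  n <- nrow(probes)
  empty_tx <- tibble(transcript_id = character(), label = character(),
                     transcript_type = character())
  per_tx <- rep(list(empty_tx), n)
  if (!is.null(transcripts) && nrow(transcripts) > 0) {
    reg <- transcript_region_table(transcripts, utr_mode = utr_mode)
    hits_all <- vector("list", 0L)
    for (ch in intersect(unique(probes$chrom), unique(reg$chrom))) {
      pidx <- which(probes$chrom == ch)
      r <- reg[reg$chrom == ch, ]
      q <- IRanges::IRanges(probes$pos[pidx], width = 1L)
      s <- IRanges::IRanges(r$start, r$end)
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      hits_all[[length(hits_all) + 1L]] <- tibble(
        probe_idx = pidx[S4Vectors::queryHits(ov)],
        transcript_id = r$transcript_id[S4Vectors::subjectHits(ov)],
        transcript_type = r$transcript_type[S4Vectors::subjectHits(ov)],
        rank = gene_region_rank(r$region[S4Vectors::subjectHits(ov)])
      )
    }
    if (length(hits_all) > 0) {
      hits <- bind_rows(hits_all) %>%
        group_by(.data$probe_idx, .data$transcript_id,
                 .data$transcript_type) %>%
        summarise(rank = min(.data$rank), .groups = "drop") %>%
        mutate(label = GENE_REGION_LEVELS[.data$rank]) %>%
        arrange(.data$probe_idx, .data$transcript_id)
      split_hits <- split(hits, hits$probe_idx)
      for (nm in names(split_hits)) {
        h <- split_hits[[nm]]
        per_tx[[as.integer(nm)]] <- h[, c("transcript_id", "label",
                                          "transcript_type")]
      }
    }
  }
  flat <- map_chr(per_tx, function(h) flatten_gene_label(h$label))
  rep_tx <- map_chr(per_tx, function(h) {
    if (nrow(h) == 0) return(NA_character_)
    top <- flatten_gene_label(h$label)
    min(h$transcript_id[h$label == top])
  })
  types <- map(per_tx, function(h) sort(unique(h$transcript_type)))
  type_top <- map_chr(types, function(tt) {
    if (length(tt) == 0) return(NA_character_)
    c("mRNA", "lncRNA", "other")[min(match(tt, c("mRNA", "lncRNA", "other")))]
  })
  state <- if (!is.null(states)) assign_track_label(probes, states)
           else rep(NA_character_, n)
  ctcf_lab <- if (!is.null(ctcf)) assign_track_label(probes, ctcf)
              else rep(NA_character_, n)
  isl <- if (!is.null(islands)) classify_island_context(probes, islands)
         else rep("OpenSea", n)
  probes %>%
    mutate(
      flat_gene_label = flat,
      per_transcript = map(per_tx, ~ .x[, c("transcript_id", "label")]),
      representative_transcript = rep_tx,
      transcript_types = types,
      transcript_type_top = type_top,
      island_context = isl,
      chromatin_state = state,
      ctcf_bound = !is.na(ctcf_lab)
    )
}

#' Summarize annotation categories as counts and percentages
#'
#' One row per (dimension, category); percentages sum to 100 within each
#' dimension (up to rounding). Dimensions: gene region, island context,
#' chromatin state (uncovered probes reported as `none`), CTCF binding and
#' transcript-type association.
#'
#' @param annotated Output of [build_annotated_manifest()].
#' @return Tibble with columns `dimension`, `category`, `n`, `pct`.
#' @export
summarize_categories <- function(annotated) {
  dims <- list(
    gene_region = annotated$flat_gene_label,
    island_context = annotated$island_context,
    chromatin_state = dplyr::coalesce(annotated$chromatin_state, "none"),
    ctcf = if_else(annotated$ctcf_bound, "bound", "unbound"),
    transcript_type = dplyr::coalesce(annotated$transcript_type_top,
                                      "intergenic")
  )
  bind_rows(imap(dims, function(v, nm) {
    tibble(dimension = nm, category = v) %>%
      count(.data$dimension, .data$category, name = "n") %>%
      mutate(pct = 100 * .data$n / sum(.data$n))
  }))
}

#' Share of probes in promoter-proximal and gene-body regions
#'
#' Promoter-proximal covers TSS1500, TSS200, 5'UTR and first exon; gene body
#' covers body and 3'UTR.
#'
#' @param annotated Output of [build_annotated_manifest()].
#' @return Tibble with `group`, `n`, `pct`.
#' @export
promoter_body_shares <- function(annotated) {
  grp <- dplyr::case_when(
    annotated$flat_gene_label %in% c("TSS1500", "TSS200", "UTR5", "Exon1") ~
      "promoter_proximal",
    annotated$flat_gene_label %in% c("Body", "UTR3") ~ "gene_body",
    TRUE ~ "intergenic"
  )
  tibble(group = grp) %>%
    count(.data$group, name = "n") %>%
    mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Write an annotated manifest to TSV
#'
#' Per-transcript labels are serialized as `transcript:label` pairs joined
#' by `;`; list-columns are flattened accordingly so the file mirrors the
#' flat annotation tables of an array manifest supplement.
#'
#' @param annotated Output of [build_annotated_manifest()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotated_manifest <- function(annotated, path) {
  flat <- annotated %>%
    mutate(
      per_transcript = map_chr(.data$per_transcript, function(h) {
        if (nrow(h) == 0) return("")
        paste(paste0(h$transcript_id, ":", h$label), collapse = ";")
      }),
      transcript_types = map_chr(.data$transcript_types, paste, collapse = ";")
    )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
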
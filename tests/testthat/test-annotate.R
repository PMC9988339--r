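make_tx <- function(id = "T1", chrom = "chr1", strand = "+",
                    tx_start, tx_end, exons, type = "mRNA") {
  ex <- tibble::tibble(start = as.integer(exons$start),
                       end = as.integer(exons$end))
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  tibble::tibble(transcript_id = id, gene_id = paste0("G_", id),
                 transcript_type = type, chrom = chrom, strand = strand,
                 tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                 exons = list(ex))
}

test_that("TSS bands classify by distance with the nested TSS200 rule", {
  tx <- make_tx(tx_start = 10000, tx_end = 12000,
                exons = list(start = 10000, end = 12000))
  at <- function(p) classify_probe_vs_transcript(
    tiny_manifest("cg01", pos = p), tx)
  expect_equal(at(10100), "TSS200")    # TSS + 100
  expect_equal(at(9000), "TSS1500")    # TSS - 1000
  expect_equal(at(10201), "TSS1500")   # just outside the inner band
  expect_equal(at(11800), "Exon1")     # single-exon transcript interior
  expect_true(is.na(at(20000)))        # outside every region
})

test_that("per-base labels over a 3-exon transcript match the brute-force oracle", {
  tx <- make_tx(tx_start = 4800, tx_end = 9400,
                exons = list(start = c(5000, 6000, 8000),
                             end = c(5400, 6500, 9000)))
  pos <- 1:12000
  engine <- build_annotated_manifest(
    tiny_manifest(sprintf("cg%05d", pos), pos = pos), tx)$flat_gene_label
  expect_equal(engine, oracle_gene_region(pos, tx))

  # and the mirrored minus-strand version of the same transcript
  txm <- mirror_transcripts(tx, 12000L)
  enginem <- build_annotated_manifest(
    tiny_manifest(sprintf("cg%05d", pos), pos = pos), txm)$flat_gene_label
  expect_equal(enginem, oracle_gene_region(pos, txm))
  # strand symmetry: mirrored labels equal reversed originals
  expect_equal(enginem, rev(engine))
})

test_that("flattening applies the 5'-to-3' priority and empty means intergenic", {
  expect_equal(flatten_gene_label(character(0)), "Intergenic")
  expect_equal(flatten_gene_label(c("Body", "TSS200")), "TSS200")
  expect_equal(flatten_gene_label(c("UTR3", "Body")), "Body")
  expect_equal(flatten_gene_label(c("TSS200", "TSS1500")), "TSS1500")
  # 1,000 random multisets vs an independent argmax over the total order
  order_ref <- c("TSS1500", "TSS200", "UTR5", "Exon1", "Body", "UTR3")
  withr::with_seed(3, {
    for (i in 1:1000) {
      labs <- sample(order_ref, sample(1:6, 1), replace = TRUE)
      expect_identical(flatten_gene_label(labs),
                       order_ref[min(match(labs, order_ref))])
    }
  })
})

test_that("island context bands by distance, with island flanks overlapping", {
  islands <- tibble::tibble(chrom = "chr1",
                            start = c(10000L, 30000L, 34500L),
                            end = c(11000L, 31000L, 35500L),
                            label = "isl")
  probes <- tiny_manifest("cg01", pos = 13500)   # 2500 bp past edge
  expect_equal(classify_island_context(probes, islands), "Shelf")
  expect_equal(classify_island_context(tiny_manifest("cg01", pos = 10500),
                                       islands), "Island")
  # the pair 3.5 kb apart: midpoint is Shore of both, never Shelf
  expect_equal(classify_island_context(tiny_manifest("cg01", pos = 32750),
                                       islands), "Shore")
  # per-base sweep against the exhaustive min-distance oracle
  pos <- 1:45000
  sweep <- classify_island_context(
    tiny_manifest(sprintf("cg%05d", pos), pos = pos), islands)
  expect_equal(sweep, oracle_island_context(pos, islands))
  # banding is monotone in distance from the island set
  d <- vapply(pos, function(p)
    min(pmax(0, islands$start - p, p - islands$end)), numeric(1))
  rank_ctx <- match(sweep, c("Island", "Shore", "Shelf", "OpenSea"))
  o <- order(d)
  expect_true(all(diff(rank_ctx[o]) >= 0 | diff(d[o]) == 0))
})

test_that("track labels come from containing intervals, first-by-coordinate", {
  track <- tibble::tibble(chrom = "chr1", start = c(100L, 150L),
                          end = c(200L, 250L), label = c("Quies", "TssA"))
  expect_equal(assign_track_label(tiny_manifest("cg01", pos = 120), track),
               "Quies")
  expect_equal(assign_track_label(tiny_manifest("cg01", pos = 180), track),
               "Quies")  # overlap resolved to first by coordinate
  expect_true(is.na(assign_track_label(tiny_manifest("cg01", pos = 300),
                                       track)))
  # 500 random probes vs 50 random intervals: equals the naive scan
  withr::with_seed(8, {
    tr <- tibble::tibble(chrom = "chr1",
                         start = as.integer(sample.int(5e4, 50)),
                         end = 0L, label = sprintf("st%02d", 1:50))
    tr$end <- tr$start + as.integer(sample.int(3000, 50, replace = TRUE))
    pr <- tiny_manifest(sprintf("cg%03d", 1:500),
                        pos = sample.int(5e4, 500))
  })
  tr <- tr[order(tr$start), ]
  expect_equal(assign_track_label(pr, tr), oracle_track_label(pr, tr))
})

test_that("annotation combines dimensions and records transcript types", {
  # probe overlapping an mRNA body and a lncRNA TSS1500 flank
  tx1 <- make_tx("Tm", tx_start = 1000, tx_end = 9000,
                 exons = list(start = c(1000, 8000), end = c(1200, 9000)),
                 type = "mRNA")
  tx2 <- make_tx("Tl", tx_start = 5000, tx_end = 7000,
                 exons = list(start = 5000, end = 7000), type = "lncRNA")
  txs <- dplyr::bind_rows(tx1, tx2)
  ann <- build_annotated_manifest(tiny_manifest("cg01", pos = 4000), txs)
  expect_equal(ann$flat_gene_label, "TSS1500")
  expect_equal(ann$transcript_types[[1]], c("lncRNA", "mRNA"))
  expect_equal(ann$transcript_type_top, "mRNA")

  # empty transcript set: everything intergenic, no associated types
  ann0 <- build_annotated_manifest(tiny_manifest(c("cg01", "cg02")),
                                   transcripts = NULL)
  expect_equal(ann0$flat_gene_label, c("Intergenic", "Intergenic"))
  expect_true(all(lengths(ann0$transcript_types) == 0))
})

test_that("flat label is intergenic iff no per-transcript label exists", {
  g <- make_genome(seed = 14)
  mp <- make_manifest_pair(g, seed = 14)
  ann <- build_annotated_manifest(mp$new, g$transcripts, g$islands,
                                  g$states, g$ctcf)
  n_per_tx <- vapply(ann$per_transcript, nrow, integer(1))
  expect_equal(ann$flat_gene_label == "Intergenic", n_per_tx == 0)
  expect_equal(lengths(ann$transcript_types) == 0, n_per_tx == 0)
  # priority soundness: flat label never lower priority than any per-tx label
  for (i in which(n_per_tx > 0)) {
    ranks <- match(ann$per_transcript[[i]]$label,
                   c("TSS1500", "TSS200", "UTR5", "Exon1", "Body", "UTR3"))
    expect_lte(match(ann$flat_gene_label[i],
                     c("TSS1500", "TSS200", "UTR5", "Exon1", "Body", "UTR3")),
               min(ranks))
  }
  # partition: exactly one flat label and one island context each
  expect_true(all(ann$flat_gene_label %in%
    c("TSS1500", "TSS200", "UTR5", "Exon1", "Body", "UTR3", "Intergenic")))
  expect_true(all(ann$island_context %in%
    c("Island", "Shore", "Shelf", "OpenSea")))
})

test_that("category summaries count and percentage correctly", {
  ann <- build_annotated_manifest(tiny_manifest(sprintf("cg%02d", 1:4)),
                                  transcripts = NULL)
  s <- summarize_categories(ann)
  gene <- s[s$dimension == "gene_region", ]
  expect_equal(gene$category, "Intergenic")
  expect_equal(gene$pct, 100)

  # planted 2/1/1 split
  islands <- tibble::tibble(chrom = "chr1", start = 90L, end = 210L,
                            label = "i")
  ann2 <- build_annotated_manifest(
    tiny_manifest(sprintf("cg%02d", 1:4), pos = c(100, 200, 1500, 5500)),
    transcripts = NULL, islands = islands)
  s2 <- summarize_categories(ann2)
  isl <- s2[s2$dimension == "island_context", ]
  expect_equal(isl$pct[match(c("Island", "Shore", "OpenSea"), isl$category)],
               c(50, 25, 25))
  # percentages sum to 100 within each dimension
  sums <- tapply(s2$pct, s2$dimension, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("genome mirroring leaves every annotation label invariant", {
  g <- make_genome(n_islands = 3, n_transcripts = 4, seed = 31)
  L <- g$chrom_sizes$size[1]
  withr::with_seed(32, pos <- sort(sample.int(L, 400)))
  probes <- tiny_manifest(sprintf("cg%04d", seq_along(pos)), pos = pos)
  ann <- build_annotated_manifest(probes, g$transcripts, g$islands,
                                  g$states, g$ctcf)
  probes_m <- probes
  probes_m$pos <- L + 1L - probes$pos
  probes_m$strand <- "-"
  ann_m <- build_annotated_manifest(probes_m, mirror_transcripts(g$transcripts, L),
                                    mirror_track(g$islands, L),
                                    mirror_track(g$states, L),
                                    mirror_track(g$ctcf, L))
  expect_equal(ann_m$flat_gene_label, ann$flat_gene_label)
  expect_equal(ann_m$island_context, ann$island_context)
  expect_equal(ann_m$ctcf_bound, ann$ctcf_bound)
  expect_equal(ann_m$chromatin_state, ann$chromatin_state)
})
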
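test_that("probe class is inferred from the ID prefix", {
  m <- tiny_manifest(c("cg000001", "ch000001", "rs000001"))
  expect_equal(m$probe_class, c("cg", "ch", "rs"))
  expect_equal(probe_class_from_id("xx123"), "other")
})

test_that("replicate probes count once at unique-position level", {
  m <- tiny_manifest(c("cg000001", "cg000002"), pos = c(500, 500))
  expect_equal(nrow(m), 2)
  expect_equal(n_unique_positions(m), 1)
  expect_lte(n_unique_positions(m), nrow(m))
})

test_that("manifest write/read round-trips every field (internal dialect)", {
  g <- make_genome(seed = 5)
  mp <- make_manifest_pair(g, n_shared = 500, n_removed = 250, n_added = 250,
                           frac_masked = 0.1, seed = 5)
  m <- mp$old
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(m, tf)
  back <- read_manifest(tf, dialect = "internal")
  expect_equal(as.data.frame(back), as.data.frame(m[, names(back)]))
})

test_that("manifest dialects normalize coordinates, strand and chromosomes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("IlmnID,CHR,MAPINFO,Strand,Infinium_Design_Type",
               "cg01,1,1000,F,II",
               "cg02,X,2000,R,I",
               "cg03,GL000191.1,50,.,II"), tf)
  expect_warning(m <- read_manifest(tf, dialect = "illumina"),
                 "non-canonical")
  expect_equal(m$chrom, c("chr1", "chrX", "chrGL000191.1"))
  expect_equal(m$strand, c("+", "-", "unknown"))
  expect_equal(m$design, c("InfiniumII", "InfiniumI", "InfiniumII"))
  expect_equal(m$chrom_canonical, c(TRUE, TRUE, FALSE))

  # sesame dialect: 0-based CpG_beg converted to 1-based
  ts <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Probe_ID\tCpG_chrm\tCpG_beg\tmask",
               "cg01\tchr1\t999\tTRUE"), ts)
  s <- read_manifest(ts, dialect = "sesame")
  expect_equal(s$pos, 1000L)
  expect_true(s$masked)
})

test_that("manifest reader errors name the missing column and bad row", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("IlmnID,CHR", "cg01,1"), tf)
  expect_error(read_manifest(tf, dialect = "illumina"), "MAPINFO")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tchrom\tpos", "cg01\tchr1\tnot_a_number"), tf2)
  expect_error(read_manifest(tf2, dialect = "internal"), "row 1")
})

test_that("GTF reader preserves coordinates and orients exons 5' to 3'", {
  tf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";'
  writeLines(c(
    paste("chr1", "src", "transcript", 100, 500, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 100, 200, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 300, 500, ".", "+", ".", attrs, sep = "\t")
  ), tf)
  tx <- read_gene_models(tf)
  expect_equal(nrow(tx), 1)
  expect_equal(tx$transcript_type, "mRNA")
  expect_equal(tx$exons[[1]]$start, c(100, 300))

  # minus strand: exon list reversed relative to genomic order
  tneg <- withr::local_tempfile(fileext = ".gtf")
  attrs2 <- 'gene_id "G2"; transcript_id "T2"; transcript_type "lncRNA";'
  writeLines(c(
    paste("chr1", "src", "transcript", 100, 500, ".", "-", ".", attrs2, sep = "\t"),
    paste("chr1", "src", "exon", 100, 200, ".", "-", ".", attrs2, sep = "\t"),
    paste("chr1", "src", "exon", 300, 500, ".", "-", ".", attrs2, sep = "\t")
  ), tneg)
  txn <- read_gene_models(tneg)
  expect_equal(txn$exons[[1]]$start, c(300, 100))
  expect_equal(txn$transcript_type, "lncRNA")
})

test_that("GTF reader skips orphan exons with a warning and errors on empty", {
  tf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";'
  orphan <- 'gene_id "G9"; transcript_id "T9"; transcript_type "protein_coding";'
  writeLines(c(
    paste("chr1", "src", "transcript", 100, 500, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 100, 500, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 700, 800, ".", "+", ".", orphan, sep = "\t")
  ), tf)
  expect_warning(tx <- read_gene_models(tf), "orphan|without a parent")
  expect_equal(tx$transcript_id, "T1")

  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", 1, 10, ".", "+", ".", 'gene_id "G";',
                   sep = "\t"), empty)
  expect_error(read_gene_models(empty), "no transcripts")
})

test_that("synthetic GTF round-trips through the reader", {
  g <- make_genome(n_transcripts = 50, seed = 21)
  tf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(g$transcripts, tf)
  back <- read_gene_models(tf)
  back <- back[match(g$transcripts$transcript_id, back$transcript_id), ]
  expect_equal(back$tx_start, g$transcripts$tx_start)
  expect_equal(back$tx_end, g$transcripts$tx_end)
  expect_equal(back$strand, g$transcripts$strand)
  expect_equal(back$transcript_type, g$transcripts$transcript_type)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$exons[[i]]$start, g$transcripts$exons[[i]]$start)
    expect_equal(back$exons[[i]]$end, g$transcripts$exons[[i]]$end)
  }
})

test_that("BED conversion is 0-based half-open to 1-based inclusive", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tisland", tf)
  tr <- read_region_track(tf, "islands")
  expect_equal(tr$start, 1000L)
  expect_equal(tr$end, 2000L)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_region_track(empty, "islands")), 0)
})

test_that("BED round-trip is the identity on random interval sets", {
  withr::with_seed(11, {
    start <- sort(sample.int(1e5, 100))
    len <- sample.int(500, 100, replace = TRUE)
  })
  tr <- tibble::tibble(chrom = "chr1", start = as.integer(start),
                       end = as.integer(start + len),
                       label = sprintf("iv%03d", 1:100))
  tf <- withr::local_tempfile(fileext = ".bed")
  write_region_track(tr, tf)
  back <- read_region_track(tf, "t")
  expect_equal(as.data.frame(back[order(back$label), ]),
               as.data.frame(tr[order(tr$label), ]),
               ignore_attr = TRUE)
  # independent one-off conversion: raw BED columns vs internal coordinates
  raw <- read.table(tf, sep = "\t")
  expect_equal(sort(raw$V2 + 1L), sort(back$start))
  expect_equal(sort(raw$V3), sort(back$end))
})

test_that("beta matrix reader validates shape, range and duplicates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "cg01\t0\t1", "cg02\t0.5\t0.25"), tf)
  bm <- read_beta_matrix(tf)
  expect_equal(unname(bm$beta["cg01", ]), c(0, 1))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1", "cg01\t1.5"), bad)
  expect_error(read_beta_matrix(bad), "outside")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1", "cg01\t0.5", "cg01\t0.4"), dup)
  expect_error(read_beta_matrix(dup), "duplicate")

  detp_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1", "cg01\t0.01", "cg02\t0.01"), detp_bad)
  expect_error(read_beta_matrix(tf, detp_bad), "shape mismatch")
})

test_that("beta matrix write/read round-trip preserves values exactly", {
  res <- make_beta_matrix(tiny_manifest(sprintf("cg%06d", 1:50)),
                          n_replicate_pairs = 1, detp_fail_rate = 0.05,
                          seed = 4)
  tb <- withr::local_tempfile(fileext = ".tsv")
  td <- withr::local_tempfile(fileext = ".tsv")
  tm <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(res$bm, tb, td, tm)
  back <- read_beta_matrix(tb, td, tm)
  expect_equal(back$beta, res$bm$beta)
  expect_equal(back$detp, res$bm$detp)
  expect_equal(back$sample_meta$group, res$bm$sample_meta$group)
})
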
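#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise
#'   ungroup bind_rows left_join anti_join semi_join inner_join n rename
#'   distinct across all_of pull count if_else row_number desc first
#'   bind_cols
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom purrr map map2 map_chr map_int map_dbl map_lgl pmap imap walk
#' @importFrom stats cor dist hclust prcomp phyper p.adjust quantile sd
#'   rnorm runif rbinom plogis qlogis median var setNames pt
#' @importFrom utils head tail
NULL

CANONICAL_CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")

GENE_REGION_LEVELS <- c("TSS1500", "TSS200", "UTR5", "Exon1", "Body",
                        "UTR3", "Intergenic")
ISLAND_LEVELS <- c("Island", "Shore", "Shelf", "OpenSea")

#' Normalize chromosome names to the "chr"-prefixed convention
#'
#' Adds the `chr` prefix where missing and maps `MT` to `chrM`. Names that are
#' still not one of chr1..chr22, chrX, chrY, chrM after normalization are
#' preserved verbatim (and flagged by callers via [is_canonical_chrom()]).
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  x[x %in% c("MT", "chrMT")] <- "chrM"
  bare <- !is.na(x) & !startsWith(x, "chr")
  x[bare] <- paste0("chr", x[bare])
  x
}

#' @rdname normalize_chrom
#' @export
is_canonical_chrom <- function(x) x %in% CANONICAL_CHROMS

#' Infer probe class from the probe identifier prefix
#'
#' Infinium probe IDs encode the assay class in their prefix: `cg` (CpG
#' methylation), `ch` (CpH methylation) and `rs` (SNP genotyping probes).
#' The class is derived from the ID, never from a manifest column, so it is
#' invariant across manifest dialects.
#'
#' @param probe_id Character vector of probe identifiers.
#' @return Character vector with values `"cg"`, `"ch"`, `"rs"` or `"other"`.
#' @export
probe_class_from_id <- function(probe_id) {
  pre <- tolower(substr(probe_id, 1, 2))
  out <- rep("other", length(probe_id))
  out[pre == "cg"] <- "cg"
  out[pre == "ch"] <- "ch"
  out[pre == "rs"] <- "rs"
  out
}

#' Strip replicate/build suffixes from EPIC v2 probe identifiers
#'
#' EPIC v2 manifests carry suffixes after an underscore (e.g.
#' `cg00000029_TC21`); the base ID is everything before the first occurrence
#' of the separator.
#'
#' @param probe_id Character vector of probe IDs.
#' @param sep Suffix separator (default `"_"`).
#' @return Character vector of base IDs.
#' @export
probe_id_base <- function(probe_id, sep = "_") {
  sub(paste0(sep, ".*$"), "", probe_id)
}

norm_strand <- function(x) {
  x <- as.character(x)
  x[x %in% c("F", "f", "1")] <- "+"
  x[x %in% c("R", "r", "-1")] <- "-"
  x[!(x %in% c("+", "-"))] <- "unknown"
  x[is.na(x)] <- "unknown"
  x
}

norm_design <- function(x) {
  x <- as.character(x)
  x[x %in% c("I", "1")] <- "InfiniumI"
  x[x %in% c("II", "2")] <- "InfiniumII"
  bad <- !(x %in% c("InfiniumI", "InfiniumII")) & !is.na(x)
  if (any(bad)) {
    abort(sprintf("unrecognized Infinium design value(s): %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

manifest_dialects <- list(
  illumina = c("CHR", "MAPINFO"),
  sesame   = c("Probe_ID", "CpG_chrm", "CpG_beg"),
  internal = c("probe_id", "chrom", "pos")
)

#' Read a probe manifest
#'
#' Reads an array manifest in one of three dialects and normalizes it into
#' the internal probe table: one row per probe with 1-based coordinates,
#' "chr"-prefixed chromosome names, strand in `{+, -, unknown}`, design in
#' `{InfiniumI, InfiniumII}` and probe class inferred from the ID prefix.
#'
#' Required columns per dialect:
#' * `illumina`: `IlmnID` or `Name`, `CHR`, `MAPINFO` (1-based); optional
#'   `Strand`, `Infinium_Design_Type`.
#' * `sesame`: `Probe_ID`, `CpG_chrm`, `CpG_beg` (0-based, converted to
#'   1-based); optional `mask`, `strand`/`mapYD_A`, `design`.
#' * `internal`: `probe_id`, `chrom`, `pos`; optional `strand`, `design`,
#'   `masked` (this is the dialect written by [write_manifest()]).
#'
#' Probe IDs must be unique at the row level; positions may repeat
#' (replicate probes), which is why total and unique-position counts can
#' differ. Non-canonical chromosome names are preserved verbatim but flagged
#' in the `chrom_canonical` column.
#'
#' @param path Path to a CSV/TSV manifest file (delimiter sniffed).
#' @param dialect One of `"internal"`, `"illumina"`, `"sesame"`.
#' @return A tibble with columns `probe_id`, `chrom`, `pos`, `strand`,
#'   `design`, `probe_class`, `masked`, `chrom_canonical`.
#' @export
read_manifest <- function(path, dialect = c("internal", "illumina", "sesame")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("manifest file not found: %s", path))
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  req <- manifest_dialects[[dialect]]
  if (dialect == "illumina") {
    idcol <- intersect(c("IlmnID", "Name"), names(df))
    if (length(idcol) == 0)
      abort("manifest format error: missing required column 'IlmnID' (or 'Name')")
    idcol <- idcol[[1]]
  }
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    abort(sprintf("manifest format error: missing required column '%s'",
                  missing_cols[[1]]))

  parse_pos <- function(raw, offset = 0L) {
    pos <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(pos) & !is.na(raw))
    if (length(bad) > 0)
      abort(sprintf("unparseable coordinate '%s' at manifest row %d",
                    raw[bad[[1]]], bad[[1]]))
    as.integer(pos) + offset
  }

  out <- switch(dialect,
    illumina = tibble(
      probe_id = df[[idcol]],
      chrom = normalize_chrom(df$CHR),
      pos = parse_pos(df$MAPINFO),
      strand = norm_strand(col_or(df, "Strand", rep(NA_character_, nrow(df)))),
      design = norm_design(col_or(df, "Infinium_Design_Type",
                           rep("InfiniumII", nrow(df)))),
      masked = FALSE
    ),
    sesame = tibble(
      probe_id = df$Probe_ID,
      chrom = normalize_chrom(df$CpG_chrm),
      pos = parse_pos(df$CpG_beg, offset = 1L),
      strand = norm_strand(col_or(df, "strand", rep(NA_character_, nrow(df)))),
      design = norm_design(col_or(df, "design", rep("InfiniumII", nrow(df)))),
      masked = as.logical(col_or(df, "mask", rep(FALSE, nrow(df))))
    ),
    internal = tibble(
      probe_id = df$probe_id,
      chrom = normalize_chrom(df$chrom),
      pos = parse_pos(df$pos),
      strand = norm_strand(col_or(df, "strand", rep(NA_character_, nrow(df)))),
      design = norm_design(col_or(df, "design", rep("InfiniumII", nrow(df)))),
      masked = as.logical(col_or(df, "masked", rep(FALSE, nrow(df))))
    )
  )
  out$masked[is.na(out$masked)] <- FALSE
  if (anyDuplicated(out$probe_id))
    abort("manifest format error: duplicate probe_id values")
  bad_pos <- which(out$pos < 1L)
  if (length(bad_pos) > 0)
    abort(sprintf("coordinate < 1 at manifest row %d", bad_pos[[1]]))
  out$probe_class <- probe_class_from_id(out$probe_id)
  out$chrom_canonical <- is_canonical_chrom(out$chrom)
  if (!all(out$chrom_canonical))
    warn(sprintf("%d probe(s) on non-canonical contigs preserved and flagged",
                 sum(!out$chrom_canonical)))
  out[, c("probe_id", "chrom", "pos", "strand", "design", "probe_class",
          "masked", "chrom_canonical")]
}

#' Write a probe manifest in the internal dialect
#'
#' @param manifest Probe tibble as returned by [read_manifest()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("probe_id", "chrom", "pos", "strand", "design", "masked")
  readr::write_tsv(manifest[, intersect(cols, names(manifest))], path,
                   progress = FALSE)
  invisible(path)
}

#' Count unique probe positions
#'
#' Replicate probes interrogate the same cytosine from distinct bead designs,
#' so a manifest can have more rows than unique (chrom, pos, strand) sites.
#'
#' @param manifest Probe tibble.
#' @return Integer count of distinct (chrom, pos, strand) triples.
#' @export
n_unique_positions <- function(manifest) {
  nrow(distinct(manifest, .data$chrom, .data$pos, .data$strand))
}

gencode_biotype_map <- function(biotype) {
  lnc <- c("lncRNA", "lincRNA", "antisense", "sense_intronic",
           "sense_overlapping", "3prime_overlapping_ncRNA", "macro_lncRNA",
           "bidirectional_promoter_lncRNA", "processed_transcript")
  dplyr::case_when(
    biotype == "protein_coding" ~ "mRNA",
    biotype %in% lnc ~ "lncRNA",
    TRUE ~ "other"
  )
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- regexpr(paste0(key, ' "[^"]*"'), attrs)
  ok <- hit > 0
  out[ok] <- sub(paste0('^', key, ' "([^"]*)"$'), "\\1",
                 regmatches(attrs, hit))
  out
}

#' Read transcript models from a GENCODE-dialect GTF
#'
#' Parses `transcript` and `exon` features. Coordinates are GTF 1-based
#' inclusive and preserved as such. Exons are stored in transcript
#' orientation (5' to 3': genomic order on `+`, reversed on `-`).
#' Transcript biotypes are collapsed to `mRNA` (protein_coding), `lncRNA`
#' (lncRNA/lincRNA/antisense and related GENCODE long-noncoding biotypes)
#' or `other`.
#'
#' @param path Path to a GTF file.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `transcript_type`, `chrom`, `strand`, `tx_start`, `tx_end` and an
#'   `exons` list-column of tibbles with `start`, `end`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) abort("no transcripts parsed from GTF")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) abort(sprintf("malformed GTF line %d", which(nf < 9)[[1]]))
  feat <- map_chr(fields, 3)
  keep <- feat %in% c("transcript", "exon")
  fields <- fields[keep]; feat <- feat[keep]
  attrs <- map_chr(fields, 9)
  tab <- tibble(
    chrom = normalize_chrom(map_chr(fields, 1)),
    feature = feat,
    start = as.integer(map_chr(fields, 4)),
    end = as.integer(map_chr(fields, 5)),
    strand = map_chr(fields, 7),
    transcript_id = gtf_attr(attrs, "transcript_id"),
    gene_id = gtf_attr(attrs, "gene_id"),
    biotype = gtf_attr(attrs, "transcript_type")
  )
  btype2 <- gtf_attr(attrs, "transcript_biotype")
  tab$biotype[is.na(tab$biotype)] <- btype2[is.na(tab$biotype)]
  tx <- filter(tab, .data$feature == "transcript")
  if (nrow(tx) == 0) abort("no transcripts parsed from GTF")
  ex <- filter(tab, .data$feature == "exon")
  orphan <- !(ex$transcript_id %in% tx$transcript_id)
  if (any(orphan)) {
    warn(sprintf("skipping %d exon(s) without a parent transcript feature",
                 sum(orphan)))
    ex <- ex[!orphan, ]
  }
  ex_by_tx <- split(ex[, c("start", "end")], ex$transcript_id)
  out <- tibble(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    transcript_type = gencode_biotype_map(tx$biotype),
    chrom = tx$chrom,
    strand = tx$strand,
    tx_start = tx$start,
    tx_end = tx$end
  )
  out$exons <- map2(out$transcript_id, out$strand, function(id, s) {
    e <- ex_by_tx[[id]]
    if (is.null(e) || nrow(e) == 0) return(tibble(start = integer(), end = integer()))
    e <- e[order(e$start), , drop = FALSE]
    if (s == "-") e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
    as_tibble(e)
  })
  out
}

#' Read a genomic region track from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention (`start + 1`, `end`) and sorted per
#' chromosome.
#'
#' @param path Path to a BED3/BED4 file (4th column used as interval label).
#' @param name Track name, e.g. `"islands"`, `"chromatin_states"`, `"ctcf"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `label` and a
#'   `track_name` attribute. Empty files yield a valid empty track.
#' @export
read_region_track <- function(path, name = "track") {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  label = character())
    attr(out, "track_name") <- name
    return(out)
  }
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 3))
    abort(sprintf("malformed BED line %d", which(lengths(parts) < 3)[[1]]))
  start0 <- as.integer(map_chr(parts, 2))
  end0 <- as.integer(map_chr(parts, 3))
  bad <- which(is.na(start0) | is.na(end0) | start0 >= end0)
  if (length(bad) > 0)
    abort(sprintf("invalid BED interval at line %d (start >= end)", bad[[1]]))
  out <- tibble(
    chrom = normalize_chrom(map_chr(parts, 1)),
    start = start0 + 1L,
    end = end0,
    label = map_chr(parts, function(p) if (length(p) >= 4) p[[4]] else name)
  )
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  attr(out, "track_name") <- name
  out
}

#' Write a region track as BED (inverse of [read_region_track()])
#'
#' @param track Tibble with `chrom`, `start`, `end`, `label` (1-based
#'   inclusive).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_region_track <- function(track, path) {
  bed <- tibble(chrom = track$chrom, start = track$start - 1L,
                end = track$end, label = track$label)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Construct a beta-value matrix container
#'
#' Bundles a probes-by-samples matrix of methylation beta values (fractions
#' in \[0, 1\], `NA` allowed) with an optional matching detection p-value
#' matrix and per-sample metadata.
#'
#' @param beta Numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param detp Optional numeric matrix of detection p-values, same
#'   dimensions and dimnames as `beta`.
#' @param sample_meta Optional tibble of per-sample labels with a
#'   `sample_id` column.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, detp = NULL, sample_meta = NULL) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (anyDuplicated(rownames(beta))) abort("duplicate probe IDs in beta matrix")
  rng <- range(beta, na.rm = TRUE)
  if (!all(is.na(beta)) && (rng[1] < 0 || rng[2] > 1))
    abort("beta values outside [0, 1]")
  if (!is.null(detp)) {
    if (!identical(dim(detp), dim(beta)))
      abort("shape mismatch between beta and detection-p matrices")
    if (!identical(dimnames(detp), dimnames(beta)))
      dimnames(detp) <- dimnames(beta)
  }
  if (is.null(sample_meta)) {
    sample_meta <- tibble(sample_id = colnames(beta))
  } else {
    sample_meta <- as_tibble(sample_meta)
    stopifnot("sample_id" %in% names(sample_meta))
    sample_meta <- sample_meta[match(colnames(beta), sample_meta$sample_id), ]
  }
  structure(list(beta = beta, detp = detp, sample_meta = sample_meta),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detp)) "" else " (+ detection p)"))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

#' @importFrom tibble as_tibble
#' @export
as_tibble.beta_matrix <- function(x, ...) {
  long <- as_tibble(x$beta, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "beta")
  if (!is.null(x$detp)) {
    dp <- as_tibble(x$detp, rownames = "probe_id") %>%
      tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                          values_to = "detp")
    long <- left_join(long, dp, by = c("probe_id", "sample_id"))
  }
  left_join(long, x$sample_meta, by = "sample_id")
}

#' Read a beta-value matrix (and optional detection p / sample metadata)
#'
#' Expects TSV files whose first column holds probe IDs and whose header row
#' holds sample IDs; the detection-p file must have the same shape and
#' dimnames as the beta file.
#'
#' @param beta_path Path to the beta TSV.
#' @param detp_path Optional path to the detection-p TSV.
#' @param meta_path Optional path to a sample-metadata TSV (must contain a
#'   `sample_id` column).
#' @return A [beta_matrix()] object.
#' @export
read_beta_matrix <- function(beta_path, detp_path = NULL, meta_path = NULL) {
  read_mat <- function(p) {
    df <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) abort(sprintf("duplicate probe IDs in %s", p))
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- ids
    m
  }
  beta <- read_mat(beta_path)
  rng <- range(beta, na.rm = TRUE)
  if (!all(is.na(beta)) && (rng[1] < 0 || rng[2] > 1))
    abort("beta values outside [0, 1]")
  detp <- if (!is.null(detp_path)) read_mat(detp_path) else NULL
  if (!is.null(detp) && !identical(dim(detp), dim(beta)))
    abort("shape mismatch between beta and detection-p matrices")
  meta <- if (!is.null(meta_path))
    readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  else NULL
  beta_matrix(beta, detp = detp, sample_meta = meta)
}

#' Write a beta_matrix to TSV files
#'
#' @param bm A [beta_matrix()] object.
#' @param beta_path Output path for beta values.
#' @param detp_path Optional output path for detection p-values.
#' @param meta_path Optional output path for sample metadata.
#' @return `beta_path`, invisibly.
#' @export
write_beta_matrix <- function(bm, beta_path, detp_path = NULL,
                              meta_path = NULL) {
  write_mat <- function(m, p) {
    df <- as_tibble(m, rownames = "probe_id")
    readr::write_tsv(df, p, progress = FALSE)
  }
  write_mat(bm$beta, beta_path)
  if (!is.null(detp_path) && !is.null(bm$detp)) write_mat(bm$detp, detp_path)
  if (!is.null(meta_path)) readr::write_tsv(bm$sample_meta, meta_path,
                                            progress = FALSE)
  invisible(beta_path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
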
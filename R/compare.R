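karyotype_order <- function(chrom) {
  ord <- match(chrom, CANONICAL_CHROMS)
  ord[is.na(ord)] <- length(CANONICAL_CHROMS) + 1L
  ord
}

diff_key <- function(manifest, match_on, suffix_sep = "_") {
  switch(match_on,
    probe_id_base = probe_id_base(manifest$probe_id, sep = suffix_sep),
    position = paste(manifest$chrom, manifest$pos, manifest$strand, sep = ":"),
    abort(sprintf("unknown matching key '%s'", match_on))
  )
}

#' Compare two probe manifests
#'
#' Partitions the probes of an old and a new manifest into shared, removed
#' (old only) and added (new only) sets under a chosen matching key, and
#' reports counts at both row level and unique-(chrom, pos, strand) level.
#' New-array EPIC v2 style probe IDs carry replicate/build suffixes, so the
#' default key strips everything after the first underscore
#' ([probe_id_base()]); position matching is offered as a cross-check.
#'
#' @param old,new Probe tibbles from [read_manifest()].
#' @param match_on `"probe_id_base"` (default) or `"position"`.
#' @param suffix_sep Suffix separator for `probe_id_base` matching.
#' @return An object of class `manifest_diff`: a list with `shared_ids`,
#'   `removed_ids`, `added_ids` (full probe IDs; shared IDs taken from the
#'   new manifest), `match_on`, and a `counts` tibble with one row per
#'   `level` (`row`, `unique_position`) holding `n_old`, `n_new`,
#'   `n_shared`, `n_removed`, `n_added` and `pct_shared_of_new`.
#' @export
diff_manifests <- function(old, new, match_on = c("probe_id_base", "position"),
                           suffix_sep = "_") {
  match_on <- match.arg(match_on)
  if (nrow(old) == 0 || nrow(new) == 0)
    abort("cannot diff an empty manifest")
  key_old <- diff_key(old, match_on, suffix_sep)
  key_new <- diff_key(new, match_on, suffix_sep)
  in_both_old <- key_old %in% key_new
  in_both_new <- key_new %in% key_old
  row_counts <- tibble(
    level = "row",
    n_old = nrow(old), n_new = nrow(new),
    n_shared = sum(in_both_new),
    n_removed = sum(!in_both_old),
    n_added = sum(!in_both_new)
  )
  uo <- distinct(old, .data$chrom, .data$pos, .data$strand)
  un <- distinct(new, .data$chrom, .data$pos, .data$strand)
  pk_old <- paste(uo$chrom, uo$pos, uo$strand, sep = ":")
  pk_new <- paste(un$chrom, un$pos, un$strand, sep = ":")
  uniq_counts <- tibble(
    level = "unique_position",
    n_old = length(pk_old), n_new = length(pk_new),
    n_shared = sum(pk_new %in% pk_old),
    n_removed = sum(!(pk_old %in% pk_new)),
    n_added = sum(!(pk_new %in% pk_old))
  )
  counts <- bind_rows(row_counts, uniq_counts) %>%
    mutate(pct_shared_of_new = 100 * .data$n_shared / .data$n_new)
  structure(list(
    shared_ids = new$probe_id[in_both_new],
    removed_ids = old$probe_id[!in_both_old],
    added_ids = new$probe_id[!in_both_new],
    match_on = match_on,
    counts = counts
  ), class = "manifest_diff")
}

#' @export
print.manifest_diff <- function(x, ...) {
  cat(sprintf("<manifest_diff> matched on %s\n", x$match_on))
  print(x$counts)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.manifest_diff <- function(x, ...) x$counts

#' Probe-class-stratified manifest-diff accounting
#'
#' Splits shared/removed/added row counts by probe class (`cg` CpG, `ch`
#' CpH, `rs` SNP genotyping; anything else `other`). The classes partition
#' every diff set, so class counts sum to the row-level totals.
#'
#' @param diff A `manifest_diff` from [diff_manifests()].
#' @param old,new The manifests the diff was computed from.
#' @return Tibble with `probe_class`, `n_shared`, `n_removed`, `n_added`,
#'   `n_old`, `n_new`.
#' @export
probe_class_accounting <- function(diff, old, new) {
  classes <- c("cg", "ch", "rs", "other")
  cls_of <- function(ids) factor(probe_class_from_id(ids), levels = classes)
  tab <- tibble(
    probe_class = classes,
    n_shared = as.integer(table(cls_of(diff$shared_ids))),
    n_removed = as.integer(table(cls_of(diff$removed_ids))),
    n_added = as.integer(table(cls_of(diff$added_ids))),
    n_old = as.integer(table(factor(old$probe_class, levels = classes))),
    n_new = as.integer(table(factor(new$probe_class, levels = classes)))
  )
  if (all(tab$n_old[tab$probe_class == "other"] == 0) &&
      all(tab$n_new[tab$probe_class == "other"] == 0))
    tab <- filter(tab, .data$probe_class != "other")
  tab
}

#' Per-chromosome probe counts and percentages
#'
#' @param manifest Probe tibble (or any tibble with a `chrom` column).
#' @return Tibble with `chrom`, `n`, `pct` in karyotype order
#'   (chr1..chr22, chrX, chrY, chrM, then non-canonical contigs).
#' @export
per_chromosome_counts <- function(manifest) {
  manifest %>%
    count(.data$chrom, name = "n") %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    arrange(karyotype_order(.data$chrom), .data$chrom)
}

#' Infinium design-chemistry counts and percentages
#'
#' @param manifest Probe tibble with a `design` column.
#' @return Tibble with `design`, `n`, `pct`.
#' @export
design_type_counts <- function(manifest) {
  manifest %>%
    count(.data$design, name = "n") %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    arrange(.data$design)
}

#' Probe density in fixed-width genomic windows
#'
#' Window `w` of a chromosome covers positions `[(w-1)*W + 1, w*W]`
#' (1-based inclusive); the last window is truncated at the chromosome end.
#' Probes mapped beyond the stated chromosome size are counted in the last
#' window and reported with a warning. Window counts over all chromosomes
#' sum to the number of probes on chromosomes present in `chrom_sizes`.
#'
#' @param probes Probe tibble (`chrom`, `pos`).
#' @param chrom_sizes Tibble with `chrom`, `size` (bp).
#' @param window_size Window width in bp (default 1 Mb).
#' @return Tibble with `chrom`, `window` (1-based index), `start`, `end`,
#'   `n`.
#' @export
windowed_density <- function(probes, chrom_sizes, window_size = 1e6) {
  stopifnot(window_size >= 1)
  rows <- map(seq_len(nrow(chrom_sizes)), function(i) {
    ch <- chrom_sizes$chrom[[i]]
    size <- chrom_sizes$size[[i]]
    nwin <- max(1L, as.integer(ceiling(size / window_size)))
    pos <- probes$pos[probes$chrom == ch]
    if (any(pos > size)) {
      warn(sprintf("%d probe(s) beyond %s size counted in last window",
                   sum(pos > size), ch))
    }
    w <- pmin(as.integer(ceiling(pos / window_size)), nwin)
    tibble(
      chrom = ch,
      window = seq_len(nwin),
      start = as.integer((seq_len(nwin) - 1L) * window_size + 1L),
      end = as.integer(pmin(seq_len(nwin) * window_size, size)),
      n = as.integer(tabulate(w, nbins = nwin))
    )
  })
  bind_rows(rows)
}

transcripts_covered <- function(annotated) {
  ids <- unlist(map(annotated$per_transcript, "transcript_id"))
  unique(ids)
}

#' Transcripts newly covered by the new array
#'
#' A transcript counts as covered when at least one probe carries a
#' per-transcript gene-region label for it. Returns the transcripts covered
#' in the new annotation but not the old.
#'
#' @param annotated_old,annotated_new Outputs of
#'   [build_annotated_manifest()] for the two manifests (each built against
#'   its own gene models).
#' @return Tibble with `transcript_id` (one row per newly covered
#'   transcript); the gain count is `nrow()` of the result.
#' @export
transcript_coverage_diff <- function(annotated_old, annotated_new) {
  new_ids <- setdiff(transcripts_covered(annotated_new),
                     transcripts_covered(annotated_old))
  tibble(transcript_id = sort(new_ids))
}
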
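# Synthetic-data generators. These emulate the study's inputs -- a pair of
# array manifests with controlled overlap, functional annotation tracks, and
# beta matrices with planted tissue/disease structure, technical-replicate
# noise and detection-p failures -- so every stage of the pipeline runs with
# no external download, against machine-readable ground truth.

CHROMATIN_STATES_15 <- c(
  "TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF_Rpts",
  "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies"
)

#' Generate a toy genome with annotation tracks
#'
#' Builds chromosome(s) carrying non-overlapping CpG islands, multi-exon
#' transcripts on both strands, a complete 15-state chromatin segmentation
#' tiling and sparse CTCF-binding intervals. Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes (named chr1, chr2, ...).
#' @param chrom_size Chromosome length in bp (>= 10 kb).
#' @param n_islands CpG islands per chromosome (lengths 200-2000 bp,
#'   non-overlapping with >= 4 kb spacing so island flank bands stay
#'   distinguishable except where deliberately close).
#' @param n_transcripts Transcripts per chromosome (1-5 exons each; a
#'   fraction carry non-degenerate 5'/3' UTR intervals, i.e. the transcript
#'   extends past its terminal exons).
#' @param n_ctcf CTCF intervals per chromosome.
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_genome`: `chrom_sizes` (tibble `chrom`,
#'   `size`), `islands`, `states`, `ctcf` (region-track tibbles) and
#'   `transcripts` (gene-model tibble as from [read_gene_models()]).
#' @export
make_genome <- function(n_chrom = 1, chrom_size = 1e5, n_islands = 5,
                        n_transcripts = 5, n_ctcf = 4, seed = 1L) {
  if (chrom_size < 1e4) abort("chrom_size must be >= 10 kb")
  slot <- floor(chrom_size / max(n_islands, 1))
  if (n_islands > 0 && slot < 2000 + 100)
    abort("too many islands for the chromosome size")
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    chrom_sizes <- tibble(chrom = chroms, size = as.integer(chrom_size))
    islands <- bind_rows(map(chroms, function(ch) {
      if (n_islands == 0)
        return(tibble(chrom = character(), start = integer(),
                      end = integer(), label = character()))
      len <- sample(200:2000, n_islands, replace = TRUE)
      offset <- map_int(seq_len(n_islands), function(i)
        sample.int(max(slot - len[i] - 1L, 1L), 1))
      start <- as.integer((seq_len(n_islands) - 1L) * slot + offset)
      tibble(chrom = ch, start = start, end = as.integer(start + len - 1L),
             label = paste0(ch, "_island", seq_len(n_islands)))
    }))
    transcripts <- bind_rows(map(chroms, function(ch) {
      rows <- map(seq_len(n_transcripts), function(i) {
        k <- sample(1:5, 1)
        ex_len <- sample(100:500, k, replace = TRUE)
        intron <- if (k > 1) sample(200:2000, k - 1, replace = TRUE) else integer()
        span <- sum(ex_len) + sum(intron)
        gstart <- sample.int(max(chrom_size - span - 4000L, 1L), 1) + 2000L
        starts <- gstart + cumsum(c(0L, head(ex_len, -1) + intron))
        ends <- starts + ex_len - 1L
        strand <- sample(c("+", "-"), 1)
        tx_start <- min(starts); tx_end <- max(ends)
        # sometimes extend the transcript past its terminal exons so the
        # literal UTR intervals are non-empty
        if (runif(1) < 0.4) tx_start <- max(1L, tx_start - sample(50:300, 1))
        if (runif(1) < 0.4) tx_end <- min(as.integer(chrom_size),
                                          tx_end + sample(50:300, 1))
        ex <- tibble(start = as.integer(starts), end = as.integer(ends))
        if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
        tibble(
          transcript_id = sprintf("TX_%s_%03d", ch, i),
          gene_id = sprintf("GENE_%s_%03d", ch, i),
          transcript_type = sample(c("mRNA", "lncRNA", "other"), 1,
                                   prob = c(0.7, 0.2, 0.1)),
          chrom = ch, strand = strand,
          tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
          exons = list(ex)
        )
      })
      bind_rows(rows)
    }))
    states <- bind_rows(map(chroms, function(ch) {
      starts <- integer(); ends <- integer(); pos <- 1L
      while (pos <= chrom_size) {
        len <- sample(500:5000, 1)
        starts <- c(starts, pos)
        ends <- c(ends, min(pos + len - 1L, as.integer(chrom_size)))
        pos <- pos + len
      }
      tibble(chrom = ch, start = starts, end = ends,
             label = sample(CHROMATIN_STATES_15, length(starts),
                            replace = TRUE))
    }))
    ctcf <- bind_rows(map(chroms, function(ch) {
      if (n_ctcf == 0)
        return(tibble(chrom = character(), start = integer(),
                      end = integer(), label = character()))
      len <- sample(200:1000, n_ctcf, replace = TRUE)
      start <- sort(sample.int(chrom_size - 1000L, n_ctcf))
      tibble(chrom = ch, start = as.integer(start),
             end = as.integer(start + len - 1L), label = "CTCF")
    })) %>% arrange(.data$chrom, .data$start)
    structure(list(chrom_sizes = chrom_sizes, islands = islands,
                   transcripts = transcripts, states = states, ctcf = ctcf),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chrom(s), %d islands, %d transcripts\n",
              nrow(x$chrom_sizes), nrow(x$islands), nrow(x$transcripts)))
  invisible(x)
}

#' Serialize a synthetic genome to standard formats
#'
#' Writes `islands.bed`, `states.bed`, `ctcf.bed` (0-based half-open BED)
#' and `genes.gtf` (GENCODE-dialect GTF) under `dir`.
#'
#' @param genome A [make_genome()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_genome_files <- function(genome, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_region_track(genome$islands, file.path(dir, "islands.bed"))
  write_region_track(genome$states, file.path(dir, "states.bed"))
  write_region_track(genome$ctcf, file.path(dir, "ctcf.bed"))
  write_gtf(genome$transcripts, file.path(dir, "genes.gtf"))
  invisible(dir)
}

#' Write transcript models as a GENCODE-dialect GTF
#'
#' @param transcripts Gene-model tibble (see [read_gene_models()]).
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  biotype_back <- c(mRNA = "protein_coding", lncRNA = "lncRNA",
                    other = "misc_RNA")
  lines <- unlist(pmap(transcripts, function(transcript_id, gene_id,
                                             transcript_type, chrom, strand,
                                             tx_start, tx_end, exons, ...) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; transcript_type "%s";',
      gene_id, transcript_id, biotype_back[[transcript_type]])
    tx_line <- paste(chrom, "synthetic", "transcript", tx_start, tx_end, ".",
                     strand, ".", attrs, sep = "\t")
    ex_lines <- paste(chrom, "synthetic", "exon", exons$start, exons$end,
                      ".", strand, ".", attrs, sep = "\t")
    c(tx_line, ex_lines)
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

random_probe_ids <- function(n, frac_ch, frac_rs, id_offset = 0L) {
  cls <- sample(c("cg", "ch", "rs"), n, replace = TRUE,
                prob = c(1 - frac_ch - frac_rs, frac_ch, frac_rs))
  sprintf("%s%08d", cls, id_offset + seq_len(n))
}

#' Generate a pair of manifests with planted overlap
#'
#' Plants exactly `n_shared` probes present in both manifests, `n_removed`
#' present only in the old one and `n_added` present only in the new one,
#' at distinct CpG positions of the synthetic genome. A random subset of the
#' new manifest's probes carries EPIC-v2-style ID suffixes (e.g.
#' `cg00000012_TC21`) to exercise suffix-aware matching. Optionally plants
#' position-replicate probes (distinct IDs at a shared (chrom, pos, strand))
#' in the new manifest.
#'
#' @param genome A [make_genome()] result.
#' @param n_shared,n_removed,n_added Planted set sizes.
#' @param frac_infinium2 Fraction of Infinium II designs (default 0.85, the
#'   type II majority typical of these arrays).
#' @param frac_ch,frac_rs Fractions of CpH and SNP probes.
#' @param frac_suffixed Fraction of new-manifest probes given a v2-style
#'   suffix.
#' @param frac_masked Fraction of masked probes in each manifest.
#' @param n_position_replicates Extra new-manifest probes duplicating an
#'   existing (chrom, pos, strand) under a fresh base ID.
#' @param seed Integer RNG seed.
#' @return List with `old`, `new` (probe tibbles) and `truth` (list with
#'   base-ID sets `shared`, `removed`, `added` and the planted counts).
#' @export
make_manifest_pair <- function(genome, n_shared = 70, n_removed = 20,
                               n_added = 30, frac_infinium2 = 0.85,
                               frac_ch = 0.02, frac_rs = 0.02,
                               frac_suffixed = 0.3, frac_masked = 0,
                               n_position_replicates = 0, seed = 1L) {
  total <- n_shared + n_removed + n_added
  gsize <- sum(genome$chrom_sizes$size)
  if (total > gsize / 2) abort("too many probes for the genome size")
  withr::with_seed(seed, {
    chrom <- sample(genome$chrom_sizes$chrom, total, replace = TRUE,
                    prob = genome$chrom_sizes$size)
    pos <- map_int(chrom, function(ch)
      sample.int(genome$chrom_sizes$size[genome$chrom_sizes$chrom == ch], 1))
    while (anyDuplicated(paste(chrom, pos))) {
      dup <- duplicated(paste(chrom, pos))
      pos[dup] <- map_int(chrom[dup], function(ch)
        sample.int(genome$chrom_sizes$size[genome$chrom_sizes$chrom == ch], 1))
    }
    base <- tibble(
      probe_id = random_probe_ids(total, frac_ch, frac_rs),
      chrom = chrom,
      pos = as.integer(pos),
      strand = sample(c("+", "-"), total, replace = TRUE),
      design = sample(c("InfiniumII", "InfiniumI"), total, replace = TRUE,
                      prob = c(frac_infinium2, 1 - frac_infinium2)),
      masked = runif(total) < frac_masked
    )
    grp <- rep(c("shared", "removed", "added"),
               c(n_shared, n_removed, n_added))
    old <- base[grp != "added", ]
    new <- base[grp != "removed", ]
    sufx <- runif(nrow(new)) < frac_suffixed
    new$probe_id[sufx] <- paste0(
      new$probe_id[sufx], "_",
      sample(c("TC21", "BC11", "TC11", "BC21"), sum(sufx), replace = TRUE))
    replicate_ids <- character()
    if (n_position_replicates > 0) {
      src <- new[sample.int(nrow(new), n_position_replicates), ]
      replicate_ids <- sprintf("cg9%07d", seq_len(n_position_replicates))
      src$probe_id <- replicate_ids
      new <- bind_rows(new, src)
    }
    finish <- function(m) {
      m$probe_class <- probe_class_from_id(m$probe_id)
      m$chrom_canonical <- is_canonical_chrom(m$chrom)
      m
    }
    list(
      old = finish(old),
      new = finish(new),
      truth = list(
        shared = base$probe_id[grp == "shared"],
        removed = base$probe_id[grp == "removed"],
        added = c(base$probe_id[grp == "added"], replicate_ids),
        n_shared = n_shared, n_removed = n_removed,
        n_added = n_added + n_position_replicates
      )
    )
  })
}

#' Generate a beta matrix with planted hierarchical group structure
#'
#' Per-probe baseline methylation is drawn from a bimodal Beta mixture
#' (modes near 0.1 and 0.9, the canonical bimodal shape of array beta
#' densities). A fraction of probes is informative: two thirds carry a
#' top-level group effect (e.g. haematological vs solid) and one third a
#' nested effect (e.g. normal vs tumour within each top group), both of size
#' `effect_size` on the logit scale, so the planted structure is a 2x2
#' nested hierarchy. Sample noise is i.i.d. Gaussian on the logit scale
#' (standard deviation `noise_sd`), keeping betas inside \[0, 1\] without
#' truncation artefacts. Replicate samples share their source sample's
#' signal and differ only by independent noise. Detection p-values exceed
#' 0.01 at rate `detp_fail_rate`.
#'
#' Group labels of the form `top_sub` (e.g. `haem_tumour`) define the
#' hierarchy: the part before the first underscore is the top-level group.
#'
#' The standard-normal noise draws do not depend on `noise_sd`, so runs with
#' the same seed and different `noise_sd` share their noise directions —
#' concordance is then exactly monotone in the noise level.
#'
#' @param manifest Probe tibble supplying probe IDs.
#' @param groups Tibble with `label`, `n` (samples per group). Default: the
#'   2x2 haematological/solid x normal/tumour design with 5 samples each.
#' @param effect_size Group shift on the logit scale (default 3).
#' @param frac_informative Fraction of probes carrying any group effect
#'   (default 0.1).
#' @param noise_sd Per-sample logit-scale noise standard deviation.
#' @param n_replicate_pairs Number of samples duplicated as technical
#'   replicates (columns named `<sample>_rep`).
#' @param detp_fail_rate Rate of detection-p failures (entries > 0.01).
#' @param seed Integer RNG seed.
#' @return List with `bm` (a [beta_matrix()]) and `truth` (planted group
#'   assignments, informative probe IDs, replicate pairings, noise level).
#' @export
make_beta_matrix <- function(manifest,
                             groups = tibble(
                               label = c("haem_normal", "haem_tumour",
                                         "solid_normal", "solid_tumour"),
                               n = c(5L, 5L, 5L, 5L)),
                             effect_size = 3, frac_informative = 0.1,
                             noise_sd = 0.05, n_replicate_pairs = 0,
                             detp_fail_rate = 0, seed = 1L) {
  probe_ids <- manifest$probe_id
  p <- length(probe_ids)
  groups <- as_tibble(groups)
  if (nrow(groups) < 2) abort("need at least 2 groups")
  withr::with_seed(seed, {
    sample_group <- rep(groups$label, groups$n)
    ns <- length(sample_group)
    sample_ids <- sprintf("S%02d_%s", seq_len(ns), sample_group)
    top <- sub("_.*$", "", sample_group)
    sub_grp <- sub("^[^_]*_?", "", sample_group)
    # bimodal baseline: Beta(2,18) and Beta(18,2) mixture, modes ~0.1 / ~0.9
    lowmode <- runif(p) < 0.5
    baseline <- ifelse(lowmode, stats::rbeta(p, 2, 18), stats::rbeta(p, 18, 2))
    mu0 <- qlogis(pmin(pmax(baseline, 1e-3), 1 - 1e-3))
    n_inf <- floor(frac_informative * p)
    inf_idx <- sample.int(p, n_inf)
    n_top <- ceiling(2 * n_inf / 3)
    top_idx <- inf_idx[seq_len(n_top)]
    sub_idx <- setdiff(inf_idx, top_idx)
    top_levels <- unique(top)
    sub_levels <- unique(sub_grp)
    top_sign <- if_else(top == top_levels[1], 0.5, -0.5)
    sub_sign <- if_else(sub_grp == sub_levels[1], 0.5, -0.5)
    signal <- matrix(mu0, p, ns)
    signal[top_idx, ] <- signal[top_idx, ] +
      outer(rep(effect_size, length(top_idx)), top_sign)
    if (length(sub_idx) > 0)
      signal[sub_idx, ] <- signal[sub_idx, ] +
        outer(rep(effect_size, length(sub_idx)), sub_sign)
    eps <- matrix(rnorm(p * ns), p, ns)
    beta <- plogis(signal + noise_sd * eps)
    colnames(beta) <- sample_ids
    rownames(beta) <- probe_ids
    meta <- tibble(sample_id = sample_ids, group = sample_group,
                   top_group = top, sub_group = sub_grp,
                   replicate_of = NA_character_)
    rep_pairs <- tibble(sample_id = character(), replicate_id = character())
    if (n_replicate_pairs > 0) {
      src <- seq_len(min(n_replicate_pairs, ns))
      eps_rep <- matrix(rnorm(p * length(src)), p, length(src))
      beta_rep <- plogis(signal[, src, drop = FALSE] + noise_sd * eps_rep)
      rep_ids <- paste0(sample_ids[src], "_rep")
      colnames(beta_rep) <- rep_ids
      beta <- cbind(beta, beta_rep)
      meta <- bind_rows(meta, tibble(
        sample_id = rep_ids, group = sample_group[src],
        top_group = top[src], sub_group = sub_grp[src],
        replicate_of = sample_ids[src]))
      rep_pairs <- tibble(sample_id = sample_ids[src], replicate_id = rep_ids)
    }
    detp <- matrix(runif(length(beta), 0, 0.005), nrow(beta), ncol(beta),
                   dimnames = dimnames(beta))
    if (detp_fail_rate > 0) {
      fail <- matrix(runif(length(detp)) < detp_fail_rate,
                     nrow(detp), ncol(detp))
      detp[fail] <- runif(sum(fail), 0.02, 0.5)
    }
    list(
      bm = beta_matrix(beta, detp = detp, sample_meta = meta),
      truth = list(
        groups = meta,
        informative_top = probe_ids[top_idx],
        informative_sub = probe_ids[sub_idx],
        effect_size = effect_size,
        noise_sd = noise_sd,
        replicate_pairs = rep_pairs,
        detp_fail_rate = detp_fail_rate
      )
    )
  })
}

#' Write a machine-readable ground-truth record
#'
#' @param truth Truth list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
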
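#' Build a validated pipeline configuration
#'
#' Collects input paths and per-stage parameters for [run_pipeline()].
#' Parameter defaults equal the study's stated analysis settings: detection-p
#' threshold 0.01, CpG fractions 1% and 100%, 100 bootstrap replications,
#' FDR threshold 0.05, literal UTR definitions, suffix-aware manifest
#' matching.
#'
#' @param manifest_old,manifest_new Manifest paths (internal dialect) or
#'   in-memory probe tibbles.
#' @param gtf_old,gtf_new GTF paths or transcript tibbles (each manifest is
#'   annotated against its own gene models).
#' @param islands,states,ctcf BED paths or region-track tibbles (optional).
#' @param beta,detp,sample_meta Beta-matrix TSV paths or a [beta_matrix()]
#'   passed as `beta` (optional; enables the concordance and clustering
#'   stages).
#' @param gmt GMT path or [gene_set_collection()] (optional; enables the
#'   enrichment stage; the study list is the gene set of newly covered
#'   transcripts).
#' @param out_dir Report directory.
#' @param detp_threshold,detp_rule,fractions,bootstrap_B,alpha,utr_mode,match_on
#'   Stage parameters (see the stage functions).
#' @param seed Integer seed for every stochastic stage (mandatory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest_old, manifest_new,
                            gtf_old = NULL, gtf_new = NULL,
                            islands = NULL, states = NULL, ctcf = NULL,
                            beta = NULL, detp = NULL, sample_meta = NULL,
                            gmt = NULL, out_dir = "epicval_report",
                            detp_threshold = 0.01, detp_rule = "any",
                            fractions = c(0.01, 1), bootstrap_B = 100,
                            alpha = 0.05, utr_mode = "literal",
                            match_on = "probe_id_base", seed = NULL) {
  if (is.null(seed)) abort("config validation: a seed is mandatory")
  cfg <- list(manifest_old = manifest_old, manifest_new = manifest_new,
              gtf_old = gtf_old, gtf_new = gtf_new, islands = islands,
              states = states, ctcf = ctcf, beta = beta, detp = detp,
              sample_meta = sample_meta, gmt = gmt, out_dir = out_dir,
              detp_threshold = detp_threshold, detp_rule = detp_rule,
              fractions = fractions, bootstrap_B = bootstrap_B,
              alpha = alpha, utr_mode = utr_mode, match_on = match_on,
              seed = as.integer(seed))
  paths <- c("manifest_old", "manifest_new", "gtf_old", "gtf_new", "islands",
             "states", "ctcf", "beta", "detp", "sample_meta", "gmt")
  for (p in paths) {
    v <- cfg[[p]]
    if (is.character(v) && length(v) == 1 && !file.exists(v))
      abort(sprintf("config validation: %s file not found: %s", p, v))
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' Only path-valued (character) inputs round-trip; in-memory objects cannot
#' be serialized to a config file.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` / the re-read `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  if (any(!vapply(ser, function(v)
    is.null(v) || is.character(v) || is.numeric(v), logical(1))))
    abort("only path-based configs can be serialized")
  jsonlite::write_json(ser[!vapply(ser, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

load_or_pass <- function(x, loader) {
  if (is.null(x) || !is.character(x)) x else loader(x)
}

#' Run the full validation pipeline
#'
#' Chains annotation of both manifests, manifest diffing and accounting,
#' QC + replicate concordance, bootstrap Ward clustering at each configured
#' CpG fraction, and gene-set over-representation of the newly covered
#' transcripts, writing every table as TSV plus a machine-readable
#' `summary.json` (versions, seed, parameters, headline numbers) under the
#' report directory. Deterministic for a fixed seed. A stage failure aborts
#' with the stage name; partial outputs stay on disk next to a `FAILED`
#' marker.
#'
#' @param config A [pipeline_config()].
#' @return The report directory path, invisibly; the parsed summary is
#'   attached as attribute `"summary"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  summary <- list(package_version = as.character(utils::packageVersion("epicval")),
                  seed = config$seed,
                  parameters = config[c("detp_threshold", "detp_rule",
                                        "fractions", "bootstrap_B", "alpha",
                                        "utr_mode", "match_on")])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  old <- load_or_pass(config$manifest_old, read_manifest)
  new <- load_or_pass(config$manifest_new, read_manifest)
  tx_old <- load_or_pass(config$gtf_old, read_gene_models)
  tx_new <- load_or_pass(config$gtf_new, read_gene_models)
  islands <- load_or_pass(config$islands,
                          function(p) read_region_track(p, "islands"))
  states <- load_or_pass(config$states,
                         function(p) read_region_track(p, "chromatin_states"))
  ctcf <- load_or_pass(config$ctcf, function(p) read_region_track(p, "ctcf"))

  ann_old <- NULL; ann_new <- NULL
  stage("annotate", {
    ann_old <- build_annotated_manifest(old, tx_old, islands, states, ctcf,
                                        utr_mode = config$utr_mode)
    ann_new <- build_annotated_manifest(new, tx_new, islands, states, ctcf,
                                        utr_mode = config$utr_mode)
    write_annotated_manifest(ann_new, file.path(out, "annotated_new.tsv"))
    cats <- summarize_categories(ann_new)
    readr::write_tsv(cats, file.path(out, "categories_new.tsv"),
                     progress = FALSE)
    shares <- promoter_body_shares(ann_new)
    summary$annotation <- list(
      categories = nrow(cats),
      pct_promoter_proximal =
        shares$pct[shares$group == "promoter_proximal"] %||% 0,
      pct_intergenic = shares$pct[shares$group == "intergenic"] %||% 0
    )
  })

  stage("diff", {
    d <- diff_manifests(old, new, match_on = config$match_on)
    readr::write_tsv(d$counts, file.path(out, "diff_counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(probe_class_accounting(d, old, new),
                     file.path(out, "class_accounting.tsv"), progress = FALSE)
    readr::write_tsv(per_chromosome_counts(new),
                     file.path(out, "per_chromosome_new.tsv"),
                     progress = FALSE)
    readr::write_tsv(design_type_counts(new),
                     file.path(out, "design_new.tsv"), progress = FALSE)
    writeLines(d$shared_ids, file.path(out, "shared_probes.txt"))
    writeLines(d$removed_ids, file.path(out, "removed_probes.txt"))
    writeLines(d$added_ids, file.path(out, "added_probes.txt"))
    newtx <- transcript_coverage_diff(ann_old, ann_new)
    readr::write_tsv(newtx, file.path(out, "new_transcripts.tsv"),
                     progress = FALSE)
    rc <- d$counts[d$counts$level == "row", ]
    summary$diff <- list(n_shared = rc$n_shared, n_removed = rc$n_removed,
                          n_added = rc$n_added,
                          n_new_transcripts = nrow(newtx))
  })

  bm <- if (inherits(config$beta, "beta_matrix")) config$beta
        else if (is.character(config$beta))
          read_beta_matrix(config$beta, config$detp, config$sample_meta)
        else NULL

  if (!is.null(bm)) {
    stage("concord", {
      qc <- qc_filter(bm, new, detp_threshold = config$detp_threshold,
                      detp_rule = config$detp_rule)
      readr::write_tsv(qc$report, file.path(out, "qc_report.tsv"),
                       progress = FALSE)
      meta <- qc$bm$sample_meta
      pairs <- if ("replicate_of" %in% names(meta)) {
        meta %>% filter(!is.na(.data$replicate_of)) %>%
          select(sample_a = "replicate_of", sample_b = "sample_id")
      } else tibble(sample_a = character(), sample_b = character())
      conc <- if (nrow(pairs) > 0) pairwise_concordance(qc$bm, pairs)
              else NULL
      if (!is.null(conc)) {
        readr::write_tsv(conc, file.path(out, "concordance.tsv"),
                         progress = FALSE)
        summary$concordance <- list(n_pairs = nrow(conc),
                                     min_rho = min(conc$rho),
                                     max_rho = max(conc$rho))
      }
      summary$qc <- as.list(qc$report)
      bm_qc <- qc$bm
    })

    stage("cluster", {
      cluster_summ <- list()
      for (i in seq_along(config$fractions)) {
        f <- config$fractions[[i]]
        sub <- select_random_cpgs(bm_qc, f, seed = config$seed + i)
        dend <- bootstrap_support(sub, B = config$bootstrap_B,
                                  seed = config$seed + 100 + i)
        tag <- sprintf("fraction_%g", f)
        readr::write_tsv(tidy(dend),
                         file.path(out, paste0("dendrogram_", tag, ".tsv")),
                         progress = FALSE)
        write_dendrogram_newick(dend,
                                file.path(out, paste0("dendrogram_", tag,
                                                      ".nwk")))
        meta <- bm_qc$sample_meta
        top_sup <- if ("top_group" %in% names(meta)) {
          tg <- unique(meta$top_group)
          setNames(map_dbl(tg, function(g)
            cluster_support(dend, meta$sample_id[meta$top_group == g])), tg)
        } else NULL
        cluster_summ[[tag]] <- list(n_probes = nrow(sub$beta),
                                    top_split_support = as.list(top_sup))
      }
      pc <- pca_beta(bm_qc)
      readr::write_tsv(pc$scores, file.path(out, "pca_scores.tsv"),
                       progress = FALSE)
      cluster_summ$pca_pc1_var <- pc$var_explained[1]
      summary$cluster <- cluster_summ
    })
  }

  gs <- if (inherits(config$gmt, "gene_set_collection")) config$gmt
        else if (is.character(config$gmt)) read_gmt(config$gmt) else NULL
  if (!is.null(gs)) {
    stage("ora", {
      newtx <- transcript_coverage_diff(ann_old, ann_new)
      study <- unique(tx_new$gene_id[tx_new$transcript_id %in%
                                       newtx$transcript_id])
      study <- intersect(study, gs$population)
      if (length(study) > 0) {
        res <- fisher_ora(study, gs)
        readr::write_tsv(res, file.path(out, "ora_results.tsv"),
                         progress = FALSE)
        sig <- significant_sets(res, alpha = config$alpha)
        readr::write_tsv(sig, file.path(out, "ora_significant.tsv"),
                         progress = FALSE)
        summary$ora <- list(n_sets = nrow(res), n_significant = nrow(sig))
      }
    })
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- invisible(out)
  attr(res, "summary") <- summary
  res
}
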
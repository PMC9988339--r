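drop_na_probes <- function(bm) {
  keep <- rowSums(is.na(bm$beta)) == 0
  if (!all(keep))
    inform(sprintf("dropping %d probe(s) with missing values", sum(!keep)))
  beta_matrix(bm$beta[keep, , drop = FALSE],
              detp = if (!is.null(bm$detp)) bm$detp[keep, , drop = FALSE],
              sample_meta = bm$sample_meta)
}

#' Subsample a random fraction of CpG probes
#'
#' Samples `floor(fraction * n_probes)` probes without replacement,
#' reproducibly for a fixed seed; `fraction = 1` returns the input probe set
#' unchanged. This mirrors clustering runs on 1% vs 100% of the CpGs.
#'
#' @param bm A [beta_matrix()].
#' @param fraction Fraction of probes in (0, 1].
#' @param seed Integer RNG seed.
#' @return A [beta_matrix()] restricted to the sampled probes.
#' @export
select_random_cpgs <- function(bm, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(bm$beta)
  if (fraction == 1) return(bm)
  k <- floor(fraction * n)
  if (k < 1) abort("fraction selects zero probes")
  idx <- sort(withr::with_seed(seed, sample.int(n, k)))
  beta_matrix(bm$beta[idx, , drop = FALSE],
              detp = if (!is.null(bm$detp)) bm$detp[idx, , drop = FALSE],
              sample_meta = bm$sample_meta)
}

#' Principal component analysis of a beta matrix
#'
#' Samples are observations and probes variables; values are mean-centred
#' but not scaled to unit variance (the analysis runs on beta values as
#' they are). Probes with any missing value are dropped first. Setting
#' `m_values = TRUE` transforms to M-values `log2(beta / (1 - beta))`
#' (betas clamped to `[eps, 1 - eps]`) before the decomposition.
#'
#' @param bm A [beta_matrix()].
#' @param n_components Number of components to return (default all).
#' @param m_values Analyse M-values instead of betas (default `FALSE`).
#' @param eps Clamp for the M-value transform.
#' @return An object of class `epic_pca`: list with `scores` (tibble,
#'   sample metadata + PC columns), `loadings`, `var_explained` (fractions
#'   summing to 1 over all components), `degenerate` (TRUE when total
#'   variance is numerically zero, e.g. identical samples) and
#'   `n_probes_used`.
#' @export
pca_beta <- function(bm, n_components = NULL, m_values = FALSE, eps = 1e-6) {
  bm <- drop_na_probes(bm)
  x <- t(bm$beta)
  if (nrow(x) < 2) abort("PCA needs at least 2 samples")
  if (m_values) {
    x <- pmin(pmax(x, eps), 1 - eps)
    x <- log2(x / (1 - x))
  }
  total_var <- sum(apply(x, 2, var))
  degenerate <- !is.finite(total_var) || total_var < 1e-12
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- if (degenerate) rep(NA_real_, length(fit$sdev))
        else fit$sdev^2 / sum(fit$sdev^2)
  k <- n_components %||% ncol(fit$x)
  k <- min(k, ncol(fit$x))
  scores <- bind_cols(bm$sample_meta,
                      as_tibble(fit$x[, seq_len(k), drop = FALSE]))
  structure(list(scores = scores,
                 loadings = fit$rotation[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)],
                 var_explained_all = ve,
                 degenerate = degenerate,
                 n_probes_used = nrow(bm$beta)),
            class = "epic_pca")
}

#' @export
print.epic_pca <- function(x, ...) {
  cat(sprintf("<epic_pca> %d samples, %d probes%s\n", nrow(x$scores),
              x$n_probes_used, if (x$degenerate) " [degenerate]" else ""))
  if (!x$degenerate)
    cat(sprintf("PC1 %.1f%%, PC2 %.1f%%\n", 100 * x$var_explained[1],
                100 * x$var_explained[min(2, length(x$var_explained))]))
  invisible(x)
}

#' @export
tidy.epic_pca <- function(x, ...) x$scores

#' @export
glance.epic_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_probes = x$n_probes_used,
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) >= 2) x$var_explained[2]
                   else NA_real_,
         degenerate = x$degenerate)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the samples of a beta matrix using Euclidean
#' distances and the Ward.D linkage (Lance–Williams update applied to the
#' unsquared input distances — the classic `"ward.D"` variant, which differs
#' in heights from `"ward.D2"`). Probes with missing values are dropped
#' before computing distances. Ties are resolved deterministically
#' (lowest pair index at equal distance).
#'
#' @param bm A [beta_matrix()].
#' @return An object of class `epic_dendrogram`: list with `hc` (the
#'   `hclust` object), `leaves` (sample IDs), `merges` (tibble `left`,
#'   `right`, `height`; negative entries index leaves, positive entries
#'   earlier merges, as in `hclust`), and `support` (`NULL` until
#'   [bootstrap_support()] fills it).
#' @export
hclust_ward <- function(bm) {
  bm <- drop_na_probes(bm)
  if (ncol(bm$beta) < 2) abort("clustering needs at least 2 samples")
  d <- dist(t(bm$beta), method = "euclidean")
  hc <- hclust(d, method = "ward.D")
  new_epic_dendrogram(hc, support = NULL)
}

new_epic_dendrogram <- function(hc, support = NULL) {
  structure(list(
    hc = hc,
    leaves = hc$labels,
    merges = tibble(left = hc$merge[, 1], right = hc$merge[, 2],
                    height = hc$height),
    support = support
  ), class = "epic_dendrogram")
}

#' @export
print.epic_dendrogram <- function(x, ...) {
  cat(sprintf("<epic_dendrogram> %d leaves, %d merges%s\n",
              length(x$leaves), nrow(x$merges),
              if (is.null(x$support)) "" else " (+ bootstrap support)"))
  invisible(x)
}

#' @export
tidy.epic_dendrogram <- function(x, ...) {
  out <- x$merges %>% mutate(node = row_number(), .before = 1)
  out$leaf_set <- map_chr(dendrogram_leaf_sets(x), paste, collapse = ",")
  if (!is.null(x$support)) out$support <- x$support
  out
}

#' @export
as.hclust.epic_dendrogram <- function(x, ...) x$hc

#' Leaf sets of every internal node of a dendrogram
#'
#' @param dend An `epic_dendrogram`.
#' @return List of length `n - 1`; element `i` is the sorted character
#'   vector of leaf labels under merge `i`.
#' @export
dendrogram_leaf_sets <- function(dend) {
  hc <- dend$hc
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    grab <- function(v) if (v < 0) hc$labels[-v] else sets[[v]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  sets
}

#' Bootstrap support for dendrogram clusters
#'
#' Resamples probes (features) with replacement `B` times, re-clusters the
#' samples for each resample, and scores each internal node of the full-data
#' tree by the fraction of bootstrap trees containing an internal node with
#' the identical leaf set (plain bootstrap proportion, BP). The root always
#' has support 1.
#'
#' @param bm A [beta_matrix()] (at least 3 samples).
#' @param B Number of bootstrap replications (default 100).
#' @param seed Integer RNG seed.
#' @return An `epic_dendrogram` with its `support` field filled (numeric,
#'   one value per merge).
#' @export
bootstrap_support <- function(bm, B = 100, seed = 1L) {
  if (B < 1) abort("B must be >= 1")
  bm <- drop_na_probes(bm)
  if (ncol(bm$beta) < 3) abort("bootstrap support needs at least 3 samples")
  dend <- hclust_ward(bm)
  target <- map_chr(dendrogram_leaf_sets(dend), paste, collapse = "\r")
  nprobe <- nrow(bm$beta)
  counts <- numeric(length(target))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nprobe, nprobe, replace = TRUE)
      hc_b <- hclust(dist(t(bm$beta[idx, , drop = FALSE])), method = "ward.D")
      sets_b <- map_chr(dendrogram_leaf_sets(new_epic_dendrogram(hc_b)),
                        paste, collapse = "\r")
      counts <- counts + (target %in% sets_b)
    }
  })
  dend$support <- counts / B
  dend
}

#' Bootstrap support of arbitrary sample splits
#'
#' Scores given sample sets (e.g. a planted top-level split) by the fraction
#' of feature-bootstrap trees containing an internal node with exactly that
#' leaf set — the same resampling protocol as [bootstrap_support()], but for
#' leaf sets that need not appear in the full-data tree.
#'
#' @param bm A [beta_matrix()] (at least 3 samples).
#' @param leaf_sets List of character vectors of sample IDs.
#' @param B Number of bootstrap replications.
#' @param seed Integer RNG seed.
#' @return Numeric vector of supports in \[0, 1\], one per leaf set.
#' @export
bootstrap_leafset_support <- function(bm, leaf_sets, B = 100, seed = 1L) {
  if (B < 1) abort("B must be >= 1")
  bm <- drop_na_probes(bm)
  if (ncol(bm$beta) < 3) abort("bootstrap support needs at least 3 samples")
  target <- map_chr(leaf_sets, function(s) paste(sort(s), collapse = "\r"))
  nprobe <- nrow(bm$beta)
  counts <- numeric(length(target))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nprobe, nprobe, replace = TRUE)
      hc_b <- hclust(dist(t(bm$beta[idx, , drop = FALSE])), method = "ward.D")
      sets_b <- map_chr(dendrogram_leaf_sets(new_epic_dendrogram(hc_b)),
                        paste, collapse = "\r")
      counts <- counts + (target %in% sets_b)
    }
  })
  counts / B
}

#' Support of the cluster matching a given sample set
#'
#' Looks up the bootstrap support of the internal node whose leaf set equals
#' `samples`, e.g. a planted top-level split.
#'
#' @param dend An `epic_dendrogram` with support values.
#' @param samples Character vector of sample IDs.
#' @return The support value, or `NA` if no node has that exact leaf set.
#' @export
cluster_support <- function(dend, samples) {
  if (is.null(dend$support)) abort("dendrogram carries no support values")
  key <- paste(sort(samples), collapse = "\r")
  sets <- map_chr(dendrogram_leaf_sets(dend), paste, collapse = "\r")
  i <- match(key, sets)
  if (is.na(i)) NA_real_ else dend$support[[i]]
}

#' Cut a dendrogram into k clusters
#'
#' @param dend An `epic_dendrogram`.
#' @param k Number of clusters.
#' @return Tibble with `sample_id`, `cluster`.
#' @export
cut_dendrogram <- function(dend, k) {
  cl <- stats::cutree(dend$hc, k = k)
  tibble(sample_id = names(cl), cluster = unname(cl))
}

#' Compare two dendrograms over the same samples
#'
#' Internal nodes are matched by leaf-set equality. `common_fraction` is the
#' number of leaf sets present in both trees divided by `n - 1` (the number
#' of internal nodes of a binary tree over n leaves); `distinct_edges_a/_b`
#' count the internal nodes of each tree with no leaf-set match in the
#' other.
#'
#' @param a,b `epic_dendrogram` objects over identical leaf sets.
#' @return A one-row tibble of class `dendro_comparison` with `n_leaves`,
#'   `n_common`, `distinct_edges_a`, `distinct_edges_b`, `common_fraction`,
#'   plus a `common_subtrees` list-column holding the shared leaf sets.
#' @export
compare_dendrograms <- function(a, b) {
  la <- sort(a$leaves); lb <- sort(b$leaves)
  if (!identical(la, lb)) {
    only_a <- setdiff(la, lb); only_b <- setdiff(lb, la)
    abort(sprintf(
      "dendrograms have different leaf sets (only in a: %s; only in b: %s)",
      paste(only_a, collapse = ","), paste(only_b, collapse = ",")))
  }
  sets_a <- map_chr(dendrogram_leaf_sets(a), paste, collapse = "\r")
  sets_b <- map_chr(dendrogram_leaf_sets(b), paste, collapse = "\r")
  common <- intersect(sets_a, sets_b)
  n <- length(a$leaves)
  out <- tibble(
    n_leaves = n,
    n_common = length(common),
    distinct_edges_a = sum(!(sets_a %in% sets_b)),
    distinct_edges_b = sum(!(sets_b %in% sets_a)),
    common_fraction = length(common) / (n - 1),
    common_subtrees = list(map(strsplit(common, "\r"), identity))
  )
  class(out) <- c("dendro_comparison", class(out))
  out
}

#' Serialize a dendrogram to newick
#'
#' Bootstrap supports, when present, are written as internal node labels.
#'
#' @param dend An `epic_dendrogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  phy <- ape::as.phylo(dend$hc)
  if (!is.null(dend$support)) {
    # ape numbers internal nodes in its own order; map via clade leaf sets
    sets <- map_chr(dendrogram_leaf_sets(dend), paste, collapse = "\r")
    lab <- character(phy$Nnode)
    for (node in seq_len(phy$Nnode) + length(phy$tip.label)) {
      tips <- sort(ape::extract.clade(phy, node)$tip.label)
      i <- match(paste(tips, collapse = "\r"), sets)
      lab[node - length(phy$tip.label)] <-
        if (is.na(i)) "" else formatC(dend$support[[i]], format = "g")
    }
    phy$node.label <- lab
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a newick dendrogram
#'
#' @param path Newick file path.
#' @return An `epic_dendrogram` (support from node labels when present).
#' @export
read_dendrogram_newick <- function(path) {
  phy <- ape::read.tree(path)
  hc <- ape::as.hclust.phylo(phy)
  dend <- new_epic_dendrogram(hc)
  if (!is.null(phy$node.label) && any(nzchar(phy$node.label))) {
    sets <- map_chr(dendrogram_leaf_sets(dend), paste, collapse = "\r")
    sup <- rep(NA_real_, length(sets))
    for (node in seq_len(phy$Nnode) + length(phy$tip.label)) {
      tips <- sort(ape::extract.clade(phy, node)$tip.label)
      i <- match(paste(tips, collapse = "\r"), sets)
      v <- phy$node.label[node - length(phy$tip.label)]
      if (!is.na(i) && nzchar(v)) sup[i] <- as.numeric(v)
    }
    dend$support <- sup
  }
  dend
}
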
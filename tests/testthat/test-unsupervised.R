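small_bm <- function(n_probes = 60, groups = NULL, noise = 0.3, seed = 1) {
  m <- tiny_manifest(sprintf("cg%05d", seq_len(n_probes)))
  if (is.null(groups))
    groups <- tibble::tibble(label = c("haem_normal", "haem_tumour",
                                       "solid_normal", "solid_tumour"),
                             n = c(3L, 3L, 3L, 3L))
  make_beta_matrix(m, groups = groups, noise_sd = noise, seed = seed)$bm
}

test_that("random CpG selection is reproducible and size-exact", {
  bm <- small_bm(n_probes = 10)
  expect_identical(rownames(select_random_cpgs(bm, 1)$beta),
                   rownames(bm$beta))
  s1 <- select_random_cpgs(bm, 0.5, seed = 1)
  s2 <- select_random_cpgs(bm, 0.5, seed = 2)
  s1b <- select_random_cpgs(bm, 0.5, seed = 1)
  expect_equal(nrow(s1$beta), 5)
  expect_equal(nrow(s2$beta), 5)
  expect_identical(rownames(s1$beta), rownames(s1b$beta))
  expect_error(select_random_cpgs(bm, 0.01), "zero probes")
})

test_that("PCA matches an independent eigendecomposition up to sign", {
  withr::with_seed(10, beta <- matrix(runif(20), 5, 4))
  dimnames(beta) <- list(sprintf("cg%02d", 1:5), sprintf("s%d", 1:4))
  bm <- beta_matrix(beta)
  fit <- pca_beta(bm)
  x <- scale(t(beta), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(x) / (nrow(x) - 1))
  scores_oracle <- x %*% eig$vectors
  for (j in 1:3) {
    got <- fit$scores[[paste0("PC", j)]]
    expect_true(max(abs(got - scores_oracle[, j])) < 1e-8 ||
                  max(abs(got + scores_oracle[, j])) < 1e-8)
  }
  ve_oracle <- eig$values / sum(eig$values)
  expect_equal(fit$var_explained[1:3], ve_oracle[1:3], tolerance = 1e-8)
  expect_equal(sum(fit$var_explained_all), 1, tolerance = 1e-8)

  # collinear samples: PC1 explains everything
  beta2 <- outer(seq(0.1, 0.5, length.out = 5), c(1, 2, 0.4, 1.4))
  beta2 <- beta2 / max(beta2)
  dimnames(beta2) <- dimnames(beta)
  expect_equal(pca_beta(beta_matrix(beta2))$var_explained[1], 1,
               tolerance = 1e-8)

  # identical samples: degenerate, flagged
  beta3 <- matrix(0.5, 5, 4, dimnames = dimnames(beta))
  expect_true(pca_beta(beta_matrix(beta3))$degenerate)
  expect_error(pca_beta(beta_matrix(beta[, 1, drop = FALSE])), "2 samples")
})

test_that("two samples merge at their Ward height and tight pairs pair first", {
  beta <- matrix(c(0.1, 0.2, 0.5, 0.8), 2, 2,
                 dimnames = list(c("cg1", "cg2"), c("a", "b")))
  dend <- hclust_ward(beta_matrix(beta))
  expect_equal(nrow(dend$merges), 1)
  expect_equal(dend$merges$height, sqrt(0.4^2 + 0.6^2))

  beta4 <- cbind(a1 = c(0.10, 0.10), a2 = c(0.11, 0.10),
                 b1 = c(0.90, 0.95), b2 = c(0.91, 0.95))
  rownames(beta4) <- c("cg1", "cg2")
  d4 <- hclust_ward(beta_matrix(beta4))
  sets <- dendrogram_leaf_sets(d4)
  expect_true(any(vapply(sets, identical, logical(1), y = c("a1", "a2"))))
  expect_true(any(vapply(sets, identical, logical(1), y = c("b1", "b2"))))
})

test_that("Ward.D agglomeration equals the Lance-Williams recurrence oracle", {
  withr::with_seed(23, beta <- matrix(runif(60), 10, 6))
  dimnames(beta) <- list(sprintf("cg%02d", 1:10), sprintf("s%d", 1:6))
  bm <- beta_matrix(beta)
  dend <- hclust_ward(bm)
  oracle <- oracle_ward_d(dist(t(beta)))
  expect_equal(dend$merges$height, oracle$heights, tolerance = 1e-10)
  sets <- dendrogram_leaf_sets(dend)
  for (i in seq_along(sets)) expect_identical(sets[[i]], oracle$sets[[i]])
})

test_that("dendrogram structural invariants hold on generated data", {
  for (seed in 1:5) {
    bm <- small_bm(seed = seed)
    dend <- hclust_ward(bm)
    n <- length(dend$leaves)
    expect_equal(nrow(dend$merges), n - 1)
    expect_true(all(diff(dend$merges$height) >= -1e-12))
    sets <- dendrogram_leaf_sets(dend)
    expect_setequal(sets[[n - 1]], dend$leaves)   # root closure
    # each internal node is the disjoint union of its children
    for (i in seq_len(n - 1)) {
      kids <- unlist(lapply(dend$merges[i, c("left", "right")], function(v)
        if (v < 0) dend$leaves[-v] else sets[[v]]))
      expect_setequal(sets[[i]], kids)
      expect_equal(anyDuplicated(kids), 0)
    }
  }
})

test_that("bootstrap supports are proportions with a fully supported root", {
  bm <- small_bm(n_probes = 100, noise = 0.4, seed = 3)
  dend <- bootstrap_support(bm, B = 25, seed = 5)
  expect_true(all(dend$support >= 0 & dend$support <= 1))
  expect_equal(dend$support[[length(dend$support)]], 1)  # root
  # B = 1: supports are 0 or 1
  d1 <- bootstrap_support(bm, B = 1, seed = 5)
  expect_true(all(d1$support %in% c(0, 1)))
  expect_error(bootstrap_support(bm, B = 0), "B must be")
  # reproducible for a fixed seed
  d2 <- bootstrap_support(bm, B = 25, seed = 5)
  expect_identical(dend$support, d2$support)
})

test_that("well-separated planted clusters earn high support; duplication changes little", {
  bm <- small_bm(n_probes = 400, noise = 0.2, seed = 8)
  dend <- bootstrap_support(bm, B = 50, seed = 9)
  meta <- bm$sample_meta
  sup_haem <- cluster_support(dend, meta$sample_id[meta$top_group == "haem"])
  sup_solid <- cluster_support(dend, meta$sample_id[meta$top_group == "solid"])
  expect_gte(sup_haem, 0.9)
  expect_gte(sup_solid, 0.9)

  # direct leaf-set support agrees with the base-tree lookup under the
  # same resampling protocol
  direct <- bootstrap_leafset_support(
    bm, list(meta$sample_id[meta$top_group == "haem"],
             meta$sample_id[meta$top_group == "solid"]),
    B = 50, seed = 9)
  expect_equal(direct, c(sup_haem, sup_solid))

  # duplicated probes: supports statistically indistinguishable
  bdup <- bm$beta[rep(seq_len(nrow(bm$beta)), 2), ]
  rownames(bdup) <- sprintf("cg%05d", seq_len(nrow(bdup)))
  dup <- beta_matrix(bdup, sample_meta = bm$sample_meta)
  dend_dup <- bootstrap_support(dup, B = 50, seed = 9)
  expect_lte(abs(cluster_support(dend_dup,
                                 meta$sample_id[meta$top_group == "haem"]) -
                   sup_haem), 0.1)
})

test_that("dendrogram comparison counts shared leaf sets", {
  bm <- small_bm(seed = 2)
  a <- hclust_ward(bm)
  self <- compare_dendrograms(a, a)
  expect_equal(self$common_fraction, 1)
  expect_equal(self$distinct_edges_a, 0)

  # 4-leaf swap case, hand-enumerated: ((A,B),(C,D)) vs ((A,C),(B,D))
  t1 <- dend_from_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- dend_from_newick("((A:1,C:1):1,(B:1,D:1):1);")
  cmp <- compare_dendrograms(t1, t2)
  # brute force: sets of t1 = {AB},{CD},{ABCD}; t2 = {AC},{BD},{ABCD}
  expect_equal(cmp$n_common, 1)
  expect_equal(cmp$common_fraction, 1 / 3)
  expect_equal(cmp$distinct_edges_a, 2)
  expect_equal(cmp$distinct_edges_b, 2)

  # caterpillar vs its mirror: only the root leaf set is shared
  c1 <- dend_from_newick("(((A:1,B:1):1,C:2):1,D:3);")
  c2 <- dend_from_newick("(((D:1,C:1):1,B:2):1,A:3);")
  cmpc <- compare_dendrograms(c1, c2)
  expect_equal(cmpc$n_common, 1)
  expect_equal(cmpc$common_fraction, 1 / 3)

  t3 <- dend_from_newick("((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(compare_dendrograms(t1, t3), "different leaf sets")
})

test_that("newick serialization round-trips topology and support", {
  bm <- small_bm(n_probes = 150, seed = 12)
  dend <- bootstrap_support(bm, B = 10, seed = 13)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, tf)
  back <- read_dendrogram_newick(tf)
  expect_equal(compare_dendrograms(dend, back)$common_fraction, 1)
  key <- function(d) {
    s <- dendrogram_leaf_sets(d)
    o <- order(vapply(s, paste, character(1), collapse = ","))
    list(sets = s[o], sup = d$support[o])
  }
  expect_equal(key(back)$sup, key(dend)$sup, tolerance = 1e-6)
})

test_that("t-SNE separates planted groups and is seed-deterministic", {
  bm <- small_bm(n_probes = 200,
                 groups = tibble::tibble(label = c("haem_a", "solid_b"),
                                         n = c(6L, 6L)),
                 noise = 0.3, seed = 20)
  emb <- tsne_embed(bm, perplexity = 3, seed = 21, max_iter = 350)
  lab <- as.integer(factor(bm$sample_meta$top_group))
  sil <- cluster::silhouette(lab, dist(cbind(emb$tsne1, emb$tsne2)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  emb2 <- tsne_embed(bm, perplexity = 3, seed = 21, max_iter = 350)
  expect_identical(emb$tsne1, emb2$tsne1)

  small <- beta_matrix(bm$beta[, 1:4],
                       sample_meta = bm$sample_meta[1:4, ])
  expect_error(tsne_embed(small, perplexity = 5), "infeasible")
})

test_that("clustering at 1% and 100% CpG fractions recovers the planted split", {
  m <- tiny_manifest(sprintf("cg%05d", 1:5000))
  bm <- make_beta_matrix(m, noise_sd = 0.3, seed = 30)$bm
  meta <- bm$sample_meta
  for (f in c(0.01, 1)) {
    sub <- select_random_cpgs(bm, f, seed = 31)
    dend <- hclust_ward(sub)
    cl <- cut_dendrogram(dend, 2)
    split_tab <- table(cl$cluster, meta$top_group)
    expect_equal(min(apply(split_tab, 1, max) / rowSums(split_tab)), 1)
  }
})
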
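#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (set ID -> gene IDs), or a
#'   tibble with `set_id`, `gene_id` (optional `name`, `namespace`).
#' @param names Optional named character vector of set display names.
#' @param namespaces Optional named character vector of namespaces (e.g.
#'   `BP`, `MF`, `CC`).
#' @param population Optional explicit background gene universe; when
#'   omitted, the union of all set members is used.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names = NULL, namespaces = NULL,
                                population = NULL) {
  if (is.data.frame(sets)) {
    tab <- sets
    sets <- split(tab$gene_id, tab$set_id)
    if (is.null(names) && "name" %in% colnames(tab))
      names <- vapply(split(tab$name, tab$set_id), dplyr::first, character(1))
    if (is.null(namespaces) && "namespace" %in% colnames(tab))
      namespaces <- vapply(split(tab$namespace, tab$set_id), dplyr::first,
                           character(1))
  }
  sets <- map(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) abort("every gene set must be non-empty")
  if (is.null(population)) {
    population <- sort(unique(unlist(sets)))
  } else {
    population <- unique(as.character(population))
    stray <- setdiff(unlist(sets), population)
    if (length(stray) > 0)
      abort(sprintf("%d set member(s) outside the stated population",
                    length(stray)))
  }
  structure(list(sets = sets,
                 names = names %||% setNames(base::names(sets), base::names(sets)),
                 namespaces = namespaces,
                 population = population),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d genes\n",
              length(x$sets), length(x$population)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, `description`,
#' then gene IDs.
#'
#' @param path GMT file path.
#' @param population Optional explicit background (see
#'   [gene_set_collection()]).
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, population = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) abort("malformed GMT line (need id, name, genes)")
  ids <- map_chr(parts, 1)
  gene_set_collection(
    sets = setNames(map(parts, ~ .x[-(1:2)]), ids),
    names = setNames(map_chr(parts, 2), ids),
    population = population
  )
}

#' One-sided Fisher (hypergeometric upper-tail) enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` study hits in a gene set of size `K` when drawing
#' `n` study genes from a population of `N`.
#'
#' @param k Observed hits (vectorized).
#' @param K Set size in the population.
#' @param n Study size.
#' @param N Population size.
#' @return Numeric vector of p-values.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher over-representation analysis
#'
#' Tests each gene set for over-representation of a study gene list against
#' the collection's background population using the one-sided Fisher exact
#' test, i.e. the hypergeometric upper tail `P(X >= k)` with `k` study hits
#' in a set of size `K`, study size `n` and population size `N`. Study genes
#' outside the population are dropped with a warning. Fold enrichment is the
#' observed/expected ratio `(k/n) / (K/N)`. p-values are BH-adjusted across
#' all tested sets ([bh_fdr()]).
#'
#' @param study Character vector of study gene IDs.
#' @param collection A [gene_set_collection()].
#' @param two_sided Use the two-sided Fisher test instead (default `FALSE`,
#'   enrichment-only, as over-representation analyses report).
#' @return Tibble with one row per set: `set_id`, `name`, `namespace`, `k`,
#'   `K`, `n`, `N`, `fold`, `p`, `q`.
#' @export
fisher_ora <- function(study, collection, two_sided = FALSE) {
  study <- unique(as.character(study))
  pop <- collection$population
  outside <- setdiff(study, pop)
  if (length(outside) > 0) {
    warn(sprintf("%d study gene(s) outside the population dropped",
                 length(outside)))
    study <- intersect(study, pop)
  }
  if (length(study) == 0) abort("study list empty after intersecting with population")
  n <- length(study); N <- length(pop)
  res <- imap(collection$sets, function(genes, id) {
    K <- length(genes)
    k <- length(intersect(study, genes))
    if (two_sided) {
      p <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                              alternative = "two.sided")$p.value
    } else {
      p <- hypergeom_tail(k, K, n, N)
    }
    tibble(set_id = id, k = k, K = K, n = n, N = N,
           fold = (k / n) / (K / N), p = min(p, 1))
  })
  out <- bind_rows(res)
  out$name <- unname(collection$names[out$set_id])
  out$namespace <- if (is.null(collection$namespaces)) NA_character_
                   else unname(collection$namespaces[out$set_id])
  out$q <- bh_fdr(out$p)
  out[, c("set_id", "name", "namespace", "k", "K", "n", "N", "fold", "p", "q")]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; order-preserving (ties
#' in p give ties in q). Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Filter enrichment results at an FDR threshold
#'
#' Strict `q < alpha` cut (a set with q exactly at the threshold is
#' excluded), sorted by q then by decreasing fold enrichment.
#'
#' @param results Tibble from [fisher_ora()].
#' @param alpha FDR threshold (default 0.05).
#' @return The filtered, sorted tibble.
#' @export
significant_sets <- function(results, alpha = 0.05) {
  results %>%
    filter(.data$q < alpha) %>%
    arrange(.data$q, desc(.data$fold))
}
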
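#' QC-filter a beta matrix
#'
#' Removes, in this order, (1) masked probes, (2) genotyping (`rs`) probes,
#' (3) X/Y-chromosome probes, and (4) probes failing the detection-p rule.
#' Each removed probe is counted under the first rule that removed it, so
#' the report categories partition the removals and
#' `n_input = n_retained + sum(removals)` always holds.
#'
#' The detection-p rule is configurable: `"any"` (default, strict — remove a
#' probe if `detp > detp_threshold` in any sample), `"all"` (remove only if
#' it fails in every sample) or `"fraction"` (remove if it fails in more
#' than `detp_fraction` of samples).
#'
#' Probes of `bm` absent from the manifest are retained (unless removed by
#' detection p) and reported via a warning.
#'
#' @param bm A [beta_matrix()].
#' @param manifest Probe tibble covering the probes of `bm` (needs
#'   `probe_id`, `chrom`, `probe_class`, `masked`).
#' @param detp_threshold Detection-p cut-off (default 0.01).
#' @param detp_rule `"any"`, `"all"` or `"fraction"`.
#' @param detp_fraction Failure fraction for `detp_rule = "fraction"`.
#' @return A list with `bm` (filtered [beta_matrix()]) and `report`, a
#'   one-row tibble with `n_input`, `n_removed_masked`,
#'   `n_removed_genotyping`, `n_removed_xy`, `n_removed_detp`,
#'   `n_retained`.
#' @export
qc_filter <- function(bm, manifest, detp_threshold = 0.01,
                      detp_rule = c("any", "all", "fraction"),
                      detp_fraction = 0.5) {
  detp_rule <- match.arg(detp_rule)
  ids <- rownames(bm$beta)
  m <- manifest[match(ids, manifest$probe_id), ]
  uncovered <- is.na(m$probe_id)
  if (any(uncovered))
    warn(sprintf("%d probe(s) in the beta matrix are not in the manifest",
                 sum(uncovered)))
  masked <- !uncovered & m$masked
  genotyping <- !masked & !uncovered & m$probe_class == "rs"
  xy <- !masked & !genotyping & !uncovered & m$chrom %in% c("chrX", "chrY")
  if (is.null(bm$detp)) {
    # no detection-p matrix: skip that filter unless one was explicitly asked
    if (!missing(detp_threshold))
      abort("detection-p filtering requested but no detection-p matrix present")
    detp_fail <- rep(FALSE, length(ids))
  } else {
    fail <- bm$detp > detp_threshold
    fail[is.na(fail)] <- FALSE
    detp_fail <- switch(detp_rule,
      any = rowSums(fail) > 0,
      all = rowSums(fail) == ncol(fail),
      fraction = rowMeans(fail) > detp_fraction
    )
  }
  detp_rm <- !masked & !genotyping & !xy & detp_fail
  removed <- masked | genotyping | xy | detp_rm
  keep <- which(!removed)
  report <- tibble(
    n_input = length(ids),
    n_removed_masked = sum(masked),
    n_removed_genotyping = sum(genotyping),
    n_removed_xy = sum(xy),
    n_removed_detp = sum(detp_rm),
    n_retained = length(keep)
  )
  out <- beta_matrix(bm$beta[keep, , drop = FALSE],
                     detp = if (!is.null(bm$detp))
                       bm$detp[keep, , drop = FALSE] else NULL,
                     sample_meta = bm$sample_meta)
  list(bm = out, report = report)
}

#' Spearman concordance between two beta profiles
#'
#' Rank correlation (average ranks for ties) over the paired, non-missing
#' values of two beta vectors — the replicate/FFPE concordance statistic.
#' The p-value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom
#' (two-sided); `|rho| = 1` yields p = 0.
#'
#' @param x,y Paired numeric vectors of beta values (same length; pairs with
#'   a missing value in either vector are dropped).
#' @return A one-row tibble of class `concordance_result` with
#'   `n_common_probes`, `rho`, `p_value`, `degenerate` (TRUE when either
#'   vector has zero rank variance, in which case `rho` is `NA`) and the
#'   beta-difference summary `diff_mean`, `diff_sd`, `diff_min`, `diff_q25`,
#'   `diff_median`, `diff_q75`, `diff_max`.
#' @export
spearman_concordance <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired non-missing values")
  degenerate <- var(x) == 0 || var(y) == 0
  if (degenerate) {
    rho <- NA_real_; p <- NA_real_
  } else {
    rho <- cor(x, y, method = "spearman")
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  d <- x - y
  q <- quantile(d, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  out <- tibble(
    n_common_probes = n, rho = rho, p_value = p, degenerate = degenerate,
    diff_mean = mean(d), diff_sd = sd(d),
    diff_min = q[1], diff_q25 = q[2], diff_median = q[3],
    diff_q75 = q[4], diff_max = q[5]
  )
  class(out) <- c("concordance_result", class(out))
  out
}

#' @importFrom generics glance
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(n_common_probes = x$n_common_probes, rho = x$rho,
         p_value = x$p_value,
         p_display = if_else(x$p_value < 1e-4, "<1e-04",
                             formatC(x$p_value, digits = 3)))
}

#' Histogram of paired beta differences
#'
#' Bins `x - y` over `[-1, 1]`; counts conserve the number of pairs.
#'
#' @param x,y Paired beta vectors (missing pairs dropped).
#' @param bins Number of equal-width bins over `[-1, 1]` (default 100).
#' @return Tibble with `bin_left`, `bin_right`, `mid`, `count`.
#' @export
beta_difference_density <- function(x, y, bins = 100) {
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  breaks <- seq(-1, 1, length.out = bins + 1)
  idx <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tibble(
    bin_left = breaks[-length(breaks)],
    bin_right = breaks[-1],
    mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = as.integer(tabulate(idx, nbins = bins))
  )
}

#' Concordance for sample pairs of a beta matrix
#'
#' Convenience wrapper running [spearman_concordance()] and
#' [beta_difference_density()] for each listed sample pair.
#'
#' @param bm A [beta_matrix()].
#' @param pairs Tibble with columns `sample_a`, `sample_b`.
#' @return Tibble with one row per pair: the pair IDs plus the
#'   [spearman_concordance()] columns.
#' @export
pairwise_concordance <- function(bm, pairs) {
  bind_rows(pmap(pairs, function(sample_a, sample_b, ...) {
    res <- spearman_concordance(bm$beta[, sample_a], bm$beta[, sample_b])
    bind_cols(tibble(sample_a = sample_a, sample_b = sample_b), res)
  }))
}
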
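# Exact (non-Barnes-Hut) t-SNE. The arrays clustered here have tens of
# samples, so the quadratic algorithm is the right tool and keeps the
# embedding fully deterministic for a fixed seed.

tsne_affinities <- function(d2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))   # Shannon entropy of row
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {            # entropy too high -> narrower kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of samples
#'
#' Exact t-distributed stochastic neighbour embedding of the samples of a
#' beta matrix into two dimensions: Gaussian input affinities calibrated per
#' sample to the target perplexity by bisection, Student-t output kernel,
#' gradient descent with momentum, adaptive gains and early exaggeration.
#' Deterministic for a fixed seed.
#'
#' @param bm A [beta_matrix()].
#' @param perplexity Target perplexity; requires
#'   `n_samples > 3 * perplexity`.
#' @param seed Integer RNG seed (initial coordinates).
#' @param max_iter Gradient-descent iterations (default 500).
#' @return Tibble: sample metadata plus `tsne1`, `tsne2`.
#' @export
tsne_embed <- function(bm, perplexity = 5, seed = 1L, max_iter = 500) {
  bm <- drop_na_probes(bm)
  x <- t(bm$beta)
  n <- nrow(x)
  if (n <= 3 * perplexity)
    abort(sprintf("perplexity %g infeasible for %d samples (need n > 3*perplexity)",
                  perplexity, n))
  d2 <- as.matrix(dist(x))^2
  P <- tsne_affinities(d2, perplexity)
  y <- withr::with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  dy <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  eta <- 200
  for (iter in seq_len(max_iter)) {
    exag <- if (iter <= 100) 12 else 1
    momentum <- if (iter <= 250) 0.5 else 0.8
    ynorm2 <- rowSums(y^2)
    num <- 1 / (1 + outer(ynorm2, ynorm2, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (exag * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(dy),
                               gains + 0.2, gains * 0.8))
    dy <- momentum * dy - eta * gains * grad
    y <- y + dy
    y <- sweep(y, 2, colMeans(y))
  }
  bind_cols(bm$sample_meta, tibble(tsne1 = y[, 1], tsne2 = y[, 2]))
}
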
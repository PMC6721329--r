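# Dimensionality reduction: PCA to a retained-variance target, then exact
# (dense) t-distributed stochastic neighbor embedding to a 2D map. The t-SNE
# here is the standard formulation -- per-point Gaussian bandwidths calibrated
# to a fixed perplexity, Student-t (1 d.f.) map kernel, KL-divergence gradient
# descent with early exaggeration and momentum. Dense N x N matrices are used
# throughout, which is the right regime for posture-pair databases
# (N of order a few hundred).

#' PCA reduction to a retained-variance threshold
#'
#' Mean-centers the feature matrix, computes principal components (via the
#' singular value decomposition, equivalent to an eigendecomposition of the
#' sample covariance matrix) and keeps the smallest number of leading
#' components whose cumulative explained-variance fraction reaches
#' `variance_threshold`.
#'
#' @param features Numeric matrix, observations in rows (N >= 2).
#' @param variance_threshold Fraction of total variance to retain
#'   (0 < threshold <= 1, default 0.95).
#' @param scale. Standardize columns to unit variance before PCA
#'   (default `FALSE`: directions are bounded unit vectors and lengths are in
#'   model units of comparable magnitude when `L = 1`, so raw covariance is
#'   the default).
#' @return List of class `pca_reduction`: `scores` (N x n), `n_components`,
#'   `explained` (per-component variance fractions, all components),
#'   `cumulative` (cumsum of `explained`), `rotation`, `center`, `scale`.
#' @export
pca_reduce <- function(features, variance_threshold = 0.95, scale. = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("PCA needs at least 2 observations")
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  p <- stats::prcomp(features, center = TRUE, scale. = scale.)
  var <- p$sdev^2
  explained <- var / sum(var)
  cumulative <- cumsum(explained)
  # small slack absorbs floating-point round-off at threshold = 1 (rank-
  # deficient data never sums to exactly 1)
  n <- which(cumulative >= variance_threshold - 1e-8)[1]
  structure(list(scores = p$x[, seq_len(n), drop = FALSE], n_components = n,
                 explained = explained, cumulative = cumulative,
                 rotation = p$rotation, center = p$center, scale = p$scale,
                 variance_threshold = variance_threshold),
            class = "pca_reduction")
}

# Calibrate per-point Gaussian bandwidths so every conditional similarity
# distribution P(j|i) has the requested perplexity (2^entropy), then return
# the symmetrized joint probabilities P = (P(j|i) + P(i|j)) / (2N).
# Returns list(P, P_conditional, beta). Internal; exercised directly by the
# test suite's perplexity-calibration check.
tsne_affinities <- function(X, perplexity, tol = 1e-7, max_tries = 200L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (perplexity >= n) stop("perplexity must be smaller than the sample size")
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  beta <- numeric(n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    b <- 1; bmin <- -Inf; bmax <- Inf
    for (it in seq_len(max_tries)) {
      w <- exp(-di * b)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- w } else {
        p <- w / sw
        # Shannon entropy of the conditional distribution (nats)
        H <- log(sw) + b * sum(di * w) / sw
      }
      err <- H - target
      if (abs(err) < tol) break
      if (err > 0) {          # too spread: increase precision
        bmin <- b
        b <- if (is.finite(bmax)) (b + bmax) / 2 else b * 2
      } else {
        bmax <- b
        b <- if (is.finite(bmin)) (b + bmin) / 2 else b / 2
      }
    }
    P[i, -i] <- p
    beta[i] <- b
  }
  joint <- (P + t(P)) / (2 * n)
  list(P = joint, P_conditional = P, beta = beta)
}

#' Embed PCA scores into a 2D map with t-SNE
#'
#' Exact (dense) t-SNE: input similarities are Gaussian conditionals with
#' per-point bandwidths calibrated so each conditional distribution's
#' perplexity equals `perplexity`; map similarities use a Student-t kernel
#' with one degree of freedom; the Kullback-Leibler divergence between the
#' two is minimized by gradient descent with momentum, gain adaptation and
#' early exaggeration (the usual optimizer defaults). The run is fully
#' deterministic given `seed`.
#'
#' @param scores Numeric matrix (N x n), e.g. `pca_reduce(...)$scores`, or a
#'   `pca_reduction` object.
#' @param perplexity Effective neighbor count for the bandwidth calibration
#'   (default 30). Must be `< N`; a warning is issued when `N <= 3 *
#'   perplexity`, where calibration becomes strained.
#' @param seed Integer seed for the random map initialization (mandatory:
#'   t-SNE maps are reproducible only per seed).
#' @param max_iter,eta,momentum,final_momentum,mom_switch,exaggeration,stop_lying
#'   Optimizer settings: iteration count (1000), learning rate (200),
#'   momentum schedule (0.5 until `mom_switch` = 250, then 0.8), early
#'   exaggeration factor (12) applied for the first `stop_lying` = 250
#'   iterations.
#' @return Object of class `map2d`: `coords` (N x 2 matrix, rownames carried
#'   over from `scores`), `kl` (final KL divergence), and a `provenance` list
#'   (perplexity, seed, optimizer settings, input dimension).
#' @export
tsne_embed <- function(scores, perplexity = 30, seed,
                       max_iter = 1000L, eta = 200, momentum = 0.5,
                       final_momentum = 0.8, mom_switch = 250L,
                       exaggeration = 12, stop_lying = 250L) {
  if (inherits(scores, "pca_reduction")) scores <- scores$scores
  X <- as.matrix(scores)
  n <- nrow(X)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required for a reproducible map")
  if (perplexity >= n) stop("perplexity must be smaller than the sample size")
  if (n <= 3 * perplexity)
    warning("sample size ", n, " is small for perplexity ", perplexity,
            " (want N > 3 * perplexity)")

  P <- tsne_affinities(X, perplexity)$P
  P <- pmax(P, .Machine$double.xmin)
  P_ex <- P * exaggeration

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)

  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  kl <- NA_real_
  for (iter in seq_len(max_iter)) {
    Pi <- if (iter <= stop_lying) P_ex else P
    sq <- rowSums(Y^2)
    W <- 1 / (1 + pmax(outer(sq, sq, "+") - 2 * tcrossprod(Y), 0))
    diag(W) <- 0
    Q <- W / sum(W)
    Q <- pmax(Q, .Machine$double.xmin)
    L <- (Pi - Q) * W
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= mom_switch) momentum else final_momentum
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == max_iter) kl <- sum(P * log(P / Q))
  }
  dimnames(Y) <- list(rownames(X), c("x", "y"))
  structure(list(coords = Y, kl = kl,
                 provenance = list(perplexity = perplexity, seed = as.integer(seed),
                                   max_iter = max_iter, eta = eta,
                                   exaggeration = exaggeration,
                                   input_dim = ncol(X), n = n)),
            class = "map2d")
}

#' @export
print.map2d <- function(x, ...) {
  cat("map2d:", nrow(x$coords), "points, perplexity",
      x$provenance$perplexity, ", seed", x$provenance$seed,
      ", final KL", format(x$kl, digits = 4), "\n")
  invisible(x)
}

#' Write a 2D map as delimited text
#'
#' @param map A `map2d` object.
#' @param path Output path.
#' @param sep Delimiter.
#' @return `path`, invisibly. Provenance is embedded as `#`-prefixed header
#'   comments.
#' @export
write_map <- function(map, path, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  pv <- map$provenance
  writeLines(sprintf("# t-SNE map: n=%d perplexity=%g seed=%d input_dim=%d",
                     pv$n, pv$perplexity, pv$seed, pv$input_dim), con)
  df <- data.frame(pair_id = rownames(map$coords), map$coords, row.names = NULL)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
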
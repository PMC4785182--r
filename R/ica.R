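#' Infomax independent component analysis
#'
#' Natural-gradient infomax (logistic nonlinearity with a bias term) on
#' whitened data, the estimator classically used to parse multichannel EEG
#' into spatially fixed, temporally independent component signals. Data are
#' centered per channel, sphered by PCA, and the square unmixing rotation is
#' learned by stochastic natural-gradient ascent with learning-rate
#' annealing and blow-up restarts.
#'
#' Each component carries a quality score in `[0, 1]`: the fraction of the
#' energy of the data attributed to that component (input minus the
#' back-projection of all other components) that is captured by a single
#' fixed spatial pattern, i.e. the top-eigenvalue share of that residual's
#' channel covariance. A perfectly spatially fixed component scores 1;
#' components below `quality_threshold` are flagged `excluded` (the analog
#' of discarding components whose single-dipole model explains too little
#' scalp variance).
#'
#' @param rec A [recording] or a channels x samples numeric matrix.
#' @param n_components Number of components (default: number of channels,
#'   reduced to the numerical rank if necessary).
#' @param max_iter Maximum training sweeps.
#' @param tol Weight-change convergence tolerance.
#' @param seed Integer seed (sample order and any restart jitter).
#' @param quality_threshold Components scoring below this are flagged.
#' @return An object of class `ica_decomposition` with fields `unmixing`
#'   (components x channels), `mixing` (channels x components,
#'   pseudo-inverse), `activations` (components x samples), `quality`,
#'   `excluded`, `center`, and a convergence record (`converged`,
#'   `iterations`, `final_lrate`, `wchange`).
#' @export
infomax_ica <- function(rec, n_components = NULL, max_iter = 512,
                        tol = 1e-6, seed = 1, quality_threshold = 0.85) {
  X <- if (inherits(rec, "recording")) rec$data else as.matrix(rec)
  M <- nrow(X); N <- ncol(X)
  if (N < M * M) warning("few samples relative to channels^2; ICA may be unreliable")
  ctr <- rowMeans(X)
  X <- X - ctr
  eg <- eigen(tcrossprod(X) / N, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  k <- min(n_components %||% M, rank)
  sph <- diag(1 / sqrt(eg$values[seq_len(k)]), k) %*% t(eg$vectors[, seq_len(k), drop = FALSE])
  Xw <- sph %*% X

  set.seed(seed)
  W <- diag(k)
  bias <- numeric(k)
  lrate <- 0.00065 / log(max(k, 2))
  block <- as.integer(ceiling(min(5 * log(N), 0.3 * N)))
  BI <- block * diag(k)
  old_delta <- NULL
  wchange <- Inf
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    W_old <- W
    perm <- sample.int(N)
    t0 <- 1
    blown <- FALSE
    while (t0 + block - 1 <= N) {
      u <- W %*% Xw[, perm[t0:(t0 + block - 1)], drop = FALSE] + bias
      y <- 1 / (1 + exp(-u))
      W <- W + lrate * (BI + (1 - 2 * y) %*% t(u)) %*% W
      bias <- bias + lrate * rowSums(1 - 2 * y)
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) { blown <- TRUE; break }
      t0 <- t0 + block
    }
    if (blown) {
      W <- diag(k); bias <- numeric(k); old_delta <- NULL
      lrate <- lrate * 0.5
      if (lrate < 1e-9) break
      next
    }
    delta <- W - W_old
    wchange <- sum(delta^2) / sum(W_old^2)
    if (!is.null(old_delta)) {
      cosang <- sum(delta * old_delta) /
        sqrt(sum(delta^2) * sum(old_delta^2) + 1e-30)
      if (cosang < cos(60 * pi / 180)) lrate <- lrate * 0.9
    }
    old_delta <- delta
    if (it > 2 && wchange < tol) break
  }
  converged <- is.finite(wchange) && wchange < tol

  unmix <- W %*% sph                       # k x M
  act <- unmix %*% X
  mixing <- pinv(unmix)                    # M x k
  # order by back-projected variance, fix map signs
  bpvar <- colSums(mixing^2) * apply(act, 1, stats::var)
  ord <- order(bpvar, decreasing = TRUE)
  unmix <- unmix[ord, , drop = FALSE]
  act <- act[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  sgn <- apply(mixing, 2, function(a) sign(a[which.max(abs(a))]))
  sgn[sgn == 0] <- 1
  mixing <- sweep(mixing, 2, sgn, "*")
  unmix <- sweep(unmix, 1, sgn, "*")
  act <- sweep(act, 1, sgn, "*")

  qual <- component_quality(X, mixing, act)
  structure(list(unmixing = unmix, mixing = mixing, activations = act,
                 quality = qual, excluded = qual < quality_threshold,
                 center = ctr, converged = converged, iterations = it,
                 final_lrate = lrate, wchange = wchange),
            class = "ica_decomposition")
}

# top-eigenvalue share of the channel covariance of the data left to each
# component after removing every other component's back-projection
component_quality <- function(Xc, A, U) {
  k <- nrow(U); M <- nrow(Xc)
  R <- Xc - A %*% U
  RRt <- tcrossprod(R)
  URt <- U %*% t(R)                        # k x M
  uu <- rowSums(U^2)
  vapply(seq_len(k), function(i) {
    a <- A[, i]
    Ci <- uu[i] * tcrossprod(a) + outer(a, URt[i, ]) + outer(URt[i, ], a) + RRt
    ev <- eigen((Ci + t(Ci)) / 2, symmetric = TRUE, only.values = TRUE)$values
    tot <- sum(pmax(ev, 0))
    if (tot <= 0) return(1)
    max(ev) / tot
  }, 0)
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components, %s after %d sweeps (wchange %.2e)\n",
              nrow(x$unmixing),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$wchange))
  cat(sprintf("  quality: %s (%d flagged excluded)\n",
              paste(sprintf("%.2f", x$quality), collapse = " "),
              sum(x$excluded)))
  invisible(x)
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(X, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > max(s$d) * tol
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance of `P = unmixing %*% mixing`
#' from a scaled permutation matrix; 0 means perfect separation, values
#' below ~0.05 indicate excellent unmixing.
#'
#' @param P Square matrix, typically `unmixing %*% true_mixing`.
#' @return A non-negative scalar.
#' @export
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  rows <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cols <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (rows + cols) / (2 * n * (n - 1))
}

#' Cluster independent components
#'
#' K-means clustering of per-component feature vectors (source coordinates,
#' scalp topography and log spectrum for real data; generator coordinates
#' for synthetic data). Feature blocks are standardized column-wise, scaled
#' to equal total weight, optionally reweighted, then concatenated. Clusters
#' containing components from fewer than `min_subjects` distinct subjects
#' are marked not retained.
#'
#' @param features A numeric matrix (components x features) or a list of
#'   such matrices (feature blocks).
#' @param k Number of clusters (1 <= k <= number of components).
#' @param subjects Vector of subject identifiers, one per component.
#' @param min_subjects Retention rule: a cluster is retained when it has
#'   components from at least this many distinct subjects.
#' @param weights Optional per-block weights (default equal).
#' @param seed Integer seed; restarts pick the lowest within-cluster SSQ.
#' @param nstart Number of k-means restarts.
#' @return An object of class `cluster_set`: `assignment` (integer per
#'   component), `clusters` (per-cluster table with `n_components`,
#'   `n_subjects`, `retained`), `centers`, `tot_withinss`.
#' @export
cluster_components <- function(features, k, subjects,
                               min_subjects = 5, weights = NULL,
                               seed = 1, nstart = 20) {
  blocks <- if (is.list(features)) features else list(features)
  n <- nrow(blocks[[1]])
  if (k > n) stop("k exceeds the number of components")
  if (k < 1) stop("k must be >= 1")
  if (length(subjects) != n) stop("one subject id per component required")
  weights <- weights %||% rep(1, length(blocks))
  std <- lapply(seq_along(blocks), function(b) {
    B <- as.matrix(blocks[[b]])
    if (!all(is.finite(B))) stop("features must be finite")
    mu <- colMeans(B); sd_ <- apply(B, 2, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    scale(B, mu, sd_) * weights[b] / sqrt(ncol(B))
  })
  F <- do.call(cbind, std)
  set.seed(seed)
  km <- stats::kmeans(F, centers = k, nstart = nstart, iter.max = 100)
  tab <- data.frame(cluster = seq_len(k))
  tab$n_components <- as.integer(table(factor(km$cluster, levels = seq_len(k))))
  tab$n_subjects <- vapply(seq_len(k), function(cl)
    length(unique(subjects[km$cluster == cl])), 0L)
  tab$retained <- tab$n_subjects >= min_subjects
  structure(list(assignment = km$cluster, clusters = tab,
                 centers = km$centers, tot_withinss = km$tot.withinss),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (%d retained)\n",
              nrow(x$clusters), sum(x$clusters$retained)))
  print(x$clusters)
  invisible(x)
}
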
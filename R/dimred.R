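#' PCA of a genotype matrix
#'
#' EIGENSTRAT-style normalization: each locus is centered by `2 * p_hat` and
#' scaled by `sqrt(p_hat * (1 - p_hat))`, where
#' `p_hat = (1 + allele count) / (2 + 2 n)` is the posterior allele frequency
#' over the locus's non-missing genotypes; missing entries are set to 0 after
#' centering. Monomorphic loci are dropped. Scores come from the singular
#' value decomposition of the normalized matrix; the proportion of variance of
#' each component is its eigenvalue over the sum of all eigenvalues. Each
#' component's loading vector is oriented so its largest-magnitude entry is
#' positive, making the output sign-deterministic.
#'
#' @param dataset A [genotype_dataset].
#' @param n_components Number of components to return (default 10, capped at
#'   the matrix rank).
#' @return Object of class `genotype_pca`: `scores` (samples x components),
#'   `eigenvalues` (all, descending), `proportion` (per returned component),
#'   `loadings` (loci x components), `center`, `scale`, `kept_loci`.
#' @export
pca_genotypes <- function(dataset, n_components = 10L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$dosage
  storage.mode(G) <- "double"
  if (nrow(G) < 2L) stop("PCA needs >= 2 samples")
  n_obs <- colSums(!is.na(G))
  cnt <- colSums(G, na.rm = TRUE)
  poly <- n_obs > 0 & cnt > 0 & cnt < 2 * n_obs   # polymorphic loci only
  if (sum(poly) < 2L) stop("fewer than 2 polymorphic loci")
  G <- G[, poly, drop = FALSE]
  phat <- (1 + cnt[poly]) / (2 + 2 * n_obs[poly])
  ctr <- 2 * phat
  scl <- sqrt(phat * (1 - phat))
  X <- sweep(G, 2L, ctr)
  X <- sweep(X, 2L, scl, "/")
  X[is.na(X)] <- 0
  sv <- svd(X)
  eig <- sv$d^2
  k <- min(n_components, sum(sv$d > 1e-12))
  # orient loadings: largest-magnitude entry positive
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2L, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, "*")
  rownames(scores) <- dataset$sample_ids
  rownames(loadings) <- dataset$loci$locus_id[poly]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = eig,
                 proportion = eig[seq_len(k)] / sum(eig),
                 loadings = loadings, center = ctr, scale = scl,
                 kept_loci = dataset$loci$locus_id[poly]),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat("genotype_pca:", nrow(x$scores), "samples,", length(x$kept_loci),
      "loci,", k, "components\n")
  cat("% variance:", paste0(round(100 * x$proportion, 1), "%",
                            collapse = " "), "\n")
  invisible(x)
}

#' Per-population mean PC scores
#'
#' Averages the scores of each population's members, the usual device for
#' displaying many populations on one PC plot.
#'
#' @param pca A `genotype_pca` (or a bare score matrix).
#' @param metadata `data.frame` with `sample_id` and `population`, covering
#'   the score rows.
#' @return Matrix populations x components of mean scores.
#' @export
population_centroids <- function(pca, metadata) {
  scores <- if (inherits(pca, "genotype_pca")) pca$scores else as.matrix(pca)
  pop <- metadata$population[match(rownames(scores), metadata$sample_id)]
  if (anyNA(pop)) stop("metadata does not cover all samples")
  pops <- unique(pop)
  out <- t(vapply(pops, function(p)
    colMeans(scores[pop == p, , drop = FALSE]), numeric(ncol(scores))))
  rownames(out) <- pops
  out
}

#' Identity-by-state distance matrix
#'
#' Pairwise allele sharing over jointly non-missing loci:
#' `s_ij = sum_l (2 - |g_il - g_jl|) / (2 L_ij)`; distance `1 - s_ij`,
#' diagonal 0.
#'
#' @param dataset A [genotype_dataset].
#' @return Symmetric samples x samples distance matrix.
#' @export
ibs_distance <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$dosage
  storage.mode(G) <- "double"
  n <- nrow(G)
  D <- matrix(0, n, n, dimnames = list(dataset$sample_ids,
                                       dataset$sample_ids))
  obs <- !is.na(G)
  for (i in seq_len(n - 1L)) {
    gi <- G[i, ]; oi <- obs[i, ]
    for (j in seq((i + 1L), n)) {
      shared <- oi & obs[j, ]
      Lij <- sum(shared)
      if (Lij == 0L)
        stop("samples ", dataset$sample_ids[i], " and ",
             dataset$sample_ids[j], " share no non-missing locus")
      s <- sum(2 - abs(gi[shared] - G[j, shared])) / (2 * Lij)
      D[i, j] <- D[j, i] <- 1 - s
    }
  }
  D
}

#' Classical (metric) MDS of a distance matrix
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns
#' `eigenvector * sqrt(eigenvalue)` scores for the top k positive eigenvalues
#' (via `stats::cmdscale`). Negative eigenvalues are dropped with a warning;
#' if fewer than k positive eigenvalues exist the result is truncated with a
#' warning.
#'
#' @param D Square symmetric distance matrix, zero diagonal.
#' @param k Number of dimensions requested (default 2).
#' @return Samples x k' score matrix (k' <= k); attribute `"eig"` holds all
#'   eigenvalues.
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) ||
      any(abs(diag(D)) > 1e-12))
    stop("D must be square symmetric with zero diagonal")
  if (all(D == 0)) return(matrix(0, nrow(D), k,
                                 dimnames = list(rownames(D),
                                                 paste0("MDS", seq_len(k)))))
  res <- stats::cmdscale(D, k = min(k, nrow(D) - 1L), eig = TRUE)
  n_pos <- sum(res$eig > 1e-9)
  if (any(res$eig < -1e-9))
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  kk <- min(k, n_pos)
  if (kk < k)
    warning("only ", kk, " positive eigenvalue(s); result truncated to ", kk,
            " dimension(s)")
  pts <- res$points[, seq_len(kk), drop = FALSE]
  colnames(pts) <- paste0("MDS", seq_len(kk))
  rownames(pts) <- rownames(D)
  structure(pts, eig = res$eig)
}
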
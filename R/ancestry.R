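#' Estimate reference cluster allele frequencies
#'
#' Counted-allele frequency per cluster with a Jeffreys-like pseudocount:
#' `p_lk = (count + pseudocount) / (2 n_lk + 2 pseudocount)`, clamped to
#' `[eps, 1 - eps]` so the admixture likelihood never sees a 0 or 1.
#'
#' @param dataset A [genotype_dataset].
#' @param labels Cluster labels per sample.
#' @param pseudocount Added to each allele's count (default 0.5).
#' @param eps Clamp constant (default 1e-6).
#' @return Object of class `ref_freqs`: list with `p` (loci x K, clamped),
#'   `clusters`, `locus_id`, `eps`, and `flagged` (loci x K logical: cells
#'   estimated from the pseudocount alone).
#' @export
estimate_ref_freqs <- function(dataset, labels, pseudocount = 0.5,
                               eps = 1e-6) {
  ft <- group_allele_freqs(dataset, labels)
  n2 <- ft$count                      # observed allele counts (2n)
  counts <- ifelse(is.na(ft$freq), 0, ft$freq) * n2
  p <- (counts + pseudocount) / (n2 + 2 * pseudocount)
  flagged <- n2 == 0L
  if (any(flagged) && pseudocount == 0)
    stop("cluster with zero calls at a locus and pseudocount 0: p undefined")
  p <- pmin(pmax(p, eps), 1 - eps)
  structure(list(p = p, clusters = colnames(ft$freq),
                 locus_id = ft$loci, eps = eps, flagged = flagged),
            class = "ref_freqs")
}

#' @export
print.ref_freqs <- function(x, ...) {
  cat("ref_freqs:", nrow(x$p), "loci x", length(x$clusters), "clusters (",
      paste(x$clusters, collapse = ", "), ")\n")
  invisible(x)
}

#' Build a ref_freqs object from a frequency matrix
#'
#' @param p Loci x K matrix of counted-allele frequencies.
#' @param clusters Cluster labels (default: column names).
#' @param eps Clamp constant.
#' @return A `ref_freqs` object.
#' @export
as_ref_freqs <- function(p, clusters = colnames(p), eps = 1e-6) {
  p <- as.matrix(p)
  if (is.null(clusters)) clusters <- paste0("K", seq_len(ncol(p)))
  if (anyDuplicated(clusters)) stop("cluster labels must be unique")
  colnames(p) <- clusters
  structure(list(p = pmin(pmax(p, eps), 1 - eps), clusters = clusters,
                 locus_id = rownames(p), eps = eps,
                 flagged = matrix(FALSE, nrow(p), ncol(p))),
            class = "ref_freqs")
}

# One-sample EM on the admixture likelihood
# l(q) = sum_l g_l log(sum_k q_k p_lk) + (2 - g_l) log(sum_k q_k (1 - p_lk))
.em_one_sample <- function(g, P, tol = 1e-7, max_iter = 2000L,
                           q0 = NULL, check_monotone = FALSE) {
  obs <- !is.na(g)
  if (!any(obs)) stop("all loci missing for a sample")
  g <- as.numeric(g[obs])
  P <- P[obs, , drop = FALSE]
  K <- ncol(P)
  L <- nrow(P)
  q <- if (is.null(q0)) rep(1 / K, K) else q0
  ll_old <- -Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    s1 <- as.vector(P %*% q)
    s0 <- as.vector((1 - P) %*% q)
    ll <- sum(g * log(s1) + (2 - g) * log(s0))
    if (check_monotone && ll < ll_old - 1e-9)
      stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
    w <- as.vector(crossprod(P, g / s1) + crossprod(1 - P, (2 - g) / s0))
    q <- q * w / (2 * L)
    q <- q / sum(q)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  s1 <- as.vector(P %*% q)
  s0 <- as.vector((1 - P) %*% q)
  list(q = q, loglik = sum(g * log(s1) + (2 - g) * log(s0)),
       iterations = it, converged = converged)
}

#' Supervised admixture EM for a single sample
#'
#' Maximum-likelihood ancestry proportions q on the K-simplex given fixed
#' reference cluster frequencies, by EM on the independent-locus admixture
#' likelihood. Missing loci are excluded per sample. The log-likelihood is
#' non-decreasing at every iteration.
#'
#' @param g Dosage vector for one sample (`NA` = missing).
#' @param ref A `ref_freqs` object.
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-7).
#' @param max_iter Iteration cap (default 2000).
#' @return List with `q` (simplex vector, named by cluster), `loglik`,
#'   `iterations`, `converged`.
#' @export
supervised_em <- function(g, ref, tol = 1e-7, max_iter = 2000L) {
  stopifnot(inherits(ref, "ref_freqs"))
  res <- .em_one_sample(g, ref$p, tol, max_iter)
  names(res$q) <- ref$clusters
  res
}

#' Fit an admixture model to a genotype dataset
#'
#' The package's central model fit. Each individual's genome is a mixture of K
#' ancestral clusters with proportions q on the simplex; given cluster allele
#' frequencies `p_lk`, each of the 2 allele copies at locus l draws its
#' ancestry from q and then the counted allele with probability `p_lk`. Loci
#' are treated as independent (panels here are LD-pruned by construction).
#'
#' Supervised mode (reference frequencies fixed, from `ref` or estimated from
#' `labels`) maximizes each sample's likelihood independently by EM.
#' Unsupervised mode alternates EM updates of every sample's q with
#' responsibility-weighted updates of `p_lk`, from `restarts` random
#' Dirichlet(1,...,1) starts, keeping the best final likelihood. Both modes
#' have non-decreasing log-likelihood across iterations.
#'
#' @param dataset A [genotype_dataset].
#' @param K Number of clusters (unsupervised mode).
#' @param ref A `ref_freqs` object (supervised mode).
#' @param labels Optional cluster labels; with `ref` absent they are used to
#'   estimate reference frequencies via [estimate_ref_freqs()].
#' @param method `"supervised"` or `"unsupervised"` (inferred from arguments
#'   when omitted).
#' @param seed Integer seed (unsupervised restarts).
#' @param restarts Random restarts for unsupervised mode (default 10).
#' @param tol,max_iter EM control (defaults 1e-7, 2000 supervised; 1e-6, 500
#'   unsupervised).
#' @return Object of class `admix_fit`: `Q` (samples x K on the simplex),
#'   `loglik` (per sample, supervised) or `total_loglik`, `ref` (`ref_freqs`
#'   used or estimated), `method`, `iterations`, `converged`,
#'   `restart_logliks`.
#' @seealso [assign_clusters()], [population_summary()], [align_replicates()]
#' @export
admixture_fit <- function(dataset, K = NULL, ref = NULL, labels = NULL,
                          method = NULL, seed = 1L, restarts = 10L,
                          tol = NULL, max_iter = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(method))
    method <- if (!is.null(ref) || !is.null(labels)) "supervised"
              else "unsupervised"
  method <- match.arg(method, c("supervised", "unsupervised"))
  if (method == "supervised") {
    if (is.null(ref)) {
      if (is.null(labels)) stop("supervised fit needs ref or labels")
      ref <- estimate_ref_freqs(dataset, labels)
    }
    if (nrow(ref$p) != nrow(dataset$loci))
      stop("ref has ", nrow(ref$p), " loci; dataset has ",
           nrow(dataset$loci))
    if (is.null(tol)) tol <- 1e-7
    if (is.null(max_iter)) max_iter <- 2000L
    n <- length(dataset$sample_ids)
    K <- length(ref$clusters)
    Q <- matrix(NA_real_, n, K,
                dimnames = list(dataset$sample_ids, ref$clusters))
    ll <- numeric(n); its <- integer(n); conv <- logical(n)
    for (i in seq_len(n)) {
      res <- .em_one_sample(dataset$dosage[i, ], ref$p, tol, max_iter)
      Q[i, ] <- res$q; ll[i] <- res$loglik
      its[i] <- res$iterations; conv[i] <- res$converged
    }
    out <- list(Q = Q, loglik = ll, total_loglik = sum(ll), ref = ref,
                method = "supervised", K = K, iterations = its,
                converged = conv, restart_logliks = NULL)
  } else {
    if (is.null(K)) stop("unsupervised fit needs K")
    if (is.null(tol)) tol <- 1e-6
    if (is.null(max_iter)) max_iter <- 500L
    out <- .unsupervised_fit(dataset, K, seed, restarts, tol, max_iter)
  }
  structure(out, class = "admix_fit")
}

#' Unsupervised admixture EM
#'
#' Functional interface to the unsupervised mode of [admixture_fit()].
#'
#' @inheritParams admixture_fit
#' @return An `admix_fit` (see [admixture_fit()]); also carries the estimated
#'   cluster frequencies as `ref`.
#' @export
unsupervised_em <- function(dataset, K, seed = 1L, restarts = 10L,
                            tol = 1e-6, max_iter = 500L) {
  admixture_fit(dataset, K = K, method = "unsupervised", seed = seed,
                restarts = restarts, tol = tol, max_iter = max_iter)
}

.unsupervised_fit <- function(dataset, K, seed, restarts, tol, max_iter) {
  G <- dataset$dosage
  storage.mode(G) <- "double"
  n <- nrow(G); L <- ncol(G)
  if (K > n) stop("K (", K, ") exceeds sample count (", n, ")")
  obs <- !is.na(G)
  L_obs <- rowSums(obs)
  if (any(L_obs == 0L)) stop("sample(s) with all loci missing")
  G0 <- ifelse(obs, G, 0)           # missing contribute nothing
  G2 <- ifelse(obs, 2 - G, 0)
  eps <- 1e-6
  clusters <- paste0("K", seq_len(K))
  if (K == 1L) {
    p <- pmin(pmax(colSums(G0) / (2 * colSums(obs)), eps), 1 - eps)
    ll <- sum(G0 * log(p)[col(G0)] + G2 * log(1 - p)[col(G0)])
    return(list(Q = matrix(1, n, 1, dimnames = list(dataset$sample_ids,
                                                    clusters)),
                loglik = NULL, total_loglik = ll,
                ref = as_ref_freqs(matrix(p, L, 1,
                                          dimnames = list(colnames(G),
                                                          clusters))),
                method = "unsupervised", K = 1L, iterations = 0L,
                converged = TRUE, restart_logliks = ll))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  restart_ll <- numeric(restarts)
  for (rs in seq_len(restarts)) {
    # Dirichlet(1,...,1) row-wise initialization of Q
    Q <- matrix(stats::rexp(n * K), n, K)
    Q <- Q / rowSums(Q)
    # initial cluster frequencies: q-weighted allele frequencies
    P <- crossprod(G0, Q) / pmax(crossprod(2 * obs, Q), 1e-12)
    P <- pmin(pmax(P, eps), 1 - eps)
    ll_old <- -Inf; it <- 0L; converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      S1 <- tcrossprod(Q, P)              # n x L: sum_k q_ik p_lk
      S0 <- tcrossprod(Q, 1 - P)
      ll <- sum(G0 * log(S1) + G2 * log(S0))
      num_q <- matrix(0, n, K)
      num_p <- matrix(0, L, K)
      den_p <- matrix(0, L, K)
      R1 <- G0 / S1                       # shared factors
      R0 <- G2 / S0
      for (k in seq_len(K)) {
        gA <- R1 * outer(Q[, k], P[, k])      # g * a-responsibility
        gB <- R0 * outer(Q[, k], 1 - P[, k])  # (2-g) * b-responsibility
        num_q[, k] <- rowSums(gA) + rowSums(gB)
        num_p[, k] <- colSums(gA)
        den_p[, k] <- colSums(gA) + colSums(gB)
      }
      Q <- num_q / (2 * L_obs)
      Q <- Q / rowSums(Q)
      P <- pmin(pmax(num_p / pmax(den_p, 1e-300), eps), 1 - eps)
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    S1 <- tcrossprod(Q, P); S0 <- tcrossprod(Q, 1 - P)
    ll <- sum(G0 * log(S1) + G2 * log(S0))
    restart_ll[rs] <- ll
    if (is.null(best) || ll > best$total_loglik)
      best <- list(Q = Q, P = P, total_loglik = ll, iterations = it,
                   converged = converged)
  }
  dimnames(best$Q) <- list(dataset$sample_ids, clusters)
  dimnames(best$P) <- list(colnames(G), clusters)
  list(Q = best$Q, loglik = NULL, total_loglik = best$total_loglik,
       ref = as_ref_freqs(best$P), method = "unsupervised", K = K,
       iterations = best$iterations, converged = best$converged,
       restart_logliks = restart_ll)
}

#' @export
print.admix_fit <- function(x, ...) {
  cat("admix_fit (", x$method, "): ", nrow(x$Q), " samples, K = ", x$K,
      ", total log-likelihood ", format(x$total_loglik), "\n", sep = "")
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, threshold = 0.85, ...) {
  asg <- assign_clusters(object$Q, threshold)
  cat("admix_fit (", object$method, "), K = ", object$K, ", ",
      nrow(object$Q), " samples\n", sep = "")
  cat("mean membership per cluster:\n")
  print(round(colMeans(object$Q), 4))
  cat("assignments at >", threshold * 100, "% membership:\n", sep = "")
  print(table(asg))
  invisible(list(mean_membership = colMeans(object$Q),
                 assignments = table(asg)))
}

#' @export
coef.admix_fit <- function(object, ...) object$Q

#' @export
#' @importFrom stats predict
predict.admix_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "genotype_dataset"))
  refit <- admixture_fit(newdata, ref = object$ref, method = "supervised")
  refit$Q
}

#' @export
#' @importFrom graphics barplot
plot.admix_fit <- function(x, order_by = 1L, ...) {
  Q <- x$Q[order(x$Q[, order_by], decreasing = TRUE), , drop = FALSE]
  graphics::barplot(t(Q), col = seq_len(x$K) + 1L, border = NA, space = 0,
                    names.arg = rep("", nrow(Q)),
                    ylab = "ancestry proportion", ...)
  invisible(x)
}

# all permutations of 1..k (k small)
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1L
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Align cluster labels across replicate runs
#'
#' Resolves label switching: every run's Q columns are permuted to match the
#' first run, maximizing the sum over samples of the inner product of
#' membership rows, by exhaustive search over all K! column permutations
#' (K <= 10).
#'
#' @param Q_list List of Q matrices sharing samples and K.
#' @return List with `aligned` (permuted matrices), `permutations` (list of
#'   integer vectors; `aligned[[r]] = Q_list[[r]][, perm]`), and
#'   `mean_similarity` (mean over runs and samples of the row inner product
#'   with run 1).
#' @export
align_replicates <- function(Q_list) {
  stopifnot(is.list(Q_list), length(Q_list) >= 1L)
  K <- ncol(Q_list[[1L]])
  if (K > 10L)
    stop("K > 10: exhaustive alignment infeasible; reduce K or align greedily")
  if (!all(vapply(Q_list, ncol, 1L) == K) ||
      !all(vapply(Q_list, nrow, 1L) == nrow(Q_list[[1L]])))
    stop("all Q matrices must share samples and K")
  perms <- .permutations(K)
  ref <- Q_list[[1L]]
  aligned <- vector("list", length(Q_list))
  permutations <- vector("list", length(Q_list))
  sims <- numeric(length(Q_list))
  for (r in seq_along(Q_list)) {
    M <- crossprod(ref, Q_list[[r]])   # M[a, b] = sum_i ref[i,a] * Q[i,b]
    scores <- apply(perms, 1L, function(pp)
      sum(M[cbind(seq_len(K), pp)]))
    best <- perms[which.max(scores), ]
    permutations[[r]] <- best
    A <- Q_list[[r]][, best, drop = FALSE]
    colnames(A) <- colnames(ref)
    aligned[[r]] <- A
    sims[r] <- max(scores) / nrow(ref)
  }
  list(aligned = aligned, permutations = permutations,
       mean_similarity = mean(sims))
}

#' Membership-threshold cluster assignment
#'
#' A sample is assigned to cluster k iff its membership `q_k` strictly exceeds
#' `threshold`; otherwise it is `"unassigned"`. At thresholds > 0.5 at most
#' one cluster can qualify; at exactly 0.5 a 50/50 sample stays unassigned
#' (strict inequality).
#'
#' @param Q Samples x K membership matrix (or an `admix_fit`).
#' @param threshold Membership cutoff in (0, 1]; conventional values 0.85 and
#'   0.5.
#' @return Character vector: cluster label or `"unassigned"` per sample.
#' @export
assign_clusters <- function(Q, threshold = 0.85) {
  if (inherits(Q, "admix_fit")) Q <- Q$Q
  stopifnot(threshold > 0, threshold <= 1)
  top <- max.col(Q, ties.method = "first")
  val <- Q[cbind(seq_len(nrow(Q)), top)]
  lab <- colnames(Q)[top]
  ifelse(val > threshold, lab, "unassigned")
}

#' Per-population ancestry summary
#'
#' For every population: mean cluster membership, and for each threshold the
#' fraction of its samples assigned (strict majority-membership rule) to the
#' population's expected cluster.
#'
#' @param Q Samples x K membership matrix (or an `admix_fit`), rows aligned
#'   with `metadata`.
#' @param metadata `data.frame` with `sample_id`, `population`, `region`.
#' @param thresholds Membership cutoffs (default `c(0.85, 0.5)`).
#' @param expected_map Named character vector population -> expected cluster
#'   label; populations absent from it get `NA` fractions. Default: each
#'   population's `region` (when regions are the cluster labels).
#' @return `data.frame`: population, n, one mean-membership column per
#'   cluster, one assigned-fraction column per threshold.
#' @export
population_summary <- function(Q, metadata, thresholds = c(0.85, 0.5),
                               expected_map = NULL) {
  if (inherits(Q, "admix_fit")) Q <- Q$Q
  if (nrow(Q) != nrow(metadata))
    stop("Q rows (", nrow(Q), ") != metadata rows (", nrow(metadata), ")")
  if (is.null(expected_map)) {
    u <- unique(metadata[, c("population", "region")])
    expected_map <- stats::setNames(u$region, u$population)
  }
  pops <- unique(metadata$population)
  asg <- lapply(thresholds, function(th) assign_clusters(Q, th))
  rows <- lapply(pops, function(pop) {
    idx <- which(metadata$population == pop)
    means <- colMeans(Q[idx, , drop = FALSE])
    expected <- if (pop %in% names(expected_map)) expected_map[[pop]]
                else NA_character_
    fr <- vapply(asg, function(a) {
      if (is.na(expected)) NA_real_ else mean(a[idx] == expected)
    }, numeric(1L))
    out <- data.frame(population = pop, n = length(idx), t(means),
                      check.names = FALSE, stringsAsFactors = FALSE)
    for (ti in seq_along(thresholds))
      out[[sprintf("MS%g", 100 * thresholds[ti])]] <- fr[ti]
    out
  })
  do.call(rbind, rows)
}

#' Compare two sets of admixture estimates
#'
#' Pearson correlation over samples of one ancestry component estimated by two
#' marker panels (or against simulation truth), with the least-squares
#' slope/intercept of `y` on `x` for scatter plotting.
#'
#' @param x,y Numeric vectors of one ancestry component, same samples.
#' @return List with `r`, `slope`, `intercept`, `n`.
#' @export
compare_admixture <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired estimates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant estimate vector; correlation undefined")
  slope <- stats::cov(x, y) / stats::var(x)
  list(r = stats::cor(x, y), slope = slope,
       intercept = mean(y) - slope * mean(x), n = length(x))
}

#' Write an admixture Q matrix as TSV
#'
#' Columns: sample id, K membership columns, per-sample log-likelihood (when
#' available), assignment at each threshold.
#'
#' @param fit An `admix_fit`.
#' @param path Output path.
#' @param thresholds Assignment cutoffs recorded as columns.
#' @return Invisibly, `path`.
#' @export
write_q_matrix <- function(fit, path, thresholds = c(0.85, 0.5)) {
  stopifnot(inherits(fit, "admix_fit"))
  df <- data.frame(sample_id = rownames(fit$Q), fit$Q, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(fit$loglik)) df$loglik <- fit$loglik
  for (th in thresholds)
    df[[sprintf("assign_MS%g", 100 * th)]] <- assign_clusters(fit$Q, th)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
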
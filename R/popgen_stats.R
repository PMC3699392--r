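# Per-group, per-locus sufficient statistics for Weir-Cockerham theta:
# non-missing sample size, counted-allele frequency, observed heterozygosity.
.wc_components <- function(dos_list) {
  r <- length(dos_list)
  L <- ncol(dos_list[[1L]])
  n <- p <- h <- matrix(0, r, L)
  for (i in seq_len(r)) {
    d <- dos_list[[i]]
    n[i, ] <- colSums(!is.na(d))
    p[i, ] <- ifelse(n[i, ] > 0, colSums(d, na.rm = TRUE) / (2 * n[i, ]), NA)
    h[i, ] <- ifelse(n[i, ] > 0, colSums(d == 1L, na.rm = TRUE) / n[i, ], NA)
  }
  # Weir & Cockerham (1984) variance components, r populations
  ok <- colSums(n >= 1 & !is.na(p)) == r & colSums(n) > r  # defined everywhere
  nbar <- colMeans(n)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2L, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ok <- ok & is.finite(a) & is.finite(b) & is.finite(cc) & (a + b + cc) != 0
  list(a = a, b = b, c = cc, ok = ok)
}

#' Weir-Cockerham FST for one group pair
#'
#' Multi-locus Weir-Cockerham (1984) theta between two groups: per-locus
#' variance components a (among groups), b (among individuals within groups)
#' and c (within individuals, from observed heterozygosity) are combined as a
#' ratio of sums, `theta = sum(a) / sum(a + b + c)`, over loci with defined
#' components. Negative estimates are reported as computed unless
#' `floor_zero = TRUE`.
#'
#' @param dataset A [genotype_dataset].
#' @param labels Group labels per sample.
#' @param pair Character vector of the two group labels to compare.
#' @param floor_zero Truncate negative estimates at 0 (default `FALSE`).
#' @return Multi-locus FST (numeric scalar); attribute `"components"` holds
#'   the per-locus a, b, c for audit.
#' @export
wc_fst <- function(dataset, labels, pair, floor_zero = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"), length(pair) == 2L)
  labels <- as.character(labels)
  d1 <- dataset$dosage[labels == pair[1L], , drop = FALSE]
  d2 <- dataset$dosage[labels == pair[2L], , drop = FALSE]
  if (nrow(d1) < 2L || nrow(d2) < 2L)
    stop("each group needs >= 2 individuals (", pair[1L], ": ", nrow(d1),
         ", ", pair[2L], ": ", nrow(d2), ")")
  .wc_theta(d1, d2, floor_zero)
}

.wc_theta <- function(d1, d2, floor_zero = FALSE) {
  comp <- .wc_components(list(d1, d2))
  if (!any(comp$ok))
    stop("no locus with defined variance components in both groups")
  theta <- sum(comp$a[comp$ok]) /
    sum(comp$a[comp$ok] + comp$b[comp$ok] + comp$c[comp$ok])
  if (floor_zero) theta <- max(theta, 0)
  structure(theta, components = comp)
}

#' Permutation test for pairwise FST
#'
#' Individuals are permuted between the two groups (group sizes preserved);
#' `p = (1 + #{FST_perm >= FST_obs}) / (n_perm + 1)`, so p is never exactly 0.
#'
#' @inheritParams wc_fst
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; results are reproducible.
#' @return List with `fst`, `p_value`, `n_perm`.
#' @export
fst_permutation_test <- function(dataset, labels, pair, n_perm = 10000L,
                                 seed = 1L) {
  stopifnot(n_perm >= 1L)
  labels <- as.character(labels)
  idx <- which(labels %in% pair)
  sub <- dataset$dosage[idx, , drop = FALSE]
  lab <- labels[idx]
  n1 <- sum(lab == pair[1L])
  if (n1 < 2L || length(idx) - n1 < 2L) stop("degenerate groups for ",
                                             paste(pair, collapse = " vs "))
  obs <- as.numeric(.wc_theta(sub[lab == pair[1L], , drop = FALSE],
                              sub[lab == pair[2L], , drop = FALSE]))
  hits <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    take <- sample.int(length(idx), n1)
    th <- tryCatch(as.numeric(.wc_theta(sub[take, , drop = FALSE],
                                        sub[-take, , drop = FALSE])),
                   error = function(e) -Inf)
    if (th >= obs) hits <- hits + 1L
  }
  list(fst = obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Pairwise FST matrix with permutation p-values
#'
#' All unordered group pairs. An optional exclusion list of sample ids (e.g.
#' all members of an atypical population) is applied before grouping.
#'
#' @inheritParams wc_fst
#' @param n_perm Permutations per pair (0 = no test, p-values `NA`).
#' @param seed Integer seed.
#' @param exclude Sample ids dropped before analysis.
#' @return Object of class `fst_matrix`: list with symmetric `fst` (diagonal
#'   0), `p_value`, `n_perm`.
#' @export
pairwise_fst_matrix <- function(dataset, labels, n_perm = 0L, seed = 1L,
                                exclude = NULL) {
  labels <- as.character(labels)
  if (!is.null(exclude)) {
    keep <- !(dataset$sample_ids %in% exclude)
    dataset <- subset_dataset(dataset, samples = which(keep))
    labels <- labels[keep]
  }
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop(">= 2 groups required")
  K <- length(groups)
  fst <- matrix(0, K, K, dimnames = list(groups, groups))
  pv <- matrix(NA_real_, K, K, dimnames = list(groups, groups))
  for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
    pair <- c(groups[i], groups[j])
    if (n_perm > 0L) {
      res <- fst_permutation_test(dataset, labels, pair, n_perm,
                                  seed = seed + i * K + j)
      fst[i, j] <- fst[j, i] <- res$fst
      pv[i, j] <- pv[j, i] <- res$p_value
    } else {
      fst[i, j] <- fst[j, i] <- as.numeric(wc_fst(dataset, labels, pair))
    }
  }
  structure(list(fst = fst, p_value = pv, n_perm = n_perm),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Weir-Cockerham FST (", x$n_perm, "permutations )\n")
  print(round(x$fst, digits))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the lower-triangle off-diagonal entries;
#' significance comes from jointly permuting rows and columns of `D2`, with a
#' two-sided criterion `p = (1 + #{|r_perm| >= |r|}) / (n_perm + 1)`.
#'
#' @param D1,D2 Square symmetric matrices with matching dimnames (or both
#'   unlabelled and of equal dimension).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999L, seed = 1L) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2)) || nrow(D1) != ncol(D1))
    stop("D1 and D2 must be square matrices of equal dimension")
  if (nrow(D1) < 3L) stop("Mantel test needs matrices of dimension >= 3")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("D1/D2 label mismatch")
  lt <- lower.tri(D1)
  x <- D1[lt]
  if (stats::sd(x) == 0 || stats::sd(D2[lt]) == 0)
    stop("zero variance in a lower triangle; r undefined")
  r_obs <- stats::cor(x, D2[lt])
  hits <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(D2))
    rp <- stats::cor(x, D2[perm, perm][lt])
    if (abs(rp) >= abs(r_obs)) hits <- hits + 1L
  }
  list(r = r_obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Write / read a labeled square matrix as TSV
#'
#' @param m Square matrix with dimnames.
#' @param path TSV path.
#' @return `write_matrix_tsv`: invisibly `path`; `read_matrix_tsv`: the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(m), path, quote = FALSE, sep = "\t",
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}
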
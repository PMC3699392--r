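# Independent oracle implementations used to cross-check the package.
# These deliberately use a different coding style (scalar loops, textbook
# formulas) from the implementations they verify.

# informativeness for assignment, literal two-allele formula
brute_in <- function(p) {
  K <- length(p)
  xlogx <- function(x) if (x > 0) x * log(x) else 0
  total <- 0
  for (j in 1:2) {
    pj <- if (j == 1) p else 1 - p
    pbar <- sum(pj) / K
    term <- -xlogx(pbar)
    for (i in 1:K) term <- term + xlogx(pj[i]) / K
    total <- total + term
  }
  total
}

# Weir-Cockerham (1984) theta for two groups of dosage rows, scalar loops
oracle_wc_theta <- function(d1, d2) {
  r <- 2
  num <- den <- 0
  for (l in seq_len(ncol(d1))) {
    g1 <- d1[, l][!is.na(d1[, l])]
    g2 <- d2[, l][!is.na(d2[, l])]
    n <- c(length(g1), length(g2))
    if (any(n < 1)) next
    p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
    h <- c(sum(g1 == 1) / n[1], sum(g2 == 1) / n[2])
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    if (!is.finite(a + b + cc) || (a + b + cc) == 0) next
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# exhaustive subset search under the min-over-pairs top-3-delta objective
oracle_best_subset <- function(locus_ids, scores, target_size) {
  objective <- function(ids) {
    d <- scores$delta[match(ids, scores$locus_id), , drop = FALSE]
    worst <- Inf
    for (j in seq_len(ncol(d))) {
      top3 <- sum(sort(d[, j], decreasing = TRUE)[1:3])
      if (top3 < worst) worst <- top3
    }
    worst
  }
  subsets <- utils::combn(locus_ids, target_size, simplify = FALSE)
  vals <- vapply(subsets, objective, numeric(1))
  best <- max(vals)
  list(best_value = best,
       best_subsets = lapply(subsets[vals == best], sort))
}

# brute-force best column permutation aligning Q to ref
oracle_align <- function(ref, Q) {
  K <- ncol(ref)
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == K), ,
                 drop = FALSE]
  best_score <- -Inf
  best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    pp <- perms[i, ]
    s <- sum(ref * Q[, pp, drop = FALSE])
    if (s > best_score) { best_score <- s; best_perm <- pp }
  }
  list(perm = as.integer(best_perm), score = best_score)
}

# small hand-constructable dataset: dosage matrix + auto-generated registry
toy_dataset <- function(dosage, chromosome = NULL, position = NULL,
                        allele_a = NULL, allele_b = NULL) {
  L <- ncol(dosage)
  loci <- data.frame(
    locus_id = paste0("L", seq_len(L)),
    chromosome = if (is.null(chromosome)) rep("1", L) else chromosome,
    position = if (is.null(position)) seq_len(L) * 1000L else position,
    allele_a = if (is.null(allele_a)) rep("A", L) else allele_a,
    allele_b = if (is.null(allele_b)) rep("G", L) else allele_b,
    on_array = TRUE, stringsAsFactors = FALSE)
  genotype_dataset(dosage, loci, paste0("S", seq_len(nrow(dosage))))
}

# two groups fixed for opposite alleles at every locus
fixed_difference_dataset <- function(n_per_group = 20L, L = 10L) {
  dosage <- rbind(matrix(2L, n_per_group, L), matrix(0L, n_per_group, L))
  list(dataset = toy_dataset(dosage),
       labels = rep(c("g1", "g2"), each = n_per_group))
}

aim41_path <- function() {
  system.file("extdata", "aim41_scores.tsv", package = "aimpanel")
}
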
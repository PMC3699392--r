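test_that("reference frequency estimation is hand-checkable and clamps", {
  # one cluster, dosages (0,1,2), pseudocount 0.5: p = 3.5/7
  ds <- toy_dataset(matrix(c(0L, 1L, 2L), 3, 1))
  ref <- estimate_ref_freqs(ds, rep("k1", 3), pseudocount = 0.5)
  expect_equal(unname(ref$p[1, 1]), 3.5 / 7)
  # dosages (2,2), pseudocount 0: p = 1 -> clamped to 1 - eps
  ds2 <- toy_dataset(matrix(c(2L, 2L), 2, 1))
  ref2 <- estimate_ref_freqs(ds2, rep("k1", 2), pseudocount = 0)
  expect_equal(unname(ref2$p[1, 1]), 1 - 1e-6)
  # zero-call cell flagged, estimated from pseudocount alone
  ds3 <- toy_dataset(rbind(c(2L, NA), c(0L, 1L)))
  ref3 <- estimate_ref_freqs(ds3, c("a", "b"))
  expect_true(ref3$flagged["L2", "a"])
  expect_equal(unname(ref3$p["L2", "a"]), 0.5)
})

test_that("supervised EM solves separable clusters and flat likelihoods", {
  P <- cbind(k1 = rep(1e-6, 50), k2 = rep(1 - 1e-6, 50))
  ref <- as_ref_freqs(P)
  res <- supervised_em(rep(2L, 50), ref)   # pure cluster-2 sample
  expect_gte(res$q[["k2"]], 0.999)
  # identical cluster frequencies: q stays uniform
  Pflat <- cbind(k1 = rep(0.4, 30), k2 = rep(0.4, 30), k3 = rep(0.4, 30))
  res2 <- supervised_em(rbinom(30, 2, 0.4), as_ref_freqs(Pflat))
  expect_equal(unname(res2$q), rep(1 / 3, 3), tolerance = 1e-9)
  expect_error(supervised_em(rep(NA_integer_, 30), as_ref_freqs(Pflat)),
               "missing")
})

test_that("EM log-likelihood is non-decreasing along the trajectory", {
  set.seed(71)
  P <- matrix(runif(200, 0.05, 0.95), 100, 2)
  g <- rbinom(100, 2, rowMeans(P))
  # run step by step and record the likelihood path
  ll_path <- numeric(40)
  q <- c(0.5, 0.5)
  for (it in 1:40) {
    s1 <- as.vector(P %*% q); s0 <- as.vector((1 - P) %*% q)
    ll_path[it] <- sum(g * log(s1) + (2 - g) * log(s0))
    w <- as.vector(crossprod(P, g / s1) + crossprod(1 - P, (2 - g) / s0))
    q <- q * w / (2 * 100); q <- q / sum(q)
  }
  expect_true(all(diff(ll_path) >= -1e-9))
  # internal monotonicity assertion does not fire
  expect_silent(aimpanel:::.em_one_sample(g, P, check_monotone = TRUE))
})

test_that("supervised recovery improves with panel size and admixture level", {
  set.seed(73)
  K <- 2
  make_ref <- function(L) {
    # fixed mean delta ~ 0.8 between the two clusters
    p1 <- runif(L, 0.85, 0.95); p2 <- p1 - 0.8
    as_ref_freqs(cbind(k1 = p1, k2 = p2))
  }
  draw <- function(ref, q, n = 30) {
    P <- ref$p
    t(vapply(seq_len(n), function(i) {
      z1 <- rbinom(nrow(P), 1, q[1]); z2 <- rbinom(nrow(P), 1, q[1])
      p_mix1 <- ifelse(z1 == 1, P[, 1], P[, 2])
      p_mix2 <- ifelse(z2 == 1, P[, 1], P[, 2])
      as.integer(rbinom(nrow(P), 1, p_mix1) + rbinom(nrow(P), 1, p_mix2))
    }, integer(nrow(P))))
  }
  rmse_at <- function(L, q1) {
    ref <- make_ref(L)
    G <- draw(ref, c(q1, 1 - q1))
    qs <- apply(G, 1, function(g) supervised_em(g, ref)$q[[1]])
    sqrt(mean((qs - q1)^2))
  }
  r41_half <- rmse_at(41, 0.5)
  r200_half <- rmse_at(200, 0.5)
  r1000_half <- rmse_at(1000, 0.5)
  expect_gt(r41_half, r1000_half)           # error shrinks with L
  expect_gt(r200_half, r1000_half)
  expect_lt(r1000_half, 0.05)               # near-truth at L = 1000
  # low admixture (q = 0.1) is harder than balanced admixture at L = 41
  r41_low <- rmse_at(41, 0.1)
  expect_gt(r41_low, r1000_half)
})

test_that("unsupervised EM separates two diverged regions", {
  cfg <- sim_config(L = 500, regions = c("r1", "r2"), F = c(0.3, 0.3),
                    n_per_region = 30)
  sc <- simulate_scenario(cfg, seed = 77)
  fit <- admixture_fit(sc$dataset, K = 2, method = "unsupervised",
                       seed = 5, restarts = 3)
  # align cluster labels to truth by majority
  truth <- sc$metadata$region
  q1_r1 <- mean(fit$Q[truth == "r1", 1])
  col_r1 <- if (q1_r1 > 0.5) 1 else 2
  member <- ifelse(truth == "r1", fit$Q[, col_r1], fit$Q[, 3 - col_r1])
  expect_gt(mean(member >= 0.9), 0.95)
  # determinism under the same seed
  fit2 <- admixture_fit(sc$dataset, K = 2, method = "unsupervised",
                        seed = 5, restarts = 3)
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$total_loglik, fit2$total_loglik)
})

test_that("K = 1 gives unit memberships and the pooled binomial likelihood", {
  set.seed(79)
  d <- matrix(rbinom(20 * 40, 2, 0.3), 20, 40)
  ds <- toy_dataset(d)
  fit <- admixture_fit(ds, K = 1, method = "unsupervised")
  expect_true(all(fit$Q == 1))
  p <- pmin(pmax(colMeans(d) / 2, 1e-6), 1 - 1e-6)
  ll <- sum(t(d) * log(p) + (2 - t(d)) * log(1 - p))
  expect_equal(fit$total_loglik, ll, tolerance = 1e-8)
})

test_that("replicate alignment recovers column permutations exactly", {
  set.seed(83)
  Q <- matrix(rexp(40 * 4), 40, 4); Q <- Q / rowSums(Q)
  perm <- c(3L, 1L, 4L, 2L)
  Qp <- Q[, perm]
  res <- align_replicates(list(Q, Qp))
  expect_equal(res$aligned[[2]], Q, ignore_attr = TRUE)
  expect_identical(res$permutations[[1]], 1:4)
  # identical runs: identity permutations
  res2 <- align_replicates(list(Q, Q, Q))
  expect_true(all(vapply(res2$permutations, identical, TRUE, 1:4)))
  # mild noise: equals an independently coded brute-force search
  Qn <- Qp + matrix(runif(160, 0, 0.05), 40, 4)
  Qn <- Qn / rowSums(Qn)
  res3 <- align_replicates(list(Q, Qn))
  expect_identical(res3$permutations[[2]], oracle_align(Q, Qn)$perm)
  expect_error(align_replicates(list(matrix(1, 2, 11))), "K > 10")
})

test_that("threshold assignment is strict and nested across cutoffs", {
  Q <- rbind(c(0.90, 0.06, 0.04),
             c(0.60, 0.40, 0.00),
             c(0.50, 0.50, 0.00),
             c(0.86, 0.10, 0.04))
  colnames(Q) <- c("A", "B", "C")
  expect_identical(assign_clusters(Q, 0.85),
                   c("A", "unassigned", "unassigned", "A"))
  expect_identical(assign_clusters(Q, 0.5),
                   c("A", "A", "unassigned", "A"))  # 0.5/0.5 stays out
  # nesting property on random simplex matrices
  set.seed(87)
  R <- matrix(rexp(300 * 4), 300, 4); R <- R / rowSums(R)
  colnames(R) <- paste0("k", 1:4)
  a85 <- assign_clusters(R, 0.85); a50 <- assign_clusters(R, 0.5)
  assigned85 <- which(a85 != "unassigned")
  expect_true(all(a50[assigned85] == a85[assigned85]))
})

test_that("population summaries conserve cluster means and track admixture", {
  cfg <- sim_config(L = 400, regions = c("r1", "r2"), F = c(0.25, 0.25),
                    n_per_region = 20,
                    admixed = list(list(name = "mix",
                                        q = c(r1 = 0.6, r2 = 0.4),
                                        count = 15)))
  sc <- simulate_scenario(cfg, seed = 91)
  ref_idx <- which(!grepl("mix", sc$metadata$population))
  ref <- estimate_ref_freqs(subset_dataset(sc$dataset, samples = ref_idx),
                            sc$metadata$region[ref_idx])
  fit <- admixture_fit(sc$dataset, ref = ref)
  summ <- population_summary(fit$Q, sc$metadata)
  # weighted column means of per-population means equal overall means
  w <- summ$n / sum(summ$n)
  for (k in colnames(fit$Q))
    expect_equal(sum(w * summ[[k]]), mean(fit$Q[, k]), tolerance = 1e-12)
  # admixed population: high 50% MS fraction, low 85% MS fraction
  mix_row <- summ[summ$population == "mix", ]
  pure_row <- summ[summ$population == "r1_pop", ]
  expect_gt(mix_row$MS50, mix_row$MS85)
  expect_gt(pure_row$MS85, 0.9)
  expect_lt(mix_row$MS85, 0.5)
})

test_that("admixture comparisons report r, slope and degenerate errors", {
  expect_equal(compare_admixture(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))$r, 1)
  set.seed(93)
  x <- runif(50); y <- 0.8 * x + rnorm(50, 0, 0.05)
  res <- compare_admixture(x, y)
  expect_gt(res$r, 0.9)
  expect_equal(res$slope, 0.8, tolerance = 0.15)
  expect_error(compare_admixture(x, rep(0.3, 50)), "constant")
  expect_error(compare_admixture(1:2 / 10, 1:2 / 10), ">= 3")
})

test_that("admix_fit methods expose the fit the standard way", {
  cfg <- sim_config(L = 150, regions = c("r1", "r2"), F = c(0.3, 0.3),
                    n_per_region = 10)
  sc <- simulate_scenario(cfg, seed = 95)
  fit <- admixture_fit(sc$dataset, labels = sc$metadata$region)
  expect_s3_class(fit, "admix_fit")
  expect_identical(coef(fit), fit$Q)
  expect_equal(rowSums(coef(fit)), rep(1, nrow(fit$Q)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_output(print(fit), "admix_fit")
  expect_output(summary(fit), "mean membership")
  # predict on new data reuses the reference frequencies
  sc2 <- simulate_scenario(cfg, seed = 96)
  Qnew <- predict(fit, sc2$dataset)
  expect_identical(dim(Qnew), dim(fit$Q))
  expect_equal(rowSums(Qnew), rep(1, nrow(Qnew)), tolerance = 1e-8,
               ignore_attr = TRUE)
})
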
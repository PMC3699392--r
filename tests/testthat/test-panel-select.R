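test_that("candidate filtering applies autosome/ambiguity/array rules", {
  loci <- data.frame(
    locus_id = paste0("L", 1:6),
    chromosome = c("1", "X", "22", "5", "3", "7"),
    position = 1:6 * 1000L,
    allele_a = c("A", "A", "A", "C", "A", "T"),
    allele_b = c("C", "G", "T", "G", "G", "C"),
    on_array = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  # hand-filtered: L2 non-autosomal, L3 A/T ambiguous, L4 C/G ambiguous
  kept <- filter_candidates(loci)
  expect_identical(as.character(kept), c("L1", "L5", "L6"))
  kept_arr <- filter_candidates(loci, require_on_array = TRUE)
  expect_identical(as.character(kept_arr), c("L1", "L6"))
  rej <- attr(kept_arr, "rejected")
  expect_identical(unname(rej["non_autosomal"]), 1L)
  expect_identical(unname(rej["ambiguous"]), 2L)
  expect_identical(unname(rej["off_array"]), 1L)
})

test_that("vif_prune removes exactly one of two identical loci", {
  set.seed(21)
  g <- sample(0:2, 40, replace = TRUE)
  dosage <- cbind(g, g, sample(0:2, 40, replace = TRUE))
  ds <- toy_dataset(dosage)
  kept <- vif_prune(ds, window_size = 3, window_step = 1, vif_threshold = 1.5)
  expect_length(kept, 2L)
  expect_true("L3" %in% kept)
  # the later duplicate (tie at infinite VIF) is removed
  expect_identical(kept, c("L1", "L3"))
})

test_that("vif_prune keeps mutually orthogonal loci", {
  # orthogonal dosage columns: VIF = 1 everywhere
  dosage <- cbind(c(0L, 0L, 2L, 2L, 1L, 1L),
                  c(0L, 2L, 0L, 2L, 1L, 1L),
                  c(1L, 1L, 1L, 1L, 0L, 2L))
  ds <- toy_dataset(dosage)
  expect_identical(vif_prune(ds, 3, 1, 1.5), c("L1", "L2", "L3"))
})

test_that("after vif_prune every retained window has VIF <= threshold", {
  sc <- simulate_scenario(sim_config(L = 120, n_per_region = 15), seed = 9)
  ds <- sc$dataset
  # inject LD by duplicating some loci with noise
  dosage <- ds$dosage
  for (j in seq(1, 110, by = 10)) {
    dosage[, j + 1] <- dosage[, j]
    flip <- sample(nrow(dosage), 3)
    dosage[flip, j + 1] <- sample(0:2, 3, replace = TRUE)
  }
  ds2 <- toy_dataset(dosage)
  thr <- 1.5
  kept <- vif_prune(ds2, window_size = 10, window_step = 2,
                    vif_threshold = thr)
  X <- ds2$dosage[, kept, drop = FALSE]
  storage.mode(X) <- "double"
  # direct recomputation over all windows of retained loci
  for (s in seq(1, ncol(X) - 9, by = 2)) {
    W <- X[, s:(s + 9), drop = FALSE]
    vifs <- aimpanel:::.window_vifs(W)
    expect_true(all(vifs <= thr + 1e-8))
  }
})

test_that("top-delta claiming walks rankings and never double-claims", {
  # 3 groups, per_pair = 2, one marker (M1) best for two pairs
  delta <- rbind(
    M1 = c(0.9, 0.85, 0.1),
    M2 = c(0.8, 0.20, 0.2),
    M3 = c(0.1, 0.80, 0.3),
    M4 = c(0.7, 0.75, 0.4),
    M5 = c(0.2, 0.10, 0.9),
    M6 = c(0.3, 0.15, 0.8),
    M7 = c(0.4, 0.30, 0.7))
  colnames(delta) <- c("a|b", "a|c", "b|c")
  ms <- structure(list(locus_id = rownames(delta),
                       In = seq(0.7, 0.1, length.out = 7), delta = delta,
                       groups = c("a", "b", "c"),
                       pairs = utils::combn(c("a", "b", "c"), 2),
                       excluded = character()),
                  class = "marker_scores")
  panel <- select_top_delta_per_pair(ms, per_pair = 2)
  # hand-walk: a|b claims M1, M2; a|c skips claimed M1 -> M3, M4; b|c: M5, M6
  expect_identical(sort(panel$loci), sort(c("M1", "M2", "M3", "M4",
                                            "M5", "M6")))
  prov <- panel$provenance
  expect_identical(prov$pair[prov$locus_id == "M1"], "a|b")
  expect_identical(sort(prov$locus_id[prov$pair == "a|c"]), c("M3", "M4"))
})

test_that("abundant markers give exactly per_pair x n_pairs panel loci", {
  sc <- simulate_scenario(sim_config(L = 500, n_per_region = 12), seed = 13)
  ms <- score_markers(sc$dataset, sc$metadata$region)
  panel <- select_top_delta_per_pair(ms, per_pair = 10)
  expect_length(panel$loci, 10L * 21L)
  expect_false(anyDuplicated(panel$loci) > 0)
})

test_that("reduce_panel equals exhaustive subset search on small panels", {
  set.seed(31)
  for (trial in 1:3) {
    delta <- matrix(runif(6 * 3), 6, 3,
                    dimnames = list(paste0("M", 1:6),
                                    c("a|b", "a|c", "b|c")))
    ms <- structure(list(locus_id = rownames(delta), In = runif(6),
                         delta = delta, groups = c("a", "b", "c"),
                         pairs = utils::combn(c("a", "b", "c"), 2),
                         excluded = character()),
                    class = "marker_scores")
    panel <- select_top_delta_per_pair(ms, per_pair = 2)
    full <- structure(list(loci = rownames(delta),
                           provenance = data.frame(
                             locus_id = rownames(delta), stage = "top_delta",
                             pair = NA, delta = NA, In = ms$In),
                           groups = ms$groups, config = NULL,
                           stage_counts = NULL),
                      class = "aim_panel")
    red <- reduce_panel(full, ms, target_size = 4)
    oracle <- oracle_best_subset(rownames(delta), ms, 4)
    got <- aimpanel:::.panel_objective(red$loci, ms)
    expect_equal(got, oracle$best_value, tolerance = 1e-12)
  }
})

test_that("reduce_panel respects identity, exclusions, and infeasibility", {
  delta <- matrix(seq(0.1, 0.9, length.out = 8), 8, 1,
                  dimnames = list(paste0("M", 1:8), "a|b"))
  ms <- structure(list(locus_id = rownames(delta), In = rep(0.2, 8),
                       delta = delta, groups = c("a", "b"),
                       pairs = matrix(c("a", "b"), 2, 1),
                       excluded = character()),
                  class = "marker_scores")
  panel <- structure(list(loci = rownames(delta),
                          provenance = data.frame(
                            locus_id = rownames(delta), stage = "top_delta",
                            pair = "a|b", delta = delta[, 1], In = 0.2),
                          groups = c("a", "b"), config = NULL,
                          stage_counts = NULL),
                     class = "aim_panel")
  expect_identical(reduce_panel(panel, ms, 8)$loci, panel$loci)
  red <- reduce_panel(panel, ms, 5, exclusion_list = "M8")
  expect_false("M8" %in% red$loci)
  expect_length(red$loci, 5L)
  expect_error(reduce_panel(panel, ms, 8, exclusion_list = "M1"), "below")
})

test_that("the full pipeline is deterministic and enriches high-delta markers", {
  cfg <- selection_config(top_n_by_In = 150, window_size = 20,
                          window_step = 5, per_pair = 2, target_size = 12)
  sc <- simulate_scenario(sim_config(L = 300, n_per_region = 15), seed = 17)
  expect_warning(p1 <- run_pipeline(sc$dataset, sc$metadata$region, cfg),
                 NA)
  p2 <- run_pipeline(sc$dataset, sc$metadata$region, cfg)
  expect_identical(p1$loci, p2$loci)
  # sample-order invariance
  perm <- sample(length(sc$dataset$sample_ids))
  ds_perm <- subset_dataset(sc$dataset, samples = perm)
  p3 <- run_pipeline(ds_perm, sc$metadata$region[perm], cfg)
  expect_identical(sort(p3$loci), sort(p1$loci))
  # every pair's best panel delta reaches that pair's genome-wide 90th pctile
  ms <- score_markers(sc$dataset, sc$metadata$region)
  panel_rows <- match(p1$loci, ms$locus_id)
  for (pair in colnames(ms$delta)) {
    expect_gte(max(ms$delta[panel_rows, pair]),
               stats::quantile(ms$delta[, pair], 0.9))
  }
})

test_that("oversized top_n proceeds with all loci and a warning", {
  sc <- simulate_scenario(sim_config(L = 60, n_per_region = 10), seed = 23)
  cfg <- selection_config(top_n_by_In = 10000, per_pair = 1, target_size = 5,
                          window_size = 10, window_step = 2)
  expect_warning(panel <- run_pipeline(sc$dataset, sc$metadata$region, cfg),
                 "exceeds")
  expect_length(panel$loci, 5L)
})
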
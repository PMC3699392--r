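#' Panel-selection configuration
#'
#' Defaults mirror the multi-stage design of a small multiplexable AIM panel:
#' keep the top 5,000 markers by In, LD-prune at VIF 1.5 (sliding window of 50
#' SNPs, step 5), claim the top 10 markers per group pair by delta, then reduce
#' to a 41-marker multiplex.
#'
#' @param top_n_by_In Cap on the In ranking (default 5000).
#' @param vif_threshold VIF pruning threshold, > 1 (default 1.5).
#' @param window_size,window_step Sliding window (SNPs) for VIF pruning.
#' @param per_pair Markers claimed per group pair (default 10).
#' @param target_size Final panel size (default 41).
#' @param exclusion_list Locus ids infeasible for multiplexing.
#' @param require_autosomal,require_unambiguous,require_on_array Candidate
#'   filters; see [filter_candidates()].
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(top_n_by_In = 5000L, vif_threshold = 1.5,
                             window_size = 50L, window_step = 5L,
                             per_pair = 10L, target_size = 41L,
                             exclusion_list = character(),
                             require_autosomal = TRUE,
                             require_unambiguous = TRUE,
                             require_on_array = FALSE) {
  if (vif_threshold <= 1) stop("vif_threshold must exceed 1")
  if (window_step > window_size) stop("window_step must be <= window_size")
  structure(list(top_n_by_In = as.integer(top_n_by_In),
                 vif_threshold = vif_threshold,
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 per_pair = as.integer(per_pair),
                 target_size = as.integer(target_size),
                 exclusion_list = as.character(exclusion_list),
                 require_autosomal = isTRUE(require_autosomal),
                 require_unambiguous = isTRUE(require_unambiguous),
                 require_on_array = isTRUE(require_on_array)),
            class = "selection_config")
}

#' Filter candidate loci
#'
#' Retains loci that are autosomal (chromosome 1-22), strand-unambiguous
#' (allele pair among A/C, A/G, T/C, T/G — i.e. not A/T or C/G, whose strand
#' cannot be resolved across genotyping platforms) and, optionally, flagged as
#' present on the genotyping array.
#'
#' @param loci Locus registry `data.frame` (see [genotype_dataset()]).
#' @param require_autosomal,require_unambiguous,require_on_array Logical.
#' @return Character vector of retained locus ids; attribute `"rejected"`
#'   holds counts per rejection reason.
#' @export
filter_candidates <- function(loci, require_autosomal = TRUE,
                              require_unambiguous = TRUE,
                              require_on_array = FALSE) {
  keep <- rep(TRUE, nrow(loci))
  rejected <- c(non_autosomal = 0L, ambiguous = 0L, off_array = 0L)
  if (require_autosomal) {
    ok <- loci$chromosome %in% as.character(1:22)
    rejected["non_autosomal"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (require_unambiguous) {
    pair <- paste0(pmin(loci$allele_a, loci$allele_b),
                   pmax(loci$allele_a, loci$allele_b))
    ok <- !(pair %in% c("AT", "CG"))
    rejected["ambiguous"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (require_on_array) {
    ok <- as.logical(loci$on_array)
    rejected["off_array"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  structure(loci$locus_id[keep], rejected = rejected)
}

# VIFs of a dosage window: diag of the inverse correlation matrix when it is
# invertible; on a singular window each locus's R^2 is recomputed by a
# pseudoinverse regression on the others (exact collinearity -> VIF Inf).
# Constant (monomorphic) columns have no LD signal: VIF 1.
.window_vifs <- function(X) {
  v <- apply(X, 2L, stats::var)
  out <- rep(1, ncol(X))
  use <- which(v > 1e-12)
  if (length(use) < 2L) return(out)
  Xu <- X[, use, drop = FALSE]
  R <- stats::cor(Xu)
  Ri <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(Ri) && all(is.finite(diag(Ri))) && all(diag(Ri) > 0)) {
    out[use] <- pmax(diag(Ri), 1)
    return(out)
  }
  Xc <- scale(Xu, center = TRUE, scale = FALSE)
  for (jj in seq_along(use)) {
    y <- Xc[, jj]
    Z <- Xc[, -jj, drop = FALSE]
    beta <- MASS::ginv(Z) %*% y
    r2 <- 1 - sum((y - Z %*% beta)^2) / sum(y^2)
    out[use[jj]] <- if (r2 >= 1 - 1e-12) Inf else max(1 / (1 - r2), 1)
  }
  out
}

#' LD pruning by variance inflation factor
#'
#' Sliding-window pruning: within each window of `window_size` retained loci
#' (ordered by chromosome and position), while any locus has
#' `VIF = 1/(1 - R^2) > vif_threshold` (R^2 = multiple correlation of that
#' locus's dosage on the other retained loci in the window), the locus with
#' the highest VIF is removed — permanently; the window then advances by
#' `window_step` loci. Dosages are mean-imputed per locus for the regression
#' only. Deterministic: VIF ties are broken by removing the later locus in
#' map order.
#'
#' @param dataset A [genotype_dataset].
#' @param window_size,window_step Window extent and step, in SNPs.
#' @param vif_threshold Retention threshold (default 1.5).
#' @return Character vector of retained locus ids, in map order.
#' @export
vif_prune <- function(dataset, window_size = 50L, window_step = 5L,
                      vif_threshold = 1.5) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  ord <- order(suppressWarnings(as.numeric(dataset$loci$chromosome)),
               dataset$loci$chromosome, dataset$loci$position)
  ids <- dataset$loci$locus_id[ord]
  X <- dataset$dosage[, ord, drop = FALSE]
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {            # mean-impute per locus
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- mean(X[, j], na.rm = TRUE)
  }
  X[is.nan(X)] <- 0
  alive <- rep(TRUE, length(ids))
  start <- 1L
  repeat {
    pool <- which(alive)
    if (length(pool) < 2L || start > length(pool)) break
    end <- min(start + window_size - 1L, length(pool))
    win <- pool[start:end]
    if (length(win) >= 2L) {
      repeat {
        vifs <- .window_vifs(X[, win, drop = FALSE])
        worst <- max(vifs)
        if (worst <= vif_threshold) break
        drop_local <- max(which(vifs == worst))   # tie -> later in map order
        alive[win[drop_local]] <- FALSE
        win <- win[-drop_local]
        if (length(win) < 2L) break
      }
    }
    if (end >= length(pool)) break  # window reached the end of the map
    start <- start + window_step
  }
  ids[alive]
}

#' Select the top-delta markers for every group pair
#'
#' For each group pair (processed in a fixed order: ascending index of the
#' first group, then of the second, in the score object's group order), walk
#' that pair's delta-descending ranking and claim the top `per_pair` markers
#' not yet claimed by an earlier pair. With enough distinct markers the union
#' has exactly `per_pair * n_pairs` loci; each locus's provenance records the
#' claiming pair and its delta.
#'
#' @param scores A `marker_scores` object (all loci eligible).
#' @param per_pair Markers claimed per pair (default 10).
#' @return An `aim_panel` object (see [run_pipeline()]) with stage
#'   `"top_delta"` provenance.
#' @export
select_top_delta_per_pair <- function(scores, per_pair = 10L) {
  stopifnot(inherits(scores, "marker_scores"), per_pair >= 1L)
  pair_names <- colnames(scores$delta)
  claimed <- character()
  prov <- list()
  for (pn in pair_names) {
    d <- scores$delta[, pn]
    ord <- order(-d, scores$locus_id)
    want <- setdiff(scores$locus_id[ord], claimed)
    take <- utils::head(want, per_pair)
    if (length(take) < per_pair)
      warning("pair ", pn, ": only ", length(take),
              " unclaimed markers available (wanted ", per_pair, ")")
    claimed <- c(claimed, take)
    if (length(take) == 0L) next
    prov[[pn]] <- data.frame(locus_id = take, stage = "top_delta", pair = pn,
                             delta = unname(d[match(take, scores$locus_id)]),
                             stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, prov)
  rownames(prov) <- NULL
  prov$In <- scores$In[match(prov$locus_id, scores$locus_id)]
  new_aim_panel(prov$locus_id, prov, scores)
}

new_aim_panel <- function(loci, provenance, scores, config = NULL,
                          stage_counts = NULL) {
  structure(list(loci = loci, provenance = provenance,
                 groups = scores$groups, config = config,
                 stage_counts = stage_counts),
            class = "aim_panel")
}

#' @export
print.aim_panel <- function(x, ...) {
  cat("aim_panel:", length(x$loci), "markers for",
      length(x$groups), "groups\n")
  if (!is.null(x$stage_counts)) {
    cat("stage counts:\n")
    for (nm in names(x$stage_counts))
      cat("  ", nm, ": ", x$stage_counts[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.aim_panel <- function(x, ...) {
  x$provenance[match(x$loci, x$provenance$locus_id), , drop = FALSE]
}

# Panel objective: minimum over group pairs of the sum of the top-3 retained
# deltas for that pair. Rewards keeping several high-delta markers per pair.
.panel_objective <- function(locus_ids, scores) {
  d <- scores$delta[match(locus_ids, scores$locus_id), , drop = FALSE]
  min(apply(d, 2L, function(col) sum(utils::head(sort(col, decreasing = TRUE),
                                                 3L))))
}

#' Reduce a panel to multiplex size
#'
#' First removes loci on `exclusion_list` (encoding real multiplex-chemistry
#' constraints), then maximizes the panel objective — the minimum over group
#' pairs of the sum of the top-3 retained deltas for that pair — over
#' `target_size`-subsets. Small problems (at most `exact_limit` candidate
#' subsets) are solved exactly by enumeration; larger ones by greedy backward
#' elimination, repeatedly deleting the locus whose removal maximizes the
#' objective. Ties are broken by lower In, then by locus id, so the reduction
#' is deterministic.
#'
#' @param panel An `aim_panel`.
#' @param scores The `marker_scores` used to build the panel.
#' @param target_size Final size (default 41).
#' @param exclusion_list Locus ids removed up front.
#' @param exact_limit Enumerate all subsets when `choose(n, target_size)` is
#'   at most this (default 20000); otherwise reduce greedily.
#' @return A reduced `aim_panel`; removed loci are dropped from provenance and
#'   survivors gain stage `"reduced"` provenance rows.
#' @export
reduce_panel <- function(panel, scores, target_size = 41L,
                         exclusion_list = character(), exact_limit = 20000) {
  stopifnot(inherits(panel, "aim_panel"), inherits(scores, "marker_scores"))
  keep <- setdiff(panel$loci, exclusion_list)
  if (length(keep) < target_size)
    stop("exclusions leave ", length(keep), " loci, below target_size ",
         target_size)
  if (length(keep) > target_size &&
      choose(length(keep), target_size) <= exact_limit) {
    subsets <- utils::combn(keep, target_size, simplify = FALSE)
    vals <- vapply(subsets, .panel_objective, numeric(1L), scores = scores)
    # deterministic tie-break: among optimal subsets take lowest total In,
    # then the lexicographically smallest id set
    best <- which(vals == max(vals))
    if (length(best) > 1L) {
      tot_in <- vapply(subsets[best], function(s)
        sum(scores$In[match(s, scores$locus_id)]), numeric(1L))
      keys <- vapply(subsets[best], function(s)
        paste(sort(s), collapse = "\r"), character(1L))
      best <- best[order(tot_in, keys)][1L]
    }
    keep <- keep[keep %in% subsets[[best]]]
  }
  while (length(keep) > target_size) {
    obj <- vapply(seq_along(keep), function(i)
      .panel_objective(keep[-i], scores), numeric(1L))
    In <- scores$In[match(keep, scores$locus_id)]
    best <- order(-obj, In, keep)[1L]  # max objective; ties: lower In, then id
    keep <- keep[-best]
  }
  prov <- panel$provenance[panel$provenance$locus_id %in% keep, , drop = FALSE]
  new_aim_panel(keep, prov, scores, config = panel$config,
                stage_counts = panel$stage_counts)
}

#' Run the full panel-selection pipeline
#'
#' filter candidates -> score markers -> cap at the top `top_n_by_In` by In ->
#' VIF LD pruning -> claim the top `per_pair` markers per group pair by delta
#' -> iterative reduction to `target_size`. Per-stage marker counts are kept
#' on the returned panel.
#'
#' @param dataset A [genotype_dataset].
#' @param labels Group labels per sample (e.g. continental region).
#' @param config A [selection_config()].
#' @return An `aim_panel` with per-locus provenance, the config snapshot and
#'   per-stage counts.
#' @export
run_pipeline <- function(dataset, labels, config = selection_config()) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "selection_config"))
  counts <- list(input = nrow(dataset$loci))
  cand <- filter_candidates(dataset$loci, config$require_autosomal,
                            config$require_unambiguous,
                            config$require_on_array)
  counts$candidates <- length(cand)
  ds <- subset_dataset(dataset, loci = as.character(cand))
  scores <- score_markers(ds, labels)
  counts$scored <- length(scores$locus_id)
  top_n <- config$top_n_by_In
  if (top_n > length(scores$locus_id)) {
    warning("top_n_by_In = ", top_n, " exceeds scored loci (",
            length(scores$locus_id), "); using all")
    top_n <- length(scores$locus_id)
  }
  top_ids <- rank_markers(scores, "In", top_n)
  counts$top_In <- length(top_ids)
  ds_top <- subset_dataset(ds, loci = top_ids)
  pruned <- vif_prune(ds_top, config$window_size, config$window_step,
                      config$vif_threshold)
  counts$vif_pruned <- length(pruned)
  sc_pruned <- subset_scores(scores, pruned)
  panel <- select_top_delta_per_pair(sc_pruned, config$per_pair)
  counts$top_delta <- length(panel$loci)
  panel <- reduce_panel(panel, sc_pruned,
                        min(config$target_size, length(panel$loci)),
                        config$exclusion_list)
  counts$final <- length(panel$loci)
  panel$config <- config
  panel$stage_counts <- counts
  panel
}

# Restrict a marker_scores object to a subset of loci (kept in given order).
subset_scores <- function(scores, locus_ids) {
  idx <- match(locus_ids, scores$locus_id)
  if (anyNA(idx)) stop("unknown locus id(s) in subset")
  structure(list(locus_id = scores$locus_id[idx], In = scores$In[idx],
                 delta = scores$delta[idx, , drop = FALSE],
                 groups = scores$groups, pairs = scores$pairs,
                 excluded = scores$excluded),
            class = "marker_scores")
}

#' Write a panel as TSV
#'
#' Columns: locus_id, stage, claiming pair, delta at admission, In.
#'
#' @param panel An `aim_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
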
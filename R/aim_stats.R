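#' Informativeness for assignment (In)
#'
#' Rosenberg's entropy-based informativeness of a biallelic marker for
#' assignment among K predefined groups. With group frequencies `p_i` of the
#' counted allele, unweighted mean `pbar = mean(p)` and `j` ranging over the
#' two alleles (frequencies `p` and `1 - p`),
#' `In = sum_j ( -pbar_j * log(pbar_j) + mean_i( p_ij * log(p_ij) ) )`
#' with `0 * log(0) := 0`. Natural-log units: `0 <= In <= log(K)`, 0 iff all
#' groups share the same frequency. Groups enter unweighted (sample sizes do
#' not weight the mean).
#'
#' @param p Numeric vector of K counted-allele frequencies (K >= 2), or a
#'   matrix with one locus per row.
#' @return A single In value, or a vector (one per row) for matrix input.
#' @export
#' @examples
#' informativeness(c(1, 0))            # log(2): maximal biallelic divergence
#' informativeness(c(0.4, 0.4, 0.4))   # 0: no information
informativeness <- function(p) {
  if (is.matrix(p)) return(apply(p, 1L, informativeness))
  if (length(p) < 2L) stop("In requires K >= 2 group frequencies")
  if (anyNA(p)) stop("In requires all group frequencies defined")
  if (any(p < 0 | p > 1)) stop("frequencies must lie in [0, 1]")
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  total <- 0
  for (q in list(p, 1 - p)) {
    qbar <- mean(q)
    total <- total + (-xlogx(qbar) + mean(xlogx(q)))
  }
  total
}

#' Pairwise allele-frequency differences (delta)
#'
#' `delta = |p_i - p_k|` of the counted allele for each group pair — for a
#' biallelic marker this equals half the L1 distance over both alleles. Pairs
#' with an undefined frequency get `NA`.
#'
#' @param p Named numeric vector of K group frequencies.
#' @param pairs 2-row character matrix of group pairs (default: all unordered
#'   pairs in ascending group order).
#' @return Named numeric vector of deltas, names `"<g1>|<g2>"`.
#' @export
pairwise_delta <- function(p, pairs = NULL) {
  if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  if (is.null(pairs)) pairs <- utils::combn(names(p), 2L)
  d <- abs(p[pairs[1L, ]] - p[pairs[2L, ]])
  stats::setNames(as.numeric(d), paste(pairs[1L, ], pairs[2L, ], sep = "|"))
}

#' Score all markers: In and pairwise deltas
#'
#' Computes per-locus informativeness for assignment and all 21 (for K = 7)
#' pairwise deltas from pooled group frequencies. Loci with an undefined
#' frequency in any group are excluded from scoring and reported separately.
#'
#' @param dataset A [genotype_dataset], or a `freq_table` from
#'   [group_allele_freqs()].
#' @param labels Group labels per sample (ignored for `freq_table` input).
#' @return An object of class `marker_scores`: list with `locus_id`, `In`
#'   (numeric), `delta` (loci x pairs matrix, columns `"<g1>|<g2>"`), `groups`,
#'   `pairs` (2 x P character matrix) and `excluded` (locus ids dropped for
#'   undefined frequencies).
#' @export
score_markers <- function(dataset, labels = NULL) {
  ft <- if (inherits(dataset, "freq_table")) dataset
        else group_allele_freqs(dataset, labels)
  if (ncol(ft$freq) < 2L) stop("scoring requires >= 2 groups")
  defined <- rowSums(is.na(ft$freq)) == 0L
  excluded <- rownames(ft$freq)[!defined]
  if (length(excluded) > 0L)
    warning(length(excluded),
            " locus/loci excluded for undefined group frequencies")
  fr <- ft$freq[defined, , drop = FALSE]
  groups <- colnames(fr)
  pairs <- utils::combn(groups, 2L)
  In <- informativeness(fr)
  delta <- abs(fr[, pairs[1L, ], drop = FALSE] -
               fr[, pairs[2L, ], drop = FALSE])
  colnames(delta) <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  structure(list(locus_id = rownames(fr), In = unname(In), delta = delta,
                 groups = groups, pairs = pairs, excluded = excluded),
            class = "marker_scores")
}

#' @export
print.marker_scores <- function(x, ...) {
  cat("marker_scores:", length(x$locus_id), "loci,", length(x$groups),
      "groups (", ncol(x$delta), "pairs );",
      length(x$excluded), "excluded\n")
  cat("In: mean", round(mean(x$In), 4), " range",
      round(min(x$In), 4), "-", round(max(x$In), 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.marker_scores <- function(x, ...) {
  data.frame(locus_id = x$locus_id, In = x$In, x$delta,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Rank markers by In or by one pair's delta
#'
#' Descending stable sort; ties broken by `locus_id` lexicographic order so
#' rankings are deterministic.
#'
#' @param scores A `marker_scores` object.
#' @param by `"In"` (default) or a delta column name `"<g1>|<g2>"`.
#' @param top_n Number of loci to return; if it exceeds the available loci,
#'   all are returned with a warning.
#' @return Character vector of locus ids, best first.
#' @export
rank_markers <- function(scores, by = "In", top_n = length(scores$locus_id)) {
  stopifnot(inherits(scores, "marker_scores"), top_n >= 1L)
  key <- if (identical(by, "In")) scores$In else {
    if (!by %in% colnames(scores$delta))
      stop("unknown ranking key: ", by)
    scores$delta[, by]
  }
  ord <- order(-key, scores$locus_id)
  if (top_n > length(ord)) {
    warning("top_n = ", top_n, " exceeds available loci (", length(ord),
            "); returning all")
    top_n <- length(ord)
  }
  scores$locus_id[ord[seq_len(top_n)]]
}

#' Write / read marker scores as TSV
#'
#' Layout: `locus_id`, `In`, then one delta column per group pair. This is the
#' layout of a published 41-AIM score table, so such tables can be read back
#' as `marker_scores` for summaries and panel work.
#'
#' @param scores A `marker_scores` object.
#' @param path TSV path.
#' @return `write_marker_scores`: invisibly, `path`. `read_marker_scores`: a
#'   `marker_scores` object.
#' @export
write_marker_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_scores
#' @export
read_marker_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("locus_id", "In") %in% names(df)))
    stop("marker-score table must have locus_id and In columns")
  dcols <- grep("|", names(df), fixed = TRUE, value = TRUE)
  delta <- as.matrix(df[, dcols, drop = FALSE])
  rownames(delta) <- df$locus_id
  pairs <- vapply(strsplit(dcols, "|", fixed = TRUE), identity, character(2L))
  groups <- sort(unique(as.vector(pairs)))
  structure(list(locus_id = df$locus_id, In = df$In, delta = delta,
                 groups = groups, pairs = pairs, excluded = character()),
            class = "marker_scores")
}
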
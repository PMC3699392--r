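#' Simulation configuration
#'
#' Defines a multi-region Balding-Nichols scenario with optional admixed
#' groups. The packaged default mimics a 7-continental-region study: per-region
#' divergence F chosen so Eurasian pairs (Middle East, Europe, CS Asia) are the
#' least differentiated and Africa/East Asia/Americas/Oceania the most, 50
#' samples per region, plus two admixed series (Europe/Africa and
#' Europe/Americas mixtures with ancestry fractions spanning 0.05-0.95).
#'
#' @param L Number of loci (default 2000).
#' @param regions Region labels (default [default_regions()]).
#' @param F Per-region divergence in (0,1), one per region. Default
#'   `c(0.15, 0.03, 0.03, 0.05, 0.10, 0.20, 0.18)` in the default region
#'   order.
#' @param p_range Ancestral-frequency range (default `c(0.1, 0.9)`).
#' @param n_per_region Samples per unadmixed region (default 50).
#' @param admixed List of admixed groups, each a list with `name`, `q` (named
#'   ancestry vector on the simplex, names from `regions`) and `count`.
#' @param missing_rate i.i.d. missing-genotype rate in [0,1) (default 0).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 2000L, regions = default_regions(),
                       F = c(0.15, 0.03, 0.03, 0.05, 0.10, 0.20, 0.18),
                       p_range = c(0.1, 0.9), n_per_region = 50L,
                       admixed = list(), missing_rate = 0) {
  if (length(F) != length(regions))
    stop("F must give one divergence per region")
  if (any(F <= 0 | F >= 1)) stop("all F must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  admixed <- lapply(admixed, function(g) {
    g$q <- unlist(g$q)   # tolerate YAML-style nested lists
    g$count <- as.integer(g$count)
    g
  })
  for (g in admixed) {
    if (!all(names(g$q) %in% regions)) stop("admixed q names must be regions")
    if (abs(sum(g$q) - 1) > 1e-8) stop("admixed q must sum to 1")
  }
  structure(list(L = as.integer(L), regions = regions, F = F,
                 p_range = p_range, n_per_region = as.integer(n_per_region),
                 admixed = admixed, missing_rate = missing_rate),
            class = "sim_config")
}

#' Balding-Nichols region allele frequencies
#'
#' For each locus an ancestral frequency p is drawn uniformly on `p_range`;
#' region k's frequency is then Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k), so the
#' expected Weir-Cockerham FST of region k against the ancestral pool is F_k.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is reproducible.
#' @return List with `p_anc` (length L) and `p_region` (L x K matrix, columns
#'   named by region).
#' @export
balding_nichols_freqs <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  L <- config$L
  p_anc <- stats::runif(L, config$p_range[1L], config$p_range[2L])
  K <- length(config$regions)
  p_region <- matrix(NA_real_, L, K,
                     dimnames = list(paste0("rs", seq_len(L)),
                                     config$regions))
  for (k in seq_len(K)) {
    Fk <- config$F[k]
    p_region[, k] <- stats::rbeta(L, p_anc * (1 - Fk) / Fk,
                                  (1 - p_anc) * (1 - Fk) / Fk)
  }
  list(p_anc = p_anc, p_region = p_region)
}

#' Sample genotypes under the admixture model
#'
#' Each of a sample's two allele copies at each locus independently draws its
#' ancestral region from the sample's q and then the counted allele from that
#' region's frequency. Missingness is applied i.i.d. at `missing_rate`. Loci
#' are assigned round-robin to chromosomes 1-22 with 1 Mb spacing so the map
#' exercises windowed procedures.
#'
#' @param p_region Loci x K region frequency matrix (columns named).
#' @param Q Samples x K matrix of true ancestry proportions (rows on the
#'   simplex), rownames = sample ids.
#' @param missing_rate i.i.d. missing rate in [0,1).
#' @param seed Integer seed.
#' @return List with `dataset` (a [genotype_dataset]) and `truth` (list:
#'   `Q`, `p_region`, `labels` — the majority region per sample).
#' @export
sample_genotypes <- function(p_region, Q, missing_rate = 0, seed = 1L) {
  Q <- as.matrix(Q)
  if (ncol(Q) != ncol(p_region)) stop("Q and p_region disagree on K")
  if (any(abs(rowSums(Q) - 1) > 1e-8)) stop("Q rows must sum to 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(Q); L <- nrow(p_region); K <- ncol(p_region)
  if (is.null(rownames(Q))) rownames(Q) <- sprintf("S%04d", seq_len(n))
  if (is.null(rownames(p_region)))
    rownames(p_region) <- paste0("rs", seq_len(L))
  dosage <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g <- 0L
    for (copy in 1:2) {
      z <- sample.int(K, L, replace = TRUE, prob = Q[i, ])
      g <- g + (stats::runif(L) < p_region[cbind(seq_len(L), z)])
    }
    dosage[i, ] <- as.integer(g)
  }
  if (missing_rate > 0)
    dosage[matrix(stats::runif(n * L) < missing_rate, n, L)] <- NA_integer_
  pair_pool <- c("A", "C", "A", "G", "T", "C", "T", "G")
  pick <- (seq_len(L) - 1L) %% 4L
  loci <- data.frame(
    locus_id = rownames(p_region),
    chromosome = as.character(((seq_len(L) - 1L) %% 22L) + 1L),
    position = as.integer(((seq_len(L) - 1L) %/% 22L + 1L) * 1e6L),
    allele_a = pair_pool[2L * pick + 1L],
    allele_b = pair_pool[2L * pick + 2L],
    on_array = TRUE, stringsAsFactors = FALSE)
  labels <- colnames(p_region)[max.col(Q, ties.method = "first")]
  list(dataset = genotype_dataset(dosage, loci, rownames(Q)),
       truth = list(Q = Q, p_region = p_region,
                    labels = stats::setNames(labels, rownames(Q))))
}

#' Simulate a complete study scenario
#'
#' Draws region frequencies, builds the sample sheet (n_per_region unadmixed
#' samples per region plus any admixed groups) and samples genotypes. The
#' default configuration is the package's standard truth-known test surface.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return List of class `sim_scenario`: `dataset` (a [genotype_dataset]),
#'   `metadata` (`data.frame` sample_id/population/region), `truth` (true Q,
#'   region frequencies, ancestral frequencies), `config`, `seed`.
#' @export
simulate_scenario <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  fr <- balding_nichols_freqs(config, seed = seed)
  K <- length(config$regions)
  qs <- list(); pops <- character(); regs <- character()
  for (k in seq_len(K)) {
    q <- rep(0, K); q[k] <- 1
    for (i in seq_len(config$n_per_region)) qs[[length(qs) + 1L]] <- q
    pops <- c(pops, rep(paste0(config$regions[k], "_pop"),
                        config$n_per_region))
    regs <- c(regs, rep(config$regions[k], config$n_per_region))
  }
  for (g in config$admixed) {
    q <- rep(0, K)
    q[match(names(g$q), config$regions)] <- g$q
    main <- config$regions[which.max(q)]
    for (i in seq_len(g$count)) qs[[length(qs) + 1L]] <- q
    pops <- c(pops, rep(g$name, g$count))
    regs <- c(regs, rep(main, g$count))
  }
  Q <- do.call(rbind, qs)
  colnames(Q) <- config$regions
  rownames(Q) <- sprintf("S%04d", seq_len(nrow(Q)))
  sg <- sample_genotypes(fr$p_region, Q, config$missing_rate,
                         seed = seed + 1L)
  metadata <- data.frame(sample_id = rownames(Q), population = pops,
                         region = regs, stringsAsFactors = FALSE)
  structure(list(dataset = sg$dataset, metadata = metadata,
                 truth = list(Q = Q, p_region = fr$p_region,
                              p_anc = fr$p_anc),
                 config = config, seed = seed),
            class = "sim_scenario")
}

#' Default admixed groups for the packaged scenario
#'
#' Two admixed series echoing common two-way admixture settings: Europe/Africa
#' and Europe/Americas mixtures with the minor-ancestry fraction spanning
#' 0.05-0.95 in steps of 0.05 (2 individuals per value, 38 per series).
#'
#' @param per_value Individuals per ancestry fraction (default 2).
#' @return List suitable for `sim_config(admixed = ...)`.
#' @export
default_admixed_groups <- function(per_value = 2L) {
  fracs <- seq(0.05, 0.95, by = 0.05)
  out <- list()
  for (spec in list(c("Africa", "AfrEur_admixed"),
                    c("Americas", "AmerEur_admixed"))) {
    for (f in fracs) {
      q <- stats::setNames(c(f, 1 - f), c(spec[1L], "Europe"))
      out[[length(out) + 1L]] <- list(name = spec[2L], q = q,
                                      count = per_value)
    }
  }
  out
}

#' Write a simulated scenario to disk
#'
#' Produces a complete, CLI-consumable scenario: PED/MAP genotypes, a
#' metadata TSV and a truth TSV (true ancestry proportions per sample).
#' Regenerating with the same config and seed yields byte-identical files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the scenario (see [simulate_scenario()]); files
#'   `genotypes.ped`, `genotypes.map`, `metadata.tsv`, `truth.tsv` in
#'   `outdir`.
#' @export
make_reference_scenario <- function(config = sim_config(), outdir,
                                    seed = 1L) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  sc <- simulate_scenario(config, seed = seed)
  write_ped_map(sc$dataset, file.path(outdir, "genotypes.ped"),
                file.path(outdir, "genotypes.map"))
  write_metadata(sc$metadata, file.path(outdir, "metadata.tsv"))
  truth <- data.frame(sample_id = rownames(sc$truth$Q),
                      round(sc$truth$Q, 6), check.names = FALSE,
                      stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(outdir, "truth.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(sc)
}
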
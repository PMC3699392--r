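#' Default continental region set
#'
#' The seven continental regions used throughout: Africa, the Middle East,
#' Europe, Central/South Asia, East Asia, the Americas and Oceania. An eighth
#' region ("Siberia") can be added by passing `extra`; populations such as the
#' western-Siberian Khanty do not fit any of the seven default clusters.
#'
#' @param extra Character vector of additional region labels (e.g. "Siberia").
#' @return Character vector of region labels.
#' @export
#' @examples
#' default_regions()
#' default_regions(extra = "Siberia")
default_regions <- function(extra = character()) {
  c("Africa", "Middle East", "Europe", "CS Asia", "E Asia", "Americas",
    "Oceania", extra)
}

#' Construct a genotype dataset
#'
#' The central container: a samples x loci matrix of counted-allele dosages
#' (0, 1, 2 or `NA` for missing) plus a locus registry. The counted allele of
#' every locus is `allele_a`; all downstream frequencies, deltas, In values and
#' FST components refer to it.
#'
#' @param dosage Integer matrix, samples x loci, entries in `{0,1,2,NA}`.
#' @param loci `data.frame` with columns `locus_id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b` and optionally `on_array` (logical; default `TRUE`).
#' @param sample_ids Character vector, one id per dosage row.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosage`, `loci`, `sample_ids`.
#' @export
genotype_dataset <- function(dosage, loci, sample_ids) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("locus_id", "chromosome", "position", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0L)
    stop("locus registry lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"on_array" %in% names(loci)) loci$on_array <- TRUE
  loci$chromosome <- as.character(loci$chromosome)
  loci$position <- as.integer(loci$position)
  if (anyDuplicated(loci$locus_id))
    stop("duplicate locus_id in locus registry")
  if (any(loci$allele_a == loci$allele_b))
    stop("allele_a must differ from allele_b at every locus")
  if (any(!is.na(loci$position) & loci$position < 1L))
    stop("positions must be >= 1 (1-based)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_id")
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != nrow(loci))
    stop("dosage dimensions (", nrow(dosage), " x ", ncol(dosage),
         ") do not match registries (", length(sample_ids), " samples, ",
         nrow(loci), " loci)")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L))
    stop("non-missing dosages must be in {0, 1, 2}")
  dimnames(dosage) <- list(sample_ids, loci$locus_id)
  structure(list(dosage = dosage, loci = loci,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$dosage))
  cat("genotype_dataset:", length(x$sample_ids), "samples x",
      nrow(x$loci), "loci;",
      sprintf("%.2f%% missing\n", 100 * n_miss / length(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

#' Subset a genotype dataset
#'
#' @param x A `genotype_dataset`.
#' @param samples Sample ids or indices to keep (default all).
#' @param loci Locus ids or indices to keep (default all).
#' @return A `genotype_dataset` restricted to the requested samples and loci.
#' @export
subset_dataset <- function(x, samples = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  li <- if (is.null(loci)) seq_len(nrow(x$loci)) else {
    if (is.character(loci)) match(loci, x$loci$locus_id) else loci
  }
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(li)) stop("unknown locus id(s)")
  genotype_dataset(x$dosage[si, li, drop = FALSE],
                   x$loci[li, , drop = FALSE],
                   x$sample_ids[si])
}

#' Read PED/MAP genotype files
#'
#' Parses whitespace-delimited PED (six leading pedigree columns, then two
#' allele columns per locus; "0" = missing allele call) plus the matching
#' 4-column MAP (chromosome, locus id, genetic distance, base-pair position).
#' A half-missing genotype (exactly one allele "0") is treated as fully
#' missing. The counted allele of each locus is the first non-missing allele
#' observed in file order unless `counted_alleles` supplies one per locus.
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @param counted_alleles Optional named character vector, `locus_id` ->
#'   counted allele, overriding the first-observed convention.
#' @return A [genotype_dataset].
#' @export
read_ped_map <- function(ped_path, map_path, counted_alleles = NULL) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "locus_id", "cm",
                                         "position"),
                           colClasses = c("character", "character", "numeric",
                                          "integer"))
  if (anyDuplicated(map$locus_id)) stop("duplicate locus_id in MAP")
  n_loci <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("empty PED file: ", ped_path)
  a1 <- matrix("0", n, n_loci)
  a2 <- matrix("0", n, n_loci)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * n_loci)
      stop("PED row ", i, " has ", length(f), " fields; expected ",
           6L + 2L * n_loci, " for ", n_loci, " MAP loci")
    sample_ids[i] <- f[2L]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, by = 2L, length.out = n_loci)]
    a2[i, ] <- al[seq(2L, by = 2L, length.out = n_loci)]
  }
  dosage <- matrix(NA_integer_, n, n_loci)
  allele_a <- character(n_loci)
  allele_b <- character(n_loci)
  for (j in seq_len(n_loci)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs_int <- c(rbind(x1, x2))  # interleaved: file (reading) order
    obs_int <- obs_int[obs_int != "0"]
    alleles <- unique(obs_int)
    if (length(alleles) > 2L)
      stop("locus ", map$locus_id[j], " has >2 alleles: ",
           paste(alleles, collapse = ","))
    counted <- if (!is.null(counted_alleles) &&
                   map$locus_id[j] %in% names(counted_alleles)) {
      counted_alleles[[map$locus_id[j]]]
    } else if (length(alleles) >= 1L) alleles[1L] else "A"
    other <- setdiff(alleles, counted)
    if (length(other) == 0L) other <- setdiff(c("A", "C", "G", "T"), counted)[1L]
    bad <- !miss & !(x1 %in% c(counted, other)) |
           !miss & !(x2 %in% c(counted, other))
    if (any(bad))
      stop("unexpected allele at locus ", map$locus_id[j], " in sample ",
           sample_ids[which(bad)[1L]])
    dosage[, j] <- ifelse(miss, NA_integer_,
                          (x1 == counted) + (x2 == counted))
    allele_a[j] <- counted
    allele_b[j] <- other
  }
  loci <- data.frame(locus_id = map$locus_id, chromosome = map$chromosome,
                     position = map$position, allele_a = allele_a,
                     allele_b = allele_b, on_array = TRUE,
                     stringsAsFactors = FALSE)
  genotype_dataset(dosage, loci, sample_ids)
}

#' Write PED/MAP genotype files
#'
#' Inverse of [read_ped_map()]; round-trips dosages and missingness exactly.
#'
#' @param dataset A [genotype_dataset].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  loci <- dataset$loci
  map <- data.frame(loci$chromosome, loci$locus_id, 0, loci$position)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- length(dataset$sample_ids)
  out <- character(n)
  for (i in seq_len(n)) {
    g <- dataset$dosage[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, loci$allele_a, loci$allele_b))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, loci$allele_a, loci$allele_b))
    out[i] <- paste(c("FAM", dataset$sample_ids[i], "0", "0", "0", "-9",
                      as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(out, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read biallelic SNPs from a VCF file
#'
#' Wraps `vcfR::read.vcfR`. GT fields are mapped to REF-allele dosage (the
#' counted allele is REF), `./.` to missing. Multiallelic records are skipped
#' with a warning, or rejected if `multiallelic = "error"`.
#'
#' @param vcf_path Path to a VCF file.
#' @param multiallelic One of "skip" (default) or "error".
#' @return A [genotype_dataset].
#' @export
read_vcf <- function(vcf_path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1L |
    nchar(fix[, "ALT"]) != 1L
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic/non-SNP records present: ",
           paste(fix[multi, "ID"], collapse = ","))
    warning(sum(multi), " multiallelic/non-SNP record(s) skipped")
  }
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no biallelic SNP records in ", vcf_path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT format field")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # REF-allele dosage: count "0" alleles in the GT string
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "0")
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  loci <- data.frame(locus_id = ids, chromosome = fix[, "CHROM"],
                     position = as.integer(fix[, "POS"]),
                     allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                     on_array = TRUE, stringsAsFactors = FALSE)
  genotype_dataset(t(dos), loci, colnames(gt))
}

#' Read a sample metadata table
#'
#' TSV with header columns `sample_id`, `population`, `region`. Every region
#' label must belong to `region_set`.
#'
#' @param tsv_path Path to the TSV file.
#' @param region_set Allowed region labels; see [default_regions()].
#' @return `data.frame` with columns `sample_id`, `population`, `region`.
#' @export
read_metadata <- function(tsv_path, region_set = default_regions()) {
  md <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("sample_id", "population", "region")
  if (!all(required %in% names(md)))
    stop("metadata must have columns: ", paste(required, collapse = ", "))
  if (nrow(md) == 0L) {
    warning("empty metadata file: ", tsv_path)
    return(md[, required])
  }
  bad <- setdiff(unique(md$region), region_set)
  if (length(bad) > 0L)
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         " (declared set: ", paste(region_set, collapse = ", "), ")")
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup) > 0L)
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  md[, required]
}

#' Write a sample metadata table
#'
#' @param metadata `data.frame` with `sample_id`, `population`, `region`.
#' @param tsv_path Output path.
#' @return Invisibly, `tsv_path`.
#' @export
write_metadata <- function(metadata, tsv_path) {
  utils::write.table(metadata, tsv_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(tsv_path)
}

#' Group allele frequencies
#'
#' Pools the individuals of each group and computes the counted-allele
#' frequency per locus: counted-allele count among non-missing genotypes
#' divided by twice the non-missing sample count. Cells with zero non-missing
#' calls are flagged undefined (`NA` frequency, count 0) rather than set to 0.
#'
#' @param dataset A [genotype_dataset].
#' @param labels Character/factor vector assigning each sample to one group.
#' @return An object of class `freq_table`: list with `freq` (loci x groups,
#'   `NA` where undefined), `count` (loci x groups, observed allele counts
#'   `2 * n_nonmissing`), `counted_allele`, and `loci`.
#' @export
group_allele_freqs <- function(dataset, labels) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (length(labels) != length(dataset$sample_ids))
    stop("labels length (", length(labels), ") != sample count (",
         length(dataset$sample_ids), ")")
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must not contain NA")
  groups <- sort(unique(labels))
  L <- nrow(dataset$loci)
  freq <- matrix(NA_real_, L, length(groups),
                 dimnames = list(dataset$loci$locus_id, groups))
  count <- matrix(0L, L, length(groups),
                  dimnames = list(dataset$loci$locus_id, groups))
  for (gi in seq_along(groups)) {
    d <- dataset$dosage[labels == groups[gi], , drop = FALSE]
    n_obs <- colSums(!is.na(d))
    alle <- colSums(d, na.rm = TRUE)
    count[, gi] <- as.integer(2L * n_obs)
    freq[, gi] <- ifelse(n_obs > 0L, alle / (2 * n_obs), NA_real_)
  }
  structure(list(freq = freq, count = count,
                 counted_allele = dataset$loci$allele_a,
                 loci = dataset$loci$locus_id),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", nrow(x$freq), "loci x", ncol(x$freq), "groups (",
      paste(colnames(x$freq), collapse = ", "), ");",
      sum(is.na(x$freq)), "undefined cell(s)\n")
  invisible(x)
}

#' Write / read an allele-frequency table
#'
#' TSV round-trip lossless at 6 decimal places. The header records group
#' names; each locus row carries the counted allele, then per group a
#' frequency and an observed allele count. Undefined cells (count 0) are
#' written as `NA` and round-trip as undefined.
#'
#' @param table A `freq_table` from [group_allele_freqs()].
#' @param path Output (or input) TSV path.
#' @return `write_freq_table`: invisibly, `path`. `read_freq_table`: a
#'   `freq_table`.
#' @export
write_freq_table <- function(table, path) {
  stopifnot(inherits(table, "freq_table"))
  groups <- colnames(table$freq)
  df <- data.frame(locus_id = table$loci,
                   counted_allele = table$counted_allele,
                   stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    df[[paste0("freq.", groups[g])]] <- round(table$freq[, g], 6)
    df[[paste0("count.", groups[g])]] <- table$count[, g]
  }
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  fcols <- grep("^freq\\.", names(df), value = TRUE)
  ccols <- grep("^count\\.", names(df), value = TRUE)
  if (!all(c("locus_id", "counted_allele") %in% names(df)) ||
      length(fcols) == 0L || length(fcols) != length(ccols))
    stop("malformed frequency-table header in ", path)
  groups <- sub("^freq\\.", "", fcols)
  if (!identical(groups, sub("^count\\.", "", ccols)))
    stop("malformed frequency-table header: freq/count group mismatch")
  freq <- as.matrix(df[, fcols, drop = FALSE])
  count <- as.matrix(df[, ccols, drop = FALSE])
  dimnames(freq) <- dimnames(count) <- list(df$locus_id, groups)
  defined <- !is.na(freq)
  if (any(freq[defined] < 0 | freq[defined] > 1))
    stop("frequency outside [0,1] in ", path)
  storage.mode(count) <- "integer"
  structure(list(freq = freq, count = count,
                 counted_allele = df$counted_allele, loci = df$locus_id),
            class = "freq_table")
}
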
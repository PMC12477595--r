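#' Build a one-sample feature table from truth labels
#'
#' Surrogate for read mapping on simulated data: each species' sequencing
#' depth is `reads labeled to it x read length / genome length`, so the
#' conservation identity `sum(SD_i x length_i) = total labeled bp` holds
#' exactly.
#'
#' @param reads a labeled `read_set` (see [simulate_reads()]).
#' @param pool the [make_genomes()] pool the reads were simulated from.
#' @param sample_id sample name for the resulting column.
#' @return A `feature_table` with one sample, counts included; GEQ is total
#'   bp over the pool genome length (all genomes equal length).
#' @export
depth_from_labels <- function(reads, pool, sample_id = "sample1") {
  stopifnot(inherits(reads, "read_set"), inherits(pool, "genome_pool"))
  if (is.null(reads$labels)) stop("read set carries no truth labels")
  unknown <- setdiff(unique(reads$labels$species_id), names(pool$genomes))
  if (length(unknown)) stop("labels reference unknown genome(s): ",
                            paste(head(unknown, 5), collapse = ", "))
  rl <- reads$read_length
  species <- names(pool$genomes)
  counts <- table(factor(reads$labels$species_id, levels = species))
  counts <- as.numeric(counts)
  L <- pool$genome_length
  sdx <- counts * rl / L
  total_reads <- length(reads$seq)
  total_bp <- total_reads * rl
  stats <- sample_stats(sample_id, total_reads, total_bp,
                        avg_genome_size = L)
  m <- matrix(sdx, ncol = 1, dimnames = list(species, sample_id))
  cm <- matrix(counts, ncol = 1, dimnames = list(species, sample_id))
  feature_table(m, setNames(rep(L, length(species)), species), stats,
                counts = cm)
}

#' Combine one-sample feature tables over the same features
#'
#' @param tables list of `feature_table`s sharing identical feature sets.
#' @return A multi-sample `feature_table`.
#' @export
bind_feature_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  feats <- rownames(tables[[1]]$sd)
  for (t in tables) stopifnot(identical(rownames(t$sd), feats))
  sd <- do.call(cbind, lapply(tables, function(t) t$sd))
  counts <- if (all(vapply(tables, function(t) !is.null(t$counts), TRUE)))
    do.call(cbind, lapply(tables, function(t) t$counts)) else NULL
  stats <- do.call(rbind, lapply(tables, function(t) as.data.frame(t$stats)))
  class(stats) <- c("sample_stats", "data.frame")
  feature_table(sd, tables[[1]]$lengths, stats, counts = counts)
}

#' Genome equivalents
#'
#' GEQ = total sequenced bp divided by the community's average genome size:
#' the denominator of the SD/GEQ relative-abundance metric.
#'
#' @param total_bp total sequenced base pairs (> 0).
#' @param avg_genome_size average genome size in bp (> 0).
#' @return Genome equivalents (real).
#' @examples genome_equivalents(10e6, 5e6)  # 2
#' @export
genome_equivalents <- function(total_bp, avg_genome_size) {
  if (any(total_bp <= 0) || any(avg_genome_size <= 0))
    stop("total_bp and avg_genome_size must be positive")
  total_bp / avg_genome_size
}

#' Relative abundance as SD/GEQ
#'
#' Divides every sequencing-depth cell by its sample's genome equivalents.
#' SD/GEQ is invariant to proportional changes in sequencing effort, which is
#' what makes it the natural metric for coverage standardization.
#'
#' @param table a `feature_table`.
#' @return A features x samples matrix of SD/GEQ values.
#' @export
rel_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  geq <- table$stats$geq
  if (anyNA(geq) || any(geq <= 0)) stop("missing or non-positive GEQ")
  sweep(table$sd, 2, geq, "/")
}

#' Reads per kilobase per million (RPKM)
#'
#' @param count mapped read count.
#' @param feature_length feature length in bp (> 0).
#' @param total_reads total reads in the sample (> 0).
#' @return `count / ((feature_length/1000) * (total_reads/1e6))`.
#' @examples rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, feature_length, total_reads) {
  if (any(feature_length <= 0) || any(total_reads <= 0))
    stop("feature_length and total_reads must be positive")
  count / ((feature_length / 1000) * (total_reads / 1e6))
}

#' Expected coverage breadth at a sequencing depth (Lander-Waterman)
#'
#' Under random read placement, the expected fraction of a reference covered
#' by at least one read at depth `d` is `1 - exp(-d)`. At the 0.1X detection
#' threshold this is ~10% breadth, which is the justification for treating
#' features below 0.1X as undetected.
#'
#' @param depth sequencing depth in X units (>= 0; vectorized).
#' @return Expected coverage breadth in `[0, 1]`.
#' @examples lander_waterman_breadth(0.1)  # ~0.0952
#' @export
lander_waterman_breadth <- function(depth) {
  if (any(depth < 0)) stop("depth must be >= 0")
  -expm1(-depth)
}

#' Apply the minimum-depth detection rule
#'
#' Cells with SD strictly below `min_sd` are set to 0 (undetected); the
#' boundary value is kept. Counts, when present, are zeroed for undetected
#' cells. Idempotent.
#'
#' @param table a `feature_table`.
#' @param min_sd detection threshold in X units (default 0.1).
#' @return The filtered `feature_table`.
#' @export
detection_filter <- function(table, min_sd = 0.1) {
  stopifnot(inherits(table, "feature_table"), min_sd >= 0)
  drop <- table$sd < min_sd
  table$sd[drop] <- 0
  if (!is.null(table$counts)) table$counts[drop] <- 0
  table
}

#' Aggregate features by taxon
#'
#' Each taxon's SD (and counts) is the sum over its member features; taxon
#' length is the sum of member lengths (bookkeeping only). Features missing
#' from the taxonomy, or with NA at the requested rank, are collected under
#' `"Unclassified"` so that column sums are conserved.
#'
#' @param table a `feature_table`.
#' @param tax data.frame with `feature_id` and rank columns (see
#'   [read_taxonomy()]).
#' @param rank column of `tax` to aggregate at.
#' @return A `feature_table` over taxa.
#' @export
aggregate_by_taxon <- function(table, tax, rank) {
  stopifnot(inherits(table, "feature_table"))
  if (!rank %in% names(tax)) stop("rank '", rank, "' not in taxonomy map")
  grp <- tax[[rank]][match(rownames(table$sd), tax$feature_id)]
  n_un <- sum(is.na(grp))
  if (n_un > 0)
    message(n_un, " feature(s) unclassified at rank '", rank, "'")
  grp[is.na(grp)] <- "Unclassified"
  agg <- function(m) {
    out <- rowsum(m, grp)
    out[order(rownames(out)), , drop = FALSE]
  }
  sd <- agg(table$sd)
  counts <- if (!is.null(table$counts)) agg(table$counts) else NULL
  lens <- rowsum(unname(table$lengths), grp)[, 1]
  lens <- lens[rownames(sd)]
  feature_table(sd, lens, table$stats, counts = counts)
}
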
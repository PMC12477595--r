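#' Per-sample sequencing statistics
#'
#' Holds, for each sample, the totals required to normalize sequencing depth
#' to relative abundance: total reads, total bp, community average genome size
#' and genome equivalents (GEQ = total bp / average genome size), plus an
#' optional diversity coverage (Npc).
#'
#' @param sample_id sample identifier(s).
#' @param total_reads,total_bp per-sample totals (positive).
#' @param avg_genome_size community average genome size in bp (positive).
#' @param geq genome equivalents; computed as `total_bp / avg_genome_size`
#'   when missing, validated (to 1e-9 relative) when given.
#' @param npc optional diversity coverage in `[0, 1]`.
#' @return A data.frame of class `sample_stats`.
#' @export
sample_stats <- function(sample_id, total_reads, total_bp, avg_genome_size,
                         geq = NULL, npc = NA_real_) {
  if (any(total_reads <= 0) || any(total_bp <= 0) || any(avg_genome_size <= 0))
    stop("totals and average genome size must be positive")
  implied <- total_bp / avg_genome_size
  if (is.null(geq)) {
    geq <- implied
  } else if (any(abs(geq - implied) > 1e-9 * pmax(1, implied))) {
    stop("geq inconsistent with total_bp / avg_genome_size")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    total_reads = total_reads, total_bp = total_bp,
                    avg_genome_size = avg_genome_size, geq = geq, npc = npc,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_stats", "data.frame")
  out
}

#' Feature-by-sample abundance table
#'
#' Cells hold sequencing depth (SD, in X units: mapped read bp divided by
#' feature length); raw read counts are carried alongside when available.
#'
#' @param sd numeric matrix of sequencing depths, features x samples, with
#'   dimnames.
#' @param lengths named feature lengths in bp (positive).
#' @param stats a [sample_stats()] covering every column.
#' @param counts optional matrix of raw read counts, same shape as `sd`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(sd, lengths, stats, counts = NULL) {
  sd <- as.matrix(sd)
  if (is.null(rownames(sd)) || is.null(colnames(sd)))
    stop("sd matrix needs feature and sample dimnames")
  if (any(sd < 0)) stop("SD values must be >= 0")
  lengths <- lengths[rownames(sd)]
  if (anyNA(lengths) || any(lengths <= 0))
    stop("every feature needs a positive length")
  stopifnot(inherits(stats, "sample_stats"))
  missing <- setdiff(colnames(sd), stats$sample_id)
  if (length(missing)) stop("stats missing for sample(s): ",
                            paste(missing, collapse = ", "))
  stats <- stats[match(colnames(sd), stats$sample_id), , drop = FALSE]
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(identical(dim(counts), dim(sd)))
  }
  structure(list(sd = sd, counts = counts, lengths = lengths, stats = stats),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n",
              nrow(x$sd), ncol(x$sd)))
  cat("samples:", paste(colnames(x$sd), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write feature tables and sample statistics as TSV
#'
#' The table format is tab-separated with header
#' `feature_id length <sample...>`; `#`-prefixed lines are comments. Sample
#' statistics use columns
#' `sample_id total_reads total_bp avg_genome_size geq npc`. Counts, when
#' present, are written to a second file with suffix `.counts.tsv`.
#'
#' @param table a `feature_table`.
#' @param path output/input path for the SD table.
#' @param stats_path path for the sample-statistics TSV.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` a `feature_table`.
#' @export
write_feature_table <- function(table, path, stats_path = NULL) {
  df <- data.frame(feature_id = rownames(table$sd),
                   length = unname(table$lengths), table$sd,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(table$counts)) {
    cdf <- data.frame(feature_id = rownames(table$sd),
                      length = unname(table$lengths), table$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(cdf, paste0(sub("\\.tsv$", "", path), ".counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(stats_path))
    write.table(as.data.frame(table$stats), stats_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, stats_path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  st <- read.table(stats_path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  stats <- sample_stats(st$sample_id, st$total_reads, st$total_bp,
                        st$avg_genome_size, geq = st$geq,
                        npc = if ("npc" %in% names(st)) st$npc else NA_real_)
  sd <- as.matrix(df[, setdiff(names(df), c("feature_id", "length")),
                     drop = FALSE])
  rownames(sd) <- df$feature_id
  feature_table(sd, setNames(df$length, df$feature_id), stats)
}

#' Read a taxonomy map
#'
#' Tab-separated with header `feature_id` followed by rank columns (e.g.
#' `phylum class order family`).
#'
#' @param path TSV path.
#' @return A data.frame with `feature_id` and one column per rank.
#' @export
read_taxonomy <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
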
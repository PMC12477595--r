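#' Redundancy-curve estimation parameters
#'
#' @param k canonical k-mer length (8-32; default 24, aimed at detecting
#'   overlap at roughly the species level of sequence identity).
#' @param min_shared_fraction fraction `L` of a query read's canonical k-mers
#'   that must occur elsewhere in the subset for the read to be called
#'   redundant (default 0.5).
#' @param query_cap maximum number of query reads evaluated per subset
#'   (default 10000).
#' @param subset_fractions strictly increasing subset sizes as fractions of
#'   the full read set, last <= 1. Default: 12 geometrically spaced points
#'   from 0.001 to 1.
#' @param replicates_per_subset random subset replicates per fraction
#'   (default 3).
#' @param seed optional integer seed.
#' @return A list of class `redundancy_params`.
#' @export
redundancy_params <- function(k = 24, min_shared_fraction = 0.5,
                              query_cap = 10000,
                              subset_fractions = exp(seq(log(0.001), log(1),
                                                         length.out = 12)),
                              replicates_per_subset = 3, seed = NULL) {
  if (k < 8 || k > 32) stop("k must be in [8, 32]")
  if (min_shared_fraction <= 0 || min_shared_fraction > 1)
    stop("min_shared_fraction must be in (0, 1]")
  sf <- subset_fractions
  if (any(diff(sf) <= 0) || sf[length(sf)] > 1 || any(sf <= 0))
    stop("subset_fractions must be strictly increasing, in (0, 1]")
  structure(list(k = as.integer(k), min_shared_fraction = min_shared_fraction,
                 query_cap = as.integer(query_cap), subset_fractions = sf,
                 replicates_per_subset = as.integer(replicates_per_subset),
                 seed = seed),
            class = "redundancy_params")
}

#' Estimate a read-redundancy curve
#'
#' The engine behind Nonpareil-style diversity-coverage estimation: for each
#' subset size, a uniform random subset of reads is drawn without replacement
#' and the fraction of redundant query reads is measured. A query read (drawn
#' from the subset, up to `query_cap` queries) is redundant iff at least
#' `min_shared_fraction` of its canonical k-mers (lexicographic minimum of
#' each k-mer and its reverse complement, so strand is irrelevant) occur in
#' the subset outside the read itself. Reads contributing no valid k-mer
#' (shorter than `k`, or non-ACGT-only windows) are skipped and counted.
#'
#' @param reads a `read_set`, character vector of read sequences, or a path
#'   to a FASTQ/FASTA file (gz accepted).
#' @param params a [redundancy_params()] object.
#' @param total_bp total sequenced bp; computed from the reads by default.
#' @return An object of class `redundancy_curve`: a data.frame with columns
#'   `effort` (subset size, reads), `redundancy` (mean fraction in `[0,1]`)
#'   and `sd` (across replicates), with attributes `total_reads`, `total_bp`,
#'   `params` and `skipped_short`.
#' @examples
#' rc <- redundancy_curve(rep(strrep("ACGT", 40), 50),
#'                        redundancy_params(subset_fractions = c(0.5, 1),
#'                                          replicates_per_subset = 2,
#'                                          seed = 1))
#' rc$redundancy  # identical reads are fully redundant
#' @export
redundancy_curve <- function(reads, params = redundancy_params(),
                             total_bp = NULL) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 reads")
  if (is.null(total_bp)) total_bp <- sum(nchar(seqs))

  sizes <- unique(pmax(2L, as.integer(round(params$subset_fractions * n))))
  reps <- params$replicates_per_subset
  skipped <- 0L

  res <- with_seed(params$seed, {
    lapply(sizes, function(sz) {
      r <- numeric(reps)
      for (j in seq_len(reps)) {
        subset <- if (sz >= n) seq_len(n) else sample.int(n, sz)
        queries <- if (length(subset) > params$query_cap)
          sample(subset, params$query_cap) else subset
        out <- .cpp_subset_redundancy(seqs, subset, queries,
                                      params$k, params$min_shared_fraction)
        skipped <<- max(skipped, out$skipped_short)
        r[j] <- if (out$queries > 0) out$redundant / out$queries else NA_real_
      }
      c(mean(r, na.rm = TRUE), if (reps > 1) sd(r, na.rm = TRUE) else NA_real_)
    })
  })
  m <- do.call(rbind, res)
  curve <- data.frame(effort = sizes, redundancy = m[, 1], sd = m[, 2])
  if (skipped > 0)
    message(skipped, " read(s) contributed no valid k-mer and were skipped")
  structure(curve, class = c("redundancy_curve", "data.frame"),
            total_reads = n, total_bp = total_bp, params = params,
            skipped_short = skipped)
}

#' @export
print.redundancy_curve <- function(x, ...) {
  cat(sprintf("redundancy_curve: %d points, %d reads (%.3g bp)\n",
              nrow(x), attr(x, "total_reads"), attr(x, "total_bp")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @rdname read_curve_file
#' @param curve a `redundancy_curve`.
#' @export
write_curve_file <- function(curve, path) {
  p <- attr(curve, "params")
  hdr <- c("# npcstand redundancy curve",
           if (!is.null(p))
             sprintf("# k=%d L=%g query_cap=%d", p$k, p$min_shared_fraction,
                     p$query_cap),
           sprintf("# total_reads=%d total_bp=%.0f",
                   attr(curve, "total_reads"), attr(curve, "total_bp")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(data.frame(curve$effort, curve$redundancy, curve$sd),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write redundancy-curve files
#'
#' The file dialect is a compatible subset of Nonpareil `.npo` files:
#' whitespace-separated rows with `#`-prefixed metadata lines; column 1 is
#' sequencing effort (reads), column 2 mean redundancy, optional column 3 the
#' replicate standard deviation; further columns are ignored. `total_reads`
#' and `total_bp` are recovered from a `# total_reads=... total_bp=...`
#' header when present, otherwise the largest effort is used.
#'
#' @param path file path.
#' @return `read_curve_file()` returns a `redundancy_curve`;
#'   `write_curve_file()` returns `path` invisibly.
#' @export
read_curve_file <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(trimws(lines), "#")]
  dat <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(dat) == 0) stop("no data rows in ", path)
  rows <- lapply(seq_along(dat), function(i) {
    f <- strsplit(trimws(dat[i]), "[ \t]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || anyNA(v[1:2]))
      stop("fewer than 2 numeric columns on line: ", dat[i])
    c(v[1], v[2], if (length(v) >= 3) v[3] else NA_real_)
  })
  m <- do.call(rbind, rows)
  total_reads <- max(m[, 1])
  total_bp <- NA_real_
  tr <- regmatches(meta, regexec("total_reads=([0-9.eE+]+)", meta))
  tb <- regmatches(meta, regexec("total_bp=([0-9.eE+]+)", meta))
  tr <- unlist(lapply(tr, function(x) if (length(x) == 2) x[2] else NULL))
  tb <- unlist(lapply(tb, function(x) if (length(x) == 2) x[2] else NULL))
  if (length(tr)) total_reads <- as.numeric(tr[1])
  if (length(tb)) total_bp <- as.numeric(tb[1])
  curve <- data.frame(effort = m[, 1], redundancy = m[, 2], sd = m[, 3])
  structure(curve, class = c("redundancy_curve", "data.frame"),
            total_reads = total_reads, total_bp = total_bp, params = NULL,
            skipped_short = 0L)
}
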
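#' Write a read set to FASTQ
#'
#' Writes reads with constant quality `'I'`. Truth labels, when present, are
#' encoded in the header as space-separated `key=value` fields
#' (`species`, `genome`, `start`, `end`, `strand`; 0-based half-open
#' coordinates) so that [read_fastq()] can recover them. Output is gzipped
#' when `path` ends in `.gz`.
#'
#' @param reads a `read_set` (see [simulate_reads()]).
#' @param path output path (`.fastq`, `.fq`, optionally `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  ids <- reads$id
  if (!is.null(reads$labels)) {
    lb <- reads$labels
    ids <- sprintf("%s species=%s genome=%s start=%d end=%d strand=%s",
                   lb$read_id, lb$species_id, lb$genome_id, lb$start, lb$end,
                   lb$strand)
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  q <- Biostrings::PhredQuality(vapply(nchar(reads$seq),
                                       function(n) strrep("I", n), ""))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ or FASTA file as a read set
#'
#' Headers written by [write_fastq()] have their truth labels decoded;
#' arbitrary external FASTQ/FASTA (gzipped accepted) yields an unlabeled
#' read set.
#'
#' @param path input path; format inferred from the extension (`.fa`,
#'   `.fasta` read as FASTA, otherwise FASTQ).
#' @return A `read_set`.
#' @export
read_fastq <- function(path) {
  fmt <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path)) "fasta" else "fastq"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(x) == 0) {
    return(structure(list(id = character(), seq = character(), labels = NULL,
                          read_length = NA_integer_), class = "read_set"))
  }
  headers <- names(x)
  seqs <- as.character(x)
  ids <- sub(" .*$", "", headers)
  labels <- NULL
  if (all(grepl("species=", headers))) {
    get <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", headers)
    labels <- data.frame(read_id = ids, species_id = get("species"),
                         genome_id = get("genome"),
                         start = as.integer(get("start")),
                         end = as.integer(get("end")),
                         strand = get("strand"), stringsAsFactors = FALSE)
  }
  rl <- nchar(seqs[1])
  structure(list(id = ids, seq = unname(seqs), labels = labels,
                 read_length = as.integer(rl)), class = "read_set")
}
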
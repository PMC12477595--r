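#' Log-normal community abundance design
#'
#' Describes a synthetic community whose species abundances follow a
#' log-normal distribution with location `mu` (natural-log scale) and scale
#' `sigma`, affinely rescaled in log space so that the ratio of the largest to
#' the smallest abundance equals `maxmin_ratio` exactly. Evenness is governed
#' jointly by `mu` and the ratio: the uneven design used throughout is
#' `mu = 2, maxmin_ratio = 10000`; the even design is `mu = 5,
#' maxmin_ratio = 500`.
#'
#' @param n_species number of species (>= 1).
#' @param mu log-normal location parameter (natural-log scale).
#' @param maxmin_ratio target ratio of largest to smallest abundance
#'   (> 1 when `n_species > 1`).
#' @param sigma log-normal scale parameter (> 0). The rescaling to the target
#'   ratio dominates realized evenness, so the default of 1 is rarely worth
#'   changing.
#' @param seed optional integer seed used by [sample_abundances()].
#' @return An object of class `abundance_design`.
#' @seealso [sample_abundances()]
#' @export
abundance_design <- function(n_species, mu, maxmin_ratio, sigma = 1,
                             seed = NULL) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 1)
    stop("n_species must be a positive integer")
  n_species <- as.integer(n_species)
  if (n_species > 1 && (!is.numeric(maxmin_ratio) || maxmin_ratio <= 1))
    stop("maxmin_ratio must be > 1 when n_species > 1")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(n_species = n_species, mu = mu,
                 maxmin_ratio = maxmin_ratio, sigma = sigma, seed = seed),
            class = "abundance_design")
}

#' Sample a species-abundance profile from a design
#'
#' Draws `n_species` values from Normal(`mu`, `sigma`) on the log scale,
#' rescales them affinely so the extremes hit exactly `log(maxmin_ratio)`
#' apart (preserving the log-normal rank shape), exponentiates and normalizes
#' to sum 1. The returned abundances are sorted in decreasing order (a taxon
#' rank curve). Deterministic given `design$seed`.
#'
#' @param design an [abundance_design()].
#' @return An object of class `abundance_profile`: a list with `species_ids`
#'   and `abundance` (fractions summing to 1, max/min equal to the design
#'   ratio).
#' @examples
#' d <- abundance_design(100, mu = 5, maxmin_ratio = 500, seed = 1)
#' p <- sample_abundances(d)
#' max(p$abundance) / min(p$abundance)  # exactly 500
#' @export
sample_abundances <- function(design) {
  stopifnot(inherits(design, "abundance_design"))
  n <- design$n_species
  if (n == 1) {
    p <- 1
  } else {
    x <- with_seed(design$seed, rnorm(n, design$mu, design$sigma))
    span <- max(x) - min(x)
    if (span <= 0) stop("degenerate log-normal draw; increase sigma")
    y <- x * (log(design$maxmin_ratio) / span)
    p <- exp(y - max(y))
    p <- p / sum(p)
    p <- sort(p, decreasing = TRUE)
  }
  structure(list(species_ids = sprintf("sp%05d", seq_len(n)), abundance = p),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("abundance_profile: %d species, max/min ratio %.6g\n",
              length(x$abundance),
              max(x$abundance) / min(x$abundance)))
  invisible(x)
}

#' Generate a pool of synthetic genomes with controlled microdiversity
#'
#' One i.i.d. uniform A/C/G/T base genome per species; within-species variants
#' are derived by point substitutions whose positions are drawn disjointly
#' across variants, so every pairwise identity is exact by construction:
#' base-versus-variant identity is `1 - m_i/L` and variant-versus-variant is
#' `1 - (m_i + m_j)/L`, with the per-variant substitution count `m_i` sampled
#' so that all pairs land inside `[ani_low, ani_high]`. This mimics
#' within-species microdiversity at, e.g., 95-99.5% ANI.
#'
#' @param n_species number of species.
#' @param genome_length genome length in bp (all genomes equal length).
#' @param variants_per_species genomes per species (>= 1); the first is the
#'   unmutated base genome.
#' @param ani_low,ani_high pairwise identity band, `0 < ani_low <= ani_high
#'   < 1`. For more than two variants the band must satisfy
#'   `1 - ani_high <= (1 - ani_low)/2`.
#' @param seed optional integer seed.
#' @return An object of class `genome_pool`.
#' @export
make_genomes <- function(n_species, genome_length, variants_per_species = 1,
                         ani_low = 0.95, ani_high = 0.995, seed = NULL) {
  if (variants_per_species < 1) stop("variants_per_species must be >= 1")
  if (variants_per_species > 1) {
    if (!(ani_low > 0 && ani_low <= ani_high && ani_high < 1))
      stop("require 0 < ani_low <= ani_high < 1")
  }
  n_species <- as.integer(n_species)
  genome_length <- as.integer(genome_length)
  V <- as.integer(variants_per_species)
  L <- genome_length
  bases <- c("A", "C", "G", "T")

  genomes <- with_seed(seed, {
    lapply(seq_len(n_species), function(s) {
      base <- sample(bases, L, replace = TRUE)
      out <- vector("list", V)
      out[[1]] <- paste(base, collapse = "")
      if (V > 1) {
        if (V == 2) {
          mlo <- ceiling((1 - ani_high) * L)
          mhi <- floor((1 - ani_low) * L)
        } else {
          mlo <- ceiling((1 - ani_high) * L)
          mhi <- floor((1 - ani_low) * L / 2)
        }
        if (mlo > mhi)
          stop("ANI band [", ani_low, ", ", ani_high, "] not satisfiable ",
               "with disjoint substitutions; need 1 - ani_high <= ",
               "(1 - ani_low)/2 for more than two variants")
        if (mlo < 1) mlo <- 1
        m <- sample(mlo:mhi, V - 1, replace = TRUE)
        if (sum(m) > L) stop("too many variants for the genome length")
        pos_pool <- sample.int(L, sum(m))
        off <- 0
        for (v in seq_len(V - 1)) {
          g <- base
          pos <- pos_pool[(off + 1):(off + m[v])]
          off <- off + m[v]
          g[pos] <- vapply(g[pos],
                           function(b) sample(setdiff(bases, b), 1), "")
          out[[v + 1]] <- paste(g, collapse = "")
        }
      }
      unlist(out)
    })
  })
  names(genomes) <- sprintf("sp%05d", seq_len(n_species))
  structure(list(genomes = genomes, genome_length = genome_length,
                 variants_per_species = V,
                 ani_low = ani_low, ani_high = ani_high),
            class = "genome_pool")
}

#' @export
print.genome_pool <- function(x, ...) {
  cat(sprintf("genome_pool: %d species x %d variant(s), %d bp each\n",
              length(x$genomes), x$variants_per_species, x$genome_length))
  invisible(x)
}

#' Simulate labeled short reads from a community
#'
#' Per-species read counts are the largest-remainder rounding of
#' `total_reads * abundance` (with equal-length genomes, cell fraction and
#' read fraction coincide). Each read takes a uniformly chosen variant,
#' uniform start position and strand, and i.i.d. per-base substitutions at
#' `substitution_rate`. Species whose rounded count is 0 are legitimately
#' absent from the reads and recorded with 0 in the truth table. Reads are
#' reported 5'-to-3' and shuffled; labels use 0-based, half-open coordinates.
#'
#' @param pool a [make_genomes()] pool.
#' @param profile a [sample_abundances()] profile over the same species.
#' @param total_reads total number of reads to simulate.
#' @param read_length read length in bp (default 150).
#' @param substitution_rate per-base substitution probability (default 0.001).
#' @param seed optional integer seed; identical seeds give identical output.
#' @return A list with `reads` (class `read_set`: `id`, `seq`, `labels`) and
#'   `truth` (data.frame `species_id`, `n_reads`, `rel_abund`, `genome_len`).
#' @export
simulate_reads <- function(pool, profile, total_reads, read_length = 150,
                           substitution_rate = 0.001, seed = NULL) {
  stopifnot(inherits(pool, "genome_pool"), inherits(profile, "abundance_profile"))
  if (total_reads < 1) stop("total_reads must be >= 1")
  read_length <- as.integer(read_length)
  L <- pool$genome_length
  if (L < read_length) stop("genomes shorter than read_length")
  if (!all(profile$species_ids %in% names(pool$genomes)))
    stop("profile species missing from genome pool")

  counts <- largest_remainder(total_reads, profile$abundance)
  species <- rep(profile$species_ids, counts)

  out <- with_seed(seed, {
    n <- length(species)
    vidx <- sample.int(pool$variants_per_species, n, replace = TRUE)
    start0 <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- character(n)
    gkey <- paste0(species, ".", vidx)
    for (grp in split(seq_len(n), gkey)) {
      i1 <- grp[1]
      g <- pool$genomes[[species[i1]]][vidx[i1]]
      seqs[grp] <- substring(g, start0[grp] + 1L, start0[grp] + read_length)
    }
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
    if (substitution_rate > 0) {
      nsub <- rbinom(n, read_length, substitution_rate)
      bases <- c("A", "C", "G", "T")
      for (i in which(nsub > 0)) {
        pos <- sample.int(read_length, nsub[i])
        s <- seqs[i]
        for (p in pos) {
          b <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(bases, b), 1)
        }
        seqs[i] <- s
      }
    }
    ord <- sample.int(n)
    list(seqs = seqs[ord], species = species[ord], vidx = vidx[ord],
         start0 = start0[ord], strand = strand[ord])
  })

  n <- length(out$seqs)
  ids <- sprintf("read%08d", seq_len(n))
  labels <- data.frame(read_id = ids, species_id = out$species,
                       genome_id = sprintf("%s.g%02d", out$species, out$vidx),
                       start = out$start0, end = out$start0 + read_length,
                       strand = out$strand, stringsAsFactors = FALSE)
  reads <- structure(list(id = ids, seq = out$seqs, labels = labels,
                          read_length = as.integer(read_length)),
                     class = "read_set")
  truth <- data.frame(species_id = profile$species_ids,
                      n_reads = counts,
                      rel_abund = profile$abundance,
                      genome_len = L, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads x %d bp%s\n", length(x$seq), x$read_length,
              if (is.null(x$labels)) "" else " (labeled)"))
  invisible(x)
}
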
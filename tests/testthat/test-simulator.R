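test_that("single-species profile carries all abundance", {
  p <- sample_abundances(abundance_design(1, mu = 3, maxmin_ratio = 10))
  expect_identical(p$abundance, 1)
})

test_that("max/min abundance ratio is enforced exactly across seeds", {
  for (s in 1:5) {
    p <- sample_abundances(abundance_design(100, 5, 500, seed = s))
    expect_equal(max(p$abundance) / min(p$abundance), 500, tolerance = 1e-9)
    expect_equal(sum(p$abundance), 1, tolerance = 1e-12)
    expect_true(all(p$abundance > 0))
  }
  p <- sample_abundances(abundance_design(200, 2, 10000, seed = 9))
  expect_equal(max(p$abundance) / min(p$abundance), 10000, tolerance = 1e-9)
})

test_that("invalid abundance designs are rejected", {
  expect_error(abundance_design(0, 2, 10), "positive")
  expect_error(abundance_design(10, 2, maxmin_ratio = 1), "maxmin_ratio")
  expect_error(abundance_design(10, 2, maxmin_ratio = 0.5), "maxmin_ratio")
})

test_that("rescaled log-normal sampling matches an independent direct sampler", {
  # oracle: an independent draw + the same affine rescale, compared
  # distributionally on log abundances
  oracle <- function(n, mu, ratio, seed) {
    set.seed(seed)
    x <- rnorm(n, mu, 1)
    y <- x * log(ratio) / (max(x) - min(x))
    p <- exp(y - max(y))
    sort(p / sum(p), decreasing = TRUE)
  }
  p <- sample_abundances(abundance_design(10000, 2, 10000, sigma = 1,
                                          seed = 123))
  q <- oracle(10000, 2, 10000, seed = 456)
  # standardize the log abundances: the affine ratio rescale carries a
  # random common factor (the draw range) that is not part of the shape
  z <- function(v) (v - mean(v)) / sd(v)
  ks <- suppressWarnings(stats::ks.test(z(log(p$abundance)), z(log(q))))
  # two-sample KS critical value at alpha = 0.01
  crit <- 1.628 * sqrt(2 / 10000)
  expect_lt(unname(ks$statistic), crit)
})

test_that("variant genomes keep pairwise identities inside the ANI band", {
  pool <- make_genomes(3, 4000, variants_per_species = 10,
                       ani_low = 0.95, ani_high = 0.995, seed = 5)
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  for (sp in pool$genomes) {
    expect_length(sp, 10)
    expect_true(all(nchar(sp) == 4000))
    for (i in 1:9) for (j in (i + 1):10) {
      id <- ident(sp[i], sp[j])
      expect_gte(id, 0.95)
      expect_lte(id, 0.995)
    }
  }
})

test_that("single-variant pools contain exactly one genome per species", {
  pool <- make_genomes(4, 1000, variants_per_species = 1, seed = 2)
  expect_true(all(lengths(pool$genomes) == 1))
  expect_error(make_genomes(2, 1000, variants_per_species = 0), "variants")
})

test_that("substitution count maps to identity as 1 - m/L", {
  # plant m substitutions by hand and verify position-wise identity
  set.seed(42)
  L <- 2000
  g <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- 37
  pos <- sample.int(L, m)
  g2 <- g
  g2[pos] <- vapply(g[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  expect_equal(mean(g == g2), 1 - m / L)
})

test_that("read counts follow exact largest-remainder allocation", {
  pool <- make_genomes(2, 1000, seed = 1)
  prof <- structure(list(species_ids = c("sp00001", "sp00002"),
                         abundance = c(0.9, 0.1)),
                    class = "abundance_profile")
  sim <- simulate_reads(pool, prof, 1000, read_length = 100, seed = 3)
  expect_identical(sim$truth$n_reads, c(900L, 100L))
  expect_identical(sum(sim$truth$n_reads), 1000L)
  expect_equal(sum(sim$truth$rel_abund), 1)
})

test_that("error-free reads are exact substrings at their labeled positions", {
  fx <- tiny_fixture()
  sim <- simulate_reads(fx$pool, fx$profile, 300, substitution_rate = 0,
                        seed = 11)
  lb <- sim$reads$labels
  for (i in seq_len(nrow(lb))) {
    v <- as.integer(sub(".*\\.g", "", lb$genome_id[i]))
    ref <- substring(fx$pool$genomes[[lb$species_id[i]]][v],
                     lb$start[i] + 1, lb$end[i])
    obs <- sim$reads$seq[i]
    if (lb$strand[i] == "-")
      ref <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ref)))
    expect_identical(obs, ref)
  }
})

test_that("substitution rate is realized at the binomial rate", {
  pool <- make_genomes(1, 3000, seed = 21)
  prof <- structure(list(species_ids = "sp00001", abundance = 1),
                    class = "abundance_profile")
  rate <- 0.01
  sim <- simulate_reads(pool, prof, 700, read_length = 150,
                        substitution_rate = rate, seed = 22)
  lb <- sim$reads$labels
  mism <- 0L
  for (i in seq_len(nrow(lb))) {
    ref <- substring(pool$genomes[[1]][1], lb$start[i] + 1, lb$end[i])
    obs <- sim$reads$seq[i]
    if (lb$strand[i] == "-")
      obs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(obs)))
    mism <- mism + sum(strsplit(ref, "")[[1]] != strsplit(obs, "")[[1]])
  }
  n_bases <- nrow(lb) * 150
  se <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(mism / n_bases - rate), 3 * se)
})

test_that("identical seeds give byte-identical FASTQ output", {
  fx <- tiny_fixture()
  sim1 <- simulate_reads(fx$pool, fx$profile, 200, seed = 33)
  sim2 <- simulate_reads(fx$pool, fx$profile, 200, seed = 33)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(sim1$reads, f1)
  write_fastq(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("FASTQ round trip preserves sequences and labels", {
  fx <- tiny_fixture()
  sim <- simulate_reads(fx$pool, fx$profile, 150, seed = 44)
  f <- tempfile(fileext = ".fastq.gz")
  write_fastq(sim$reads, f)
  back <- read_fastq(f)
  expect_identical(back$seq, sim$reads$seq)
  expect_identical(back$labels, sim$reads$labels)
})
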
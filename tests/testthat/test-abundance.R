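test_that("label depths satisfy exact conservation and the SD formula", {
  fx <- tiny_fixture()
  tab <- depth_from_labels(fx$reads, fx$pool, "s1")
  rl <- fx$reads$read_length
  n <- length(fx$reads$seq)
  # 100 reads x 150 bp on a 15,000 bp genome would give 1X; here: counts
  expect_equal(unname(tab$sd[, 1]),
               unname(tab$counts[, 1]) * rl / fx$pool$genome_length)
  expect_equal(sum(tab$sd[, 1] * tab$lengths), n * rl)
  expect_equal(sum(tab$counts[, 1]), n)
  expect_equal(tab$stats$geq,
               tab$stats$total_bp / tab$stats$avg_genome_size)
  # species absent from reads have SD exactly 0
  zero <- fx$truth$species_id[fx$truth$n_reads == 0]
  if (length(zero)) expect_true(all(tab$sd[zero, 1] == 0))
})

test_that("genome equivalents follow total bp over average genome size", {
  expect_equal(genome_equivalents(10e6, 5e6), 2)
  expect_equal(genome_equivalents(3.3e7, 3.3e7), 1)
  expect_error(genome_equivalents(0, 5), "positive")
  expect_error(genome_equivalents(5, -1), "positive")
  fx <- tiny_fixture()
  tab <- depth_from_labels(fx$reads, fx$pool)
  expect_equal(tab$stats$geq * fx$pool$genome_length, tab$stats$total_bp)
})

test_that("SD/GEQ is invariant to proportional sequencing-effort changes", {
  expect_equal(unname(rel_abundance(feature_table(
    matrix(2, 1, 1, dimnames = list("f", "s")), c(f = 1000),
    sample_stats("s", 100, 15000, 3750)))[1, 1]), 2 / 4)
  fx <- tiny_fixture()
  full <- depth_from_labels(fx$reads, fx$pool, "s")
  half <- depth_from_labels(subsample_reads(fx$reads, 2500, seed = 3),
                            fx$pool, "s")
  ra_full <- rel_abundance(full)[, 1]
  ra_half <- rel_abundance(half)[, 1]
  keep <- full$sd[, 1] >= 1  # well-covered features only
  expect_true(all(abs(ra_half[keep] / ra_full[keep] - 1) < 0.15))
})

test_that("rpkm follows its definition", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(25, 2500, 5e6), 2)
  expect_error(rpkm(1, 0, 10), "positive")
})

test_that("Lander-Waterman breadth matches 1 - exp(-depth)", {
  expect_equal(lander_waterman_breadth(0.1), 0.09516, tolerance = 1e-4)
  expect_equal(round(100 * lander_waterman_breadth(0.1)), 10)
  expect_equal(lander_waterman_breadth(0), 0)
  expect_equal(lander_waterman_breadth(3), 0.95021, tolerance = 1e-5)
  expect_error(lander_waterman_breadth(-1), ">= 0")
})

test_that("detection filter zeroes strictly-below-threshold cells and is idempotent", {
  sd <- matrix(c(0.0999, 0.1, 0.5, 0), 4, 1,
               dimnames = list(paste0("f", 1:4), "s"))
  tab <- feature_table(sd, setNames(rep(1000, 4), paste0("f", 1:4)),
                       sample_stats("s", 100, 15000, 5000))
  filt <- detection_filter(tab, 0.1)
  expect_equal(unname(filt$sd[, 1]), c(0, 0.1, 0.5, 0))
  expect_identical(detection_filter(filt, 0.1)$sd, filt$sd)
  # unchanged when everything passes
  tab2 <- detection_filter(tab, 0.01)
  expect_equal(unname(tab2$sd[, 1]), c(0.0999, 0.1, 0.5, 0))
})

test_that("taxon aggregation sums members and conserves totals", {
  sd <- matrix(c(0.3, 0.2, 0.7, 0.05), 4, 1,
               dimnames = list(paste0("f", 1:4), "s"))
  tab <- feature_table(sd, setNames(rep(1000, 4), paste0("f", 1:4)),
                       sample_stats("s", 100, 15000, 5000))
  tax <- data.frame(feature_id = c("f1", "f2", "f3"),
                    phylum = c("A", "A", "B"))
  expect_message(agg <- aggregate_by_taxon(tab, tax, "phylum"),
                 "unclassified")
  expect_equal(unname(agg$sd["A", 1]), 0.5)
  expect_equal(unname(agg$sd["B", 1]), 0.7)
  expect_equal(unname(agg$sd["Unclassified", 1]), 0.05)
  expect_equal(sum(agg$sd), sum(tab$sd))
  expect_equal(unname(agg$lengths["A"]), 2000)
  expect_error(aggregate_by_taxon(tab, tax, "order"), "not in taxonomy")
})

test_that("filtering before aggregation never increases a taxon's value", {
  fx <- tiny_fixture()
  tab <- depth_from_labels(fx$reads, fx$pool, "s")
  tax <- data.frame(feature_id = rownames(tab$sd),
                    phylum = rep(c("A", "B", "C"), length.out = nrow(tab$sd)))
  base <- aggregate_by_taxon(tab, tax, "phylum")$sd[, 1]
  for (thr in c(0.05, 0.1, 0.5, 1, 5)) {
    v <- aggregate_by_taxon(detection_filter(tab, thr), tax, "phylum")$sd[, 1]
    expect_true(all(v <= base + 1e-12))
    base_thr <- v
  }
})

test_that("feature table TSV round trip preserves values and stats", {
  fx <- tiny_fixture()
  tab <- depth_from_labels(fx$reads, fx$pool, "s1")
  tab$stats$npc <- 0.93
  f <- tempfile(fileext = ".tsv")
  fs <- tempfile(fileext = ".tsv")
  write_feature_table(tab, f, fs)
  back <- read_feature_table(f, fs)
  expect_equal(back$sd, tab$sd)
  expect_equal(back$lengths, tab$lengths)
  expect_equal(back$stats$geq, tab$stats$geq)
  expect_equal(back$stats$npc, 0.93)
})

test_that("detected SD/GEQ is stable across subsamples while taxa grow with coverage", {
  # the core mechanism: individual detected members keep their relative
  # abundance, but aggregated taxa gain members (hence abundance) as
  # coverage rises
  # 100 kb genomes: at >=1X a feature holds >= ~667 reads, so subsampling
  # noise stays well under a 10% coefficient of variation
  fx <- cached("uneven20", function() {
    prof <- sample_abundances(abundance_design(20, 2, 100, seed = 61))
    pool <- make_genomes(20, 100000, seed = 62)
    sim <- simulate_reads(pool, prof, 60000, seed = 63)
    list(pool = pool, reads = sim$reads)
  })
  full <- depth_from_labels(fx$reads, fx$pool, "s")
  fracs <- c(0.25, 0.5, 1)
  tabs <- lapply(fracs, function(f) {
    if (f == 1) full else
      depth_from_labels(subsample_reads(fx$reads,
                                        round(f * length(fx$reads$seq)),
                                        seed = round(100 * f)),
                        fx$pool, "s")
  })
  ra <- sapply(tabs, function(t) rel_abundance(t)[, 1])
  deep <- full$sd[, 1] >= 1
  cv <- apply(ra[deep, ], 1, function(x) sd(x) / mean(x))
  expect_true(all(cv < 0.10))
  # aggregated taxon abundance nondecreasing in coverage (after detection)
  tax <- data.frame(feature_id = rownames(full$sd),
                    phylum = rep(c("A", "B", "C"), length.out = 20))
  agg <- sapply(tabs, function(t)
    rel_abundance(aggregate_by_taxon(detection_filter(t), tax, "phylum"))[, 1])
  # statistical assertion: allow a small tolerance for sampling noise
  expect_true(all(diff(t(agg)) > -0.02 * max(agg)))
})
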
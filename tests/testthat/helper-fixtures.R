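# Shared fixtures, built once per test run, and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 10 species x 5 kb, 5000 reads: the workhorse for abundance/standardize tests
tiny_fixture <- function() {
  cached("tiny", function() make_fixtures("tiny", seed = 7)$tiny)
}

# a fitted coverage model for the tiny fixture
tiny_model <- function() {
  cached("tiny_model", function() {
    fx <- tiny_fixture()
    rc <- redundancy_curve(fx$reads,
                           redundancy_params(seed = 71, query_cap = 1500,
                                             replicates_per_subset = 2))
    fit_npc(rc)
  })
}

# Brute-force redundancy oracle: for each read, compare its canonical k-mer
# positions against the union of canonical k-mers of all other reads.
# Independent of the package's C++ path (pure R string handling).
oracle_redundancy <- function(seqs, k = 24, min_frac = 0.5) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  read_kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1), k:n)
    ok <- !grepl("[^ACGT]", km)
    km <- km[ok]
    vapply(km, function(x) min(x, revcomp(x)), "", USE.NAMES = FALSE)
  }
  all_km <- lapply(seqs, read_kmers)
  flags <- vapply(seq_along(seqs), function(i) {
    q <- all_km[[i]]
    if (length(q) == 0) return(NA)
    others <- unlist(all_km[-i], use.names = FALSE)
    mean(q %in% others) >= min_frac
  }, NA)
  mean(flags, na.rm = TRUE)
}

# construct an npc_model analytically (known shape/scale), bypassing fitting
synthetic_model <- function(shape, scale, total_reads) {
  structure(list(shape = shape, scale = scale, total_reads = total_reads,
                 npc_total = pgamma(log1p(total_reads), shape = shape,
                                    scale = scale),
                 rss = 0, degenerate = FALSE, curve = NULL),
            class = "npc_model")
}

# light-weight redundancy parameters used where full defaults are too slow
fast_params <- function(seed, n_points = 10) {
  redundancy_params(seed = seed, query_cap = 2000, replicates_per_subset = 2,
                    subset_fractions = exp(seq(log(0.002), log(1),
                                               length.out = n_points)))
}

make_curve <- function(effort, redundancy, sd = NA_real_, total_reads = NULL,
                       total_bp = NA_real_) {
  structure(data.frame(effort = effort, redundancy = redundancy, sd = sd),
            class = c("redundancy_curve", "data.frame"),
            total_reads = total_reads %||% max(effort), total_bp = total_bp,
            params = NULL, skipped_short = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
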
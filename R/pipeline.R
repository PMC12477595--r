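# End-to-end pipeline driver and deterministic fixture generation.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the simulate -> coverage -> abundance -> standardize pipeline
#'
#' Simulates the configured communities, estimates their redundancy curves
#' and coverage models, builds the truth-label feature table, optionally
#' standardizes it to a common Npc, and writes all artifacts plus a manifest
#' (parameters, seeds, md5 hashes of every output) to `out_dir`. Identical
#' configurations and seeds give identical manifest hashes.
#'
#' @param config a list with elements:
#'   * `seed` integer run seed (every stochastic step derives its own seed
#'     from it);
#'   * `out_dir` output directory (created);
#'   * `communities` list of community specs: `name`, `n_species`, `mu`,
#'     `maxmin_ratio`, `total_reads`, and optionally `sigma` (1),
#'     `genome_length` (5000), `variants_per_species` (1), `ani_low` (0.95),
#'     `ani_high` (0.995), `read_length` (150), `substitution_rate` (0.001);
#'   * `coverage` optional list of [redundancy_params()] overrides;
#'   * `target_npc` `"min"` (default), a numeric target, or `NA` to skip
#'     standardization;
#'   * `min_sd` detection threshold (0.1);
#'   * `write_reads` write FASTQ files (default `FALSE`; they dominate run
#'     time and disk for large simulations).
#' @return Invisibly, a list with the `manifest`, the feature `table`, the
#'   standardized table (`std_table` or `NULL`) and the `models`.
#' @export
run_pipeline <- function(config) {
  for (field in c("seed", "out_dir", "communities"))
    if (is.null(config[[field]])) stop("config lacks '", field, "'")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  min_sd <- config$min_sd %||% 0.1
  target_npc <- config$target_npc %||% "min"

  tables <- list()
  models <- list()
  files <- character()
  seeds <- list()
  for (i in seq_along(config$communities)) {
    cm <- modifyList(list(sigma = 1, genome_length = 5000,
                          variants_per_species = 1, ani_low = 0.95,
                          ani_high = 0.995, read_length = 150,
                          substitution_rate = 0.001),
                     config$communities[[i]])
    if (is.null(cm$name)) stop("community ", i, " lacks a name")
    sim_seed <- derive_seed(config$seed, 100 + i)
    cov_seed <- derive_seed(config$seed, 200 + i)
    seeds[[cm$name]] <- list(sim = sim_seed, coverage = cov_seed)

    sim <- stage(paste0("simulate:", cm$name), {
      prof <- sample_abundances(abundance_design(cm$n_species, cm$mu,
                                                 cm$maxmin_ratio, cm$sigma,
                                                 seed = sim_seed))
      pool <- make_genomes(cm$n_species, cm$genome_length,
                           cm$variants_per_species, cm$ani_low, cm$ani_high,
                           seed = derive_seed(sim_seed, 1))
      c(simulate_reads(pool, prof, cm$total_reads, cm$read_length,
                       cm$substitution_rate, seed = derive_seed(sim_seed, 2)),
        list(pool = pool))
    })
    if (isTRUE(config$write_reads)) {
      fq <- file.path(out_dir, paste0(cm$name, ".fastq.gz"))
      stage(paste0("write_reads:", cm$name), write_fastq(sim$reads, fq))
      files <- c(files, fq)
    }
    truth_path <- file.path(out_dir, paste0(cm$name, ".truth.tsv"))
    write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    model <- stage(paste0("coverage:", cm$name), {
      rp <- do.call(redundancy_params,
                    modifyList(list(seed = cov_seed), config$coverage %||% list()))
      curve <- redundancy_curve(sim$reads, rp)
      write_curve_file(curve, file.path(out_dir, paste0(cm$name, ".curve.tsv")))
      m <- fit_npc(curve)
      write_npc_model(m, file.path(out_dir, paste0(cm$name, ".npc.json")))
      m
    })
    tables[[cm$name]] <- stage(paste0("abundance:", cm$name),
                               depth_from_labels(sim$reads, sim$pool, cm$name))
    tables[[cm$name]]$stats$npc <- model$npc_total
    models[[cm$name]] <- model
    files <- c(files, truth_path,
               file.path(out_dir, paste0(cm$name, c(".curve.tsv", ".npc.json"))))
  }

  # community tables can have different feature sets; write them separately
  # and standardize each against the common plan
  std_tables <- NULL
  plan <- NULL
  if (!isTRUE(is.na(target_npc))) {
    plan <- stage("standardize:plan", plan_for_target(models, target_npc))
    std_tables <- lapply(tables, function(t)
      standardize_table(t, plan, min_sd))
  }
  for (nm in names(tables)) {
    tp <- file.path(out_dir, paste0(nm, ".table.tsv"))
    sp <- file.path(out_dir, paste0(nm, ".stats.tsv"))
    write_feature_table(detection_filter(tables[[nm]], min_sd), tp, sp)
    files <- c(files, tp, sp)
    if (!is.null(std_tables)) {
      stp <- file.path(out_dir, paste0(nm, ".std.table.tsv"))
      write_feature_table(std_tables[[nm]], stp)
      files <- c(files, stp)
    }
  }

  summary_df <- data.frame(
    sample_id = names(tables),
    npc_total = vapply(models, function(m) m$npc_total, 0),
    richness_full = vapply(tables, function(t)
      observed_richness(detection_filter(t, min_sd)$sd[, 1]), 0L),
    richness_std = if (is.null(std_tables)) NA_integer_ else
      vapply(std_tables, function(t) observed_richness(t$sd[, 1]), 0L),
    f = if (is.null(plan)) NA_real_ else plan$f[match(names(tables),
                                                      plan$sample_id)],
    stringsAsFactors = FALSE)
  sum_path <- file.path(out_dir, "summary.tsv")
  write.table(summary_df, sum_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, sum_path)

  manifest <- list(seed = config$seed, seeds = seeds,
                   parameters = config[setdiff(names(config), "out_dir")],
                   target_npc = if (is.null(plan)) NA else
                     attr(plan, "target_npc"),
                   outputs = as.list(tools::md5sum(sort(files))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)

  invisible(list(manifest = manifest, tables = tables,
                 std_tables = std_tables, models = models, plan = plan,
                 summary = summary_df))
}

#' Deterministic test fixtures
#'
#' Generates the in-memory datasets used by the test suite: `"tiny"` is a
#' 10-species, 5 kb-genome community with 5000 reads; `"demo"` is the
#' richness-ratio experiment design (two even communities, 1000 vs 100
#' species, log-normal mu = 5 with max/min ratio 500, 5 kb genomes) at
#' efforts sized for both to exceed Npc 0.9.
#'
#' @param scale `"tiny"` or `"demo"`.
#' @param seed integer seed.
#' @return A named list per community: `profile`, `pool`, `reads`, `truth`.
#' @export
make_fixtures <- function(scale = c("tiny", "demo"), seed = 1) {
  scale <- match.arg(scale)
  specs <- switch(scale,
    tiny = list(tiny = list(n_species = 10, mu = 2, maxmin_ratio = 50,
                            total_reads = 5000)),
    demo = list(
      even1000sp = list(n_species = 1000, mu = 5, maxmin_ratio = 500,
                        total_reads = 320000),
      even100sp = list(n_species = 100, mu = 5, maxmin_ratio = 500,
                       total_reads = 40000)))
  out <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    s <- derive_seed(seed, i)
    prof <- sample_abundances(abundance_design(sp$n_species, sp$mu,
                                               sp$maxmin_ratio, sigma = 1,
                                               seed = s))
    pool <- make_genomes(sp$n_species, 5000, seed = derive_seed(s, 1))
    sim <- simulate_reads(pool, prof, sp$total_reads,
                          seed = derive_seed(s, 2))
    list(profile = prof, pool = pool, reads = sim$reads, truth = sim$truth)
  })
  names(out) <- names(specs)
  out
}
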
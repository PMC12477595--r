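#' Plan standardization of samples to a common Npc
#'
#' Step 1 of coverage standardization: for each sample, the fraction of reads
#' needed to reach the target Npc is `f = effort_for_npc(model, target) /
#' total_reads`, clipped to at most 1. The target must not exceed any
#' sample's achieved coverage (`npc_total`): a sample cannot be up-sampled,
#' and extrapolating the model beyond the observed effort would be
#' speculation. A warning is emitted for targets below 0.3 (results at such
#' low coverage are unreliable) and a note below 0.6 (the commonly used
#' adequacy threshold).
#'
#' @param models named list of `npc_model`s, one per sample.
#' @param target_npc common target Npc in (0, 1), or `"min"` (default) for the
#'   smallest `npc_total` across samples.
#' @return A data.frame of class `standardization_plan` with columns
#'   `sample_id`, `f`, `predicted_reads` and attribute `target_npc`.
#' @export
plan_for_target <- function(models, target_npc = "min") {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  npcs <- vapply(models, function(m) m$npc_total, 0)
  if (identical(target_npc, "min")) target_npc <- min(npcs)
  if (target_npc <= 0 || target_npc >= 1)
    stop("target_npc must be in (0, 1)")
  low <- which(npcs < target_npc)
  if (length(low))
    stop("target Npc ", signif(target_npc, 3),
         " exceeds the achieved coverage of sample(s): ",
         paste(sprintf("%s (%.3f)", names(models)[low], npcs[low]),
               collapse = ", "), "; cannot up-sample")
  if (target_npc < 0.3)
    warning("standardizing below Npc 0.3; results are unreliable at such ",
            "low coverage", call. = FALSE)
  else if (target_npc < 0.6)
    message("note: target Npc ", signif(target_npc, 3),
            " is below the 0.6 adequacy threshold")
  reads <- vapply(models, function(m) effort_for_npc(m, target_npc), 0)
  f <- pmin(1, reads / vapply(models, function(m) m$total_reads, 0))
  out <- data.frame(sample_id = names(models), f = unname(f),
                    predicted_reads = unname(reads), stringsAsFactors = FALSE)
  attr(out, "target_npc") <- target_npc
  class(out) <- c("standardization_plan", "data.frame")
  out
}

#' Standardize a feature table to a common Npc
#'
#' Step 2 and 3 of coverage standardization: per sample, SD and GEQ are
#' multiplied by the planned read fraction `f` (counts are rounded
#' half-to-even), then the minimum-depth detection rule is applied. Because
#' `f` cancels in SD/GEQ, standardization never changes the relative
#' abundance of a feature that stays detected - it only changes which
#' features are detected, which is exactly the coverage effect being
#' equalized.
#'
#' @param table a `feature_table` covering the planned samples.
#' @param plan a [plan_for_target()] plan.
#' @param min_sd detection threshold in X units (default 0.1).
#' @return A standardized, detection-filtered `feature_table`; sample stats
#'   are rescaled and `npc` set to the plan's target.
#' @export
standardize_table <- function(table, plan, min_sd = 0.1) {
  stopifnot(inherits(table, "feature_table"),
            inherits(plan, "standardization_plan"))
  samples <- colnames(table$sd)
  missing <- setdiff(samples, plan$sample_id)
  if (length(missing)) stop("plan does not cover sample(s): ",
                            paste(missing, collapse = ", "))
  f <- plan$f[match(samples, plan$sample_id)]
  table$sd <- sweep(table$sd, 2, f, "*")
  if (!is.null(table$counts))
    table$counts <- round(sweep(table$counts, 2, f, "*"))
  st <- table$stats
  st$total_reads <- round(st$total_reads * f)
  st$total_bp <- st$total_bp * f
  st$geq <- st$geq * f
  st$npc <- attr(plan, "target_npc")
  table$stats <- st
  detection_filter(table, min_sd)
}

#' Subsample a read set without replacement
#'
#' Uniform sampling without replacement, deterministic given `seed`; the
#' original order of retained reads is preserved. This is the manual
#' (oracle) counterpart of the analytic standardization estimator.
#'
#' @param reads a `read_set`, or a FASTQ/FASTA path.
#' @param n_target number of reads to keep (0 <= n_target <= total).
#' @param seed optional integer seed.
#' @param out optional output FASTQ path; when given together with a path
#'   input, the subsample is written there.
#' @return A `read_set` (labels subset accordingly), or `out` invisibly when
#'   writing to file.
#' @export
subsample_reads <- function(reads, n_target, seed = NULL, out = NULL) {
  from_file <- is.character(reads) && length(reads) == 1
  if (from_file) reads <- read_fastq(reads)
  stopifnot(inherits(reads, "read_set"))
  n <- length(reads$seq)
  if (n_target > n) stop("n_target exceeds the number of reads (", n, ")")
  if (n_target < 0) stop("n_target must be >= 0")
  keep <- sort(with_seed(seed, sample.int(n, n_target)))
  reads$id <- reads$id[keep]
  reads$seq <- reads$seq[keep]
  if (!is.null(reads$labels)) {
    reads$labels <- reads$labels[keep, , drop = FALSE]
    rownames(reads$labels) <- NULL
  }
  if (!is.null(out)) {
    write_fastq(reads, out)
    return(invisible(out))
  }
  reads
}

#' Compare the analytic standardization estimator against subsampling
#'
#' Validation mode: runs both the analytic estimator (SD multiplied by the
#' model-predicted read fraction at the target Npc, then the detection
#' filter) and the manual pipeline (actually subsampling the reads, then
#' recomputing truth-label depths and filtering), and reports their
#' agreement over features detected by both routes.
#'
#' @param reads labeled `read_set` of the full sample.
#' @param pool the `genome_pool` the reads were simulated from.
#' @param model the sample's `npc_model`.
#' @param target_npc target Npc for the comparison.
#' @param min_sd detection threshold (default 0.1).
#' @param seed seed for the manual subsampling.
#' @return A list of class `estimator_report`: `comparison` (data.frame with
#'   per-feature `predicted_sd`, `observed_sd`), `r_squared` (squared Pearson
#'   correlation), `mean_rel_dev` (mean |observed - predicted| / predicted),
#'   `f`, and detection bookkeeping.
#' @export
estimator_vs_oracle <- function(reads, pool, model, target_npc, min_sd = 0.1,
                                seed = NULL) {
  full <- depth_from_labels(reads, pool)
  n <- length(reads$seq)
  f <- min(1, effort_for_npc(model, target_npc) / model$total_reads)

  predicted <- full
  predicted$sd <- predicted$sd * f
  predicted <- detection_filter(predicted, min_sd)

  sub <- subsample_reads(reads, round(f * n), seed = seed)
  observed <- detection_filter(depth_from_labels(sub, pool), min_sd)

  p <- predicted$sd[, 1]
  o <- observed$sd[, 1]
  both <- p > 0 & o > 0
  comparison <- data.frame(feature_id = rownames(full$sd),
                           predicted_sd = unname(p), observed_sd = unname(o),
                           detected_both = unname(both))
  pb <- p[both]; ob <- o[both]
  r2 <- if (sum(both) >= 2 && var(pb) > 0) stats::cor(pb, ob)^2 else NA_real_
  mrd <- if (any(both)) mean(abs(ob - pb) / pb) else NA_real_
  structure(list(comparison = comparison, r_squared = r2,
                 mean_rel_dev = mrd, f = f, target_npc = target_npc,
                 n_detected_predicted = sum(p > 0),
                 n_detected_observed = sum(o > 0),
                 n_detected_both = sum(both)),
            class = "estimator_report")
}

#' @export
print.estimator_report <- function(x, ...) {
  cat(sprintf(
    "estimator_vs_oracle at Npc %.3g (f = %.4g):\n  R^2 = %.6f, mean |relative deviation| = %.4g\n  detected: %d predicted / %d observed / %d both\n",
    x$target_npc, x$f, x$r_squared, x$mean_rel_dev,
    x$n_detected_predicted, x$n_detected_observed, x$n_detected_both))
  invisible(x)
}
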
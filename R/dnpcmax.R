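# Maximum acceptable difference in Npc per feature, and the decision rule
# built on it.

npc_grid <- function(ref_npc, step, grid_floor) {
  if (!(step > 0 && step < ref_npc && ref_npc < 1))
    stop("require 0 < step < ref_npc < 1")
  round(seq(ref_npc - step, grid_floor, by = -step), 10)
}

# Two-sample t-test with the degenerate-variance convention: when both sides
# are (essentially) constant, equal means -> p = 1 (skipped, not
# significant), different means -> p = 0 (an unambiguous difference).
safe_t_test <- function(a, b, var_equal = FALSE) {
  degenerate <- function() {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
         p.value = if (equal) 1 else 0)
  }
  if (var(a) == 0 && var(b) == 0) return(degenerate())
  tryCatch(t.test(a, b, var.equal = var_equal),
           error = function(e) degenerate())
}

welch_p <- function(a, b, var_equal = FALSE) {
  safe_t_test(a, b, var_equal)$p.value
}

# Per-sample fraction of reads at each Npc of c(ref, grid), clipped to <= 1.
f_matrix <- function(models, npcs) {
  vapply(models, function(m)
    pmin(1, effort_for_npc(m, npcs) / m$total_reads),
    numeric(length(npcs)))
}

#' Maximum acceptable difference in Npc per feature
#'
#' For every feature (taxon), replicate samples are standardized to a
#' reference coverage (`ref_npc`, default 0.7) with the analytic estimator,
#' giving the reference abundance vector (aggregated SD/GEQ across
#' replicates). The target coverage is then lowered stepwise (`step` per
#' step); at each step the abundances recomputed at that coverage are
#' compared against the reference with a two-sample Welch t-test. The loop
#' stops at the first significant difference (`p < alpha`): that coverage is
#' the feature's break point `npc_break`, and `delta_npc_max = ref_npc -
#' npc_break` is the largest coverage difference at which comparisons of the
#' feature remain unbiased. Features that never break are censored at the
#' grid floor. Features with exactly one member use the detection rule
#' instead: their break point is the lowest grid coverage at which the member
#' is still detected in every replicate (see [single_member_delta()]).
#'
#' @param table `feature_table` whose columns are replicate samples (>=
#'   `min_replicates`), at the member (e.g. MAG) level.
#' @param models named list of `npc_model`s covering every sample, each with
#'   `npc_total >= ref_npc`.
#' @param tax optional taxonomy map (see [read_taxonomy()]); when given,
#'   members are grouped at `rank`, otherwise every feature is treated as a
#'   single-member feature.
#' @param rank rank column of `tax` to aggregate at.
#' @param ref_npc reference coverage (default 0.7).
#' @param step grid step (default 0.01).
#' @param alpha significance level of the stopping rule (default 0.05). No
#'   multiplicity correction is applied inside the sequential loop.
#' @param min_replicates minimum replicate samples (default 3).
#' @param grid_floor lowest coverage scanned (default 0.1, below which the
#'   model is typically unreliable).
#' @param min_sd detection threshold (default 0.1).
#' @param var_equal use a pooled-variance t-test instead of Welch.
#' @return A data.frame of class `dnpc_result`: `feature_id`, `n_members`,
#'   `npc_break`, `delta_npc_max`, `delta_pct`
#'   (`delta_npc_max / ref_npc`), `mean_abundance` (SD/GEQ at the reference),
#'   `censored`, `not_comparable`.
#' @export
delta_npc_max <- function(table, models, tax = NULL, rank = NULL,
                          ref_npc = 0.7, step = 0.01, alpha = 0.05,
                          min_replicates = 3, grid_floor = 0.1,
                          min_sd = 0.1, var_equal = FALSE) {
  stopifnot(inherits(table, "feature_table"), alpha > 0, alpha < 1)
  samples <- colnames(table$sd)
  if (length(samples) < min_replicates)
    stop("need at least ", min_replicates, " replicate samples")
  if (!all(samples %in% names(models)))
    stop("models missing for sample(s): ",
         paste(setdiff(samples, names(models)), collapse = ", "))
  models <- models[samples]
  npcs_total <- vapply(models, function(m) m$npc_total, 0)
  if (any(npcs_total < ref_npc))
    stop("sample(s) below the reference Npc: ",
         paste(samples[npcs_total < ref_npc], collapse = ", "))

  grid <- npc_grid(ref_npc, step, grid_floor)
  fm <- f_matrix(models, c(ref_npc, grid))  # (1+len(grid)) x samples
  geq <- table$stats$geq

  if (is.null(tax)) {
    groups <- setNames(as.list(seq_len(nrow(table$sd))), rownames(table$sd))
  } else {
    if (is.null(rank) || !rank %in% names(tax))
      stop("rank must name a column of tax")
    g <- tax[[rank]][match(rownames(table$sd), tax$feature_id)]
    g[is.na(g)] <- "Unclassified"
    groups <- split(seq_len(nrow(table$sd)), g)
  }

  # aggregated SD/GEQ of member rows `idx` at grid row `k` (1 = reference)
  agg_at <- function(idx, k) {
    vapply(seq_along(samples), function(s) {
      sdv <- table$sd[idx, s]
      sum(sdv[sdv * fm[k, s] >= min_sd]) / geq[s]
    }, 0)
  }

  rows <- lapply(names(groups), function(tx) {
    idx <- groups[[tx]]
    if (length(idx) == 1) {
      res <- single_member_core(table$sd[idx, ], fm, grid, ref_npc, min_sd)
    } else {
      ref_vec <- agg_at(idx, 1)
      npc_break <- NA_real_
      for (k in seq_along(grid)) {
        cur <- agg_at(idx, k + 1)
        if (welch_p(ref_vec, cur, var_equal) < alpha) {
          npc_break <- grid[k]
          break
        }
      }
      censored <- is.na(npc_break)
      if (censored) npc_break <- grid[length(grid)]
      res <- list(npc_break = npc_break, censored = censored,
                  not_comparable = FALSE)
    }
    ref_ab <- mean(agg_at(idx, 1))
    data.frame(feature_id = tx, n_members = length(idx),
               npc_break = res$npc_break,
               delta_npc_max = if (res$not_comparable) NA_real_ else
                 ref_npc - res$npc_break,
               delta_pct = if (res$not_comparable) NA_real_ else
                 (ref_npc - res$npc_break) / ref_npc,
               mean_abundance = ref_ab,
               censored = res$censored,
               not_comparable = res$not_comparable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ref_npc") <- ref_npc
  attr(out, "grid_floor") <- grid_floor
  class(out) <- c("dnpc_result", "data.frame")
  out
}

# shared core of the single-member rule: detected iff f * SD >= min_sd in
# every replicate; break point = lowest grid Npc still detected.
single_member_core <- function(sdv, fm, grid, ref_npc, min_sd) {
  detected <- function(k) all(sdv * fm[k, ] >= min_sd)
  if (!detected(1))
    return(list(npc_break = NA_real_, censored = FALSE, not_comparable = TRUE))
  lowest <- ref_npc
  for (k in seq_along(grid)) {
    if (!detected(k + 1)) break
    lowest <- grid[k]
  }
  list(npc_break = lowest,
       censored = lowest == grid[length(grid)],
       not_comparable = FALSE)
}

#' Maximum acceptable Npc difference for a single-member feature
#'
#' For a feature with exactly one member, coverage differences cannot distort
#' the composition of the feature, only its detectability: the break point is
#' the minimum grid coverage at which the member's estimated depth stays at
#' or above `min_sd` in every replicate. A member undetected even at the
#' reference coverage is flagged not comparable.
#'
#' @param sd named vector of the member's full-sample sequencing depths, one
#'   per replicate sample.
#' @param models named list of `npc_model`s matching `sd`.
#' @inheritParams delta_npc_max
#' @return A one-row data.frame matching [delta_npc_max()] output (without
#'   `mean_abundance`, which requires GEQ).
#' @export
single_member_delta <- function(sd, models, ref_npc = 0.7, step = 0.01,
                                grid_floor = 0.1, min_sd = 0.1) {
  stopifnot(all(names(sd) %in% names(models)))
  models <- models[names(sd)]
  grid <- npc_grid(ref_npc, step, grid_floor)
  fm <- f_matrix(models, c(ref_npc, grid))
  res <- single_member_core(sd, fm, grid, ref_npc, min_sd)
  data.frame(feature_id = NA_character_, n_members = 1L,
             npc_break = res$npc_break,
             delta_npc_max = if (res$not_comparable) NA_real_ else
               ref_npc - res$npc_break,
             delta_pct = if (res$not_comparable) NA_real_ else
               (ref_npc - res$npc_break) / ref_npc,
             censored = res$censored, not_comparable = res$not_comparable,
             stringsAsFactors = FALSE)
}

#' Regress delta-Npc-max on feature abundance
#'
#' Ordinary least squares of `delta_pct` on `log10(mean_abundance)` over
#' uncensored, comparable features: abundant features tolerate larger
#' coverage differences, so the slope is expected positive.
#'
#' @param results a `dnpc_result` from [delta_npc_max()].
#' @return A list with `slope`, `intercept`, `r_squared`, `n_used`,
#'   `n_censored`.
#' @export
fit_delta_vs_abundance <- function(results) {
  stopifnot(inherits(results, "dnpc_result"))
  use <- !results$censored & !results$not_comparable &
    is.finite(results$mean_abundance) & results$mean_abundance > 0
  if (sum(use) < 3)
    stop("need >= 3 uncensored, comparable features (have ", sum(use), ")")
  fit <- lm(delta_pct ~ log10(mean_abundance), data = results[use, ])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n_used = sum(use),
       n_censored = sum(results$censored))
}

#' Decide how to compare metagenomes of given coverages
#'
#' The decision rule for comparative analyses: when every metagenome has high
#' coverage (Npc >= `high_npc`, default 0.9) the samples can be compared
#' directly. Otherwise the observed coverage difference
#' `delta_npc = max(npc) - min(npc)` is compared with each feature's
#' `delta_npc_max`: if the tolerated difference is smaller than the observed
#' one the comparison may be biased, so standardize to a common (lowest) Npc
#' first; otherwise compare with caution. Low-coverage warnings are attached
#' when the smallest Npc is below 0.6 / 0.3.
#'
#' @param npc numeric vector of per-sample Npc values (>= 2 samples).
#' @param delta_max named numeric vector of per-feature `delta_npc_max`
#'   values, or a `dnpc_result`.
#' @param high_npc direct-comparison threshold (default 0.9).
#' @return A data.frame with `feature_id`, `delta_npc_max`,
#'   `delta_npc_observed` and `decision` (one of `compare_directly`,
#'   `standardize_to_common_npc`, `compare_with_caution`).
#' @export
comparability_check <- function(npc, delta_max, high_npc = 0.9) {
  if (length(npc) < 2) stop("need at least 2 samples")
  if (inherits(delta_max, "dnpc_result"))
    delta_max <- setNames(delta_max$delta_npc_max, delta_max$feature_id)
  dnpc_obs <- max(npc) - min(npc)
  decision <- if (all(npc >= high_npc)) {
    rep("compare_directly", length(delta_max))
  } else {
    ifelse(is.na(delta_max), "standardize_to_common_npc",
           ifelse(delta_max < dnpc_obs, "standardize_to_common_npc",
                  "compare_with_caution"))
  }
  if (min(npc) < 0.3)
    warning("lowest Npc below 0.3; comparisons are unreliable", call. = FALSE)
  else if (min(npc) < 0.6)
    message("note: lowest Npc below the 0.6 adequacy threshold")
  data.frame(feature_id = names(delta_max) %||% seq_along(delta_max),
             delta_npc_max = unname(delta_max),
             delta_npc_observed = dnpc_obs,
             decision = decision, stringsAsFactors = FALSE)
}
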
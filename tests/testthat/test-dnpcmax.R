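# Constructed-model tests: models with known (shape, scale) make the read
# fraction f(npc) analytic, so detection-dropout points can be planted.

dnpc_fixture <- function(n_rep = 5, jitter = 1e-4, seed = 17) {
  model <- synthetic_model(shape = 2, scale = 1, total_reads = 148)
  models <- setNames(rep(list(model), n_rep), paste0("r", seq_len(n_rep)))
  f_at <- function(npc) min(1, effort_for_npc(model, npc) / model$total_reads)
  sd_drop40 <- 0.1 / f_at(0.40) * 1.001  # drops below 0.1X just under Npc 0.40
  sd_stable <- 0.12 / f_at(0.10) # survives the whole grid
  set.seed(seed)
  base <- c(t1_m1 = sd_stable, t1_m2 = sd_drop40,
            t2_m1 = sd_stable, t2_m2 = sd_stable * 2)
  sd <- sapply(seq_len(n_rep), function(r) base * (1 + rnorm(4, 0, jitter)))
  dimnames(sd) <- list(names(base), names(models))
  stats <- sample_stats(names(models), rep(1000, n_rep), rep(150000, n_rep),
                        rep(150000, n_rep))  # geq = 1
  tab <- feature_table(sd, setNames(rep(5000, 4), names(base)), stats)
  tax <- data.frame(feature_id = names(base),
                    family = c("T1", "T1", "T2", "T2"))
  list(tab = tab, models = models, tax = tax, model = model,
       sd_drop40 = sd_drop40, f_at = f_at)
}

test_that("the loop finds a planted detection dropout at Npc 0.40", {
  fx <- dnpc_fixture()
  res <- delta_npc_max(fx$tab, fx$models, fx$tax, rank = "family",
                       ref_npc = 0.7, step = 0.01, alpha = 0.05)
  t1 <- res[res$feature_id == "T1", ]
  expect_false(t1$censored)
  expect_lt(abs(t1$npc_break - 0.40), 0.011)  # within one grid step
  expect_equal(t1$delta_npc_max, 0.7 - t1$npc_break)
  expect_equal(t1$delta_pct, t1$delta_npc_max / 0.7)
  expect_lt(abs(t1$delta_pct - 0.43), 0.02)
  # the all-stable taxon never breaks: censored at the grid floor
  t2 <- res[res$feature_id == "T2", ]
  expect_true(t2$censored)
  expect_equal(t2$npc_break, 0.1)
  expect_equal(t2$delta_npc_max, 0.6)
})

test_that("delta results are invariant to replicate order", {
  fx <- dnpc_fixture()
  perm <- c(3, 1, 5, 2, 4)
  tab2 <- fx$tab
  tab2$sd <- tab2$sd[, perm]
  tab2$stats <- tab2$stats[perm, ]
  res1 <- delta_npc_max(fx$tab, fx$models, fx$tax, rank = "family")
  res2 <- delta_npc_max(tab2, fx$models, fx$tax, rank = "family")
  expect_equal(res1$npc_break, res2$npc_break)
})

test_that("delta bounds and censoring flags are consistent", {
  fx <- dnpc_fixture()
  res <- delta_npc_max(fx$tab, fx$models, fx$tax, rank = "family")
  ok <- !res$not_comparable
  expect_true(all(res$delta_npc_max[ok] >= 0 & res$delta_npc_max[ok] <= 0.7))
  expect_true(all(res$delta_pct[ok] >= 0 & res$delta_pct[ok] <= 1))
  expect_identical(res$censored, res$npc_break == 0.1 & !res$not_comparable)
})

test_that("preconditions on replicates and reference coverage are enforced", {
  fx <- dnpc_fixture(n_rep = 2)
  expect_error(delta_npc_max(fx$tab, fx$models, fx$tax, rank = "family"),
               "at least 3")
  fx5 <- dnpc_fixture()
  expect_error(delta_npc_max(fx5$tab, fx5$models, fx5$tax, rank = "family",
                             ref_npc = 0.99), "below the reference")
})

test_that("single-member rule: closed-form dropout from the fitted fraction", {
  fx <- dnpc_fixture()
  models <- fx$models[1:3]
  # member at SD = 3.0X: detected at the reference, drops where f(npc) < 0.1/3
  sd1 <- setNames(rep(3.0, 3), names(models))
  res <- single_member_delta(sd1, models, ref_npc = 0.7, step = 0.01)
  grid <- round(seq(0.69, 0.1, by = -0.01), 10)
  expected_break <- min(grid[vapply(grid, function(t)
    fx$f_at(t) * 3.0 >= 0.1, TRUE)])
  expect_equal(res$npc_break, expected_break)
  expect_false(res$not_comparable)

  # deeply covered member: censored at the grid floor
  sd_deep <- setNames(rep(0.1 / fx$f_at(0.1) * 2, 3), names(models))
  res2 <- single_member_delta(sd_deep, models)
  expect_true(res2$censored)
  expect_equal(res2$npc_break, 0.1)

  # undetected at the reference: flagged not comparable
  sd_low <- setNames(rep(0.1 / fx$f_at(0.7) * 0.5, 3), names(models))
  res3 <- single_member_delta(sd_low, models)
  expect_true(res3$not_comparable)
  expect_true(is.na(res3$delta_npc_max))
})

test_that("delta_pct rises with abundance: exact inputs and simulated features", {
  # perfectly collinear input
  res <- structure(data.frame(feature_id = paste0("f", 1:5), n_members = 1L,
                              npc_break = seq(0.6, 0.2, by = -0.1),
                              delta_npc_max = seq(0.1, 0.5, by = 0.1),
                              delta_pct = seq(0.1, 0.5, by = 0.1) / 0.7,
                              mean_abundance = 10^seq(-2, 2),
                              censored = FALSE, not_comparable = FALSE),
                   class = c("dnpc_result", "data.frame"))
  # exact collinearity triggers R's "essentially perfect fit" warning
  fit <- suppressWarnings(fit_delta_vs_abundance(res))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_gt(fit$slope, 0)
  # scrambled response destroys the correlation
  res_shuf <- res
  res_shuf$delta_pct <- res$delta_pct[c(3, 5, 1, 2, 4)]
  expect_lt(fit_delta_vs_abundance(res_shuf)$r_squared, 0.9)
  # all censored -> error
  res_c <- res
  res_c$censored <- TRUE
  expect_error(fit_delta_vs_abundance(res_c), "uncensored")

  # simulated uneven community of single-member features: positive slope
  model <- synthetic_model(2, 1, 148)
  models <- setNames(rep(list(model), 3), paste0("r", 1:3))
  set.seed(31)
  sd_levels <- 10^seq(log10(0.3), log10(60), length.out = 40)
  sd <- sapply(1:3, function(r) sd_levels * (1 + rnorm(40, 0, 0.01)))
  dimnames(sd) <- list(sprintf("f%02d", 1:40), names(models))
  stats <- sample_stats(names(models), rep(1000, 3), rep(150000, 3),
                        rep(150000, 3))
  tab <- feature_table(sd, setNames(rep(5000, 40), rownames(sd)), stats)
  res_sim <- delta_npc_max(tab, models, tax = NULL)
  fit_sim <- fit_delta_vs_abundance(res_sim)
  expect_gt(fit_sim$slope, 0)
})

test_that("comparability decisions follow the decision tree", {
  dm <- c(fA = 0.1, fB = 0.2)
  d1 <- comparability_check(c(0.95, 0.92), dm)
  expect_true(all(d1$decision == "compare_directly"))
  d2 <- suppressMessages(comparability_check(c(0.8, 0.5), c(fA = 0.1)))
  expect_equal(d2$decision, "standardize_to_common_npc")
  expect_equal(d2$delta_npc_observed, 0.3, tolerance = 1e-12)
  d3 <- comparability_check(c(0.8, 0.78), c(fA = 0.2))
  expect_equal(d3$decision, "compare_with_caution")
  expect_error(comparability_check(0.9, dm), "at least 2")
  expect_warning(comparability_check(c(0.8, 0.2), dm), "below 0.3")
})
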
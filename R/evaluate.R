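# Richness, diversity, dissimilarity and differential-abundance evaluation.

#' Observed richness of a sample
#'
#' Number of detected features (value > 0) in a detection-filtered column.
#'
#' @param x numeric vector of abundances (e.g. SD/GEQ after the detection
#'   filter).
#' @return Integer count of features with value > 0.
#' @export
observed_richness <- function(x) {
  sum(x > 0)
}

#' Shannon and Simpson diversity
#'
#' Wrappers around [vegan::diversity()]: values are normalized to
#' proportions `p`; Shannon is `-sum(p log p)` (natural log) and Simpson is
#' the Gini-Simpson index `1 - sum(p^2)`.
#'
#' @param x nonnegative abundance vector with positive sum.
#' @return The diversity index value.
#' @examples
#' shannon_index(rep(1, 4))  # log(4)
#' simpson_index(rep(1, 4))  # 0.75
#' @export
shannon_index <- function(x) {
  if (any(x < 0) || sum(x) <= 0) stop("need nonnegative values, positive sum")
  unname(vegan::diversity(x, index = "shannon"))
}

#' @rdname shannon_index
#' @export
simpson_index <- function(x) {
  if (any(x < 0) || sum(x) <= 0) stop("need nonnegative values, positive sum")
  unname(vegan::diversity(x, index = "simpson"))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|x - y|) / sum(x + y)` via [vegan::vegdist()].
#'
#' @param x,y equal-length nonnegative abundance vectors, not both all zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative")
  if (sum(x) + sum(y) <= 0) stop("both samples are all zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Per-taxon differential abundance tests between two groups
#'
#' Two-sample t-test (Welch by default) per taxon on the replicate columns of
#' the two groups, Benjamini-Hochberg adjustment across the taxa tested
#' within this one group-pair comparison. Taxa absent (all zero) in both
#' groups are skipped and recorded in the `skipped` attribute. Degenerate
#' zero-variance cases follow the convention of [delta_npc_max()].
#'
#' @param a,b matrices taxa x replicate samples (same rownames), e.g.
#'   SD/GEQ of aggregated tables; >= 2 replicates per group.
#' @param alpha significance level applied to the adjusted p-values.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return A data.frame of class `diffabund_result`: `taxon`, `mean_a`,
#'   `mean_b`, `t`, `p`, `p_adj`, `significant`, `direction` (`"A>B"`,
#'   `"B>A"`, or `"none"` when not significant).
#' @export
diff_abund_tests <- function(a, b, alpha = 0.05, var_equal = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(rownames(a), rownames(b)))
    stop("groups must share an identical taxon set")
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 replicates per group")
  present <- rowSums(a) > 0 | rowSums(b) > 0
  skipped <- rownames(a)[!present]
  taxa <- rownames(a)[present]
  res <- lapply(taxa, function(tx) {
    xa <- a[tx, ]; xb <- b[tx, ]
    tt <- safe_t_test(xa, xb, var_equal)
    data.frame(taxon = tx, mean_a = mean(xa), mean_b = mean(xb),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$mean_a > out$mean_b, "A>B", "B>A"))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("diffabund_result", "data.frame")
  out
}

#' Accuracy of differential abundance tests against a reference
#'
#' A test on subsampled (or standardized) data is accurate when its outcome
#' matches the test on the original data: same significance status and, when
#' both are significant, the same direction. When the reference is not
#' significant, direction is undefined and only the status must match.
#'
#' @param tests_sub,tests_ref `diffabund_result`s over the same taxon set.
#' @return Percentage of matching taxa (0-100).
#' @export
accuracy_vs_reference <- function(tests_sub, tests_ref) {
  if (!setequal(tests_sub$taxon, tests_ref$taxon)) {
    only_sub <- setdiff(tests_sub$taxon, tests_ref$taxon)
    only_ref <- setdiff(tests_ref$taxon, tests_sub$taxon)
    stop("taxon sets differ; only in subsampled: ",
         paste(only_sub, collapse = ", "), "; only in reference: ",
         paste(only_ref, collapse = ", "))
  }
  m <- match(tests_ref$taxon, tests_sub$taxon)
  sig_match <- tests_sub$significant[m] == tests_ref$significant
  dir_match <- !tests_ref$significant |
    tests_sub$direction[m] == tests_ref$direction
  100 * mean(sig_match & dir_match)
}

#' Richness ratio between two samples
#'
#' @param richness_a,richness_b observed richness values; `richness_b > 0`.
#' @return `richness_a / richness_b`.
#' @export
richness_ratio <- function(richness_a, richness_b) {
  if (any(richness_b <= 0)) stop("denominator richness must be > 0")
  richness_a / richness_b
}
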
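#' Fit the log-gamma diversity-coverage model to a redundancy curve
#'
#' Nonpareil-style coverage modelling: mean redundancy `r` at sequencing
#' effort `E` (reads) is modelled as the gamma CDF of `log(1 + E)`,
#' `C(E) = pgamma(log1p(E), shape = a, scale = theta)`, which is bounded in
#' `[0, 1]`, nondecreasing in `E`, and exactly 0 at `E = 0`. Fitting is
#' weighted nonlinear least squares (weights `1/sd` where replicate standard
#' deviations are available and positive) over a multi-start grid of initial
#' `(a, theta)` with BFGS refinement on log-parameters; the best start by
#' residual sum of squares wins, ties broken by the lower shape.
#'
#' The value of the fitted curve at the full sequencing effort,
#' `npc_total = C(total_reads)`, is the estimated diversity coverage (Npc) of
#' the dataset. A curve whose redundancies are all zero is flagged degenerate
#' (coverage indistinguishable from zero) with `npc_total = 0`.
#'
#' @param curve a [redundancy_curve()] (>= 4 points, at least two distinct
#'   redundancy values unless all are zero).
#' @param starts_shape,starts_scale multi-start grids for the initial shape
#'   and scale.
#' @return An object of class `npc_model` with elements `shape`, `scale`,
#'   `total_reads`, `npc_total`, `rss`, `degenerate`, and the fitting data.
#' @seealso [npc_at()], [effort_for_npc()], [predict.npc_model()]
#' @export
fit_npc <- function(curve, starts_shape = c(0.5, 1, 2, 4, 8),
                    starts_scale = c(0.1, 0.3, 1, 3)) {
  stopifnot(inherits(curve, "redundancy_curve"))
  E <- curve$effort
  r <- curve$redundancy
  ok <- is.finite(E) & is.finite(r)
  E <- E[ok]; r <- r[ok]
  total_reads <- attr(curve, "total_reads")

  if (all(r == 0)) {
    return(structure(list(shape = NA_real_, scale = NA_real_,
                          total_reads = total_reads, npc_total = 0,
                          rss = 0, degenerate = TRUE, curve = curve),
                     class = "npc_model"))
  }
  if (length(E) < 4) stop("need >= 4 curve points")
  if (length(unique(r)) < 2) stop("need at least two distinct redundancies")

  w <- curve$sd[ok]
  w <- ifelse(is.finite(w) & w > 0, 1 / w, NA_real_)
  w[!is.finite(w)] <- if (any(is.finite(w))) max(w, na.rm = TRUE) else 1
  x <- log1p(E)
  obj <- function(par) {
    if (any(par > 50) || any(par < -50)) return(1e10)  # guard optimizer overflow
    pred <- suppressWarnings(pgamma(x, shape = exp(par[1]),
                                    scale = exp(par[2])))
    if (!all(is.finite(pred))) return(1e10)
    sum(w * (r - pred)^2)
  }
  best <- NULL
  for (a0 in starts_shape) for (t0 in starts_scale) {
    fit <- tryCatch(
      optim(c(log(a0), log(t0)), obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-15 ||
        (abs(fit$value - best$value) <= 1e-15 &&
         fit$par[1] < best$par[1]))
      best <- fit
  }
  if (!is.null(best)) {
    # Levenberg-Marquardt polish from the best multi-start point
    polish <- tryCatch({
      df <- data.frame(x = x, r = r, w = w)
      fit <- minpack.lm::nlsLM(
        r ~ pgamma(x, shape = a, scale = theta), data = df,
        start = list(a = exp(best$par[1]), theta = exp(best$par[2])),
        weights = w, lower = c(1e-8, 1e-8),
        control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                             maxiter = 200))
      log(unname(coef(fit)))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(polish) && is.finite(obj(polish)) &&
        obj(polish) <= best$value)
      best <- list(par = polish, value = obj(polish))
  }
  if (is.null(best))
    stop("log-gamma fit failed to converge from all starts; ",
         "efforts: ", paste(signif(range(E), 3), collapse = "-"),
         ", redundancy range: ", paste(signif(range(r), 3), collapse = "-"))
  shape <- exp(best$par[1]); scale <- exp(best$par[2])
  # unweighted residual sum of squares for reporting
  rss <- sum((r - pgamma(x, shape = shape, scale = scale))^2)
  structure(list(shape = shape, scale = scale, total_reads = total_reads,
                 npc_total = pgamma(log1p(total_reads), shape = shape,
                                    scale = scale),
                 rss = rss, degenerate = FALSE, curve = curve),
            class = "npc_model")
}

#' Evaluate the coverage model at a sequencing effort
#'
#' @param model an `npc_model` from [fit_npc()].
#' @param effort sequencing effort in reads (>= 0; vectorized).
#' @return Estimated diversity coverage (Npc) in `[0, 1]`.
#' @export
npc_at <- function(model, effort) {
  stopifnot(inherits(model, "npc_model"))
  if (any(effort < 0)) stop("effort must be >= 0")
  if (model$degenerate) return(rep(0, length(effort)))
  pgamma(log1p(effort), shape = model$shape, scale = model$scale)
}

#' Invert the coverage model: effort needed for a target Npc
#'
#' Returns `exp(qgamma(target, shape, scale)) - 1`, the sequencing effort
#' (reads) at which the fitted curve reaches `target`; the round trip
#' `npc_at(model, effort_for_npc(model, t)) == t` holds to 1e-6.
#'
#' @param model an `npc_model`.
#' @param target target Npc, strictly inside (0, 1): no finite effort reaches
#'   1 under the model.
#' @return Sequencing effort in reads (not rounded).
#' @export
effort_for_npc <- function(model, target) {
  stopifnot(inherits(model, "npc_model"))
  if (any(target <= 0)) stop("target must be > 0")
  if (any(target >= 1)) stop("target must be < 1: finite effort cannot reach 1")
  if (model$degenerate) stop("degenerate model: coverage indistinguishable from zero")
  expm1(qgamma(target, shape = model$shape, scale = model$scale))
}

#' @export
print.npc_model <- function(x, ...) {
  if (x$degenerate) {
    cat("npc_model: degenerate (coverage indistinguishable from zero)\n")
  } else {
    cat(sprintf(
      "npc_model: shape %.4g, scale %.4g; Npc at %.4g reads = %.4f (rss %.3g)\n",
      x$shape, x$scale, x$total_reads, x$npc_total, x$rss))
  }
  invisible(x)
}

#' @method summary npc_model
#' @export
summary.npc_model <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    eff <- vapply(c(0.5, 0.6, 0.9, 0.95), function(t)
      effort_for_npc(object, t), 0)
    cat("effort (reads) for Npc 0.5/0.6/0.9/0.95: ",
        paste(signif(eff, 4), collapse = " / "), "\n", sep = "")
  }
  invisible(object)
}

#' @method coef npc_model
#' @export
coef.npc_model <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' Predict from a fitted coverage model
#'
#' @param object an `npc_model`.
#' @param effort sequencing effort(s) at which to evaluate Npc; defaults to
#'   the model's curve efforts.
#' @param npc if given instead, target Npc value(s) whose required effort is
#'   returned (inverse prediction).
#' @param ... unused.
#' @return Npc values, or efforts when `npc` is supplied.
#' @export
predict.npc_model <- function(object, effort = NULL, npc = NULL, ...) {
  if (!is.null(npc)) return(effort_for_npc(object, npc))
  if (is.null(effort)) effort <- object$curve$effort
  npc_at(object, effort)
}

#' @method residuals npc_model
#' @export
residuals.npc_model <- function(object, ...) {
  if (object$degenerate) return(numeric(0))
  object$curve$redundancy - npc_at(object, object$curve$effort)
}

#' @method plot npc_model
#' @export
plot.npc_model <- function(x, ...) {
  cv <- x$curve
  plot(cv$effort, cv$redundancy, log = "x", xlab = "sequencing effort (reads)",
       ylab = "redundancy / Npc", ylim = c(0, 1), ...)
  if (!x$degenerate) {
    ee <- exp(seq(log(max(1, min(cv$effort))), log(max(cv$effort)),
                  length.out = 200))
    lines(ee, npc_at(x, ee))
    abline(v = x$total_reads, lty = 2)
  }
  invisible(x)
}

#' Serialize and restore coverage models as JSON
#'
#' Keys: `shape`, `scale`, `total_reads`, `npc_total`, `rss`, `degenerate`.
#'
#' @param model an `npc_model`.
#' @param path JSON file path.
#' @return `write_npc_model()` returns `path` invisibly; `read_npc_model()`
#'   an `npc_model` (without the fitting data).
#' @export
write_npc_model <- function(model, path) {
  stopifnot(inherits(model, "npc_model"))
  jsonlite::write_json(model[c("shape", "scale", "total_reads", "npc_total",
                               "rss", "degenerate")],
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_npc_model
#' @export
read_npc_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(shape = x$shape %||% NA_real_,
                 scale = x$scale %||% NA_real_,
                 total_reads = x$total_reads,
                 npc_total = x$npc_total, rss = x$rss,
                 degenerate = isTRUE(x$degenerate), curve = NULL),
            class = "npc_model")
}
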
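# Inverse-variance meta-analysis of per-study log-ORs / log-HRs:
# fixed effects, DerSimonian-Laird random effects, and the model-choice
# rule (fixed when the Cochran Q heterogeneity p exceeds 0.05, random
# otherwise).

meta_result <- function(pooled, se, Q, df, i2, tau2, model, k) {
  q_p <- if (df >= 1) pchisq(Q, df, lower.tail = FALSE) else NA_real_
  structure(list(
    pooled = pooled, se = se,
    ci = pooled + c(-1, 1) * 1.96 * se,
    Q = Q, q_p = q_p, i2 = i2, tau2 = tau2, model = model, k = k
  ), class = "meta_result")
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools estimates with weights `1/se^2`; reports Cochran's Q, its
#' chi-square(k-1) p-value, and `I2 = max(0, (Q - (k-1))/Q) * 100`
#' (truncated at zero). The 95\% CI is `pooled +/- 1.96 se` on the log
#' scale.
#'
#' @param estimates per-study log-ORs (or log-HRs).
#' @param ses per-study standard errors (all positive).
#' @return object of class `meta_result`.
#' @export
fixed_effects <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 1) stop("empty input")
  if (length(ses) != k || any(ses <= 0) || anyNA(estimates) || anyNA(ses)) {
    stop("estimates and positive ses of equal length required")
  }
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - pooled)^2)
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  meta_result(pooled, 1 / sqrt(sum(w)), Q, k - 1, i2, 0, "fixed", k)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum
#' w))` with fixed-effects weights, then inverse-variance pooling with
#' `w* = 1/(se^2 + tau2)`. With `Q <= k-1` this collapses to the
#' fixed-effects result.
#'
#' @inheritParams fixed_effects
#' @return `meta_result` with `model = "random"`.
#' @export
random_effects <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 2) stop("random-effects pooling needs at least 2 studies")
  fe <- fixed_effects(estimates, ses)
  w <- 1 / ses^2
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (fe$Q - (k - 1)) / C)
  ws <- 1 / (ses^2 + tau2)
  pooled <- sum(ws * estimates) / sum(ws)
  meta_result(pooled, 1 / sqrt(sum(ws)), fe$Q, k - 1, fe$i2, tau2, "random", k)
}

#' Pool per-study associations with the heterogeneity-driven model choice
#'
#' Runs [fixed_effects()] first; when there is evidence of heterogeneity
#' (Cochran Q p-value at or below 0.05 -- "no evidence" is strictly
#' p > 0.05) the pool is re-run as [random_effects()]. Studies with
#' missing estimates (non-convergence) are dropped with a recorded count.
#'
#' @param assoc data.frame with columns `beta` and `se` (the
#'   [study_assoc_table()] schema); a mix of `outcome` or `coding` values
#'   is an error.
#' @param het_p heterogeneity threshold for switching to random effects.
#' @return `meta_result`; attribute `n_dropped` counts excluded studies.
#' @export
pool <- function(assoc, het_p = 0.05) {
  stopifnot(is.data.frame(assoc), all(c("beta", "se") %in% names(assoc)))
  for (col in c("outcome", "coding")) {
    if (col %in% names(assoc) && length(unique(assoc[[col]])) > 1) {
      stop("cannot pool mixed ", col, " values")
    }
  }
  ok <- !is.na(assoc$beta) & !is.na(assoc$se) & assoc$se > 0
  dropped <- sum(!ok)
  if (dropped > 0) message(dropped, " studies dropped from pool (no estimate)")
  if (!any(ok)) stop("no usable studies")
  est <- assoc$beta[ok]; ses <- assoc$se[ok]
  res <- fixed_effects(est, ses)
  if (!is.na(res$q_p) && res$q_p <= het_p && length(est) >= 2) {
    res <- random_effects(est, ses)
  }
  attr(res, "n_dropped") <- dropped
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "%s-effects pool of %d studies: %.4f (95%% CI %.4f, %.4f); Q = %.2f (p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
    x$model, x$k, x$pooled, x$ci[1], x$ci[2], x$Q,
    if (is.na(x$q_p)) NA else x$q_p, x$i2, x$tau2
  ))
  invisible(x)
}

#' Write pooled results as a TSV forest table
#'
#' @param pools named list of `meta_result`s (names like `snp.outcome`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meta_tsv <- function(pools, path) {
  rows <- lapply(names(pools), function(nm) {
    x <- pools[[nm]]
    data.frame(id = nm, or = exp(x$pooled), ci_low = exp(x$ci[1]),
               ci_high = exp(x$ci[2]),
               p = 2 * pnorm(-abs(x$pooled / x$se)),
               i2 = x$i2, tau2 = x$tau2, model = x$model, k = x$k)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
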